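#' Read raw small-RNA reads from FASTA/FASTQ
#'
#' Loads reads into a one-column tibble. The format is inferred from the file
#' extension (`.fq`/`.fastq` vs `.fa`/`.fasta`, `.gz` transparent).
#'
#' @param path File path.
#' @return A tibble with a single character column `read` (DNA alphabet; U is
#'   converted to T on input).
#' @export
read_reads <- function(path) {
  ext <- sub("\\.gz$", "", tolower(path))
  fmt <- if (grepl("\\.(fq|fastq)$", ext)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read = chartr("U", "T", as.character(x)))
}

#' Structural cleaning of raw small-RNA reads
#'
#' Applies the structural removal rules in a fixed order so that every read
#' has exactly one removal cause, then trims the 3' adapter from survivors:
#'
#' 1. `poly_n` — the read contains any N.
#' 2. `five_prime_adapter` — the first `adapter_match_len` nt match the 3'
#'    end of the 5' adapter with at most one mismatch.
#' 3. `homopolymer` — a single base accounts for at least
#'    `homopolymer_frac` of the raw read, or the read carries a single-base
#'    run of at least `homopolymer_run` nt (this raw-read check runs before
#'    the adapter search so that adapter-less homopolymer artifacts are
#'    attributed to this rule; it is re-applied to the trimmed insert).
#' 4. `no_3prime_adapter` — the first `adapter_match_len` nt of the 3'
#'    adapter are not found in the read.
#' 5. `no_insert` — the 3' adapter match starts at position 1.
#' 6. `homopolymer` again, on the trimmed insert.
#' 7. `length_range` — the trimmed insert is outside `[min_len, max_len]`.
#'
#' @param reads A tibble with column `read` (from [read_reads()]), or a
#'   character vector.
#' @param adapter_3p,adapter_5p Adapter sequences (required, non-empty).
#' @param min_len,max_len Retained insert length range (default 18-30 nt).
#' @param homopolymer_frac,homopolymer_run Homopolymer rule parameters.
#' @param adapter_match_len Seed length for adapter location (default 8 nt).
#' @return A list with `clean` (tibble: column `sequence`, trimmed inserts)
#'   and `qc` (tibble: `rule`, `removed`, plus attribute-free totals rows via
#'   [qc_totals()]); `raw = clean + sum(removed)` always holds.
#' @export
#' @examples
#' r <- tibble::tibble(read = c(
#'   paste0(strrep("ACGT", 5), "T", "TGGAATTCTCGGGTGCCAAGG"),
#'   strrep("A", 21)))
#' filter_and_trim(r, adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
#'                 adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC")$qc
filter_and_trim <- function(reads,
                            adapter_3p,
                            adapter_5p,
                            min_len = 18L,
                            max_len = 30L,
                            homopolymer_frac = 0.8,
                            homopolymer_run = 15L,
                            adapter_match_len = 8L) {
  if (is.data.frame(reads)) reads <- reads$read
  if (is.null(adapter_3p) || is.null(adapter_5p) ||
      !nzchar(adapter_3p) || !nzchar(adapter_5p)) {
    stop("adapter_3p and adapter_5p must be non-empty", call. = FALSE)
  }
  rules <- c("poly_n", "five_prime_adapter", "homopolymer",
             "no_3prime_adapter", "no_insert", "length_range")
  n_raw <- length(reads)
  removed <- setNames(integer(length(rules)), rules)
  if (n_raw == 0) {
    return(list(clean = tibble(sequence = character(0)),
                qc = qc_table(0L, removed)))
  }

  cause <- rep(NA_character_, n_raw)

  # 1. poly-N
  hit <- grepl("N", reads, fixed = TRUE)
  cause[hit] <- "poly_n"

  # 2. 5' adapter contaminants: read start vs adapter 3' end, <=1 mismatch
  live <- is.na(cause)
  ad5 <- str_sub(adapter_5p, -adapter_match_len)
  mism <- hamming_prefix(reads, ad5, adapter_match_len)
  hit <- live & !is.na(mism) & mism <= 1L
  cause[hit] <- "five_prime_adapter"

  # 3. homopolymer on the raw read
  live <- is.na(cause)
  hit <- live & is_homopolymer(reads, homopolymer_frac, homopolymer_run)
  cause[hit] <- "homopolymer"

  # 4./5. locate the 3' adapter by exact seed match
  live <- is.na(cause)
  seed <- substr(adapter_3p, 1L, adapter_match_len)
  pos <- rep(-1L, n_raw)
  pos[live] <- as.integer(regexpr(seed, reads[live], fixed = TRUE))
  cause[live & pos < 0L] <- "no_3prime_adapter"
  cause[is.na(cause) & pos == 1L] <- "no_insert"

  # trim survivors
  live <- is.na(cause)
  insert <- substr(reads, 1L, pos - 1L)

  # 6. homopolymer on the insert
  hit <- live & is_homopolymer(insert, homopolymer_frac, homopolymer_run)
  cause[hit] <- "homopolymer"

  # 7. length range
  live <- is.na(cause)
  len <- nchar(insert)
  cause[live & (len < min_len | len > max_len)] <- "length_range"

  live <- is.na(cause)
  tab <- table(factor(cause, levels = rules))
  removed[rules] <- as.integer(tab[rules])

  list(clean = tibble(sequence = insert[live]),
       qc = qc_table(n_raw, removed))
}

qc_table <- function(n_raw, removed) {
  qc <- tibble(rule = names(removed), removed = unname(removed))
  attr(qc, "raw_reads") <- n_raw
  attr(qc, "clean_reads") <- n_raw - sum(removed)
  attr(qc, "clean_fraction") <- if (n_raw > 0) {
    (n_raw - sum(removed)) / n_raw
  } else NA_real_
  qc
}

#' QC totals as a one-row tibble
#'
#' @param qc The `qc` element returned by [filter_and_trim()].
#' @return Tibble with `raw_reads`, `clean_reads`, `removed`,
#'   `clean_fraction`.
#' @export
qc_totals <- function(qc) {
  tibble(raw_reads = attr(qc, "raw_reads"),
         clean_reads = attr(qc, "clean_reads"),
         removed = sum(qc$removed),
         clean_fraction = attr(qc, "clean_fraction"))
}

hamming_prefix <- function(reads, ref, k) {
  short <- nchar(reads) < k
  m <- integer(length(reads))
  for (i in seq_len(k)) {
    m <- m + (substr(reads, i, i) != substr(ref, i, i))
  }
  m[short] <- NA_integer_
  m
}

is_homopolymer <- function(x, frac, run) {
  n <- nchar(x)
  maxfrac <- rep(0, length(x))
  for (b in c("A", "C", "G", "T")) {
    maxfrac <- pmax(maxfrac, str_count(x, stringr::fixed(b)) / pmax(n, 1L))
  }
  run_re <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", run, run, run, run)
  (n > 0 & maxfrac >= frac) | grepl(run_re, x)
}

#' Collapse clean reads into the unique-tag table
#'
#' One row per distinct sequence with per-library counts, ordered by
#' descending total count (ties broken lexicographically by sequence).
#'
#' @param clean A tibble with columns `library` and `sequence` (one row per
#'   clean read), e.g. built by stacking [filter_and_trim()] outputs.
#' @param libraries Optional library ordering for the count columns.
#' @return A tibble: `tag` (sequence), one integer count column per library,
#'   `total`.
#' @export
#' @examples
#' x <- tibble::tibble(library = c("EC", "EC", "EC", "NEC", "NEC"),
#'                     sequence = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA",
#'                                  "ACGTACGTACGTACGTAA", "TTTTACGTACGTACGTAC",
#'                                  "ACGTACGTACGTACGTAA"))
#' collapse_unique(x)
collapse_unique <- function(clean, libraries = NULL) {
  stopifnot(all(c("library", "sequence") %in% names(clean)))
  if (is.null(libraries)) libraries <- unique(clean$library)
  out <- clean |>
    count(.data$sequence, .data$library, name = "n") |>
    pivot_wider(names_from = "library", values_from = "n", values_fill = 0L)
  for (lib in setdiff(libraries, names(out))) out[[lib]] <- 0L
  out <- out[, c("sequence", libraries)]
  out$total <- rowSums(out[libraries])
  out |>
    arrange(desc(.data$total), .data$sequence) |>
    rename(tag = "sequence") |>
    mutate(total = as.integer(.data$total))
}
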