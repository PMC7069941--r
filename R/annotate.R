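#' Exact full-length mapping of tags to a reference
#'
#' Finds every exact, full-length occurrence of each tag on both strands of
#' the reference (minus-strand hits are found via the reverse complement and
#' reported with strand `-`). No mismatches are tolerated.
#'
#' @param tags Character vector of tag sequences (DNA alphabet), or a tibble
#'   with a `tag` column.
#' @param ref A `srna_reference` (see [simulate_reference()] /
#'   [read_reference()]).
#' @return A tibble of placements: `tag`, `seqname`, `start` (0-based),
#'   `end` (half-open), `strand`. Tags with no occurrence are absent.
#' @export
map_exact <- function(tags, ref) {
  if (is.data.frame(tags)) tags <- tags$tag
  tags <- unique(tags)
  if (length(ref$sequences) == 0 || sum(Biostrings::width(ref$sequences)) == 0) {
    stop("empty reference", call. = FALSE)
  }
  hit_one <- function(seq, strand) {
    pat <- if (strand == "-") revcomp_chr(seq) else seq
    res <- purrr::imap(as.list(ref$sequences), function(subject, nm) {
      m <- Biostrings::matchPattern(pat, subject)
      if (length(m) == 0) return(NULL)
      tibble(tag = seq, seqname = nm,
             start = Biostrings::start(m) - 1L,
             end = Biostrings::end(m),
             strand = strand)
    })
    list_rbind(purrr::compact(res))
  }
  out <- purrr::map(tags, function(s) {
    bind_rows(hit_one(s, "+"), hit_one(s, "-"))
  }) |> list_rbind()
  if (nrow(out) == 0) {
    return(tibble(tag = character(0), seqname = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0)))
  }
  out
}

cascade_ranks <- function(cascade = CASCADE) {
  setNames(seq_along(cascade), cascade)
}

#' Assign one category per unique tag by the priority cascade
#'
#' Each tag receives a single annotation: the highest-priority category among
#' the features overlapped by any of its placements, with precedence
#' rRNA > tRNA > snRNA > snoRNA > known miRNA > piRNA > repeat > exon >
#' intron. Tags matching a mature-miRNA catalog sequence (exactly, with up to
#' `mirna_3p_tolerance` nt of 3' shift) are `known_miRNA` unless a
#' structural-ncRNA (rRNA-tier) feature claims them. Exon and intron
#' assignments are split into `_sense`/`_antisense` by comparing tag and
#' feature strands. Mapped tags overlapping nothing, and unmapped tags, are
#' `unannotated`.
#'
#' @param tags Tag table from [collapse_unique()] (columns `tag` + counts) or
#'   a character vector.
#' @param ref A `srna_reference`.
#' @param min_overlap Minimum overlap as a fraction of the tag length for a
#'   feature to claim a placement (default 1: the tag must lie inside the
#'   feature).
#' @param mirna_3p_tolerance Allowed 3'-end length difference for catalog
#'   matches (default 2 nt; 5' ends must align exactly).
#' @param cascade Category precedence, highest first.
#' @return The input tibble with added columns `mapped` (logical) and
#'   `category`.
#' @export
annotate_tags <- function(tags, ref, min_overlap = 1.0,
                          mirna_3p_tolerance = 2L, cascade = CASCADE) {
  if (!is.data.frame(tags)) tags <- tibble(tag = tags)
  stopifnot("tag" %in% names(tags))
  bad <- setdiff(unique(ref$features$category), CASCADE)
  if (length(bad)) {
    stop("unknown categories in features: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ranks <- cascade_ranks(cascade)

  pl <- map_exact(tags$tag, ref)
  mapped_tags <- unique(pl$tag)

  # feature overlap, strand-aware labels
  hits <- tibble(tag = character(0), label = character(0))
  if (nrow(pl) > 0 && nrow(ref$features) > 0) {
    q <- GenomicRanges::GRanges(pl$seqname,
                                IRanges::IRanges(pl$start + 1L, pl$end),
                                strand = pl$strand)
    s <- GenomicRanges::GRanges(ref$features$seqname,
                                IRanges::IRanges(ref$features$start + 1L,
                                                 ref$features$end),
                                strand = ref$features$strand)
    ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    if (length(ov) > 0) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      ow <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(q)[qi], GenomicRanges::ranges(s)[si]))
      keep <- ow >= min_overlap * (pl$end[qi] - pl$start[qi])
      qi <- qi[keep]; si <- si[keep]
      cat_hit <- ref$features$category[si]
      sense <- pl$strand[qi] == ref$features$strand[si]
      label <- ifelse(cat_hit %in% c("exon", "intron"),
                      paste0(cat_hit, ifelse(sense, "_sense", "_antisense")),
                      cat_hit)
      hits <- tibble(tag = pl$tag[qi], base_cat = cat_hit, label = label,
                     sense = sense)
    }
  }

  # catalog (mature miRNA) matches: 5'-anchored, <= tol nt 3' shift
  catalog_hit <- mirna_catalog_match(tags$tag, ref$mature_mirnas,
                                     mirna_3p_tolerance)

  structural <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  best <- tags["tag"]
  best$mapped <- best$tag %in% mapped_tags
  best$category <- "unannotated"

  if (nrow(hits) > 0) {
    picked <- hits |>
      mutate(rank = ranks[.data$base_cat],
             # within a tier, sense before antisense for determinism
             subrank = if_else(.data$sense, 0L, 1L)) |>
      arrange(.data$rank, .data$subrank) |>
      distinct(.data$tag, .keep_all = TRUE)
    m <- match(best$tag, picked$tag)
    has <- !is.na(m)
    best$category[has] <- picked$label[m[has]]
    best$.rank <- ifelse(has, picked$rank[m], Inf)
  } else {
    best$.rank <- Inf
  }

  # known-miRNA catalog claims beat everything below the structural tier
  is_cat <- best$tag %in% catalog_hit
  promote <- is_cat & best$.rank > ranks[["known_miRNA"]]
  best$category[promote] <- "known_miRNA"
  best$mapped[is_cat] <- best$mapped[is_cat] | TRUE
  best$.rank <- NULL

  bind_cols(tags, best[, c("mapped", "category")])
}

mirna_catalog_match <- function(tags, mature, tol) {
  mature <- unname(mature)
  hit <- character(0)
  lens_m <- nchar(mature)
  for (d in 0:tol) {
    # tag shorter than mature by d: tag is a prefix of mature
    pref_m <- substr(mature, 1L, lens_m - d)
    hit <- c(hit, tags[tags %in% pref_m])
    if (d > 0) {
      # tag longer than mature by d: mature is a prefix of tag
      idx <- nchar(tags) >= 18L
      cand <- tags[idx]
      pref_t <- substr(cand, 1L, nchar(cand) - d)
      hit <- c(hit, cand[pref_t %in% mature])
    }
  }
  unique(hit)
}

#' Category summary in the unique/total two-column style
#'
#' Produces, per library, the unique-tag and total-read count of every
#' category (plus the genome-mapping and grand-total rows), with percentages
#' of the library total formatted as printed summaries: round half up to two
#' decimals, trailing zeros stripped (so 0.70 renders "0.7").
#'
#' @param annotated Tag table from [annotate_tags()] with per-library count
#'   columns.
#' @param libraries Library (count column) names; defaults to all numeric
#'   columns apart from `total`.
#' @return A tibble: `row` (category or `Total sRNAs` / `Mapping to genome` /
#'   `unannotated`), `library`, `unique_count`, `total_count`, `unique_pct`,
#'   `total_pct` (character).
#' @export
summarize_categories <- function(annotated, libraries = NULL) {
  stopifnot(all(c("tag", "category") %in% names(annotated)))
  if (is.null(libraries)) {
    num <- vapply(annotated, is.numeric, logical(1))
    libraries <- setdiff(names(annotated)[num], c("total", "start", "end"))
  }
  long <- annotated |>
    select("tag", "category", "mapped", dplyr::all_of(libraries)) |>
    pivot_longer(dplyr::all_of(libraries), names_to = "library",
                 values_to = "count") |>
    filter(.data$count > 0)

  tot <- long |>
    group_by(.data$library) |>
    summarise(unique_count = dplyr::n_distinct(.data$tag),
              total_count = sum(.data$count), .groups = "drop") |>
    mutate(row = "Total sRNAs")
  mapg <- long |>
    filter(.data$mapped) |>
    group_by(.data$library) |>
    summarise(unique_count = dplyr::n_distinct(.data$tag),
              total_count = sum(.data$count), .groups = "drop") |>
    mutate(row = "Mapping to genome")
  bycat <- long |>
    group_by(.data$library, row = .data$category) |>
    summarise(unique_count = dplyr::n_distinct(.data$tag),
              total_count = sum(.data$count), .groups = "drop")

  denom <- tot |> select("library", u_tot = "unique_count",
                         t_tot = "total_count")
  bind_rows(tot, mapg, bycat) |>
    left_join(denom, by = "library") |>
    mutate(unique_pct = fmt_pct(.data$unique_count / .data$u_tot * 100),
           total_pct = fmt_pct(.data$total_count / .data$t_tot * 100)) |>
    select("row", "library", "unique_count", "total_count",
           "unique_pct", "total_pct") |>
    arrange(factor(.data$row,
                   levels = c("Total sRNAs", "Mapping to genome",
                              sort(setdiff(unique(.data$row),
                                           c("Total sRNAs",
                                             "Mapping to genome"))))),
            .data$library)
}

#' Format a percentage: round half up to 2 decimals, strip trailing zeros
#'
#' @param x Numeric percentages (already on the 0-100 scale).
#' @return Character vector, e.g. `c("0.7", "86.19", "100")`.
#' @export
#' @examples
#' fmt_pct(c(7099 / 1008620 * 100, 100))
fmt_pct <- function(x) {
  r <- floor(x * 100 + 0.5) / 100
  out <- sprintf("%.2f", r)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' Tag length distribution per library
#'
#' @param tags Tag table with `tag` and per-library counts.
#' @param libraries Count column names (default: numeric columns except
#'   `total`).
#' @param lengths Length range reported (default 18:30); lengths with no tags
#'   get zero rows.
#' @return Tibble: `length`, `library`, `unique` (tag count), `total`
#'   (read-weighted count).
#' @export
length_distribution <- function(tags, libraries = NULL, lengths = 18:30) {
  if (is.null(libraries)) {
    num <- vapply(tags, is.numeric, logical(1))
    libraries <- setdiff(names(tags)[num], "total")
  }
  long <- tags |>
    mutate(length = nchar(.data$tag)) |>
    select("tag", "length", dplyr::all_of(libraries)) |>
    pivot_longer(dplyr::all_of(libraries), names_to = "library",
                 values_to = "count") |>
    filter(.data$count > 0)
  long |>
    group_by(.data$length, .data$library) |>
    summarise(unique = n(), total = sum(.data$count), .groups = "drop") |>
    complete(length = lengths, library = libraries,
             fill = list(unique = 0L, total = 0L)) |>
    arrange(.data$length, .data$library)
}

#' Positional base composition by length class
#'
#' For each analysed length class, tabulates the base frequency at every
#' position (position 1 is the 5' first base). Frequencies are reported in
#' the RNA alphabet (U, not T). Length classes with no sequences are flagged
#' `insufficient_data` rather than computed.
#'
#' @param sequences Character vector of tag/miRNA sequences (T or U
#'   alphabet), or a tibble with a `tag` column.
#' @param lengths Length classes to analyse (default 20:23).
#' @return A tibble: `length`, `n` (sequences in the class),
#'   `insufficient_data`, `position`, `base` (A/C/G/U), `freq`. For empty
#'   classes a single row with `insufficient_data = TRUE` and `NA` position.
#' @export
base_composition <- function(sequences, lengths = 20:23) {
  if (is.data.frame(sequences)) sequences <- sequences$tag
  sequences <- chartr("U", "T", toupper(sequences))
  out <- purrr::map(lengths, function(len) {
    grp <- sequences[nchar(sequences) == len]
    n <- length(grp)
    if (n == 0) {
      return(tibble(length = len, n = 0L, insufficient_data = TRUE,
                    position = NA_integer_, base = NA_character_,
                    freq = NA_real_))
    }
    mat <- do.call(rbind, strsplit(grp, ""))
    purrr::map(seq_len(len), function(p) {
      tab <- table(factor(mat[, p], levels = c("A", "C", "G", "T")))
      tibble(length = len, n = n, insufficient_data = FALSE,
             position = p, base = chartr("T", "U", names(tab)),
             freq = as.numeric(tab) / n)
    }) |> list_rbind()
  }) |> list_rbind()
  out
}

#' First-base frequencies by length class
#'
#' Convenience wrapper over [base_composition()] restricted to position 1.
#'
#' @inheritParams base_composition
#' @return Tibble: `length`, `n`, `base`, `freq`.
#' @export
first_base_profile <- function(sequences, lengths = 20:23) {
  base_composition(sequences, lengths) |>
    filter(is.na(.data$position) | .data$position == 1L) |>
    select("length", "n", "insufficient_data", "base", "freq")
}

#' Recompute percentage columns for a printed-style category table
#'
#' Takes per-category unique/total counts (e.g. a published summary table) and
#' recomputes the percentage columns from the counts against the
#' `Total sRNAs` row, using the same formatting as [summarize_categories()].
#' Also verifies the row-sum identity: category counts (including
#' `unannotated`, excluding the `Mapping to genome` subtotal) must sum to the
#' stated totals.
#'
#' @param counts Tibble with columns `row`, `library`, `unique_count`,
#'   `total_count`; `row` must include `Total sRNAs` and may include
#'   `Mapping to genome`.
#' @param check_sums Stop if the row-sum identity fails (default TRUE).
#' @return The input with `unique_pct` and `total_pct` character columns
#'   added.
#' @export
format_category_counts <- function(counts, check_sums = TRUE) {
  stopifnot(all(c("row", "library", "unique_count", "total_count") %in%
                  names(counts)))
  denom <- counts |>
    filter(.data$row == "Total sRNAs") |>
    select("library", u_tot = "unique_count", t_tot = "total_count")
  if (nrow(denom) == 0) stop("missing 'Total sRNAs' row", call. = FALSE)
  if (check_sums) {
    chk <- counts |>
      filter(!.data$row %in% c("Total sRNAs", "Mapping to genome")) |>
      group_by(.data$library) |>
      summarise(u = sum(.data$unique_count), t = sum(.data$total_count),
                .groups = "drop") |>
      left_join(denom, by = "library")
    bad <- chk$u != chk$u_tot | chk$t != chk$t_tot
    if (any(bad)) {
      stop("row-sum identity violated for library ",
           paste(chk$library[bad], collapse = ", "), call. = FALSE)
    }
  }
  counts |>
    left_join(denom, by = "library") |>
    mutate(unique_pct = fmt_pct(.data$unique_count / .data$u_tot * 100),
           total_pct = fmt_pct(.data$total_count / .data$t_tot * 100)) |>
    select(-"u_tot", -"t_tot")
}
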