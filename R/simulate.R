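#' Simulate a reference with planted annotation features and mature miRNAs
#'
#' Generates a random reference sequence, plants non-overlapping feature
#' intervals for every cascade category on both strands, and embeds
#' `n_mirnas` mature miRNA sequences (18-24 nt, first base drawn from the
#' configured 5'-base bias) verbatim at their loci. Deterministic for a fixed
#' seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `srna_reference` with elements
#'   `sequences` (a [Biostrings::DNAStringSet]), `features` (tibble with
#'   columns `feature_id`, `category`, `seqname`, `start`, `end`, `strand`;
#'   0-based half-open coordinates) and `mature_mirnas` (named character,
#'   DNA alphabet).
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(seed = 1, reference_length = 2e4,
#'                                      n_mirnas = 10))
#' head(ref$features)
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  L <- as.integer(config$reference_length)
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, L, replace = TRUE)

  # Mature miRNA sequences: lengths 18-24 (length mix restricted), biased
  # first base, remainder uniform.
  mir_lens <- draw_lengths(config$n_mirnas, config$length_mix, max_len = 24L)
  mir_first <- vapply(mir_lens, function(len) {
    bias <- config$first_base_bias[[as.character(len)]]
    if (is.null(bias)) bias <- config$first_base_bias[["default"]]
    b <- sample(names(bias), 1L, prob = bias)
    if (b == "U") "T" else b
  }, character(1))
  mature <- vapply(seq_along(mir_lens), function(i) {
    paste0(mir_first[i],
           paste(sample(bases, mir_lens[i] - 1L, replace = TRUE),
                 collapse = ""))
  }, character(1))
  names(mature) <- sprintf("mir_%04d", seq_along(mature))

  # Feature plan: miRNA loci plus interval features for the other categories,
  # counts proportional to the configured composition.
  other_cats <- setdiff(CASCADE, "known_miRNA")
  props <- config$category_proportions[other_cats]
  n_feat <- ifelse(props > 0,
                   pmax(2L, round(config$n_features * props / sum(props))),
                   0L)
  plan <- tibble(
    category = c(rep(names(mature), 0) %||% character(0),
                 rep(other_cats, n_feat)),
    width = sample(80:250, sum(n_feat), replace = TRUE),
    mirna = NA_character_
  )
  plan <- bind_rows(
    plan,
    tibble(category = "known_miRNA", width = mir_lens, mirna = names(mature))
  )
  plan <- plan[sample(nrow(plan)), ]
  plan$strand <- sample(c("+", "-"), nrow(plan), replace = TRUE)

  # Lay features left to right with random gaps (gaps remain unfeatured).
  pos <- 1L
  starts <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pos <- pos + sample(30:120, 1L)
    starts[i] <- pos
    pos <- pos + plan$width[i]
  }
  if (pos + 200L > L) {
    stop("reference_length too small to fit the planted features (need > ",
         pos + 200L, " nt)", call. = FALSE)
  }
  plan$start1 <- starts                 # 1-based inclusive
  plan$end1 <- starts + plan$width - 1L

  # Embed mature miRNAs at their loci (reverse complement on the minus
  # strand so the transcript equals the mature sequence).
  for (i in which(!is.na(plan$mirna))) {
    s <- mature[[plan$mirna[i]]]
    if (plan$strand[i] == "-") s <- revcomp_chr(s)
    genome[plan$start1[i]:plan$end1[i]] <- strsplit(s, "")[[1]]
  }

  seqs <- Biostrings::DNAStringSet(setNames(paste(genome, collapse = ""),
                                            "chr1"))
  features <- tibble(
    feature_id = sprintf("%s_%03d", plan$category,
                         stats::ave(seq_len(nrow(plan)), plan$category,
                                    FUN = seq_along)),
    category = plan$category,
    seqname = "chr1",
    start = plan$start1 - 1L,           # 0-based half-open
    end = plan$end1,
    strand = plan$strand,
    mirna = plan$mirna
  )

  structure(
    list(sequences = seqs, features = features, mature_mirnas = mature),
    class = "srna_reference"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

draw_lengths <- function(n, length_mix, min_len = 18L, max_len = 30L) {
  lens <- as.integer(names(length_mix))
  keep <- lens >= min_len & lens <= max_len
  p <- length_mix[keep] / sum(length_mix[keep])
  lens[keep][sample.int(sum(keep), n, replace = TRUE, prob = p)]
}

#' Simulate per-library tag counts with known ground truth
#'
#' Draws a unique-tag count matrix over the configured libraries: planted
#' miRNAs follow their assigned stage-presence pattern (hard zeros in absent
#' stages) and abundance tier, with a fraction of all-stage miRNAs carrying a
#' planted fold change; background tags from every other category fill the
#' configured composition. Counts are negative-binomial around the planted
#' means (`variance = mu + dispersion * mu^2`); per-library scaling makes the
#' expected library total equal `library_size`.
#'
#' @param config A [sim_config()] object.
#' @param ref A reference from [simulate_reference()].
#' @return A list of class `srna_sim` with `counts` (tibble: `id`, `sequence`,
#'   `true_category`, `is_mirna`, one count column per library),
#'   `library_sizes` (named numeric, realised totals used as the RPM
#'   denominators) and `ground_truth` (list with per-miRNA planted labels and
#'   per-pair true differential-expression status).
#' @export
simulate_counts <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "srna_reference"))
  set.seed(config$seed + 1L)
  libs <- config$libraries
  nlib <- length(libs)
  if (!setequal(libs, STAGES)) {
    stop("pattern-based simulation requires the four stage libraries ",
         paste(STAGES, collapse = "/"), call. = FALSE)
  }

  ## --- planted miRNAs ------------------------------------------------------
  mir_ids <- names(ref$mature_mirnas)
  n_mir <- length(mir_ids)
  if (n_mir != config$n_mirnas) {
    stop("reference carries ", n_mir, " miRNAs but config expects ",
         config$n_mirnas, call. = FALSE)
  }
  labels <- rep(names(config$pattern_assignments), config$pattern_assignments)
  n_other <- n_mir - length(labels)
  labels <- c(labels, rep("OTHER", n_other))
  labels <- sample(labels)

  other_vectors <- setdiff(all_presence_vectors(), NAMED_PATTERNS)
  presence <- vapply(labels, function(lb) {
    if (lb == "OTHER") sample(other_vectors, 1L) else NAMED_PATTERNS[[lb]]
  }, character(1))
  pres_mat <- do.call(rbind, lapply(strsplit(presence, ""), as.integer))
  colnames(pres_mat) <- STAGES
  pres_mat <- pres_mat[, libs, drop = FALSE]

  tiers <- sample(names(config$abundance_levels), n_mir, replace = TRUE,
                  prob = config$tier_weights)
  base_mean <- config$abundance_levels[tiers]
  mu <- pres_mat * base_mean

  # Planted fold changes among all-stage miRNAs: one stage up-shifted.
  de_stage <- rep(NA_character_, n_mir)
  is_all <- labels == "ALL_STAGES"
  planted <- is_all & runif(n_mir) < config$de_fraction
  de_stage[planted] <- sample(libs, sum(planted), replace = TRUE)
  for (i in which(planted)) {
    mu[i, de_stage[i]] <- mu[i, de_stage[i]] * config$de_multiplier
  }

  # Tier means are planted clean-read counts directly (they anchor the
  # study's abundance-highlight thresholds); background mass fills the rest
  # of the library.
  mir_mass <- colSums(mu)
  bg_mass <- config$library_size - mir_mass
  if (any(bg_mass <= 0)) {
    stop("library_size too small for the configured abundance tiers ",
         "(expected miRNA read mass ", round(max(mir_mass)),
         "); scale abundance_levels down with library_size", call. = FALSE)
  }

  mir_counts <- draw_counts(mu, config$dispersion)
  colnames(mir_counts) <- libs

  ## --- background tags -----------------------------------------------------
  bg <- simulate_background_tags(config, ref, bg_mass)
  bg_counts <- bg$counts

  counts <- bind_rows(
    tibble(id = mir_ids,
           sequence = unname(ref$mature_mirnas),
           true_category = "known_miRNA",
           is_mirna = TRUE,
           as_tibble(mir_counts)),
    bind_cols(bg$tags, as_tibble(bg_counts))
  )
  counts <- counts[rowSums(counts[libs]) > 0, ]
  counts <- dplyr::distinct(counts, .data$sequence, .keep_all = TRUE)

  library_sizes <- colSums(as.matrix(counts[libs]))

  ## --- ground truth --------------------------------------------------------
  exp_rpm <- sweep(mu, 2, config$library_size, `/`) * 1e6
  pairs <- utils::combn(libs, 2, simplify = FALSE)
  de_truth <- purrr::map(pairs, function(pr) {
    a <- exp_rpm[, pr[1]]; b <- exp_rpm[, pr[2]]
    ratio <- b / a
    status <- dplyr::case_when(
      a == 0 & b == 0 ~ "absent",
      a == 0 & b > 0 ~ "up",
      b == 0 & a > 0 ~ "down",
      ratio > 2 ~ "up",
      ratio < 0.5 ~ "down",
      TRUE ~ "none"
    )
    tibble(pair = paste(pr[1], "vs", pr[2]),
           library_a = pr[1], library_b = pr[2],
           id = mir_ids, true_call = status)
  }) |> list_rbind()

  gt <- list(
    mirnas = tibble(id = mir_ids, sequence = unname(ref$mature_mirnas),
                    pattern = unname(labels), presence = unname(presence),
                    tier = tiers, de_stage = de_stage,
                    length = nchar(ref$mature_mirnas),
                    first_base = chartr("T", "U",
                                        substr(ref$mature_mirnas, 1, 1))),
    de = de_truth,
    tag_categories = counts |> select("id", "true_category")
  )

  structure(list(counts = counts, library_sizes = library_sizes,
                 ground_truth = gt, libraries = libs),
            class = "srna_sim")
}

draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) {
    out <- round(mu)
  } else {
    out <- mu
    pos <- mu > 0
    out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
    out[!pos] <- 0
  }
  storage.mode(out) <- "integer"
  out
}

# Background (non-miRNA) tags: sequences sampled from planted feature loci of
# the matching category (antisense with the configured probability for
# exon/intron), gap regions for mapped-unannotated tags, random sequence for
# unmapped ones.  Read mass follows the configured composition; tag weights
# within a category are log-normal and shared across libraries (background is
# not differentially expressed).
simulate_background_tags <- function(config, ref, bg_mass) {
  libs <- config$libraries
  props <- config$category_proportions
  cats <- setdiff(names(props), "known_miRNA")
  p_bg <- props[cats]
  n_tags <- setNames(
    ifelse(p_bg > 0,
           pmax(1L, round(config$n_background_tags * p_bg / sum(p_bg))), 0L),
    cats)
  mass_share <- config$read_mass_proportions[cats]
  mass_share <- mass_share / sum(mass_share)

  gaps <- gap_regions(ref)
  seq_chr <- as.character(ref$sequences[["chr1"]])

  out_tags <- list()
  out_counts <- list()
  for (cat in cats) {
    n <- n_tags[[cat]]
    lens <- draw_lengths(n, config$length_mix)
    if (cat == "unannotated") {
      mapped <- runif(n) < config$unannotated_mapped_fraction
      seqs <- character(n)
      seqs[mapped] <- sample_from_intervals(seq_chr, gaps, lens[mapped])
      seqs[!mapped] <- vapply(lens[!mapped], function(len) {
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
      }, character(1))
      truec <- "unannotated"
    } else {
      feats <- ref$features[ref$features$category == cat, ]
      idx <- sample(nrow(feats), n, replace = TRUE)
      anti <- cat %in% c("exon", "intron") &
        runif(n) < config$antisense_fraction
      seqs <- vapply(seq_len(n), function(i) {
        f <- feats[idx[i], ]
        len <- min(lens[i], f$end - f$start)
        at <- f$start + sample.int(f$end - f$start - len + 1L, 1L)  # 0-based
        s <- substr(seq_chr, at + 1L, at + len)
        sense_tag <- if (f$strand == "-") revcomp_chr(s) else s
        if (anti[i]) revcomp_chr(sense_tag) else sense_tag
      }, character(1))
      truec <- if (cat %in% c("exon", "intron")) {
        ifelse(anti, paste0(cat, "_antisense"), paste0(cat, "_sense"))
      } else rep(cat, n)
    }
    keep <- !duplicated(seqs) & !grepl("N", seqs, fixed = TRUE)
    seqs <- seqs[keep]; truec <- rep_len(truec, n)[keep]
    n <- length(seqs)
    if (n == 0) next

    w <- stats::rlnorm(n, 0, 1.0)
    mu <- outer(w / sum(w), mass_share[[cat]] * bg_mass[libs])
    dimnames(mu) <- list(NULL, libs)
    out_counts[[cat]] <- draw_counts(mu, config$dispersion)
    out_tags[[cat]] <- tibble(
      id = sprintf("%s_tag_%04d", gsub("_$", "", cat), seq_len(n)),
      sequence = seqs, true_category = truec, is_mirna = FALSE
    )
  }
  list(tags = list_rbind(out_tags), counts = do.call(rbind, out_counts))
}

# Unfeatured intervals of the reference (0-based half-open), min width 40 nt.
gap_regions <- function(ref) {
  f <- ref$features[order(ref$features$start), ]
  L <- Biostrings::width(ref$sequences)[1]
  starts <- c(0L, f$end)
  ends <- c(f$start, L)
  g <- tibble(start = starts, end = ends)
  g[g$end - g$start >= 40L, ]
}

sample_from_intervals <- function(seq_chr, intervals, lens) {
  if (length(lens) == 0) return(character(0))
  idx <- sample(nrow(intervals), length(lens), replace = TRUE)
  vapply(seq_along(lens), function(i) {
    iv <- intervals[idx[i], ]
    len <- min(lens[i], iv$end - iv$start)
    at <- iv$start + sample.int(iv$end - iv$start - len + 1L, 1L)
    substr(seq_chr, at + 1L, at + len)
  }, character(1))
}

#' Simulate raw FASTQ read files with structural contaminants
#'
#' Emits one FASTQ per library containing count-many copies of every tag with
#' the 3' adapter appended, plus contaminant reads at the configured rates:
#' poly-N reads, full-length homopolymers, reads missing the 3' adapter, and
#' reads beginning with the 5' adapter. Contaminant fractions are fractions of
#' all emitted reads.
#'
#' @param config A [sim_config()] object.
#' @param ref Reference from [simulate_reference()] (unused for sequence
#'   content beyond validation; tags already carry their sequences).
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return A tibble with one row per library: `library`, `path`, `n_reads`,
#'   `n_legit`, and one column per contaminant rule with the planted count.
#' @export
simulate_reads <- function(config, ref, sim, dir) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "srna_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- config$libraries
  rates <- config$contamination_rates
  rules <- c("poly_n", "homopolymer", "no_3prime_adapter",
             "five_prime_adapter")
  stopifnot(all(rules %in% names(rates)))
  bases <- c("A", "C", "G", "T")

  out <- purrr::imap(libs, function(lib, k) {
    set.seed(config$seed + 10L + k)
    cnt <- sim$counts[[lib]]
    legit <- paste0(rep(sim$counts$sequence, cnt), config$adapter_3p)
    n_legit <- length(legit)
    legit_share <- 1 - sum(rates)
    if (legit_share < 1e-12) {
      # all-contaminant library: same emitted volume, no legitimate reads
      n_total <- max(n_legit, 1000L)
      legit <- character(0)
    } else {
      n_total <- round(n_legit / legit_share)
    }
    n_rule <- setNames(round(rates[rules] * n_total), rules)

    poly_n <- vapply(seq_len(n_rule[["poly_n"]]), function(i) {
      s <- if (length(legit)) legit[sample.int(length(legit), 1L)] else
        paste0(paste(sample(bases, 21L, TRUE), collapse = ""),
               config$adapter_3p)
      at <- sample.int(nchar(s) - 4L, 1L)
      paste0(substr(s, 1, at - 1), strrep("N", 4L),
             substr(s, at + 4L, nchar(s)))
    }, character(1))
    homopol <- vapply(seq_len(n_rule[["homopolymer"]]), function(i) {
      strrep(sample(bases, 1L), sample(35:50, 1L))
    }, character(1))
    no_ad <- vapply(draw_lengths(n_rule[["no_3prime_adapter"]],
                                 config$length_mix),
                    function(len) paste(sample(bases, len, TRUE),
                                        collapse = ""),
                    character(1))
    ad5 <- str_sub(config$adapter_5p, -10L)
    five_p <- vapply(draw_lengths(n_rule[["five_prime_adapter"]],
                                  config$length_mix),
                     function(len) paste0(ad5,
                                          paste(sample(bases, len, TRUE),
                                                collapse = ""),
                                          config$adapter_3p),
                     character(1))

    reads <- sample(c(legit, poly_n, homopol, no_ad, five_p))
    path <- file.path(dir, paste0(lib, ".fastq"))
    write_fastq(reads, path)
    tibble(library = lib, path = path, n_reads = length(reads),
           n_legit = n_legit, !!!as.list(n_rule))
  }) |> list_rbind()
  out
}

write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read_%07d", seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

all_presence_vectors <- function() {
  grid <- expand.grid(rep(list(0:1), 4))[-1, 4:1]
  apply(grid, 1, paste, collapse = "")
}

#' Write a simulated reference set to disk
#'
#' Emits the reference FASTA, the feature table as BED6 (0-based half-open,
#' category in the name column, strand set) and the mature-miRNA catalog
#' FASTA.
#'
#' @param ref A `srna_reference`.
#' @param dir Output directory.
#' @return Invisibly, a named character vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(ref$sequences, fa)
  bed <- file.path(dir, "features.bed")
  gr <- GenomicRanges::GRanges(
    seqnames = ref$features$seqname,
    ranges = IRanges::IRanges(start = ref$features$start + 1L,
                              end = ref$features$end),
    strand = ref$features$strand,
    name = ref$features$category,
    score = 0L
  )
  rtracklayer::export(gr, bed, format = "BED")
  mat <- file.path(dir, "mature.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$mature_mirnas), mat)
  invisible(c(fasta = fa, bed = bed, mature = mat))
}

#' Read a reference set from disk
#'
#' Counterpart of [write_reference()]: loads a reference FASTA, a BED6 (or
#' GFF3) feature table whose name field carries the category, and a mature
#' miRNA catalog FASTA.
#'
#' @param fasta,features,mature File paths.
#' @return A `srna_reference` list.
#' @export
read_reference <- function(fasta, features, mature) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  gr <- rtracklayer::import(features)
  cat_col <- if (!is.null(gr$name)) gr$name else as.character(gr$type)
  feat <- tibble(
    feature_id = sprintf("%s_%03d", cat_col, seq_along(gr)),
    category = cat_col,
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  bad <- setdiff(unique(feat$category), CASCADE)
  if (length(bad)) {
    stop("unknown feature categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mat <- Biostrings::readDNAStringSet(mature)
  structure(list(sequences = seqs, features = feat,
                 mature_mirnas = setNames(as.character(mat), names(mat))),
            class = "srna_reference")
}
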