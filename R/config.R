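#' Simulation configuration for the synthetic small-RNA study
#'
#' Builds the configuration object consumed by [simulate_reference()],
#' [simulate_counts()] and [simulate_reads()]. Defaults emulate the structure
#' of a four-stage somatic-embryogenesis small-RNA experiment: libraries
#' EC/ICpEC/GE/NEC, tag lengths 18-30 nt with modes at 21 and 24 nt, a
#' category composition dominated by unannotated tags with rRNA/repeat/
#' exon/intron minorities, six planted stage-presence patterns (52 all-stage,
#' 40 early-SE-only, 43 NEC-only, 19 EC-only, 42 ICpEC-only, 41 GE-only,
#' rescaled when `n_mirnas` differs from 237), a 5'-U first-base bias, and a
#' small load of structural contaminants.
#'
#' @param seed Integer seed; all downstream randomness derives from it.
#' @param libraries Character vector of stage labels (default the four-stage
#'   series EC, ICpEC, GE, NEC).
#' @param library_size Target total clean reads per library.
#' @param category_proportions Named numeric summing to 1 over the cascade
#'   categories plus `unannotated`; fractions of unique tags per category
#'   (drives how many distinct tags and feature loci each category gets).
#' @param read_mass_proportions Named numeric summing to 1 over the same
#'   categories; fractions of total clean reads per category. miRNA read
#'   mass is set by the abundance tiers, so the non-miRNA entries are
#'   renormalised over the remaining mass.
#' @param n_mirnas Number of planted mature miRNAs.
#' @param pattern_assignments Named integer vector (names from the pattern
#'   vocabulary) giving how many miRNAs carry each stage-presence pattern.
#'   Defaults to the six-class census above rescaled to `n_mirnas`. Total must
#'   not exceed `n_mirnas`; any remainder is assigned non-named (`OTHER`)
#'   presence vectors.
#' @param abundance_levels Named numeric: mean clean-read count per abundance
#'   tier before library scaling.
#' @param tier_weights Sampling weights of the abundance tiers.
#' @param dispersion Negative-binomial dispersion phi, with
#'   `variance = mu + phi * mu^2`. `0` means deterministic rounded means.
#' @param length_mix Named numeric over lengths 18-30 summing to 1; tag length
#'   distribution (modes at 21 and 24 by default).
#' @param first_base_bias Named list: per mature-miRNA length, a named numeric
#'   over U/A/G/C summing to 1 giving the 5'-first-base distribution. Lengths
#'   not listed fall back to the `default` entry.
#' @param contamination_rates Named numeric in `[0,1]`: fraction of emitted
#'   raw reads that are poly-N, full-length homopolymer, missing the 3'
#'   adapter, or 5'-adapter contaminants.
#' @param adapter_3p,adapter_5p Adapter sequences (defaults: Illumina TruSeq
#'   small-RNA adapters).
#' @param reference_length Total simulated reference length in nt.
#' @param n_features Number of non-miRNA feature intervals planted,
#'   apportioned across categories by `category_proportions`.
#' @param n_background_tags Number of unique non-miRNA tags planted.
#' @param antisense_fraction Fraction of exon/intron background tags drawn
#'   antisense to their feature.
#' @param unannotated_mapped_fraction Among unannotated tags, the fraction
#'   drawn from unfeatured reference regions (genome-mapping) rather than
#'   random unmappable sequence.
#' @param de_fraction Fraction of all-stage miRNAs planted with a
#'   differential fold change.
#' @param de_multiplier Planted fold change (linear scale) for those miRNAs.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, library_size = 1e4, n_mirnas = 20)
#' cfg$pattern_assignments
sim_config <- function(seed = 1L,
                       libraries = STAGES,
                       library_size = 1e6,
                       category_proportions = NULL,
                       read_mass_proportions = NULL,
                       n_mirnas = 237L,
                       pattern_assignments = NULL,
                       abundance_levels = c(high = 20000, mid = 800, low = 150),
                       tier_weights = c(high = 0.1, mid = 0.4, low = 0.5),
                       dispersion = 0.1,
                       length_mix = NULL,
                       first_base_bias = NULL,
                       contamination_rates = c(poly_n = 0.02,
                                               homopolymer = 0.01,
                                               no_3prime_adapter = 0.03,
                                               five_prime_adapter = 0.01),
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       reference_length = 1e5,
                       n_features = 60L,
                       n_background_tags = 2000L,
                       antisense_fraction = 0.4,
                       unannotated_mapped_fraction = 0.45,
                       de_fraction = 0.3,
                       de_multiplier = 8) {
  if (is.null(category_proportions)) {
    category_proportions <- c(
      rRNA = 0.034, tRNA = 0.004, snRNA = 0.002, snoRNA = 0.002,
      known_miRNA = 0.007, piRNA = 0.002, repeat_ = 0.077,
      exon = 0.104, intron = 0.063, unannotated = 0.705
    )
    names(category_proportions)[names(category_proportions) == "repeat_"] <- "repeat"
  }
  if (is.null(read_mass_proportions)) {
    read_mass_proportions <- c(
      rRNA = 0.115, tRNA = 0.009, snRNA = 0.004, snoRNA = 0.006,
      known_miRNA = 0.03, piRNA = 0.003, repeat_ = 0.103,
      exon = 0.195, intron = 0.105, unannotated = 0.43
    )
    names(read_mass_proportions)[names(read_mass_proportions) == "repeat_"] <- "repeat"
  }
  if (is.null(length_mix)) {
    length_mix <- c(`18` = 0.02, `19` = 0.03, `20` = 0.06, `21` = 0.22,
                    `22` = 0.08, `23` = 0.07, `24` = 0.35, `25` = 0.06,
                    `26` = 0.04, `27` = 0.03, `28` = 0.02, `29` = 0.01,
                    `30` = 0.01)
  }
  if (is.null(first_base_bias)) {
    first_base_bias <- list(
      `23`    = c(U = 1.0, A = 0, G = 0, C = 0),
      default = c(U = 0.6, A = 0.15, G = 0.15, C = 0.10)
    )
  }
  if (is.null(pattern_assignments)) {
    pattern_assignments <- scale_pattern_assignments(n_mirnas)
  }

  cfg <- list(
    seed = as.integer(seed),
    libraries = libraries,
    library_size = library_size,
    category_proportions = category_proportions,
    read_mass_proportions = read_mass_proportions,
    n_mirnas = as.integer(n_mirnas),
    pattern_assignments = pattern_assignments,
    abundance_levels = abundance_levels,
    tier_weights = tier_weights,
    dispersion = dispersion,
    length_mix = length_mix,
    first_base_bias = first_base_bias,
    contamination_rates = contamination_rates,
    adapter_3p = adapter_3p,
    adapter_5p = adapter_5p,
    reference_length = reference_length,
    n_features = as.integer(n_features),
    n_background_tags = as.integer(n_background_tags),
    antisense_fraction = antisense_fraction,
    unannotated_mapped_fraction = unannotated_mapped_fraction,
    de_fraction = de_fraction,
    de_multiplier = de_multiplier
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# Default pattern census of the four-stage study, rescaled to n miRNAs by
# largest remainder so the total is exact.
scale_pattern_assignments <- function(n) {
  census <- c(ALL_STAGES = 52L, EARLY_SE_ONLY = 40L, NEC_ONLY = 43L,
              EC_ONLY = 19L, ICPEC_ONLY = 42L, GE_ONLY = 41L)
  raw <- census / sum(census) * n
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  setNames(as.integer(out), names(census))
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$libraries) >= 2, !anyDuplicated(cfg$libraries))
  chk_sum1 <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-9) {
      stop(what, " must sum to 1 (got ", format(sum(x), digits = 12), ")",
           call. = FALSE)
    }
  }
  chk_sum1(cfg$category_proportions, "category_proportions")
  chk_sum1(cfg$read_mass_proportions, "read_mass_proportions")
  chk_sum1(cfg$length_mix, "length_mix")
  for (nm in names(cfg$first_base_bias)) {
    chk_sum1(cfg$first_base_bias[[nm]], paste0("first_base_bias[['", nm, "']]"))
  }
  missing_cat <- setdiff(CASCADE, names(cfg$category_proportions))
  if (length(missing_cat)) {
    stop("category_proportions must cover all cascade categories; missing: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$category_proportions < 0)) {
    stop("category_proportions must be non-negative", call. = FALSE)
  }
  rates <- cfg$contamination_rates
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("contamination_rates must lie in [0,1] with total <= 1",
         call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (!all(names(cfg$pattern_assignments) %in% PATTERN_LABELS)) {
    stop("pattern_assignments names must come from the pattern vocabulary",
         call. = FALSE)
  }
  if (sum(cfg$pattern_assignments) > cfg$n_mirnas) {
    stop("pattern_assignments total exceeds n_mirnas", call. = FALSE)
  }
  bad_len <- setdiff(names(cfg$length_mix),
                     as.character(18:30))
  if (length(bad_len)) {
    stop("length_mix lengths must be within 18-30 nt", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  libraries      :", paste(x$libraries, collapse = ", "), "\n")
  cat("  library_size   :", format(x$library_size, big.mark = ","), "\n")
  cat("  n_mirnas       :", x$n_mirnas, "\n")
  cat("  patterns       :",
      paste(names(x$pattern_assignments), x$pattern_assignments,
            sep = "=", collapse = ", "), "\n")
  cat("  dispersion     :", x$dispersion, "\n")
  cat("  contamination  :",
      paste(names(x$contamination_rates), x$contamination_rates,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
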