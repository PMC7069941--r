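# Shared scaled-down study configurations. Abundance tiers shrink with
# library_size (counts per million preserved) so planted signals keep the
# study's relative magnitudes at desk scale.

small_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, library_size = 3e4, n_mirnas = 40,
             abundance_levels = c(high = 600, mid = 50, low = 15),
             reference_length = 4e4, n_background_tags = 300, ...)
}

# The round-trip benchmark scale: 100 miRNAs, 1e5 clean reads per library.
study_config <- function(seed = 101L, ...) {
  sim_config(seed = seed, library_size = 1e5, n_mirnas = 100,
             abundance_levels = c(high = 2000, mid = 80, low = 15),
             reference_length = 6e4, n_background_tags = 800, ...)
}

# Recovery of planted stage-presence patterns: fraction of planted miRNAs
# whose classified label equals the planted one (missing ids count as misses).
pattern_recovery <- function(sim, presence_min = 1L) {
  pats <- classify_patterns(sim$counts[sim$counts$is_mirna, ],
                            presence_min = presence_min)
  gt <- sim$ground_truth$mirnas
  m <- dplyr::left_join(gt, pats, by = "id")
  mean(!is.na(m$label) & m$label == m$pattern)
}

# Sensitivity on planted differential-expression calls: among pairs where the
# planted expected-RPM ratio exceeds the thresholds (or one side is absent),
# the fraction called with the right direction.
de_recovery <- function(sim) {
  de <- call_de(sim$counts[sim$counts$is_mirna,
                           c("id", names(sim$library_sizes))],
                sim$library_sizes)
  d <- dplyr::inner_join(tidy(de)[c("id", "pair", "call")],
                         sim$ground_truth$de, by = c("id", "pair"))
  d <- d[d$true_call %in% c("up", "down"), ]
  mean(d$call == d$true_call)
}
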