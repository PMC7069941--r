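test_that("reference simulation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 4L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_identical(r1$features, r2$features)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_reference(r1, d1); p2 <- write_reference(r2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("a degenerate all-rRNA mixture plants only rRNA intervals", {
  props <- c(rRNA = 1, tRNA = 0, snRNA = 0, snoRNA = 0, known_miRNA = 0,
             piRNA = 0, intron = 0, exon = 0, unannotated = 0)
  props["repeat"] <- 0
  cfg <- sim_config(seed = 2L, n_mirnas = 0L, reference_length = 4e4,
                    category_proportions = props)
  ref <- simulate_reference(cfg)
  expect_true(all(ref$features$category == "rRNA"))
  expect_gt(nrow(ref$features), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(category_proportions = c(rRNA = 0.5, exon = 0.4)),
               "sum to 1")
  expect_error(sim_config(contamination_rates = c(poly_n = 1, homopolymer = 1,
                                                  no_3prime_adapter = 0,
                                                  five_prime_adapter = 0)),
               "contamination_rates")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_mirnas = 10,
                          pattern_assignments = c(ALL_STAGES = 11L)),
               "exceeds n_mirnas")
})

test_that("planted mature miRNAs occur verbatim at their recorded loci", {
  cfg <- small_config(seed = 9L)
  ref <- simulate_reference(cfg)
  genome <- as.character(ref$sequences[["chr1"]])
  loci <- ref$features[ref$features$category == "known_miRNA", ]
  expect_equal(nrow(loci), cfg$n_mirnas)
  for (i in seq_len(nrow(loci))) {
    sub <- substr(genome, loci$start[i] + 1L, loci$end[i])
    mat <- ref$mature_mirnas[[loci$mirna[i]]]
    expected <- if (loci$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(mat)))
    } else mat
    expect_identical(sub, expected)
  }
  # and every mature sequence is a substring of the FASTA on some strand
  rc <- as.character(Biostrings::reverseComplement(ref$sequences[["chr1"]]))
  hits <- vapply(ref$mature_mirnas, function(m) {
    grepl(m, genome, fixed = TRUE) || grepl(m, rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("absent stages get hard zero counts and tiers behave", {
  cfg <- small_config(seed = 21L)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  gt <- sim$ground_truth$mirnas
  mir <- dplyr::inner_join(sim$counts, gt, by = "id")
  early <- mir[mir$pattern == "EARLY_SE_ONLY", ]
  expect_gt(nrow(early), 0)
  expect_true(all(early$NEC == 0))
  single <- mir[mir$pattern == "GE_ONLY", ]
  expect_true(all(single$EC == 0 & single$ICpEC == 0 & single$NEC == 0))
})

test_that("zero dispersion gives deterministic rounded means", {
  cfg <- small_config(seed = 5L, dispersion = 0)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  gt <- sim$ground_truth$mirnas
  mir <- dplyr::inner_join(sim$counts, gt, by = "id")
  # miRNAs without a planted fold change have one constant count across all
  # present stages, equal to their tier mean
  flat <- mir[is.na(mir$de_stage), ]
  for (i in seq_len(nrow(flat))) {
    pres <- strsplit(flat$presence[i], "")[[1]] == "1"
    vals <- unlist(flat[i, STAGES])[pres]
    expect_true(all(vals == vals[1]))
    expect_equal(unname(vals[1]),
                 unname(round(cfg$abundance_levels[[flat$tier[i]]])))
  }
})

test_that("library totals land within 10% of the configured size", {
  cfg <- study_config(seed = 31L)
  sim <- simulate_counts(cfg, simulate_reference(cfg))
  expect_true(all(abs(sim$library_sizes / cfg$library_size - 1) < 0.1))
  # conservation: per-category read mass sums to the library total
  tot <- sim$counts |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cfg$libraries), sum))
  expect_equal(unname(unlist(tot)), unname(sim$library_sizes),
               ignore_attr = TRUE)
})

test_that("contaminant reads appear at the configured rates", {
  cfg <- sim_config(seed = 8L, library_size = 1e4, n_mirnas = 20L,
                    abundance_levels = c(high = 200, mid = 30, low = 10),
                    reference_length = 3e4, n_background_tags = 150L,
                    contamination_rates = c(poly_n = 0.1, homopolymer = 0,
                                            no_3prime_adapter = 0,
                                            five_prime_adapter = 0))
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  dir <- withr::local_tempdir()
  rt <- simulate_reads(cfg, ref, sim, dir)
  reads <- read_reads(rt$path[rt$library == "EC"])$read
  frac_n <- mean(grepl("N", reads, fixed = TRUE))
  expect_lt(abs(frac_n - 0.1), 0.01)
})

test_that("clean-rate extremes behave: zero contamination and all-homopolymer", {
  base <- list(seed = 13L, library_size = 5e3, n_mirnas = 10L,
               abundance_levels = c(high = 100, mid = 30, low = 10),
               reference_length = 2e4, n_background_tags = 80L)
  cfg0 <- do.call(sim_config, c(base, list(
    contamination_rates = c(poly_n = 0, homopolymer = 0,
                            no_3prime_adapter = 0, five_prime_adapter = 0))))
  ref <- simulate_reference(cfg0)
  sim <- simulate_counts(cfg0, ref)
  dir <- withr::local_tempdir()
  rt <- simulate_reads(cfg0, ref, sim, dir)
  fr <- filter_and_trim(read_reads(rt$path[1]), cfg0$adapter_3p,
                        cfg0$adapter_5p)
  expect_equal(sum(fr$qc$removed), 0)
  expect_equal(nrow(fr$clean), rt$n_reads[1])

  cfg1 <- do.call(sim_config, c(base, list(
    contamination_rates = c(poly_n = 0, homopolymer = 1,
                            no_3prime_adapter = 0, five_prime_adapter = 0))))
  rt1 <- simulate_reads(cfg1, ref, sim, withr::local_tempdir())
  fr1 <- filter_and_trim(read_reads(rt1$path[1]), cfg1$adapter_3p,
                         cfg1$adapter_5p)
  expect_equal(nrow(fr1$clean), 0)
})
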