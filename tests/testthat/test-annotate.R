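# A tiny hand-built reference used across annotation tests.
tiny_ref <- function() {
  set.seed(99)
  genome <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  feats <- tibble::tibble(
    feature_id = c("rRNA_001", "exon_001", "intron_001", "repeat_001"),
    category = c("rRNA", "exon", "intron", "repeat"),
    seqname = "chr1",
    start = c(50L, 150L, 300L, 420L),
    end = c(120L, 250L, 400L, 520L),
    strand = c("+", "+", "-", "+")
  )
  structure(list(sequences = Biostrings::DNAStringSet(c(chr1 = genome)),
                 features = feats,
                 mature_mirnas = c(mir_a = substr(genome, 161, 181))),
            class = "srna_reference")
}

sub_chr <- function(ref, from, to) {
  substr(as.character(ref$sequences[["chr1"]]), from, to)
}

test_that("map_exact finds full-length hits on both strands and nothing else", {
  ref <- tiny_ref()
  tag_plus <- sub_chr(ref, 60, 80)
  tag_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub_chr(ref, 310, 330))))
  pl <- map_exact(c(tag_plus, tag_minus), ref)
  p1 <- pl[pl$tag == tag_plus, ]
  expect_equal(p1$strand, "+")
  expect_equal(p1$start, 59L)   # 0-based
  expect_equal(p1$end, 80L)
  p2 <- pl[pl$tag == tag_minus, ]
  expect_equal(p2$strand, "-")
  expect_equal(p2$start, 309L)
  # one mismatch breaks an exact mapping
  mm <- tag_plus
  substr(mm, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                substr(mm, 11, 11))[1]
  expect_equal(nrow(map_exact(mm, ref)), 0L)
  expect_error(map_exact("ACGT", list(sequences = Biostrings::DNAStringSet())),
               "empty reference")
})

test_that("map_exact agrees with a naive all-substrings scan", {
  cfg <- sim_config(seed = 17L, reference_length = 8e3, n_mirnas = 15L,
                    n_features = 15L, n_background_tags = 50L)
  ref <- simulate_reference(cfg)
  genome <- as.character(ref$sequences[["chr1"]])
  rc <- as.character(Biostrings::reverseComplement(ref$sequences[["chr1"]]))
  L <- nchar(genome)
  set.seed(18)
  tags <- c(
    unname(ref$mature_mirnas[1:10]),
    vapply(1:10, function(i) {         # random substrings of either strand
      len <- sample(18:30, 1); at <- sample(L - len, 1)
      substr(if (i %% 2) genome else rc, at, at + len - 1)
    }, character(1)),
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                                  collapse = ""), character(1))
  )
  naive <- function(tag) {
    hits <- list()
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") tag else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tag)))
      k <- nchar(subj)
      for (at in seq_len(L - k + 1)) {
        if (substr(genome, at, at + k - 1) == subj) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            tag = tag, start = at - 1L, end = at + k - 1L, strand = strand)
        }
      }
    }
    dplyr::bind_rows(hits)
  }
  got <- map_exact(tags, ref) |>
    dplyr::select("tag", "start", "end", "strand") |>
    dplyr::arrange(tag, start, strand)
  want <- dplyr::bind_rows(lapply(unique(tags), naive)) |>
    dplyr::arrange(tag, start, strand)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("the priority cascade assigns a single category per tag", {
  ref <- tiny_ref()
  # a tag inside the exon, sense
  exon_sense <- sub_chr(ref, 161, 181)
  # same location read from the minus strand: exon antisense
  exon_anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub_chr(ref, 190, 210))))
  # intron feature is on '-', so a plus-strand genome substring is antisense
  intron_anti <- sub_chr(ref, 310, 330)
  # mapped, no feature overlap
  nofeat <- sub_chr(ref, 540, 560)
  ann <- annotate_tags(c(exon_sense, exon_anti, intron_anti, nofeat), ref)
  got <- setNames(ann$category, ann$tag)
  # exon_sense also matches the mature catalog (mir_a) -> known_miRNA beats exon
  expect_equal(unname(got[exon_sense]), "known_miRNA")
  expect_equal(unname(got[exon_anti]), "exon_antisense")
  expect_equal(unname(got[intron_anti]), "intron_antisense")
  expect_equal(unname(got[nofeat]), "unannotated")
  expect_true(all(ann$mapped))
})

test_that("rRNA-tier features outrank a known-miRNA catalog match", {
  ref <- tiny_ref()
  rtag <- sub_chr(ref, 60, 80)
  ref2 <- ref
  ref2$mature_mirnas <- c(ref$mature_mirnas, mir_r = rtag)
  ann <- annotate_tags(rtag, ref2)
  expect_equal(ann$category, "rRNA")
  # catalog match with a 2-nt 3' shift is still known_miRNA off-genome
  shifted <- substr(ref$mature_mirnas[["mir_a"]], 1,
                    nchar(ref$mature_mirnas[["mir_a"]]) - 2)
  ann2 <- annotate_tags(shifted, tiny_ref())
  expect_equal(ann2$category, "known_miRNA")
})

test_that("assignments are invariant to feature-row permutation", {
  cfg <- small_config(seed = 23L)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  tags <- head(sim$counts$sequence, 150)
  a1 <- annotate_tags(tags, ref)
  ref_perm <- ref
  set.seed(1)
  ref_perm$features <- ref$features[sample(nrow(ref$features)), ]
  a2 <- annotate_tags(tags, ref_perm)
  expect_equal(a1$category, a2$category)
})

test_that("raising min_overlap never promotes a tag up the cascade", {
  cfg <- small_config(seed = 29L)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  tags <- head(sim$counts$sequence, 200)
  rank_of <- function(category) {
    base <- sub("_(sense|antisense)$", "", category)
    r <- sRNAstage:::cascade_ranks()[base]
    ifelse(is.na(r), 10L, r)  # unannotated ranks below the whole cascade
  }
  a_lo <- annotate_tags(tags, ref, min_overlap = 0.5)
  a_hi <- annotate_tags(tags, ref, min_overlap = 1.0)
  expect_true(all(rank_of(a_hi$category) >= rank_of(a_lo$category)))
})

test_that("simulated tags are recovered into their planted categories", {
  cfg <- small_config(seed = 37L)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  ann <- annotate_tags(dplyr::rename(sim$counts, tag = "sequence"), ref)
  agree <- mean(ann$category == ann$true_category)
  expect_gt(agree, 0.95)
})

test_that("category summary satisfies the row-sum identity on simulated data", {
  cfg <- small_config(seed = 41L)
  ref <- simulate_reference(cfg)
  sim <- simulate_counts(cfg, ref)
  ann <- annotate_tags(dplyr::rename(sim$counts, tag = "sequence"), ref)
  cs <- summarize_categories(ann, libraries = cfg$libraries)
  for (lib in cfg$libraries) {
    d <- cs[cs$library == lib, ]
    tot <- d[d$row == "Total sRNAs", ]
    cats <- d[!d$row %in% c("Total sRNAs", "Mapping to genome"), ]
    expect_equal(sum(cats$unique_count), tot$unique_count)
    expect_equal(sum(cats$total_count), tot$total_count)
    # percentages recompute from counts
    expect_equal(cats$unique_pct,
                 fmt_pct(cats$unique_count / tot$unique_count * 100))
  }
})

test_that("percentage formatting rounds half up and strips trailing zeros", {
  expect_equal(fmt_pct(7099 / 1008620 * 100), "0.7")
  expect_equal(fmt_pct(c(0.255, 0.26)), c("0.26", "0.26"))
  expect_equal(fmt_pct(100), "100")
  expect_equal(fmt_pct(85.395), "85.4")
  expect_equal(fmt_pct(0), "0")
})

test_that("length distribution counts per length and library", {
  tags <- tibble::tibble(
    tag = c(strrep("C", 21), strrep("G", 21), strrep("T", 21),
            strrep("A", 24)),
    EC = c(2L, 1L, 3L, 5L), NEC = 0L
  )
  ld <- length_distribution(tags, libraries = c("EC", "NEC"))
  ec21 <- ld[ld$length == 21 & ld$library == "EC", ]
  expect_equal(ec21$unique, 3L)
  expect_equal(ec21$total, 6L)
  expect_equal(ld[ld$length == 24 & ld$library == "EC", ]$unique, 1L)
  # empty library: all-zero rows
  expect_true(all(ld$total[ld$library == "NEC"] == 0L))
  expect_equal(sum(ld$total[ld$library == "EC"]), sum(tags$EC))
})

test_that("simulated length mix recovers its 21/24-nt modes", {
  cfg <- study_config(seed = 43L)
  sim <- simulate_counts(cfg, simulate_reference(cfg))
  ld <- length_distribution(
    dplyr::rename(sim$counts, tag = "sequence"), libraries = cfg$libraries) |>
    dplyr::group_by(length) |>
    dplyr::summarise(unique = sum(unique))
  top2 <- ld$length[order(ld$unique, decreasing = TRUE)][1:2]
  expect_setequal(top2, c(21, 24))
})

test_that("base composition reports RNA-alphabet frequencies by position", {
  cmp <- base_composition(c("UACGUACGUACGUACGUACG", "UGGCUACGUACGUACGUACG"),
                          lengths = 20)
  first <- cmp[cmp$position == 1 & cmp$base == "U", ]
  expect_equal(first$freq, 1)
  # alternating sequence gives an exactly alternating position matrix
  alt <- base_composition("UAUAUAUAUAUAUAUAUAUAU", lengths = 21)
  u_rows <- alt[alt$base == "U" & alt$freq == 1, "position", drop = TRUE]
  expect_equal(u_rows, seq(1, 21, by = 2))
  # empty length class is flagged, not computed
  empty <- base_composition(character(0), lengths = 22)
  expect_true(all(empty$insufficient_data))
})

test_that("a planted first-base bias is recovered from mature sequences", {
  bias <- list(`22` = c(U = 0.7, A = 0.1, G = 0.1, C = 0.1),
               default = c(U = 0.25, A = 0.25, G = 0.25, C = 0.25))
  mix <- c(`22` = 1)
  cfg <- sim_config(seed = 47L, n_mirnas = 1000L, reference_length = 3e5,
                    length_mix = mix, first_base_bias = bias,
                    n_background_tags = 10L)
  ref <- simulate_reference(cfg)
  prof <- first_base_profile(unname(ref$mature_mirnas), lengths = 22)
  u <- prof$freq[prof$base == "U"]
  expect_lt(abs(u - 0.7), 0.05)
})

test_that("printed category counts reproduce their printed percentages", {
  counts <- longan_category_counts()
  fc <- format_category_counts(counts)
  pick <- function(rw, lib, col) fc[[col]][fc$row == rw & fc$library == lib]
  expect_equal(pick("miRNA", "NEC", "unique_pct"), "0.7")
  expect_equal(pick("Mapping to genome", "EC", "total_pct"), "86.19")
  expect_equal(pick("Mapping to genome", "NEC", "total_pct"), "85.4")
  expect_equal(pick("unannotated", "GE", "total_pct"), "52.21")
  expect_equal(pick("rRNA", "NEC", "total_pct"), "16.71")
  # row-sum identity enforced: a corrupted table is rejected
  bad <- counts
  bad$unique_count[bad$row == "rRNA" & bad$library == "NEC"] <- 1L
  expect_error(format_category_counts(bad), "row-sum identity")
})
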