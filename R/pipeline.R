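#' Run the full stage-wise small-RNA pipeline on synthetic data
#'
#' Orchestrates simulate -> write raw files -> clean -> collapse -> annotate ->
#' differential expression -> pattern classification, entirely from one
#' configuration, writing every module output plus a run manifest to
#' `out_dir`. Deterministic: the same configuration and seed give identical
#' output hashes.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created).
#' @param presence_min Pattern-presence floor passed to
#'   [classify_patterns()].
#' @param p_threshold,lfc_threshold Differential-expression thresholds.
#' @param min_overlap Annotation overlap fraction.
#' @return A list of class `srna_run`: all intermediate tibbles plus
#'   `manifest` (tibble of written files with md5 hashes and record counts).
#' @export
run_pipeline <- function(config, out_dir,
                         presence_min = 1L,
                         p_threshold = 0.01,
                         lfc_threshold = 1,
                         min_overlap = 1.0) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## simulate
  ref <- simulate_reference(config)
  sim <- simulate_counts(config, ref)
  ref_paths <- write_reference(ref, out_dir)
  reads_tbl <- simulate_reads(config, ref, sim, file.path(out_dir, "raw"))
  readr::write_tsv(sim$counts, file.path(out_dir, "true_counts.tsv"))
  readr::write_tsv(sim$ground_truth$mirnas,
                   file.path(out_dir, "ground_truth_mirnas.tsv"))
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))

  ## preprocess
  clean <- purrr::map2(reads_tbl$library, reads_tbl$path, function(lib, p) {
    fr <- filter_and_trim(read_reads(p), adapter_3p = config$adapter_3p,
                          adapter_5p = config$adapter_5p)
    list(reads = mutate(fr$clean, library = lib),
         qc = mutate(fr$qc, library = lib) |>
           bind_cols(rename(qc_totals(fr$qc), removed_total = "removed")))
  })
  qc <- list_rbind(purrr::map(clean, "qc"))
  tags <- collapse_unique(list_rbind(purrr::map(clean, "reads")),
                          libraries = config$libraries)
  readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
  jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"))
  readr::write_tsv(tags, file.path(out_dir, "clean_tags.tsv"))

  ## annotate
  annotated <- annotate_tags(tags, ref, min_overlap = min_overlap)
  cat_summary <- summarize_categories(annotated,
                                      libraries = config$libraries)
  len_dist <- length_distribution(annotated, libraries = config$libraries)
  mir_tags <- filter(annotated, .data$category == "known_miRNA")
  composition <- base_composition(mir_tags$tag)
  readr::write_tsv(annotated, file.path(out_dir, "annotated_tags.tsv"))
  readr::write_tsv(cat_summary, file.path(out_dir, "category_summary.tsv"))
  readr::write_tsv(len_dist, file.path(out_dir, "length_distribution.tsv"))
  readr::write_tsv(composition, file.path(out_dir, "base_composition.tsv"))

  ## differential expression on observed miRNA tags
  lib_sizes <- qc |>
    distinct(.data$library, .keep_all = TRUE) |>
    (\(d) setNames(d$clean_reads, d$library))()
  mir_counts <- mir_tags |>
    mutate(id = .data$tag) |>
    select("id", dplyr::all_of(config$libraries))
  de <- call_de(mir_counts, lib_sizes, p_threshold = p_threshold,
                lfc_threshold = lfc_threshold)
  readr::write_tsv(de_for_output(de), file.path(out_dir, "diffexpr.tsv"))

  ## patterns
  pats <- classify_patterns(mir_counts, stages = config$libraries,
                            presence_min = presence_min) |>
    flag_abundance()
  venn <- venn_sets(pats, stages = config$libraries)
  readr::write_tsv(pats, file.path(out_dir, "patterns.tsv"))
  readr::write_tsv(select(venn, -"ids"), file.path(out_dir, "venn.tsv"))

  ## manifest
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest <- tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  counts_manifest <- tibble(
    stage = c("raw_reads", "clean_reads", "unique_tags", "mirna_tags",
              "de_records", "pattern_calls"),
    records = c(sum(reads_tbl$n_reads), sum(qc$clean_reads[!duplicated(qc$library)]),
                nrow(tags), nrow(mir_tags), nrow(de), nrow(pats))
  )
  jsonlite::write_json(list(files = manifest, records = counts_manifest,
                            seed = config$seed),
                       file.path(out_dir, "manifest.json"))

  structure(list(config = config, reference = ref, sim = sim,
                 reads = reads_tbl, qc = qc, tags = tags,
                 annotated = annotated, category_summary = cat_summary,
                 length_distribution = len_dist, composition = composition,
                 de = de, patterns = pats, venn = venn,
                 manifest = manifest, record_counts = counts_manifest),
            class = "srna_run")
}

de_for_output <- function(de) {
  out <- as_tibble(de)
  out$log2fc <- ifelse(is.infinite(out$log2fc),
                       ifelse(out$log2fc > 0, "inf", "-inf"),
                       format(out$log2fc, digits = 6))
  out
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$first_base_bias <- purrr::map(out$first_base_bias, as.list)
  purrr::map(out, function(x) if (is.numeric(x) && !is.null(names(x))) {
    as.list(x)
  } else x)
}

#' Plain-text summary report of a pipeline run
#'
#' Writes a single human-readable report: QC totals, the category table, the
#' length distribution, per-pair differential-expression counts and the
#' pattern tally. Missing upstream components are noted as gaps rather than
#' failing.
#'
#' @param run A `srna_run` from [run_pipeline()] (or a partial list with the
#'   same element names).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_summary_report <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Stage-wise small RNA pipeline summary")
  w(strrep("=", 42))
  section <- function(name, x, render) {
    w("")
    w("## ", name)
    if (is.null(x)) {
      w("[missing upstream output]")
    } else {
      render(x)
    }
  }
  section("Cleaning", run$qc, function(qc) {
    tot <- qc |> distinct(.data$library, .keep_all = TRUE)
    for (i in seq_len(nrow(tot))) {
      w(sprintf("%-6s raw=%d clean=%d (%.1f%%)", tot$library[i],
                tot$raw_reads[i], tot$clean_reads[i],
                100 * tot$clean_fraction[i]))
    }
  })
  section("Category composition", run$category_summary, function(cs) {
    apply(cs, 1, function(r) {
      w(sprintf("%-18s %-6s unique=%s (%s%%) total=%s (%s%%)",
                r[["row"]], r[["library"]], r[["unique_count"]],
                r[["unique_pct"]], r[["total_count"]], r[["total_pct"]]))
    })
  })
  section("Length distribution (total reads)", run$length_distribution,
          function(ld) {
    wtab <- ld |> select("length", "library", "total") |>
      pivot_wider(names_from = "library", values_from = "total")
    w(paste(names(wtab), collapse = "\t"))
    apply(wtab, 1, function(r) w(paste(r, collapse = "\t")))
  })
  section("Differential expression (per pair)", run$de, function(de) {
    g <- glance(de)
    for (i in seq_len(nrow(g))) {
      w(sprintf("%-16s up=%d down=%d ns=%d", g$pair[i], g$up[i], g$down[i],
                g$not_significant[i]))
    }
  })
  section("Expression patterns", run$patterns, function(p) {
    tab <- p |> filter(!is.na(.data$label)) |> count(.data$label)
    for (i in seq_len(nrow(tab))) {
      w(sprintf("%-14s %d", tab$label[i], tab$n[i]))
    }
    flagged <- sum(p$abundance_flag %||% FALSE, na.rm = TRUE)
    w(sprintf("abundance-flagged: %d", flagged))
  })
  invisible(path)
}
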