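#' Published category counts of the four-stage longan study
#'
#' Loads the bundled per-library unique/total category counts from the
#' four-stage (EC, ICpEC, GE, NEC) longan somatic-embryogenesis small-RNA
#' experiment, as printed in its summary table. Useful for checking the
#' percentage arithmetic and the row-sum identity with
#' [format_category_counts()].
#'
#' @return Tibble: `row`, `library`, `unique_count`, `total_count`.
#' @export
#' @examples
#' counts <- longan_category_counts()
#' format_category_counts(counts) |> head()
longan_category_counts <- function() {
  path <- system.file("extdata", "longan_se_category_counts.tsv",
                      package = "sRNAstage", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    row = readr::col_character(),
                    library = readr::col_character(),
                    unique_count = readr::col_double(),
                    total_count = readr::col_double()
                  ))
}

#' Write / read a tag count table
#'
#' Thin TSV round-trip for the collapsed tag table (`tag` + per-library
#' counts) so pipeline stages can be run from files.
#'
#' @param tags Tag tibble.
#' @param path File path.
#' @return `write_tag_counts` returns the path invisibly; `read_tag_counts`
#'   returns the tibble.
#' @export
write_tag_counts <- function(tags, path) {
  readr::write_tsv(tags, path)
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
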