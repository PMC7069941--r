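#' Classify stage-presence expression patterns
#'
#' Converts per-stage counts into a presence vector (count >= `presence_min`)
#' over (EC, ICpEC, GE, NEC) and labels it with the closed pattern
#' vocabulary: `ALL_STAGES` (1111), `EARLY_SE_ONLY` (1110: EC, ICpEC and GE
#' but not NEC), `NEC_ONLY` (0001), `EC_ONLY` (1000), `ICPEC_ONLY` (0100),
#' `GE_ONLY` (0010); every other non-zero vector is `OTHER`. Rows with all
#' counts below `presence_min` are rejected: returned with `label = NA` and a
#' `reason`.
#'
#' @param counts Tibble with `id` and one count column per stage.
#' @param stages Stage column names in presence-vector order
#'   (default EC, ICpEC, GE, NEC).
#' @param presence_min Minimum count that counts as "expressed" (default 1:
#'   any detection).
#' @return A tibble of class `srna_patterns`: `id`, `presence` (e.g.
#'   `"1110"`), `label`, `max_relevant_count` (largest count among present
#'   stages), `reason` (`NA` unless rejected).
#' @export
#' @examples
#' x <- tibble::tibble(id = c("a", "b", "c"),
#'                     EC = c(50, 0, 5), ICpEC = c(30, 0, 0),
#'                     GE = c(700, 120, 5), NEC = c(0, 0, 5))
#' classify_patterns(x)
classify_patterns <- function(counts, stages = STAGES, presence_min = 1L) {
  stopifnot("id" %in% names(counts), presence_min >= 1,
            all(stages %in% names(counts)))
  m <- as.matrix(counts[stages])
  if (any(m < 0)) stop("stage counts must be non-negative", call. = FALSE)
  pres <- m >= presence_min
  presence <- apply(pres, 1, function(r) paste(as.integer(r), collapse = ""))
  label <- names(NAMED_PATTERNS)[match(presence, NAMED_PATTERNS)]
  label[is.na(label)] <- "OTHER"
  rejected <- presence == strrep("0", length(stages))
  label[rejected] <- NA_character_
  max_rel <- vapply(seq_len(nrow(m)), function(i) {
    if (rejected[i]) return(NA_integer_)
    as.integer(max(m[i, pres[i, ]]))
  }, integer(1))
  out <- tibble(
    id = counts$id,
    presence = presence,
    label = label,
    max_relevant_count = max_rel,
    reason = if_else(rejected, "all counts below presence_min",
                     NA_character_)
  )
  class(out) <- c("srna_patterns", class(out))
  attr(out, "presence_min") <- presence_min
  out
}

#' Flag highly abundant patterned miRNAs
#'
#' Adds the abundance highlight of the pattern classes: flagged when the
#' maximum count over present stages strictly exceeds the class threshold —
#' 10,000 for `ALL_STAGES`, 500 for `EARLY_SE_ONLY`, 100 for the four
#' single-stage classes (and, by documented default, for `OTHER`).
#'
#' @param calls Output of [classify_patterns()].
#' @param thresholds Named integer vector of per-label thresholds; labels not
#'   named fall back to the `OTHER` entry.
#' @return `calls` with `threshold_used` and `abundance_flag` columns added.
#' @export
flag_abundance <- function(calls, thresholds = ABUNDANCE_THRESHOLDS) {
  thr <- unname(thresholds[calls$label])
  thr[is.na(thr) & !is.na(calls$label)] <- thresholds[["OTHER"]]
  calls$threshold_used <- as.integer(thr)
  calls$abundance_flag <- calls$max_relevant_count > thr
  calls
}

#' Four-set Venn partition of stage-expressed identifiers
#'
#' Partitions ids into the 15 disjoint non-empty-subset regions of the four
#' stage sets (e.g. ids present in EC and GE only). Region counts sum to the
#' size of the union.
#'
#' @param sets Named list of character vectors (ids per stage), or a
#'   `srna_patterns` tibble (presence vectors are reused).
#' @param stages Stage names (and order) when `sets` is a patterns table.
#' @return A tibble: `region` (stage names joined by `&`), `degree` (number of
#'   stages in the region), `count`, `ids` (list column).
#' @export
#' @examples
#' venn_sets(list(EC = c("a", "b"), ICpEC = "a", GE = "a", NEC = character(0)))
venn_sets <- function(sets, stages = STAGES) {
  if (inherits(sets, "srna_patterns")) {
    pres <- sets
    sets <- purrr::map(seq_along(stages), function(i) {
      pres$id[!is.na(pres$label) &
                substr(pres$presence, i, i) == "1"]
    })
    names(sets) <- stages
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  stages <- names(sets)
  k <- length(stages)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, stages))
  key <- apply(member, 1, function(r) paste(stages[r], collapse = "&"))
  combos <- unlist(purrr::map(seq_len(k), function(d) {
    utils::combn(stages, d, FUN = paste, collapse = "&")
  }))
  tibble(region = unname(combos),
         degree = unname(str_count(combos, stringr::fixed("&")) + 1L),
         count = vapply(combos, function(cb) sum(key == cb), integer(1),
                        USE.NAMES = FALSE),
         ids = unname(purrr::map(combos, function(cb) ids[key == cb])))
}
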