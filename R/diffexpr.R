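#' Reads-per-million normalisation
#'
#' `rpm = count / N * 1e6`, where `N` is the library's total clean reads.
#'
#' @param count Non-negative counts.
#' @param total Total clean reads in the library (positive).
#' @return Numeric RPM values.
#' @export
#' @examples
#' rpm(200, 1e6)   # 200
#' rpm(13, 2e6)    # 6.5
rpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count / total * 1e6
}

#' Log2 fold change of normalised expression
#'
#' `log2(rpm_treatment / rpm_control)`. Zero-vs-positive comparisons return
#' signed infinities (the expression-specificity cases); 0/0 returns `NaN`.
#'
#' @param rpm_treatment,rpm_control Non-negative normalised expressions.
#' @return Numeric; may be `Inf`, `-Inf` or `NaN`.
#' @export
#' @examples
#' log2_fold_change(400, 100)  # 2
#' log2_fold_change(50, 0)     # Inf
log2_fold_change <- function(rpm_treatment, rpm_control) {
  if (any(rpm_treatment < 0) || any(rpm_control < 0)) {
    stop("normalised expressions must be non-negative", call. = FALSE)
  }
  out <- log2(rpm_treatment / rpm_control)
  out[rpm_treatment == 0 & rpm_control == 0] <- NaN
  out
}

#' Exact two-library count probability
#'
#' The probability of observing count `y` in the second library given count
#' `x` in the first, for library sizes `N1`, `N2`:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' evaluated in log space via `lgamma` so large counts do not overflow. For
#' `N1 = N2` this reduces to `choose(x+y, x) / 2^(x+y+1)`.
#'
#' @param y,x Non-negative integer counts (`y` may be a vector).
#' @param n1,n2 Positive library totals.
#' @return Probabilities in (0, 1].
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)    # 0.5
#' ac_probability(10, 10, 1e6, 1e6)  # choose(20, 10) / 2^21
ac_probability <- function(y, x, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be > 0",
                                         call. = FALSE)
  logr <- log(n2) - log(n1)
  exp(y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(exp(logr)))
}

# Lower tail C(y) = sum_{k=0..y} p(k|x), computed by direct log-space
# summation.
ac_lower_tail <- function(x, y, n1, n2) {
  if (y < 0) return(0)
  sum(ac_probability(0:y, x, n1, n2))
}

# Upper tail D(y) = sum_{k=y..inf} p(k|x), summed directly from k = y until
# the increment falls below 1e-16 of the running sum (hard cap on terms), so
# tiny tails keep full relative precision.
ac_upper_tail <- function(x, y, n1, n2) {
  cap <- ceiling(x + y + 10 * sqrt(x + y) + 1000)
  total <- 0
  k <- y
  block <- 256L
  repeat {
    ks <- k:(k + block - 1L)
    terms <- ac_probability(ks, x, n1, n2)
    cs <- cumsum(terms)
    total_new <- total + cs[block]
    # stop when the last term is negligible relative to the running sum
    if (terms[block] < 1e-16 * total_new || k + block > y + cap) {
      return(total + cs[block])
    }
    total <- total_new
    k <- k + block
  }
}

#' Exact two-library test p-value
#'
#' Two-sided p-value for the difference between counts `x` and `y` observed
#' in libraries of size `N1` and `N2`: with lower tail
#' `C = sum_{k<=y} p(k|x)` and upper tail `D = sum_{k>=y} p(k|x)`,
#' `p = min(1, 2 min(C, D))` (doubled smaller tail, capped at 1).
#'
#' @param x,y Non-negative integer counts (vectorised, recycled).
#' @param n1,n2 Positive library totals.
#' @return p-values in (0, 1].
#' @export
#' @examples
#' ac_pvalue(3, 3, 1e6, 1e6)    # 1: tails overlap at the observation
#' ac_pvalue(0, 100, 1e6, 1e6)  # 2 * 2^-100
ac_pvalue <- function(x, y, n1, n2) {
  args <- vctrs_recycle(x, y, n1, n2)
  vapply(seq_along(args$x), function(i) {
    xi <- args$x[i]; yi <- args$y[i]
    C <- ac_lower_tail(xi, yi, args$n1[i], args$n2[i])
    D <- ac_upper_tail(xi, yi, args$n1[i], args$n2[i])
    min(1, 2 * min(C, D))
  }, numeric(1))
}

vctrs_recycle <- function(x, y, n1, n2) {
  n <- max(length(x), length(y))
  list(x = rep_len(x, n), y = rep_len(y, n),
       n1 = rep_len(n1, n), n2 = rep_len(n2, n))
}

#' Pairwise differential-expression calls
#'
#' For every id and library pair, computes RPMs, the log2 fold change
#' (`B` over `A`), the exact two-library p-value, and the call: `up` when the
#' normalised ratio exceeds 2 (log2 fold change > 1) with `p < p_threshold`,
#' `down` when below 1/2, else `not_significant`. Ids detected in exactly one
#' library of the pair carry a specificity flag (`A_only` / `B_only`); the
#' infinite log2 fold change is kept as is. Ids with zero counts in both
#' libraries of a pair are excluded. A secondary significance tier records
#' `p<0.01`, `p<0.05` or `ns`.
#'
#' @param counts Tibble with an `id` column and one count column per library
#'   (e.g. `sim$counts` renamed, or any count matrix).
#' @param library_sizes Named numeric: total clean reads per library.
#' @param pairs List of 2-vectors `c(A, B)`; default all unordered pairs of
#'   the libraries present in `library_sizes`.
#' @param p_threshold p-value cut-off for a call (default 0.01).
#' @param lfc_threshold Absolute log2-fold-change cut-off (default 1).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   applied within each pair (default `"none"`, matching raw two-library
#'   practice; `"BH"` available). Calls use the adjusted value when not
#'   `"none"`.
#' @return A tibble of class `srna_de`: `id`, `pair`, `library_a`,
#'   `library_b`, `x`, `y`, `rpm_a`, `rpm_b`, `log2fc`, `p_value`, `call`,
#'   `specificity`, `tier`.
#' @export
call_de <- function(counts, library_sizes, pairs = NULL,
                    p_threshold = 0.01, lfc_threshold = 1,
                    adjust = "none") {
  stopifnot("id" %in% names(counts))
  libs <- names(library_sizes)
  missing_lib <- setdiff(libs, names(counts))
  if (length(missing_lib)) {
    stop("count columns missing for: ", paste(missing_lib, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(pairs)) pairs <- utils::combn(libs, 2, simplify = FALSE)
  for (pr in pairs) {
    if (!all(pr %in% libs)) {
      stop("pair references unknown library: ", paste(pr, collapse = ", "),
           call. = FALSE)
    }
  }

  res <- purrr::map(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    x <- counts[[a]]; y <- counts[[b]]
    keep <- x > 0 | y > 0
    x <- x[keep]; y <- y[keep]
    n1 <- library_sizes[[a]]; n2 <- library_sizes[[b]]
    rpm_a <- rpm(x, n1); rpm_b <- rpm(y, n2)
    lfc <- log2_fold_change(rpm_b, rpm_a)
    # The exact test conditions on the first count, so its p-value is not
    # perfectly symmetric in the two libraries; evaluate it in a canonical
    # orientation (alphabetical library order) so calls do not depend on how
    # the pair was written.
    p <- if (a <= b) ac_pvalue(x, y, n1, n2) else ac_pvalue(y, x, n2, n1)
    p_eff <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
    call <- dplyr::case_when(
      lfc > lfc_threshold & p_eff < p_threshold ~ "up",
      lfc < -lfc_threshold & p_eff < p_threshold ~ "down",
      TRUE ~ "not_significant"
    )
    tibble(
      id = counts$id[keep],
      pair = paste(a, "vs", b),
      library_a = a, library_b = b,
      x = x, y = y, rpm_a = rpm_a, rpm_b = rpm_b,
      log2fc = lfc, p_value = p,
      p_adjusted = if (identical(adjust, "none")) NA_real_ else p_eff,
      call = call,
      specificity = dplyr::case_when(
        x == 0 & y > 0 ~ "B_only",
        y == 0 & x > 0 ~ "A_only",
        TRUE ~ "none"
      ),
      tier = dplyr::case_when(
        p_eff < 0.01 ~ "p<0.01",
        p_eff < 0.05 ~ "p<0.05",
        TRUE ~ "ns"
      )
    )
  }) |> list_rbind()
  if (identical(adjust, "none")) res$p_adjusted <- NULL
  class(res) <- c("srna_de", class(res))
  attr(res, "library_sizes") <- library_sizes
  res
}

#' @export
#' @rdname call_de
#' @method tidy srna_de
#' @param x A `srna_de` object (for `tidy`/`glance`).
#' @param ... Unused.
tidy.srna_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
#' @rdname call_de
#' @method glance srna_de
glance.srna_de <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$pair) |>
    summarise(n = n(),
              up = sum(.data$call == "up"),
              down = sum(.data$call == "down"),
              not_significant = sum(.data$call == "not_significant"),
              a_only = sum(.data$specificity == "A_only"),
              b_only = sum(.data$specificity == "B_only"),
              .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
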