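# Standard-error-based variant filtering, count-based comparators, replicate
# concordance, and z-test hypothesis testing.

#' Filter variants by standard error or read count
#'
#' Ranks variants by the chosen criterion and retains the top fraction:
#' lowest standard error for the SE criteria, highest count for the count
#' criteria (the directions implied by each filter's purpose). Ties are broken
#' by variant-label order, so results are deterministic. The returned set
#' always has exactly `ceiling(fraction * n)` variants.
#'
#' @param data Data frame with a `variant` column and a column named by
#'   `criterion`.
#' @param criterion One of `"se"` (random-effects standard error),
#'   `"fixed_se"`, `"input_count"`, `"total_count"`.
#' @param fraction Retention fraction in (0, 1]; e.g. `0.25` keeps the top
#'   quartile.
#' @return Character vector of retained variant labels.
#' @export
filter_variants <- function(data, criterion = c("se", "fixed_se",
                                                "input_count", "total_count"),
                            fraction) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data), "variant" %in% names(data))
  if (!criterion %in% names(data)) {
    stop("criterion column '", criterion, "' not available in data")
  }
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  values <- data[[criterion]]
  if (any(!is.finite(values))) {
    stop("criterion '", criterion, "' has non-finite values; filter input ",
         "must be restricted to scored variants")
  }
  decreasing <- criterion %in% c("input_count", "total_count")
  ord <- order(if (decreasing) -values else values, data$variant)
  keep <- ord[seq_len(ceiling(fraction * nrow(data)))]
  data$variant[keep]
}

#' Squared Pearson correlation between two replicates' scores
#'
#' Computed over the intersection of variants with finite scores in both
#' replicates; used to quantify replicate agreement before/after filtering.
#'
#' @param a,b Named numeric vectors of scores (names are variant labels).
#' @return Squared Pearson correlation coefficient.
#' @export
replicate_concordance <- function(a, b) {
  stopifnot(!is.null(names(a)), !is.null(names(b)))
  shared <- intersect(names(a)[is.finite(a)], names(b)[is.finite(b)])
  if (length(shared) < 3L) {
    stop("need at least three shared, finite-scored variants")
  }
  stats::cor(a[shared], b[shared])^2
}

#' z-test of a score against wild-type
#'
#' Under the null hypothesis that the variant behaves like wild-type its
#' score is 0, so `z = score / se` with a two-sided standard-normal p-value.
#' A zero standard error is degenerate: p is 0 when the score is nonzero
#' (flagged) and 1 when it is exactly 0.
#'
#' @param score,se Numeric vectors of scores and standard errors.
#' @return Data frame with columns `z`, `p`, `degenerate`.
#' @export
z_test_vs_wildtype <- function(score, se) {
  stopifnot(length(score) == length(se))
  if (any(se[is.finite(se)] < 0)) stop("standard errors must be nonnegative")
  z <- ifelse(se > 0, score / se, sign(score) * Inf)
  z[se == 0 & score == 0] <- 0
  data.frame(z = z, p = two_sided_p(score, se),
             degenerate = se == 0 & score != 0)
}

#' z-test comparing a variant between two conditions
#'
#' Tests whether a variant's functional consequence differs between
#' conditions: `z = (score_a - score_b) / sqrt(se_a^2 + se_b^2)`, two-sided.
#' No cross-condition score normalization is applied; the test assumes the
#' score distributions in the two conditions are roughly similar (recorded in
#' the result's `caveat` attribute).
#'
#' @param score_a,se_a Scores and standard errors in condition A.
#' @param score_b,se_b Scores and standard errors in condition B.
#' @return Data frame with columns `z`, `p`, `degenerate`.
#' @export
z_test_between_conditions <- function(score_a, se_a, score_b, se_b) {
  if (any(c(se_a, se_b)[is.finite(c(se_a, se_b))] < 0)) {
    stop("standard errors must be nonnegative")
  }
  diff <- score_a - score_b
  se <- sqrt(se_a^2 + se_b^2)
  out <- z_test_vs_wildtype(diff, se)
  attr(out, "caveat") <-
    "assumes score distributions are similar between conditions; no cross-condition normalization applied"
  out
}

#' Benjamini-Hochberg adjustment of raw p-values
#'
#' The scoring functions report raw p-values; this applies the
#' Benjamini-Hochberg step-up procedure for multiple-testing control.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Condition comparison report
#'
#' Joins combined scores from two conditions on variant label and reports the
#' between-condition z-test with BH-adjusted p-values.
#'
#' @param scores_a,scores_b Combined score data frames (with `variant`,
#'   `score`, `se` columns) for the two conditions.
#' @return Data frame with columns `variant`, `score_a`, `se_a`, `score_b`,
#'   `se_b`, `z`, `p_raw`, `p_adj`.
#' @export
compare_conditions <- function(scores_a, scores_b) {
  shared <- intersect(scores_a$variant, scores_b$variant)
  a <- scores_a[match(shared, scores_a$variant), ]
  b <- scores_b[match(shared, scores_b$variant), ]
  zt <- z_test_between_conditions(a$score, a$se, b$score, b$se)
  out <- data.frame(
    variant = shared, score_a = a$score, se_a = a$se,
    score_b = b$score, se_b = b$se, z = zt$z, p_raw = zt$p,
    p_adj = adjust_pvalues(zt$p), stringsAsFactors = FALSE
  )
  attr(out, "caveat") <- attr(zt, "caveat")
  out
}
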