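# Per-selection enrichment scores: Poisson-weighted least-squares regression
# of wild-type-normalized log ratios on normalized time (>= 3 timepoints), or
# the two-timepoint ratio score with a closed-form standard error.

check_counts <- function(...) {
  for (c in list(...)) {
    if (any(c < 0) || any(c != floor(c))) {
      stop("counts must be nonnegative integers")
    }
  }
}

#' Pseudocounted log ratio
#'
#' `ln((c_v + 1/2) / (c_ref + 1/2))`. The 1/2 pseudocount keeps the ratio
#' finite for very small counts. `c_ref` is the wild-type count under
#' wild-type normalization, or the filtered library size under library-size
#' normalization.
#'
#' @param c_v,c_ref Nonnegative integer counts (vectorized).
#' @return Numeric log ratio(s).
#' @export
log_ratio <- function(c_v, c_ref) {
  check_counts(c_v, c_ref)
  log((c_v + 0.5) / (c_ref + 0.5))
}

#' Poisson variance of a log ratio
#'
#' `1/(c_v + 1/2) + 1/(c_ref + 1/2)`, the approximate variance of the
#' pseudocounted log ratio under Poisson sampling of both counts. Its inverse
#' is the regression weight, so low-coverage timepoints are downweighted.
#'
#' @inheritParams log_ratio
#' @return Numeric variance(s), strictly positive.
#' @export
poisson_variance <- function(c_v, c_ref) {
  check_counts(c_v, c_ref)
  1 / (c_v + 0.5) + 1 / (c_ref + 0.5)
}

# Row-wise weighted least squares of M (variants x timepoints) on x.
# Returns slope, intercept, and slope SE where the nominal slope variance is
# scaled by the weighted residual mean square s^2 = sum(w e^2) / (n - 2).
wls_fit <- function(M, w, x) {
  M <- rbind(M)
  w <- rbind(w)
  n <- length(x)
  if (n < 3L) stop("weighted regression needs at least three timepoints")
  if (length(unique(x)) == 1L) stop("all timepoints identical; cannot regress")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  sw <- rowSums(w)
  swx <- as.vector(w %*% x)
  swx2 <- as.vector(w %*% x^2)
  swy <- rowSums(w * M)
  swxy <- as.vector((w * M) %*% x)
  d <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swx2 * swy - swx * swxy) / d
  resid <- M - (intercept + outer(slope, x))
  s2 <- pmax(rowSums(w * resid^2), 0) / (n - 2)
  se <- sqrt(s2 * sw / d)
  list(slope = slope, intercept = intercept, se = se)
}

two_sided_p <- function(score, se) {
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(score / se)),
              ifelse(score == 0, 1, 0))
  as.numeric(p)
}

#' Weighted regression enrichment score
#'
#' Fits `M_{v,t}` (wild-type-normalized log ratios) against the normalized
#' time axis `x_t = t / max(T)` by weighted least squares with weights
#' `1/V_{v,t}`. The score is the slope; the intercept is estimated but not
#' part of the score. The slope standard error scales the nominal weighted
#' variance by the weighted residual mean square `s^2 = sum(w e^2)/(n-2)`, so
#' it is zero for an exact fit. The p-value is a two-sided z-test of the slope
#' against 0 (the null that the variant behaves like wild-type).
#'
#' @param M Numeric matrix (variants x timepoints) or vector of log ratios.
#' @param V Matching matrix/vector of variances (see [poisson_variance()]).
#' @param x Normalized timepoints `t/max(T)` (length = number of timepoints).
#' @return Data frame with columns `score`, `se`, `p`.
#' @export
wls_score <- function(M, V, x) {
  fit <- wls_fit(rbind(M), 1 / rbind(V), x)
  data.frame(score = fit$slope, se = fit$se,
             p = two_sided_p(fit$slope, fit$se))
}

#' Two-timepoint ratio score
#'
#' For input/selected designs the score is the wild-type-adjusted log ratio
#' `L_v = ln((c_{v,sel}+1/2)/(c_{wt,sel}+1/2)) -
#' ln((c_{v,inp}+1/2)/(c_{wt,inp}+1/2))`, the slope of the line connecting the
#' two timepoints. Because there is no residual about a two-point line, the
#' standard error comes from Poisson assumptions:
#' `SE_v = sqrt(1/(c_{v,inp}+1/2) + 1/(c_{wt,inp}+1/2) +
#' 1/(c_{v,sel}+1/2) + 1/(c_{wt,sel}+1/2))`.
#'
#' @param c_v_inp,c_v_sel Variant counts at the input and selected timepoints
#'   (vectorized).
#' @param c_ref_inp,c_ref_sel Wild-type (or filtered-library-size) counts at
#'   the two timepoints.
#' @return Data frame with columns `score`, `se`, `p`.
#' @export
ratio_score <- function(c_v_inp, c_v_sel, c_ref_inp, c_ref_sel) {
  check_counts(c_v_inp, c_v_sel, c_ref_inp, c_ref_sel)
  L <- log_ratio(c_v_sel, c_ref_sel) - log_ratio(c_v_inp, c_ref_inp)
  se <- sqrt(1 / (c_v_inp + 0.5) + 1 / (c_ref_inp + 0.5) +
             1 / (c_v_sel + 0.5) + 1 / (c_ref_sel + 0.5))
  data.frame(score = L, se = se, p = two_sided_p(L, se))
}

#' Score every variant in a selection
#'
#' Dispatches to the weighted regression score (three or more timepoints) or
#' the ratio score (exactly two). Only variants present in the input
#' (`c_{v,0} > 0`) are scored; others are reported with `NA` score and method
#' `"unscored"`. Under wild-type normalization the reference counts are the
#' wild-type row; under library-size normalization they are the rounded
#' filtered library sizes, with the same pseudocount and variance formulas.
#'
#' @param table A [variant_count_table()].
#' @param normalization `"wildtype"` (default) or `"library"`.
#' @return Data frame with columns `variant`, `score`, `se`, `p`, `method`
#'   (`"wls"`, `"ratio"`, or `"unscored"`), `n_timepoints`.
#' @export
score_selection <- function(table, normalization = c("wildtype", "library")) {
  stopifnot(inherits(table, "variant_count_table"))
  normalization <- match.arg(normalization)
  counts <- table$counts
  nt <- ncol(counts)
  if (normalization == "wildtype") {
    if (!has_wildtype(table)) {
      stop("wild-type row '", table$wildtype,
           "' not present; wild-type normalization is not possible ",
           "(use normalization = \"library\")")
    }
    c_ref <- counts[table$wildtype, ]
  } else {
    c_ref <- round(filtered_library_size(table))
  }
  eligible <- counts[, 1] > 0
  method <- if (nt >= 3L) "wls" else "ratio"
  out <- data.frame(
    variant = rownames(counts), score = NA_real_, se = NA_real_, p = NA_real_,
    method = "unscored", n_timepoints = nt, stringsAsFactors = FALSE
  )
  if (any(eligible)) {
    cv <- counts[eligible, , drop = FALSE]
    if (nt >= 3L) {
      M <- log_ratio(cv, rep(c_ref, each = nrow(cv)))
      V <- poisson_variance(cv, rep(c_ref, each = nrow(cv)))
      sc <- wls_score(M, V, table$schedule$x)
    } else {
      sc <- ratio_score(cv[, 1], cv[, 2], c_ref[1], c_ref[2])
    }
    out$score[eligible] <- sc$score
    out$se[eligible] <- sc$se
    out$p[eligible] <- sc$p
    out$method[eligible] <- method
  }
  rownames(out) <- NULL
  attr(out, "normalization") <- normalization
  out
}

#' Write a per-selection or combined score table as TSV
#'
#' @param scores Data frame of scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
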