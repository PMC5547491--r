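# Combining replicate scores: a single-random-effect meta-analysis model fit
# by a fixed number of Fisher scoring iterations, plus the fixed-effect
# comparator.

as_rep_matrix <- function(x, name) {
  x <- rbind(x)
  if (ncol(x) < 2L) stop(name, " needs scores from at least two replicates; ",
                         "pass single-replicate scores through unchanged")
  x
}

#' Random-effects combination of replicate scores
#'
#' Combines per-replicate scores `beta_i` with standard errors `sigma_i` into
#' one score per variant using a meta-analysis model with a single random
#' effect, fit independently per variant by restricted maximum likelihood via
#' Fisher scoring. The between-replicate variance starts at the sample
#' variance of the replicate scores and is updated with the multiplicative
#' fixed-point rule; the combined score is recomputed each iteration as the
#' precision-weighted average with weights `(sigma_s^2 + sigma_i^2)^-1`. A
#' fixed number of iterations is run for all variants in parallel (testing
#' convergence per variant is slower); the last change in the variance
#' component `eps` is recorded and variants whose `|eps|` exceeds `tol` are
#' flagged as unconverged. The combined standard error
#' `sqrt(1 / sum((sigma_s^2 + sigma_i^2)^-1))` captures both within-selection
#' sampling error and between-replicate spread, so it is never smaller than
#' the fixed-effect standard error on the same inputs.
#'
#' Replicates with non-finite score or standard error are dropped per variant;
#' variants with fewer than two usable replicates get `NA` results.
#'
#' @param beta Numeric matrix (variants x replicates) of replicate scores, or
#'   a vector for a single variant.
#' @param se Matching matrix/vector of replicate standard errors.
#' @param iterations Number of Fisher scoring iterations (default 50).
#' @param tol Convergence flag threshold on `|eps|` (default 1e-6).
#' @return Data frame with columns `score`, `se`, `var_between` (the
#'   between-replicate variance component), `eps` (final-iteration change in
#'   `var_between`), `converged`, `p` (two-sided z-test against 0), and
#'   `n_reps`.
#' @export
random_effects <- function(beta, se, iterations = 50L, tol = 1e-6) {
  beta <- as_rep_matrix(beta, "random_effects")
  se <- as_rep_matrix(se, "random_effects")
  stopifnot(identical(dim(beta), dim(se)))
  if (any(se[is.finite(se)] < 0)) stop("standard errors must be nonnegative")
  mask <- is.finite(beta) & is.finite(se)
  n_v <- rowSums(mask)
  usable <- n_v >= 2L
  b <- ifelse(mask, beta, 0)
  # masked entries get a positive dummy variance so their weight is exactly 0
  # even when the between-replicate variance is 0
  s2 <- ifelse(mask, se^2, 1)

  bbar <- rowSums(b) / pmax(n_v, 1L)
  sigma2 <- rowSums(mask * (b - bbar)^2) / pmax(n_v - 1L, 1L)
  sigma2[!usable] <- NA_real_
  clamped <- rep(FALSE, nrow(beta))
  eps <- rep(NA_real_, nrow(beta))

  # Degenerate rows: every usable replicate has zero variance. If the scores
  # agree (e.g. the wild-type under wild-type normalization) the combined
  # score is exact with zero SE; weights would be infinite, so handle apart.
  degen <- usable & rowSums(mask * (se^2 > 0), na.rm = TRUE) == 0 & sigma2 == 0
  iter <- usable & !degen
  iter_idx <- which(iter)

  for (k in seq_len(iterations)) {
    w <- mask[iter, , drop = FALSE] /
      (sigma2[iter] + s2[iter, , drop = FALSE])
    sw <- rowSums(w)
    bhat <- rowSums(w * b[iter, , drop = FALSE]) / sw
    num <- rowSums(w^2 * (b[iter, , drop = FALSE] - bhat)^2)
    den <- sw - rowSums(w^2) / sw
    new_sigma2 <- sigma2[iter] * num / den
    neg <- !is.na(new_sigma2) & new_sigma2 < 0
    if (any(neg)) {
      new_sigma2[neg] <- 0
      clamped[iter_idx[neg]] <- TRUE
    }
    if (k == iterations) eps[iter] <- new_sigma2 - sigma2[iter]
    sigma2[iter] <- new_sigma2
  }

  score <- se_out <- rep(NA_real_, nrow(beta))
  if (any(iter)) {
    w <- mask[iter, , drop = FALSE] /
      (sigma2[iter] + s2[iter, , drop = FALSE])
    score[iter] <- rowSums(w * b[iter, , drop = FALSE]) / rowSums(w)
    se_out[iter] <- sqrt(1 / rowSums(w))
  }
  score[degen] <- bbar[degen]
  se_out[degen] <- 0
  eps[degen] <- 0
  # a replicate with zero SE while the variance component hits zero makes its
  # weight infinite: that replicate is then exact, so report it directly
  fix <- which(usable & !degen & !is.finite(score))
  for (r in fix) {
    zv <- mask[r, ] & se[r, ] == 0
    if (any(zv)) {
      score[r] <- mean(beta[r, zv])
      se_out[r] <- 0
      sigma2[r] <- 0
      eps[r] <- 0
    }
  }
  out <- data.frame(
    score = score, se = se_out, var_between = sigma2, eps = eps,
    converged = ifelse(is.na(eps), NA, abs(eps) <= tol),
    p = ifelse(is.na(score), NA_real_, two_sided_p(score, se_out)),
    n_reps = n_v
  )
  out$clamped <- clamped
  rownames(out) <- rownames(beta)
  out
}

#' Fixed-effect combination of replicate scores
#'
#' Inverse-variance-weighted average with standard error
#' `sqrt(1 / sum(sigma_i^-2))`. This ignores between-replicate heterogeneity
#' and underestimates uncertainty when replicates disagree; it is provided as
#' a comparison baseline for the random-effects model, not as a recommended
#' estimator.
#'
#' @inheritParams random_effects
#' @return Data frame with columns `score`, `se`, `p`.
#' @export
fixed_effect <- function(beta, se) {
  beta <- as_rep_matrix(beta, "fixed_effect")
  se <- as_rep_matrix(se, "fixed_effect")
  stopifnot(identical(dim(beta), dim(se)))
  mask <- is.finite(beta) & is.finite(se)
  if (any(se[mask] == 0)) {
    stop("fixed_effect requires strictly positive standard errors ",
         "(zero SE implies infinite weight)")
  }
  w <- ifelse(mask, 1 / se^2, 0)
  n_v <- rowSums(mask)
  sw <- rowSums(w)
  score <- ifelse(n_v >= 2L, rowSums(w * ifelse(mask, beta, 0)) / sw, NA_real_)
  se_out <- ifelse(n_v >= 2L, sqrt(1 / sw), NA_real_)
  out <- data.frame(score = score, se = se_out,
                    p = ifelse(is.na(score), NA_real_,
                               two_sided_p(score, se_out)))
  rownames(out) <- rownames(beta)
  out
}

#' Score replicate selections and combine them
#'
#' Convenience wrapper: aligns replicate count tables, scores each selection,
#' and combines the per-replicate scores with the random-effects model.
#'
#' @param tables List of [variant_count_table()]s (one per replicate).
#' @param normalization Passed to [score_selection()].
#' @param iterations,tol Passed to [random_effects()].
#' @return List with `replicates` (list of per-selection score data frames)
#'   and `combined` (data frame with a `variant` column plus the
#'   [random_effects()] output).
#' @export
score_replicates <- function(tables, normalization = "wildtype",
                             iterations = 50L, tol = 1e-6) {
  tables <- align_replicates(tables)
  per_rep <- lapply(tables, score_selection, normalization = normalization)
  variants <- per_rep[[1]]$variant
  beta <- do.call(cbind, lapply(per_rep, `[[`, "score"))
  se <- do.call(cbind, lapply(per_rep, `[[`, "se"))
  rownames(beta) <- rownames(se) <- variants
  combined <- random_effects(beta, se, iterations = iterations, tol = tol)
  combined <- cbind(variant = variants, combined)
  rownames(combined) <- NULL
  list(replicates = per_rep, combined = combined)
}
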