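# Dependent variables of the Monte-Carlo evaluation.

offdiag_upper <- function(m) m[upper.tri(m)]

#' Bias of estimated factor inter-correlations
#'
#' Mean, over the q(q-1)/2 factor pairs, of the difference between the
#' estimated (aligned) inter-correlations and the constant population
#' inter-correlation.
#'
#' @param phi_hat Aligned q x q estimated factor inter-correlation matrix.
#' @param phi_pop Scalar population inter-correlation.
#' @return A single number; negative values mean under-estimation.
#' @export
phi_bias <- function(phi_hat, phi_pop) {
  phi_hat <- as.matrix(phi_hat)
  if (nrow(phi_hat) < 2) abort("phi_bias needs at least two factors.")
  mean(offdiag_upper(phi_hat) - phi_pop)
}

#' Root mean square difference between two loading matrices
#'
#' \eqn{\sqrt{\mathrm{mean}((a - b)^2)}} over all p x q cells. With
#' `truncate_at_one = TRUE`, RMS values exceeding 1 are reported as 1 — the
#' convention used when summarizing subsample stability, where a rotation
#' that degenerates completely should not dominate the mean.
#'
#' @param a,b Aligned loading matrices of identical shape.
#' @param truncate_at_one Report values above 1 as 1.
#' @return A single nonnegative number.
#' @export
rms_difference <- function(a, b, truncate_at_one = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  out <- sqrt(mean((a - b)^2))
  if (truncate_at_one) out <- min(out, 1)
  out
}

#' Factor score indeterminacy of a rotated sample solution
#'
#' Computes regression factor-score predictors from the rotated solution —
#' weight matrix \eqn{W = R^{-1}\Lambda_O\Phi_O}, scores
#' \eqn{\hat\xi = X_{std} W} — and correlates each predictor with the
#' corresponding true common-factor scores carried by the synthetic sample.
#' High values mean the factor is well determined by the observed variables.
#'
#' @param sample A `synthetic_sample` (must carry true factor scores).
#' @param rotated A `target_rotation`, or a list with `pattern` and `phi`
#'   (aligned to the population factors of the generating model).
#' @return Numeric vector of length q of predictor-true correlations.
#' @export
factor_score_indeterminacy <- function(sample, rotated) {
  stopifnot(inherits(sample, "synthetic_sample"))
  pattern <- as.matrix(rotated$pattern)
  phi <- as.matrix(rotated$phi)
  r <- sample$corr
  s <- pattern %*% phi                      # factor structure
  w <- tryCatch(solve(r, s), error = function(e) NULL)
  if (is.null(w)) {
    warn("Singular sample correlation matrix; ridge-regularizing by 1e-8.")
    w <- solve(r + diag(1e-8, nrow(r)), s)
  }
  scores <- scale(sample$data) %*% w
  vapply(seq_len(ncol(pattern)),
         function(j) cor(scores[, j], sample$factor_scores[, j]),
         numeric(1))
}

#' Predictor-factor correlation under exact moment control
#'
#' The same predictor-true-factor correlation as
#' [factor_score_indeterminacy()], evaluated for score data generated under
#' exact moment control: when the observed scores exactly reproduce the
#' analyzed correlation matrix R and the true factor scores exactly satisfy
#' the population model moments (\eqn{X'\xi/n = \Lambda\Phi},
#' \eqn{\xi'\xi/n = \Phi}), the empirical Pearson correlation reduces to the
#' closed form
#' \deqn{\rho_j = (W'\Lambda_{pop}\Phi_{pop})_{jj} /
#'   \sqrt{(W'RW)_{jj}},\qquad W = R^{-1}\hat\Lambda\hat\Phi.}
#' The numerator is the population covariance of the predictor with the
#' factor; the denominator is the realized variance of the predictor, which
#' the sample-fitted weights inflate, so the statistic is free of the
#' incidental score-sampling noise of a finite raw sample while still
#' reflecting the quality of the estimated rotation. At the population
#' parameters it equals the closed-form determinacy
#' \eqn{\sqrt{\mathrm{diag}(\Phi\Lambda'\Sigma^{-1}\Lambda\Phi)}}.
#'
#' @param r Sample correlation matrix the solution was estimated from.
#' @param rotated A `target_rotation` or list with aligned `pattern`/`phi`.
#' @param model The generating `population_model`.
#' @return Numeric vector of length q.
#' @export
exact_moment_indeterminacy <- function(r, rotated, model) {
  stopifnot(inherits(model, "population_model"))
  pattern <- as.matrix(rotated$pattern)
  phi <- as.matrix(rotated$phi)
  r <- as.matrix(r)
  s <- pattern %*% phi
  w <- tryCatch(solve(r, s), error = function(e) solve(r + diag(1e-8, nrow(r)), s))
  num <- diag(crossprod(w, model$loadings %*% model$phi_matrix))
  den <- sqrt(diag(crossprod(w, r %*% w)))
  num / den
}

#' Stability of rotated solutions across subsamples
#'
#' For each subsample solution, aligns it to the total-sample solution and
#' computes the RMS difference of the loading patterns and of the
#' off-diagonal factor inter-correlations (both truncated at 1), then
#' summarizes across subsamples. Non-converged subsample solutions are
#' skipped and counted, never imputed.
#'
#' @param total_pattern,total_phi Rotated solution of the total sample (the
#'   alignment reference).
#' @param sub_patterns,sub_phis Lists of subsample patterns and
#'   inter-correlation matrices.
#' @param converged Optional logical vector flagging usable subsamples.
#' @return A list with `per_subsample` (tibble: subsample, rms_loadings,
#'   rms_phi) and `summary` (tibble: means, SDs, counts).
#' @export
subsample_stability <- function(total_pattern, total_phi, sub_patterns,
                                sub_phis, converged = NULL) {
  total_pattern <- as_loading_matrix(total_pattern)
  total_phi <- as.matrix(total_phi)
  stopifnot(length(sub_patterns) == length(sub_phis))
  m <- length(sub_patterns)
  if (is.null(converged)) converged <- rep(TRUE, m)
  rows <- purrr::map(seq_len(m), function(i) {
    if (!converged[i]) {
      return(tibble::tibble(subsample = i, rms_loadings = NA_real_,
                            rms_phi = NA_real_, converged = FALSE))
    }
    al <- align_to_population(sub_patterns[[i]], sub_phis[[i]], total_pattern)
    rms_l <- rms_difference(al$pattern, total_pattern, truncate_at_one = TRUE)
    d_phi <- offdiag_upper(al$phi) - offdiag_upper(total_phi)
    rms_p <- min(sqrt(mean(d_phi^2)), 1)
    tibble::tibble(subsample = i, rms_loadings = rms_l, rms_phi = rms_p,
                   converged = TRUE)
  })
  per <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(per, .data$converged)
  summary <- tibble::tibble(
    n_subsamples = m,
    n_converged = nrow(ok),
    mean_rms_loadings = mean(ok$rms_loadings),
    sd_rms_loadings = stats::sd(ok$rms_loadings),
    mean_rms_phi = mean(ok$rms_phi),
    sd_rms_phi = stats::sd(ok$rms_phi)
  )
  list(per_subsample = per, summary = summary)
}
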