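#' Condition number of a square matrix
#'
#' Ratio of the largest to the smallest singular value. A large value flags a
#' numerically unstable inversion, which the rotation pipeline mitigates with
#' a ridge constant.
#'
#' @param m A square numeric matrix.
#' @return A scalar >= 1; `Inf` when the smallest singular value is exactly 0.
#' @export
condition_kappa <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(is.finite(m)))
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) == 0) return(Inf)
  max(d) / min(d)
}

#' Tucker congruence between loading columns
#'
#' Column-wise cosine similarity \eqn{\sum a_i b_i / \sqrt{\sum a_i^2 \sum
#' b_i^2}} between two loading matrices of the same shape.
#'
#' @param a,b Loading matrices (or data frames) with identical dimensions.
#' @return Numeric vector of length q with one coefficient per column pair.
#' @examples
#' tucker_congruence(cbind(c(1, 0, 1)), cbind(c(1, 1, 1)))  # 2/sqrt(6)
#' @export
tucker_congruence <- function(a, b) {
  a <- as_loading_matrix(a); b <- as_loading_matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  zero <- which(na == 0 | nb == 0)
  if (length(zero) > 0) {
    abort(paste0("Zero-norm column(s), congruence undefined: ",
                 paste(zero, collapse = ", ")))
  }
  colSums(a * b) / (na * nb)
}

#' Orthogonal target (Procrustes) rotation
#'
#' Finds the orthogonal matrix M minimizing \eqn{\|\Lambda_u M -
#' \Lambda_T\|^2} via the singular value decomposition of
#' \eqn{\Lambda_u'\Lambda_T}, and applies it.
#'
#' @param lam_u Unrotated (orthogonal) loading matrix.
#' @param target Binary target pattern of the same shape.
#' @return A list with `lambda1` (the rotated loadings `lam_u %*% rotation`)
#'   and `rotation` (the q x q orthogonal matrix).
#' @export
orthogonal_target_rotation <- function(lam_u, target) {
  lam_u <- as_loading_matrix(lam_u)
  target <- as_loading_matrix(target)
  stopifnot(all(dim(lam_u) == dim(target)))
  s <- svd(crossprod(lam_u, target))
  if (min(s$d) < 1e-12 * max(s$d, 1e-300)) {
    warn("Degenerate singular values in orthogonal target rotation; the SVD branch taken is arbitrary (downstream alignment makes the solution canonical).")
  }
  m <- s$u %*% t(s$v)
  lam1 <- lam_u %*% m
  dimnames(lam1) <- dimnames(lam_u)
  list(lambda1 = lam1, rotation = m)
}

#' Block-wise salient-weighted mean loadings
#'
#' For each block of salient loadings defined by the 0/1 target, computes the
#' mean loading of the block on every factor, weighting each variable by its
#' own salient loading:
#' \deqn{\Lambda_{1m} = [(\Lambda_1 \circ \Lambda_T)'\Lambda_T]^{-1}
#'   [(\Lambda_1 \circ \Lambda_T)'\Lambda_1],}
#' where \eqn{\circ} is the Hadamard product. Row j of the resulting q x q
#' matrix holds block j's weighted mean salient loading (diagonal) and
#' weighted mean cross-loadings (off-diagonal); the latter are exactly zero
#' whenever positive and negative cross-loadings balance within the block.
#'
#' @param lam1 Orthogonally target-rotated loadings.
#' @param target Binary target pattern.
#' @return A q x q matrix of weighted block means.
#' @export
block_mean_loadings <- function(lam1, target) {
  lam1 <- as_loading_matrix(lam1)
  target <- as_loading_matrix(target)
  stopifnot(all(dim(lam1) == dim(target)))
  w <- lam1 * target
  denom <- crossprod(w, target)                 # diagonal: per-block salient sums
  small <- which(abs(diag(denom)) < 1e-12)
  if (length(small) > 0) {
    abort(paste0("Salient-loading sum is zero for factor(s) ",
                 paste(small, collapse = ", "),
                 "; block means are undefined."))
  }
  # left-divide by the per-block salient sums so that row j holds block j's
  # weighted mean loadings on every factor
  lam1m <- solve(denom, crossprod(w, lam1))
  dimnames(lam1m) <- list(colnames(target), colnames(target))
  lam1m
}

#' Least-squares oblique transformation toward a target
#'
#' Solves the (optionally ridged) normal equations
#' \eqn{T = (S'S + c I)^{-1} S' \,\mathrm{target}} and column-normalizes:
#' \eqn{T_n = T\,\mathrm{diag}(T'T)^{-1/2}}. The condition number reported is
#' that of \eqn{S'S} before ridging.
#'
#' @param source Source matrix S (q x q block means, or the full p x q
#'   loadings for conventional target rotation).
#' @param target Target matrix of conforming shape.
#' @param ridge Nonnegative ridge constant added to the diagonal before
#'   inversion.
#' @return A list with `T`, `Tn` (unit-norm columns), `kappa`, `ridge`.
#' @export
oblique_transform <- function(source, target, ridge = 0) {
  stopifnot(is.numeric(source), is.numeric(target), ridge >= 0)
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target))
  sts <- crossprod(source)
  kappa <- condition_kappa(sts)
  a <- sts + diag(ridge, ncol(source))
  tr <- tryCatch(solve(a, crossprod(source, target)), error = function(e) NULL)
  if (is.null(tr)) {
    abort(sprintf(
      "Source cross-product is singular even after ridging (kappa = %.3g, ridge = %g).",
      kappa, ridge))
  }
  norms <- sqrt(diag(crossprod(tr)))
  if (any(norms < 1e-300)) abort("Transformation has a zero column; cannot normalize.")
  tn <- tr %*% diag(1 / norms, ncol(tr))
  list(T = tr, Tn = tn, kappa = kappa, ridge = ridge)
}

#' Apply a normalized oblique transformation to a loading matrix
#'
#' Produces the reference structure \eqn{\Lambda_2 = \Lambda_1 T_n}, the
#' pattern \eqn{\Lambda_O = \Lambda_2\,
#' \mathrm{diag}((T_n'T_n)^{-1})^{1/2}} and the factor inter-correlations
#' \eqn{\Phi_O = (\Lambda_O'\Lambda_O)^{-1}\Lambda_O'
#' (\Lambda_u\Lambda_u')\Lambda_O(\Lambda_O'\Lambda_O)^{-1}}. \eqn{\Phi_O} is
#' symmetrized and its diagonal forced to 1 (machine-precision cleanup; the
#' maximum adjustment is recorded as an attribute).
#'
#' @param lam1 Loadings to rotate (orthogonally pre-rotated for the mean-target
#'   path, the unrotated loadings for the conventional path).
#' @param lam_u Unrotated loadings defining the common part
#'   \eqn{\Lambda_u\Lambda_u'}.
#' @param tn Normalized transformation matrix (field `Tn` of
#'   [oblique_transform()]).
#' @return A list with `lambda2`, `pattern`, `phi`.
#' @export
apply_oblique <- function(lam1, lam_u, tn) {
  lam1 <- as_loading_matrix(lam1); lam_u <- as_loading_matrix(lam_u)
  tn <- as.matrix(tn)
  lam2 <- lam1 %*% tn
  g <- tryCatch(solve(crossprod(tn)), error = function(e) NULL)
  if (is.null(g)) abort("Normalized transformation is singular.")
  pattern <- lam2 %*% diag(sqrt(diag(g)), ncol(tn))
  ppi <- tryCatch(solve(crossprod(pattern)), error = function(e) NULL)
  if (is.null(ppi)) abort("Degenerate pattern: pattern cross-product is singular.")
  proj <- ppi %*% crossprod(pattern, lam_u)
  phi <- tcrossprod(proj)
  adj <- max(abs(phi - t(phi)) / 2, abs(diag(phi) - 1))
  phi <- (phi + t(phi)) / 2
  diag(phi) <- 1
  dimnames(lam2) <- dimnames(pattern) <- dimnames(lam1)
  dimnames(phi) <- list(colnames(lam1), colnames(lam1))
  attr(phi, "max_adjustment") <- adj
  list(lambda2 = lam2, pattern = pattern, phi = phi)
}

# Orient a rotated solution against its target: permute columns to maximize
# absolute diagonal congruence with the target, then reflect each factor so
# its salient-weighted mean loading is positive. Rotation is sign- and
# permutation-indeterminate; this makes reported solutions canonical.
orient_to_target <- function(pattern, lambda2, phi, tn, target) {
  mt <- match_columns(pattern, target)
  perm <- mt$perm; signs <- mt$signs
  # reflection criterion: salient-weighted mean loading positive
  pat <- pattern[, perm, drop = FALSE] %*% diag(signs, length(signs))
  sal <- colSums(pat * target)
  flip <- ifelse(sal < 0, -1, 1)
  signs <- signs * flip
  d <- diag(signs, length(signs))
  out <- list(
    pattern = pattern[, perm, drop = FALSE] %*% d,
    lambda2 = lambda2[, perm, drop = FALSE] %*% d,
    tn      = tn[, perm, drop = FALSE] %*% d,
    phi     = d %*% phi[perm, perm, drop = FALSE] %*% d,
    perm    = perm, signs = signs
  )
  dimnames(out$pattern) <- dimnames(out$lambda2) <- dimnames(pattern)
  dimnames(out$phi) <- list(colnames(target), colnames(target))
  attr(out$phi, "max_adjustment") <- attr(phi, "max_adjustment")
  out
}

# Default ridge search grid (used when kappa exceeds ridge_threshold).
default_ridge_grid <- function() c(0, seq(0.001, 0.01, by = 0.001), seq(0.02, 0.30, by = 0.01))

# Shared back end of ot_rotate()/omt_rotate(): given the source matrix for
# the least-squares transform and its target, run the transform over the
# ridge grid (only when ill-conditioned), apply it to `lam1`, orient, and
# keep the candidate with the largest mean Tucker congruence with `target`.
rotate_engine <- function(lam_u, lam1, source, source_target, target,
                          ridge_threshold, ridge_grid, method, lambda1m = NULL) {
  kappa <- condition_kappa(crossprod(source))
  ridges <- if (is.finite(kappa) && kappa <= ridge_threshold) 0 else ridge_grid
  best <- NULL
  for (c0 in ridges) {
    tr <- tryCatch(oblique_transform(source, source_target, ridge = c0),
                   error = function(e) NULL)
    if (is.null(tr)) next
    ob <- tryCatch(apply_oblique(lam1, lam_u, tr$Tn), error = function(e) NULL)
    if (is.null(ob)) next
    ori <- orient_to_target(ob$pattern, ob$lambda2, ob$phi, tr$Tn, target)
    cong <- mean(tucker_congruence(ori$pattern, target))
    if (is.null(best) || cong > best$congruence) {
      best <- list(tr = tr, ori = ori, congruence = cong, ridge = c0)
    }
  }
  if (is.null(best)) {
    abort(sprintf("No valid oblique solution found (kappa = %.3g).", kappa))
  }
  structure(
    list(
      method = method,
      lambda_u = lam_u,
      lambda1 = lam1,
      lambda1m = lambda1m,
      target = target,
      transform = list(T = best$tr$T, Tn = best$ori$tn, kappa = kappa,
                       ridge = best$ridge),
      lambda2 = best$ori$lambda2,
      pattern = best$ori$pattern,
      phi = best$ori$phi,
      congruence = best$congruence
    ),
    class = "target_rotation"
  )
}

#' Oblique Mean-Target rotation (OMT)
#'
#' Rotates an unrotated loading matrix toward an independent-clusters target
#' by (1) orthogonal target rotation, (2) collapsing each block of salient
#' loadings to its salient-weighted mean loadings, (3) least-squares oblique
#' rotation of the q x q block-mean matrix toward the identity, and (4)
#' applying the resulting normalized transformation to the complete loading
#' matrix. Minimizing block *means* rather than single cross-loadings damps
#' the influence of sampling error on the rotated pattern and on the factor
#' inter-correlations.
#'
#' When the block-mean cross-product is ill-conditioned (condition number
#' above `ridge_threshold`) a grid of ridge constants is tried and the
#' solution with the largest mean Tucker congruence with the target is
#' retained.
#'
#' @param lam_u Unrotated loading matrix (matrix or labelled data frame).
#' @param target `NULL` or `"icm"` for the uniform independent-clusters
#'   pattern (requires q to divide p), or a custom 0/1 pattern.
#' @param ridge_threshold Condition-number trigger for the ridge search.
#' @param ridge_grid Candidate ridge constants.
#' @return A `target_rotation` object; see [tidy.target_rotation()] and
#'   [glance.target_rotation()].
#' @examples
#' lam <- population_example_loadings()
#' fit <- omt_rotate(lam)
#' glance(fit)
#' @export
omt_rotate <- function(lam_u, target = NULL, ridge_threshold = 1e4,
                       ridge_grid = default_ridge_grid()) {
  lam_u <- as_loading_matrix(lam_u)
  tgt <- resolve_target(target, nrow(lam_u), ncol(lam_u))
  ortho <- orthogonal_target_rotation(lam_u, tgt)
  lam1m <- block_mean_loadings(ortho$lambda1, tgt)
  rotate_engine(lam_u, ortho$lambda1, source = lam1m,
                source_target = diag(ncol(lam_u)), target = tgt,
                ridge_threshold = ridge_threshold, ridge_grid = ridge_grid,
                method = "OMT", lambda1m = lam1m)
}

#' Conventional complete oblique Target rotation (OT)
#'
#' Least-squares oblique rotation of the unrotated loadings toward a fully
#' specified 0/1 target pattern: the transformation is fit to the single
#' loadings (every cell of the target specified), normalized, and applied to
#' the full matrix, yielding the rotated pattern and the implied factor
#' inter-correlations.
#'
#' @inheritParams omt_rotate
#' @return A `target_rotation` object.
#' @examples
#' fit <- ot_rotate(population_example_loadings())
#' round(fit$phi, 2)
#' @export
ot_rotate <- function(lam_u, target = NULL, ridge_threshold = 1e4,
                      ridge_grid = default_ridge_grid()) {
  lam_u <- as_loading_matrix(lam_u)
  tgt <- resolve_target(target, nrow(lam_u), ncol(lam_u))
  rotate_engine(lam_u, lam_u, source = lam_u, source_target = tgt,
                target = tgt, ridge_threshold = ridge_threshold,
                ridge_grid = ridge_grid, method = "OT")
}

#' Rotate a loading matrix toward a simple-structure target
#'
#' Tibble-friendly front end dispatching to [omt_rotate()] or [ot_rotate()].
#'
#' @param loadings Unrotated loadings: a labelled data frame (first column
#'   variable labels) or a numeric matrix.
#' @param method `"omt"` (mean-target, the default) or `"ot"` (conventional
#'   complete target rotation).
#' @inheritParams omt_rotate
#' @return A `target_rotation` object.
#' @export
rotate_target <- function(loadings, method = c("omt", "ot"), target = NULL,
                          ridge_threshold = 1e4,
                          ridge_grid = default_ridge_grid()) {
  method <- match.arg(method)
  fn <- if (method == "omt") omt_rotate else ot_rotate
  fn(as_loading_matrix(loadings), target = target,
     ridge_threshold = ridge_threshold, ridge_grid = ridge_grid)
}

#' @export
print.target_rotation <- function(x, digits = 2, ...) {
  cat(sprintf("%s rotation: %d variables, %d factors\n",
              x$method, nrow(x$pattern), ncol(x$pattern)))
  cat(sprintf("kappa = %.3g, ridge = %g, mean congruence with target = %.3f\n",
              x$transform$kappa, x$transform$ridge, x$congruence))
  cat("\nPattern loadings:\n")
  print(round(x$pattern, digits))
  cat("\nFactor inter-correlations:\n")
  print(round(x$phi, digits))
  invisible(x)
}
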