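# Sample generation and least-squares factor extraction.

#' Simulate a multivariate-normal sample with known true factor scores
#'
#' Draws common-factor scores \eqn{\xi \sim N(0, \Phi)} and unique scores
#' \eqn{\delta \sim N(0, I)} independently and forms the observed scores
#' \eqn{x = \xi\Lambda' + \delta\,\mathrm{diag}(\Psi)}. Keeping the true
#' factor scores makes the factor-score indeterminacy statistic computable
#' for every replication.
#'
#' @param model A `population_model` from [build_population()].
#' @param n Sample size (>= 10).
#' @param seed Integer RNG seed; the sample is fully reproducible from it.
#' @return A `synthetic_sample` list with `data` (n x p), `factor_scores`
#'   (n x q), `unique_scores` (n x p), `corr` (sample Pearson correlations)
#'   and `seed`.
#' @export
simulate_sample <- function(model, n, seed) {
  stopifnot(inherits(model, "population_model"), n >= 10)
  lam <- model$loadings
  p <- nrow(lam); q <- ncol(lam)
  if (n < p) warn(sprintf("n = %d < p = %d: the sample correlation matrix is singular.", n, p))
  set.seed(as.integer(seed))
  xi <- matrix(rnorm(n * q), n, q) %*% chol(model$phi_matrix)
  delta <- matrix(rnorm(n * p), n, p)
  x <- xi %*% t(lam) + delta %*% diag(sqrt(model$uniqueness))
  colnames(x) <- rownames(lam); colnames(xi) <- colnames(lam)
  structure(
    list(data = x, factor_scores = xi, unique_scores = delta,
         corr = cor(x), seed = as.integer(seed)),
    class = "synthetic_sample"
  )
}

#' Draw a sample correlation matrix directly (Wishart fast path)
#'
#' For bias/RMS-only runs where true factor scores are not needed, a sample
#' covariance can be drawn from the Wishart distribution implied by the
#' population correlation matrix and rescaled to a correlation matrix.
#'
#' @inheritParams simulate_sample
#' @return A p x p sample correlation matrix.
#' @export
simulate_corr_wishart <- function(model, n, seed) {
  stopifnot(inherits(model, "population_model"), n > nrow(model$loadings))
  set.seed(as.integer(seed))
  w <- rWishart(1, df = n - 1, Sigma = model$sigma)[, , 1] / (n - 1)
  cov2cor(w)
}

# squared multiple correlations (start values for communalities)
smc <- function(r) {
  ri <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(ri)) ri <- solve(r + diag(1e-6, nrow(r)))
  1 - 1 / diag(ri)
}

# Assemble loadings from the reduced correlation matrix at given
# uniquenesses: eigenvectors scaled by the square roots of the leading
# eigenvalues (clipped at zero).
loadings_from_reduced <- function(r, u, q) {
  rr <- r; diag(rr) <- 1 - u
  e <- eigen(rr, symmetric = TRUE)
  lam <- e$vectors[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(q)], 0)), q)
  rownames(lam) <- rownames(r)
  lam
}

finish_extraction <- function(r, lam, converged, iterations, method) {
  # order columns by explained variance, orient so the column sum is >= 0
  ss <- colSums(lam^2)
  lam <- lam[, order(ss, decreasing = TRUE), drop = FALSE]
  sgn <- ifelse(colSums(lam) < 0, -1, 1)
  lam <- lam %*% diag(sgn, ncol(lam))
  colnames(lam) <- paste0("F", seq_len(ncol(lam)))
  h <- pmin(rowSums(lam^2), 0.998)
  structure(
    list(loadings_u = lam, communalities = h, converged = converged,
         iterations = iterations, method = method),
    class = "efa_extraction"
  )
}

#' Unweighted least squares (minres) factor extraction
#'
#' Minimizes the sum of squared residuals of the reduced correlation matrix
#' over the uniquenesses: for fixed uniquenesses u the best rank-q
#' approximation of R - diag(u) leaves a residual whose squared Frobenius
#' norm is the sum of the squared trailing eigenvalues, which gives both the
#' objective and its analytic gradient
#' \eqn{\partial F/\partial u_i = -2\sum_{j>q}\lambda_j v_{ij}^2} from a
#' single eigendecomposition. Optimized with box-constrained quasi-Newton
#' (L-BFGS-B), squared-multiple-correlation start values, and a Heywood
#' guard clipping communalities at 0.998.
#'
#' @param r Sample correlation matrix (symmetric, unit diagonal).
#' @param q Number of factors to extract (the true number, in the
#'   simulations).
#' @return An `efa_extraction` with `loadings_u` (columns ordered by
#'   explained variance), `communalities`, `converged`, `iterations`.
#' @export
extract_uls <- function(r, q) {
  r <- as.matrix(r)
  p <- nrow(r)
  stopifnot(ncol(r) == p, q >= 1, q < p)
  stopifnot(max(abs(diag(r) - 1)) < 1e-8)
  idx <- seq_len(q)
  objective <- function(u) {
    rr <- r; diag(rr) <- 1 - u
    ev <- eigen(rr, symmetric = TRUE, only.values = TRUE)$values
    sum(ev[-idx]^2)
  }
  gradient <- function(u) {
    rr <- r; diag(rr) <- 1 - u
    e <- eigen(rr, symmetric = TRUE)
    tailv <- e$vectors[, -idx, drop = FALSE]
    taill <- e$values[-idx]
    -2 * as.vector((tailv^2) %*% taill)
  }
  start <- pmin(pmax(1 - smc(r), 0.002), 1)
  opt <- optim(start, objective, gradient, method = "L-BFGS-B",
               lower = 0.002, upper = 1,
               control = list(maxit = 500, factr = 1e4))
  lam <- loadings_from_reduced(r, opt$par, q)
  finish_extraction(r, lam, converged = opt$convergence == 0,
                    iterations = opt$counts[["function"]], method = "ULS")
}

#' Principal axis factoring
#'
#' Iterated eigendecomposition of the reduced correlation matrix with
#' squared-multiple-correlation start values: communalities are updated from
#' the current loadings until the largest change falls below `tol` or
#' `max_iter` iterations, with the same Heywood guard as [extract_uls()].
#'
#' @inheritParams extract_uls
#' @param tol Convergence tolerance on the communalities.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   (the result is still returned).
#' @return An `efa_extraction`.
#' @export
extract_paf <- function(r, q, tol = 1e-6, max_iter = 200) {
  r <- as.matrix(r)
  p <- nrow(r)
  stopifnot(ncol(r) == p, q >= 1, q < p)
  h <- pmin(pmax(smc(r), 0), 0.998)
  converged <- FALSE
  iter <- 0
  lam <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    lam <- loadings_from_reduced(r, 1 - h, q)
    hnew <- pmin(rowSums(lam^2), 0.998)
    if (max(abs(hnew - h)) < tol) {
      h <- hnew; converged <- TRUE
      break
    }
    h <- hnew
  }
  finish_extraction(r, lam, converged = converged, iterations = iter,
                    method = "PAF")
}

#' @export
print.efa_extraction <- function(x, digits = 3, ...) {
  cat(sprintf("%s extraction: %d variables, %d factors, %sconverged (%d iterations)\n",
              x$method, nrow(x$loadings_u), ncol(x$loadings_u),
              if (x$converged) "" else "NOT ", x$iterations))
  print(round(x$loadings_u, digits))
  invisible(x)
}
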