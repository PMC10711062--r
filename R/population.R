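# Population factor models for the Monte-Carlo design.
#
# The simulation sweeps correlated independent-clusters models (ICM: all
# population cross-loadings zero) and zero-mean cross-loading models (ZCLM:
# balanced non-zero cross-loadings whose block-wise means are ~0) over a
# crossed design: number of factors q, salient loadings per factor p/q,
# salient loading level, cross-loading regime, factor inter-correlation phi,
# and sample size n.

# Printed salient-loading ramps (mean = level, SD ~ 0.08).
.salient_table <- list(
  "5_0.5" = c(.40, .45, .50, .55, .60),
  "5_0.7" = c(.60, .65, .70, .75, .80),
  "8_0.5" = c(.38, .42, .45, .48, .52, .55, .58, .62),
  "8_0.7" = c(.58, .62, .65, .68, .72, .75, .78, .82)
)

# Balanced non-zero cross-loading columns: largest |entry| is one third of
# the mean salient loading, signs alternate, magnitudes decay, column mean
# close to (but deliberately not exactly) zero. The p/q = 5 vectors are the
# published ones; the p/q = 8 vectors follow the same construction rules and
# are frozen here (and in inst/extdata) for reproducibility.
.cross_table <- list(
  "5_0.5" = c(.17, -.08, .06, -.04, .03),
  "5_0.7" = c(.23, -.12, .08, -.06, .05),
  "8_0.5" = c(.17, -.12, .09, -.07, .06, -.05, .04, -.03),
  "8_0.7" = c(.23, -.17, .13, -.10, .08, -.07, .06, -.04)
)

#' Salient loading vector for a design cell
#'
#' Returns the fixed ramp of salient loadings used in a simulation cell.
#' The four canonical cells (p/q in \{5, 8\} crossed with loading level in
#' \{0.50, 0.70\}) return the frozen study vectors; other combinations are
#' only available with `extended = TRUE`, where an arithmetic ramp with the
#' requested mean and an SD of about 0.08 is generated.
#'
#' @param p_per_q Number of salient loadings per factor.
#' @param level Mean salient loading.
#' @param extended Allow levels outside the canonical design.
#' @return Numeric vector of length `p_per_q`.
#' @export
salient_vector <- function(p_per_q, level, extended = FALSE) {
  key <- paste0(p_per_q, "_", level)
  if (!is.null(.salient_table[[key]])) return(.salient_table[[key]])
  if (!extended) {
    abort(sprintf("No canonical salient vector for p/q = %s, level = %s; use extended = TRUE.",
                  p_per_q, level))
  }
  x <- seq(-1, 1, length.out = p_per_q)
  level + x * 0.08 / stats::sd(x)
}

#' Cross-loading vector for a design cell
#'
#' Balanced non-zero cross-loadings for the zero-mean cross-loading model:
#' largest absolute entry one third of the mean salient loading, alternating
#' signs, decaying magnitudes, near-zero mean. Multiplying the vector by -1
#' (see `flip_schedule` in [build_population()]) yields a different pattern
#' with the same properties.
#'
#' @inheritParams salient_vector
#' @return Numeric vector of length `p_per_q`.
#' @export
cross_vector <- function(p_per_q, level, extended = FALSE) {
  key <- paste0(p_per_q, "_", level)
  if (!is.null(.cross_table[[key]])) return(.cross_table[[key]])
  if (!extended) {
    abort(sprintf("No canonical cross-loading vector for p/q = %s, level = %s; use extended = TRUE.",
                  p_per_q, level))
  }
  base <- .cross_table[["5_0.5"]]
  v <- base[((seq_len(p_per_q) - 1) %% 5) + 1] * (level / 0.5)
  round(v, 2)
}

#' Specify one cell of the simulation design
#'
#' Validates a single condition against the canonical design levels
#' (q in \{3, 6, 9, 12\}, p/q in \{5, 8\}, loading level in \{0.50, 0.70\},
#' cross-loadings zero or nonzero, phi in \{0, 0.25, 0.50\}, n in
#' \{100, 150, 200, 300, 500\}); `extended = TRUE` lifts the restriction.
#'
#' @param q Number of factors.
#' @param p_per_q Salient loadings per factor.
#' @param loading Mean salient loading level.
#' @param cross `"zero"` or `"nonzero"` population cross-loadings.
#' @param phi Population factor inter-correlation (constant off-diagonal).
#' @param n Sample size.
#' @param extended Allow values outside the canonical design.
#' @return A one-row tibble (a `condition` record).
#' @export
condition_spec <- function(q, p_per_q, loading, cross = c("zero", "nonzero"),
                           phi = 0, n = 100, extended = FALSE) {
  cross <- match.arg(cross)
  if (!extended) {
    ok <- q %in% c(3, 6, 9, 12) && p_per_q %in% c(5, 8) &&
      loading %in% c(0.5, 0.7) && phi %in% c(0, 0.25, 0.5) &&
      n %in% c(100, 150, 200, 300, 500)
    if (!ok) {
      abort("Condition outside the canonical design levels; use extended = TRUE.")
    }
  }
  stopifnot(q >= 1, p_per_q >= 2, phi >= 0, phi < 1, n >= 10)
  tibble::tibble(q = q, p_per_q = p_per_q, loading = loading,
                 cross = cross, phi = phi, n = n)
}

#' The crossed condition grid of the simulation design
#'
#' All combinations of the supplied levels, defaulting to the full canonical
#' design (480 cells).
#'
#' @param q,p_per_q,loading,cross,phi,n Design levels to cross.
#' @param extended Allow values outside the canonical design.
#' @return A tibble with one row per condition and a `condition` id column.
#' @export
condition_grid <- function(q = c(3, 6, 9, 12), p_per_q = c(5, 8),
                           loading = c(0.5, 0.7), cross = c("zero", "nonzero"),
                           phi = c(0, 0.25, 0.5), n = c(100, 150, 200, 300, 500),
                           extended = FALSE) {
  grid <- tidyr::expand_grid(q = q, p_per_q = p_per_q, loading = loading,
                             cross = cross, phi = phi, n = n)
  # validate each row through condition_spec
  purrr::pwalk(grid, function(q, p_per_q, loading, cross, phi, n) {
    condition_spec(q, p_per_q, loading, cross, phi, n, extended = extended)
  })
  dplyr::mutate(grid, condition = dplyr::row_number(), .before = 1)
}

#' Construct a population factor model for one condition
#'
#' Builds the population loading pattern (contiguous salient blocks; for the
#' zero-mean cross-loading model, block j additionally carries the
#' cross-loading vector on the cyclically next factor, with every second
#' block's vector multiplied by -1 so the design is balanced), the
#' compound-symmetric factor inter-correlation matrix
#' \eqn{\Phi = (1-\phi)I + \phi 11'}, uniquenesses \eqn{\Psi^2 = I -
#' \mathrm{diag}(\Lambda\Phi\Lambda')} and the model-implied correlation
#' matrix \eqn{\Sigma = \Lambda\Phi\Lambda' + \Psi^2} (unit diagonal by
#' construction).
#'
#' @param cond A one-row condition tibble from [condition_spec()], or a list
#'   with fields `q`, `p_per_q`, `loading`, `cross`, `phi`.
#' @param flip_schedule Optional vector of +1/-1 of length q overriding the
#'   default alternating sign applied to each block's cross-loading vector.
#' @param extended Passed to the loading-vector constructors.
#' @return A `population_model` list with `loadings`, `phi_matrix`,
#'   `uniqueness`, `sigma` and the condition fields.
#' @export
build_population <- function(cond, flip_schedule = NULL, extended = FALSE) {
  q <- cond$q; ppq <- cond$p_per_q; level <- cond$loading
  cross <- cond$cross; phi <- cond$phi
  p <- q * ppq
  sal <- salient_vector(ppq, level, extended = extended)
  lam <- matrix(0, p, q, dimnames = list(paste0("x", seq_len(p)),
                                         paste0("F", seq_len(q))))
  if (is.null(flip_schedule)) flip_schedule <- ifelse(seq_len(q) %% 2 == 0, -1, 1)
  stopifnot(length(flip_schedule) == q, all(flip_schedule %in% c(-1, 1)))
  for (j in seq_len(q)) {
    rows <- ((j - 1) * ppq + 1):(j * ppq)
    lam[rows, j] <- sal
    if (cross == "nonzero" && q > 1) {
      k <- (j %% q) + 1
      lam[rows, k] <- flip_schedule[j] * cross_vector(ppq, level, extended = extended)
    }
  }
  phim <- matrix(phi, q, q); diag(phim) <- 1
  common <- lam %*% phim %*% t(lam)
  psi2 <- 1 - diag(common)
  if (any(psi2 <= 0)) {
    bad <- which(psi2 <= 0)
    abort(paste0("Population Heywood case: communality >= 1 for variable(s) ",
                 paste(rownames(lam)[bad], collapse = ", ")))
  }
  sigma <- common + diag(psi2)
  dimnames(sigma) <- list(rownames(lam), rownames(lam))
  dimnames(phim) <- list(colnames(lam), colnames(lam))
  structure(
    list(loadings = lam, phi_matrix = phim, uniqueness = psi2, sigma = sigma,
         q = q, p_per_q = ppq, loading = level, cross = cross, phi = phi),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population %s model: p = %d, q = %d, salient level %.2f, phi = %.2f\n",
              if (x$cross == "zero") "ICM" else "ZCLM",
              nrow(x$loadings), x$q, x$loading, x$phi))
  invisible(x)
}

#' Closed-form factor score determinacy of a population model
#'
#' The correlation between the best linear factor-score predictor
#' (regression scores) and the factor itself, at the population parameters:
#' \eqn{\rho = \sqrt{\mathrm{diag}(\Phi\Lambda'\Sigma^{-1}\Lambda\Phi)}}.
#' Serves as the analytic benchmark for the sample indeterminacy statistic.
#'
#' @param model A `population_model`.
#' @return Numeric vector of length q.
#' @export
population_determinacy <- function(model) {
  s <- model$phi_matrix %*% t(model$loadings)   # q x p structure (transposed)
  sqrt(diag(s %*% solve(model$sigma, t(s))))
}
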