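# In-package reference matrices: the published population example (18
# variables, 3 factors, balanced +/-0.20 cross-loadings) and the 9 x 3
# population pattern illustrating how a factor inter-correlation surfaces as
# shared positive cross-loadings of the corresponding orthogonal factors.

#' Population example: initial orthogonal loadings
#'
#' An 18 x 3 orthogonal loading matrix with three blocks of six variables:
#' salient loadings of 0.50 and within-block cross-loadings alternating
#' between +0.20 and -0.20, so every block's mean cross-loading is exactly
#' zero. Mean-target rotation leaves this matrix unchanged (its block means
#' are already an identity pattern), while conventional complete target
#' rotation shrinks the negative cross-loadings at the price of negative
#' factor inter-correlations.
#'
#' @return An 18 x 3 labelled matrix.
#' @examples
#' round(ot_rotate(population_example_loadings())$phi, 2)
#' @export
population_example_loadings <- function() {
  lam <- matrix(0, 18, 3,
                dimnames = list(paste0("x", 1:18), paste0("F", 1:3)))
  for (i in 1:18) {
    block <- ceiling(i / 6)
    cross <- if (i %% 2 == 1) c(0.2, -0.2) else c(-0.2, 0.2)
    lam[i, block] <- 0.5
    lam[i, setdiff(1:3, block)] <- cross
  }
  lam
}

#' Population example: expected rotated solutions
#'
#' The rotated solutions implied by the population example: under complete
#' target rotation every salient pattern loading becomes 0.52, the
#' within-block cross-loadings become 0.25 and -0.11, and all factor
#' inter-correlations -0.22 (2-decimal values); under mean-target rotation
#' the pattern is the input itself and the factors stay uncorrelated.
#'
#' @return A list with `ot_pattern`, `ot_phi`, `omt_pattern`, `omt_phi`
#'   (2-decimal matrices).
#' @export
population_example_expected <- function() {
  init <- population_example_loadings()
  ot_pattern <- init
  for (i in 1:18) {
    block <- ceiling(i / 6)
    cross <- if (i %% 2 == 1) c(0.25, -0.11) else c(-0.11, 0.25)
    ot_pattern[i, block] <- 0.52
    ot_pattern[i, setdiff(1:3, block)] <- cross
  }
  ot_phi <- matrix(-0.22, 3, 3); diag(ot_phi) <- 1
  omt_phi <- diag(3)
  dimnames(ot_phi) <- dimnames(omt_phi) <- list(paste0("F", 1:3), paste0("F", 1:3))
  list(ot_pattern = ot_pattern, ot_phi = ot_phi,
       omt_pattern = init, omt_phi = omt_phi)
}

#' Sampling-error illustration: population orthogonal loadings
#'
#' The 9 x 3 orthogonal population pattern with two correlated blocks
#' (salient 0.48, shared cross-loading 0.13) and one clean block (salient
#' 0.50): the positive shared cross-loadings are the orthogonal fingerprint
#' of a positive inter-correlation between the first two factors.
#'
#' @return A 9 x 3 labelled matrix.
#' @export
correlated_blocks_loadings <- function() {
  lam <- rbind(
    matrix(rep(c(0.48, 0.13, 0.00), each = 3), 3, 3),
    matrix(rep(c(0.13, 0.48, 0.00), each = 3), 3, 3),
    matrix(rep(c(0.00, 0.00, 0.50), each = 3), 3, 3)
  )
  dimnames(lam) <- list(paste0("x", 1:9), paste0("F", 1:3))
  lam
}

#' Write the reference fixtures to disk
#'
#' Writes every in-package reference matrix and design vector as CSV into
#' `out_dir` (idempotent): the population-example initial loadings and the
#' expected rotated solutions, the 9 x 3 correlated-block pattern, and the
#' salient/cross loading ramps of the simulation design.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- population_example_expected()
  paths <- c(
    population_example_initial = file.path(out_dir, "population_example_initial.csv"),
    population_example_ot_pattern = file.path(out_dir, "population_example_ot_pattern.csv"),
    population_example_ot_phi = file.path(out_dir, "population_example_ot_phi.csv"),
    population_example_omt_pattern = file.path(out_dir, "population_example_omt_pattern.csv"),
    population_example_omt_phi = file.path(out_dir, "population_example_omt_phi.csv"),
    correlated_blocks = file.path(out_dir, "correlated_blocks.csv"),
    design_vectors = file.path(out_dir, "design_vectors.csv")
  )
  write_loadings(population_example_loadings(), paths["population_example_initial"])
  write_loadings(exp$ot_pattern, paths["population_example_ot_pattern"])
  write_loadings(exp$ot_phi, paths["population_example_ot_phi"])
  write_loadings(exp$omt_pattern, paths["population_example_omt_pattern"])
  write_loadings(exp$omt_phi, paths["population_example_omt_phi"])
  write_loadings(correlated_blocks_loadings(), paths["correlated_blocks"])
  vecs <- dplyr::bind_rows(purrr::map(
    tidyr::expand_grid(kind = c("salient", "cross"), p_per_q = c(5L, 8L),
                       level = c(0.5, 0.7)) |> purrr::transpose(),
    function(cell) {
      v <- if (cell$kind == "salient") salient_vector(cell$p_per_q, cell$level)
           else cross_vector(cell$p_per_q, cell$level)
      tibble::tibble(kind = cell$kind, p_per_q = cell$p_per_q,
                     level = cell$level, position = seq_along(v), value = v)
    }))
  readr::write_csv(vecs, paths["design_vectors"], progress = FALSE)
  invisible(paths)
}
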