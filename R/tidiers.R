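# broom-style accessors and ggplot2 displays.

#' Tidy a target rotation
#'
#' @param x A `target_rotation`.
#' @param matrix Which component to return in long form: the rotated
#'   `"pattern"` (default), the factor inter-correlations `"phi"`, the
#'   reference structure `"reference"`, the orthogonally pre-rotated
#'   loadings `"lambda1"`, or the `"target"`.
#' @param ... Unused.
#' @return A tibble in long form: `variable`/`factor`/`loading` for loading
#'   matrices, `factor_row`/`factor_col`/`correlation` for `"phi"`.
#' @export
tidy.target_rotation <- function(x, matrix = c("pattern", "phi", "reference",
                                               "lambda1", "target"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "phi") {
    q <- ncol(x$phi)
    return(tibble::tibble(
      factor_row = rep(colnames(x$phi), times = q),
      factor_col = rep(colnames(x$phi), each = q),
      correlation = as.vector(x$phi)
    ))
  }
  m <- switch(matrix, pattern = x$pattern, reference = x$lambda2,
              lambda1 = x$lambda1, target = x$target)
  loadings_tbl(m)
}

#' One-row summary of a target rotation
#'
#' @param x A `target_rotation`.
#' @param ... Unused.
#' @return A tibble with dimensions, method, condition number of the
#'   inverted cross-product, chosen ridge constant, mean Tucker congruence
#'   with the target, mean absolute off-diagonal inter-correlation, and the
#'   machine-precision adjustment applied when symmetrizing phi.
#' @export
glance.target_rotation <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    p = nrow(x$pattern),
    q = ncol(x$pattern),
    kappa = x$transform$kappa,
    ridge = x$transform$ridge,
    mean_congruence = x$congruence,
    mean_abs_phi = mean(abs(offdiag_upper(x$phi))),
    phi_adjustment = attr(x$phi, "max_adjustment")
  )
}

#' Heatmap of a rotated loading pattern
#'
#' @param object A `target_rotation`.
#' @param ... Unused.
#' @return A ggplot: variables by factors, tiles filled by loading, salient
#'   target cells outlined.
#' @export
autoplot.target_rotation <- function(object, ...) {
  df <- tidy.target_rotation(object, "pattern")
  tgt <- loadings_tbl(object$target)
  df$salient <- tgt$loading > 0
  df$variable <- factor(df$variable, levels = rev(rownames(object$pattern)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$salient),
                       linewidth = 0.4, width = 0.95, height = 0.95) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(title = sprintf("%s-rotated pattern", object$method),
                  x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Tidy a Monte-Carlo study
#'
#' @param x An `mc_study` from [run_study()].
#' @param ... Unused.
#' @return The per-replication log tibble.
#' @export
tidy.mc_study <- function(x, ...) x$log

#' One-row-per-method summary of a Monte-Carlo study
#'
#' @param x An `mc_study`.
#' @param ... Unused.
#' @return A tibble of marginal means by rotation method.
#' @export
glance.mc_study <- function(x, ...) summarize_study(x$log, by = "method")

#' Mean factor inter-correlation against sample size
#'
#' @param object An `mc_study`.
#' @param metric Metric column of the summary to display
#'   (`"phi_mean_mean"`, `"phi_bias_mean"`, `"rms_loadings_mean"`, ...).
#' @param ... Unused.
#' @return A ggplot faceted by number of factors, coloured by rotation
#'   method, with one line per method across sample sizes.
#' @export
autoplot.mc_study <- function(object, metric = "phi_mean_mean", ...) {
  s <- object$summary
  if (!metric %in% names(s)) {
    abort(sprintf("Metric '%s' not found in the study summary.", metric))
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~q, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = metric, colour = "rotation") +
    ggplot2::theme_minimal()
}
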