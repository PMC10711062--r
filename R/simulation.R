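# Monte-Carlo sweep over the condition grid.

# Deterministic per-replication seed from (base_seed, condition, rep); kept
# below 2^31 so it is a valid R integer seed. Doubles are exact well past
# this range, so the arithmetic is reproducible across platforms.
replication_seed <- function(base_seed, condition, rep) {
  as.integer((base_seed * 100003 + condition * 10007 + rep * 7919) %% 2147483647L) + 1L
}

#' Run a Monte-Carlo study over a condition grid
#'
#' For every condition and replication: build the population model, draw a
#' sample (raw multivariate-normal data by default, so true factor scores
#' are available; a Wishart correlation-matrix fast path is available when
#' indeterminacy is not requested), extract the true number of factors by
#' least squares, rotate by each requested method, align the solution to the
#' population factors, and record the recovery metrics. Replication seeds
#' derive deterministically from `base_seed`, the condition index and the
#' replication index, so any cell can be re-run in isolation.
#'
#' Non-convergent extractions are kept in the log with `converged = FALSE`
#' and excluded from summaries; they are never imputed.
#'
#' @param conditions Tibble of conditions from [condition_grid()] /
#'   [condition_spec()].
#' @param reps Replications per condition.
#' @param base_seed Integer master seed.
#' @param methods Character subset of `c("OMT", "OT")`.
#' @param extraction `"uls"` or `"paf"`.
#' @param fsi Also compute factor score indeterminacy.
#' @param fsi_method How the predictor-true-factor correlation is computed:
#'   `"exact_moments"` (default) evaluates it for score data under exact
#'   moment control via [exact_moment_indeterminacy()]; `"empirical"`
#'   correlates predictor scores with the raw sample's true factor scores
#'   via [factor_score_indeterminacy()] (requires `sampling = "raw"`).
#' @param sampling `"raw"` (default) or `"wishart"`.
#' @param flip_schedule Passed to [build_population()].
#' @param extended Passed to [build_population()].
#' @return A `mc_study` object: list with `log` (tibble, one row per
#'   condition x replication x method), `summary` (see [summarize_study()]),
#'   `reps`, `base_seed`.
#' @examples
#' \donttest{
#' grid <- condition_spec(q = 3, p_per_q = 5, loading = 0.5,
#'                        cross = "zero", phi = 0.25, n = 500)
#' st <- run_study(grid, reps = 5, base_seed = 1)
#' st$summary
#' }
#' @export
run_study <- function(conditions, reps, base_seed = 1,
                      methods = c("OMT", "OT"), extraction = c("uls", "paf"),
                      fsi = FALSE, fsi_method = c("exact_moments", "empirical"),
                      sampling = c("raw", "wishart"),
                      flip_schedule = NULL, extended = FALSE) {
  extraction <- match.arg(extraction)
  sampling <- match.arg(sampling)
  fsi_method <- match.arg(fsi_method)
  methods <- match.arg(methods, c("OMT", "OT"), several.ok = TRUE)
  stopifnot(reps >= 1)
  if (fsi && fsi_method == "empirical" && sampling == "wishart") {
    abort("Empirical indeterminacy needs true factor scores; use sampling = 'raw'.")
  }
  conditions <- tibble::as_tibble(conditions)
  if (!"condition" %in% names(conditions)) {
    conditions <- dplyr::mutate(conditions, condition = dplyr::row_number(),
                                .before = 1)
  }
  extract_fn <- if (extraction == "uls") extract_uls else extract_paf

  logs <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    model <- tryCatch(
      build_population(cond, flip_schedule = flip_schedule, extended = extended),
      error = function(e) {
        warn(sprintf("Condition %d skipped: %s", cond$condition,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(model)) next
    p <- nrow(model$loadings); q <- ncol(model$loadings)
    target <- build_icm_target(p, q)
    rep_rows <- vector("list", reps)
    for (r in seq_len(reps)) {
      seed <- replication_seed(base_seed, cond$condition, r)
      if (sampling == "raw") {
        smp <- simulate_sample(model, cond$n, seed)
        rmat <- smp$corr
      } else {
        smp <- NULL
        rmat <- simulate_corr_wishart(model, cond$n, seed)
      }
      ext <- tryCatch(extract_fn(rmat, q), error = function(e) NULL)
      conv <- !is.null(ext) && ext$converged
      method_rows <- purrr::map(methods, function(m) {
        base <- tibble::tibble(
          cond[, c("condition", "q", "p_per_q", "loading", "cross", "phi", "n")],
          method = m, rep = r, seed = seed, converged = conv,
          phi_mean = NA_real_, phi_bias = NA_real_, rms_loadings = NA_real_,
          fsi = NA_real_
        )
        if (is.null(ext)) return(base)
        fit <- tryCatch({
          rot <- if (m == "OMT") omt_rotate(ext$loadings_u, target)
                 else ot_rotate(ext$loadings_u, target)
          align_to_population(rot$pattern, rot$phi, model$loadings)
        }, error = function(e) NULL)
        if (is.null(fit)) {
          base$converged <- FALSE
          return(base)
        }
        base$phi_mean <- mean(offdiag_upper(fit$phi))
        base$phi_bias <- phi_bias(fit$phi, cond$phi)
        base$rms_loadings <- rms_difference(fit$pattern, model$loadings)
        if (fsi) {
          base$fsi <- if (fsi_method == "exact_moments") {
            mean(exact_moment_indeterminacy(rmat, fit, model))
          } else {
            mean(factor_score_indeterminacy(smp, fit))
          }
        }
        base
      })
      rep_rows[[r]] <- dplyr::bind_rows(method_rows)
    }
    logs[[i]] <- dplyr::bind_rows(rep_rows)
  }
  log <- dplyr::bind_rows(logs)
  structure(
    list(log = log, summary = summarize_study(log), reps = reps,
         base_seed = base_seed, methods = methods, extraction = extraction),
    class = "mc_study"
  )
}

#' Summarize a per-replication simulation log
#'
#' Grouped means and standard deviations of the recovery metrics, by default
#' per condition and rotation method; pass a subset of design factors in
#' `by` to obtain marginal means (e.g. `by = c("method", "cross")` for the
#' rotation-by-cross-loading interaction means).
#'
#' @param log Per-replication tibble (field `log` of a `mc_study`, or the
#'   study object itself).
#' @param by Grouping columns.
#' @return A tibble of group sizes, convergence counts, and mean/SD of
#'   `phi_mean`, `phi_bias`, `rms_loadings` and (when present) `fsi`.
#' @export
summarize_study <- function(log,
                            by = c("condition", "q", "p_per_q", "loading",
                                   "cross", "phi", "n", "method")) {
  if (inherits(log, "mc_study")) log <- log$log
  by <- intersect(by, names(log))
  ok <- dplyr::filter(log, .data$converged)
  dropped <- dplyr::anti_join(dplyr::distinct(log[, by]),
                              dplyr::distinct(ok[, by]), by = by)
  if (nrow(dropped) > 0) {
    warn(sprintf("%d group(s) had no converged replications and were omitted.",
                 nrow(dropped)))
  }
  dplyr::summarise(
    dplyr::group_by(ok, dplyr::across(dplyr::all_of(by))),
    n_reps = dplyr::n(),
    dplyr::across(dplyr::any_of(c("phi_mean", "phi_bias", "rms_loadings", "fsi")),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x, na.rm = TRUE))),
    .groups = "drop"
  )
}

#' @export
print.mc_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo study: %d conditions x %d reps, methods %s, base seed %d\n",
              dplyr::n_distinct(x$log$condition), x$reps,
              paste(x$methods, collapse = "/"), x$base_seed))
  print(x$summary)
  invisible(x)
}
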