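test_that("phi bias averages the off-diagonal deviations", {
  phi <- matrix(0.5, 3, 3); diag(phi) <- 1
  expect_equal(phi_bias(phi, 0.5), 0)

  sym <- diag(3)
  sym[upper.tri(sym)] <- sym[lower.tri(sym)] <- c(.4, .5, .6)
  expect_equal(phi_bias(sym, 0.5), 0)

  low <- matrix(0.3, 3, 3); diag(low) <- 1
  expect_equal(phi_bias(low, 0.5), -0.2)

  expect_error(phi_bias(matrix(1, 1, 1), 0.5), "two factors")

  # linearity in a constant off-diagonal shift
  set.seed(1)
  base <- diag(4); base[upper.tri(base)] <- runif(6, -.3, .3)
  base <- (base + t(base)) / 2; diag(base) <- 1
  shifted <- base + 0.1 * (1 - diag(4))
  expect_equal(phi_bias(shifted, 0.25), phi_bias(base, 0.25) + 0.1)
})

test_that("RMS difference behaves as a metric and truncates at one when asked", {
  a <- rand_loadings(9, 3, seed = 1)
  expect_equal(rms_difference(a, a), 0)
  expect_equal(rms_difference(a, a + 0.1), 0.1)
  big <- a + 1.37 * sign(a + 1e-9)
  expect_gt(rms_difference(big, a), 1)
  expect_equal(rms_difference(big, a, truncate_at_one = TRUE), 1)

  # triangle inequality on random triples
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rnorm(12), 4, 3); y <- matrix(rnorm(12), 4, 3)
    z <- matrix(rnorm(12), 4, 3)
    expect_lte(rms_difference(x, z), rms_difference(x, y) + rms_difference(y, z) + 1e-12)
  }
})

test_that("sample indeterminacy converges to the closed-form determinacy", {
  model <- build_population(condition_spec(3, 5, 0.5, "zero", 0.25, 100))
  closed <- population_determinacy(model)
  s <- simulate_sample(model, 1e5, 13)
  rho <- factor_score_indeterminacy(
    s, list(pattern = model$loadings, phi = model$phi_matrix))
  expect_lt(max(abs(rho - closed)), 0.01)
  # the exact-moment statistic shares the same population limit
  em <- exact_moment_indeterminacy(
    model$sigma, list(pattern = model$loadings, phi = model$phi_matrix), model)
  expect_equal(unname(em), unname(closed), tolerance = 1e-10)
})

test_that("indeterminacy hits the limiting cases", {
  # near-deterministic factor: 20 indicators loading 0.9
  lam <- matrix(0.9, 20, 1)
  psi2 <- 1 - 0.81
  sigma <- tcrossprod(lam) + diag(psi2, 20)
  model <- structure(list(loadings = lam, phi_matrix = diag(1),
                          uniqueness = rep(psi2, 20), sigma = sigma,
                          q = 1, p_per_q = 20, loading = 0.9,
                          cross = "zero", phi = 0),
                     class = "population_model")
  expect_gt(population_determinacy(model), 0.99)
  s <- simulate_sample(model, 2000, 3)
  rho <- factor_score_indeterminacy(s, list(pattern = lam, phi = diag(1)))
  expect_gt(rho, 0.98)

  # no common variance: correlation with the factor is noise around zero
  lam0 <- matrix(1e-4, 10, 1)
  model0 <- structure(list(loadings = lam0, phi_matrix = diag(1),
                           uniqueness = rep(1 - 1e-8, 10),
                           sigma = tcrossprod(lam0) + diag(1 - 1e-8, 10),
                           q = 1, p_per_q = 10, loading = 0, cross = "zero",
                           phi = 0),
                      class = "population_model")
  s0 <- simulate_sample(model0, 5000, 4)
  expect_lt(abs(factor_score_indeterminacy(s0, list(pattern = lam0,
                                                    phi = diag(1)))), 0.05)
})

test_that("subsample stability aggregates aligned RMS differences", {
  model <- build_population(condition_spec(3, 5, 0.5, "zero", 0.25, 100))
  tot <- list(pattern = model$loadings, phi = model$phi_matrix)

  # identical subsamples
  subs <- replicate(4, tot, simplify = FALSE)
  res <- subsample_stability(tot$pattern, tot$phi,
                             lapply(subs, `[[`, "pattern"),
                             lapply(subs, `[[`, "phi"))
  expect_equal(res$per_subsample$rms_loadings, rep(0, 4))
  expect_equal(res$summary$sd_rms_loadings, 0)

  # a constant +0.1 offset gives RMS exactly 0.1; scrambled columns are
  # realigned before comparison
  off <- tot; off$pattern <- tot$pattern + 0.1
  scr <- list(pattern = tot$pattern[, c(2, 1, 3)],
              phi = tot$phi[c(2, 1, 3), c(2, 1, 3)])
  res2 <- subsample_stability(tot$pattern, tot$phi,
                              list(off$pattern, scr$pattern),
                              list(off$phi, scr$phi))
  expect_equal(res2$per_subsample$rms_loadings, c(0.1, 0))

  # non-converged subsamples are skipped and counted
  res3 <- subsample_stability(tot$pattern, tot$phi,
                              list(off$pattern, scr$pattern),
                              list(off$phi, scr$phi),
                              converged = c(TRUE, FALSE))
  expect_equal(res3$summary$n_converged, 1L)
  expect_true(is.na(res3$per_subsample$rms_loadings[2]))
})

test_that("mean-target subsample solutions are more stable than single-target ones", {
  # five-factor model with four indicators per factor, mirroring a short
  # questionnaire; many small subsamples versus a large total sample
  cond <- condition_spec(5, 4, 0.5, "zero", 0.5, 100, extended = TRUE)
  model <- build_population(cond, extended = TRUE)
  q <- 5
  total <- simulate_sample(model, 20000, 1001)
  tgt <- build_icm_target(20, 5)
  ext_t <- extract_paf(total$corr, q)
  rms_means <- sapply(c("OT", "OMT"), function(m) {
    rot_t <- if (m == "OMT") omt_rotate(ext_t$loadings_u, tgt)
             else ot_rotate(ext_t$loadings_u, tgt)
    pats <- list(); phis <- list(); conv <- logical(0)
    for (i in 1:50) {
      s <- simulate_sample(model, 100, 2000 + i)
      e <- extract_paf(s$corr, q)
      r <- if (m == "OMT") omt_rotate(e$loadings_u, tgt)
           else ot_rotate(e$loadings_u, tgt)
      pats[[i]] <- r$pattern; phis[[i]] <- r$phi; conv[i] <- e$converged
    }
    subsample_stability(rot_t$pattern, rot_t$phi, pats, phis,
                        converged = conv)$summary$mean_rms_loadings
  })
  expect_lte(rms_means[["OMT"]], rms_means[["OT"]])
})
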