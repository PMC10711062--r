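test_that("orthogonal target rotation solves the Procrustes problem", {
  # already at the optimum
  tgt <- build_icm_target(9, 3)
  res <- orthogonal_target_rotation(tgt, tgt)
  expect_equal(res$rotation, diag(3), tolerance = 1e-10)

  # invertibility and orthogonality on a generic input
  lam <- rand_loadings(12, 3, seed = 2)
  res <- orthogonal_target_rotation(lam, build_icm_target(12, 3))
  expect_lt(max(abs(crossprod(res$rotation) - diag(3))), 1e-10)
  expect_lt(max(abs(res$lambda1 %*% solve(res$rotation) - lam)), 1e-10)

  # swapped columns: brute force over rotation angle x reflection confirms
  # the optimum is the un-swapping permutation
  lam2 <- rand_loadings(6, 2, noise = 0.05, seed = 3)[, c(2, 1)]
  tgt2 <- build_icm_target(6, 2)
  crit <- function(m) sum((lam2 %*% m - tgt2)^2)
  best <- Inf; best_m <- NULL
  for (th in seq(0, 2 * pi, length.out = 2000)) {
    for (refl in list(diag(2), diag(c(1, -1)))) {
      m <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% refl
      if (crit(m) < best) { best <- crit(m); best_m <- m }
    }
  }
  got <- orthogonal_target_rotation(lam2, tgt2)
  expect_equal(abs(got$rotation), matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-2)
  expect_lt(crit(got$rotation), best + 1e-8)
})

test_that("orthogonality holds across many random inputs", {
  worst <- 0
  for (i in 1:1000) {
    p <- sample(c(6, 9, 12), 1)
    q <- 3
    lam <- rand_loadings(p, q, noise = 0.2, seed = i)
    m <- orthogonal_target_rotation(lam, build_icm_target(p, q))$rotation
    worst <- max(worst, max(abs(crossprod(m) - diag(q))))
  }
  expect_lt(worst, 1e-10)
})

test_that("block means weight cross-loadings by the block's salient loadings", {
  # published population example: blocks cancel exactly to 0.5 * I
  lam1m <- block_mean_loadings(population_example_loadings(), build_icm_target(18, 3))
  expect_equal(unname(lam1m), 0.5 * diag(3), tolerance = 1e-12)

  # a perfect binary pattern gives the identity
  tgt <- build_icm_target(10, 2)
  expect_equal(unname(block_mean_loadings(tgt, tgt)), diag(2), tolerance = 1e-12)

  # hand-computed 6 x 2 case
  lam <- rbind(c(.4, .1), c(.5, .2), c(.6, .3),
               c(.1, .5), c(.2, .6), c(.3, .7))
  got <- block_mean_loadings(lam, build_icm_target(6, 2))
  expect_equal(got[1, 1], (.16 + .25 + .36) / 1.5, tolerance = 1e-12)
  expect_equal(got[1, 2], (.04 + .10 + .18) / 1.5, tolerance = 1e-12)

  # zero salient block is rejected with the factor index
  lam0 <- lam; lam0[4:6, 2] <- 0
  expect_error(block_mean_loadings(lam0, build_icm_target(6, 2)), "factor\\(s\\) 2")
})

test_that("oblique transform solves the ridged normal equations and normalizes columns", {
  # diagonal case
  tr <- oblique_transform(3 * diag(2), diag(2))
  expect_equal(tr$T, diag(2) / 3, tolerance = 1e-12)
  expect_equal(tr$Tn, diag(2), tolerance = 1e-12)

  # closed-form 2 x 2 inversion oracle
  s <- rbind(c(2, 0), c(1, 1))
  sts <- t(s) %*% s
  inv <- matrix(c(sts[2, 2], -sts[2, 1], -sts[1, 2], sts[1, 1]), 2, 2) /
    (sts[1, 1] * sts[2, 2] - sts[1, 2] * sts[2, 1])
  tr2 <- oblique_transform(s, diag(2))
  expect_equal(tr2$T, inv %*% t(s), tolerance = 1e-12)
  expect_equal(unname(sqrt(colSums(tr2$Tn^2))), c(1, 1), tolerance = 1e-10)

  # unit columns on random inputs; kappa is pre-ridge
  for (i in 1:25) {
    set.seed(i)
    s <- matrix(rnorm(9), 3, 3)
    tr <- oblique_transform(s, diag(3), ridge = 0.05)
    expect_equal(unname(sqrt(colSums(tr$Tn^2))), rep(1, 3), tolerance = 1e-10)
    expect_equal(tr$kappa, condition_kappa(crossprod(s)))
  }
})

test_that("applying the identity transform is a no-op with Phi = I", {
  lam <- rand_loadings(12, 3, seed = 5)
  res <- apply_oblique(lam, lam, diag(3))
  expect_equal(res$pattern, lam, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$lambda2, lam, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(res$phi), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("tucker congruence matches hand values and flags zero columns", {
  expect_equal(tucker_congruence(cbind(c(1, 0, 1)), cbind(c(1, 1, 1))),
               2 / sqrt(6), ignore_attr = TRUE)
  a <- rand_loadings(9, 3, seed = 6)
  expect_equal(unname(tucker_congruence(a, a)), rep(1, 3))
  expect_equal(unname(tucker_congruence(a, -a)), rep(-1, 3))
  expect_error(tucker_congruence(a, a * 0), "Zero-norm")
})

test_that("condition number equals the singular value ratio", {
  expect_equal(condition_kappa(diag(4)), 1)
  expect_equal(condition_kappa(diag(c(10, 0.1))), 100)
  expect_equal(condition_kappa(diag(c(1, 0))), Inf)
  set.seed(8)
  a <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)  # symmetric PD
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(condition_kappa(a), max(ev) / min(ev), tolerance = 1e-10)
})

test_that("the population example reproduces the printed rotated solutions", {
  init <- population_example_loadings()
  exp <- population_example_expected()

  ot <- ot_rotate(init)
  expect_equal(round(ot$pattern, 2), exp$ot_pattern)
  expect_equal(round(unclass(ot$phi), 2), exp$ot_phi, ignore_attr = TRUE)

  omt <- omt_rotate(init)
  expect_lt(max(abs(omt$pattern - init)), 1e-8)
  expect_lt(max(abs(omt$phi - diag(3))), 1e-8)
  expect_equal(unname(omt$lambda1m), 0.5 * diag(3), tolerance = 1e-10)
})

test_that("mean-target rotation leaves balanced zero-block-mean patterns unchanged", {
  # constant salients per block and paired +/-c cross-loadings make every
  # block's weighted mean cross-loading exactly zero and keep the input at
  # the orthogonal-Procrustes optimum, so the full pipeline is an identity
  for (seed in 1:20) {
    set.seed(seed)
    q <- sample(2:4, 1); bs <- sample(c(4, 6), 1)
    p <- q * bs
    tgt <- build_icm_target(p, q)
    lam <- matrix(0, p, q)
    for (j in seq_len(q)) {
      rows <- which(tgt[, j] == 1)
      lam[rows, j] <- runif(1, .4, .7)
      for (k in seq_len(q)[-j]) {
        c_jk <- runif(1, .05, .25)
        lam[rows, k] <- rep(c(c_jk, -c_jk), bs / 2)
      }
    }
    res <- omt_rotate(lam)
    expect_lt(max(abs(res$pattern - lam)), 1e-8)
    expect_lt(max(abs(res$phi - diag(q))), 1e-8)
  }
})

test_that("correlated blocks in the orthogonal pattern surface as positive phi", {
  res <- omt_rotate(correlated_blocks_loadings())
  expect_gt(res$phi[1, 2], 0.1)
  expect_lt(abs(res$phi[1, 3]), 0.02)
  expect_lt(abs(res$phi[2, 3]), 0.02)
})

test_that("both pipelines preserve the common part and return valid phi", {
  for (seed in 1:25) {
    lam <- rand_loadings(12, 3, seed = seed)
    for (fit in list(ot_rotate(lam), omt_rotate(lam))) {
      common <- fit$pattern %*% fit$phi %*% t(fit$pattern)
      expect_lt(max(abs(common - tcrossprod(lam))), 1e-6)
      expect_equal(unname(diag(fit$phi)), rep(1, 3), tolerance = 1e-10)
      expect_lt(max(abs(fit$phi - t(fit$phi))), 1e-10)
      expect_gt(min(eigen(fit$phi, symmetric = TRUE)$values), -1e-8)
    }
  }
})

test_that("rotation results are invariant to orthogonal re-orientation of the input", {
  lam <- rand_loadings(15, 3, seed = 11)
  for (method in c("omt", "ot")) {
    base <- rotate_target(lam, method)
    for (seed in 1:5) {
      rot <- rotate_target(lam %*% rand_orthogonal(3, seed), method)
      expect_lt(max(abs(rot$pattern - base$pattern)), 1e-8)
      expect_lt(max(abs(rot$phi - base$phi)), 1e-8)
    }
  }
})

test_that("complete target rotation matches a dense 2-parameter grid oracle", {
  # 6 x 2 with unequal blocks; oracle: per-column direction grid with the
  # closed-form optimal scale, minimizing the target least-squares criterion
  lam <- rbind(c(.62, .18), c(.55, .10), c(.48, .05),
               c(.12, .58), c(.05, .66), c(-.02, .49))
  tgt <- build_icm_target(6, 2)
  thetas <- seq(0, pi, length.out = 20001)[-20001]  # directions up to sign
  best <- function(j) {
    vals <- vapply(thetas, function(th) {
      u <- c(cos(th), sin(th))
      v <- lam %*% u
      cc <- sum(v * tgt[, j]) / sum(v^2)
      sum((cc * v - tgt[, j])^2)
    }, numeric(1))
    th <- thetas[which.min(vals)]
    u <- c(cos(th), sin(th))
    v <- lam %*% u
    if (sum(v * tgt[, j]) < 0) u <- -u
    u
  }
  tn_oracle <- cbind(best(1), best(2))
  ob <- apply_oblique(lam, lam, tn_oracle)
  fit <- ot_rotate(lam)
  expect_equal(round(fit$pattern, 3), round(ob$pattern, 3), ignore_attr = TRUE)
  expect_equal(round(unclass(fit$phi), 3), round(unclass(ob$phi), 3),
               ignore_attr = TRUE)
})

test_that("tidiers and plots expose the rotation results", {
  fit <- ot_rotate(population_example_loadings())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 54L)
  expect_equal(nrow(tidy(fit, "phi")), 9L)
  gl <- glance(fit)
  expect_equal(gl$method, "OT")
  expect_equal(gl$ridge, 0)
  expect_gt(gl$kappa, 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "OT rotation")
})
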