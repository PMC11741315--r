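test_that("locus penalty weights follow the variable-sites-plus-median rule", {
  expect_equal(group_penalty_weights(c(G1 = 2, G2 = 5, G3 = 9)),
               c(G1 = 7, G2 = 10, G3 = 14), ignore_attr = TRUE)
  expect_equal(group_penalty_weights(c(G1 = 4)), c(G1 = 8), ignore_attr = TRUE)
  # invariant loci are excluded from the model and the median
  w <- group_penalty_weights(c(G1 = 0, G2 = 3, G3 = 7))
  expect_equal(w, c(G2 = 8, G3 = 12), ignore_attr = TRUE)
  expect_equal(attr(w, "median"), 5)      # even count: mean of central values
  expect_error(group_penalty_weights(c(G1 = 0)), "invariant")
})

test_that("penalty maxima match the null-model gradient", {
  y <- c(1, -1, 1, -1)
  X <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0))
  pm <- penalty_max(X, y, c("G1", "G1"), c(G1 = 2))
  expect_equal(pm$site_lambda_max, 0.25)  # |-(1/8) * 2| for column a
  # column b is orthogonal to y and contributes nothing
  expect_equal(pm$group_lambda_max, 0.25 / 2)
  # doubling group weights halves the group maximum, site maximum unchanged
  pm2 <- penalty_max(X, y, c("G1", "G1"), c(G1 = 4))
  expect_equal(pm2$group_lambda_max, pm$group_lambda_max / 2)
  expect_equal(pm2$site_lambda_max, pm$site_lambda_max)
  expect_error(penalty_max(cbind(c(1, 1, 0, 0)), y, "G1", c(G1 = 1)),
               "degenerate signal")
})

test_that("a dense lambda sweep confirms the site penalty maximum", {
  y <- c(1, -1, 1, -1)
  X <- cbind(a = c(1, 0, 1, 0))
  for (lam in c(0.05, 0.125, 0.2, 0.24)) {
    fit <- oracle_sgl(X, y, lam, 0, "G1", c(G1 = 1))
    expect_gt(sum(abs(fit$beta)), 1e-6)
  }
  for (lam in c(0.2501, 0.3, 0.5, 1)) {
    fit <- oracle_sgl(X, y, lam, 0, "G1", c(G1 = 1))
    expect_lt(sum(abs(fit$beta)), 1e-8)
  }
})

test_that("the penalty grid is a log-spaced site-major Cartesian product", {
  g <- penalty_grid(20, 20)
  expect_equal(nrow(g), 400)
  expect_equal(nrow(penalty_grid(4, 4)), 16)
  # log-spacing: ratios between consecutive site fractions are constant
  sf <- unique(g$site_fraction)
  expect_equal(sf[1], 0.01)
  expect_equal(tail(sf, 1), 0.99)
  expect_equal(diff(log(sf)), rep(diff(log(sf))[1], 19), tolerance = 1e-12)
  # site-major: group fraction varies fastest
  expect_equal(g$site_fraction[1:20], rep(0.01, 20))
  # degenerate single-value axis sits at the lower endpoint
  g1 <- penalty_grid(1, 1)
  expect_equal(unlist(g1), c(site_fraction = 0.01, group_fraction = 0.01))
  expect_error(penalty_grid(2, 2, lo = 0.5, hi = 0.4), "0 < lo < hi < 1")
})

test_that("fits match the reference proximal-gradient oracle on random problems", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    g0 <- abs(crossprod(inst$X, inst$y))
    if (max(g0) == 0) next
    pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
    for (fr in list(c(0.05, 0.3), c(0.3, 0.05), c(0.5, 0.5))) {
      lam1 <- fr[1] * pm$site_lambda_max
      lam2 <- fr[2] * pm$group_lambda_max
      fit <- fit_sgl(inst$X, inst$y, lam1, lam2, inst$groups, inst$gw)
      ref <- oracle_sgl(inst$X, inst$y, lam1, lam2, inst$groups, inst$gw)
      expect_true(fit$converged)
      expect_lt(abs(fit$objective - ref$objective), 1e-5)
    }
  }
})

test_that("penalties at and beyond the maxima force the exact all-zero model", {
  for (seed in 1:6) {
    inst <- random_instance(seed + 100)
    if (max(abs(crossprod(inst$X, inst$y))) == 0) next
    pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
    f1 <- fit_sgl(inst$X, inst$y, 1.001 * pm$site_lambda_max, 0,
                  inst$groups, inst$gw)
    expect_identical(unname(f1$beta), rep(0, ncol(inst$X)))
    expect_equal(f1$intercept, 0)
    f2 <- fit_sgl(inst$X, inst$y, 0, 1.001 * pm$group_lambda_max,
                  inst$groups, inst$gw)
    expect_identical(unname(f2$beta), rep(0, ncol(inst$X)))
    f3 <- fit_sgl(inst$X, inst$y, 0.5 * pm$site_lambda_max, 0,
                  inst$groups, inst$gw)
    expect_gt(sum(abs(f3$beta)), 0)
    f4 <- fit_sgl(inst$X, inst$y, 0, 0.5 * pm$group_lambda_max,
                  inst$groups, inst$gw)
    expect_gt(sum(abs(f4$beta)), 0)
  }
})

test_that("clade-tracking columns stay at exactly zero under a valid contrast design", {
  # site 1 separates the trait, site 2 is identical within each pair
  y <- c(1, -1, 1, -1)
  X <- cbind(s1A = c(1, 0, 1, 0), s1T = c(0, 1, 0, 1),
             s2K = c(1, 1, 0, 0), s2R = c(0, 0, 1, 1))
  groups <- rep("G1", 4)
  gw <- c(G1 = 2)
  pm <- penalty_max(X, y, groups, gw)
  # keep the combined penalty below the all-zero threshold (fractions sum < 1)
  for (fr in c(0.05, 0.2, 0.4)) {
    fit <- fit_sgl(X, y, fr * pm$site_lambda_max, fr * pm$group_lambda_max,
                   groups, gw)
    expect_identical(unname(fit$beta[c("s2K", "s2R")]), c(0, 0))
    expect_gt(abs(fit$beta["s1A"]) + abs(fit$beta["s1T"]), 0)
    ref <- oracle_sgl(X, y, fr * pm$site_lambda_max, fr * pm$group_lambda_max,
                      groups, gw)
    expect_lt(abs(fit$objective - ref$objective), 1e-6)
  }
})

test_that("the fitted objective never exceeds the all-zero objective", {
  for (seed in 11:14) {
    inst <- random_instance(seed)
    if (max(abs(crossprod(inst$X, inst$y))) == 0) next
    pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
    fit <- fit_sgl(inst$X, inst$y, 0.2 * pm$site_lambda_max,
                   0.2 * pm$group_lambda_max, inst$groups, inst$gw)
    expect_lte(fit$objective, log(2) + 1e-12)
    if (any(fit$beta != 0)) expect_lt(fit$objective, log(2))
  }
})

test_that("flipping the response flips the sign of every coefficient", {
  inst <- random_instance(21)
  pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
  f1 <- fit_sgl(inst$X, inst$y, 0.2 * pm$site_lambda_max,
                0.2 * pm$group_lambda_max, inst$groups, inst$gw)
  f2 <- fit_sgl(inst$X, -inst$y, 0.2 * pm$site_lambda_max,
                0.2 * pm$group_lambda_max, inst$groups, inst$gw)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-4)
  expect_equal(f2$intercept, -f1$intercept, tolerance = 1e-4)
})

test_that("the pure-lasso limit agrees with an L1-logistic reference", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(31)
  pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
  lam <- 0.3 * pm$site_lambda_max
  fit <- fit_sgl(inst$X, inst$y, lam, 0, inst$groups, inst$gw, tol = 1e-10)
  gfit <- suppressWarnings(
    glmnet::glmnet(inst$X, factor(inst$y), family = "binomial",
                   lambda = lam, standardize = FALSE, thresh = 1e-12))
  expect_equal(unname(fit$beta), as.vector(gfit$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, as.numeric(gfit$a0), tolerance = 1e-3)
})

test_that("the active set shrinks as either penalty grows", {
  # raising the group penalty can reshuffle coefficients within groups, so
  # exact monotonicity of the column count is checked on fixed instances
  for (seed in c(11, 21, 41, 43, 44)) {
    inst <- random_instance(seed)
    pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
    sizes_site <- vapply(c(0.05, 0.2, 0.5, 0.9), function(fr)
      sum(fit_sgl(inst$X, inst$y, fr * pm$site_lambda_max, 0.1 * pm$group_lambda_max,
                  inst$groups, inst$gw)$beta != 0), numeric(1))
    expect_true(all(diff(sizes_site) <= 0))
  }
  for (seed in c(21, 43, 44)) {
    inst <- random_instance(seed)
    pm <- penalty_max(inst$X, inst$y, inst$groups, inst$gw)
    sizes_group <- vapply(c(0.05, 0.2, 0.5, 0.9), function(fr)
      sum(fit_sgl(inst$X, inst$y, 0.1 * pm$site_lambda_max, fr * pm$group_lambda_max,
                  inst$groups, inst$gw)$beta != 0), numeric(1))
    expect_true(all(diff(sizes_group) <= 0))
  }
})

test_that("sequence prediction scores are the linear score of the encoding", {
  m <- structure(list(intercept = 0.1, beta = c(c1 = 0.5, c2 = -0.2),
                      groups = c("G1", "G1")), class = "esl_model")
  expect_equal(predict_sps(m, c(1, 0)), 0.6)
  expect_equal(predict_sps(m, c(0, 0)), 0.1)
  expect_equal(predict_sps(m, rbind(a = c(1, 0), b = c(0, 1))), c(0.6, -0.1))
  expect_error(predict_sps(m, c(1, 0, 0)), "feature-space mismatch")
  zero <- structure(list(intercept = 0.3, beta = c(0, 0),
                         groups = c("G1", "G1")), class = "esl_model")
  expect_equal(predict_sps(zero, c(1, 1)), 0.3)
})
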