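test_that("exactly linear data collapse to the basis: zero process variance, exact predictions", {
  d <- maximin_lhs(30, 2, seed = 2, iterations = 500)
  y <- 1 + 2 * d$points[, 1] - 3 * d$points[, 2]
  em <- suppressWarnings(gp_emulator(d$points, y, seed = 1, starts = 4))
  expect_lt(em$sigma2, 1e-10)
  xt <- matrix(runif(20), 10, 2)
  expect_equal(predict(em, xt), 1 + 2 * xt[, 1] - 3 * xt[, 2], tolerance = 1e-9)
  cv <- cross_validate(em)
  # held-out residuals vanish (standardized errors are 0/0 noise here)
  expect_lt(max(abs(cv$predicted - cv$actual)), 1e-6)
  expect_length(cv$predicted, 30)
})

test_that("with zero nugget the emulator interpolates its training data", {
  d <- maximin_lhs(25, 2, seed = 5, iterations = 500)
  y <- smooth2(d$points)
  em <- gp_emulator(d$points, y, nugget = 0, seed = 1, starts = 4,
                    length_bounds = c(1e-2, 2))
  expect_equal(em$jitter_added, 0)
  pr <- predict(em, d$points, se.fit = TRUE)
  expect_lt(max(abs(pr$fit - y)) / sd(y), 1e-8)
  expect_lt(max(pr$se.fit) / sd(y), 1e-4)  # predictive sd ~ 0 at training points
  expect_true(all(pr$se.fit >= 0))
})

test_that("far from all data the mean reverts to the fitted basis", {
  X <- maximin_lhs(20, 2, seed = 6, iterations = 200)$points * 0.2
  y <- smooth2(X)
  em <- gp_emulator(X, y, lengths = c(0.04, 0.04), nugget = 1e-8)
  far <- matrix(c(0.95, 0.95), 1)
  prior_mean <- drop(c(1, far) %*% em$beta) * em$s_y + em$m_y
  expect_equal(predict(em, far), prior_mean, tolerance = 1e-8)
  pr <- predict(em, far, se.fit = TRUE)
  # prior predictive sd (basis uncertainty inflates it beyond sqrt(sigma2))
  expect_gte(pr$se.fit, sqrt(em$sigma2) * em$s_y * 0.99)
})

test_that("closed-form leave-one-out equals explicit refitting", {
  d <- maximin_lhs(30, 2, seed = 9, iterations = 300)
  y <- smooth2(d$points)
  em <- gp_emulator(d$points, y, nugget = 1e-6, seed = 2, starts = 4,
                    length_bounds = c(1e-2, 2))
  cv <- cross_validate(em)
  for (i in c(1, 7, 18, 30)) {
    emi <- gp_emulator(d$points[-i, ], y[-i], nugget = 1e-6, lengths = em$lengths)
    pr <- predict(emi, d$points[i, , drop = FALSE], se.fit = TRUE)
    expect_equal(cv$predicted[i], pr$fit, tolerance = 1e-5)
    # sd differs by the refit's re-estimated process variance, O(1/n)
    expect_equal(cv$sd[i], pr$se.fit, tolerance = 0.15)
  }
  expect_length(cv$std_errors, 30)
  expect_length(cv$sd, 30)
})

test_that("white-noise training data yield calibrated LOO diagnostics", {
  set.seed(9)
  X <- matrix(runif(240), 120, 2)
  y <- rnorm(120)
  em <- gp_emulator(X, y, nugget = 1, seed = 2, starts = 3)
  cv <- cross_validate(em)
  # |e| > 2 should occur for roughly 5% of points
  expect_gt(cv$fraction_abs_err_gt2, 0.001)
  expect_lt(cv$fraction_abs_err_gt2, 0.15)
  expect_lt(abs(cv$bias_slope), 0.35)
  expect_lt(abs(mean(cv$std_errors)), 0.35)
  expect_gt(sd(cv$std_errors), 0.6)
  expect_lt(sd(cv$std_errors), 1.5)
})

test_that("emulator commutes with affine rescaling of the output", {
  d <- maximin_lhs(25, 2, seed = 11, iterations = 300)
  y <- smooth2(d$points)
  em1 <- gp_emulator(d$points, y, lengths = c(0.5, 0.5), nugget = 1e-8)
  em2 <- gp_emulator(d$points, 100 - 7 * y, lengths = c(0.5, 0.5), nugget = 1e-8)
  xt <- matrix(runif(16), 8, 2)
  expect_equal(predict(em2, xt), 100 - 7 * predict(em1, xt), tolerance = 1e-8)
})

test_that("degenerate and invalid inputs are handled", {
  # single run with constant basis: GLS mean everywhere
  em <- gp_emulator(matrix(0.5, 1, 2), 3.2, basis = "constant",
                    lengths = c(1, 1))
  expect_equal(predict(em, matrix(c(0.1, 0.9), 1)), 3.2)
  # linear basis needs n > k + 1
  expect_error(gp_emulator(matrix(runif(4), 2, 2), c(1, 2)), "at least")
  # duplicate rows demand a nugget
  X <- rbind(c(0.2, 0.2), c(0.2, 0.2),
             maximin_lhs(8, 2, seed = 14, iterations = 100)$points)
  expect_error(gp_emulator(X, 1:10, nugget = 0, lengths = c(1, 1)), "duplicate")
  emn <- gp_emulator(X, c(1, 1.1, 2:9), nugget = 0.1, lengths = c(1, 1))
  expect_error(cross_validate(emn), NA)  # positive nugget keeps LOO defined
  expect_error(gp_emulator(matrix(runif(20), 10, 2), rep(c(1, NA), 5)), "finite")
  em2 <- gp_emulator(matrix(runif(20), 10, 2), runif(10), lengths = c(0.5, 0.5))
  expect_warning(predict(em2, matrix(c(1.5, 0.5), 1)), "extrapolat")
})

test_that("stochastic-simulator mode recovers a noise nugget by likelihood", {
  set.seed(15)
  X <- matrix(runif(160), 80, 2)
  y_clean <- 2 * X[, 1] + sin(3 * X[, 2])
  y <- y_clean + rnorm(80, sd = 0.3)        # noise var ~ 0.09 / var(y) ~ 0.15
  em <- gp_emulator(X, y, estimate_nugget = TRUE, seed = 3, starts = 4)
  expect_gt(em$nugget, 1e-3)                # found a real noise floor
  # smoothing: predictions track the clean surface better than the data do
  err_fit <- sqrt(mean((predict(em, X) - y_clean)^2))
  expect_lt(err_fit, 0.25)
})

test_that("prediction scales to large batches quickly", {
  d <- maximin_lhs(100, 3, seed = 13, iterations = 300)
  y <- d$points[, 1] + sin(4 * d$points[, 2]) * d$points[, 3]
  em <- gp_emulator(d$points, y, seed = 1, starts = 3)
  t0 <- proc.time()[3]
  pr <- predict(em, matrix(runif(3e4), ncol = 3))
  expect_lt(proc.time()[3] - t0, 5)
  expect_length(pr, 1e4)
})
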