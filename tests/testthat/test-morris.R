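check_trajectory <- function(tr, k, p) {
  delta <- p / (2 * (p - 1))
  expect_equal(dim(tr), c(k + 1L, k))
  grid <- seq(0, 1, by = 1 / (p - 1))
  expect_true(all(vapply(c(tr), function(v) min(abs(v - grid)), 1) < 1e-12))
  moved <- integer()
  for (s in seq_len(k)) {
    du <- tr[s + 1, ] - tr[s, ]
    i <- which(abs(du) > 1e-12)
    expect_length(i, 1L)
    expect_equal(abs(du[i]), delta, tolerance = 1e-12)
    moved <- c(moved, i)
  }
  expect_setequal(moved, seq_len(k))   # each coordinate perturbed exactly once
}

test_that("trajectories live on the level grid with single-coordinate steps", {
  d <- morris_trajectories(2, p = 4, r = 5, seed = 1)
  expect_equal(d$delta, 2 / 3)
  for (tr in d$trajectories) check_trajectory(tr, 2, 4)
  d2 <- morris_trajectories(7, p = 6, r = 4, seed = 2)
  expect_equal(d2$delta, 6 / 10)
  for (tr in d2$trajectories) check_trajectory(tr, 7, 6)
  expect_error(morris_trajectories(3, p = 5), "even")
  expect_error(morris_trajectories(0, p = 4), "positive integer")
})

test_that("trajectory generation is seed-deterministic", {
  a <- morris_trajectories(4, r = 6, seed = 99)
  b <- morris_trajectories(4, r = 6, seed = 99)
  c <- morris_trajectories(4, r = 6, seed = 100)
  expect_identical(a$trajectories, b$trajectories)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("optimized subset matches exhaustive search on small pools", {
  for (seed in c(3, 17, 31)) {
    pool <- morris_trajectories(3, p = 4, r = 4, seed = seed)
    opt <- optimize_trajectories(pool, 2)
    pairs <- utils::combn(4, 2)
    crits <- apply(pairs, 2, function(ix) trajectory_spread(pool, ix))
    expect_equal(attr(opt, "criterion"), max(crits), tolerance = 1e-10)
    expect_setequal(attr(opt, "selected"), pairs[, which.max(crits)])
  }
})

test_that("optimized subset beats the unoptimized leading candidates", {
  pool <- morris_trajectories(5, p = 4, r = 30, seed = 8)
  opt <- optimize_trajectories(pool, 10)
  expect_gte(attr(opt, "criterion"), trajectory_spread(pool, 1:10) - 1e-12)
  set.seed(5)
  rand <- sort(sample.int(30, 10))
  expect_gte(attr(opt, "criterion"), trajectory_spread(pool, rand) - 1e-12)
  # identity when the subset is the whole pool
  all_sel <- optimize_trajectories(pool, 30)
  expect_identical(all_sel$trajectories, pool$trajectories)
  expect_error(optimize_trajectories(pool, 31), "cannot select")
})

test_that("elementary effects of an additive model are its constant slopes", {
  m <- test_function("linear_additive", a = c(2, 3))
  mo <- morris(m, r = 8, candidates = 16, seed = 42)
  expect_equal(unname(mo$mu), c(2, 3), tolerance = 1e-10)
  expect_equal(unname(mo$mu_star), c(2, 3), tolerance = 1e-10)
  expect_lt(max(mo$sigma), 1e-10)
  expect_true(all(mo$ee[, 1] - 2 < 1e-10))
})

test_that("elementary effects of y = u1*u2 expose the interaction", {
  m <- test_function("product")
  d <- morris_trajectories(2, p = 4, r = 12, seed = 6)
  mo <- morris(m, design = d)
  # dy/du1 = u2, so each EE1 sample must equal a grid value of u2
  grid <- seq(0, 1, by = 1 / 3)
  expect_true(all(vapply(mo$ee[, 1], function(e) min(abs(e - grid)) < 1e-10, TRUE)))
  expect_gt(mo$sigma[1], 0)
  expect_gte(mo$mu_star[1], abs(mo$mu[1]))
})

test_that("constant models give all-zero screening measures", {
  mo <- morris(test_function("constant"), r = 5, candidates = 10, seed = 4)
  expect_true(all(mo$mu == 0) && all(mo$mu_star == 0) && all(mo$sigma == 0))
})

test_that("mu_star dominates |mu| with equality only for single-signed effects", {
  mo <- morris(test_function("ishigami"), r = 20, candidates = 60, seed = 13)
  expect_true(all(mo$mu_star >= abs(mo$mu) - 1e-12))
  i <- which.max(mo$mu_star - abs(mo$mu))
  expect_true(min(mo$ee[, i]) < 0 && max(mo$ee[, i]) > 0)
})

test_that("reported effects equal a brute-force recomputation from the same design", {
  m <- test_function("ishigami")
  d <- optimize_trajectories(morris_trajectories(3, r = 15, seed = 21), 8)
  mo <- morris(m, design = d)
  ee <- matrix(0, 8, 3)
  for (t in seq_along(d$trajectories)) {
    tr <- d$trajectories[[t]]
    y <- apply(tr, 1, m$fn)
    for (s in 1:3) {
      du <- tr[s + 1, ] - tr[s, ]
      i <- which(du != 0)
      ee[t, i] <- (y[s + 1] - y[s]) / du[i]
    }
  }
  expect_equal(unname(mo$ee), ee, tolerance = 1e-12)
})

test_that("screening honors thresholds, forced inclusions and repeats", {
  m <- test_function("linear_additive", a = c(5, 0.1, 0))
  mo <- morris(m, r = 6, candidates = 12, seed = 3)
  sc <- screen_parameters(mo, threshold = 1)
  expect_identical(sc$screened, "x1")
  expect_identical(sc$table$name[1], "x1")
  all_in <- screen_parameters(mo, threshold = 1e-6)
  expect_setequal(all_in$screened, c("x1", "x2"))   # x3 has mu exactly 0
  forced_only <- screen_parameters(mo, threshold = 100, forced = "x3")
  expect_identical(forced_only$screened, "x3")
  # repeats: screened in ANY repeat counts; concordance reported
  mo2 <- morris(m, r = 6, candidates = 12, seed = 4)
  sc2 <- screen_parameters(list(mo, mo2), threshold = 1)
  expect_identical(sc2$screened, "x1")
  expect_equal(dim(sc2$concordance), c(2L, 2L))
  expect_gte(sc2$concordance[1, 2], 0.5)
  other <- morris(test_function("product"), r = 4, candidates = 8, seed = 1)
  expect_error(screen_parameters(list(mo, other), threshold = 1), "different parameter sets")
  expect_error(screen_parameters(mo, threshold = 0), "positive")
})

test_that("dummy inputs never screen in at any positive threshold", {
  m <- augment_with_dummies(test_function("linear_additive", a = c(2, 3)), 3)
  mo <- morris(m, r = 8, candidates = 20, seed = 10)
  expect_true(all(mo$ee[, 3:5] == 0))
  sc <- screen_parameters(mo, threshold = 1e-12)
  expect_setequal(sc$screened, c("x1", "x2"))
})

test_that("local sensitivity recovers elasticities and directions", {
  m <- gsa_model("square", 1, function(th) 4 * th[1]^2, nominal = 2)
  ls <- local_sensitivity(m, delta = 0.01)
  expect_equal(ls$nsc, 2.01, tolerance = 1e-9)   # ((1.01^2 - 1)) / 0.01
  m2 <- gsa_model("partial", 2, function(th) th[1], nominal = c(1, 1))
  ls2 <- local_sensitivity(m2)
  expect_equal(ls2$nsc[ls2$name == "x2"], 0)
  hp <- local_sensitivity(hpt_model())
  expect_lt(hp$nsc[hp$name == "clu"], 0)
  expect_gt(hp$nsc[hp$name == "vmax"], 0)
  zero <- gsa_model("zero", 1, function(th) 0, nominal = 1)
  expect_warning(local_sensitivity(zero), "zero")
})
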