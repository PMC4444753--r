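test_that("Gaussian 95% ranges reproduce worked table values", {
  b <- derive_bounds(72.3, 0.14)
  expect_equal(b$rule, "gaussian95")
  expect_equal(round(b$lower, 1), 52.5)
  expect_equal(round(b$upper, 1), 92.1)
  b <- derive_bounds(31500, 0.38)
  expect_equal(b$lower, 8038.8)
  expect_equal(b$upper, 54961.2)
  b <- derive_bounds(3.4, 0.13)
  expect_equal(round(c(b$lower, b$upper), 1), c(2.5, 4.3))
  b <- derive_bounds(15.6, 0.20)
  expect_equal(round(c(b$lower, b$upper), 1), c(9.5, 21.7))
})

test_that("one-SD fallback takes over when the Gaussian percentile is non-positive", {
  b <- derive_bounds(750, 0.62)
  expect_equal(b$rule, "one_sd")
  expect_equal(c(b$lower, b$upper), c(285, 1215))
  b <- derive_bounds(3000, 0.75)
  expect_equal(c(b$lower, b$upper), c(750, 5250))
  # zero-variance degenerate range
  b <- derive_bounds(5, 0)
  expect_equal(c(b$lower, b$upper), c(5, 5))
})

test_that("bound derivation is scale-equivariant and the fallback threshold is exact", {
  set.seed(42)
  for (i in 1:25) {
    m <- runif(1, 1e-6, 1e6); cv <- runif(1, 0, 1.2); c0 <- runif(1, 1e-3, 1e3)
    b1 <- derive_bounds(m, cv); b2 <- derive_bounds(c0 * m, cv)
    expect_equal(c(b2$lower, b2$upper), c0 * c(b1$lower, b1$upper), tolerance = 1e-12)
  }
  cvs <- c(0.1, 0.3, 0.5, 0.51, 1 / 1.96, 0.52, 0.75, 1.5)
  rules <- derive_bounds(rep(1, length(cvs)), cvs)$rule
  expect_identical(rules, ifelse(cvs >= 1 / 1.96, "one_sd", "gaussian95"))
  # every high-CV table row takes the fallback branch
  sp <- hpt_parameter_table()
  hi <- sp$cv >= 0.53
  expect_true(all(derive_bounds(sp$mean[hi], sp$cv[hi])$rule == "one_sd"))
  expect_error(derive_bounds(1, -0.1), "nonnegative")
  expect_error(derive_bounds(-1, 0.1), "positive")
})

test_that("packaged table loads 66 parameters with a bound cross-check report", {
  sp <- hpt_parameter_table()
  expect_s3_class(sp, "param_space")
  expect_equal(nrow(sp), 66L)
  expect_equal(sp$name[1:2], c("BW_F", "BW_M"))
  row <- sp[sp$name == "CLF_UIM", ]
  expect_equal(row$mean, 0.17)
  expect_equal(row$cv, 0.32)
  chk <- attr(sp, "bound_check")
  expect_equal(nrow(chk), 66L)
  # worked rows agree at printed precision
  ok <- chk$name %in% c("BW_M", "KMNIS_I", "VMAXNISF_PLC_MI", "CLF_BIND_FI")
  expect_true(all(chk$lower_ok[ok] & chk$upper_ok[ok]))
  # rows whose printed bounds were set by other means are flagged, not dropped
  expect_false(chk$lower_ok[chk$name == "VMAXNISF_THY_MI"])
  expect_false(chk$upper_ok[chk$name == "KPRODT4F_MI"])
  # every constraint group's nominal means hit the required total
  g <- attr(sp, "groups")
  expect_setequal(names(g), c("qflow_m", "qflow_f", "vol_m", "vol_f",
                              "plc_m", "thy_f", "thy_m"))
  for (gi in names(g))
    expect_equal(sum(sp$mean[sp$group == gi]), g[[gi]], tolerance = 1e-9)
})

test_that("table loader rejects malformed input with row identity", {
  good <- tiny_table()
  expect_s3_class(read_parameter_table(write_param_csv(good)), "param_space")
  expect_error(read_parameter_table(write_param_csv(good[, -2])), "missing column")
  bad <- good; bad$name[2] <- "a"
  expect_error(read_parameter_table(write_param_csv(bad)), "duplicate.*a")
  bad <- good; bad$mean <- c("10", "oops")
  expect_error(read_parameter_table(write_param_csv(bad)), "non-numeric.*b")
  empty <- good[0, ]
  expect_error(read_parameter_table(write_param_csv(empty)), "empty")
  expect_error(read_parameter_table(tempfile()), "not found")
})

test_that("range overrides revise rows without touching the original", {
  sp <- hpt_parameter_table()
  rev <- apply_range_overrides(sp, data.frame(name = "CLF_UIM",
                                              lower = 7.87e-2, upper = 2.11e-1))
  row <- rev[rev$name == "CLF_UIM", ]
  expect_equal(c(row$lower, row$upper), c(7.87e-2, 2.11e-1))
  expect_equal(row$provenance, "revised")
  expect_equal(sp[sp$name == "CLF_UIM", "lower"], 0.1)  # original untouched
  expect_identical(apply_range_overrides(sp, data.frame(name = character(),
                                                        lower = numeric(),
                                                        upper = numeric())), sp)
  expect_error(apply_range_overrides(sp, data.frame(name = "NOPE", lower = 0, upper = 1)),
               "unknown")
  expect_error(apply_range_overrides(sp, data.frame(name = "CLF_UIM", lower = 1, upper = 0)),
               "lower >= upper")
  # packaged revised ranges apply cleanly to all 26 screened rows
  rev2 <- apply_range_overrides(sp, hpt_revised_ranges())
  expect_equal(sum(rev2$provenance == "revised"), 26L)
})

test_that("unit-cube mapping is affine with exact group renormalization", {
  sp <- read_parameter_table(write_param_csv(tiny_table()))
  expect_equal(unname(map_unit_to_physical(sp, c(0, 0))), sp$lower)
  expect_equal(unname(map_unit_to_physical(sp, c(1, 1))), sp$upper)
  expect_error(map_unit_to_physical(sp, c(0.5, 1.2)), "0, 1")

  gs <- group_space()
  mid <- map_unit_to_physical(gs, c(0.5, 0.5))
  # midpoints 0.7 and 0.25 rescale by 1/0.95 to restore the unit sum
  expect_equal(unname(mid), c(0.7, 0.25) / 0.95, tolerance = 1e-12)
  expect_equal(sum(mid), 1, tolerance = 1e-12)

  sp66 <- hpt_parameter_table()
  set.seed(7)
  U <- matrix(runif(20 * nrow(sp66)), 20)
  X <- map_unit_to_physical(sp66, U)
  g <- attr(sp66, "groups")
  for (gi in names(g)) {
    sums <- rowSums(X[, sp66$name[sp66$group == gi], drop = FALSE])
    expect_true(all(abs(sums - g[[gi]]) < 1e-12))
  }
  # non-group entries are the plain affine image
  j <- which(sp66$group == "")[1]
  expect_equal(X[, j], sp66$lower[j] + U[, j] * (sp66$upper[j] - sp66$lower[j]))
})
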