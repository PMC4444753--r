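fake_report <- function(main_pct, total_pct, names = paste0("p", seq_along(main_pct)),
                        main_se = 0, total_se = 0) {
  tab <- data.frame(name = names, main = main_pct / 100, main_se = main_se,
                    total = total_pct / 100, total_se = total_se,
                    main_pct = main_pct, total_pct = total_pct,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pairwise = NULL, curves = NULL,
                 variance = 1, undefined = FALSE, N = 0, seed = 0),
            class = "gsa_report")
}

test_that("Lowry series accumulates and caps correctly", {
  lo <- lowry(fake_report(100, 100, "only"))
  expect_equal(lo$cum_main, 100)
  expect_equal(lo$ribbon_upper, 100)
  # additive model: ribbon coincides with the cumulative main effects
  lo2 <- lowry(fake_report(c(60, 40), c(60, 40)))
  expect_equal(lo2$ribbon_upper, lo2$cum_main)
  # interactions open a band; ordering is by descending main effect
  lo3 <- lowry(fake_report(c(10, 50, 20), c(15, 60, 30), c("a", "b", "c")))
  expect_equal(lo3$name, c("b", "c", "a"))
  expect_equal(lo3$cum_main, c(50, 70, 80))
  expect_equal(lo3$ribbon_upper, c(60, 90, 100))   # capped at 100
  expect_true(all(diff(lo3$cum_main) >= 0))
  expect_true(all(lo3$ribbon_upper >= lo3$cum_main))
  expect_true(all(lo3$ribbon_upper <= 100))
  # a total below its main beyond MC tolerance is flagged
  lo4 <- lowry(fake_report(c(50, 30), c(45, 30)))
  expect_true(lo4$flag[1])
  expect_false(lo4$flag[2])
})

test_that("influence cut keeps parameters above 0.5% by main and/or total effect", {
  rep <- fake_report(c(20, 0.3, 0.1), c(25, 0.8, 0.2), c("a", "b", "c"))
  expect_identical(influential_parameters(rep), c("a", "b"))  # b via total only
  expect_identical(influential_parameters(rep, cut_pct = 1), "a")
})

test_that("ranking comparison reports concordance and overlaps", {
  r1 <- data.frame(name = letters[1:6], rank = 1:6)
  same <- compare_rankings(m1 = r1, m2 = r1, m = 3)
  expect_equal(same$spearman[1, 2], 1)
  expect_equal(same$top_overlap[1, 2], 3L)
  rev <- data.frame(name = letters[1:6], rank = 6:1)
  opp <- compare_rankings(m1 = r1, m2 = rev)
  expect_equal(opp$spearman[1, 2], -1)
  expect_error(compare_rankings(m1 = r1,
                                m2 = data.frame(name = letters[2:7], rank = 1:6)),
               "different parameter sets")
  # named vectors also accepted
  v <- setNames(1:6, letters[1:6])
  expect_equal(compare_rankings(a = v, b = v)$spearman[1, 2], 1)
})

test_that("Morris and local rankings concord at the extremes on the stand-in", {
  m <- hpt_model()
  mo <- morris(m, r = 12, candidates = 30, seed = 17)
  sc <- screen_parameters(mo, threshold = 1e-6)
  loc <- local_sensitivity(m)
  loc_rank <- data.frame(name = loc$name, rank = loc$rank)
  mor_rank <- data.frame(name = sc$table$name, rank = sc$table$rank)
  cmp <- compare_rankings(morris = mor_rank, local = loc_rank, m = 3)
  expect_gt(cmp$spearman[1, 2], 0.5)
  expect_gte(cmp$top_overlap[1, 2], 2L)
  expect_gte(cmp$bottom_overlap[1, 2], 2L)
})

test_that("pipeline runs end to end, reproducibly, and fails fast on bad config", {
  cfg <- list(model = "ishigami", seed = 5, morris_r = 6, morris_candidates = 12,
              morris_repeats = 2, design_n = 40, design_iterations = 400,
              gp_starts = 3, gsa_N = 2048, pairs_top = 3, curves = TRUE,
              grid_size = 6, threshold = 1e-6)
  d1 <- file.path(tempdir(), "pipe_a"); d2 <- file.path(tempdir(), "pipe_b")
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  for (f in c("screening.csv", "morris_run1.csv", "training.csv",
              "indices.csv", "pairwise.csv", "lowry.csv", "main_effect_curves.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = sprintf("artifact %s reproducible", f))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(as.numeric(man$config$seed), 5)
  expect_gt(length(man$artifacts), 5)
  # manifest hashes match the artifacts on disk
  for (nm in names(man$artifacts)) {
    expect_equal(unname(tools::md5sum(r1$paths[[nm]])[[1]]), man$artifacts[[nm]])
  }
  # screened set and indices are sane for the Ishigami truth; x2's signed
  # effects can cancel exactly on the 4-level grid (sin^2 symmetry), which
  # is why mu_star is reported alongside mu
  expect_true("x1" %in% r1$screening$screened)
  expect_true(all(r1$screening$table$mu_star > 0.1))
  tab <- r1$report$table
  expect_equal(tab$name[which.min(tab$main)], "x3")  # x3 acts via interaction only
  expect_gt(max(tab$total), 0.3)
  expect_error(run_pipeline(list(model = "nope"), file.path(tempdir(), "x")),
               "unknown model")
  expect_error(run_pipeline(list(model = "ishigami", bogus = 1),
                            file.path(tempdir(), "x")), "unknown config")
})

test_that("a failing model halts the pipeline with the stage name", {
  bad <- gsa_model("bad", 2, function(u) if (u[1] > 0.5) stop("sim crash") else u[1])
  expect_error(run_pipeline(list(model = bad, morris_r = 3, morris_candidates = 6,
                                 morris_repeats = 1, design_n = 10,
                                 design_iterations = 50),
                            file.path(tempdir(), "pipe_fail")),
               "stage")
})
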