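#' Lowry-plot series
#'
#' Orders parameters by descending main effect and accumulates: the lower
#' envelope is the cumulative sum of main effects, the upper envelope the
#' running cumulative total effect capped at 100%.  The band between the
#' two is variance attributable to interactions.  Any total effect below
#' its main effect by more than three Monte-Carlo standard errors is
#' flagged (`flag` column) rather than silently adjusted.
#'
#' @param report a `gsa_report` from [sensitivity_indices()].
#' @return Object of class `lowry_series`: data frame with `name`,
#'   `main_pct`, `total_pct`, `cum_main`, `ribbon_upper`, `flag`.
#' @export
lowry <- function(report) {
  stopifnot(inherits(report, "gsa_report"))
  if (report$undefined) stop_("indices are undefined (zero output variance)")
  tab <- report$table[order(-report$table$main), ]
  tol <- 3 * ifelse(is.na(tab$total_se), 0, tab$total_se) +
         3 * ifelse(is.na(tab$main_se), 0, tab$main_se)
  out <- data.frame(name = tab$name,
                    main_pct = tab$main_pct, total_pct = tab$total_pct,
                    cum_main = pmin(100, cumsum(tab$main_pct)),
                    ribbon_upper = pmin(100, cumsum(tab$total_pct)),
                    flag = tab$total_pct < tab$main_pct - 100 * tol,
                    stringsAsFactors = FALSE)
  out$ribbon_upper <- pmax(out$ribbon_upper, out$cum_main)
  class(out) <- c("lowry_series", "data.frame")
  out
}

#' Lowry plot
#'
#' Paired bars (main effect black, interaction remainder grey) with the
#' cumulative ribbon: lower edge the cumulative main effects, upper edge
#' the cumulative total effects capped at 100%.
#'
#' @param x a [lowry()] series.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lowry_series <- function(x, ...) {
  h <- rbind(x$main_pct, pmax(x$total_pct - x$main_pct, 0))
  mid <- graphics::barplot(h, names.arg = x$name, las = 2,
                           col = c("black", "grey70"),
                           ylab = "% of output variance",
                           ylim = c(0, 105), ...)
  graphics::polygon(c(mid, rev(mid)), c(x$cum_main, rev(x$ribbon_upper)),
                    col = grDevices::adjustcolor("steelblue", 0.35), border = NA)
  graphics::lines(mid, x$cum_main, col = "steelblue4")
  graphics::lines(mid, x$ribbon_upper, col = "steelblue4", lty = 2)
  invisible(x)
}

#' Select the influential parameter subset from a sensitivity report
#'
#' The conventional influence cut: a parameter is influential when its
#' main effect and/or total effect exceeds the cut (default 0.5% of the
#' output variance).
#'
#' @param report a `gsa_report`.
#' @param cut_pct threshold, percent of output variance.
#' @return character vector of influential parameter names, in descending
#'   main-effect order.
#' @export
influential_parameters <- function(report, cut_pct = 0.5) {
  stopifnot(inherits(report, "gsa_report"))
  if (report$undefined) return(character())
  tab <- report$table[order(-report$table$main), ]
  tab$name[tab$main_pct > cut_pct | tab$total_pct > cut_pct]
}

#' Compare parameter rankings across methods
#'
#' Aligns two or more named rank tables over a common parameter universe
#' and reports side-by-side ranks, the Spearman rank-correlation matrix,
#' and top-/bottom-`m` overlap counts for each method pair.
#'
#' @param ... two or more named arguments, each either a data frame with
#'   columns `name` and `rank` or a named numeric vector of ranks.
#' @param m overlap depth for the top/bottom comparison.
#' @return list with `table`, `spearman`, `top_overlap`, `bottom_overlap`.
#' @export
compare_rankings <- function(..., m = 5) {
  tabs <- list(...)
  if (length(tabs) < 2) stop_("need at least two rankings to compare")
  if (is.null(names(tabs)) || any(!nzchar(names(tabs))))
    names(tabs) <- paste0("method", seq_along(tabs))
  as_ranks <- function(t) {
    if (is.data.frame(t)) stats::setNames(t$rank, t$name)
    else if (!is.null(names(t))) t
    else stop_("rankings must be data frames (name, rank) or named vectors")
  }
  ranks <- lapply(tabs, as_ranks)
  base_names <- sort(names(ranks[[1]]))
  for (r in ranks)
    if (!setequal(names(r), base_names))
      stop_("rankings cover different parameter sets")
  Rm <- vapply(ranks, function(r) unname(r[base_names]), numeric(length(base_names)))
  rownames(Rm) <- base_names
  rho <- stats::cor(Rm, method = "spearman")
  npair <- ncol(Rm)
  topm <- function(v) names(sort(v))[seq_len(min(m, length(v)))]
  botm <- function(v) names(sort(v, decreasing = TRUE))[seq_len(min(m, length(v)))]
  ov <- function(f) {
    M <- matrix(NA_integer_, npair, npair, dimnames = dimnames(rho))
    for (i in seq_len(npair)) for (j in seq_len(npair))
      M[i, j] <- length(intersect(f(Rm[, i]), f(Rm[, j])))
    M
  }
  tab <- data.frame(name = base_names, Rm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab[[2]]), ]
  rownames(tab) <- NULL
  list(table = tab, spearman = rho, top_overlap = ov(topm),
       bottom_overlap = ov(botm), m = m)
}

# Models the pipeline can address by name.
pipeline_model <- function(name) {
  switch(name,
    hpt = hpt_model(),
    hpt_fetal = hpt_model("fetal_ft4"),
    ishigami = test_function("ishigami"),
    sobol_g = test_function("sobol_g"),
    linear_additive = test_function("linear_additive"),
    product = test_function("product"),
    stop_("unknown model '%s'", name))
}

write_stage_csv <- function(x, dir, file) {
  path <- file.path(dir, file)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full two-stage sensitivity-analysis pipeline
#'
#' Executes bounds derivation, Morris screening (with repeats), design
#' generation, model evaluation, emulator fitting and validation,
#' variance-based indices, and Lowry reporting, writing every artifact as
#' CSV plus a JSON manifest (configuration, seeds, package version, file
#' hashes).  All randomness derives from `config$seed`, so a re-run with
#' the same configuration reproduces every artifact bit-for-bit.  A stage
#' failure halts the pipeline with the stage name; artifacts of completed
#' stages remain on disk.
#'
#' @param config a named list or the path of a YAML file.  Recognized
#'   entries (defaults in parentheses): `model` ("hpt"), `seed` (1),
#'   `morris_r` (50), `morris_candidates` (150), `morris_p` (4),
#'   `morris_repeats` (3), `threshold` (6e-4), `forced` (character()),
#'   `design_n` (120), `design_iterations` (5000), `gp_starts` (6),
#'   `gsa_N` (8192), `pairs_top` (6), `curves` (TRUE), `grid_size` (15).
#' @param out_dir artifact directory (created if missing).
#' @return Invisibly, a list with the stage objects and artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(model = "hpt", seed = 1, morris_r = 50,
                   morris_candidates = 150, morris_p = 4, morris_repeats = 3,
                   threshold = 6e-4, forced = character(),
                   design_n = 120, design_iterations = 5000, gp_starts = 6,
                   gsa_N = 8192, pairs_top = 6, curves = TRUE, grid_size = 15)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop_("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  model <- if (inherits(cfg$model, "gsa_model")) cfg$model else pipeline_model(cfg$model)
  if (missing(out_dir)) stop_("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## 1. bounds --------------------------------------------------------------
  space <- model$space
  bounds_tab <- if (!is.null(space)) as.data.frame(space)
                else data.frame(name = paste0("x", seq_len(model$k)),
                                lower = 0, upper = 1)
  stage("bounds", paths["bounds"] <- write_stage_csv(bounds_tab, out_dir, "bounds.csv"))

  ## 2. screening -----------------------------------------------------------
  screens <- stage("screen", lapply(seq_len(cfg$morris_repeats), function(rep_i) {
    morris(model, r = cfg$morris_r, candidates = cfg$morris_candidates,
           p = cfg$morris_p, seed = child_seed(cfg$seed, rep_i))
  }))
  stage("screen", {
    for (rep_i in seq_along(screens)) {
      mo <- screens[[rep_i]]
      tab <- data.frame(name = mo$parameters, mu = mo$mu,
                        mu_star = mo$mu_star, sigma = mo$sigma)
      tab <- tab[order(-abs(tab$mu)), ]
      tab$rank <- seq_len(nrow(tab))
      paths[paste0("morris_run", rep_i)] <-
        write_stage_csv(tab, out_dir, sprintf("morris_run%d.csv", rep_i))
    }
  })
  screening <- stage("screen", screen_parameters(screens, threshold = cfg$threshold,
                                                 forced = cfg$forced))
  paths["screening"] <- write_stage_csv(screening$table, out_dir, "screening.csv")

  ## 3. design + evaluation --------------------------------------------------
  design <- stage("design", maximin_lhs(cfg$design_n, model$k,
                                        seed = child_seed(cfg$seed, 101),
                                        iterations = cfg$design_iterations))
  training <- stage("evaluate", evaluate_design(model, design))
  if (!is.null(attr(training, "failed")))
    stop_("pipeline stage 'evaluate' failed: model failed at design row(s) %s",
          paste(attr(training, "failed"), collapse = ", "))
  paths["training"] <- write_stage_csv(training, out_dir, "training.csv")

  ## 4. emulator + validation ------------------------------------------------
  em <- stage("emulate", gp_emulator(design$points, training$y,
                                     starts = cfg$gp_starts,
                                     seed = child_seed(cfg$seed, 202)))
  cv <- stage("validate", cross_validate(em))
  paths["emulator"] <- file.path(out_dir, "emulator.json")
  stage("emulate", jsonlite::write_json(
    list(lengths = em$lengths, beta = em$beta, sigma2 = em$sigma2,
         nugget = em$nugget, m_y = em$m_y, s_y = em$s_y, basis = em$basis),
    paths["emulator"], digits = NA, auto_unbox = TRUE))
  paths["cv"] <- write_stage_csv(
    data.frame(actual = cv$actual, predicted = cv$predicted, sd = cv$sd,
               std_error = cv$std_errors), out_dir, "cross_validation.csv")

  ## 5. variance-based indices ----------------------------------------------
  report <- stage("gsa", sensitivity_indices(
    em, N = cfg$gsa_N, seed = child_seed(cfg$seed, 303),
    pairs = "top", n_top = cfg$pairs_top,
    curves = isTRUE(cfg$curves), grid_size = cfg$grid_size,
    space = space))
  paths["indices"] <- write_stage_csv(
    report$table[, c("name", "main_pct", "total_pct", "main_se", "total_se")],
    out_dir, "indices.csv")
  if (!is.null(report$pairwise))
    paths["pairwise"] <- write_stage_csv(
      report$pairwise[, c("i", "j", "interaction_pct", "interaction_se")],
      out_dir, "pairwise.csv")
  if (!is.null(report$curves)) {
    curve_tab <- do.call(rbind, lapply(names(report$curves), function(nm)
      cbind(parameter = nm, report$curves[[nm]])))
    paths["curves"] <- write_stage_csv(curve_tab, out_dir, "main_effect_curves.csv")
  }

  ## 6. report ---------------------------------------------------------------
  low <- stage("report", lowry(report))
  paths["lowry"] <- write_stage_csv(as.data.frame(low), out_dir, "lowry.csv")

  manifest <- list(
    package = "emugsa",
    version = as.character(utils::packageVersion("emugsa")),
    config = cfg[order(names(cfg))],
    model = model$name,
    seeds = list(master = cfg$seed,
                 screen = vapply(seq_len(cfg$morris_repeats),
                                 function(i) child_seed(cfg$seed, i), integer(1)),
                 design = child_seed(cfg$seed, 101),
                 emulator = child_seed(cfg$seed, 202),
                 gsa = child_seed(cfg$seed, 303)),
    artifacts = as.list(vapply(paths, function(p)
      unname(tools::md5sum(p)), character(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- file.path(out_dir, "manifest.json")

  invisible(list(screening = screening, design = design, training = training,
                 emulator = em, cv = cv, report = report, lowry = low,
                 paths = paths))
}
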