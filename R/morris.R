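#' Generate random Morris trajectories
#'
#' Builds `r` random trajectories on the `p`-level grid in `[0,1]^k` with
#' the standard B* construction: each trajectory has `k + 1` points,
#' consecutive points differ in exactly one coordinate by `+/- delta`, and
#' every coordinate is perturbed exactly once.  The step is
#' `delta = p / (2 (p - 1))`, which requires an even number of levels.
#'
#' @param k input dimension.
#' @param p number of grid levels (interference factor); even, >= 2.
#' @param r number of trajectories.
#' @param seed optional integer seed (the caller's RNG stream is untouched).
#' @return An object of class `morris_design`: list with `trajectories`
#'   (list of `(k+1) x k` matrices), `k`, `p`, `delta`, `seed`.
#' @references Morris (1991); Campolongo, Cariboni & Saltelli (2007).
#' @export
morris_trajectories <- function(k, p = 4, r = 10, seed = NULL) {
  if (!is_count(k)) stop_("k must be a positive integer")
  if (!is_count(p) || p < 2 || p %% 2 != 0)
    stop_("p must be an even integer >= 2 (the step rule delta = p/(2(p-1)) assumes even p)")
  if (!is_count(r)) stop_("r must be a positive integer")
  delta <- p / (2 * (p - 1))
  base_levels <- seq(0, 1 - delta, by = 1 / (p - 1))  # grid values with room for +delta
  trajectories <- with_seed(seed, {
    lapply(seq_len(r), function(m) {
      xstar <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
      Bmat <- matrix(0, k + 1, k); Bmat[lower.tri(Bmat)] <- 1
      Dstar <- diag(sample(c(-1, 1), k, replace = TRUE), k)
      Pstar <- diag(k)[, sample.int(k), drop = FALSE]
      J <- matrix(1, k + 1, k)
      Bstar <- (J %*% diag(xstar, k) +
                  (delta / 2) * ((2 * Bmat - J) %*% Dstar + J)) %*% Pstar
      # round tiny FP noise back onto the grid
      round(Bstar * (p - 1)) / (p - 1)
    })
  })
  structure(list(trajectories = trajectories, k = as.integer(k),
                 p = as.integer(p), delta = delta, seed = seed),
            class = "morris_design")
}

#' @export
print.morris_design <- function(x, ...) {
  cat(sprintf("<morris_design> %d trajectories, k = %d, p = %d, delta = %.4g\n",
              length(x$trajectories), x$k, x$p, x$delta))
  invisible(x)
}

# Aggregate Campolongo distance between two trajectories: the sum of
# Euclidean distances over all point pairs (0 if the trajectories coincide).
trajectory_distance <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- pmax(outer(a2, b2, "+") - 2 * A %*% t(B), 0)
  sum(sqrt(d2))
}

# Spread criterion of a trajectory subset: sqrt of the sum of squared
# pairwise distances (Campolongo et al. 2007).
trajectory_spread <- function(design, idx = seq_along(design$trajectories)) {
  D2 <- trajectory_dist2_matrix(design)
  sqrt(sum(D2[idx, idx]) / 2)
}

trajectory_dist2_matrix <- function(design) {
  tr <- design$trajectories
  M <- length(tr)
  D2 <- matrix(0, M, M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    d <- trajectory_distance(tr[[i]], tr[[j]])
    D2[i, j] <- D2[j, i] <- d^2
  }
  D2
}

#' Select a well-spread subset of Morris trajectories
#'
#' From a candidate pool, selects `r` trajectories approximately maximizing
#' the spread criterion (square root of the sum of squared pairwise
#' aggregate distances) by greedy accretion followed by swap refinement.
#' Exhaustive search over all subsets is infeasible at realistic pool
#' sizes, but on small instances the greedy-plus-swap result can be checked
#' against full enumeration (the test suite does).
#'
#' @param candidates a [morris_trajectories()] design (the candidate pool).
#' @param r subset size.
#' @param max_sweeps maximum swap-refinement sweeps.
#' @return A `morris_design` of `r` trajectories with attributes
#'   `criterion` (achieved spread) and `selected` (candidate indices).
#' @export
optimize_trajectories <- function(candidates, r, max_sweeps = 20) {
  stopifnot(inherits(candidates, "morris_design"))
  M <- length(candidates$trajectories)
  if (r > M) stop_("cannot select %d trajectories from %d candidates", r, M)
  if (r == M) {
    out <- candidates
    attr(out, "criterion") <- trajectory_spread(candidates)
    attr(out, "selected") <- seq_len(M)
    return(out)
  }
  D2 <- trajectory_dist2_matrix(candidates)
  # swap refinement: replace a selected trajectory by an outside candidate
  # whenever that increases the criterion; repeat until a full sweep makes
  # no improvement
  refine <- function(sel) {
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (s_pos in seq_along(sel)) {
        s <- sel[s_pos]
        others <- sel[-s_pos]
        cur <- sum(D2[s, others])
        rest <- setdiff(seq_len(M), sel)
        cand_gain <- colSums(D2[others, rest, drop = FALSE])
        best <- which.max(cand_gain)
        if (length(best) && cand_gain[best] > cur + 1e-12) {
          sel[s_pos] <- rest[best]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    sel
  }
  # greedy accretion: start from the most distant pair, then add the
  # trajectory with the largest summed squared distance to the selection
  sel <- as.integer(arrayInd(which.max(D2), dim(D2)))
  while (length(sel) < r) {
    rest <- setdiff(seq_len(M), sel)
    gain <- colSums(D2[sel, rest, drop = FALSE])
    sel <- c(sel, rest[which.max(gain)])
  }
  crit2 <- function(sel) sum(D2[sel, sel]) / 2
  # refine from the greedy start and from the leading candidates; keeping
  # the better guarantees the result never falls below the unoptimized
  # leading-r subset
  s1 <- refine(sel)
  s2 <- refine(seq_len(r))
  sel <- if (crit2(s1) >= crit2(s2)) s1 else s2
  sel <- sort(sel)
  out <- candidates
  out$trajectories <- candidates$trajectories[sel]
  attr(out, "criterion") <- sqrt(sum(D2[sel, sel]) / 2)
  attr(out, "selected") <- sel
  out
}

#' Morris elementary-effects screening
#'
#' Computes one elementary effect per parameter per trajectory,
#' `EE_i = (y(x + delta e_i) - y(x)) / (+/- delta)` with the sign of the
#' actual step, and summarizes each parameter's effect distribution by
#' `mu` (mean of signed effects: overall influence), `mu_star` (mean of
#' absolute effects, immune to sign cancellation) and `sigma` (standard
#' deviation of signed effects: interaction propensity or nonlinearity).
#'
#' Models carrying a [parameter_space()] are evaluated in physical units
#' via [map_unit_to_physical()]; unit-cube models are evaluated directly.
#' A failed model evaluation drops the whole trajectory (keeping
#' per-parameter sample counts equal); the number dropped is reported.
#'
#' @param model a [gsa_model()].
#' @param design optional [morris_trajectories()] design; by default
#'   `candidates` random trajectories are generated and `r` are kept by
#'   [optimize_trajectories()].
#' @param r number of trajectories (elementary effects per parameter).
#' @param candidates candidate-pool size for trajectory optimization.
#' @param p number of grid levels.
#' @param seed integer seed for the design.
#' @return An object of class `morris`: list with the `r x k` matrix `ee`,
#'   vectors `mu`, `mu_star`, `sigma`, the design, and `n_failed`.
#' @examples
#' m <- test_function("linear_additive", a = c(2, 3))
#' morris(m, r = 6, candidates = 12, seed = 1)
#' @export
morris <- function(model, design = NULL, r = 100, candidates = 500, p = 4,
                   seed = NULL) {
  stopifnot(inherits(model, "gsa_model"))
  if (is.null(design)) {
    pool <- morris_trajectories(model$k, p = p, r = candidates, seed = seed)
    design <- if (candidates > r) optimize_trajectories(pool, r) else pool
  }
  if (design$k != model$k) stop_("design dimension %d != model dimension %d",
                                 design$k, model$k)
  k <- model$k
  names <- if (!is.null(model$space)) model$space$name else paste0("x", seq_len(k))
  ee_rows <- list()
  n_failed <- 0L
  for (tr in design$trajectories) {
    y <- model_evaluate(model, tr, unit = TRUE)
    if (any(!is.finite(y))) { n_failed <- n_failed + 1L; next }
    ee <- numeric(k)
    for (s in seq_len(k)) {
      du <- tr[s + 1, ] - tr[s, ]
      i <- which(du != 0)
      if (length(i) != 1L) stop_("trajectory step %d changes %d coordinates", s, length(i))
      ee[i] <- (y[s + 1] - y[s]) / du[i]
    }
    ee_rows[[length(ee_rows) + 1L]] <- ee
  }
  if (!length(ee_rows)) stop_("all %d trajectories failed to evaluate", length(design$trajectories))
  EE <- do.call(rbind, ee_rows)
  colnames(EE) <- names
  structure(list(ee = EE,
                 mu = colMeans(EE),
                 mu_star = colMeans(abs(EE)),
                 sigma = apply(EE, 2, stats::sd),
                 r = nrow(EE), parameters = names,
                 design = design, n_failed = n_failed,
                 output_label = model$output_label),
            class = "morris")
}

#' @export
print.morris <- function(x, ...) {
  cat(sprintf("Morris screening: %d parameters, r = %d trajectories", ncol(x$ee), x$r))
  if (x$n_failed > 0) cat(sprintf(" (%d dropped)", x$n_failed))
  cat("\n")
  tab <- data.frame(mu = x$mu, mu_star = x$mu_star, sigma = x$sigma)
  tab <- tab[order(-abs(tab$mu)), ]
  print(utils::head(tab, 15))
  if (nrow(tab) > 15) cat(sprintf("... %d more\n", nrow(tab) - 15))
  invisible(x)
}

#' Morris mu--sigma scatter plot
#' @param x a [morris()] result.
#' @param labels label the `n_label` largest-|mu| points.
#' @param n_label number of points to label.
#' @param ... passed to [graphics::plot()].
#' @export
plot.morris <- function(x, labels = TRUE, n_label = 10, ...) {
  graphics::plot(abs(x$mu), x$sigma, pch = 19,
                 xlab = expression("|" * mu * "|"), ylab = expression(sigma), ...)
  if (labels) {
    top <- order(-abs(x$mu))[seq_len(min(n_label, length(x$mu)))]
    graphics::text(abs(x$mu)[top], x$sigma[top], x$parameters[top],
                   pos = 4, cex = 0.7, xpd = NA)
  }
  invisible(x)
}

#' Rank parameters and screen the influential subset
#'
#' Parameters are ranked by descending `|mu|` (ties broken by `sigma`,
#' then name).  The screened set contains every parameter whose `|mu|`
#' exceeds the threshold in any repeat -- screening is repeated because
#' the method is stochastic -- plus any forced inclusions.  Spearman rank
#' concordance across repeats is reported.
#'
#' @param results a [morris()] result or a list of them (repeats).
#' @param threshold screening threshold on `|mu|`, in output units.
#' @param forced parameter names always included in the screened set.
#' @return list with `table` (ranked data frame), `screened` (character
#'   vector), and `concordance` (Spearman correlation matrix of the
#'   repeats' rankings).
#' @export
screen_parameters <- function(results, threshold, forced = character()) {
  if (inherits(results, "morris")) results <- list(results)
  if (!length(results)) stop_("no screening results given")
  if (!is.numeric(threshold) || threshold <= 0) stop_("threshold must be positive")
  nm <- results[[1]]$parameters
  for (res in results)
    if (!identical(res$parameters, nm))
      stop_("repeats cover different parameter sets")
  bad <- setdiff(forced, nm)
  if (length(bad)) stop_("forced parameter(s) not in the results: %s",
                         paste(bad, collapse = ", "))
  first <- results[[1]]
  ord <- order(-abs(first$mu), -first$sigma, nm)
  tab <- data.frame(name = nm[ord],
                    mu = first$mu[ord], mu_star = first$mu_star[ord],
                    sigma = first$sigma[ord],
                    rank = seq_along(nm), stringsAsFactors = FALSE)
  over <- Reduce(`|`, lapply(results, function(res) abs(res$mu) > threshold))
  screened <- union(nm[over], forced)
  ranks <- vapply(results, function(res)
    rank(-abs(res$mu), ties.method = "average"), numeric(length(nm)))
  conc <- stats::cor(ranks, method = "spearman")
  dimnames(conc) <- list(paste0("run", seq_along(results)),
                         paste0("run", seq_along(results)))
  tab$screened <- tab$name %in% screened
  list(table = tab, screened = screened, concordance = conc)
}

#' One-at-a-time local sensitivity analysis
#'
#' The classical comparator to screening: each parameter is perturbed
#' individually by a small fraction `delta` around the nominal point and
#' the normalized sensitivity coefficient
#' `NSC_i = ((y(theta (1 + delta) e_i) - y(theta)) / y(theta)) / delta`
#' is reported, ranked by `|NSC|`.
#'
#' @param model a [gsa_model()] with a nominal point.
#' @param delta relative perturbation, in (0, 1).
#' @return data frame `name`, `nsc`, `rank` (NA coefficients if the
#'   nominal output is zero).
#' @export
local_sensitivity <- function(model, delta = 0.01) {
  stopifnot(inherits(model, "gsa_model"))
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop_("delta must lie in (0, 1)")
  theta <- model$nominal
  if (is.null(theta)) stop_("model '%s' has no nominal point", model$name)
  y0 <- model$fn(theta)
  nm <- if (!is.null(model$space)) model$space$name else paste0("x", seq_len(model$k))
  nsc <- vapply(seq_len(model$k), function(i) {
    th <- theta; th[i] <- th[i] * (1 + delta)
    y1 <- model$fn(th)
    if (y0 == 0) return(NA_real_)
    ((y1 - y0) / y0) / delta
  }, numeric(1))
  if (y0 == 0) warning("nominal output is zero; coefficients undefined")
  out <- data.frame(name = nm, nsc = nsc, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$nsc), out$name), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
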