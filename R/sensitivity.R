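# Normalize the different "predict-callable" shapes (gp_emulator, gsa_model
# on the unit cube, plain function of a matrix) into one batch evaluator.
as_batch_fn <- function(f) {
  if (inherits(f, "gp_emulator")) {
    k <- f$k
    list(fn = function(U) predict(f, U), k = k,
         names = colnames(f$X) %||% paste0("x", seq_len(k)))
  } else if (inherits(f, "gsa_model")) {
    list(fn = function(U) model_evaluate(f, U, unit = TRUE), k = f$k,
         names = if (!is.null(f$space)) f$space$name else paste0("x", seq_len(f$k)))
  } else if (is.function(f)) {
    list(fn = f, k = NULL, names = NULL)
  } else stop_("f must be a gp_emulator, gsa_model, or function")
}

#' Variance-based sensitivity indices by pick-freeze Monte Carlo
#'
#' Estimates, for independent uniform inputs on the unit cube, the main
#' effect `S_i = Var(E[Y|X_i]) / Var(Y)` (expected fractional variance
#' reduction were `X_i` known), the total effect
#' `T_i = 1 - Var(E[Y|X_{-i}]) / Var(Y)` (expected fraction left were only
#' `X_i` unknown), and optionally closed pairwise interaction fractions
#' `V_ij = Var(E[Y|X_i, X_j])/Var(Y) - S_i - S_j` and main-effect curves
#' `x_i -> E[Y|X_i = x_i]`.
#'
#' The estimators are the standard pick-freeze forms on two base matrices
#' `A`, `B` with column substitutions: Saltelli (2010) for `S_i` and the
#' closed pair fraction, Jansen (1999) for `T_i`.  All estimates carry
#' Monte-Carlo standard errors; small-index estimates may come out
#' (insignificantly) negative and are reported as-is rather than clipped.
#' Intended for cheap predictors, typically an emulator's posterior mean.
#'
#' @param f a [gp_emulator()], a unit-cube [gsa_model()], or a function
#'   mapping an `n x k` matrix of unit-cube rows to `n` outputs.
#' @param k input dimension (required when `f` is a plain function).
#' @param N base-sample size (total evaluations `N * (k + 2)` plus
#'   `N` per requested pair).
#' @param seed integer seed for the base samples.
#' @param pairs `NULL` for no interactions, `"top"` for all pairs among
#'   the `n_top` largest total effects, `"all"`, or a 2-column index
#'   matrix.
#' @param n_top number of parameters whose pairs are computed when
#'   `pairs = "top"`.
#' @param curves compute main-effect curves? (logical)
#' @param grid_size,curve_N grid resolution and per-point sample size for
#'   the curves.
#' @param space optional [parameter_space()] used to express curve
#'   abscissae in physical units.
#' @return Object of class `gsa_report`: list with `table` (per-parameter
#'   `main`, `total`, their standard errors, and percent versions),
#'   `pairwise` (data frame or NULL), `curves` (list or NULL),
#'   `variance`, `undefined`, `N`, `seed`.
#' @examples
#' m <- test_function("linear_additive", a = c(2, 3))
#' sensitivity_indices(m, N = 4096, seed = 1)$table
#' @export
sensitivity_indices <- function(f, k = NULL, N = 2^14, seed = 20150527,
                                pairs = NULL, n_top = 6, curves = FALSE,
                                grid_size = 25, curve_N = 1024, space = NULL) {
  bf <- as_batch_fn(f)
  k <- bf$k %||% k
  if (is.null(k)) stop_("supply k for a plain function")
  if (!is_count(N) || N < 8) stop_("N must be an integer >= 8")
  nm <- bf$names %||% paste0("x", seq_len(k))
  if (!is.null(space)) nm <- space$name

  AB <- with_seed(seed, list(A = matrix(stats::runif(N * k), N, k),
                             B = matrix(stats::runif(N * k), N, k)))
  A <- AB$A; B <- AB$B
  yA <- bf$fn(A); yB <- bf$fn(B)
  if (any(!is.finite(c(yA, yB)))) stop_("non-finite output in base samples")
  V <- stats::var(c(yA, yB))
  y_scale <- mean(abs(c(yA, yB))) + 1e-300
  undefined <- V <= (1e-12 * y_scale)^2 + 1e-300
  if (undefined) {
    tab <- data.frame(name = nm, main = NA_real_, main_se = NA_real_,
                      total = NA_real_, total_se = NA_real_,
                      main_pct = NA_real_, total_pct = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, pairwise = NULL, curves = NULL,
                          variance = V, undefined = TRUE, N = N, seed = seed),
                     class = "gsa_report"))
  }

  S <- Tt <- S_se <- T_se <- numeric(k)
  yAB <- vector("list", k)
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    yi <- bf$fn(ABi)
    yAB[[i]] <- yi
    u <- yB * (yi - yA)
    S[i] <- mean(u) / V
    S_se[i] <- stats::sd(u) / sqrt(N) / V
    w <- (yA - yi)^2 / 2
    Tt[i] <- mean(w) / V
    T_se[i] <- stats::sd(w) / sqrt(N) / V
  }

  pair_idx <- NULL
  if (!is.null(pairs)) {
    if (is.character(pairs)) {
      cand <- if (pairs == "all") seq_len(k)
              else order(-Tt)[seq_len(min(n_top, k))]
      if (length(cand) >= 2) pair_idx <- t(utils::combn(sort(cand), 2))
    } else pair_idx <- as_matrix_rows(pairs, 2)
  }
  pairwise <- NULL
  if (!is.null(pair_idx) && nrow(pair_idx)) {
    rows <- lapply(seq_len(nrow(pair_idx)), function(r) {
      i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
      ABij <- A; ABij[, i] <- B[, i]; ABij[, j] <- B[, j]
      yij <- bf$fn(ABij)
      # per-sample combination under common random numbers gives the
      # standard error of the interaction contrast directly
      u <- (yB * (yij - yA) - yB * (yAB[[i]] - yA) - yB * (yAB[[j]] - yA)) / V
      data.frame(i = nm[i], j = nm[j],
                 interaction = mean(u), interaction_se = stats::sd(u) / sqrt(N),
                 stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    pairwise$interaction_pct <- 100 * pairwise$interaction
  }

  curve_list <- NULL
  if (isTRUE(curves)) {
    curve_list <- lapply(seq_len(k), function(i)
      main_effect_curve(bf$fn, i, k = k, grid_size = grid_size, N = curve_N,
                        seed = child_seed(seed, i), space = space))
    names(curve_list) <- nm
  }

  tab <- data.frame(name = nm, main = S, main_se = S_se,
                    total = Tt, total_se = T_se,
                    main_pct = 100 * S, total_pct = 100 * Tt,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pairwise = pairwise, curves = curve_list,
                 variance = V, undefined = FALSE, N = N, seed = seed),
            class = "gsa_report")
}

#' @export
print.gsa_report <- function(x, ...) {
  if (x$undefined) {
    cat("Sensitivity indices undefined: output variance is (numerically) zero\n")
    return(invisible(x))
  }
  cat(sprintf("Variance-based sensitivity indices (N = %d, Var(Y) = %.4g)\n",
              x$N, x$variance))
  tab <- x$table[order(-x$table$main), c("name", "main_pct", "total_pct",
                                         "main_se", "total_se")]
  tab$main_pct <- round(tab$main_pct, 2)
  tab$total_pct <- round(tab$total_pct, 2)
  print(tab, row.names = FALSE, digits = 3)
  if (!is.null(x$pairwise)) {
    cat("Largest pairwise interactions (% of variance):\n")
    pw <- x$pairwise[order(-x$pairwise$interaction), ]
    print(utils::head(pw[, c("i", "j", "interaction_pct")], 5),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Main-effect sensitivity index of one input
#'
#' @inheritParams sensitivity_indices
#' @param i input index.
#' @return list `estimate`, `se`.
#' @export
main_effect <- function(f, i, k = NULL, N = 2^14, seed = 20150527) {
  res <- sensitivity_indices(f, k = k, N = N, seed = seed)
  if (res$undefined) return(list(estimate = NA_real_, se = NA_real_))
  list(estimate = res$table$main[i], se = res$table$main_se[i])
}

#' Total-effect sensitivity index of one input
#' @inheritParams main_effect
#' @return list `estimate`, `se`.
#' @export
total_effect <- function(f, i, k = NULL, N = 2^14, seed = 20150527) {
  res <- sensitivity_indices(f, k = k, N = N, seed = seed)
  if (res$undefined) return(list(estimate = NA_real_, se = NA_real_))
  list(estimate = res$table$total[i], se = res$table$total_se[i])
}

#' Pairwise interaction variance fraction
#' @inheritParams main_effect
#' @param j second input index (`i != j`).
#' @return list `estimate`, `se` (symmetric in `i`, `j`).
#' @export
pairwise_interaction <- function(f, i, j, k = NULL, N = 2^14, seed = 20150527) {
  if (i == j) stop_("pairwise interaction needs two distinct inputs")
  res <- sensitivity_indices(f, k = k, N = N, seed = seed,
                             pairs = matrix(sort(c(i, j)), 1))
  if (res$undefined) return(list(estimate = NA_real_, se = NA_real_))
  list(estimate = res$pairwise$interaction[1], se = res$pairwise$interaction_se[1])
}

#' Main-effect curve of one input
#'
#' Estimates `g -> E[Y | X_i = g]` over a grid of the input's range by
#' averaging the predictor over `N` samples of the remaining inputs
#' (common random numbers across grid points, so the curve is smooth).
#'
#' @inheritParams main_effect
#' @param grid_size number of grid points (>= 2).
#' @param space optional [parameter_space()]; when given, the returned
#'   abscissa `x` is in input `i`'s physical units.
#' @return data frame `x`, `mean`, `se`.
#' @export
main_effect_curve <- function(f, i, k = NULL, grid_size = 25, N = 1024,
                              seed = 20150527, space = NULL) {
  bf <- as_batch_fn(f)
  k <- bf$k %||% k
  if (is.null(k)) stop_("supply k for a plain function")
  if (!is_count(grid_size) || grid_size < 2) stop_("grid_size must be >= 2")
  grid <- seq(0, 1, length.out = grid_size)
  U <- with_seed(seed, matrix(stats::runif(N * k), N, k))
  est <- vapply(grid, function(g) {
    U[, i] <- g
    yg <- bf$fn(U)
    c(mean(yg), stats::sd(yg) / sqrt(N))
  }, numeric(2))
  x <- grid
  if (!is.null(space)) {
    x <- space$lower[i] + grid * (space$upper[i] - space$lower[i])
  }
  data.frame(x = x, mean = est[1, ], se = est[2, ])
}

#' Brute-force (double-loop) sensitivity indices
#'
#' The textbook nested-loop estimator, run directly on the model with no
#' emulator: for `S_i`, condition on `N_outer` values of `X_i` and average
#' the model over `N_inner` draws of the others; `Var` of the conditional
#' means (with the standard inner-noise bias correction) over the total
#' variance gives the index.  Totals condition on `X_{-i}` instead.  Far
#' too expensive for real simulators -- it exists as the independent
#' oracle against which the pick-freeze/emulator route is verified.
#'
#' @param model a unit-cube [gsa_model()] or function of a matrix.
#' @param k input dimension for a plain function.
#' @param N_outer,N_inner loop sizes.
#' @param seed integer seed.
#' @return Object of class `gsa_report` (method `"double_loop"`).
#' @export
brute_force_indices <- function(model, k = NULL, N_outer = 256, N_inner = 256,
                                seed = 20150527) {
  bf <- as_batch_fn(model)
  k <- bf$k %||% k
  if (is.null(k)) stop_("supply k for a plain function")
  nm <- bf$names %||% paste0("x", seq_len(k))
  res <- with_seed(seed, {
    Uvar <- matrix(stats::runif(N_outer * N_inner * k), ncol = k)
    yall <- bf$fn(Uvar)
    V <- stats::var(yall)
    S <- Tt <- numeric(k)
    for (i in seq_len(k)) {
      # main: outer over x_i, inner over the rest
      xi <- stats::runif(N_outer)
      Ui <- matrix(stats::runif(N_outer * N_inner * k), ncol = k)
      Ui[, i] <- rep(xi, each = N_inner)
      yi <- bf$fn(Ui)
      Mi <- matrix(yi, nrow = N_inner)
      m <- colMeans(Mi)
      s2 <- apply(Mi, 2, stats::var)
      S[i] <- (stats::var(m) - mean(s2) / N_inner) / V
      # total: outer over x_{-i}, inner over x_i
      Uo <- matrix(stats::runif(N_outer * k), ncol = k)
      Ut <- Uo[rep(seq_len(N_outer), each = N_inner), , drop = FALSE]
      Ut[, i] <- stats::runif(N_outer * N_inner)
      yt <- bf$fn(Ut)
      Mt <- matrix(yt, nrow = N_inner)
      mt <- colMeans(Mt)
      st2 <- apply(Mt, 2, stats::var)
      Tt[i] <- 1 - (stats::var(mt) - mean(st2) / N_inner) / V
    }
    list(S = S, T = Tt, V = V)
  })
  if (res$V <= 1e-300) {
    res$S[] <- 0; res$T[] <- 0
  }
  tab <- data.frame(name = nm, main = res$S, main_se = NA_real_,
                    total = res$T, total_se = NA_real_,
                    main_pct = 100 * res$S, total_pct = 100 * res$T,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pairwise = NULL, curves = NULL,
                 variance = res$V, undefined = res$V <= 1e-300,
                 N = N_outer * N_inner, seed = seed, method = "double_loop"),
            class = "gsa_report")
}
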