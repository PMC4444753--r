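#' Maximin Latin hypercube design
#'
#' Generates an `n`-run Latin hypercube in `[0,1]^k` (one point per
#' column stratum, jittered within the stratum to avoid grid artifacts)
#' and improves it by a stochastic pairwise-swap hill climb on the
#' minimum inter-point Euclidean distance.  A swap exchanges the values of
#' two runs in one column, which preserves the one-point-per-stratum
#' property; a proposal is accepted only if it strictly increases the
#' minimum distance, so the criterion is monotonically nondecreasing.  To
#' raise the acceptance rate, half of the proposals involve a run from the
#' current closest pair.
#'
#' @param n number of runs (>= 2).
#' @param k number of input dimensions.
#' @param seed optional integer seed.
#' @param iterations number of swap proposals.
#' @param jitter place points uniformly within strata (`TRUE`, default) or
#'   at stratum midpoints.
#' @return Object of class `lhs_design`: list with `points` (`n x k`),
#'   `kind = "lhs_maximin"`, `criterion` (achieved minimum distance),
#'   `criterion_initial`, `seed`, `accepted`.
#' @references Kennedy (2004), GEM-SA; Morris & Mitchell (1995).
#' @export
maximin_lhs <- function(n, k, seed = NULL, iterations = 10000, jitter = TRUE) {
  if (!is_count(n) || n < 2) stop_("n must be an integer >= 2")
  if (!is_count(k)) stop_("k must be a positive integer")
  with_seed(seed, {
    X <- vapply(seq_len(k), function(j) {
      off <- if (jitter) stats::runif(n) else rep(0.5, n)
      (sample.int(n) - off) / n
    }, numeric(n))
    X <- matrix(X, n, k)
    d2 <- as.matrix(stats::dist(X))^2
    diag(d2) <- Inf
    cur_min <- min(d2)
    init_min <- cur_min
    accepted <- 0L
    for (it in seq_len(iterations)) {
      if (stats::runif(1) < 0.5) {
        # pick one run from the current closest pair
        amin <- arrayInd(which.min(d2), dim(d2))
        r1 <- amin[1, sample.int(2, 1)]
        r2 <- sample.int(n - 1, 1); if (r2 >= r1) r2 <- r2 + 1L
      } else {
        pick <- sample.int(n, 2)
        r1 <- pick[1]; r2 <- pick[2]
      }
      j <- sample.int(k, 1)
      Xn1 <- X[r1, ]; Xn2 <- X[r2, ]
      tmp <- Xn1[j]; Xn1[j] <- Xn2[j]; Xn2[j] <- tmp
      dn1 <- colSums((t(X) - Xn1)^2); dn2 <- colSums((t(X) - Xn2)^2)
      dn1[r1] <- Inf; dn2[r2] <- Inf
      dn1[r2] <- dn2[r1] <- sum((Xn1 - Xn2)^2)
      old1 <- d2[r1, ]; old2 <- d2[r2, ]
      d2[r1, ] <- dn1; d2[, r1] <- dn1
      d2[r2, ] <- dn2; d2[, r2] <- dn2
      d2[r1, r1] <- d2[r2, r2] <- Inf
      new_min <- min(d2)
      if (new_min > cur_min) {
        X[r1, j] <- Xn1[j]; X[r2, j] <- Xn2[j]
        cur_min <- new_min
        accepted <- accepted + 1L
      } else {
        d2[r1, ] <- old1; d2[, r1] <- old1
        d2[r2, ] <- old2; d2[, r2] <- old2
        d2[r1, r2] <- old1[r2]; d2[r2, r1] <- old1[r2]
        d2[r1, r1] <- d2[r2, r2] <- Inf
      }
    }
    structure(list(points = X, kind = "lhs_maximin",
                   criterion = sqrt(cur_min),
                   criterion_initial = sqrt(init_min),
                   seed = seed, iterations = iterations, accepted = accepted),
              class = "lhs_design")
  })
}

#' @export
print.lhs_design <- function(x, ...) {
  cat(sprintf("<lhs_design> %d x %d %s, min distance %.4g (initial %.4g, %d swaps)\n",
              nrow(x$points), ncol(x$points), x$kind,
              x$criterion, x$criterion_initial, x$accepted))
  invisible(x)
}

#' Check the Latin hypercube property
#'
#' @param points `n x k` matrix in `[0,1]^k`.
#' @return `TRUE` when every column has exactly one point per stratum
#'   `[j/n, (j+1)/n)`.
#' @export
is_latin_hypercube <- function(points) {
  n <- nrow(points)
  all(apply(points, 2, function(col) {
    s <- floor(col * n)
    s[s == n] <- n - 1          # boundary point 1.0 belongs to the top stratum
    setequal(s, 0:(n - 1))
  }))
}

#' Evaluate a model over a design
#'
#' Runs the model at every design point (unit-cube rows mapped to physical
#' units through the model's parameter space when it has one) in
#' deterministic row order.  Failures are kept as `NA` rows and flagged,
#' never silently dropped.
#'
#' @param model a [gsa_model()].
#' @param design an `lhs_design`, `morris_design`, or plain matrix of
#'   unit-cube rows.
#' @param space optional [parameter_space()] overriding the model's own.
#' @return data frame with unit-cube columns (`u_*`), physical-value
#'   columns (for models with a space), and output column `y`; failed row
#'   indices in attribute `"failed"`.
#' @export
evaluate_design <- function(model, design, space = NULL) {
  stopifnot(inherits(model, "gsa_model"))
  U <- if (is.matrix(design)) design
       else if (inherits(design, "lhs_design")) design$points
       else if (inherits(design, "morris_design")) do.call(rbind, design$trajectories)
       else stop_("unsupported design object")
  U <- as_matrix_rows(U, model$k)
  space <- space %||% model$space
  out <- as.data.frame(U)
  nm <- if (!is.null(space)) space$name else paste0("x", seq_len(model$k))
  names(out) <- paste0("u_", nm)
  if (!is.null(space) && !model$unit_cube) {
    X <- map_unit_to_physical(space, U)
    phys <- as.data.frame(X)
    names(phys) <- nm
    out <- cbind(out, phys)
    y <- model_evaluate(model, X, unit = FALSE)
  } else {
    y <- model_evaluate(model, U, unit = FALSE)
  }
  out$y <- as.numeric(y)
  failed <- which(!is.finite(out$y))
  if (length(failed)) attr(out, "failed") <- failed
  out
}
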