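#' Fit a Gaussian-process emulator
#'
#' Fits the standard deterministic-simulator emulator: a Gaussian process
#' with linear mean basis `h(x) = (1, x_1, ..., x_k)` and squared
#' exponential correlation
#' \deqn{c(x, x') = \exp\{-\sum_i ((x_i - x_i')/\ell_i)^2\}}
#' over training inputs on the unit cube.  Outputs are standardized
#' internally.  Given correlation lengths, the basis coefficients and the
#' process variance have closed-form (generalized least squares /
#' concentrated maximum likelihood) solutions; the lengths themselves are
#' chosen by maximizing the concentrated log-likelihood with multi-start
#' local optimization.  With `nugget = 0` the emulator interpolates the
#' training data exactly; the default nugget `1e-8` (on the standardized
#' scale, i.e. `1e-8 * var(y)`) is for numerical conditioning only.
#'
#' If the correlation matrix is numerically singular at some candidate
#' lengths, the jitter is escalated in decades and the escalation recorded
#' in the fitted object (`$jitter_added`).
#'
#' @param X `n x k` matrix of training inputs in `[0, 1]^k` (duplicate
#'   rows require a positive nugget).
#' @param y numeric vector of `n` training outputs.
#' @param basis `"linear"` (default) or `"constant"` mean basis.
#' @param nugget nonnegative jitter added to the correlation diagonal;
#'   `NULL` uses `1e-8`.
#' @param starts number of optimizer starts (the first starts from
#'   moderate lengths, the rest are randomized under `seed`).
#' @param seed integer seed for the randomized starts.
#' @param length_bounds allowed correlation-length range on the unit-cube
#'   scale.
#' @param lengths optional fixed correlation lengths (length `k`); skips
#'   the likelihood optimization.
#' @param estimate_nugget stochastic-simulator mode: estimate the nugget
#'   by maximum likelihood alongside the lengths (off by default; a
#'   deterministic simulator needs only the conditioning nugget).
#' @return An object of class `gp_emulator`.
#' @references Oakley & O'Hagan (2004); Kennedy (2004), GEM-SA.
#' @examples
#' d <- maximin_lhs(40, 2, seed = 1)
#' y <- apply(d$points, 1, function(u) sin(2 * u[1]) + u[2]^2)
#' em <- gp_emulator(d$points, y, seed = 1)
#' predict(em, cbind(0.3, 0.7))
#' @export
gp_emulator <- function(X, y, basis = c("linear", "constant"), nugget = NULL,
                        starts = 8, seed = NULL, length_bounds = c(1e-2, 1e2),
                        lengths = NULL, estimate_nugget = FALSE) {
  basis <- match.arg(basis)
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  y <- as.numeric(y)
  if (length(y) != n) stop_("X has %d rows but y has length %d", n, length(y))
  if (any(!is.finite(y))) stop_("y must be finite")
  if (any(X < -1e-8 | X > 1 + 1e-8))
    warning("training inputs outside [0,1]; emulator assumes unit-cube scaling")
  q <- if (basis == "linear") k + 1L else 1L
  if (n < q) stop_("need at least %d runs to identify the %s basis", q, basis)
  nugget <- nugget %||% 1e-8
  if (nugget < 0) stop_("nugget must be nonnegative")
  dup <- anyDuplicated(X)
  if (dup && nugget == 0)
    stop_("duplicate training inputs (row %d) require a positive nugget", dup)

  m_y <- mean(y); s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y == 0) s_y <- 1
  ys <- (y - m_y) / s_y
  H <- if (basis == "linear") cbind(1, X) else matrix(1, n, 1)

  Dh <- lapply(seq_len(k), function(j) outer(X[, j], X[, j], "-")^2)

  decompose <- function(loglen, nug = nugget) {
    len2 <- exp(2 * loglen)
    S <- matrix(0, n, n)
    for (j in seq_len(k)) S <- S + Dh[[j]] / len2[j]
    R <- exp(-S)
    total_jit <- nug
    repeat {
      U <- tryCatch(chol(R + diag(total_jit, n)), error = function(e) NULL)
      if (!is.null(U)) break
      total_jit <- max(total_jit * 10, 1e-10)
      if (total_jit > 1e-2) stop_("correlation matrix not positive definite even with jitter 1e-2")
    }
    Hw <- forwardsolve(t(U), H)
    yw <- forwardsolve(t(U), ys)
    qrH <- qr(Hw)
    beta <- qr.coef(qrH, yw)
    rw <- yw - Hw %*% beta
    sigma2 <- max(sum(rw^2) / n, 1e-300)
    list(U = U, beta = drop(beta), sigma2 = sigma2, jit = total_jit - nug,
         nll = 0.5 * (n * log(sigma2) + 2 * sum(log(diag(U)))))
  }

  lb <- log(length_bounds[1]); ub <- log(length_bounds[2])
  convergence <- 0L
  nug_lb <- log(1e-8); nug_ub <- log(0.25)
  if (!is.null(lengths)) {
    if (length(lengths) != k || any(lengths <= 0)) stop_("need %d positive lengths", k)
    best <- log(lengths)
    best_val <- decompose(best)$nll
  } else {
    start_list <- with_seed(seed, {
      s0 <- rep(log(0.5 * sqrt(k)), k)
      extra <- if (starts > 1)
        lapply(seq_len(starts - 1), function(i) stats::runif(k, log(0.1), log(10)))
      else list()
      c(list(pmin(pmax(s0, lb), ub)), lapply(extra, function(s) pmin(pmax(s, lb), ub)))
    })
    best <- NULL; best_val <- Inf; convergence <- 1L
    # candidates whose correlation matrix is unusable even with capped
    # jitter get a finite penalty so one bad corner cannot kill a start
    objective <- function(par) {
      nug <- if (estimate_nugget) exp(par[k + 1]) else nugget
      d <- tryCatch(decompose(par[seq_len(k)], nug), error = function(e) NULL)
      if (is.null(d)) 1e10 else d$nll
    }
    lo <- if (estimate_nugget) c(rep(lb, k), nug_lb) else rep(lb, k)
    hi <- if (estimate_nugget) c(rep(ub, k), nug_ub) else rep(ub, k)
    for (s0 in start_list) {
      if (estimate_nugget) s0 <- c(s0, log(1e-3))
      fit <- tryCatch(
        stats::optim(s0, objective,
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit) || fit$value >= 1e10) next
      if (fit$value < best_val) {
        best_val <- fit$value; best <- fit$par; convergence <- fit$convergence
      }
    }
    if (is.null(best)) stop_("length-scale optimization failed from every start")
    if (estimate_nugget) {
      nugget <- exp(best[k + 1])
      best <- best[seq_len(k)]
    }
  }

  dec <- decompose(best)
  if (convergence != 0 && dec$sigma2 > 1e-10)
    warning("length-scale optimizer did not formally converge; best value returned")
  U <- dec$U
  RinvH <- backsolve(U, forwardsolve(t(U), H))
  A <- solve(crossprod(forwardsolve(t(U), H)))
  resid <- ys - H %*% dec$beta
  alpha <- backsolve(U, forwardsolve(t(U), resid))
  # one step of iterative refinement keeps training-point reproduction at
  # interpolation accuracy even when the correlation matrix is ill-conditioned
  len2 <- exp(2 * best)
  Ssum <- matrix(0, n, n)
  for (j in seq_len(k)) Ssum <- Ssum + Dh[[j]] / len2[j]
  Rn <- exp(-Ssum) + diag(nugget + dec$jit, n)
  res2 <- resid - Rn %*% alpha
  alpha <- alpha + backsolve(U, forwardsolve(t(U), res2))

  structure(list(X = X, y = y, m_y = m_y, s_y = s_y, basis = basis,
                 lengths = exp(best), sigma2 = dec$sigma2, beta = dec$beta,
                 nugget = nugget, jitter_added = dec$jit,
                 chol = U, alpha = drop(alpha), RinvH = RinvH, A = A,
                 n = n, k = k, nll = best_val, convergence = convergence),
            class = "gp_emulator")
}

basis_matrix <- function(object, X) {
  if (object$basis == "linear") cbind(1, X) else matrix(1, nrow(X), 1)
}

#' Predict from a Gaussian-process emulator
#'
#' Posterior mean and (optionally) variance at new inputs, in the original
#' output units.  Predictions at training points reproduce the training
#' outputs when the nugget is zero; far from all training points the mean
#' reverts to the fitted basis `h(x) beta`.  Inputs outside the unit cube
#' are extrapolation: a warning is issued and the prediction computed.
#'
#' @param object a [gp_emulator()].
#' @param newdata matrix of inputs (`m x k`), or a vector of length `k`.
#' @param se.fit also return predictive standard deviations?
#' @param batch internal chunk size for large prediction sets.
#' @param ... unused.
#' @return Numeric vector of means, or `list(fit, se.fit)`.
#' @export
predict.gp_emulator <- function(object, newdata, se.fit = FALSE,
                                batch = 4096L, ...) {
  Xn <- as_matrix_rows(newdata, object$k)
  if (any(Xn < -1e-8 | Xn > 1 + 1e-8))
    warning("prediction inputs outside [0,1]^k: extrapolating")
  m <- nrow(Xn)
  fit <- numeric(m); sefit <- if (se.fit) numeric(m) else NULL
  len2 <- object$lengths^2
  U <- object$chol
  for (start in seq(1L, m, by = batch)) {
    idx <- start:min(start + batch - 1L, m)
    Xb <- Xn[idx, , drop = FALSE]
    S <- matrix(0, length(idx), object$n)
    for (j in seq_len(object$k))
      S <- S + outer(Xb[, j], object$X[, j], "-")^2 / len2[j]
    r <- exp(-S)
    Hb <- basis_matrix(object, Xb)
    mu_s <- drop(Hb %*% object$beta + r %*% object$alpha)
    fit[idx] <- mu_s * object$s_y + object$m_y
    if (se.fit) {
      w <- forwardsolve(t(U), t(r))
      rRr <- colSums(w^2)
      u <- t(Hb) - crossprod(object$RinvH, t(r))
      varb <- colSums(u * (object$A %*% u))
      v_s <- object$sigma2 * pmax(1 - rRr + varb, 0)
      sefit[idx] <- sqrt(v_s) * object$s_y
    }
  }
  if (se.fit) list(fit = fit, se.fit = sefit) else fit
}

#' @export
print.gp_emulator <- function(x, ...) {
  cat(sprintf("Gaussian-process emulator: n = %d, k = %d, %s basis\n",
              x$n, x$k, x$basis))
  cat("  correlation lengths:", paste(signif(x$lengths, 3), collapse = ", "), "\n")
  cat(sprintf("  process variance (standardized): %.4g   nugget: %.3g\n",
              x$sigma2, x$nugget))
  if (x$jitter_added > 0)
    cat(sprintf("  jitter escalated by %.3g for conditioning\n", x$jitter_added))
  invisible(x)
}

#' @export
coef.gp_emulator <- function(object, ...) {
  list(beta = object$beta, lengths = object$lengths,
       sigma2 = object$sigma2, nugget = object$nugget)
}

#' Leave-one-out cross-validation of an emulator
#'
#' Computes, for every training run, the predictive mean and variance the
#' emulator would give that run if it were held out, using the closed-form
#' downdating identity for universal kriging (no refitting; the identity
#' is validated against explicit refits in the test suite).  Hyperparameters
#' -- correlation lengths and process variance -- are held at their
#' full-fit values, so predictive variances differ from a from-scratch
#' refit by O(1/n).  Checks mirror regression residual
#' diagnostics: predictions and model outputs should lie on a 1-to-1 line
#' and standardized errors `e_i = (y_i - yhat_(-i)) / sd_(-i)` should look
#' standard normal.
#'
#' @param em a [gp_emulator()].
#' @return Object of class `gp_cv`: list with `predicted`, `sd`,
#'   `std_errors`, `actual`, `rmse` (output units),
#'   `fraction_abs_err_gt2`, `bias_slope`, `bias_intercept`, `n`.
#' @export
cross_validate <- function(em) {
  stopifnot(inherits(em, "gp_emulator"))
  if (em$n < 3) stop_("need at least 3 training runs for cross-validation")
  U <- em$chol
  Rinv <- chol2inv(U)
  G <- Rinv - em$RinvH %*% em$A %*% t(em$RinvH)
  g <- diag(G)
  if (any(g <= 1e-12))
    stop_("zero leave-one-out predictive variance: duplicate (or near-duplicate) training rows")
  e_s <- em$alpha / g                 # LOO residual, standardized output scale
  var_s <- em$sigma2 / g
  ys <- (em$y - em$m_y) / em$s_y
  pred <- (ys - e_s) * em$s_y + em$m_y
  sd_loo <- sqrt(var_s) * em$s_y
  std_err <- e_s / sqrt(var_s)
  fit <- stats::lm(pred ~ em$y)
  structure(list(predicted = pred, sd = sd_loo, std_errors = std_err,
                 actual = em$y,
                 rmse = sqrt(mean((em$y - pred)^2)),
                 fraction_abs_err_gt2 = mean(abs(std_err) > 2),
                 bias_slope = unname(stats::coef(fit)[2]),
                 bias_intercept = unname(stats::coef(fit)[1]),
                 n = em$n),
            class = "gp_cv")
}

#' @export
print.gp_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (n = %d)\n", x$n))
  cat(sprintf("  RMSE: %.4g   |std err| > 2: %.1f%%\n",
              x$rmse, 100 * x$fraction_abs_err_gt2))
  cat(sprintf("  predicted ~ actual: slope %.3f, intercept %.3g\n",
              x$bias_slope, x$bias_intercept))
  invisible(x)
}

#' Predicted-versus-actual validation plot
#' @param x a `gp_cv` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gp_cv <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$actual, x$predicted, pch = 19,
                 xlab = "model output", ylab = "emulator LOO prediction", ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::plot(x$predicted, x$std_errors, pch = 19,
                 xlab = "LOO prediction", ylab = "standardized error")
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}

#' @export
plot.gp_emulator <- function(x, ...) plot(cross_validate(x), ...)

#' @export
residuals.gp_emulator <- function(object, type = c("loo", "training"), ...) {
  type <- match.arg(type)
  if (type == "loo") {
    cv <- cross_validate(object)
    object$y - cv$predicted
  } else {
    drop(object$y - (basis_matrix(object, object$X) %*% object$beta * object$s_y + object$m_y))
  }
}

#' @export
summary.gp_emulator <- function(object, ...) {
  cv <- tryCatch(cross_validate(object), error = function(e) NULL)
  out <- list(n = object$n, k = object$k, basis = object$basis,
              lengths = object$lengths, sigma2 = object$sigma2,
              nugget = object$nugget, cv = cv)
  class(out) <- "summary.gp_emulator"
  out
}

#' @export
print.summary.gp_emulator <- function(x, ...) {
  cat(sprintf("Gaussian-process emulator (n = %d, k = %d, %s basis)\n",
              x$n, x$k, x$basis))
  cat("  lengths:", paste(signif(x$lengths, 3), collapse = ", "), "\n")
  cat(sprintf("  sigma2 (standardized): %.4g, nugget %.3g\n", x$sigma2, x$nugget))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}
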