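#' Wrap a deterministic scalar-output model
#'
#' A `gsa_model` packages the contract the screening and emulation stages
#' need: a deterministic function from a parameter vector to one real
#' output, the input dimension, a nominal input, and optionally the
#' [parameter_space()] describing the inputs' uncertainty (in which case
#' the model is evaluated in native physical units and designs on the unit
#' cube are mapped through [map_unit_to_physical()] first).
#'
#' @param name model identifier.
#' @param k input dimension.
#' @param fn function taking a numeric vector of length `k`, returning one
#'   finite numeric.
#' @param nominal nominal input vector (native units, or unit cube for
#'   `unit_cube = TRUE` models).
#' @param space optional [parameter_space()] with `k` rows.
#' @param unit_cube logical: does `fn` expect coordinates in `[0,1]^k`?
#' @param output_label free-text description of the output.
#' @param oracle optional list of analytic reference values
#'   (`main`, `total`, `variance`, `pairwise`) used by tests.
#' @param batch_fn optional vectorized evaluator (matrix of rows ->
#'   vector of outputs) used by [model_evaluate()] when present; must
#'   agree with `fn` row by row.
#' @return An object of class `gsa_model`.
#' @export
gsa_model <- function(name, k, fn, nominal = NULL, space = NULL,
                      unit_cube = is.null(space), output_label = "y",
                      oracle = NULL, batch_fn = NULL) {
  stopifnot(is.function(fn), is_count(k))
  if (!is.null(space)) {
    stopifnot(inherits(space, "param_space"))
    if (nrow(space) != k) stop_("space has %d rows, model dimension is %d", nrow(space), k)
  }
  if (!is.null(nominal) && length(nominal) != k)
    stop_("nominal has length %d, expected %d", length(nominal), k)
  structure(list(name = name, k = as.integer(k), fn = fn, nominal = nominal,
                 space = space, unit_cube = isTRUE(unit_cube),
                 output_label = output_label, oracle = oracle,
                 batch_fn = batch_fn),
            class = "gsa_model")
}

#' @export
print.gsa_model <- function(x, ...) {
  cat(sprintf("<gsa_model '%s'>  k = %d, output: %s, inputs: %s\n",
              x$name, x$k, x$output_label,
              if (x$unit_cube) "unit cube" else "physical units"))
  invisible(x)
}

#' Evaluate a model over rows of a design matrix
#'
#' @param model a [gsa_model()].
#' @param X `n x k` matrix.  If `unit = TRUE` the rows are unit-cube
#'   coordinates and are mapped to physical units through the model's
#'   parameter space (identity for unit-cube models).
#' @param unit are the rows of `X` unit-cube coordinates?
#' @return numeric vector of length `n`; failed evaluations are `NA` with
#'   the failing row indices in attribute `"failed"`.
#' @export
model_evaluate <- function(model, X, unit = TRUE) {
  stopifnot(inherits(model, "gsa_model"))
  X <- as_matrix_rows(X, model$k)
  if (unit && !model$unit_cube) {
    if (is.null(model$space)) stop_("model '%s' has no parameter space to map with", model$name)
    X <- map_unit_to_physical(model$space, X)
  }
  y <- if (!is.null(model$batch_fn)) {
    tryCatch(as.numeric(model$batch_fn(X)), error = function(e) NULL)
  } else NULL
  if (is.null(y) || length(y) != nrow(X)) {
    y <- vapply(seq_len(nrow(X)), function(i) {
      tryCatch(as.numeric(model$fn(X[i, ])), error = function(e) NA_real_)
    }, numeric(1))
  }
  failed <- which(!is.finite(y))
  if (length(failed)) attr(y, "failed") <- failed
  y
}

## ---------------------------------------------------------------------------
## Steady-state maternal-fetal thyroid-iodide stand-in
## ---------------------------------------------------------------------------

# Fixed physical and structural constants of the stand-in.  All scalable
# parameters live in hpt_nominal(); these are stoichiometry and disposition
# fractions that the model treats as known.
.hpt <- local({
  bw <- 72.3                      # maternal body weight, kg (table mean)
  s <- bw^0.75                    # allometric scale
  kdeg_nom <- 1.9e-4 * s          # nominal T4 deiodination rate, 1/h
  vd_nom <- 0.12 * bw             # nominal T4 distribution volume, L
  list(
    mw_iodine = 126.9,            # g/mol
    iodine_per_t4 = 4,            # iodine atoms per thyroxine
    organification = 0.7,         # fraction of thyroidal uptake organified
    hct = 0.33,                   # pregnancy hematocrit (plasma flow = (1-hct)*blood flow)
    clt4 = kdeg_nom * vd_nom / 3, # non-deiodinative T4 disposal, L/h (25% share)
    endo_ratio = 1,               # fetal endogenous fT4 relative to maternal
    bw = bw, scale = s, qc = 15.6 # maternal cardiac output, L/h/BW^0.75
  )
})

#' Nominal parameters of the thyroid--iodide stand-in model
#'
#' Nominal values are the literature means of the corresponding rows of the
#' packaged parameter table, scaled to whole-body units with the nominal
#' maternal body weight (72.3 kg, allometric exponent 0.75): urinary iodide
#' clearance `clu` (L/h), thyroidal NIS capacity `vmax` (nmol/h) and
#' affinity `km` (nM), passive thyroid permeability `pa_thy` (L/h),
#' thyroid plasma flow `q_thy` (L/h), T4 production rate constant `kprod`
#' (1/h), T4 deiodination rate constant `kdeg` (1/h), T4 distribution
#' volume `vd` (L), serum free fraction `frconv`, recycled fraction of
#' hormone-bound iodine `frecycle`, and the fraction of fetal T4 of
#' maternal (placental) origin `placental_share`.
#'
#' @param intake dietary iodide intake, micrograms/day (euthyroid
#'   evaluation condition: 200).
#' @param placental_share fraction of fetal T4 of maternal origin
#'   (calibrated value: 0.20).
#' @return Named list of class `hpt_parameters`.
#' @export
hpt_nominal <- function(intake = 200, placental_share = 0.2) {
  s <- .hpt$scale
  p <- list(
    intake = intake,
    clu    = 0.17 * s,
    vmax   = 3800 * s,
    km     = 31500,
    pa_thy = 1e-4 * s,
    q_thy  = 0.016 * .hpt$qc * (1 - .hpt$hct) * s,
    kprod  = 2.5e-6 * s,
    kdeg   = 1.9e-4 * s,
    vd     = 0.12 * .hpt$bw,
    frconv = 9e-5,
    frecycle = 0.9,
    placental_share = placental_share)
  class(p) <- "hpt_parameters"
  validate_hpt(p)
  p
}

validate_hpt <- function(p) {
  num <- c("intake", "clu", "vmax", "km", "pa_thy", "q_thy", "kprod",
           "kdeg", "vd", "frconv", "frecycle", "placental_share")
  miss <- setdiff(num, names(p))
  if (length(miss)) stop_("missing parameter(s): %s", paste(miss, collapse = ", "))
  v <- vapply(p[num], function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(v))) stop_("non-finite parameter(s): %s",
                                paste(num[!is.finite(v)], collapse = ", "))
  # vmax/pa may be 0 in limiting cases; placental_share has its own [0,1] rule
  pos <- setdiff(num, c("vmax", "pa_thy", "placental_share"))
  if (any(v[pos] <= 0)) stop_("parameter(s) must be positive: %s",
                              paste(pos[v[pos] <= 0], collapse = ", "))
  if (any(v[c("vmax", "pa_thy")] < 0)) stop_("vmax and pa_thy must be nonnegative")
  frac <- c("frconv", "frecycle")
  if (any(v[frac] <= 0 | v[frac] >= 1)) stop_("%s must lie in (0, 1)",
                                              paste(frac[v[frac] <= 0 | v[frac] >= 1], collapse = ", "))
  if (v["placental_share"] < 0 || v["placental_share"] > 1)
    stop_("placental_share must lie in [0, 1]")
  invisible(p)
}

# Net organification flux J (nmol iodine/h) at plasma iodide C (nM).
# Thyroid capillary iodide Cb solves the quasi-steady delivery balance
#   q_thy (C - Cb) = phi (vmax Cb/(km + Cb) + pa_thy Cb),
# a quadratic in Cb solved in closed, numerically stable form.
hpt_organification_flux <- function(p, C) {
  phi <- .hpt$organification
  A <- p$q_thy + phi * p$pa_thy
  B <- p$q_thy * p$km + phi * p$pa_thy * p$km + phi * p$vmax - p$q_thy * C
  Cc <- -p$q_thy * C * p$km
  disc <- sqrt(B^2 - 4 * A * Cc)
  Cb <- if (B >= 0) 2 * (-Cc) / (B + disc) else (-B + disc) / (2 * A)
  p$q_thy * (C - Cb)
}

#' Steady state of the thyroid--iodide stand-in model
#'
#' A one-pool steady-state reduction of maternal iodide kinetics and
#' thyroid function.  Dietary iodide enters plasma; urinary clearance
#' (`clu`) competes with thyroidal sequestration, which is NIS-mediated
#' Michaelis--Menten uptake plus passive diffusion, rate-limited by
#' thyroid plasma flow (`q_thy`).  Organified iodine (fraction 0.7 of
#' uptake) supports T4 synthesis (4 iodine atoms per T4); serum total T4
#' follows from first-order disposal (deiodination `kdeg` over volume `vd`
#' plus a fixed non-deiodinative clearance), free T4 from the serum free
#' fraction `frconv`, and a fraction `frecycle` of the iodine bound in
#' degraded hormone re-enters the plasma iodide pool.  Fetal free T4
#' combines a placental (maternal-origin) share with an endogenous term
#' that tracks the maternal level.
#'
#' The plasma iodide balance
#' \deqn{D + f_{rec} J(C) = cl_u C + J(C)}
#' (intake plus recycling against excretion plus organification) is solved
#' for the iodide concentration `C` by bracketed root finding to a relative
#' tolerance of 1e-10; `J(C)` is the flow-limited organification flux.
#'
#' @param p parameters from [hpt_nominal()] (or a modified copy).
#' @return Named vector `serum_iodide` (nM), `tt4` (nmol/L), `ft4`
#'   (pmol/L), `fetal_ft4` (pmol/L), with attribute `mass_balance_rel`
#'   giving the relative residual of the iodide balance at the root.
#' @examples
#' hpt_steady_state(hpt_nominal())
#' @export
hpt_steady_state <- function(p) {
  validate_hpt(p)
  D <- p$intake / 24 / .hpt$mw_iodine * 1000      # ug/day -> nmol/h
  balance <- function(C) D - p$clu * C - (1 - p$frecycle) * hpt_organification_flux(p, C)
  hi <- D / p$clu
  lo <- 0
  f_lo <- balance(lo); f_hi <- balance(hi * (1 + 1e-9))
  if (!(f_lo >= 0 && f_hi <= 0)) {
    stop_(paste0("no sign change when bracketing the iodide balance ",
                 "(clu=%.3g, vmax=%.3g, km=%.3g, q_thy=%.3g, frecycle=%.3g)"),
          p$clu, p$vmax, p$km, p$q_thy, p$frecycle)
  }
  C <- stats::uniroot(balance, c(lo, hi * (1 + 1e-9)), tol = 1e-10 * hi)$root
  J <- hpt_organification_flux(p, C)
  tt4 <- (J / .hpt$iodine_per_t4) / (p$kdeg * p$vd + .hpt$clt4)
  ft4 <- p$frconv * tt4 * 1e3                     # nmol/L free -> pmol/L
  endo <- .hpt$endo_ratio * ft4
  fetal <- p$placental_share * ft4 + (1 - p$placental_share) * endo
  out <- c(serum_iodide = C, tt4 = tt4, ft4 = ft4, fetal_ft4 = fetal)
  influx <- D + p$frecycle * J
  attr(out, "mass_balance_rel") <- abs(influx - (p$clu * C + J)) / influx
  out
}

#' Nominal stand-in parameters with a chosen placental share
#'
#' Returns the nominal parameterization with `placental_share` set so that
#' the maternal-origin fraction of fetal T4 equals `target` at nominal
#' conditions (post-calibration estimate: 20%).
#'
#' @param target maternal-origin fraction of fetal T4, in `[0, 1]`.
#' @return `hpt_parameters` list.
#' @export
calibrate_placental_share <- function(target = 0.20) {
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target) ||
      target < 0 || target > 1)
    stop_("target must be a fraction in [0, 1]")
  hpt_nominal(placental_share = target)
}

#' Maternal-origin fraction of fetal free T4 at steady state
#' @param p parameters from [hpt_nominal()].
#' @return scalar fraction.
#' @export
fetal_maternal_fraction <- function(p) {
  st <- hpt_steady_state(p)
  if (st[["fetal_ft4"]] == 0) return(0)
  unname(p$placental_share * st[["ft4"]] / st[["fetal_ft4"]])
}

# Names of the stand-in parameters varied in the sensitivity demos.
.hpt_varied <- c("clu", "vmax", "km", "q_thy", "pa_thy", "kprod",
                 "kdeg", "vd", "frconv", "frecycle")

#' Vectorized steady-state evaluation of the stand-in
#'
#' Evaluates [hpt_steady_state()] over many parameter vectors at once,
#' solving the plasma-iodide balance for all rows simultaneously by
#' bisection (the balance is strictly monotone, so bisection is exact to
#' the bracket width; 100 halvings take it far below the scalar solver's
#' tolerance).  Row-by-row agreement with [hpt_steady_state()] is part of
#' the test suite.
#'
#' @param X matrix whose named columns override fields of `base` (any
#'   subset of the parameters of [hpt_nominal()]).
#' @param base baseline parameter list.
#' @param output which steady-state quantity to return.
#' @return numeric vector, one output per row of `X`.
#' @export
hpt_batch <- function(X, base = hpt_nominal(),
                      output = c("ft4", "tt4", "serum_iodide", "fetal_ft4")) {
  output <- match.arg(output)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop_("X needs parameter names as column names")
  unknown <- setdiff(colnames(X), names(base))
  if (length(unknown)) stop_("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  n <- nrow(X)
  get <- function(nm) if (nm %in% colnames(X)) X[, nm] else rep(base[[nm]], n)
  clu <- get("clu"); vmax <- get("vmax"); km <- get("km")
  pa <- get("pa_thy"); q <- get("q_thy"); kdeg <- get("kdeg")
  vd <- get("vd"); frconv <- get("frconv"); fre <- get("frecycle")
  share <- get("placental_share"); intake <- get("intake")
  phi <- .hpt$organification
  D <- intake / 24 / .hpt$mw_iodine * 1000
  Jfun <- function(C) {
    A <- q + phi * pa
    B <- q * km + phi * pa * km + phi * vmax - q * C
    Cc <- -q * C * km
    disc <- sqrt(pmax(B^2 - 4 * A * Cc, 0))
    Cb <- ifelse(B >= 0, 2 * (-Cc) / (B + disc), (-B + disc) / (2 * A))
    q * (C - Cb)
  }
  lo <- rep(0, n); hi <- D / clu * (1 + 1e-9)
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    pos <- (D - clu * mid - (1 - fre) * Jfun(mid)) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  C <- (lo + hi) / 2
  J <- Jfun(C)
  tt4 <- (J / .hpt$iodine_per_t4) / (kdeg * vd + .hpt$clt4)
  ft4 <- frconv * tt4 * 1e3
  switch(output,
         ft4 = ft4, tt4 = tt4, serum_iodide = C,
         fetal_ft4 = share * ft4 + (1 - share) * .hpt$endo_ratio * ft4)
}

#' Uncertainty space of the stand-in's ten varied parameters
#'
#' Ranges follow the revised (physiologically plausible) ranges of the
#' corresponding rows of the packaged tables, scaled to whole-body units
#' with the nominal body weight; thyroid plasma flow additionally carries
#' the plasma-fraction factor.  The recycled fraction, which has no table
#' counterpart, gets a Gaussian 95% range with an assumed 5% CV around its
#' nominal 0.9.
#'
#' @return A [parameter_space()] with 10 rows named as in [hpt_nominal()].
#' @export
hpt_space <- function() {
  s <- .hpt$scale
  nom <- hpt_nominal()
  qf <- .hpt$qc * (1 - .hpt$hct) * s
  rng <- rbind(
    clu    = c(7.87e-2, 2.11e-1) * s,
    vmax   = c(1.22e3, 5.64e3) * s,
    km     = c(1.33e4, 4.46e4),
    q_thy  = c(5.43e-3, 2.66e-2) * qf,
    pa_thy = c(4e-5, 1.6e-4) * s,
    kprod  = c(6.85e-7, 4.21e-6) * s,
    kdeg   = c(1.03e-4, 2.52e-4) * s,
    vd     = c(7.69e-2, 1.63e-1) * .hpt$bw,
    frconv = c(5.67e-5, 1.14e-4),
    frecycle = 0.9 * c(1 - 1.96 * 0.05, 1 + 1.96 * 0.05))
  means <- unlist(nom[.hpt_varied])
  units <- c(clu = "L/h", vmax = "nmol/h", km = "nM", q_thy = "L/h",
             pa_thy = "L/h", kprod = "1/h", kdeg = "1/h", vd = "L",
             frconv = "dimensionless", frecycle = "dimensionless")
  parameter_space(data.frame(
    name = .hpt_varied, mean = unname(means),
    cv = unname((rng[, 2] - rng[, 1]) / (2 * 1.96 * means)),
    lower = unname(rng[, 1]), upper = unname(rng[, 2]),
    units = unname(units[.hpt_varied]), group = "",
    provenance = "revised", stringsAsFactors = FALSE))
}

#' The thyroid--iodide stand-in as a `gsa_model`
#'
#' Ten parameters are varied (see [hpt_space()]); the remainder stay at
#' nominal.  The default output is maternal serum free T4 at steady state.
#'
#' @param output one of `"ft4"`, `"tt4"`, `"serum_iodide"`, `"fetal_ft4"`.
#' @param intake dietary iodide intake, micrograms/day.
#' @return A [gsa_model()] evaluating in physical units with the stand-in's
#'   uncertainty space attached.
#' @export
hpt_model <- function(output = c("ft4", "tt4", "serum_iodide", "fetal_ft4"),
                      intake = 200) {
  output <- match.arg(output)
  space <- hpt_space()
  base <- hpt_nominal(intake = intake)
  fn <- function(theta) {
    p <- base
    p[.hpt_varied] <- as.list(unname(theta))
    hpt_steady_state(p)[[output]]
  }
  labels <- c(ft4 = "maternal fT4, pmol/L", tt4 = "maternal TT4, nmol/L",
              serum_iodide = "maternal serum iodide, nM",
              fetal_ft4 = "fetal fT4, pmol/L")
  bfn <- function(X) {
    colnames(X) <- .hpt_varied
    hpt_batch(X, base = base, output = output)
  }
  gsa_model(name = paste0("hpt_", output), k = nrow(space), fn = fn,
            nominal = unlist(base[.hpt_varied]), space = space,
            unit_cube = FALSE, output_label = unname(labels[output]),
            batch_fn = bfn)
}

## ---------------------------------------------------------------------------
## Analytic benchmark functions with known variance decompositions
## ---------------------------------------------------------------------------

#' Benchmark models with closed-form sensitivity indices
#'
#' Standard test functions on the unit hypercube, each carrying its
#' analytic variance decomposition as oracle metadata (`$oracle`):
#' \describe{
#'   \item{`linear_additive`}{`y = sum(a_i u_i)`, `S_i = T_i =
#'     a_i^2 / sum(a_j^2)` for independent U(0,1) inputs.}
#'   \item{`product`}{`y = u1 u2`; `S_1 = S_2 = 3/7`, interaction `1/7`,
#'     `T_i = 4/7`, `Var(Y) = 7/144`.}
#'   \item{`ishigami`}{the Ishigami function on `[-pi, pi]^3` (inputs given
#'     on the unit cube and rescaled internally).}
#'   \item{`sobol_g`}{Sobol' g-function with coefficients `a`.}
#'   \item{`constant`}{constant output; all indices undefined (variance 0).}
#' }
#'
#' @param name function name.
#' @param a coefficients: weights for `linear_additive` (default `c(2,3)`),
#'   `c(a, b)` for `ishigami` (default `c(7, 0.1)`), the `a_i` for
#'   `sobol_g` (default `c(0, 1, 4.5, 9)`), the constant value for
#'   `constant` (default 1).
#' @param k input dimension where free (`product` is fixed at 2,
#'   `ishigami` at 3).
#' @return A [gsa_model()] on the unit cube with oracle metadata.
#' @examples
#' m <- test_function("ishigami")
#' m$oracle$main   # 0.3139, 0.4424, 0
#' @export
test_function <- function(name = c("linear_additive", "product", "ishigami",
                                   "sobol_g", "constant"),
                          a = NULL, k = NULL) {
  name <- match.arg(name)
  switch(name,
    linear_additive = {
      a <- a %||% c(2, 3)
      if (!is.null(k) && length(a) != k) stop_("need %d coefficients, got %d", k, length(a))
      k <- length(a)
      Vi <- a^2 / 12
      gsa_model("linear_additive", k, function(u) sum(a * u),
                nominal = rep(0.5, k),
                oracle = list(main = Vi / sum(Vi), total = Vi / sum(Vi),
                              variance = sum(Vi),
                              pairwise = matrix(0, k, k)),
                batch_fn = function(U) drop(U %*% a))
    },
    product = {
      if (!is.null(k) && k != 2) stop_("product model is bivariate")
      V <- 7 / 144
      pw <- matrix(0, 2, 2); pw[1, 2] <- pw[2, 1] <- 1 / 7
      gsa_model("product", 2, function(u) u[1] * u[2], nominal = c(0.5, 0.5),
                oracle = list(main = c(3 / 7, 3 / 7), total = c(4 / 7, 4 / 7),
                              variance = V, pairwise = pw),
                batch_fn = function(U) U[, 1] * U[, 2])
    },
    ishigami = {
      a <- a %||% c(7, 0.1)
      if (length(a) != 2) stop_("ishigami takes coefficients c(a, b)")
      A <- a[1]; B <- a[2]
      V1 <- 0.5 * (1 + B * pi^4 / 5)^2
      V2 <- A^2 / 8
      V13 <- 8 * B^2 * pi^8 / 225
      V <- V1 + V2 + V13
      pw <- matrix(0, 3, 3); pw[1, 3] <- pw[3, 1] <- V13 / V
      gsa_model("ishigami", 3, function(u) {
        x <- -pi + 2 * pi * u
        sin(x[1]) + A * sin(x[2])^2 + B * x[3]^4 * sin(x[1])
      }, nominal = rep(0.5, 3),
      oracle = list(main = c(V1, V2, 0) / V,
                    total = c(V1 + V13, V2, V13) / V,
                    variance = V, pairwise = pw),
      batch_fn = function(U) {
        X <- -pi + 2 * pi * U
        sin(X[, 1]) + A * sin(X[, 2])^2 + B * X[, 3]^4 * sin(X[, 1])
      })
    },
    sobol_g = {
      a <- a %||% c(0, 1, 4.5, 9)
      if (!is.null(k) && length(a) != k) stop_("need %d coefficients, got %d", k, length(a))
      if (any(a < 0)) stop_("sobol_g coefficients must be nonnegative")
      k <- length(a)
      Vi <- 1 / (3 * (1 + a)^2)
      V <- prod(1 + Vi) - 1
      Ti <- Vi * prod(1 + Vi) / (1 + Vi) / V
      gsa_model("sobol_g", k, function(u) prod((abs(4 * u - 2) + a) / (1 + a)),
                nominal = rep(0.5, k),
                oracle = list(main = Vi / V, total = Ti, variance = V),
                batch_fn = function(U) {
                  out <- rep(1, nrow(U))
                  for (j in seq_len(k)) out <- out * (abs(4 * U[, j] - 2) + a[j]) / (1 + a[j])
                  out
                })
    },
    constant = {
      val <- (a %||% 1)[1]
      k <- k %||% 3
      gsa_model("constant", k, function(u) val, nominal = rep(0.5, k),
                oracle = list(main = rep(0, k), total = rep(0, k), variance = 0),
                batch_fn = function(U) rep(val, nrow(U)))
    })
}

#' Append inert dummy inputs to a model
#'
#' The returned model has dimension `k + n_dummy` and ignores the appended
#' coordinates, so their elementary effects and sensitivity indices are
#' exactly zero -- a screening-validation fixture.
#'
#' @param model a unit-cube [gsa_model()].
#' @param n_dummy number of dummy inputs (>= 1).
#' @return A [gsa_model()] of dimension `model$k + n_dummy`.
#' @export
augment_with_dummies <- function(model, n_dummy) {
  stopifnot(inherits(model, "gsa_model"), is_count(n_dummy))
  if (!model$unit_cube) stop_("dummy augmentation expects a unit-cube model")
  k0 <- model$k
  oracle <- model$oracle
  if (!is.null(oracle)) {
    oracle$main <- c(oracle$main, rep(0, n_dummy))
    oracle$total <- c(oracle$total, rep(0, n_dummy))
  }
  gsa_model(paste0(model$name, "+", n_dummy, "dummy"), k0 + n_dummy,
            function(u) model$fn(u[seq_len(k0)]),
            nominal = c(model$nominal %||% rep(0.5, k0), rep(0.5, n_dummy)),
            output_label = model$output_label, oracle = oracle)
}
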