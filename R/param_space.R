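#' Derive an uncertainty range from a mean and coefficient of variation
#'
#' Parameter ranges are the 2.5th and 97.5th percentiles of a Gaussian
#' distribution with the given mean and coefficient of variation (CV =
#' SD/mean), i.e. `mean * (1 +/- 1.96 * cv)`.  When the Gaussian 2.5th
#' percentile is non-positive -- which happens exactly when `cv >= 1/1.96`
#' for a positive mean -- a physical lower bound cannot come from that rule,
#' and the range falls back to one standard deviation on either side,
#' `mean * (1 +/- cv)`.
#'
#' The multiplier is fixed at 1.96 (not `qnorm(0.975)` = 1.959964) so that
#' worked ranges quoted to full precision reproduce exactly.  Returned
#' values are exact; callers round for display.
#'
#' @param mean positive parameter mean(s), native units.
#' @param cv nonnegative coefficient(s) of variation.  `cv = 0` collapses
#'   the range to the mean.
#' @return A data frame with columns `lower`, `upper` and `rule`
#'   (`"gaussian95"` or `"one_sd"`), one row per input element.
#' @examples
#' derive_bounds(72.3, 0.14)   # gaussian95: 52.46..., 92.14...
#' derive_bounds(750, 0.62)    # one_sd fallback: 285, 1215
#' @export
derive_bounds <- function(mean, cv) {
  if (!is.numeric(mean) || !is.numeric(cv)) stop_("mean and cv must be numeric")
  n <- max(length(mean), length(cv))
  mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  if (any(!is.finite(mean)) || any(!is.finite(cv))) stop_("non-finite mean or cv")
  if (any(mean <= 0)) stop_("mean must be positive")
  if (any(cv < 0)) stop_("cv must be nonnegative")
  z <- 1.96
  lower <- mean * (1 - z * cv)
  upper <- mean * (1 + z * cv)
  fb <- lower <= 0 & cv > 0
  lower[fb] <- mean[fb] * (1 - cv[fb])
  upper[fb] <- mean[fb] * (1 + cv[fb])
  data.frame(lower = lower, upper = upper,
             rule = ifelse(fb, "one_sd", "gaussian95"),
             stringsAsFactors = FALSE)
}

#' Construct a parameter space
#'
#' A parameter space is an ordered collection of uncertain scalar inputs,
#' each with a mean, CV, range, units and optional compartment group.
#' Members of a compartment group are fractions (of a flow or a volume)
#' that must sum to a fixed total; their nominal means must already do so,
#' and sampled values are renormalized by [map_unit_to_physical()].
#'
#' @param x data frame with columns `name`, `mean`, `cv`, `lower`, `upper`,
#'   and optionally `units`, `group`, `provenance`.
#' @param groups named numeric vector giving each group's required total;
#'   defaults to 1 for every group id present in `x$group`.
#' @return An object of class `param_space` (a validated data frame with a
#'   `groups` attribute).
#' @export
parameter_space <- function(x, groups = NULL) {
  req <- c("name", "mean", "cv", "lower", "upper")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop_("missing column(s): %s", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"units" %in% names(x)) x$units <- ""
  if (!"group" %in% names(x)) x$group <- ""
  if (!"provenance" %in% names(x)) x$provenance <- "literature"
  x$group[is.na(x$group)] <- ""
  x$name <- as.character(x$name)
  for (col in c("mean", "cv", "lower", "upper")) {
    if (!is.numeric(x[[col]])) stop_("column '%s' must be numeric", col)
    if (any(!is.finite(x[[col]])))
      stop_("non-finite value in column '%s' (row %s)", col,
            paste(x$name[!is.finite(x[[col]])], collapse = ", "))
  }
  dup <- x$name[duplicated(x$name)]
  if (length(dup)) stop_("duplicate parameter name(s): %s", paste(unique(dup), collapse = ", "))
  if (any(x$cv < 0)) stop_("negative cv (row %s)", paste(x$name[x$cv < 0], collapse = ", "))
  bad <- x$lower > x$upper
  if (any(bad)) stop_("lower > upper (row %s)", paste(x$name[bad], collapse = ", "))
  if (!all(x$provenance %in% c("literature", "assumed_default", "revised")))
    stop_("provenance must be literature, assumed_default or revised")
  gid <- unique(x$group[nzchar(x$group)])
  if (is.null(groups)) groups <- stats::setNames(rep(1, length(gid)), gid)
  for (g in gid) {
    if (!g %in% names(groups)) stop_("no required total given for group '%s'", g)
    tot <- sum(x$mean[x$group == g])
    if (abs(tot - groups[[g]]) > 1e-9)
      stop_("group '%s': nominal means sum to %.12g, expected %.12g", g, tot, groups[[g]])
  }
  structure(x, groups = groups[gid], class = c("param_space", "data.frame"))
}

#' @export
print.param_space <- function(x, ...) {
  cat(sprintf("Parameter space: %d parameters", nrow(x)))
  g <- attr(x, "groups")
  if (length(g)) cat(sprintf(", %d constraint group(s) [%s]",
                             length(g), paste(names(g), collapse = ", ")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Half-unit-in-last-place tolerance implied by how a number was printed:
# "52.5" -> 0.05, "478" -> 0.5, "3e-04" -> 5e-05.
printed_tolerance <- function(s) {
  s <- trimws(s)
  vapply(s, function(si) {
    if (grepl("[eE]", si)) {
      parts <- strsplit(si, "[eE]")[[1]]
      mant <- sub("-", "", parts[1])
      digits <- nchar(gsub("[^0-9]", "", mant))
      int_digits <- nchar(gsub("[^0-9]", "", sub("\\..*", "", mant)))
      0.5 * 10^(as.numeric(parts[2]) + int_digits - 1) * 10^(-(digits - 1))
    } else if (grepl("\\.", si)) {
      0.5 * 10^(-nchar(sub(".*\\.", "", si)))
    } else 0.5
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a parameter table from CSV
#'
#' Expects the columns `name,mean,cv,lower,upper,units,group,provenance`.
#' Bounds are recomputed from mean and CV by [derive_bounds()] and
#' cross-checked against the stored bounds at the precision each stored
#' value was printed with; the per-row comparison is attached as attribute
#' `"bound_check"`.  Rows whose stored bounds match neither derivation rule
#' are kept as stored (several literature ranges were set by other means)
#' and simply flagged in the report.
#'
#' @param path CSV file path.
#' @param groups optional named vector of group totals (default: 1 each).
#' @return A [parameter_space()] with a `bound_check` attribute.
#' @seealso [hpt_parameter_table()] for the packaged 66-parameter fixture.
#' @export
read_parameter_table <- function(path, groups = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop_("parameter table is empty: %s", path)
  req <- c("name", "mean", "cv", "lower", "upper")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop_("missing column(s): %s", paste(miss, collapse = ", "))
  num <- raw
  for (col in c("mean", "cv", "lower", "upper")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v)))
      stop_("non-numeric '%s' in row(s): %s", col,
            paste(raw$name[is.na(v)], collapse = ", "))
    num[[col]] <- v
  }
  space <- parameter_space(num, groups = groups)
  rec <- derive_bounds(space$mean, space$cv)
  chk <- data.frame(
    name = space$name,
    rule = rec$rule,
    lower_stored = space$lower, lower_recomputed = rec$lower,
    upper_stored = space$upper, upper_recomputed = rec$upper,
    lower_ok = abs(rec$lower - space$lower) <= printed_tolerance(raw$lower) + 1e-12,
    upper_ok = abs(rec$upper - space$upper) <= printed_tolerance(raw$upper) + 1e-12,
    stringsAsFactors = FALSE)
  attr(space, "bound_check") <- chk
  space
}

#' The packaged 66-parameter maternal--fetal thyroid model table
#'
#' Loads the packaged uncertainty table for the 66 maternal and fetal
#' physiological and biochemical parameters of a near-term-pregnancy
#' thyroid/iodide kinetics model: literature-derived means, CVs (30%
#' assumed where no variability data exist), Gaussian 95% ranges, and
#' mass-balance constraint groups for the lumped blood-flow and
#' tissue-volume fractions.  Six lumped-compartment complement rows
#' (`QFRP_MI`, `QFSP_MI`, `QFROB_FI`, `VFRP_MI`, `VFSP_MI`, `VFROB_FI`)
#' are reconstructed so that each constraint group sums to its total; they
#' are marked `assumed_default`.
#'
#' @return A [parameter_space()] with 66 rows.
#' @export
hpt_parameter_table <- function() {
  read_parameter_table(system.file("extdata", "table1_parameters.csv",
                                   package = "emugsa", mustWork = TRUE))
}

#' Revise parameter ranges
#'
#' Replaces the ranges of named parameters, e.g. after emulator diagnostics
#' reveal that a range admits physiologically irrelevant model output and
#' must be narrowed.  Revised rows get `provenance = "revised"`; the input
#' space is not modified.
#'
#' @param space a [parameter_space()].
#' @param overrides data frame with columns `name`, `lower`, `upper`, or a
#'   named list of `c(lower, upper)` pairs.
#' @return A new `param_space` with the revised ranges.
#' @export
apply_range_overrides <- function(space, overrides) {
  stopifnot(inherits(space, "param_space"))
  if (is.list(overrides) && !is.data.frame(overrides)) {
    overrides <- data.frame(name = names(overrides),
                            lower = vapply(overrides, `[`, 0, 1),
                            upper = vapply(overrides, `[`, 0, 2),
                            stringsAsFactors = FALSE)
  }
  if (nrow(overrides) == 0L) return(space)
  req <- c("name", "lower", "upper")
  if (!all(req %in% names(overrides))) stop_("overrides need columns name, lower, upper")
  unknown <- setdiff(overrides$name, space$name)
  if (length(unknown)) stop_("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  bad <- overrides$lower >= overrides$upper
  if (any(bad)) stop_("lower >= upper for: %s", paste(overrides$name[bad], collapse = ", "))
  out <- space
  i <- match(overrides$name, out$name)
  out$lower[i] <- overrides$lower
  out$upper[i] <- overrides$upper
  out$provenance[i] <- "revised"
  attr(out, "bound_check") <- NULL
  out
}

#' Read a range-override CSV (`name,lower,upper`)
#' @param path CSV file path.
#' @return data frame suitable for [apply_range_overrides()].
#' @export
read_range_overrides <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "lower", "upper")
  if (!all(req %in% names(x))) stop_("override file needs columns name, lower, upper")
  x[, req]
}

#' The packaged revised ranges for the 26 screened parameters
#'
#' Ranges narrowed to the physiologically plausible sampling space used in
#' the quantitative (emulator) stage of the analysis.
#' @return data frame `name,lower,upper` (26 rows).
#' @export
hpt_revised_ranges <- function() {
  read_range_overrides(system.file("extdata", "table3_revised_ranges.csv",
                                   package = "emugsa", mustWork = TRUE))
}

#' Map unit-cube coordinates to physical parameter values
#'
#' Each coordinate is mapped affinely, `lower + u * (upper - lower)`
#' (sampling within a range is uniform).  Afterwards every compartment
#' group is rescaled so the sampled fractions sum to the group's required
#' total exactly, preserving mass balance in lumped compartments and blood
#' flows; entries outside any group are untouched.
#'
#' @param space a [parameter_space()].
#' @param u numeric vector of length `k`, or an `n x k` matrix, with
#'   entries in `[0, 1]`; `k = nrow(space)`.
#' @return Named vector (or matrix with named columns) of physical values.
#' @export
map_unit_to_physical <- function(space, u) {
  stopifnot(inherits(space, "param_space"))
  k <- nrow(space)
  vec_in <- is.null(dim(u))
  U <- as_matrix_rows(u, k)
  if (any(U < 0 | U > 1)) stop_("unit-cube coordinates must lie in [0, 1]")
  X <- sweep(sweep(U, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(X) <- space$name
  groups <- attr(space, "groups")
  for (g in names(groups)) {
    j <- which(space$group == g)
    s <- rowSums(X[, j, drop = FALSE])
    if (any(s <= 0)) stop_("group '%s' sampled to a non-positive sum", g)
    X[, j] <- X[, j, drop = FALSE] * (groups[[g]] / s)
  }
  if (vec_in) X[1L, ] else X
}
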