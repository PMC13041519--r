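#' Aggregate per-prediction records into per-cell means
#'
#' Groups records by their unique parameter combination (scenario, escape
#' speed, delay, distance to safety, approach speed, beta) and computes the
#' cell statistic: in expectation mode the mean phase-two probability, in
#' bernoulli mode the fraction of drawn collisions.
#'
#' @param records per-prediction data.frame, e.g. from [run_cell()] or a
#'   [run_sweep()] with `keep_records = TRUE`.
#' @param statistic `"expectation"` (mean of `p_collision`) or `"bernoulli"`
#'   (mean of `outcome`; requires the records to carry outcomes).
#' @return data.frame with one row per cell: the fixed parameters plus
#'   `mean`, `sd` and `n`.
#' @export
aggregate_by_cell <- function(records,
                              statistic = c("expectation", "bernoulli")) {
  statistic <- match.arg(statistic)
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  dt <- data.table::as.data.table(records)
  val <- if (statistic == "bernoulli") {
    if (is.null(dt$outcome)) {
      stop("records carry no `outcome` column; run in bernoulli mode",
           call. = FALSE)
    }
    as.numeric(dt$outcome)
  } else {
    dt$p_collision
  }
  dt[, .value := val]
  out <- dt[, list(mean = mean(.value), sd = stats::sd(.value), n = .N),
            by = c("scenario", "Sa", "delta", "d_min", "Sv", "beta")]
  as.data.frame(out)
}

#' Bin per-prediction records by a sampled behavioral variable
#'
#' Bins the sampled escape angle or flight-initiation distance to a fixed
#' width (0.1 degree or 0.1 m by default) and returns the mean collision
#' probability per bin and scenario — the behavioral response curves.
#' Bins are half-open `[k*w, (k+1)*w)` and reported at their midpoints.
#'
#' @param records per-prediction data.frame.
#' @param by `"angle"` (escape angle, degrees) or `"fid"`
#'   (flight-initiation distance, m).
#' @param bin_width bin width in the variable's units; default 0.1.
#' @param statistic as in [aggregate_by_cell()].
#' @return data.frame with `scenario`, `bin` (midpoint), `mean`, `sd`, `n`,
#'   ordered by scenario and bin.
#' @export
aggregate_by_behavior <- function(records, by = c("angle", "fid"),
                                  bin_width = 0.1,
                                  statistic = c("expectation", "bernoulli")) {
  by <- match.arg(by)
  statistic <- match.arg(statistic)
  stopifnot(bin_width > 0)
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  x <- if (by == "angle") records$theta else records$d_fid
  val <- if (statistic == "bernoulli") {
    if (is.null(records$outcome)) {
      stop("records carry no `outcome` column; run in bernoulli mode",
           call. = FALSE)
    }
    as.numeric(records$outcome)
  } else {
    records$p_collision
  }
  dt <- data.table::data.table(
    scenario = records$scenario,
    bin = (bin_index(x, bin_width) + 0.5) * bin_width,
    .value = val)
  out <- dt[, list(mean = mean(.value), sd = stats::sd(.value), n = .N),
            by = c("scenario", "bin")]
  data.table::setorderv(out, c("scenario", "bin"))
  as.data.frame(out)
}

#' Marginal response curves over the manipulated grid variables
#'
#' For each systematically varied parameter (escape speed, delay, distance
#' to safety, approach speed, beta), averages the per-cell means over all
#' other parameters, per scenario — the mean-and-SD summaries typically
#' plotted against each manipulated variable.
#'
#' @param cells per-cell summary data.frame (the `cells` element of a
#'   [run_sweep()] result, or [aggregate_by_cell()] output).
#' @param variables which variables to marginalize over; defaults to all
#'   five.
#' @return Named list of data.frames, one per variable, each with
#'   `scenario`, `value`, `mean`, `sd` and `n_cells`.
#' @export
marginal_curves <- function(cells, variables = c("Sa", "delta", "d_min",
                                                 "Sv", "beta")) {
  variables <- match.arg(variables, several.ok = TRUE)
  dt <- data.table::as.data.table(cells)
  out <- lapply(variables, function(v) {
    m <- dt[, list(mean = mean(mean), sd = stats::sd(mean), n_cells = .N),
            by = c("scenario", v)]
    data.table::setnames(m, v, "value")
    data.table::setorderv(m, c("scenario", "value"))
    as.data.frame(m)
  })
  names(out) <- variables
  out
}

#' Grand mean per scenario
#'
#' Mean and SD of the per-cell means, per scenario — the headline summary of
#' a sweep.
#'
#' @param cells per-cell summary data.frame (see [marginal_curves()]).
#' @return data.frame with `scenario`, `mean`, `sd`, `n_cells`.
#' @export
grand_means <- function(cells) {
  dt <- data.table::as.data.table(cells)
  out <- dt[, list(mean = mean(mean), sd = stats::sd(mean), n_cells = .N),
            by = "scenario"]
  as.data.frame(out)
}
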