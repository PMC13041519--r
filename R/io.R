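#' Write sweep outputs to a directory
#'
#' Writes the components of a [run_sweep()] result as UTF-8, comma-separated,
#' period-decimal CSV files plus a JSON run manifest. Output is byte-stable
#' for a fixed seed and grid, so files can serve as regression fixtures.
#'
#' Files written: `cells.csv` (per-cell means), `angle_curve.csv` and
#' `fid_curve.csv` (behavioral bins), `marginal_<var>.csv` for each
#' manipulated variable, `grand_means.csv`, `manifest.json`, and
#' `records.csv` when per-prediction records were kept.
#'
#' @param sweep a `sweep_result` from [run_sweep()].
#' @param dir output directory; created if missing.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(sweep, dir) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    data.table::fwrite(df, p)
    paths <<- c(paths, p)
  }
  wr(sweep$cells, "cells.csv")
  wr(sweep$angle_curve, "angle_curve.csv")
  wr(sweep$fid_curve, "fid_curve.csv")
  wr(sweep$grand, "grand_means.csv")
  marg <- marginal_curves(sweep$cells)
  for (v in names(marg)) wr(marg[[v]], paste0("marginal_", v, ".csv"))
  if (!is.null(sweep$records)) wr(sweep$records, "records.csv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(sweep$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}

#' Read per-prediction records written by [write_outputs()]
#'
#' @param path a `records.csv` file.
#' @return data.frame of per-prediction records.
#' @export
read_records <- function(path) {
  as.data.frame(data.table::fread(path))
}
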