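#' Default sweep configuration
#'
#' Returns the configuration of the reference application — a Canada goose
#' (body length 1.15 m) in the path of a Boeing-737-class aircraft — as a
#' plain named list that can be written to, or overridden from, a YAML file:
#'
#' * escape speed `Sa`: 1 to 17 m/s in steps of 2 (9 values);
#' * sensory-motor delay `delta`: 0 to 1 s in steps of 0.1 (11 values);
#' * minimum distance to safety `d_min`: 10 evenly spaced values from 1 m to
#'   the 14.35-m trajectory width (step 1.4833 m);
#' * approach speed `Sv`: 15 evenly spaced values from 70.47 m/s (150 kts)
#'   to 270.97 m/s (step 14.3214 m/s);
#' * temporal light benefit `beta`: 10 evenly spaced values from 0.5 to
#'   8.5 s (step 0.8889 s);
#' * the three light scenarios (none / blue / red) with away-probabilities
#'   0.42 / 0.65 / 0.11 and baseline flight-initiation distance
#'   Normal(56.2, 16.5) m;
#' * 500 Monte-Carlo iterations per grid cell.
#'
#' `beta` is iterated for the no-light scenario as well (where it has no
#' physical effect) so every scenario contributes the same number of cells;
#' the default grid therefore enumerates
#' 9 x 11 x 10 x 15 x 10 x 3 x 500 = 222,750,000 predictions.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    body_length = 1.15,
    sa = list(from = 1, to = 17, by = 2),
    delta = list(from = 0, to = 1, by = 0.1),
    d_min = list(from = 1, to = 14.35, n = 10),
    sv = list(from = 70.47, to = 270.97, n = 15),
    beta = list(from = 0.5, to = 8.5, n = 10),
    scenarios = c("none", "blue", "red"),
    p_away = list(none = 0.42, blue = 0.65, red = 0.11),
    fid_mean = 56.2,
    fid_sd = 16.5,
    iterations = 500L,
    mode = "expectation",
    eq5_term = "cos",
    beta_speed = "Sv"
  )
}

#' Read a sweep configuration file
#'
#' Reads a YAML configuration and fills unspecified keys from
#' [default_config()].
#'
#' @param path YAML file path.
#' @return Named configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("malformed config file: ", path, call. = FALSE)
  utils::modifyList(default_config(), user)
}

axis_values <- function(ax, nm) {
  if (!is.list(ax) || is.null(ax$from) || is.null(ax$to)) {
    stop("malformed axis spec for `", nm,
         "`: need `from`, `to` and `by` or `n`", call. = FALSE)
  }
  if (ax$to < ax$from) stop("`", nm, "`: `to` must be >= `from`", call. = FALSE)
  if (!is.null(ax$n)) {
    seq(ax$from, ax$to, length.out = ax$n)
  } else if (!is.null(ax$by)) {
    seq(ax$from, ax$to, by = ax$by)
  } else {
    stop("axis spec for `", nm, "` needs `by` or `n`", call. = FALSE)
  }
}

#' Build the parameter grid for a sweep
#'
#' Expands a configuration (see [default_config()]) into explicit value
#' vectors for every swept axis plus the list of [light_scenario()] objects.
#' Grids are constructed by even spacing between the configured endpoints, so
#' the defaults reproduce the reference grid exactly.
#'
#' @param config configuration list; defaults to [default_config()].
#' @return An object of class `parameter_grid`: list with numeric vectors
#'   `sa`, `delta`, `d_min`, `sv`, `beta`, list `scenarios`, and scalars
#'   `body_length`, `iterations`, `mode`, `eq5_term`, `beta_speed`.
#' @examples
#' g <- build_grid()
#' grid_size(g)  # 222,750,000 predictions
#' @export
build_grid <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.numeric(cfg$body_length) || cfg$body_length <= 0) {
    stop("`body_length` must be positive", call. = FALSE)
  }
  iterations <- as.integer(cfg$iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  scen_names <- match.arg(cfg$scenarios, c("none", "blue", "red"),
                          several.ok = TRUE)
  scenarios <- lapply(scen_names, function(k) {
    light_scenario(kind = k, p_away = cfg$p_away[[k]],
                   fid_mean = cfg$fid_mean, fid_sd = cfg$fid_sd)
  })
  names(scenarios) <- scen_names
  g <- list(
    sa = axis_values(cfg$sa, "sa"),
    delta = axis_values(cfg$delta, "delta"),
    d_min = axis_values(cfg$d_min, "d_min"),
    sv = axis_values(cfg$sv, "sv"),
    beta = axis_values(cfg$beta, "beta"),
    scenarios = scenarios,
    body_length = cfg$body_length,
    iterations = iterations,
    mode = match.arg(cfg$mode, c("expectation", "bernoulli")),
    eq5_term = match.arg(cfg$eq5_term, c("cos", "sin")),
    beta_speed = match.arg(cfg$beta_speed, c("Sv", "Sa"))
  )
  if (any(vapply(g[c("sa", "delta", "d_min", "sv", "beta")],
                 function(v) any(v < 0), logical(1)))) {
    stop("grid values must be non-negative", call. = FALSE)
  }
  structure(g, class = "parameter_grid")
}

#' Number of cells and predictions in a grid
#'
#' @param grid a [build_grid()] result.
#' @return For `grid_cells()`, the number of unique parameter combinations;
#'   for `grid_size()`, that count times the iterations per cell (the total
#'   number of model predictions).
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  grid_cells(grid) * grid$iterations
}

#' @rdname grid_size
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  length(grid$sa) * length(grid$delta) * length(grid$d_min) *
    length(grid$sv) * length(grid$beta) * length(grid$scenarios)
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("Parameter grid:\n")
  cat(sprintf("  Sa: %d values [%g..%g] m/s\n", length(x$sa), min(x$sa),
              max(x$sa)))
  cat(sprintf("  delta: %d values [%g..%g] s\n", length(x$delta),
              min(x$delta), max(x$delta)))
  cat(sprintf("  d_min: %d values [%g..%g] m\n", length(x$d_min),
              min(x$d_min), max(x$d_min)))
  cat(sprintf("  Sv: %d values [%g..%g] m/s\n", length(x$sv), min(x$sv),
              max(x$sv)))
  cat(sprintf("  beta: %d values [%g..%g] s\n", length(x$beta), min(x$beta),
              max(x$beta)))
  cat(sprintf("  scenarios: %s\n", paste(names(x$scenarios), collapse = ", ")))
  cat(sprintf("  %d iterations/cell -> %s predictions\n", x$iterations,
              format(grid_size(x), big.mark = ",")))
  invisible(x)
}
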