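#' Deterministic per-cell seed derivation
#'
#' Every grid cell gets its own random stream, seeded from the master seed
#' and the cell's position in the enumeration order via a Lehmer-style mix:
#' `((master mod (2^31 - 1)) * 16807 + cell_id) mod (2^31 - 1)`. For a fixed
#' master seed the map is injective over cell ids, so cells are independent,
#' order-insensitive, and individually re-runnable with [run_cell()].
#'
#' @param master master seed (non-negative integer).
#' @param cell_id 1-based cell index in grid enumeration order (escape speed
#'   varies fastest, then delay, distance to safety, approach speed, beta;
#'   scenario varies slowest).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_cell_seed <- function(master, cell_id) {
  p <- 2147483647
  as.integer(((as.numeric(master) %% p) * 16807 + as.numeric(cell_id)) %% p)
}

# Monte-Carlo kernel for one grid cell. Draw order (fixed, documented):
# away indicator, angle quantile, normal FID deviate, uniform FID quantile,
# rejection redraws for negative normal FIDs, then (bernoulli mode only) the
# outcome quantile. All physics vectorized over the n iterations.
simulate_cell <- function(sa, delta, d_min, sv, beta, sc, l, pre, d_width,
                          n, seed, mode, eq5_term, beta_speed) {
  set.seed(seed)
  away <- stats::runif(n) < sc$p_away
  u_theta <- stats::runif(n)
  theta <- 0.01 + u_theta * (89.99 - 0.01)
  theta[away] <- 90.01 + u_theta[away] * (179.99 - 90.01)
  fid <- sc$fid_mean + sc$fid_sd * stats::rnorm(n)
  u_fid <- stats::runif(n)
  while (any(bad <- fid < 0)) {
    fid[bad] <- sc$fid_mean + sc$fid_sd * stats::rnorm(sum(bad))
  }
  use_unif <- away & sc$kind != "none"
  if (any(use_unif)) {
    speed <- if (beta_speed == "Sv") sv else sa
    fid[use_unif] <- u_fid[use_unif] * speed * beta
  }

  rad <- theta * (pi / 180)
  sin_t <- sin(rad)
  cos_t <- cos(rad)
  t_a <- (d_min + l) / (sin_t * sa) + delta   # Inf when sa = 0
  closing <- sv + cos_t * sa
  if (any(closing <= 0)) {
    stop("ill-posed closing speed in cell (Sv + cos(theta) * Sa <= 0)",
         call. = FALSE)
  }
  t_v <- fid / closing
  possible <- t_a >= t_v
  trig <- if (eq5_term == "cos") cos_t else sin_t
  d_coll <- (d_width - d_min) + trig * sa * t_v
  p <- window_probability_fast(pre, d_coll)
  p[!possible] <- 0

  out <- list(theta = theta, fid = fid, away = away, t_a = t_a, t_v = t_v,
              possible = possible, d_coll = d_coll, p = p)
  if (mode == "bernoulli") {
    out$outcome <- stats::runif(n) < p
    out$value <- as.numeric(out$outcome)
  } else {
    out$value <- p
  }
  out
}

#' Run the Monte-Carlo iterations for a single grid cell
#'
#' Simulates `iterations` independent encounters for one fixed combination of
#' escape speed, delay, distance to safety, approach speed and light benefit:
#' each iteration samples an escape angle and flight-initiation distance for
#' the scenario, runs phase one (can the animal clear the trajectory?), and,
#' when a collision is possible, phase two (the silhouette window integral).
#' Deterministic for a fixed seed.
#'
#' @param sa,delta,d_min,sv,beta fixed cell parameters: escape speed (m/s),
#'   sensory-motor delay (s), minimum distance to safety (m), approach speed
#'   (m/s), temporal light benefit (s).
#' @param scenario a [light_scenario()].
#' @param silhouette a [frontal_silhouette()].
#' @param iterations number of Monte-Carlo iterations.
#' @param seed integer seed for this cell (e.g. from [derive_cell_seed()]).
#' @param body_length animal body length (m).
#' @param mode `"expectation"` records the phase-two probability per
#'   iteration; `"bernoulli"` additionally draws a binary collision outcome
#'   from it.
#' @param eq5_term lateral-progress term, `"cos"` (default) or `"sin"`; see
#'   [position_at_arrival()].
#' @param beta_speed speed multiplying `beta` in the light-extended
#'   flight-initiation-distance bound: `"Sv"` (default) or `"Sa"`.
#' @return A data.frame with one row per iteration: sampled inputs (`theta`,
#'   `d_fid`, `away`), phase-one times (`t_a`, `t_v`, `collision_possible`),
#'   phase-two position and probability (`d_collision`, `p_collision`), and
#'   in bernoulli mode the drawn `outcome`.
#' @export
run_cell <- function(sa, delta, d_min, sv, beta, scenario, silhouette,
                     iterations = 500L, seed = 0L, body_length = 1.15,
                     mode = c("expectation", "bernoulli"),
                     eq5_term = c("cos", "sin"), beta_speed = c("Sv", "Sa")) {
  stopifnot(inherits(scenario, "light_scenario"),
            inherits(silhouette, "frontal_silhouette"),
            sa >= 0, delta >= 0, d_min > 0, sv > 0, beta >= 0,
            iterations >= 1L, body_length > 0)
  if (d_min > silhouette$width_m) {
    stop("`d_min` cannot exceed the trajectory width", call. = FALSE)
  }
  mode <- match.arg(mode)
  eq5_term <- match.arg(eq5_term)
  beta_speed <- match.arg(beta_speed)
  pre <- window_precompute(silhouette, body_length)
  k <- simulate_cell(sa, delta, d_min, sv, beta, scenario, body_length, pre,
                     silhouette$width_m, as.integer(iterations),
                     as.integer(seed), mode, eq5_term, beta_speed)
  rec <- data.frame(
    scenario = scenario$kind, Sa = sa, delta = delta, d_min = d_min, Sv = sv,
    beta = beta, theta = k$theta, d_fid = k$fid, away = k$away, t_a = k$t_a,
    t_v = k$t_v, collision_possible = k$possible,
    d_collision = ifelse(k$possible, k$d_coll, NA_real_),
    p_collision = k$p
  )
  if (mode == "bernoulli") rec$outcome <- k$outcome
  rec
}

#' Run a full Monte-Carlo parameter sweep
#'
#' Enumerates every cell of a [build_grid()] grid, runs the per-cell
#' Monte-Carlo iterations with deterministic per-cell seeds derived from the
#' master seed ([derive_cell_seed()]), and aggregates results on the fly:
#' a per-cell summary (the mean collision probability or collision fraction
#' per unique parameter combination) and behavioral curves (mean probability
#' binned by sampled escape angle and flight-initiation distance, 0.1-unit
#' bins). Streaming aggregation keeps memory flat, so the full default grid
#' (222.75 million predictions at 500 iterations/cell) is tractable;
#' per-prediction records can be retained for smaller runs.
#'
#' @param grid a [build_grid()] result.
#' @param silhouette a [frontal_silhouette()]; its width must cover the
#'   grid's largest `d_min`.
#' @param seed master seed (non-negative integer).
#' @param keep_records if `TRUE`, also return the per-prediction records
#'   (refused above 20 million predictions).
#' @param progress emit a per-scenario progress message with cell counts and
#'   the running grand mean.
#' @param chunk_cells cells buffered between streaming-aggregation flushes.
#' @return An object of class `sweep_result`: list with
#'   \describe{
#'     \item{cells}{data.frame of per-cell means: one row per parameter
#'       combination with `cell_id`, `seed`, the fixed parameters, `mean`
#'       (cell statistic) and `n` (iterations).}
#'     \item{angle_curve, fid_curve}{binned behavioral curves per scenario:
#'       bin midpoint, mean, SD and count per 0.1-degree / 0.1-m bin.}
#'     \item{grand}{per-scenario grand mean and SD across cell means.}
#'     \item{manifest}{run metadata: seed, grid axes, mode, total counts and
#'       a grid hash.}
#'     \item{records}{per-prediction data.frame (only with `keep_records`).}
#'   }
#' @export
run_sweep <- function(grid, silhouette, seed = 1L, keep_records = FALSE,
                      progress = FALSE, chunk_cells = 2000L) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(silhouette, "frontal_silhouette"))
  if (max(grid$d_min) > silhouette$width_m + 1e-9) {
    stop("grid `d_min` values exceed the silhouette trajectory width",
         call. = FALSE)
  }
  n <- grid$iterations
  if (keep_records && grid_size(grid) > 2e7) {
    stop("refusing to keep per-prediction records for > 20 million ",
         "predictions; use the streaming aggregates", call. = FALSE)
  }
  l <- grid$body_length
  pre <- window_precompute(silhouette, l)
  d_width <- silhouette$width_m

  n_angle_bins <- 1800L
  # FID support: truncated normal (12 SD is beyond any realizable draw) or
  # the light-extended uniform; anything past the bound is clamped into the
  # last bin.
  max_fid <- max(
    vapply(grid$scenarios, function(s) s$fid_mean + 12 * s$fid_sd, 0),
    (if (grid$beta_speed == "Sv") max(grid$sv) else max(grid$sa)) *
      max(grid$beta))
  n_fid_bins <- as.integer(ceiling(max_fid * 10)) + 1L

  cells_per_scen <- length(grid$sa) * length(grid$delta) *
    length(grid$d_min) * length(grid$sv) * length(grid$beta)
  scen_names <- names(grid$scenarios)

  cell_tabs <- vector("list", length(scen_names))
  angle_tabs <- vector("list", length(scen_names))
  fid_tabs <- vector("list", length(scen_names))
  rec_chunks <- list()

  for (si in seq_along(scen_names)) {
    sc <- grid$scenarios[[si]]
    cells <- expand.grid(Sa = grid$sa, delta = grid$delta,
                         d_min = grid$d_min, Sv = grid$sv, beta = grid$beta,
                         KEEP.OUT.ATTRS = FALSE)
    nc <- nrow(cells)
    cell_ids <- (si - 1L) * cells_per_scen + seq_len(nc)
    seeds <- derive_cell_seed(seed, cell_ids)
    cell_mean <- numeric(nc)

    acc_angle <- matrix(0, n_angle_bins, 3L)
    acc_fid <- matrix(0, n_fid_bins, 3L)
    buf_len <- chunk_cells * n
    th_buf <- numeric(buf_len); fid_buf <- numeric(buf_len)
    v_buf <- numeric(buf_len); fill <- 0L

    flush <- function() {
      if (fill == 0L) return(invisible())
      idx <- seq_len(fill)
      v <- v_buf[idx]
      ab <- pmin(bin_index(th_buf[idx], 0.1), n_angle_bins - 1L) + 1L
      m <- rowsum(cbind(v, v * v, 1), group = ab)
      ids <- as.integer(rownames(m))
      acc_angle[ids, ] <<- acc_angle[ids, , drop = FALSE] + m
      fb <- pmin(bin_index(fid_buf[idx], 0.1), n_fid_bins - 1L) + 1L
      m <- rowsum(cbind(v, v * v, 1), group = fb)
      ids <- as.integer(rownames(m))
      acc_fid[ids, ] <<- acc_fid[ids, , drop = FALSE] + m
      fill <<- 0L
    }

    for (k in seq_len(nc)) {
      kc <- simulate_cell(cells$Sa[k], cells$delta[k], cells$d_min[k],
                          cells$Sv[k], cells$beta[k], sc, l, pre, d_width,
                          n, seeds[k], grid$mode, grid$eq5_term,
                          grid$beta_speed)
      cell_mean[k] <- sum(kc$value) / n
      slot <- fill + seq_len(n)
      th_buf[slot] <- kc$theta
      fid_buf[slot] <- kc$fid
      v_buf[slot] <- kc$value
      fill <- fill + n
      if (keep_records) {
        rec <- data.table::data.table(
          scenario = sc$kind, Sa = cells$Sa[k], delta = cells$delta[k],
          d_min = cells$d_min[k], Sv = cells$Sv[k], beta = cells$beta[k],
          theta = kc$theta, d_fid = kc$fid, away = kc$away, t_a = kc$t_a,
          t_v = kc$t_v, collision_possible = kc$possible,
          d_collision = ifelse(kc$possible, kc$d_coll, NA_real_),
          p_collision = kc$p)
        if (grid$mode == "bernoulli") rec$outcome <- kc$outcome
        rec_chunks[[length(rec_chunks) + 1L]] <- rec
      }
      if (fill + n > buf_len) flush()
    }
    flush()

    cells$cell_id <- cell_ids
    cells$seed <- seeds
    cells$scenario <- sc$kind
    cells$mean <- cell_mean
    cells$n <- n
    cell_tabs[[si]] <- cells
    angle_tabs[[si]] <- finalize_bins(acc_angle, sc$kind, 0.1)
    fid_tabs[[si]] <- finalize_bins(acc_fid, sc$kind, 0.1)
    if (progress) {
      message(sprintf("scenario %-5s: %d cells x %d iterations, grand mean %.4f",
                      sc$kind, nc, n, mean(cell_mean)))
    }
  }

  cells <- do.call(rbind, cell_tabs)
  cols <- c("cell_id", "seed", "scenario", "Sa", "delta", "d_min", "Sv",
            "beta", "mean", "n")
  cells <- cells[, cols]
  rownames(cells) <- NULL
  grand <- do.call(rbind, lapply(split(cells$mean, cells$scenario), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n_cells = length(v))))
  grand <- data.frame(scenario = rownames(grand), grand, row.names = NULL)
  grand <- grand[match(scen_names, grand$scenario), , drop = FALSE]
  rownames(grand) <- NULL

  res <- list(
    cells = cells,
    angle_curve = do.call(rbind, angle_tabs),
    fid_curve = do.call(rbind, fid_tabs),
    grand = grand,
    manifest = sweep_manifest(grid, silhouette, seed)
  )
  if (keep_records) {
    res$records <- as.data.frame(data.table::rbindlist(rec_chunks))
  }
  structure(res, class = "sweep_result")
}

# half-open bins [k*w, (k+1)*w); one shared definition so the streaming path
# and aggregate_by_behavior() bin identically bit for bit
bin_index <- function(x, w) floor(x / w)

finalize_bins <- function(acc, scenario, bin_width) {
  keep <- acc[, 3] > 0
  ids <- which(keep)
  nvec <- acc[keep, 3]
  mu <- acc[keep, 1] / nvec
  var <- pmax(acc[keep, 2] / nvec - mu^2, 0)
  data.frame(scenario = scenario, bin = (ids - 1 + 0.5) * bin_width,
             mean = mu, sd = sqrt(var * nvec / pmax(nvec - 1, 1)),
             n = nvec, row.names = NULL)
}

sweep_manifest <- function(grid, silhouette, seed) {
  axes <- grid[c("sa", "delta", "d_min", "sv", "beta")]
  list(
    seed = seed,
    iterations = grid$iterations,
    mode = grid$mode,
    eq5_term = grid$eq5_term,
    beta_speed = grid$beta_speed,
    body_length = grid$body_length,
    scenarios = lapply(grid$scenarios, unclass),
    axes = axes,
    silhouette = list(columns = ncol(silhouette$mask),
                      rows = nrow(silhouette$mask),
                      width_m = silhouette$width_m,
                      height_m = silhouette$height_m,
                      scale = silhouette$scale,
                      occupied = sum(silhouette$mask)),
    n_cells = grid_cells(grid),
    n_predictions = grid_size(grid),
    grid_hash = grid_hash(grid)
  )
}

# Stable identifier for a grid: djb2-style rolling hash of the canonical
# value string, kept within exact double-precision integer range.
grid_hash <- function(grid) {
  s <- paste(
    paste(format(grid$sa, digits = 15), collapse = ","),
    paste(format(grid$delta, digits = 15), collapse = ","),
    paste(format(grid$d_min, digits = 15), collapse = ","),
    paste(format(grid$sv, digits = 15), collapse = ","),
    paste(format(grid$beta, digits = 15), collapse = ","),
    paste(names(grid$scenarios), collapse = ","),
    grid$iterations, grid$mode, grid$eq5_term, grid$beta_speed,
    format(grid$body_length, digits = 15),
    sep = "|")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", as.integer(h))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Monte-Carlo sweep:",
      format(x$manifest$n_predictions, big.mark = ","),
      "predictions over", format(x$manifest$n_cells, big.mark = ","),
      "cells\n")
  cat(sprintf("  mode %s, seed %s, grid hash %s\n", x$manifest$mode,
              x$manifest$seed, x$manifest$grid_hash))
  cat("Grand means (across cell means):\n")
  for (i in seq_len(nrow(x$grand))) {
    cat(sprintf("  %-5s %.4f +/- %.4f (%d cells)\n", x$grand$scenario[i],
                x$grand$mean[i], x$grand$sd[i], x$grand$n_cells[i]))
  }
  invisible(x)
}
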