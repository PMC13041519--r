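#' Frontal silhouette of a vehicle
#'
#' A `frontal_silhouette` represents the frontal projection of a vehicle as a
#' scaled binary occupancy grid: a matrix of 0/1 values in which rows span the
#' vehicle's height (row 1 = top), columns span its width (column 1 = left),
#' and every occupied pixel (value 1) is vehicle surface. The physical width
#' of the grid fixes the meters-per-pixel conversion factor
#' `scale = width_m / ncol(mask)`; the physical height follows from the row
#' count at the same scale, so pixels are square.
#'
#' The x-axis convention used throughout the package: physical x runs from 0
#' at the left edge of the silhouette to `width_m` at the right edge, and
#' pixel column `i` covers the half-open interval `[(i-1)*scale, i*scale)`.
#'
#' @param mask integer or logical matrix containing only 0 and 1; at least one
#'   pixel must be occupied.
#' @param width_m physical width (m) of the grid's x-extent; must be positive.
#' @return An object of class `frontal_silhouette`: a list with elements
#'   `mask` (integer matrix), `width_m`, `height_m` and `scale` (m/pixel).
#' @examples
#' s <- frontal_silhouette(matrix(1L, 10, 10), width_m = 10)
#' s$scale          # 1 m/pixel
#' silhouette_area(s)  # 100 m^2
#' @export
frontal_silhouette <- function(mask, width_m) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (is.logical(mask)) storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) {
    stop("`mask` must contain only 0 and 1", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L)) stop("empty mask: no occupied pixel", call. = FALSE)
  if (!is.numeric(width_m) || length(width_m) != 1L || !is.finite(width_m) ||
      width_m <= 0) {
    stop("`width_m` must be a single positive number", call. = FALSE)
  }
  scale <- width_m / ncol(mask)
  structure(
    list(mask = mask, width_m = width_m, height_m = nrow(mask) * scale,
         scale = scale),
    class = "frontal_silhouette"
  )
}

#' @export
print.frontal_silhouette <- function(x, ...) {
  cat("Frontal silhouette:", nrow(x$mask), "x", ncol(x$mask), "pixels\n")
  cat(sprintf("  extent: %.3f m wide x %.3f m high (%.5g m/pixel)\n",
              x$width_m, x$height_m, x$scale))
  cat(sprintf("  occupied: %d pixels = %.3f m^2 (%.1f%% of trajectory plane)\n",
              sum(x$mask), silhouette_area(x),
              100 * mean(x$mask)))
  invisible(x)
}

#' Physical frontal area of a silhouette
#'
#' Occupied-pixel count times the squared pixel scale.
#'
#' @param s a [frontal_silhouette()].
#' @return Frontal surface area in m^2.
#' @export
silhouette_area <- function(s) {
  stopifnot(inherits(s, "frontal_silhouette"))
  sum(s$mask) * s$scale^2
}

#' Read a frontal silhouette from an image or text grid
#'
#' Accepts a grayscale PNG, a PGM (P2 plain or P5 raw), or a plain-text 0/1
#' grid (one row per line, space-separated columns). Grayscale images are
#' binarized at a configurable intensity threshold: pixels darker than
#' `threshold` (on a 0..1 scale, 0 = black) are occupied, matching the usual
#' dark-vehicle-on-light-background schematic. Text grids are taken as-is
#' (1 = occupied).
#'
#' @param path file path; format is chosen by extension (`.png`, `.pgm`,
#'   anything else is parsed as a text grid).
#' @param width_m physical width (m) of the image's x-extent.
#' @param threshold binarization threshold for grayscale input, in (0, 1);
#'   default 0.5 (pixels below 50% intensity count as vehicle surface).
#' @return A [frontal_silhouette()].
#' @export
read_silhouette <- function(path, width_m, threshold = 0.5) {
  if (!file.exists(path)) stop("cannot read mask file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
    mask <- (img < threshold) * 1L
  } else if (ext %in% c("pgm", "pnm")) {
    img <- read_pgm(path)
    mask <- (img < threshold) * 1L
  } else {
    mask <- read_text_grid(path)
  }
  frontal_silhouette(mask, width_m)
}

# Minimal PGM reader (P2 plain / P5 raw, maxval <= 255), returning intensities
# scaled to [0, 1].
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment to end of line
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data", call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

read_text_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mask file: ", path, call. = FALSE)
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.integer)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("non-rectangular grid in ", path, call. = FALSE)
  }
  mask <- do.call(rbind, rows)
  if (anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    stop("text grid must contain only 0 and 1", call. = FALSE)
  }
  mask
}

#' Write a frontal silhouette to disk
#'
#' Writes either a plain-text 0/1 grid or a grayscale PNG (occupied = black).
#' Output is bit-exact for a fixed mask, so generated silhouettes can be used
#' in regression tests.
#'
#' @param s a [frontal_silhouette()].
#' @param path output path; `.png` writes PNG, anything else a text grid.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(s, path) {
  stopifnot(inherits(s, "frontal_silhouette"))
  if (tolower(tools::file_ext(path)) == "png") {
    png::writePNG(1 - s$mask, path)
  } else {
    writeLines(apply(s$mask, 1L, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Convert a physical length to whole pixels
#'
#' Divides the length by the silhouette's meters-per-pixel conversion factor
#' and rounds to the nearest whole pixel, with a minimum of one pixel. For
#' the reference application, a 1.15 m animal on a 1031-column, 14.35-m-wide
#' grid is 83 pixels long.
#'
#' @param l physical length (m), positive.
#' @param s a [frontal_silhouette()].
#' @return Integer pixel count (>= 1).
#' @export
length_to_pixels <- function(l, s) {
  stopifnot(inherits(s, "frontal_silhouette"))
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("`l` must be a single positive length in meters", call. = FALSE)
  }
  max(1L, as.integer(round(l / s$scale)))
}

#' Collision-window probability integral
#'
#' Computes the probability that an animal of body length `l`, whose midpoint
#' sits at position `d_collision` on the trajectory's x-axis at the moment the
#' vehicle arrives, occupies the same space as the vehicle's frontal surface.
#' The collision window is the body-length-wide, full-height vertical strip
#' `[d_collision - l/2, d_collision + l/2]`; the probability is the fraction
#' of that strip covered by occupied silhouette pixels, under the assumption
#' that the animal can be at any altitude within the strip.
#'
#' Discretization follows the whole-pixel procedure: `d_collision` is rounded
#' to the nearest pixel, and exactly [length_to_pixels()] columns centered on
#' that pixel (left-biased by one column when the count is even) form the
#' window. Columns falling outside the grid contribute zero occupancy but stay
#' in the denominator, so the probability decays smoothly to zero as the
#' window slides off either edge of the trajectory.
#'
#' @param s a [frontal_silhouette()].
#' @param d_collision position(s) of the animal's midpoint on the x-axis (m);
#'   may lie outside `[0, width_m]`. Vectorized.
#' @param l animal body length (m), positive.
#' @return Numeric vector of probabilities in `[0, 1]`, one per position.
#' @examples
#' s <- frontal_silhouette(matrix(1L, 8, 8), width_m = 8)
#' window_probability(s, 4, 2)     # window fully inside an all-ones mask: 1
#' window_probability(s, -80, 2)   # window fully outside: 0
#' @export
window_probability <- function(s, d_collision, l) {
  stopifnot(inherits(s, "frontal_silhouette"))
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("`l` must be a single positive length in meters", call. = FALSE)
  }
  pre <- window_precompute(s, l)
  window_probability_fast(pre, d_collision)
}

# Precompute cumulative column occupancy for repeated window evaluations.
window_precompute <- function(s, l) {
  list(
    csum  = c(0, cumsum(colSums(s$mask))),
    ncol  = ncol(s$mask),
    nrow  = nrow(s$mask),
    scale = s$scale,
    L     = length_to_pixels(l, s)
  )
}

# Vectorized window integral on precomputed column sums. Positions are mapped
# to a 0-based center pixel by nearest-pixel rounding; the window is the L
# columns starting at center - floor(L/2).
window_probability_fast <- function(pre, d_collision) {
  L <- pre$L
  c0 <- round(d_collision / pre$scale)
  start <- c0 - (L %/% 2L)
  end <- start + L - 1L
  lo <- pmax(start, 0)
  hi <- pmin(end, pre$ncol - 1)
  p <- numeric(length(d_collision))
  inb <- hi >= lo
  p[inb] <- (pre$csum[hi[inb] + 2] - pre$csum[lo[inb] + 1]) / (L * pre$nrow)
  p
}

#' Column occupancy profile of a silhouette
#'
#' The number of occupied pixels per column, optionally converted to physical
#' column height (m). Useful for locating high-risk sections of the vehicle
#' (for an airliner: engines and fuselage) and for checking window integrals.
#'
#' @param s a [frontal_silhouette()].
#' @param physical if `TRUE`, return occupied height in meters per column
#'   instead of pixel counts.
#' @return Numeric vector, one value per column.
#' @export
occupancy_profile <- function(s, physical = FALSE) {
  stopifnot(inherits(s, "frontal_silhouette"))
  prof <- colSums(s$mask)
  if (physical) prof * s$scale else prof
}

#' Local maxima of a profile
#'
#' Finds strict local maxima of a numeric profile, treating a plateau (run of
#' equal values) as a single candidate that is a maximum when both flanking
#' runs are lower. Endpoints are not counted as maxima.
#'
#' @param profile numeric vector.
#' @return Integer vector of maxima positions (index of each plateau's
#'   midpoint, rounded down).
#' @export
profile_peaks <- function(profile) {
  r <- rle(profile)
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer(0))
  is_max <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  as.integer((starts[is_max] + ends[is_max]) %/% 2L)
}
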