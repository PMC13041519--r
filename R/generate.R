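#' Shape specification for a parametric frontal silhouette
#'
#' Describes a vehicle's frontal projection as a union of geometric
#' components on a `width_m` x `height_m` canvas: disks (fuselage cross
#' section, engine nacelles) and axis-aligned rectangles (wing band,
#' stabilizers, vertical tail). Coordinates are in meters with the origin at
#' the bottom-left corner of the canvas, x increasing rightward and y upward.
#'
#' @param width_m,height_m canvas extent (m), both positive.
#' @param disks numeric matrix with columns `cx`, `cy`, `r` (one disk per
#'   row), or `NULL`.
#' @param rects numeric matrix with columns `x0`, `x1`, `y0`, `y1` (one
#'   rectangle per row), or `NULL`.
#' @return An object of class `silhouette_spec`.
#' @seealso [silhouette_spec_737()] for the default airliner-like shape,
#'   [generate_silhouette()] to rasterize.
#' @export
silhouette_spec <- function(width_m, height_m, disks = NULL, rects = NULL) {
  stopifnot(is.numeric(width_m), width_m > 0,
            is.numeric(height_m), height_m > 0)
  norm_mat <- function(m, nc, what) {
    if (is.null(m)) return(matrix(numeric(0), 0, nc))
    m <- as.matrix(m)
    if (ncol(m) != nc) stop(what, " must have ", nc, " columns", call. = FALSE)
    storage.mode(m) <- "double"
    m
  }
  disks <- norm_mat(disks, 3L, "`disks`")
  rects <- norm_mat(rects, 4L, "`rects`")
  if (nrow(disks) > 0) {
    if (any(disks[, 3] < 0)) stop("disk radii must be >= 0", call. = FALSE)
    out <- disks[, 1] - disks[, 3] < 0 | disks[, 1] + disks[, 3] > width_m |
           disks[, 2] - disks[, 3] < 0 | disks[, 2] + disks[, 3] > height_m
    if (any(out & disks[, 3] > 0)) {
      stop("disk component extends outside the canvas", call. = FALSE)
    }
  }
  if (nrow(rects) > 0) {
    if (any(rects[, 2] < rects[, 1]) || any(rects[, 4] < rects[, 3])) {
      stop("rectangles need x0 <= x1 and y0 <= y1", call. = FALSE)
    }
    out <- rects[, 1] < 0 | rects[, 2] > width_m |
           rects[, 3] < 0 | rects[, 4] > height_m
    if (any(out)) stop("rectangle component extends outside the canvas",
                       call. = FALSE)
  }
  structure(list(width_m = width_m, height_m = height_m,
                 disks = disks, rects = rects),
            class = "silhouette_spec")
}

#' Default airliner-like silhouette specification
#'
#' A synthetic stand-in for the frontal schematic of a Boeing-737-class
#' narrow-body airliner, assembled from published front-view dimensions:
#' a 3.76-m-diameter fuselage disk, two 2.06-m engine nacelles under the
#' wings, a wing band, a horizontal-stabilizer band whose 14.35-m span sets
#' the canvas width, and a vertical tail reaching the 12.5-m tail height.
#' The resulting column-occupancy profile is trimodal
#' (engine-fuselage-engine), which drives the multimodal relationship between
#' an animal's position in the trajectory and its collision probability.
#'
#' @param width_m trajectory width (m); default 14.35, the horizontal
#'   stabilizer span.
#' @param height_m trajectory height (m); default 12.5, the tail height.
#' @return A [silhouette_spec()].
#' @export
silhouette_spec_737 <- function(width_m = 14.35, height_m = 12.5) {
  cx <- width_m / 2
  silhouette_spec(
    width_m = width_m, height_m = height_m,
    disks = rbind(
      c(cx,        3.88, 1.88),   # fuselage
      c(cx - 4.70, 2.00, 1.03),   # left engine nacelle
      c(cx + 4.70, 2.00, 1.03)    # right engine nacelle
    ),
    rects = rbind(
      c(0, width_m, 3.00, 3.40),             # wing band (front view)
      c(0, width_m, 8.30, 8.70),             # horizontal stabilizers
      c(cx - 0.30, cx + 0.30, 5.50, height_m) # vertical tail
    )
  )
}

#' Rasterize a parametric silhouette specification
#'
#' Renders the union of a spec's components onto a binary grid. A pixel is
#' occupied when its center lies inside any component, so the output is
#' deterministic (bit-exact) for a fixed spec and resolution.
#'
#' @param spec a [silhouette_spec()].
#' @param resolution number of pixel columns; rows follow from the canvas
#'   aspect ratio at the same (square-pixel) scale. Default 1031 columns,
#'   which for a 14.35-m canvas gives the reference 0.0139 m/pixel scale.
#' @return A [frontal_silhouette()].
#' @examples
#' s <- generate_silhouette(silhouette_spec_737(), resolution = 200)
#' length(profile_peaks(occupancy_profile(s)))  # 3: engine, fuselage, engine
#' @export
generate_silhouette <- function(spec, resolution = 1031L) {
  stopifnot(inherits(spec, "silhouette_spec"))
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop("`resolution` must be >= 1", call. = FALSE)
  scale <- spec$width_m / resolution
  nr <- max(1L, as.integer(round(spec$height_m / scale)))
  xc <- (seq_len(resolution) - 0.5) * scale         # column centers
  yc <- (nr - seq_len(nr) + 0.5) * scale            # row centers, row 1 = top
  mask <- matrix(FALSE, nr, resolution)
  for (i in seq_len(nrow(spec$disks))) {
    d <- spec$disks[i, ]
    if (d[3] <= 0) next
    mask <- mask | (outer((yc - d[2])^2, (xc - d[1])^2, `+`) <= d[3]^2)
  }
  for (i in seq_len(nrow(spec$rects))) {
    r <- spec$rects[i, ]
    mask <- mask | outer(yc >= r[3] & yc <= r[4], xc >= r[1] & xc <= r[2], `&`)
  }
  if (!any(mask)) stop("empty mask: no component covers any pixel center",
                       call. = FALSE)
  frontal_silhouette(mask * 1L, spec$width_m)
}
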