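#' Systematic sampling design for stereological estimators
#'
#' Frame and grid geometry of the Stereo Investigator-style designs used in
#' this workflow. Convenience constructors give the two published settings:
#' plaque area (10x objective: counting frame 90 x 90 um, scan grid 450 x
#' 450 um, Cavalieri point spacing 10 um) and cell counting (40x objective:
#' frame 75 x 75 um, grid 500 x 500 um).
#'
#' @param counting_frame_um numeric length-2, frame width and height (um).
#' @param grid_um numeric length-2, frame placement period (um); the frame
#'   must fit inside the grid cell.
#' @param point_spacing_um Cavalieri point lattice spacing inside each frame
#'   (um); used by the area estimator only.
#' @param section_thickness_um user-defined section thickness for the volume
#'   term of the density estimator (um).
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(counting_frame_um = c(90, 90),
                            grid_um = c(450, 450),
                            point_spacing_um = 10,
                            section_thickness_um = NA_real_) {
  stopifnot(length(counting_frame_um) == 2, length(grid_um) == 2,
            all(counting_frame_um > 0), all(grid_um > 0),
            all(counting_frame_um <= grid_um), point_spacing_um > 0)
  structure(list(counting_frame_um = as.numeric(counting_frame_um),
                 grid_um = as.numeric(grid_um),
                 point_spacing_um = as.numeric(point_spacing_um),
                 section_thickness_um = as.numeric(section_thickness_um)),
            class = "sampling_design")
}

#' @rdname sampling_design
#' @export
plaque_design <- function()
  sampling_design(c(90, 90), c(450, 450), point_spacing_um = 10)

#' @rdname sampling_design
#' @param section_thickness_um see [sampling_design()].
#' @export
astrocyte_design <- function(section_thickness_um = 40)
  sampling_design(c(75, 75), c(500, 500), point_spacing_um = 10,
                  section_thickness_um = section_thickness_um)

# systematic-uniform frame origins covering [0, extent] with one random offset
surs_frame_origins <- function(extent_um, design) {
  off <- stats::runif(2, 0, design$grid_um)
  ox <- seq(off[1] - design$grid_um[1] *
              ceiling(off[1] / design$grid_um[1]),
            extent_um[1], by = design$grid_um[1])
  oy <- seq(off[2] - design$grid_um[2] *
              ceiling(off[2] / design$grid_um[2]),
            extent_um[2], by = design$grid_um[2])
  list(x = ox, y = oy)
}

#' Cavalieri point-counting estimate of area fraction
#'
#' Places counting frames on a systematic grid with a single uniform random
#' offset (SURS), fills each frame with a point lattice at
#' `point_spacing_um` with a shared random sub-offset, and estimates the
#' percent area covered as `100 * hits(mask & roi) / hits(roi)`. Unbiased
#' over the random offset; deterministic given the seed.
#'
#' @param mask logical matrix, the structure (e.g. plaque mask).
#' @param roi logical matrix of the same dimensions, the reference region.
#' @param design a [sampling_design()]; `plaque_design()` by default.
#' @param pixel_size_um physical pixel size of `mask`/`roi` (um).
#' @param seed integer seed for the random offsets.
#' @return an object of class `stereology_estimate`: `estimate` (percent),
#'   `points_in_roi`, `points_in_mask`, `n_frames`.
#' @export
cavalieri_area_fraction <- function(mask, roi, design = plaque_design(),
                                    pixel_size_um, seed = 1L) {
  stopifnot(is.matrix(mask), identical(dim(mask), dim(roi)),
            pixel_size_um > 0)
  nr <- nrow(mask); nc <- ncol(mask)
  extent <- c(nc, nr) * pixel_size_um
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fr <- surs_frame_origins(extent, design)
  sub <- stats::runif(2, 0, design$point_spacing_um)
  kx <- floor((design$counting_frame_um[1] - sub[1]) /
                design$point_spacing_um)
  ky <- floor((design$counting_frame_um[2] - sub[2]) /
                design$point_spacing_um)
  relx <- sub[1] + design$point_spacing_um * (0:kx)
  rely <- sub[2] + design$point_spacing_um * (0:ky)
  pts_x <- as.vector(outer(fr$x, relx, "+"))
  pts_y <- as.vector(outer(fr$y, rely, "+"))
  px <- expand.grid(x = pts_x, y = pts_y)
  keep <- px$x >= 0 & px$x < extent[1] & px$y >= 0 & px$y < extent[2]
  px <- px[keep, , drop = FALSE]
  col <- floor(px$x / pixel_size_um) + 1L
  row <- floor(px$y / pixel_size_um) + 1L
  idx <- (col - 1L) * nr + row
  in_roi <- roi[idx]
  n_roi <- sum(in_roi)
  if (n_roi == 0) stop("ROI too small: no sampling point hits it")
  n_hit <- sum(mask[idx] & in_roi)
  structure(list(estimate = 100 * n_hit / n_roi,
                 points_in_roi = n_roi, points_in_mask = n_hit,
                 n_frames = length(fr$x) * length(fr$y),
                 seed = as.integer(seed)),
            class = "stereology_estimate")
}

#' Optical-fractionator-style cell density estimate
#'
#' Counts cells falling in systematically sampled counting frames using the
#' unbiased counting-frame rule (a cell on the left or bottom frame edge is
#' counted; one on the right or top "forbidden" edge is not - frames are
#' half-open: `[x0, x0 + w) x [y0, y0 + h)`). The estimated population is
#' `count * (grid area / frame area)`; the measured volume is the ROI area
#' times the user-defined section thickness; the density is their ratio,
#' mirroring the division of "estimated population" by "measured volume".
#'
#' @param cells_xy_um two-column matrix or data.frame of cell coordinates
#'   (um), restricted to the ROI.
#' @param roi_polygon_um two-column matrix of ROI polygon vertices (um).
#' @param design a [sampling_design()] with `section_thickness_um` set;
#'   `astrocyte_design()` by default.
#' @param seed integer seed for the frame offset.
#' @return an object of class `stereology_estimate`: `estimate` (cells per
#'   um^3), `count`, `estimated_population`, `measured_volume_um3`,
#'   `n_frames`.
#' @export
fractionator_density <- function(cells_xy_um, roi_polygon_um,
                                 design = astrocyte_design(), seed = 1L) {
  cells_xy_um <- as.matrix(cells_xy_um)
  roi_polygon_um <- as.matrix(roi_polygon_um)
  if (!is.finite(design$section_thickness_um) ||
      design$section_thickness_um <= 0)
    stop("design$section_thickness_um must be positive")
  roi_area <- polygon_area(roi_polygon_um)
  xr <- range(roi_polygon_um[, 1]); yr <- range(roi_polygon_um[, 2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  off <- stats::runif(2, 0, design$grid_um)
  ox <- seq(xr[1] - off[1] - design$grid_um[1], xr[2], by = design$grid_um[1])
  oy <- seq(yr[1] - off[2] - design$grid_um[2], yr[2], by = design$grid_um[2])
  frames <- expand.grid(x0 = ox, y0 = oy)
  # a frame is used if it intersects the ROI bounding box at all
  w <- design$counting_frame_um[1]; h <- design$counting_frame_um[2]
  count <- 0L
  n_frames <- 0L
  if (nrow(cells_xy_um) > 0) {
    for (i in seq_len(nrow(frames))) {
      x0 <- frames$x0[i]; y0 <- frames$y0[i]
      if (x0 + w < xr[1] || x0 > xr[2] || y0 + h < yr[1] || y0 > yr[2]) next
      n_frames <- n_frames + 1L
      count <- count + sum(cells_xy_um[, 1] >= x0 & cells_xy_um[, 1] < x0 + w &
                           cells_xy_um[, 2] >= y0 & cells_xy_um[, 2] < y0 + h)
    }
  } else {
    n_frames <- nrow(frames)
  }
  asf <- (design$grid_um[1] * design$grid_um[2]) / (w * h)
  population <- count * asf
  volume <- roi_area * design$section_thickness_um
  structure(list(estimate = population / volume, count = count,
                 estimated_population = population,
                 measured_volume_um3 = volume,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "stereology_estimate")
}

#' @export
print.stereology_estimate <- function(x, ...) {
  cat(sprintf("stereology_estimate: %.6g (seed %d)\n", x$estimate, x$seed))
  invisible(x)
}

# shoelace area of a simple polygon (um^2)
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# save/restore the global RNG state so seeded estimators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
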