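#' Segmentation parameters
#'
#' Physical-unit parameters of the nucleus and plaque segmentation. Defaults
#' are the workflow's published settings: DAPI blur sigma 0.72 um (720 nm),
#' 4G8 blur sigma 7.2 um, and a strict minimum plaque area of 720 um^2
#' (objects must exceed it to count as plaques).
#'
#' @param sigma_nucleus_um Gaussian blur scale for the DAPI channel (um).
#' @param sigma_plaque_um Gaussian blur scale for the 4G8 channel (um).
#' @param min_plaque_area_um2 minimum plaque area (um^2); regions with area
#'   less than or equal to this are discarded.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_nucleus_um = 0.72,
                                sigma_plaque_um = 7.2,
                                min_plaque_area_um2 = 720) {
  stopifnot(sigma_nucleus_um > 0, sigma_plaque_um > 0,
            min_plaque_area_um2 > 0)
  structure(list(sigma_nucleus_um = sigma_nucleus_um,
                 sigma_plaque_um = sigma_plaque_um,
                 min_plaque_area_um2 = min_plaque_area_um2),
            class = "segmentation_params")
}

#' Otsu threshold by exhaustive between-class-variance maximisation
#'
#' Returns the intensity threshold that maximises the between-class variance
#' of the two classes `{x <= t}` and `{x > t}`, searching every distinct
#' observed value as a candidate. Pixels (or cells) strictly above the
#' returned threshold are foreground. Ties between equally good thresholds
#' resolve to the lowest candidate; if all values are equal that value is
#' returned (so the foreground is empty).
#'
#' This closed-form search over distinct values is exactly equivalent to the
#' textbook exhaustive search over a discrete histogram, but works on
#' real-valued data without binning.
#'
#' @param x numeric vector (or matrix) of intensities, or - when `counts` is
#'   given - the bin values of a histogram.
#' @param counts optional nonnegative counts per entry of `x`; at least one
#'   must be positive.
#' @return a single numeric threshold.
#' @export
otsu_threshold <- function(x, counts = NULL) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input")
  if (is.null(counts)) {
    counts <- rep(1, length(x))
  } else {
    stopifnot(length(counts) == length(x), all(counts >= 0))
    keep <- counts > 0
    x <- x[keep]; counts <- counts[keep]
    if (length(x) == 0) stop("histogram has no nonempty bin")
  }
  o <- order(x)
  x <- x[o]; counts <- counts[o]
  # prefix sums at the last index of each distinct value give the class
  # statistics for every candidate threshold at once
  cw <- cumsum(counts); cwx <- cumsum(counts * x)
  last <- c(x[-1] != x[-length(x)], TRUE)
  u <- x[last]
  if (length(u) == 1) return(u)
  cn <- cw[last]; cs <- cwx[last]
  N <- cn[length(cn)]; S <- cs[length(cs)]
  k <- seq_len(length(u) - 1)           # t = u[k]; class2 nonempty
  w1 <- cn[k] / N; w2 <- 1 - w1
  m1 <- cs[k] / cn[k]; m2 <- (S - cs[k]) / (N - cn[k])
  bcv <- w1 * w2 * (m1 - m2)^2
  u[which.max(bcv)]                     # which.max takes the first (lowest) tie
}

#' Integer-labelled segmentation mask
#'
#' Wraps a label grid (0 = background, 1..K = regions, labels contiguous and
#' numbered by raster order of each region's first pixel) together with a
#' per-region table of pixel count, physical area, centroid (um, pixel-centre
#' convention) and bounding box.
#'
#' @param labels integer matrix of labels.
#' @param pixel_size_um physical pixel size (um).
#' @return an object of class `label_mask` with elements `labels`, `regions`
#'   and `pixel_size_um`.
#' @export
label_mask <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  storage.mode(labels) <- "integer"
  k <- max(labels)
  if (k > 0 && !identical(sort(unique(as.vector(labels[labels > 0]))),
                          seq_len(k)))
    stop("labels must be contiguous 1..K")
  regions <- region_table(labels, pixel_size_um)
  structure(list(labels = labels, regions = regions,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d px, %d region(s)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$regions)))
  invisible(x)
}

# per-label area/centroid/bbox table (um, pixel-centre coordinates)
region_table <- function(labels, pixel_size_um) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0)))
  lab <- labels[idx]
  nr <- nrow(labels)
  row <- ((idx - 1) %% nr) + 1L
  col <- ((idx - 1) %/% nr) + 1L
  n <- as.integer(tapply(lab, lab, length))
  cx <- as.numeric(tapply(col, lab, mean)) - 0.5
  cy <- as.numeric(tapply(row, lab, mean)) - 0.5
  data.frame(label = as.integer(names(tapply(lab, lab, length))),
             n_pixels = n,
             area_um2 = n * pixel_size_um^2,
             centroid_x_um = cx * pixel_size_um,
             centroid_y_um = cy * pixel_size_um,
             row_min = as.integer(tapply(row, lab, min)),
             row_max = as.integer(tapply(row, lab, max)),
             col_min = as.integer(tapply(col, lab, min)),
             col_max = as.integer(tapply(col, lab, max)),
             row.names = NULL)
}

# renumber labels by raster order (rows top-to-bottom, then columns) of each
# region's first pixel; purely conventional, fixed for reproducibility
relabel_raster <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(labels)
  nr <- nrow(labels)
  row <- ((idx - 1) %% nr) + 1L
  col <- ((idx - 1) %/% nr) + 1L
  key <- (row - 1) * ncol(labels) + col      # row-major scan position
  lab <- labels[idx]
  first <- tapply(key, lab, min)
  newid <- integer(max(lab))
  newid[as.integer(names(first))] <- rank(first, ties.method = "first")
  out <- labels
  out[idx] <- newid[lab]
  storage.mode(out) <- "integer"
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally via union-find over the label graph
label_components8 <- function(binary) {
  l4 <- EBImage::bwlabel(binary)
  l4 <- matrix(as.integer(l4), nrow = nrow(binary))
  k <- max(l4)
  if (k <= 1) return(relabel_raster(l4))
  nr <- nrow(l4); nc <- ncol(l4)
  a1 <- l4[-nr, -nc]; b1 <- l4[-1, -1]       # down-right diagonal
  a2 <- l4[-nr, -1];  b2 <- l4[-1, -nc]      # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  root <- vapply(seq_len(k), find, integer(1))
  map <- match(root, sort(unique(root)))
  out <- l4
  out[out > 0] <- map[out[out > 0]]
  relabel_raster(out)
}

# physical-sigma Gaussian blur (replicate boundary padding via EBImage)
blur_um <- function(grid, sigma_um, pixel_size_um) {
  sigma_px <- sigma_um / pixel_size_um
  m <- EBImage::gblur(grid, sigma = sigma_px, boundary = "replicate")
  matrix(as.numeric(m), nrow = nrow(grid))
}

#' Segment nuclei from the DAPI channel
#'
#' Gaussian blur at `sigma_nucleus_um`, Otsu binarisation (foreground strictly
#' above the threshold), Euclidean distance map of the binary foreground, and
#' watershed segmentation of the distance map to split touching nuclei.
#' Deterministic; labels are numbered by raster order of each region's first
#' pixel.
#'
#' @param section a [multichannel_section] with a `DAPI` channel.
#' @param params a [segmentation_params] object.
#' @param dapi_channel channel name to segment (default `"DAPI"`).
#' @return a [label_mask] of nuclei.
#' @export
segment_nuclei <- function(section, params = segmentation_params(),
                           dapi_channel = "DAPI") {
  if (!is_multichannel_section(section)) stop("not a multichannel_section")
  if (!dapi_channel %in% names(section$channels))
    stop("missing channel: ", dapi_channel)
  px <- section$pixel_size_um
  blurred <- blur_um(section$channels[[dapi_channel]],
                     params$sigma_nucleus_um, px)
  thr <- otsu_threshold(blurred)
  binary <- blurred > thr
  if (!any(binary))
    return(label_mask(matrix(0L, nrow(binary), ncol(binary)), px))
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  # tolerance in distance-map units (pixels); tied to the blur scale so that
  # shallow saddles between sub-maxima of one nucleus do not split it
  tol <- max(1, params$sigma_nucleus_um / px)
  ws <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  lab <- matrix(as.integer(ws), nrow = nrow(binary))
  label_mask(relabel_raster(lab), px)
}

#' Segment plaques from the 4G8 channel
#'
#' Gaussian blur at `sigma_plaque_um`, Otsu binarisation, 8-connected
#' component labelling, and removal of every component whose area does not
#' strictly exceed `min_plaque_area_um2`.
#'
#' @param section a [multichannel_section] with the plaque channel.
#' @param params a [segmentation_params] object.
#' @param plaque_channel channel name (default `"4G8"`).
#' @return a [label_mask] of plaques.
#' @export
segment_plaques <- function(section, params = segmentation_params(),
                            plaque_channel = "4G8") {
  if (!is_multichannel_section(section)) stop("not a multichannel_section")
  if (!plaque_channel %in% names(section$channels))
    stop("missing channel: ", plaque_channel)
  px <- section$pixel_size_um
  blurred <- blur_um(section$channels[[plaque_channel]],
                     params$sigma_plaque_um, px)
  thr <- otsu_threshold(blurred)
  binary <- blurred > thr
  lab <- label_components8(binary)
  if (max(lab) > 0) {
    reg <- region_table(lab, px)
    drop <- reg$label[reg$area_um2 <= params$min_plaque_area_um2]
    if (length(drop) > 0) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_raster(lab)
    }
  }
  label_mask(lab, px)
}

#' Write a label mask as a 16-bit TIFF plus a region CSV
#'
#' @param mask a [label_mask].
#' @param path output TIFF path; the region table goes to the same path with
#'   extension `.csv`.
#' @return invisible `path`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  utils::write.csv(mask$regions[, c("label", "area_um2", "centroid_x_um",
                                    "centroid_y_um")],
                   sub("\\.tiff?$", ".csv", path, ignore.case = TRUE),
                   row.names = FALSE)
  invisible(path)
}
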