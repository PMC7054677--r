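#' Plaque-association parameters
#'
#' @param association_radius_um microglia whose nucleus centre of mass lies
#'   within this distance (inclusive) of a plaque border are counted as
#'   plaque-associated. Default 30 um.
#' @return an object of class `association_params`.
#' @export
association_params <- function(association_radius_um = 30) {
  stopifnot(association_radius_um > 0)
  structure(list(association_radius_um = association_radius_um),
            class = "association_params")
}

#' Per-cell mean expression over nuclear regions
#'
#' The mean intensity of each channel over exactly the pixels of each
#' segmented nuclear region is the per-cell expression measure (used for Iba1
#' and Clec7a levels).
#'
#' @param nuclei a [label_mask] of nuclei.
#' @param section the [multichannel_section] the mask was derived from.
#' @return a data.frame with one row per nucleus: `cell_id`, `label`,
#'   `centroid_x_um`, `centroid_y_um`, `area_um2`, and one `mean_<channel>`
#'   column per channel.
#' @export
measure_expression <- function(nuclei, section) {
  stopifnot(inherits(nuclei, "label_mask"), is_multichannel_section(section))
  if (!identical(dim(nuclei$labels), dim(section$channels[[1]])))
    stop("label mask and section dimensions differ")
  reg <- nuclei$regions
  if (nrow(reg) == 0) {
    out <- data.frame(cell_id = character(0), label = integer(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0))
    for (nm in names(section$channels))
      out[[paste0("mean_", nm)]] <- numeric(0)
    return(out)
  }
  out <- data.frame(cell_id = paste0(section$animal_id, "_s",
                                     section$section_index, "r",
                                     section$region_index, "_c", reg$label),
                    label = reg$label,
                    centroid_x_um = reg$centroid_x_um,
                    centroid_y_um = reg$centroid_y_um,
                    area_um2 = reg$area_um2)
  idx <- which(nuclei$labels > 0)
  lab <- nuclei$labels[idx]
  for (nm in names(section$channels)) {
    v <- section$channels[[nm]][idx]
    mn <- if (length(idx) > 0) as.numeric(tapply(v, lab, mean)) else numeric(0)
    out[[paste0("mean_", nm)]] <- mn
  }
  out
}

#' Classify cells as Iba1-positive by per-image Otsu thresholding
#'
#' Applies [otsu_threshold()] to the vector of per-cell mean expression values
#' of one image; cells strictly above the threshold are positive. If all
#' values are identical no cell exceeds the threshold, so all are negative.
#' Only Iba1-positive cells enter downstream analysis.
#'
#' @param values numeric vector of per-cell mean intensities from one image.
#' @return logical vector, `TRUE` = positive.
#' @export
classify_iba1 <- function(values) {
  if (length(values) == 0) return(logical(0))
  values > otsu_threshold(values)
}

#' Distance to the nearest plaque border and nearest-plaque size
#'
#' For each cell, the Euclidean distance (um) from its nucleus centre of mass
#' to the nearest plaque border pixel; cells whose centre lies inside a plaque
#' get distance 0. A border pixel is a plaque pixel with at least one
#' background 4-neighbour. The area of the nearest plaque and the association
#' flag (distance <= association radius, inclusive) are filled in alongside.
#' With no plaques in the image the distance is `NA` (sentinel), the flag is
#' `FALSE`, and the nearest area is `NA`.
#'
#' @param cells data.frame from [measure_expression()] (needs
#'   `centroid_x_um`/`centroid_y_um`).
#' @param plaques a [label_mask] of plaques from the same section.
#' @param params an [association_params] object.
#' @return `cells` with columns `dist_to_plaque_border_um`,
#'   `nearest_plaque_label`, `nearest_plaque_area_um2`, `plaque_associated`.
#' @export
nearest_plaque_metrics <- function(cells, plaques,
                                   params = association_params()) {
  stopifnot(inherits(plaques, "label_mask"))
  n <- nrow(cells)
  cells$dist_to_plaque_border_um <- rep(NA_real_, n)
  cells$nearest_plaque_label <- rep(NA_integer_, n)
  cells$nearest_plaque_area_um2 <- rep(NA_real_, n)
  cells$plaque_associated <- rep(FALSE, n)
  if (n == 0 || max(plaques$labels) == 0) return(cells)
  px <- plaques$pixel_size_um
  lab <- plaques$labels
  nr <- nrow(lab); nc <- ncol(lab)
  # border pixels: plaque pixel with >= 1 background 4-neighbour (image edge
  # counts as background)
  fg <- lab > 0
  pad <- matrix(FALSE, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- fg
  inner <- pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] &
           pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)]
  border <- fg & !inner
  bidx <- which(border)
  brow <- ((bidx - 1) %% nr) + 1L
  bcol <- ((bidx - 1) %/% nr) + 1L
  bx <- (bcol - 0.5) * px; by <- (brow - 0.5) * px
  blab <- lab[bidx]
  for (i in seq_len(n)) {
    cxy <- c(cells$centroid_x_um[i], cells$centroid_y_um[i])
    ci <- floor(cxy[1] / px) + 1; ri <- floor(cxy[2] / px) + 1
    inside <- ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && lab[ri, ci] > 0
    if (inside) {
      cells$dist_to_plaque_border_um[i] <- 0
      cells$nearest_plaque_label[i] <- lab[ri, ci]
    } else {
      d2 <- (bx - cxy[1])^2 + (by - cxy[2])^2
      j <- which.min(d2)
      cells$dist_to_plaque_border_um[i] <- sqrt(d2[j])
      cells$nearest_plaque_label[i] <- blab[j]
    }
  }
  cells$nearest_plaque_area_um2 <-
    plaques$regions$area_um2[match(cells$nearest_plaque_label,
                                   plaques$regions$label)]
  cells$plaque_associated <-
    cells$dist_to_plaque_border_um <= params$association_radius_um
  cells
}

#' Per-image summary of plaque-associated microglia
#'
#' Counts Iba1-positive plaque-associated cells and their plaque-size
#' normalised number: the sum over associated positive cells of
#' `1 / nearest_plaque_area_um2` (cells per um^2 of plaque), i.e. each cell's
#' count is normalised to the size of its own nearest plaque.
#'
#' @param cells data.frame with `iba1_positive`, `plaque_associated` and
#'   `nearest_plaque_area_um2` columns.
#' @param plaques the [label_mask] of the same image (used to detect the
#'   zero-plaque case, for which the summary is undefined).
#' @return one-row data.frame: `n_cells`, `n_iba1_positive`, `n_associated`,
#'   `normalised_count_per_um2`; or `NULL` (with a message) if the image has
#'   no plaques.
#' @export
plaque_associated_summary <- function(cells, plaques) {
  if (max(plaques$labels) == 0) {
    message("image has no plaques; plaque-associated summary undefined")
    return(NULL)
  }
  assoc <- cells$iba1_positive & cells$plaque_associated %in% TRUE
  data.frame(n_cells = nrow(cells),
             n_iba1_positive = sum(cells$iba1_positive),
             n_associated = sum(assoc),
             normalised_count_per_um2 =
               if (any(assoc)) sum(1 / cells$nearest_plaque_area_um2[assoc]) else 0)
}

#' Radial intensity profile around a point
#'
#' Mean intensity over annular bins `[i*dr, (i+1)*dr)` of radius around a
#' centre (um), typically the centre of mass of a segmented nucleus. Bins
#' that contain no pixels (entirely outside the image) are dropped.
#' Normalisation divides the curve by its own integral `sum(value * dr)`.
#'
#' @param section a [multichannel_section].
#' @param channel channel name.
#' @param centre_um numeric length-2, `(x, y)` in um; must lie inside the
#'   image.
#' @param r_max_um outer radius (um). Default 20.
#' @param dr_um bin width (um). Default 0.5.
#' @param normalise divide by the profile's own integral (default `FALSE`).
#' @return data.frame of class `radial_profile` with `bin_lo_um`, `bin_hi_um`,
#'   `bin_mid_um`, `value`; attributes `channel`, `dr_um`, `normalised`.
#' @export
radial_profile <- function(section, channel, centre_um,
                           r_max_um = 20, dr_um = 0.5, normalise = FALSE) {
  stopifnot(is_multichannel_section(section), r_max_um > 0, dr_um > 0)
  if (!channel %in% names(section$channels)) stop("missing channel: ", channel)
  g <- section$channels[[channel]]
  px <- section$pixel_size_um
  nr <- nrow(g); nc <- ncol(g)
  if (centre_um[1] < 0 || centre_um[1] > nc * px ||
      centre_um[2] < 0 || centre_um[2] > nr * px)
    stop("centre outside image")
  # only the window within r_max of the centre can contribute
  c0 <- max(1L, floor((centre_um[1] - r_max_um) / px))
  c1 <- min(nc, ceiling((centre_um[1] + r_max_um) / px) + 1L)
  r0 <- max(1L, floor((centre_um[2] - r_max_um) / px))
  r1 <- min(nr, ceiling((centre_um[2] + r_max_um) / px) + 1L)
  g <- g[r0:r1, c0:c1, drop = FALSE]
  xs <- (c0:c1 - 0.5) * px
  ys <- (r0:r1 - 0.5) * px
  r <- sqrt(outer((ys - centre_um[2])^2, (xs - centre_um[1])^2, "+"))
  nb <- ceiling(r_max_um / dr_um)
  bin <- floor(r / dr_um) + 1
  keep <- bin <= nb
  sums <- tapply(g[keep], bin[keep], mean)
  ids <- as.integer(names(sums))
  out <- data.frame(bin_lo_um = (ids - 1) * dr_um,
                    bin_hi_um = ids * dr_um,
                    bin_mid_um = (ids - 0.5) * dr_um,
                    value = as.numeric(sums))
  if (normalise) {
    integral <- sum(out$value * dr_um)
    if (integral > 0) out$value <- out$value / integral
  }
  structure(out, class = c("radial_profile", "data.frame"),
            channel = channel, dr_um = dr_um, normalised = normalise)
}

#' Normalise a profile or histogram by its own integral
#'
#' @param values per-bin values.
#' @param bin_width common bin width.
#' @return values scaled so that `sum(values * bin_width) == 1` (unchanged if
#'   the integral is zero).
#' @export
normalise_curve <- function(values, bin_width) {
  integral <- sum(values * bin_width)
  if (integral > 0) values / integral else values
}

#' Image-wise intensity histogram
#'
#' Bins values (e.g. per-cell Clec7a mean intensities of one image) on fixed
#' edges; optional integral normalisation so histograms are poolable across
#' images and animals.
#'
#' @param values numeric vector.
#' @param breaks full set of bin edges (length nbins + 1, strictly
#'   increasing); values outside the range are dropped.
#' @param normalise integral-normalise (default `TRUE`).
#' @return data.frame `bin_lo`, `bin_hi`, `bin_mid`, `value` of class
#'   `binned_histogram`.
#' @export
binned_histogram <- function(values, breaks, normalise = TRUE) {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  v <- values[values >= breaks[1] & values <= breaks[length(breaks)]]
  nb <- length(breaks) - 1
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nb)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    value = as.numeric(counts))
  if (normalise) out$value <- normalise_curve(out$value, diff(breaks)[1])
  structure(out, class = c("binned_histogram", "data.frame"),
            normalised = normalise)
}

#' Hierarchical pooling: image -> animal median -> group mean and SEM
#'
#' Implements the study's pooling rule: the animal-level value of each metric
#' is the median over that animal's images (element-wise for curves, i.e.
#' within `bin` if present), and the group-level value is the mean over
#' animals with SEM = sd / sqrt(n_animals). Animals contributing zero usable
#' (non-missing) images for a metric are dropped with a warning.
#'
#' @param images data.frame of image-level rows with columns `animal_id`,
#'   `group`, optionally `bin` (for curves), and one or more numeric metric
#'   columns.
#' @param metrics character vector of metric column names; default all
#'   numeric columns other than identifiers.
#' @return list with data.frames `animals` (one row per animal x bin) and
#'   `groups` (one row per group x bin x metric: `mean`, `sem`, `n_animals`).
#' @export
pool <- function(images, metrics = NULL) {
  stopifnot(all(c("animal_id", "group") %in% names(images)))
  has_bin <- "bin" %in% names(images)
  if (is.null(metrics))
    metrics <- setdiff(names(images)[vapply(images, is.numeric, logical(1))],
                       c("bin", "section_index", "region_index"))
  key_cols <- c("animal_id", "group", if (has_bin) "bin")
  agg_med <- stats::aggregate(images[metrics], images[key_cols],
                              FUN = function(v) stats::median(v, na.rm = TRUE),
                              drop = TRUE)
  # drop animal x metric cells with zero usable images (all-NA medians)
  for (m in metrics) {
    bad <- is.nan(agg_med[[m]]) | is.na(agg_med[[m]])
    if (any(bad)) {
      warning("dropped ", sum(bad), " animal-level value(s) of '", m,
              "' with zero usable images")
    }
  }
  animals <- agg_med[do.call(order, agg_med[key_cols]), , drop = FALSE]
  rownames(animals) <- NULL
  grp_key <- c("group", if (has_bin) "bin")
  pieces <- lapply(metrics, function(m) {
    ok <- !is.na(animals[[m]])
    a <- animals[ok, , drop = FALSE]
    g <- stats::aggregate(a[[m]], a[grp_key], FUN = function(v)
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
        n = length(v)))
    data.frame(g[, grp_key, drop = FALSE], metric = m,
               mean = g$x[, "mean"], sem = g$x[, "sem"],
               n_animals = as.integer(g$x[, "n"]))
  })
  groups <- do.call(rbind, pieces)
  groups <- groups[do.call(order, groups[c("metric", grp_key)]), , drop = FALSE]
  rownames(groups) <- NULL
  list(animals = animals, groups = groups)
}
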