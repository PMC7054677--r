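#' Contrast-stretched greyscale conversion
#'
#' Deterministic stand-in for a batch "contrast-optimised greyscale"
#' conversion: the channel is linearly stretched so that its 0.35th and
#' 99.65th intensity percentiles map to 0 and `out_max`, then clipped. No
#' lossy re-encoding is applied; the stretch is value-for-value reproducible.
#' A constant image cannot be stretched and is returned unchanged with a
#' warning.
#'
#' @param section a [multichannel_section] or a bare numeric matrix.
#' @param channel channel name (ignored for a bare matrix).
#' @param lo,hi percentiles (in percent) mapped to the display range ends.
#' @param out_max top of the display range (default 255).
#' @return numeric matrix.
#' @export
to_greyscale_contrast <- function(section, channel = NULL,
                                  lo = 0.35, hi = 99.65, out_max = 255) {
  g <- if (is_multichannel_section(section)) {
    if (is.null(channel) || !channel %in% names(section$channels))
      stop("missing channel: ", channel)
    section$channels[[channel]]
  } else section
  q <- stats::quantile(g, c(lo, hi) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant (or degenerate) image; no contrast stretch applied")
    return(g)
  }
  pmin(pmax((g - q[1]) / (q[2] - q[1]) * out_max, 0), out_max)
}

#' Fit a fixed analysis threshold from all images of one channel
#'
#' One threshold per channel for the whole run, chosen from the variance and
#' mean of the pooled pixel intensities of every analysed image of that
#' channel: `threshold = pooled_mean + k * pooled_SD` (default k = 2). The
#' provenance statistics are recorded on the returned object.
#'
#' @param images list of numeric matrices (all images of one channel, already
#'   greyscale).
#' @param k multiplier on the pooled SD (default 2).
#' @param channel optional channel name recorded for provenance.
#' @return an object of class `fixed_threshold` with fields `channel`,
#'   `threshold`, `pooled_mean`, `pooled_sd`, `k`, `n_images`.
#' @export
fit_fixed_threshold <- function(images, k = 2, channel = NA_character_) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  v <- unlist(lapply(images, as.vector), use.names = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s)) s <- 0
  structure(list(channel = channel, threshold = m + k * s,
                 pooled_mean = m, pooled_sd = s, k = k,
                 n_images = length(images)),
            class = "fixed_threshold")
}

#' @export
print.fixed_threshold <- function(x, ...) {
  cat(sprintf("fixed_threshold[%s]: %.4g (mean %.4g + %g * SD %.4g, %d images)\n",
              x$channel, x$threshold, x$pooled_mean, x$k, x$pooled_sd,
              x$n_images))
  invisible(x)
}

#' Fraction of stained pixels
#'
#' Proportion of pixels strictly above the threshold - the "stained" class of
#' the image histogram.
#'
#' @param grid numeric matrix.
#' @param threshold finite scalar, or a [fit_fixed_threshold()] object.
#' @return fraction in `[0, 1]`.
#' @export
stained_fraction <- function(grid, threshold) {
  if (inherits(threshold, "fixed_threshold")) threshold <- threshold$threshold
  stopifnot(is.finite(threshold))
  mean(grid > threshold)
}

#' Leave-one-out 2-SD image quality control
#'
#' Flags images whose QC features (typically per-channel mean intensity and
#' intensity variance) fall outside the acceptable band of mean +/- `k_sd`
#' standard deviations of (i) all other images of the same animal and
#' (ii) all other images of the same experimental group. The band is
#' inclusive: a feature exactly on the boundary is retained. Comparison
#' statistics are leave-one-out, so an extreme image cannot mask itself.
#' An image is excluded if any feature is out of band in either comparison
#' set. Comparison sets with fewer than 3 images skip QC (logged).
#'
#' @param features data.frame: `image_id`, `animal_id`, `group`, plus numeric
#'   feature columns.
#' @param k_sd half-width of the acceptance band in SDs (default 2).
#' @return data.frame: `image_id`, `animal_id`, `group`, `excluded`, `basis`
#'   (`""`, `"animal"`, `"group"` or `"animal+group"`).
#' @export
qc_filter <- function(features, k_sd = 2) {
  stopifnot(all(c("image_id", "animal_id", "group") %in% names(features)))
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       c("section_index", "region_index"))
  n <- nrow(features)
  flag_animal <- rep(FALSE, n)
  flag_group <- rep(FALSE, n)
  flag_set <- function(set_ids) {
    out <- rep(FALSE, n)
    for (s in unique(set_ids)) {
      idx <- which(set_ids == s)
      if (length(idx) < 3) {
        message("QC skipped for comparison set '", s, "' (fewer than 3 images)")
        next
      }
      for (fc in feat_cols) {
        v <- features[[fc]][idx]
        for (j in seq_along(idx)) {
          others <- v[-j]
          m <- mean(others); s2 <- stats::sd(others)
          if (!is.finite(s2)) s2 <- 0
          if (v[j] < m - k_sd * s2 || v[j] > m + k_sd * s2)
            out[idx[j]] <- TRUE
        }
      }
    }
    out
  }
  flag_animal <- flag_set(features$animal_id)
  flag_group <- flag_set(features$group)
  basis <- ifelse(flag_animal & flag_group, "animal+group",
                  ifelse(flag_animal, "animal",
                         ifelse(flag_group, "group", "")))
  data.frame(image_id = features$image_id,
             animal_id = features$animal_id,
             group = features$group,
             excluded = flag_animal | flag_group,
             basis = basis)
}

#' Image QC features for the area-ratio workflow
#'
#' Mean intensity and intensity variance of each analysed channel, per image.
#'
#' @param sections list of [multichannel_section] objects.
#' @param channels channel names to characterise.
#' @return data.frame suitable for [qc_filter()].
#' @export
qc_features <- function(sections, channels) {
  rows <- lapply(seq_along(sections), function(i) {
    s <- sections[[i]]
    row <- data.frame(image_id = paste0(s$animal_id, "_s", s$section_index,
                                        "r", s$region_index),
                      animal_id = s$animal_id, group = s$group)
    for (ch in channels) {
      row[[paste0("mean_", ch)]] <- mean(s$channels[[ch]])
      row[[paste0("var_", ch)]] <- stats::var(as.vector(s$channels[[ch]]))
    }
    row
  })
  do.call(rbind, rows)
}

#' BACE1/4G8 stained-area ratio per image and per animal
#'
#' For each QC-passing image, the stained fraction of the BACE1 channel is
#' normalised to the stained fraction of the 4G8 channel of the same image;
#' each channel uses its own run-wide [fit_fixed_threshold()]. Images with a
#' zero 4G8 fraction are dropped with a warning, as are animals left with no
#' usable image. The per-animal value is the median ratio over that animal's
#' images; group mean and SEM then follow via [pool()].
#'
#' @param sections list of [multichannel_section] objects.
#' @param thr_bace1,thr_4g8 `fixed_threshold` objects (or scalars) for the
#'   two channels.
#' @param qc optional result of [qc_filter()]; excluded images are skipped.
#' @param bace1_channel,plaque_channel channel names.
#' @return list with data.frames `images` (image_id, animal_id, group,
#'   bace1_fraction, g8_fraction, ratio) and `animals` (animal_id, group,
#'   median_ratio, n_images).
#' @export
bace1_4g8_ratio <- function(sections, thr_bace1, thr_4g8, qc = NULL,
                            bace1_channel = "BACE1", plaque_channel = "4G8") {
  rows <- lapply(sections, function(s) {
    id <- paste0(s$animal_id, "_s", s$section_index, "r", s$region_index)
    if (!is.null(qc) && id %in% qc$image_id[qc$excluded]) return(NULL)
    fb <- stained_fraction(s$channels[[bace1_channel]], thr_bace1)
    fg <- stained_fraction(s$channels[[plaque_channel]], thr_4g8)
    data.frame(image_id = id, animal_id = s$animal_id, group = s$group,
               bace1_fraction = fb, g8_fraction = fg,
               ratio = if (fg > 0) fb / fg else NA_real_)
  })
  images <- do.call(rbind, rows)
  if (is.null(images) || nrow(images) == 0) stop("no images left after QC")
  if (anyNA(images$ratio)) {
    warning(sum(is.na(images$ratio)),
            " image(s) with zero 4G8 fraction dropped")
    images <- images[!is.na(images$ratio), , drop = FALSE]
  }
  if (nrow(images) == 0) stop("no images with nonzero 4G8 fraction")
  med <- stats::aggregate(images["ratio"],
                          images[c("animal_id", "group")], stats::median)
  cnt <- stats::aggregate(list(n_images = images$ratio),
                          images[c("animal_id", "group")], length)
  animals <- merge(med, cnt, by = c("animal_id", "group"))
  names(animals)[names(animals) == "ratio"] <- "median_ratio"
  animals <- animals[order(animals$animal_id), , drop = FALSE]
  rownames(animals) <- NULL
  list(images = images, animals = animals)
}

#' pFTAA-positive area fraction inside a cortical ROI
#'
#' Percentage of pixels above a shared run-wide threshold among pixels whose
#' centres lie inside the ROI polygon.
#'
#' @param section a [multichannel_section] (the pixel size is taken from it).
#' @param roi_polygon_um two-column matrix of polygon vertices (x, y in um),
#'   at least 3 rows.
#' @param threshold scalar or `fixed_threshold` (the same threshold is shared
#'   by every section of a run).
#' @param channel channel name (default `"pFTAA"`).
#' @return percent in `[0, 100]`.
#' @export
pftaa_area_fraction <- function(section, roi_polygon_um, threshold,
                                channel = "pFTAA") {
  g <- if (is_multichannel_section(section)) {
    px <- section$pixel_size_um
    section$channels[[channel]]
  } else {
    stop("pass a multichannel_section (pixel size needed)")
  }
  if (inherits(threshold, "fixed_threshold")) threshold <- threshold$threshold
  roi_polygon_um <- as.matrix(roi_polygon_um)
  if (nrow(roi_polygon_um) < 3) stop("ROI polygon needs >= 3 vertices")
  nr <- nrow(g); nc <- ncol(g)
  xs <- rep((seq_len(nc) - 0.5) * px, each = nr)
  ys <- rep((seq_len(nr) - 0.5) * px, times = nc)
  inside <- mgcv::in.out(rbind(roi_polygon_um, roi_polygon_um[1, ]),
                         cbind(xs, ys))
  if (!any(inside)) stop("empty ROI: no pixel centres inside the polygon")
  100 * sum(g[inside] > threshold) / sum(inside)
}

#' Read an ROI polygon from a JSON vertex list
#'
#' @param path JSON file containing either a list of `[x, y]` pairs or an
#'   object with `x` and `y` arrays (um).
#' @return two-column matrix of vertices.
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.list(j) && !is.null(j$x)) cbind(j$x, j$y) else as.matrix(j)
  if (ncol(m) != 2 || nrow(m) < 3) stop("ROI polygon needs >= 3 (x, y) rows")
  colnames(m) <- c("x_um", "y_um")
  m
}
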