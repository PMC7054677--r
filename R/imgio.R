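#' Multichannel section container
#'
#' Bundles one imaged field: a named set of co-registered single-channel
#' intensity grids together with the physical pixel size and the provenance
#' needed for hierarchical pooling (animal, experimental group, section and
#' region indices).
#'
#' Grids are plain numeric matrices indexed `[row, col]`; rows run along the
#' image y axis, columns along x. The centre of pixel `[i, j]` sits at
#' physical coordinates `x = (j - 0.5) * pixel_size_um`,
#' `y = (i - 0.5) * pixel_size_um`. Intensities are arbitrary nonnegative
#' units (camera counts); nothing is rescaled, since downstream thresholding
#' and mean-intensity measures are scale-covariant.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions and nonnegative entries.
#' @param pixel_size_um physical edge length of one pixel in micrometres
#'   (strictly positive).
#' @param animal_id opaque animal identifier.
#' @param group categorical group label (e.g. sex by genotype).
#' @param section_index integer >= 1, serial section number.
#' @param region_index integer >= 1, imaged region within the section.
#' @return an object of class `multichannel_section`.
#' @export
multichannel_section <- function(channels, pixel_size_um,
                                 animal_id = NA_character_,
                                 group = NA_character_,
                                 section_index = 1L, region_index = 1L) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of matrices")
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("every channel must be a numeric matrix")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channel grids must share identical dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  for (nm in names(channels)) {
    if (anyNA(channels[[nm]]) || min(channels[[nm]]) < 0)
      stop("channel '", nm, "' contains negative or missing intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 animal_id = as.character(animal_id),
                 group = as.character(group),
                 section_index = as.integer(section_index),
                 region_index = as.integer(region_index)),
            class = "multichannel_section")
}

#' @export
print.multichannel_section <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("multichannel_section: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  animal=%s group=%s section=%d region=%d\n",
              x$animal_id, x$group, x$section_index, x$region_index))
  invisible(x)
}

#' @rdname multichannel_section
#' @param x object to test.
#' @export
is_multichannel_section <- function(x) inherits(x, "multichannel_section")

#' Confocal z-stack of sections
#'
#' An ordered list of [multichannel_section] planes acquired at a constant
#' axial step. All planes must share dimensions, channel names and metadata.
#'
#' @param planes list of `multichannel_section` objects (>= 1).
#' @param z_step_um axial spacing in micrometres (default 1, the acquisition
#'   step used for confocal stacks in this workflow).
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(planes, z_step_um = 1) {
  if (!is.list(planes) || length(planes) < 1)
    stop("'planes' must be a list with at least one plane")
  if (!all(vapply(planes, is_multichannel_section, logical(1))))
    stop("every plane must be a multichannel_section")
  ref <- planes[[1]]
  for (p in planes[-1]) {
    if (!identical(dim(p$channels[[1]]), dim(ref$channels[[1]])) ||
        !identical(names(p$channels), names(ref$channels)))
      stop("planes differ in dimensions or channel names")
  }
  if (z_step_um <= 0) stop("'z_step_um' must be positive")
  structure(list(planes = planes, z_step_um = as.numeric(z_step_um)),
            class = "section_stack")
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses a [section_stack] to a single [multichannel_section] by taking,
#' per channel, the pixelwise maximum over all z planes. Metadata are copied
#' from the first plane. Quantification in this workflow runs on maximum
#' projections of the confocal stacks.
#'
#' @param stack a `section_stack`.
#' @return a `multichannel_section`.
#' @export
max_projection <- function(stack) {
  if (!inherits(stack, "section_stack")) stop("'stack' must be a section_stack")
  ref <- stack$planes[[1]]
  out <- ref$channels
  for (p in stack$planes[-1])
    for (nm in names(out)) out[[nm]] <- pmax(out[[nm]], p$channels[[nm]])
  multichannel_section(out, ref$pixel_size_um, ref$animal_id, ref$group,
                       ref$section_index, ref$region_index)
}

#' Write a section to a multichannel TIFF
#'
#' Stores each channel as one 16-bit page of a multi-page TIFF, in the order
#' of `names(section$channels)`. Intensities must be integer-valued digital
#' numbers in `[0, 65535]` (what a camera emits); this makes the write/read
#' round trip bit-exact. Channel names and pixel size are not carried in the
#' TIFF tags; the reader takes them as arguments (resolution-independence is
#' handled by converting all physical parameters to pixels at run time).
#'
#' @param section a `multichannel_section` with integer-valued intensities.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  if (!is_multichannel_section(section)) stop("not a multichannel_section")
  pages <- lapply(section$channels, function(ch) {
    if (max(ch) > 65535)
      stop("intensities exceed 65535; 16-bit storage impossible")
    if (any(ch != round(ch)))
      stop("intensities must be integer-valued for 16-bit storage")
    ch / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' Read a multichannel section from a TIFF file
#'
#' @param path a multi-page TIFF, one page per channel.
#' @param channel_map character vector naming each page in order; its length
#'   must not exceed the page count (missing declared channels is an error).
#' @param pixel_size_um physical pixel size in micrometres (required; image
#'   tags are not trusted for it).
#' @param animal_id,group,section_index,region_index provenance, as in
#'   [multichannel_section()].
#' @return a `multichannel_section`.
#' @export
read_section <- function(path, channel_map, pixel_size_um,
                         animal_id = NA_character_, group = NA_character_,
                         section_index = 1L, region_index = 1L) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(channel_map) > length(pages))
    stop("missing channel: file has ", length(pages), " plane(s) but channel_map names ",
         length(channel_map))
  chans <- lapply(pages[seq_along(channel_map)], function(p) {
    m <- matrix(as.numeric(p), nrow = nrow(p), ncol = ncol(p))
    m
  })
  names(chans) <- channel_map
  multichannel_section(chans, pixel_size_um, animal_id, group,
                       section_index, region_index)
}

#' Write or read a confocal z-stack as a multi-page TIFF
#'
#' Pages are ordered plane-major: all channels of plane 1, then all channels
#' of plane 2, and so on. Channel names, pixel size and z-step are supplied
#' by the caller on read, as for [read_section()].
#'
#' @param stack a [section_stack].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "section_stack"))
  pages <- list()
  for (p in stack$planes)
    for (nm in names(p$channels)) {
      ch <- p$channels[[nm]]
      if (max(ch) > 65535 || any(ch != round(ch)))
        stop("intensities must be integers in [0, 65535] for 16-bit storage")
      pages[[length(pages) + 1]] <- ch / 65535
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @param path TIFF path.
#' @param channel_map channel names of each plane's pages, in order.
#' @param pixel_size_um physical pixel size (um).
#' @param z_step_um axial spacing (um).
#' @param ... provenance passed to [multichannel_section()].
#' @export
read_stack <- function(path, channel_map, pixel_size_um, z_step_um = 1, ...) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  k <- length(channel_map)
  if (length(pages) %% k != 0)
    stop("page count ", length(pages), " is not a multiple of the ",
         k, " declared channels")
  planes <- lapply(seq_len(length(pages) / k), function(z) {
    chans <- lapply(pages[(z - 1) * k + seq_len(k)], function(p)
      matrix(as.numeric(p), nrow = nrow(p)))
    names(chans) <- channel_map
    multichannel_section(chans, pixel_size_um, ...)
  })
  section_stack(planes, z_step_um = z_step_um)
}

#' Write result tables and a run summary
#'
#' Writes one CSV per pooling level plus a JSON run summary. Used by
#' [run_pipeline()]; exported so partial runs can be persisted too.
#'
#' @param tables named list of data.frames (e.g. `cells`, `images`, `animals`,
#'   `groups`, `qc`, `profiles`, `histograms`, `stereology`, `stats`).
#' @param dir output directory, created if absent.
#' @param summary optional list serialised to `run-summary.json`.
#' @return invisible character vector of written paths.
#' @export
write_result_tables <- function(tables, dir, summary = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(summary)) {
    p <- file.path(dir, "run-summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
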