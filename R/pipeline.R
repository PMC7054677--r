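#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage's parameter block. The input is either a list of
#' in-memory [multichannel_section] objects (`sections`) or simulation
#' parameters (`cohort` + `scene`), in which case the cohort is generated at
#' run time from the global seed.
#'
#' @param sections optional list of `multichannel_section` objects.
#' @param cohort,scene optional [cohort_params()] / [scene_params()] for
#'   simulated input (used when `sections` is `NULL`).
#' @param seg a [segmentation_params()] block.
#' @param assoc an [association_params()] block.
#' @param profile_r_max_um,profile_dr_um radial profile geometry (um).
#' @param profile_channels channels profiled around each analysed cell.
#' @param clec7a_bins number of Clec7a histogram bins (edges span the pooled
#'   1st-99th percentile of the run, computed once).
#' @param ratio_k SD multiplier of the fixed analysis threshold.
#' @param cavalieri a [sampling_design()] for the area estimator.
#' @param stages character subset of
#'   `c("cells", "profiles", "ratio", "stereology", "stats")`; plaque
#'   segmentation and area fraction always run.
#' @param outdir optional output directory for result tables and logs.
#' @param seed global seed; expanded per stage/image internally.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sections = NULL, cohort = cohort_params(),
                       scene = scene_params(),
                       seg = segmentation_params(),
                       assoc = association_params(),
                       profile_r_max_um = 20, profile_dr_um = 0.5,
                       profile_channels = c("Iba1", "4G8"),
                       clec7a_bins = 20,
                       ratio_k = 2,
                       cavalieri = plaque_design(),
                       stages = c("cells", "profiles", "ratio",
                                  "stereology", "stats"),
                       outdir = NULL, seed = 1L) {
  structure(list(sections = sections, cohort = cohort, scene = scene,
                 seg = seg, assoc = assoc,
                 profile_r_max_um = profile_r_max_um,
                 profile_dr_um = profile_dr_um,
                 profile_channels = profile_channels,
                 clec7a_bins = clec7a_bins, ratio_k = ratio_k,
                 cavalieri = cavalieri, stages = stages,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (if no input sections) -> segment -> per-cell
#' quantification -> radial profiles and Clec7a histograms -> BACE1/4G8
#' ratio workflow with QC -> Cavalieri stereology -> image-to-animal-to-group
#' pooling -> pairwise group statistics. Every excluded image or animal is
#' logged with its reason; identical config and seed reproduce identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return invisible list of result tables: `cells`, `images`, `animals`,
#'   `groups`, `profiles`, `histograms`, `qc`, `ratio_images`,
#'   `ratio_animals`, `stereology`, `stats`, plus `log` (character) and
#'   `summary` (list). Tables are also written to `config$outdir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  sections <- config$sections
  if (is.null(sections)) {
    say("simulate: generating cohort (seed %d)", config$seed)
    cg <- generate_cohort(config$cohort, config$scene, seed = config$seed)
    sections <- cg$sections
  }
  say("input: %d image(s)", length(sections))

  do_cells <- "cells" %in% config$stages
  do_prof <- do_cells && "profiles" %in% config$stages
  has_bace1 <- all(vapply(sections, function(s)
    "BACE1" %in% names(s$channels), logical(1)))
  do_ratio <- has_bace1 && "ratio" %in% config$stages
  do_stereo <- "stereology" %in% config$stages

  # run-wide fixed threshold for the shared-threshold burden readout (the
  # pFTAA-style area fraction: one threshold applied to every section)
  has_4g8 <- all(vapply(sections, function(s)
    "4G8" %in% names(s$channels), logical(1)))
  thr_burden <- if (has_4g8)
    fit_fixed_threshold(lapply(sections, function(s) s$channels[["4G8"]]),
                        k = config$ratio_k, channel = "4G8") else NULL

  cells_all <- list(); img_rows <- list(); prof_rows <- list()
  stereo_rows <- list()
  for (k in seq_along(sections)) {
    s <- sections[[k]]
    id <- paste0(s$animal_id, "_s", s$section_index, "r", s$region_index)
    plaques <- segment_plaques(s, config$seg)
    row <- data.frame(image_id = id, animal_id = s$animal_id,
                      group = s$group,
                      n_plaques = nrow(plaques$regions),
                      plaque_area_fraction_pct =
                        100 * mean(plaques$labels > 0))
    if (!is.null(thr_burden))
      row$g8_stained_fraction_pct <-
        100 * stained_fraction(s$channels[["4G8"]], thr_burden)
    if (do_cells) {
      nuclei <- segment_nuclei(s, config$seg)
      cells <- measure_expression(nuclei, s)
      cells$image_id <- id
      cells$animal_id <- s$animal_id
      cells$group <- s$group
      cells$iba1_positive <- classify_iba1(cells$mean_Iba1)
      cells <- nearest_plaque_metrics(cells, plaques, config$assoc)
      cells_all[[length(cells_all) + 1]] <- cells
      if (nrow(plaques$regions) == 0) {
        say("image %s: no plaques; association metrics undefined", id)
        row$n_associated <- NA_real_
        row$normalised_count_per_um2 <- NA_real_
      } else {
        sm <- plaque_associated_summary(cells, plaques)
        row$n_associated <- sm$n_associated
        row$normalised_count_per_um2 <- sm$normalised_count_per_um2
      }
      if (do_prof) {
        sel <- which(cells$iba1_positive & cells$plaque_associated %in% TRUE)
        if (length(sel) > 0) {
          for (chn in config$profile_channels) {
            mats <- lapply(sel, function(i) {
              p <- radial_profile(s, chn,
                                  c(cells$centroid_x_um[i],
                                    cells$centroid_y_um[i]),
                                  config$profile_r_max_um,
                                  config$profile_dr_um)
              stats::setNames(p$value, as.character(p$bin_mid_um))
            })
            bins <- sort(as.numeric(unique(unlist(lapply(mats, names)))))
            avg <- vapply(as.character(bins), function(b)
              mean(unlist(lapply(mats, function(m) m[b])), na.rm = TRUE),
              numeric(1))
            avg <- normalise_curve(avg, config$profile_dr_um)
            prof_rows[[length(prof_rows) + 1]] <- data.frame(
              image_id = id, animal_id = s$animal_id, group = s$group,
              channel = chn, bin = bins, value = as.numeric(avg))
          }
        }
      }
    }
    if (do_stereo) {
      st <- tryCatch(
        cavalieri_area_fraction(plaques$labels > 0,
                                matrix(TRUE, nrow(plaques$labels),
                                       ncol(plaques$labels)),
                                config$cavalieri, s$pixel_size_um,
                                seed = config$seed + k),
        error = function(e) NULL)
      if (!is.null(st))
        stereo_rows[[length(stereo_rows) + 1]] <- data.frame(
          image_id = id, animal_id = s$animal_id, group = s$group,
          cavalieri_pct = st$estimate, points_in_roi = st$points_in_roi)
    }
    img_rows[[length(img_rows) + 1]] <- row
  }
  images <- do.call(rbind, img_rows)
  cells_tab <- if (length(cells_all) > 0) do.call(rbind, cells_all) else NULL
  profiles <- if (length(prof_rows) > 0) do.call(rbind, prof_rows) else NULL
  stereology <- if (length(stereo_rows) > 0) do.call(rbind, stereo_rows)
                else NULL

  ## Clec7a histograms (image-wise binning on run-wide edges, then pooled)
  histograms <- NULL
  if (do_cells && !is.null(cells_tab)) {
    sel <- cells_tab$iba1_positive & cells_tab$plaque_associated %in% TRUE
    vals <- cells_tab$mean_Clec7a[sel]
    if (sum(sel) >= 10) {
      edges <- seq(stats::quantile(vals, 0.01), stats::quantile(vals, 0.99),
                   length.out = config$clec7a_bins + 1)
      if (diff(range(edges)) > 0) {
        hrows <- lapply(split(seq_len(nrow(cells_tab))[sel],
                              cells_tab$image_id[sel]), function(ii) {
          h <- binned_histogram(cells_tab$mean_Clec7a[ii], edges,
                                normalise = TRUE)
          data.frame(image_id = cells_tab$image_id[ii[1]],
                     animal_id = cells_tab$animal_id[ii[1]],
                     group = cells_tab$group[ii[1]],
                     bin = h$bin_mid, value = h$value)
        })
        histograms <- do.call(rbind, hrows)
        rownames(histograms) <- NULL
      }
    }
  }

  ## BACE1/4G8 ratio workflow with QC
  qc <- NULL; ratio_images <- NULL; ratio_animals <- NULL
  if (do_ratio) {
    feats <- qc_features(sections, c("BACE1", "4G8"))
    qc <- qc_filter(feats)
    say("QC: excluded %d of %d image(s) (%.1f%%)", sum(qc$excluded),
        nrow(qc), 100 * mean(qc$excluded))
    keep <- !qc$excluded
    grey_b <- lapply(sections[keep], to_greyscale_contrast, channel = "BACE1")
    grey_g <- lapply(sections[keep], to_greyscale_contrast, channel = "4G8")
    thr_b <- fit_fixed_threshold(grey_b, k = config$ratio_k, channel = "BACE1")
    thr_g <- fit_fixed_threshold(grey_g, k = config$ratio_k, channel = "4G8")
    grey_sections <- lapply(seq_along(sections), function(i) {
      s <- sections[[i]]
      s$channels$BACE1 <- to_greyscale_contrast(s, "BACE1")
      s$channels[["4G8"]] <- to_greyscale_contrast(s, "4G8")
      s
    })
    rat <- tryCatch(bace1_4g8_ratio(grey_sections, thr_b, thr_g, qc = qc),
                    error = function(e) { say("ratio: %s", conditionMessage(e)); NULL })
    if (!is.null(rat)) {
      ratio_images <- rat$images
      ratio_animals <- rat$animals
    }
  }

  ## pooling image -> animal -> group
  pooled <- pool(images[, c("animal_id", "group", "n_plaques",
                            "plaque_area_fraction_pct",
                            intersect(c("g8_stained_fraction_pct",
                                        "n_associated",
                                        "normalised_count_per_um2"),
                                      names(images)))])
  animals <- pooled$animals
  groups <- pooled$groups
  if (!is.null(ratio_animals)) {
    m <- match(animals$animal_id, ratio_animals$animal_id)
    animals$bace1_4g8_ratio <- ratio_animals$median_ratio[m]
    rg <- pool(data.frame(animal_id = ratio_animals$animal_id,
                          group = ratio_animals$group,
                          bace1_4g8_ratio = ratio_animals$median_ratio,
                          check.names = FALSE))
    # animal level already pooled; the median of one value is itself
    groups <- rbind(groups, rg$groups)
  }
  pooled_profiles <- if (!is.null(profiles))
    pool(profiles[, c("animal_id", "group", "bin", "value")])$groups else NULL
  pooled_hist <- if (!is.null(histograms))
    pool(histograms[, c("animal_id", "group", "bin", "value")])$groups
    else NULL

  ## pairwise group statistics on animal-level values
  stats_tab <- NULL
  if ("stats" %in% config$stages &&
      length(unique(animals$group)) >= 2) {
    stats_tab <- compare_groups(animals,
                                metrics = setdiff(names(animals)[vapply(animals, is.numeric, logical(1))],
                                                  c("bin")))
  }

  out <- list(cells = cells_tab, images = images, animals = animals,
              groups = groups, profiles = profiles,
              pooled_profiles = pooled_profiles,
              histograms = histograms, pooled_histograms = pooled_hist,
              qc = qc, ratio_images = ratio_images,
              ratio_animals = ratio_animals,
              stereology = stereology, stats = stats_tab, log = log,
              summary = list(seed = config$seed,
                             n_images = length(sections),
                             n_excluded_qc = if (is.null(qc)) 0
                                             else sum(qc$excluded),
                             stages = config$stages))
  if (!is.null(config$outdir)) {
    tabs <- Filter(Negate(is.null),
                   out[c("cells", "images", "animals", "groups", "profiles",
                         "histograms", "qc", "ratio_images", "ratio_animals",
                         "stereology", "stats")])
    write_result_tables(tabs, config$outdir, summary = out$summary)
    writeLines(log, file.path(config$outdir, "run.log"))
  }
  invisible(out)
}
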