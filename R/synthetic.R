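#' Parameters of one synthetic section scene
#'
#' Describes the generative model for a single multichannel field emulating a
#' cortical section of an amyloid-depositing mouse: plaques are blurred discs
#' placed by a homogeneous Poisson process with log-normal areas, a quarter
#' of them carrying a bright compact core; nuclei are soft discs, with
#' microglia enriched within the association radius of plaque borders; Iba1
#' is an isotropic exponential halo (decay ~6 um) around microglial nuclei;
#' plaque-associated microglia carry an intracellular 4G8 blob whose radial
#' signal peaks ~4 um from the nucleus centre; Clec7a expression is bimodal
#' (activated microglia near plaques vs. homeostatic elsewhere); BACE1 is an
#' annular signal at plaque rims; Poisson photon noise plus Gaussian read
#' noise is applied last and intensities are quantised to integer camera
#' counts. Ground truth is recorded before noise.
#'
#' @param image_px image side length in pixels (square images).
#' @param pixel_size_um physical pixel size (um).
#' @param plaque_per_mm2 plaque count intensity (per mm^2).
#' @param plaque_area_median_um2,plaque_area_sdlog log-normal plaque area
#'   distribution (median um^2 and sd of log area).
#' @param compact_fraction fraction of plaques carrying a dense core.
#' @param plaque_amp,plaque_edge_um,core_amp,core_radius_frac plaque disc
#'   amplitude, soft-edge scale, additional core amplitude, core radius as a
#'   fraction of the plaque radius.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd nucleus radius
#'   distribution (um).
#' @param nucleus_amp DAPI disc amplitude.
#' @param cell_density_per_mm2 background cell density.
#' @param assoc_density_mult density multiplier for cells within the
#'   association zone around plaque borders.
#' @param association_radius_um width of the plaque-associated zone (um).
#' @param microglia_fraction fraction of cells that are microglia.
#' @param iba1_amp_pos,iba1_amp_neg,iba1_decay_um Iba1 halo amplitudes
#'   (microglia vs. other cells) and exponential decay scale (um).
#' @param g8_blob_amp,g8_blob_offset_um,g8_blob_sigma_um intracellular 4G8
#'   blob amplitude, offset of its centre from the nucleus centre (um) and
#'   Gaussian scale (um).
#' @param clec7a_act_frac_assoc,clec7a_act_frac_far probability that a
#'   microglial cell is disease-activated, near vs. far from plaques.
#' @param clec7a_high_mean,clec7a_high_sd,clec7a_low_mean,clec7a_low_sd the
#'   two modes of Clec7a expression.
#' @param bace1_amp,bace1_ring_width_um BACE1 rim annulus amplitude and
#'   Gaussian width (um).
#' @param background constant background level added to every channel.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_px = 512, pixel_size_um = 0.72,
                         plaque_per_mm2 = 60,
                         plaque_area_median_um2 = 1500,
                         plaque_area_sdlog = 0.5,
                         compact_fraction = 0.25,
                         plaque_amp = 100, plaque_edge_um = 2,
                         core_amp = 150, core_radius_frac = 0.4,
                         nucleus_radius_um_mean = 3,
                         nucleus_radius_um_sd = 0.3,
                         nucleus_amp = 100,
                         cell_density_per_mm2 = 100,
                         assoc_density_mult = 8,
                         association_radius_um = 30,
                         microglia_fraction = 0.7,
                         iba1_amp_pos = 120, iba1_amp_neg = 10,
                         iba1_decay_um = 6,
                         g8_blob_amp = 200, g8_blob_offset_um = 4,
                         g8_blob_sigma_um = 1.5,
                         clec7a_act_frac_assoc = 0.7,
                         clec7a_act_frac_far = 0.05,
                         clec7a_high_mean = 150, clec7a_high_sd = 20,
                         clec7a_low_mean = 40, clec7a_low_sd = 10,
                         bace1_amp = 80, bace1_ring_width_um = 3,
                         background = 5, read_noise_sd = 2) {
  p <- as.list(environment())
  stopifnot(p$image_px >= 16, p$pixel_size_um > 0, p$plaque_per_mm2 >= 0,
            p$compact_fraction >= 0, p$compact_fraction <= 1,
            p$cell_density_per_mm2 >= 0, p$assoc_density_mult >= 1,
            p$microglia_fraction >= 0, p$microglia_fraction <= 1,
            p$iba1_decay_um > 0, p$read_noise_sd >= 0)
  structure(p, class = "scene_params")
}

#' Cohort-level generation parameters
#'
#' Group structure of a synthetic study. Each group carries a multiplier on
#' the plaque count intensity; defaults mirror the modelled cohort: female
#' burden twice the male baseline, and an IL12p40-knockout male arm at 0.42x
#' of male control (a 58% reduction in 4G8-covered area) available via
#' `groups = c(male = 1, male_ko = 0.42)`.
#'
#' @param groups named numeric vector of per-group plaque-burden multipliers.
#' @param animals_per_group animals per group (default 8).
#' @param images_per_animal images per animal (default 30: 10 serial
#'   sections, 3 regions each).
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(groups = c(female = 2, male = 1),
                          animals_per_group = 8,
                          images_per_animal = 30) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)), all(groups > 0),
            animals_per_group >= 1, images_per_animal >= 1)
  structure(list(groups = groups,
                 animals_per_group = as.integer(animals_per_group),
                 images_per_animal = as.integer(images_per_animal)),
            class = "cohort_params")
}

# splittable deterministic sub-seed: adding animals/images never perturbs
# the seeds of existing ones. The Lehmer iterations scatter the derived
# seeds across the full integer range; near-consecutive seeds must be
# avoided because streams from nearby set.seed() values are measurably
# correlated in their first draws (enough to distort cohort statistics)
derive_seed <- function(seed, group_idx, animal_idx, image_idx) {
  x <- (seed %% 2147483646) + 1
  x <- (x * 48271) %% 2147483647
  key <- (group_idx * 1000003 + animal_idx * 10007 + image_idx) %%
    2147483646 + 1
  x <- (x + key - 1) %% 2147483646 + 1
  for (j in 1:8) x <- (x * 48271) %% 2147483647   # exact in doubles (< 2^53)
  as.integer(x)
}

# paint value_fun(r) into img around (cx, cy) um within radius extent_um
paint_radial <- function(img, cx, cy, extent_um, px, value_fun) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(1L, floor((cx - extent_um) / px) + 1L)
  c1 <- min(nc, ceiling((cx + extent_um) / px))
  r0 <- max(1L, floor((cy - extent_um) / px) + 1L)
  r1 <- min(nr, ceiling((cy + extent_um) / px))
  if (c0 > c1 || r0 > r1) return(img)
  xs <- (c0:c1 - 0.5) * px
  ys <- (r0:r1 - 0.5) * px
  rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + value_fun(rr)
  img
}

soft_disc <- function(amp, radius, edge) {
  function(r) amp / (1 + exp((r - radius) / edge))
}

#' Generate one synthetic multichannel section with ground truth
#'
#' Renders DAPI, 4G8, Iba1, Clec7a and BACE1 channels according to
#' [scene_params()], deterministic given the seed. Intensities are integer
#' camera counts after Poisson photon noise and Gaussian read noise.
#'
#' @param scene a [scene_params()] object.
#' @param seed integer seed.
#' @param animal_id,group,section_index,region_index provenance for the
#'   emitted section.
#' @param burden_multiplier multiplier on the plaque count intensity (the
#'   group effect).
#' @return list with `section` (a [multichannel_section]) and `truth`: a list
#'   with `plaques` (x, y, radius_um, area_um2, compact), `cells` (positions,
#'   classes, expression draws, true border distances), `plaque_labels`
#'   (integer matrix of true disc masks), `core_mask` (logical, compact
#'   cores; the congophilic-core stand-in), `burden_area_fraction` (true
#'   fraction of pixels covered by plaque discs) and `seed`.
#' @export
generate_section <- function(scene = scene_params(), seed = 1L,
                             animal_id = "a1", group = "g1",
                             section_index = 1L, region_index = 1L,
                             burden_multiplier = 1) {
  stopifnot(inherits(scene, "scene_params"), burden_multiplier > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- scene$image_px; px <- scene$pixel_size_um
  side_um <- n * px
  area_mm2 <- (side_um / 1000)^2
  zero <- matrix(0, n, n)
  ch <- list(DAPI = zero, "4G8" = zero, Iba1 = zero, Clec7a = zero,
             BACE1 = zero)

  ## --- plaques: homogeneous Poisson process, log-normal areas -------------
  n_plq <- stats::rpois(1, scene$plaque_per_mm2 * burden_multiplier * area_mm2)
  plaques <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        radius_um = numeric(0), area_um2 = numeric(0),
                        compact = logical(0))
  plaque_labels <- matrix(0L, n, n)
  core_mask <- matrix(FALSE, n, n)
  if (n_plq > 0) {
    areas <- stats::rlnorm(n_plq, meanlog = log(scene$plaque_area_median_um2),
                           sdlog = scene$plaque_area_sdlog)
    plaques <- data.frame(x_um = stats::runif(n_plq, 0, side_um),
                          y_um = stats::runif(n_plq, 0, side_um),
                          radius_um = sqrt(areas / pi),
                          area_um2 = areas,
                          compact = stats::runif(n_plq) < scene$compact_fraction)
    xs <- (seq_len(n) - 0.5) * px
    for (i in seq_len(n_plq)) {
      R <- plaques$radius_um[i]
      ch[["4G8"]] <- paint_radial(ch[["4G8"]], plaques$x_um[i], plaques$y_um[i],
                                  R + 6 * scene$plaque_edge_um, px,
                                  soft_disc(scene$plaque_amp, R,
                                            scene$plaque_edge_um))
      ch[["BACE1"]] <- paint_radial(ch[["BACE1"]], plaques$x_um[i],
                                    plaques$y_um[i],
                                    R + 4 * scene$bace1_ring_width_um, px,
                                    function(r) scene$bace1_amp *
                                      exp(-(r - R)^2 /
                                            (2 * scene$bace1_ring_width_um^2)))
      # true disc mask (later plaques overwrite earlier on overlap)
      c0 <- max(1L, floor((plaques$x_um[i] - R) / px) + 1L)
      c1 <- min(n, ceiling((plaques$x_um[i] + R) / px))
      r0 <- max(1L, floor((plaques$y_um[i] - R) / px) + 1L)
      r1 <- min(n, ceiling((plaques$y_um[i] + R) / px))
      if (c0 <= c1 && r0 <= r1) {
        rr <- sqrt(outer((xs[r0:r1] - plaques$y_um[i])^2,
                         (xs[c0:c1] - plaques$x_um[i])^2, "+"))
        blk <- plaque_labels[r0:r1, c0:c1]
        blk[rr <= R] <- i
        plaque_labels[r0:r1, c0:c1] <- blk
        if (plaques$compact[i]) {
          core <- core_mask[r0:r1, c0:c1]
          core[rr <= R * scene$core_radius_frac] <- TRUE
          core_mask[r0:r1, c0:c1] <- core
          ch[["4G8"]] <- paint_radial(ch[["4G8"]], plaques$x_um[i],
                                      plaques$y_um[i],
                                      R * scene$core_radius_frac +
                                        4 * scene$plaque_edge_um, px,
                                      soft_disc(scene$core_amp,
                                                R * scene$core_radius_frac,
                                                scene$plaque_edge_um / 2))
        }
      }
    }
  }

  ## --- cells: background field + enrichment around plaque borders --------
  dist_to_border <- function(x, y) {
    if (nrow(plaques) == 0) return(rep(NA_real_, length(x)))
    d <- sapply(seq_len(nrow(plaques)), function(i) {
      sqrt((x - plaques$x_um[i])^2 + (y - plaques$y_um[i])^2) -
        plaques$radius_um[i]
    })
    if (is.null(dim(d))) d <- matrix(d, nrow = length(x))
    pmax(0, apply(d, 1, min))
  }
  n_bg <- stats::rpois(1, scene$cell_density_per_mm2 * area_mm2)
  cx <- stats::runif(n_bg, 0, side_um)
  cy <- stats::runif(n_bg, 0, side_um)
  if (nrow(plaques) > 0 && scene$assoc_density_mult > 1) {
    for (i in seq_len(nrow(plaques))) {
      R <- plaques$radius_um[i]
      Rz <- R + scene$association_radius_um
      zone_mm2 <- pi * (Rz^2 - R^2) / 1e6
      n_extra <- stats::rpois(1, (scene$assoc_density_mult - 1) *
                                scene$cell_density_per_mm2 * zone_mm2)
      if (n_extra > 0) {
        rr <- sqrt(R^2 + stats::runif(n_extra) * (Rz^2 - R^2))
        th <- stats::runif(n_extra, 0, 2 * pi)
        cx <- c(cx, plaques$x_um[i] + rr * cos(th))
        cy <- c(cy, plaques$y_um[i] + rr * sin(th))
      }
    }
  }
  inside <- cx > 2 & cx < side_um - 2 & cy > 2 & cy < side_um - 2
  cx <- cx[inside]; cy <- cy[inside]
  # greedy thinning: enforce a minimum centre separation so nuclei stay
  # resolvable (watershed still has to split blur-merged neighbours)
  min_sep <- 2.4 * scene$nucleus_radius_um_mean
  keep <- rep(TRUE, length(cx))
  if (length(cx) > 1) {
    for (i in 2:length(cx)) {
      prior <- which(keep[seq_len(i - 1)])
      if (length(prior) > 0 &&
          min((cx[i] - cx[prior])^2 + (cy[i] - cy[prior])^2) < min_sep^2)
        keep[i] <- FALSE
    }
  }
  cx <- cx[keep]; cy <- cy[keep]
  n_cells <- length(cx)
  cells <- data.frame(x_um = cx, y_um = cy)
  if (n_cells > 0) {
    cells$radius_um <- pmax(1, stats::rnorm(n_cells,
                                            scene$nucleus_radius_um_mean,
                                            scene$nucleus_radius_um_sd))
    cells$dist_to_border_um <- dist_to_border(cx, cy)
    cells$associated <- !is.na(cells$dist_to_border_um) &
      cells$dist_to_border_um <= scene$association_radius_um
    cells$is_microglia <- stats::runif(n_cells) < scene$microglia_fraction
    act_p <- ifelse(cells$associated, scene$clec7a_act_frac_assoc,
                    scene$clec7a_act_frac_far)
    cells$activated <- cells$is_microglia & stats::runif(n_cells) < act_p
    cells$clec7a <- ifelse(cells$activated,
                           stats::rnorm(n_cells, scene$clec7a_high_mean,
                                        scene$clec7a_high_sd),
                           stats::rnorm(n_cells, scene$clec7a_low_mean,
                                        scene$clec7a_low_sd))
    cells$clec7a <- pmax(0, cells$clec7a)
    cells$has_g8_blob <- cells$is_microglia & cells$associated
    blob_angle <- stats::runif(n_cells, 0, 2 * pi)
    cells$blob_x_um <- cells$x_um + scene$g8_blob_offset_um * cos(blob_angle)
    cells$blob_y_um <- cells$y_um + scene$g8_blob_offset_um * sin(blob_angle)
    for (i in seq_len(n_cells)) {
      rn <- cells$radius_um[i]
      ch$DAPI <- paint_radial(ch$DAPI, cx[i], cy[i], rn + 3, px,
                              soft_disc(scene$nucleus_amp, rn, 0.5))
      amp_i <- if (cells$is_microglia[i]) scene$iba1_amp_pos else
        scene$iba1_amp_neg
      ch$Iba1 <- paint_radial(ch$Iba1, cx[i], cy[i],
                              4 * scene$iba1_decay_um, px,
                              function(r) amp_i * exp(-r / scene$iba1_decay_um))
      ch$Clec7a <- paint_radial(ch$Clec7a, cx[i], cy[i], rn + 3, px,
                                soft_disc(cells$clec7a[i], rn, 0.5))
      if (cells$has_g8_blob[i])
        ch[["4G8"]] <- paint_radial(ch[["4G8"]], cells$blob_x_um[i],
                                    cells$blob_y_um[i],
                                    5 * scene$g8_blob_sigma_um, px,
                                    function(r) scene$g8_blob_amp *
                                      exp(-r^2 / (2 * scene$g8_blob_sigma_um^2)))
    }
  }

  ## --- noise model: Poisson photon noise + Gaussian read noise -----------
  for (nm in names(ch)) {
    lam <- ch[[nm]] + scene$background
    noisy <- stats::rpois(length(lam), lam) +
      stats::rnorm(length(lam), 0, scene$read_noise_sd)
    ch[[nm]] <- matrix(pmin(65535, pmax(0, round(noisy))), n, n)
  }

  section <- multichannel_section(ch, px, animal_id, group,
                                  section_index, region_index)
  truth <- list(plaques = plaques, cells = cells,
                plaque_labels = plaque_labels, core_mask = core_mask,
                burden_area_fraction = mean(plaque_labels > 0),
                seed = as.integer(seed))
  list(section = section, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' One set of sections per animal per group, each image seeded independently
#' via a splittable counter so regeneration is bit-identical and adding
#' images never perturbs existing ones. Optionally writes the cohort to disk
#' as TIFFs plus truth CSVs and a manifest JSON sufficient to regenerate it.
#'
#' @param cohort a [cohort_params()] object.
#' @param scene a [scene_params()] object (per-group multipliers are applied
#'   on top of its plaque intensity).
#' @param seed integer master seed.
#' @param dir optional output directory; when given, one sub-directory per
#'   animal of TIFF sections is written, with `truth_images.csv`,
#'   `truth_cells.csv` and `manifest.json` at the top level.
#' @return list: `sections` (flat list of [multichannel_section]), `truth`
#'   (list with `images` data.frame - one row per image with its seed and
#'   true burden - and `cells` data.frame), `cohort`, `scene`, `seed`.
#' @export
generate_cohort <- function(cohort = cohort_params(),
                            scene = scene_params(), seed = 1L, dir = NULL) {
  sections <- list()
  img_rows <- list()
  cell_rows <- list()
  gnames <- names(cohort$groups)
  for (gi in seq_along(gnames)) {
    for (ai in seq_len(cohort$animals_per_group)) {
      animal <- paste0(gnames[gi], "_", ai)
      for (ii in seq_len(cohort$images_per_animal)) {
        s_idx <- ((ii - 1) %/% 3) + 1
        r_idx <- ((ii - 1) %% 3) + 1
        sd_i <- derive_seed(seed, gi, ai, ii)
        gen <- generate_section(scene, sd_i, animal, gnames[gi],
                                s_idx, r_idx,
                                burden_multiplier = cohort$groups[[gi]])
        sections[[length(sections) + 1]] <- gen$section
        img_rows[[length(img_rows) + 1]] <- data.frame(
          image_id = paste0(animal, "_s", s_idx, "r", r_idx),
          animal_id = animal, group = gnames[gi],
          section_index = s_idx, region_index = r_idx, seed = sd_i,
          n_plaques = nrow(gen$truth$plaques),
          true_area_fraction = gen$truth$burden_area_fraction,
          true_core_fraction = mean(gen$truth$core_mask),
          total_plaque_area_um2 = sum(gen$truth$plaques$area_um2),
          compact_plaque_area_um2 =
            sum(gen$truth$plaques$area_um2[gen$truth$plaques$compact]))
        if (nrow(gen$truth$cells) > 0)
          cell_rows[[length(cell_rows) + 1]] <- cbind(
            data.frame(image_id = paste0(animal, "_s", s_idx, "r", r_idx),
                       animal_id = animal, group = gnames[gi]),
            gen$truth$cells)
      }
    }
  }
  truth <- list(images = do.call(rbind, img_rows),
                cells = if (length(cell_rows) > 0) do.call(rbind, cell_rows)
                        else NULL)
  out <- list(sections = sections, truth = truth, cohort = cohort,
              scene = scene, seed = as.integer(seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sections) {
      adir <- file.path(dir, s$animal_id)
      dir.create(adir, showWarnings = FALSE)
      write_section(s, file.path(adir, sprintf("s%02dr%d.tif",
                                               s$section_index,
                                               s$region_index)))
    }
    utils::write.csv(truth$images, file.path(dir, "truth_images.csv"),
                     row.names = FALSE)
    if (!is.null(truth$cells))
      utils::write.csv(truth$cells, file.path(dir, "truth_cells.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(seed = seed,
                              cohort = unclass(cohort),
                              scene = unclass(scene),
                              channel_order = c("DAPI", "4G8", "Iba1",
                                                "Clec7a", "BACE1")),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
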