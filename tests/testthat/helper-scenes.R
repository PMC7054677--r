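# Programmatic image fixtures: all scenes are built in code at test time.

# blank square section with the given channels
blank_section <- function(channels, n = 64, pixel_size_um = 0.72, ...) {
  ch <- stats::setNames(rep(list(matrix(0, n, n)), length(channels)),
                        channels)
  multichannel_section(ch, pixel_size_um, ...)
}

# paint a hard disc of the given amplitude into a matrix (um coordinates)
paint_disc <- function(img, cx, cy, radius_um, pixel_size_um, amp = 100) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- (seq_len(nc) - 0.5) * pixel_size_um
  ys <- (seq_len(nr) - 0.5) * pixel_size_um
  rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  img[rr <= radius_um] <- amp
  img
}

# DAPI-only scene with planted, non-touching nuclei at SNR >= 5:
# jittered grid positions, soft discs, Poisson + Gaussian noise
planted_nuclei_scene <- function(n_nuclei = 50, n = 256, pixel_size_um = 0.72,
                                 radius_um = 3, amp = 100, background = 5,
                                 read_sd = 2, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  side <- n * pixel_size_um
  k <- ceiling(sqrt(n_nuclei))
  pitch <- (side - 2 * radius_um - 4) / k
  stopifnot(pitch > 2 * radius_um + 2)   # guarantees non-touching
  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  grid <- grid[sample(nrow(grid), n_nuclei), ]
  jit <- (pitch - 2 * radius_um - 2) / 2
  cx <- radius_um + 2 + (grid$i - 0.5) * pitch + runif(n_nuclei, -jit, jit)
  cy <- radius_um + 2 + (grid$j - 0.5) * pitch + runif(n_nuclei, -jit, jit)
  img <- matrix(0, n, n)
  xs <- (seq_len(n) - 0.5) * pixel_size_um
  for (i in seq_len(n_nuclei)) {
    rr2 <- outer((xs - cy[i])^2, (xs - cx[i])^2, "+")
    img <- img + amp / (1 + exp((sqrt(rr2) - radius_um) / 0.5))
  }
  noisy <- matrix(pmax(0, round(rpois(n * n, img + background) +
                                  rnorm(n * n, 0, read_sd))), n, n)
  list(section = multichannel_section(list(DAPI = noisy), pixel_size_um),
       centres = cbind(x = cx, y = cy))
}

# match detected centroids to planted centres within a radius; returns
# recall and precision
match_centres <- function(detected, planted, radius_um = 3) {
  if (nrow(detected) == 0)
    return(c(recall = 0, precision = if (nrow(planted) == 0) 1 else 0))
  used <- rep(FALSE, nrow(detected))
  hits <- 0
  for (i in seq_len(nrow(planted))) {
    d2 <- (detected[, 1] - planted[i, 1])^2 +
      (detected[, 2] - planted[i, 2])^2
    j <- which(!used & d2 <= radius_um^2)
    if (length(j) > 0) {
      used[j[which.min(d2[j])]] <- TRUE
      hits <- hits + 1
    }
  }
  c(recall = hits / nrow(planted), precision = sum(used) / nrow(detected))
}

# fixed random blob mask on a 2.7 mm field (6 periods of the 450 um scan
# grid) with known pixel-count area truth; shared by unit + acceptance tests
blob_mask_2p7mm <- function(seed = 17) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- 1350; px <- 2
  xs <- (seq_len(n) - 0.5) * px
  mask <- matrix(FALSE, n, n)
  for (i in 1:120) {
    cx <- runif(1, 60, 2640); cy <- runif(1, 60, 2640)
    R <- runif(1, 20, 60)
    c0 <- max(1, floor((cx - R) / px)); c1 <- min(n, ceiling((cx + R) / px))
    r0 <- max(1, floor((cy - R) / px)); r1 <- min(n, ceiling((cy + R) / px))
    rr <- sqrt(outer((xs[r0:r1] - cy)^2, (xs[c0:c1] - cx)^2, "+"))
    blk <- mask[r0:r1, c0:c1]; blk[rr <= R] <- TRUE
    mask[r0:r1, c0:c1] <- blk
  }
  mask
}

# reduced-size scene for pipeline-level tests: same physical field as the
# default scene but coarser pixels, and no cells unless asked for
fast_burden_scene <- function(cells = FALSE)
  scene_params(image_px = 128, pixel_size_um = 2.88,
               cell_density_per_mm2 = if (cells) 100 else 0)
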