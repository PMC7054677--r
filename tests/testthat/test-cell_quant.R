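make_painted_scene <- function() {
  # three hand-painted nuclei with known per-region expression values
  px <- 1
  lab <- matrix(0L, 40, 40)
  lab[5:8, 5:8] <- 1L
  lab[20:24, 10:13] <- 2L
  lab[30:33, 30:34] <- 3L
  expr <- matrix(0, 40, 40)
  expr[lab == 1] <- 10; expr[lab == 2] <- 40; expr[lab == 3] <- 90
  s <- multichannel_section(list(Iba1 = expr, Clec7a = 2 * expr), px)
  list(mask = label_mask(lab, px), section = s)
}

test_that("expression means are exact over labelled pixels", {
  sc <- make_painted_scene()
  cells <- measure_expression(sc$mask, sc$section)
  expect_equal(cells$mean_Iba1, c(10, 40, 90))
  expect_equal(cells$mean_Clec7a, c(20, 80, 180))
  # constant channel -> every cell mean equals the constant
  s2 <- sc$section; s2$channels$Iba1[] <- 7
  expect_equal(measure_expression(sc$mask, s2)$mean_Iba1, rep(7, 3))
  # empty mask -> empty table
  empty <- label_mask(matrix(0L, 40, 40), 1)
  expect_equal(nrow(measure_expression(empty, sc$section)), 0)
  # dimension mismatch is an error
  expect_error(measure_expression(label_mask(matrix(0L, 10, 10), 1),
                                  sc$section), "dimensions differ")
})

test_that("Iba1 classification equals the exhaustive Otsu split", {
  expect_identical(classify_iba1(c(10, 11, 12, 200, 210)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(classify_iba1(rep(5, 8)), rep(FALSE, 8))
  expect_identical(classify_iba1(numeric(0)), logical(0))
  set.seed(21)
  for (i in 1:100) {
    v <- rnorm(100, 50, 20)
    expect_identical(classify_iba1(v), v > brute_otsu(v))
  }
})

test_that("nearest-plaque distance is analytic for a disc plaque", {
  px <- 0.5
  img <- paint_disc(matrix(0, 200, 200), 50, 50, 15, px, amp = 200)
  s <- multichannel_section(list("4G8" = img), px)
  plq <- segment_plaques(s, segmentation_params(sigma_plaque_um = 1,
                                                min_plaque_area_um2 = 100))
  expect_equal(nrow(plq$regions), 1)
  cells <- data.frame(centroid_x_um = c(50, 80, 50), centroid_y_um = c(50, 50, 90))
  out <- nearest_plaque_metrics(cells, plq, association_params(30))
  # centre of the plaque: inside -> distance 0, associated
  expect_equal(out$dist_to_plaque_border_um[1], 0)
  expect_true(out$plaque_associated[1])
  # cell at d = 30 from centre -> distance ~ 15 from border (one px diagonal)
  expect_lt(abs(out$dist_to_plaque_border_um[2] - 15), px * sqrt(2) + 0.5)
  expect_true(out$plaque_associated[2])    # 15 <= 30, inclusive band
  # cell at d = 40 -> ~25 um, associated (<= 30); nearest area is the disc
  expect_lt(abs(out$dist_to_plaque_border_um[3] - 25), px * sqrt(2) + 0.5)
  expect_equal(out$nearest_plaque_area_um2,
               rep(plq$regions$area_um2[1], 3))
})

test_that("plaque-free images give sentinel distances and no association", {
  empty <- label_mask(matrix(0L, 32, 32), 1)
  cells <- data.frame(centroid_x_um = c(5, 10), centroid_y_um = c(5, 10))
  out <- nearest_plaque_metrics(cells, empty)
  expect_true(all(is.na(out$dist_to_plaque_border_um)))
  expect_true(all(!out$plaque_associated))
  expect_message(
    expect_null(plaque_associated_summary(data.frame(), empty)),
    "no plaques")
})

test_that("normalised associated-cell count follows the closed form", {
  px <- 1
  lab <- matrix(0L, 64, 64); lab[10:41, 10:41] <- 1L   # 1024 px = 1024 um^2
  plq <- label_mask(lab, px)
  cells <- data.frame(centroid_x_um = c(25, 26, 27, 5),
                      centroid_y_um = c(25, 26, 27, 60),
                      iba1_positive = c(TRUE, TRUE, TRUE, TRUE))
  cells <- nearest_plaque_metrics(cells, plq, association_params(30))
  sm <- plaque_associated_summary(cells, plq)
  expect_equal(sm$n_associated, 4)  # corner cell is ~19.8 um away, associated
  expect_equal(sm$normalised_count_per_um2, 4 / 1024)
  # 3 cells nearest to a 1000 um^2 plaque -> 0.003 cells/um^2
  c2 <- data.frame(iba1_positive = rep(TRUE, 3),
                   plaque_associated = rep(TRUE, 3),
                   nearest_plaque_area_um2 = rep(1000, 3))
  expect_equal(plaque_associated_summary(c2, plq)$normalised_count_per_um2,
               0.003)
  # doubling all plaque areas halves the normalised count exactly
  c3 <- c2; c3$nearest_plaque_area_um2 <- 2 * c3$nearest_plaque_area_um2
  expect_equal(plaque_associated_summary(c3, plq)$normalised_count_per_um2,
               0.0015)
  # zero associated cells but plaques present -> 0
  c4 <- c2; c4$plaque_associated <- FALSE
  expect_equal(plaque_associated_summary(c4, plq)$normalised_count_per_um2, 0)
})

test_that("radial profile is exact for uniform images and Gaussian blobs", {
  px <- 0.25
  n <- 256
  s <- multichannel_section(list(a = matrix(3.5, n, n)), px)
  ctr <- c(n / 2 * px, n / 2 * px)
  p <- radial_profile(s, "a", ctr, r_max_um = 10, dr_um = 0.5)
  expect_true(all(abs(p$value - 3.5) < 1e-12))
  # isotropic Gaussian blob, scale 4 um: profile ~ analytic curve
  xs <- (seq_len(n) - 0.5) * px
  rr2 <- outer((xs - ctr[2])^2, (xs - ctr[1])^2, "+")
  g <- multichannel_section(list(a = 100 * exp(-rr2 / (2 * 16))), px)
  pg <- radial_profile(g, "a", ctr, r_max_um = 15, dr_um = 0.5)
  analytic <- 100 * exp(-pg$bin_mid_um^2 / (2 * 16))
  rmse <- sqrt(mean((pg$value - analytic)^2))
  expect_lt(rmse, 0.02 * 100)
  # centre outside image errors
  expect_error(radial_profile(s, "a", c(-1, 5)), "outside")
})

test_that("normalised profiles and histograms integrate to one", {
  set.seed(3)
  px <- 0.5
  s <- multichannel_section(list(a = matrix(runif(128 * 128) * 50, 128)), px)
  for (i in 1:10) {
    ctr <- runif(2, 10, 50)
    p <- radial_profile(s, "a", ctr, r_max_um = 12, dr_um = 0.5,
                        normalise = TRUE)
    expect_lt(abs(sum(p$value * 0.5) - 1), 1e-9)
  }
  h <- binned_histogram(rnorm(500, 50, 10), seq(0, 100, length.out = 21))
  expect_lt(abs(sum(h$value * 5) - 1), 1e-9)
})

test_that("pooling is median-within-animal then mean/SEM across animals", {
  img <- data.frame(animal_id = c("a1", "a1", "a1", "a2", "b1", "b1"),
                    group = c("g1", "g1", "g1", "g1", "g2", "g2"),
                    v = c(1, 2, 100, 7, 10, 20))
  res <- pool(img, "v")
  a <- res$animals
  expect_equal(a$v[a$animal_id == "a1"], 2)      # median beats the outlier
  expect_equal(a$v[a$animal_id == "a2"], 7)      # single image = itself
  g <- res$groups
  g1 <- g[g$group == "g1", ]
  expect_equal(g1$mean, mean(c(2, 7)))
  expect_equal(g1$sem, sd(c(2, 7)) / sqrt(2))
  expect_equal(g1$n_animals, 2L)
})

test_that("pooling is invariant to row order and matches a direct loop", {
  set.seed(13)
  img <- data.frame(animal_id = rep(paste0("a", 1:6), each = 8),
                    group = rep(c("g1", "g2"), each = 24),
                    v = rnorm(48), w = rlnorm(48))
  res1 <- pool(img, c("v", "w"))
  res2 <- pool(img[sample(nrow(img)), ], c("v", "w"))
  expect_identical(res1, res2)
  # independent recomputation
  for (an in unique(img$animal_id)) {
    expect_equal(res1$animals$v[res1$animals$animal_id == an],
                 median(img$v[img$animal_id == an]))
  }
  for (gr in c("g1", "g2")) {
    med <- sapply(unique(img$animal_id[img$group == gr]), function(an)
      median(img$w[img$animal_id == an]))
    row <- res1$groups[res1$groups$group == gr & res1$groups$metric == "w", ]
    expect_equal(row$mean, mean(med))
    expect_equal(row$sem, sd(med) / sqrt(length(med)))
  }
})

test_that("curve pooling works element-wise over bins", {
  img <- expand.grid(animal_id = c("a1", "a2"), group = "g1",
                     bin = c(1, 2, 3), img = 1:3)
  img$value <- ave(seq_len(nrow(img)), img$bin, FUN = seq_along) + img$bin * 10
  res <- pool(img[, c("animal_id", "group", "bin", "value")], "value")
  expect_equal(sort(unique(res$animals$bin)), c(1, 2, 3))
  expect_equal(nrow(res$groups), 3)
})
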