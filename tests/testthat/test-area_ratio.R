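test_that("contrast stretch maps a ramp to the display range", {
  ramp <- matrix(seq(0, 100, length.out = 10000), 100)
  out <- to_greyscale_contrast(ramp)
  # linear map of the 0.35/99.65 percentiles onto [0, 255], clipped
  q <- quantile(ramp, c(0.0035, 0.9965), names = FALSE)
  expected <- pmin(pmax((ramp - q[1]) / (q[2] - q[1]) * 255, 0), 255)
  expect_equal(out, expected)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # an image already spanning the full range is unchanged up to clipping
  full <- matrix(seq(0, 255, length.out = 4096), 64)
  out2 <- to_greyscale_contrast(full)
  expect_lt(max(abs(out2 - full)), 2.5)   # small stretch from the percentiles
  # constant image: unchanged with a warning
  expect_warning(out3 <- to_greyscale_contrast(matrix(9, 10, 10)),
                 "constant")
  expect_equal(out3, matrix(9, 10, 10))
})

test_that("fixed threshold is pooled mean + k * pooled SD", {
  expect_equal(fit_fixed_threshold(matrix(10, 5, 5), k = 2)$threshold, 10)
  set.seed(31)
  imgs <- list(matrix(rnorm(10000, 50, 10), 100),
               matrix(rnorm(10000, 50, 10), 100))
  thr <- fit_fixed_threshold(imgs, k = 2)
  expect_lt(abs(thr$threshold - 70), 1)      # 50 + 2*10 within sampling error
  thr0 <- fit_fixed_threshold(imgs, k = 0)
  expect_equal(thr0$threshold, mean(unlist(imgs)))
  expect_equal(thr0$pooled_mean, mean(unlist(imgs)))
})

test_that("stained fraction counts pixels strictly above threshold", {
  expect_equal(stained_fraction(matrix(0, 10, 10), 1), 0)
  expect_equal(stained_fraction(matrix(5, 10, 10), 4), 1)
  # painted fixture with an exact count above threshold
  set.seed(5)
  img <- matrix(10, 256, 256)
  hot <- sample(length(img), 1234)
  img[hot] <- 100
  expect_equal(stained_fraction(img, 50), 1234 / 65536)
  # monotone non-increasing in the threshold
  fr <- vapply(c(0, 5, 9, 10, 50, 99, 100), stained_fraction, numeric(1),
               grid = img)
  expect_true(all(diff(fr) <= 0))
})

test_that("BACE1/4G8 ratio follows the closed form and median pooling", {
  # fraction 0.02 / 0.08 -> ratio 0.25, built from counted pixel masks
  mk <- function(fb, fg, animal, sec) {
    n <- 100
    b <- matrix(0, n, n); b[seq_len(fb * n * n)] <- 100
    g <- matrix(0, n, n); g[seq_len(fg * n * n)] <- 100
    multichannel_section(list(BACE1 = b, "4G8" = g), 1, animal_id = animal,
                         group = "g", section_index = sec)
  }
  secs <- list(mk(0.02, 0.08, "a1", 1), mk(0.10, 0.10, "a1", 2),
               mk(0.30, 0.10, "a1", 3), mk(0.05, 0.00, "a2", 1),
               mk(0.04, 0.08, "a2", 2), mk(0.06, 0.08, "a2", 3))
  expect_warning(res <- bace1_4g8_ratio(secs, 50, 50), "zero 4G8")
  expect_equal(res$images$ratio[1], 0.25)
  expect_equal(res$images$ratio[2], 1)       # identical masks -> ratio 1
  a1 <- res$animals[res$animals$animal_id == "a1", ]
  expect_equal(a1$median_ratio, median(c(0.25, 1, 3)))
  a2 <- res$animals[res$animals$animal_id == "a2", ]
  expect_equal(a2$n_images, 2L)              # zero-4G8 image dropped
  # per-animal ratios {0.2, 0.3, 0.9} -> median 0.3
  expect_equal(median(c(0.2, 0.3, 0.9)), 0.3)
})

test_that("ratio is invariant under joint rescaling of channels+thresholds", {
  set.seed(41)
  n <- 64
  secs <- lapply(1:4, function(i)
    multichannel_section(list(BACE1 = matrix(rpois(n * n, 30), n),
                              "4G8" = matrix(rpois(n * n, 60), n)),
                         1, animal_id = "a1", group = "g",
                         section_index = i))
  r1 <- bace1_4g8_ratio(secs, 35, 65)
  secs2 <- lapply(secs, function(s) {
    s$channels$BACE1 <- s$channels$BACE1 * 3
    s$channels[["4G8"]] <- s$channels[["4G8"]] * 3
    s
  })
  r2 <- bace1_4g8_ratio(secs2, 35 * 3, 65 * 3)
  expect_equal(r1$images$ratio, r2$images$ratio)
})

test_that("QC excludes planted outliers but not the boundary or the null", {
  set.seed(51)
  n_img <- 20
  base <- data.frame(image_id = paste0("i", 1:n_img),
                     animal_id = rep(c("a1", "a2"), each = 10),
                     group = "g1",
                     f = rnorm(n_img, 100, 5))
  # identical features -> nothing excluded
  same <- base; same$f <- 100
  expect_true(all(!qc_filter(same)$excluded))
  # planted +5 SD (of the others) shift within its animal
  out <- base
  others <- out$f[2:10]
  out$f[1] <- mean(others) + 5 * sd(others)
  qc <- qc_filter(out)
  expect_true(qc$excluded[1])
  expect_true(qc$basis[1] %in% c("animal", "animal+group", "group"))
  expect_true(all(!qc$excluded[2:10]))
  # exactly on the 2 SD boundary -> retained (inclusive band)
  b <- data.frame(image_id = paste0("i", 1:4), animal_id = "a1", group = "g1",
                  f = c(1, 2, 3, NA))
  b$f[4] <- mean(b$f[1:3]) + 2 * sd(b$f[1:3])
  expect_false(qc_filter(b)$excluded[4])
  # tiny comparison sets skip QC with a message
  tiny <- data.frame(image_id = c("i1", "i2"), animal_id = "a1",
                     group = c("g1", "g2"), f = c(0, 100))
  expect_message(qc_tiny <- qc_filter(tiny), "fewer than 3")
  expect_true(all(!qc_tiny$excluded))
})

test_that("QC false-exclusion rate on null images stays low", {
  set.seed(61)
  rates <- replicate(20, {
    feats <- data.frame(image_id = paste0("i", 1:60),
                        animal_id = rep(paste0("a", 1:3), each = 20),
                        group = "g1",
                        f = rnorm(60, 100, 5))
    mean(qc_filter(feats)$excluded)
  })
  expect_lte(mean(rates), 0.10)
})

test_that("pFTAA area fraction respects ROI and threshold", {
  px <- 1
  n <- 100
  img <- matrix(0, n, n)
  img[, 1:50] <- 100                      # left half bright
  s <- multichannel_section(list(pFTAA = img), px)
  roi_all <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  # half-covered ROI -> 50% (within one boundary column)
  expect_lt(abs(pftaa_area_fraction(s, roi_all, 50) - 50), 1.5)
  # ROI fully inside the bright half -> 100%
  roi_bright <- cbind(c(5, 40, 40, 5), c(5, 5, 60, 60))
  expect_equal(pftaa_area_fraction(s, roi_bright, 50), 100)
  # threshold above the maximum -> 0%
  expect_equal(pftaa_area_fraction(s, roi_all, 1000), 0)
  expect_error(pftaa_area_fraction(s, roi_all[1:2, ], 50), ">= 3")
})
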