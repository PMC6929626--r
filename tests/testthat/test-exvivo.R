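test_that("spot detection recovers planted discs and ignores blank images", {
  expect_equal(nrow(detect_islets(matrix(5, 50, 50))), 0)

  one <- planted_disc_image(n_discs = 1, size = 80, diam_range = c(10, 10),
                            seed = 2)
  rec <- detect_islets(one$image, min_diameter_um = 100, pixel_size_um = 50)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$equivalent_diameter_um / 50 - 10), 1)

  many <- planted_disc_image(n_discs = 20, noise_frac = 0.05, seed = 5)
  rec2 <- detect_islets(many$image, min_diameter_um = 100, pixel_size_um = 50)
  # match detections to ground truth by nearest centroid
  matched <- vapply(seq_len(nrow(many$truth)), function(i) {
    d <- sqrt((rec2$centroid_row - many$truth$row[i])^2 +
                (rec2$centroid_col - many$truth$col[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] < 5 &&
        abs(rec2$equivalent_diameter_um[j] / 50 - many$truth$diam_px[i]) <= 1)
      TRUE else FALSE
  }, logical(1))
  expect_gte(sum(matched), 19)
})

test_that("detection is invariant to intensity rescaling", {
  many <- planted_disc_image(n_discs = 10, noise_frac = 0.03, seed = 9)
  r1 <- detect_islets(many$image, pixel_size_um = 50)
  r2 <- detect_islets(many$image * 7.3, pixel_size_um = 50)
  expect_equal(r1$area_px, r2$area_px)
  expect_equal(r1$islet_to_exocrine_ratio, r2$islet_to_exocrine_ratio,
               tolerance = 1e-12)
})

test_that("islet-to-exocrine ratios behave as mean ratios", {
  img <- matrix(1, 10, 10); img[3:4, 3:4] <- 4
  imask <- matrix(FALSE, 10, 10); imask[3:4, 3:4] <- TRUE
  expect_equal(islet_to_exocrine_ratio(img, imask, !imask), 4)
  expect_equal(islet_to_exocrine_ratio(matrix(2, 5, 5),
                                       diag(5) == 1, diag(5) != 1), 1)
  expect_equal(islet_to_exocrine_ratio(img * 11, imask, !imask), 4,
               tolerance = 1e-12)
  expect_error(islet_to_exocrine_ratio(img, matrix(FALSE, 10, 10), !imask),
               "non-empty")
  expect_error(islet_to_exocrine_ratio(matrix(0, 5, 5), diag(5) == 1,
                                       diag(5) != 1), "zero exocrine")
})

test_that("signal-diameter regression matches least squares in both orientations", {
  d <- c(50, 100, 150, 200)
  rec <- data.frame(equivalent_diameter_um = d,
                    islet_to_exocrine_ratio = 0.5 + 0.1 * d,
                    mean_signal = 2 * d)
  fit <- regress_signal_vs_diameter(rec)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_signal_vs_diameter(rec[1:2, ]), "at least 3")
  expect_error(regress_signal_vs_diameter(
    data.frame(equivalent_diameter_um = c(80, 80, 80),
               islet_to_exocrine_ratio = c(1, 2, 3))), "singular")
  set.seed(4)
  rec$islet_to_exocrine_ratio <- 0.5 + 0.1 * d + rnorm(4, 0, 0.5)
  noisy <- regress_signal_vs_diameter(rec)
  y <- rec$islet_to_exocrine_ratio
  bx <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
  expect_equal(noisy$slope, bx, tolerance = 1e-12)
  swapped <- regress_signal_vs_diameter(rec, orientation = "diameter_on_signal")
  by <- sum((y - mean(y)) * (d - mean(d))) / sum((y - mean(y))^2)
  expect_equal(swapped$slope, by, tolerance = 1e-12)
})

test_that("8-bit normalization and additive merge hit the channel extremes", {
  m <- matrix(c(0, 10, 5, 2), 2)
  n8 <- normalize_8bit(m)
  expect_equal(n8[1, 1], 0L)
  expect_equal(n8[2, 1], 255L)
  expect_equal(n8[1, 2], 127L)          # floor(255 * 0.5)
  expect_true(all(n8 >= 0L & n8 <= 255L))
  expect_equal(normalize_8bit(matrix(3, 4, 4)), matrix(0L, 4, 4))
  # repeated normalization is idempotent
  expect_equal(normalize_8bit(n8), n8)

  ca <- matrix(c(1, 0, 0, 0), 2); zn <- matrix(c(1, 0, 0, 0), 2)
  mn <- matrix(c(0, 0, 0, 1), 2)
  rgb <- merge_elements(ca, zn, mn)
  expect_equal(rgb[1, 1, ], c(255L, 255L, 0L))  # Ca+Zn high, Mn low: yellow
  expect_equal(rgb[2, 2, ], c(0L, 0L, 255L))
  expect_true(all(rgb >= 0L & rgb <= 255L))
  all_max <- merge_elements(m, m, m)
  expect_equal(all_max[2, 1, ], c(255L, 255L, 255L))
  expect_equal(all_max[1, 1, ], c(0L, 0L, 0L))
  expect_error(merge_elements(ca, zn, matrix(0, 3, 3)), "grid mismatch")
})

test_that("phantom sections show the enrichment crossing of retained Mn", {
  spec <- small_spec(islet_count = 8, noise_sigma_section = 0.5)
  lab <- build_label_map(spec)
  scores <- sapply(c("1h", "24h"), function(tp) {
    sec <- simulate_section(lab, spec, tp)
    imask <- sec$labels_msi == 2L | sec$labels_msi == 3L
    emask <- sec$labels_msi == 1L
    vapply(c("44Ca", "64Zn", "55Mn", "13C"), function(iso)
      islet_enrichment(sec$elemental[[iso]], imask, emask), numeric(1))
  })
  expect_true(all(scores[c("44Ca", "64Zn"), ] > 1))
  expect_lt(scores["55Mn", "1h"], 1)
  expect_gt(scores["55Mn", "24h"], 1)
  expect_equal(unname(scores["13C", "1h"]), 1, tolerance = 0.05)
})

test_that("sections round-trip through TIFF with sidecar metadata", {
  set.seed(30)
  em <- elemental_map(matrix(runif(40 * 30, 0, 90), 40), "64Zn")
  f <- file.path(tempdir(), "zn.tif")
  write_section(em, f)
  back <- read_section(f)
  expect_s3_class(back, "elemental_map")
  expect_equal(back$isotope, "64Zn")
  expect_equal(back$pixel_size_um, 60)
  expect_equal(back$intensity, em$intensity, tolerance = 1e-6)
})
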