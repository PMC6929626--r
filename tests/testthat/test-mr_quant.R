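test_that("spoiled-GRE signal model matches direct evaluation and limits", {
  acq <- acquisition_params()
  expect_equal(spgr_signal(1.0, 0, acq, 13), 0)
  # fully relaxed limit: TR >> T1
  expect_equal(spgr_signal(1e-6, 2, acq, 30), 2 * sin(30 * pi / 180),
               tolerance = 1e-9)
  # step-by-step arithmetic at T1 = 1 s, TR = 10 ms, 22 degrees
  e1 <- exp(-0.010 / 1.0)
  a <- 22 * pi / 180
  expect_equal(spgr_signal(1.0, 1, acq, 22),
               1 * sin(a) * (1 - e1) / (1 - e1 * cos(a)), tolerance = 1e-15)
  expect_error(spgr_signal(-0.5, 1, acq, 22), "positive")
})

test_that("two-angle fit inverts the forward model exactly", {
  acq <- default_acq2
  t1_true <- array(seq(0.1, 3, length.out = 27), dim = c(3, 3, 3))
  stacks <- lapply(acq$flip_deg, function(fa)
    spgr_signal(t1_true, 50, acq, fa))
  fit <- fit_t1_vfa(stacks, acq)
  expect_true(all(fit$validity))
  expect_lt(max(abs(fit$t1_s - t1_true) / t1_true), 1e-9)
  expect_equal(unique(round(as.numeric(fit$m0), 6)), 50)
})

test_that("degenerate voxels are flagged invalid, bad inputs error", {
  acq <- default_acq2
  s <- array(0, dim = c(2, 2, 2))
  fit <- fit_t1_vfa(list(s, s), acq)
  expect_false(any(fit$validity))
  expect_true(all(is.na(fit$t1_s)))
  expect_error(fit_t1_vfa(list(s, array(0, dim = c(3, 2, 2))), acq),
               "mismatched grids")
  expect_error(acquisition_params(flip_deg = 4), "at least 2")
  expect_error(fit_t1_vfa(list(s), acq), "match the number of flip angles")
})

test_that("three-angle fit agrees with an exhaustive grid search on noisy voxels", {
  acq <- default_acq3
  set.seed(101)
  n <- 300
  t1_true <- runif(n, 0.3, 2.5)
  S <- sapply(acq$flip_deg, function(fa) spgr_signal(t1_true, 100, acq, fa))
  sigma <- 0.01 * max(S)
  S <- S + matrix(rnorm(length(S), 0, sigma), n)
  fit <- fit_t1_vfa(lapply(seq_len(3), function(k) array(S[, k], c(n, 1, 1))),
                    acq)
  oracle <- oracle_t1_grid(S, acq$flip_deg, acq$tr_ms)
  agree <- abs(fit$t1_s[, 1, 1] - oracle) <= 0.001 + 1e-12
  expect_gte(mean(agree[fit$validity[, 1, 1]]), 0.99)
})

test_that("noise-free fitted T1 is strictly increasing in the generating T1", {
  for (acq in list(default_acq2, default_acq3)) {
    t1_true <- seq(0.1, 3, length.out = 60)
    stacks <- lapply(acq$flip_deg, function(fa)
      array(spgr_signal(t1_true, 80, acq, fa), c(60, 1, 1)))
    fit <- fit_t1_vfa(stacks, acq)
    expect_true(all(diff(fit$t1_s[, 1, 1]) > 0))
  }
})

test_that("R1 conversion applies the closed physiological filter", {
  t1 <- array(c(0.5, 5.0, 0.1, 1.0, 2.0, 0.09, 0.25, 1.25), c(2, 2, 2))
  fit <- structure(list(t1_s = t1, m0 = array(10, c(2, 2, 2)),
                        validity = array(TRUE, c(2, 2, 2)),
                        fit_residual = array(0, c(2, 2, 2)),
                        acq = default_acq2, voxel_size_mm = c(1, 1, 1),
                        n_invalid = 0L), class = "t1_map")
  r1 <- suppressMessages(t1_to_r1(fit))
  expect_equal(r1$r1_s_inv[1, 1, 1], 2.0, tolerance = 1e-9)
  expect_false(r1$validity[2, 1, 1])   # R1 = 0.2 below the window
  expect_true(r1$validity[1, 2, 1])    # R1 = 10.0 sits on the closed bound
  expect_false(r1$validity[2, 1, 2])   # R1 > 10 excluded
  expect_equal(r1$n_filtered, 2)
  expect_true(all(is.na(r1$r1_s_inv[!r1$validity])))
  v <- r1$r1_s_inv[r1$validity]
  expect_true(all(v >= 0.4 & v <= 10))
})

test_that("relaxivity calibration recovers exact and noisy linear series", {
  conc <- c(0, 0.1, 0.2)
  rel <- calibrate_relaxivity(conc, 0.4 + 5 * conc)
  expect_equal(rel$r1_per_mM, 5, tolerance = 1e-10)
  expect_equal(rel$intercept, 0.4, tolerance = 1e-10)
  expect_equal(rel$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(rel, 0.3), 0.4 + 5 * 0.3)

  expect_error(calibrate_relaxivity(c(0, 0.1), c(0.4, 0.9)), "at least 3")
  expect_error(calibrate_relaxivity(rep(0.2, 4), c(1, 2, 1, 2)), "distinct")

  set.seed(7)
  x <- seq(0, 0.5, by = 0.05)
  y <- 0.35 + 6.2 * x + rnorm(length(x), 0, 0.05)
  rel2 <- calibrate_relaxivity(data.frame(mn_mM = x, r1_s_inv = y))
  # normal-equations oracle
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(rel2$r1_per_mM, bx, tolerance = 1e-12)
  expect_equal(rel2$intercept, mean(y) - bx * mean(x), tolerance = 1e-12)
})

test_that("the bundled synthetic dilution series calibrates like any CSV", {
  f <- system.file("extdata", "synthetic_relaxivity_series.csv",
                   package = "memripet")
  ser <- utils::read.csv(f)
  rel <- calibrate_relaxivity(ser)
  bx <- with(ser, sum((mn_mM - mean(mn_mM)) * (r1_s_inv - mean(r1_s_inv))) /
               sum((mn_mM - mean(mn_mM))^2))
  expect_equal(rel$r1_per_mM, bx, tolerance = 1e-12)
  expect_gt(rel$r_squared, 0.99)
})

test_that("Mn estimation follows the delta-R1 relation and preserves sign", {
  mk_r1 <- function(vals, valid = TRUE) {
    a <- array(vals, c(2, 2, 1))
    structure(list(r1_s_inv = a,
                   validity = array(valid, c(2, 2, 1)),
                   r1_range = c(0.4, 10), n_filtered = 0,
                   voxel_size_mm = c(1, 1, 1)), class = "r1_map")
  }
  mn <- estimate_mn(mk_r1(0.5), mk_r1(2.0), 5.0)
  expect_equal(unique(as.numeric(mn$mn_mM)), 0.3, tolerance = 1e-12)
  mn0 <- estimate_mn(mk_r1(1.3), mk_r1(1.3), 5.0)
  expect_true(all(mn0$mn_mM == 0))
  expect_warning(mn_neg <- estimate_mn(mk_r1(2.0), mk_r1(1.0), 5.0),
                 "negative")
  expect_equal(unique(as.numeric(mn_neg$mn_mM)), -0.2, tolerance = 1e-12)
  expect_error(estimate_mn(mk_r1(1), mk_r1(2), -1), "positive")
  expect_error(estimate_mn(mk_r1(1, valid = FALSE), mk_r1(2, valid = FALSE),
                           5), "jointly valid")
  # region-mean mode tolerates differing VOIs
  pre <- mk_r1(c(1, 1, 2, 2)); post <- mk_r1(c(3, 3, 3, 3))
  idx <- estimate_mn(pre, post, 5, mode = "region_mean_24h",
                     voi_pre = array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)),
                     voi_post = array(TRUE, c(2, 2, 1)))
  expect_equal(as.numeric(idx), (3 - 1) / 5, tolerance = 1e-12)
})

test_that("noise-free phantom recovers ground-truth [Mn] end to end", {
  spec <- small_spec(islet_count = 6)
  lab <- build_label_map(spec)
  acq <- default_acq2
  r1_pre <- t1_to_r1(fit_t1_vfa(simulate_vfa_stacks(lab, spec, "pre", acq), acq))
  r1_1h <- t1_to_r1(fit_t1_vfa(simulate_vfa_stacks(lab, spec, "1h", acq), acq))
  mn <- estimate_mn(r1_pre, r1_1h, spec$relaxivity_r1)
  for (comp in 1:3) {
    vox <- lab$labels == comp & mn$validity
    expect_lt(max(abs(mn$mn_mM[vox] - spec$mn_mM[comp + 1, "1h"])), 1e-6)
  }
})
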