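test_that("label maps use only defined labels and respect the islet count", {
  spec0 <- small_spec(islet_count = 0)
  spec0$insulinoma <- NULL
  lab0 <- build_label_map(spec0)
  expect_setequal(unique(as.integer(lab0$labels)), c(0L, 1L))

  spec <- small_spec(islet_count = 12)
  spec$insulinoma <- NULL
  lab <- build_label_map(spec)
  expect_true(all(lab$labels %in% 0:2))
  expect_identical(count_components_3d(lab$labels == 2L), 12L)
})

test_that("label map generation is deterministic and placement failure is named", {
  spec <- small_spec(islet_count = 8)
  expect_identical(build_label_map(spec)$labels, build_label_map(spec)$labels)

  crowded <- small_spec(grid_shape = c(12, 12, 12), islet_count = 400)
  crowded$pancreas_semiaxes_mm <- c(1.2, 1.2, 1.2)
  expect_error(build_label_map(crowded), "islet placement error.*islet \\d+")
})

test_that("noise-free VFA stacks equal the forward model with Mn-shortened T1", {
  spec <- small_spec(islet_count = 0,
                     t1_pre_s = c(background = 1, exocrine = 1,
                                  islet = 1, insulinoma = 1),
                     relaxivity_r1 = 5.0)
  spec$mn_mM["exocrine", "1h"] <- 0.2
  lab <- build_label_map(spec)
  stacks <- simulate_vfa_stacks(lab, spec, "1h", default_acq2)
  exo <- lab$labels == 1L
  # 1/(1/1 + 5*0.2) = 0.5 s in the exocrine compartment
  for (k in seq_along(default_acq2$flip_deg)) {
    want <- spgr_signal(0.5, spec$m0, default_acq2, default_acq2$flip_deg[k])
    expect_equal(unique(stacks[[k]]$data[exo]), want, tolerance = 1e-12)
  }
  expect_error(simulate_vfa_stacks(lab, spec, "1h",
                                   list(tr_ms = 10, te_ms = 1.9,
                                        flip_deg = c(4, 95))),
               "flip angles")
})

test_that("PET volumes decay with the 12.7 h half-life and keep uptake ratios", {
  spec <- small_spec(islet_count = 6)
  spec$tracer_uptake["islet", "1h"] <- 3 * spec$tracer_uptake["exocrine", "1h"]
  lab <- build_label_map(spec)
  pet1 <- simulate_pet_volume(lab, spec, "1h")
  expect_equal(mean(pet1$data[lab$labels == 2L]) /
                 mean(pet1$data[lab$labels == 1L]), 3, tolerance = 1e-12)
  # decay referenced to acquisition time: 24 h lags 1 h by 23/12.7 half-lives
  spec24 <- spec
  spec24$tracer_uptake[, "24h"] <- spec$tracer_uptake[, "1h"]
  pet24 <- simulate_pet_volume(lab, spec24, "24h")
  expect_equal(mean(pet24$data[lab$labels == 1L]) /
                 mean(pet1$data[lab$labels == 1L]),
               2^(-(24 - 1) / 12.7), tolerance = 1e-12)
  expect_error(phantom_spec(injected_dose_kBq = 0))
})

test_that("sections reproduce the early exocrine / late islet Mn pattern", {
  spec <- small_spec(islet_count = 8)
  lab <- build_label_map(spec)
  for (tp in c("1h", "24h")) {
    sec <- simulate_section(lab, spec, tp)
    mn <- sec$elemental[["55Mn"]]$intensity
    exo <- mean(mn[sec$labels_msi == 1L])
    isl <- mean(mn[sec$labels_msi == 2L])
    if (tp == "1h") expect_gt(exo, isl) else expect_gt(isl, exo)
    expect_equal(sec$autorad$pixel_size_um, 50)
    expect_equal(sec$elemental[["55Mn"]]$pixel_size_um, 60)
  }
  # degenerate homogeneity: uniform abundances, no Mn contrast, no noise
  flat <- spec
  flat$elemental_abundance[] <- 7
  flat$mn_mM[] <- 0
  sec <- simulate_section(lab, flat, "1h")
  for (iso in c("44Ca", "64Zn", "13C"))
    expect_equal(length(unique(as.numeric(sec$elemental[[iso]]$intensity))), 1L)
  expect_error(simulate_section(matrix(0L, 5, 5), spec, "1h"), "empty slice")
})

test_that("all simulators are bit-identical for a fixed spec and seed", {
  spec <- small_spec(islet_count = 5, noise_sigma_mr = 0.05,
                     noise_sigma_pet = 5, noise_sigma_section = 2)
  lab <- build_label_map(spec)
  a <- simulate_vfa_stacks(lab, spec, "1h", default_acq2)
  b <- simulate_vfa_stacks(lab, spec, "1h", default_acq2)
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
  expect_identical(simulate_pet_volume(lab, spec, "24h")$data,
                   simulate_pet_volume(lab, spec, "24h")$data)
  s1 <- simulate_section(lab, spec, "1h")
  s2 <- simulate_section(lab, spec, "1h")
  expect_identical(s1$autorad$intensity, s2$autorad$intensity)
  expect_identical(simulate_secretion(seed = 9), simulate_secretion(seed = 9))
})

test_that("noise-free simulate/fit round trip recovers per-compartment T1", {
  for (t1 in c(0.1, 0.5, 1.0, 2.0, 3.0)) {
    spec <- small_spec(grid_shape = c(16, 16, 16), islet_count = 0,
                       t1_pre_s = c(background = t1, exocrine = t1,
                                    islet = t1, insulinoma = t1))
    spec$insulinoma <- NULL
    spec$mn_mM[] <- 0
    lab <- build_label_map(spec)
    for (acq in list(default_acq2, default_acq3)) {
      fit <- fit_t1_vfa(simulate_vfa_stacks(lab, spec, "pre", acq), acq)
      expect_lt(max(abs(fit$t1_s[fit$validity] - t1)) / t1, 1e-6)
    }
  }
})
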