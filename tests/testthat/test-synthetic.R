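# Strain-model sampling, kinetics law, rendering, wine scenarios.

test_that("model sampling is deterministic per seed and leaves global RNG alone", {
  m1 <- sample_strain_models(5, seed = 77)
  m2 <- sample_strain_models(5, seed = 77)
  expect_identical(m1, m2)
  set.seed(123); before <- runif(1)
  sample_strain_models(5, seed = 99)
  set.seed(123); expect_identical(runif(1), before)
})

test_that("archetype counts respect the default mixture proportions", {
  m <- sample_strain_models(175, seed = 5)
  counts <- table(factor(m$archetype, levels = c("low_tolerance",
                                                 "intermediate", "resistant")))
  probs <- c(0.15, 0.60, 0.25)
  # multinomial 95% bounds per class
  half <- 1.96 * sqrt(probs * (1 - probs) * 175)
  expect_true(all(abs(as.numeric(counts) - 175 * probs) <= half))
})

test_that("degenerate proportions force the corresponding archetype", {
  m <- sample_strain_models(20, seed = 6, proportions = c(1, 0, 0))
  expect_true(all(m$archetype == "low_tolerance"))
  expect_true(all(is.finite(m$max_inhibitory_dose)))
  m2 <- sample_strain_models(20, seed = 6, proportions = c(0, 0, 1))
  expect_true(all(is.infinite(m2$max_inhibitory_dose)))
})

test_that("model invariants hold across a large draw", {
  m <- sample_strain_models(200, seed = 8)
  expect_true(all(m$base_lag > 0))
  expect_true(all(m$amax_base > 500))
  expect_true(all(m$amax_dose_slope >= 0 & m$amax_dose_slope <= 1))
})

test_that("kinetics law: inhibition zeroes the curve, plateau reaches Amax", {
  m <- sample_strain_models(1, seed = 10, proportions = c(1, 0, 0))
  expect_true(all(drop_area_curve(m, m$max_inhibitory_dose, "low",
                                  c(0, 5, 20)) == 0))
  expect_equal(drop_area_curve(m, 0, "low", 1e4), m$amax_base, tolerance = 1e-6)
  # base_lag anchors the dose-0 low-density crossing of 250 px
  expect_equal(crossing_time(m, 0, "low", 250), m$base_lag, tolerance = 1e-9)
})

test_that("a 7.2-day engineered crossing lands at grid day 8", {
  m <- sample_strain_models(1, seed = 12, proportions = c(0, 1, 0))
  m$base_lag <- 7.2
  expect_equal(crossing_time(m, 0, "low", 250), 7.2, tolerance = 1e-9)
  tt <- seq(0, 20, by = 0.01)
  a <- drop_area_curve(m, 0, "low", tt)
  expect_equal(tt[which(a > 250)[1]], 7.2, tolerance = 0.011)
  days <- c(3, 6, 8, 10, 14, 17, 20)
  cur <- make_curve(days, ceiling(drop_area_curve(m, 0, "low", days)), "low")
  expect_equal(extract_lag(cur)$lag_days, 8)
})

test_that("lag is monotone in dose for every archetype (below inhibition)", {
  m <- sample_strain_models(30, seed = 13)
  for (i in seq_len(nrow(m))) {
    doses <- STANDARD_DOSES[STANDARD_DOSES < m$max_inhibitory_dose[i]]
    tc <- vapply(doses, function(d) crossing_time(m[i, ], d, "low", 250),
                 numeric(1))
    expect_true(all(diff(tc) >= 0))
  }
})

test_that("density shortens the lag as specified", {
  m <- sample_strain_models(5, seed = 14)
  for (i in seq_len(nrow(m))) {
    t_low <- crossing_time(m[i, ], 0.05, "low", 500)
    t_high <- crossing_time(m[i, ], 0.05, "high", 500)
    # two decades of density at density_effect days per decade
    expect_equal(t_low - t_high, 2 * m$density_effect[i], tolerance = 1e-9)
  }
})

test_that("rendered output is bitwise deterministic for a fixed seed", {
  grid <- data.frame(strain = c("S001", "S002"), dose = 0,
                     density_class = "low", stringsAsFactors = FALSE)
  lay <- synthetic_layouts(grid, frame_px = 600)
  des <- experiment_design(lay, imaging_days = c(3, 10, 20))
  mods <- sample_strain_models(2, seed = 15)
  r1 <- render_series(des, mods, seed = 20, noise_sd = 0.05)
  r2 <- render_series(des, mods, seed = 20, noise_sd = 0.05)
  expect_identical(r1$series[[1]]$images, r2$series[[1]]$images)
  expect_identical(r1$truth, r2$truth)
})

test_that("fully inhibited drops leave fiducial-only frames", {
  mods <- sample_strain_models(1, seed = 16, proportions = c(1, 0, 0))
  grid <- data.frame(strain = mods$strain, dose = 0.5, density_class = "low",
                     stringsAsFactors = FALSE)
  lay <- synthetic_layouts(grid, frame_px = 600)
  des <- experiment_design(lay, imaging_days = c(3, 20))
  r <- render_series(des, mods, seed = 21, noise_sd = 0, jitter = FALSE,
                     gradient_amplitude = 0)
  img <- r$series[[1]]$images[[2]]
  # nothing bright except the four fiducial disks
  bright <- which(img > 0.5)
  fid <- unlist(lapply(1:4, function(i) {
    spotlag:::roi_pixel_indices(dim(img), lay[[1]]$corners[i, 1],
                                lay[[1]]$corners[i, 2], 10)
  }))
  expect_true(all(bright %in% fid))
  expect_true(all(r$truth$true_amax == 0))
  expect_true(all(is.infinite(r$truth$true_lag)))
})

test_that("areas above ROI capacity are clipped with a warning", {
  mods <- sample_strain_models(1, seed = 17, proportions = c(0, 0, 1))
  mods$amax_base <- 9000  # exceeds the ~5000 px ROI capacity
  mods$base_lag <- 2
  grid <- data.frame(strain = mods$strain, dose = 0, density_class = "low",
                     stringsAsFactors = FALSE)
  lay <- synthetic_layouts(grid, frame_px = 600)
  des <- experiment_design(lay, imaging_days = c(3, 20))
  expect_warning(r <- render_series(des, mods, seed = 22, noise_sd = 0,
                                    jitter = FALSE), "capacity")
  cap <- length(spotlag:::roi_pixel_indices(c(600, 600), lay[[1]]$drops$cx,
                                            lay[[1]]$drops$cy, 40))
  expect_equal(r$truth$true_amax, cap)
})

test_that("wine stress scenarios shift lags by the documented ranges", {
  base <- sample_strain_models(100, seed = 23)
  expect_identical(make_wine_stress_scenario(base, "original")$lag_offset_top,
                   rep(0, 100))
  eth <- make_wine_stress_scenario(base, "ethanol14.5", seed = 24)
  expect_true(all(eth$lag_offset_top >= 3 & eth$lag_offset_top <= 5))
  expect_gte(mean(eth$lag_offset_top), 3)
  expect_lte(mean(eth$lag_offset_top), 5)
  so2 <- make_wine_stress_scenario(base, "SO2", seed = 24)
  expect_true(all(so2$lag_offset_top >= 2 & so2$lag_offset_top <= 3))
  expect_error(make_wine_stress_scenario(base, "brine"), "unknown modality")
})

test_that("modality mean lags preserve the stress hierarchy at any dose", {
  base <- sample_strain_models(100, seed = 25)
  mean_lag <- function(modality, dose) {
    mods <- make_wine_stress_scenario(base, modality, seed = 26)
    mean(vapply(seq_len(nrow(mods)), function(i) {
      tc <- crossing_time(mods[i, ], dose, "low", 250)
      if (is.finite(tc)) tc else 21
    }, numeric(1)))
  }
  for (dose in c(0.05, 0.1, 0.5)) {
    m_eth <- mean_lag("ethanol14.5", dose)
    m_so2 <- mean_lag("SO2", dose)
    m_ph <- mean_lag("pH3.0", dose)
    m_orig <- mean_lag("original", dose)
    expect_gte(m_eth, m_so2)
    expect_gte(m_so2, m_ph)
    expect_gte(m_ph, m_orig)
  }
})

test_that("noise-free pipeline lag equals the truth crossing for every drop", {
  sim <- small_clean_sim()
  kin <- small_clean_kinetics()
  ph <- phenotype_table(kin, sim$design)
  m <- merge(ph, sim$truth[, c("drop_id", "true_lag")], by = "drop_id")
  expected <- grid_lag_from_truth(m$true_lag, sim$design$imaging_days)
  noncens <- !is.na(expected)
  expect_true(all(m$lag_days[noncens] == expected[noncens]))
  expect_true(all(m$censored[!noncens]))
})

test_that("Amax is recovered within 10% under default noise and jitter", {
  sim <- small_noisy_sim()
  kin <- quantify_experiment(sim$series, sim$design, register = TRUE)
  ph <- phenotype_table(kin, sim$design)
  m <- merge(ph, sim$truth[, c("drop_id", "true_lag", "true_amax")],
             by = "drop_id")
  nc <- is.finite(m$true_lag) &
    !is.na(grid_lag_from_truth(m$true_lag, sim$design$imaging_days))
  rel <- abs(m$amax_px[nc] - m$true_amax[nc]) / pmax(m$true_amax[nc], 1)
  expect_gte(mean(rel < 0.10), 0.95)
})

test_that("series I/O round-trips frames through PNG within 8-bit quantization", {
  sim <- small_clean_sim()
  pid <- names(sim$series)[1]
  dir <- withr::local_tempdir()
  manifest <- write_series(sim$series[[pid]], dir)
  back <- load_series(manifest)
  expect_equal(names(back), pid)
  expect_equal(back[[pid]]$days, sim$series[[pid]]$days)
  orig <- sim$series[[pid]]$images[[1]]
  expect_lt(max(abs(back[[pid]]$images[[1]] - orig)), 1 / 255)
})
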