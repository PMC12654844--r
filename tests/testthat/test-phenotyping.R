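# Lag, Amax, normalization, tolerance profiles, lag-class distributions.

test_that("lag is the first day strictly above the density-resolved threshold", {
  # high density crosses 500 px at day 8
  cur <- make_curve(c(3, 6, 8, 10), c(0, 210, 640, 900), "high")
  expect_equal(extract_lag(cur)$lag_days, 8)
  # never above threshold: censored at the horizon
  flat <- make_curve(c(3, 6, 8, 10, 14, 17, 20), rep(100, 7), "high")
  lag <- extract_lag(flat)
  expect_true(lag$censored)
  expect_equal(lag$label, ">20")
  # the inequality is strict: exactly 500 does not count
  edge <- make_curve(c(3, 6, 8), c(0, 500, 700), "high")
  expect_equal(extract_lag(edge)$lag_days, 8)
  # lowest density uses the 250 px threshold
  low <- make_curve(c(3, 6, 8), c(0, 300, 700), "low")
  expect_equal(extract_lag(low)$lag_days, 6)
  expect_equal(extract_lag(make_curve(c(3, 6, 8), c(0, 300, 700), "high"))$lag_days, 8)
})

test_that("discrete lag equals the dense-grid crossing oracle on model curves", {
  models <- sample_strain_models(10, seed = 3)
  days <- c(3, 6, 8, 10, 14, 17, 20)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    for (dose in c(0, 0.05, 0.5)) {
      thr <- 250
      # oracle: dense evaluation at 0.01 d resolution
      tt <- seq(0, 20, by = 0.01)
      a <- drop_area_curve(m, dose, "low", tt)
      dense_cross <- if (any(a > thr)) tt[which(a > thr)[1]] else Inf
      closed <- crossing_time(m, dose, "low", thr)
      if (is.finite(closed)) expect_lt(abs(dense_cross - closed), 0.011)
      cur <- make_curve(days, ceiling(drop_area_curve(m, dose, "low", days)),
                        "low")
      lag <- extract_lag(cur)
      expected_day <- days[days > closed]
      if (length(expected_day)) {
        expect_equal(lag$lag_days, expected_day[1])
      } else {
        expect_true(lag$censored)
      }
    }
  }
})

test_that("Amax is the curve maximum", {
  expect_equal(extract_amax(make_curve(c(3, 6, 8), c(0, 120, 800))), 800)
  expect_equal(extract_amax(make_curve(c(3, 6, 8), c(0, 0, 0))), 0)
  # non-monotone artifact: maximum, not final value
  expect_equal(extract_amax(make_curve(c(3, 6, 8), c(0, 900, 850))), 900)
  # a curve that plateaus early reaches its model plateau within 5%
  m <- sample_strain_models(1, seed = 9)
  m$base_lag <- 3; m$growth_rate <- 1.5
  days <- c(3, 6, 8, 10, 14, 17, 20)
  cur <- make_curve(days, round(drop_area_curve(m, 0, "low", days)))
  expect_lt(abs(extract_amax(cur) - m$amax_base) / m$amax_base, 0.05)
})

test_that("normalization subtracts the matched control, propagating censoring", {
  ctrl <- make_record(dose = 0, lag = 3)
  rec <- make_record(dose = 0.05, lag = 8)
  expect_equal(normalize_lag(rec, ctrl)$value, 5)
  expect_equal(normalize_lag(ctrl, ctrl)$value, 0)
  cens <- make_record(dose = 0.5, censored = TRUE, horizon = 20)
  out <- normalize_lag(cens, make_record(dose = 0, lag = 4))
  expect_true(out$censored)
  expect_equal(out$value, 16)
  expect_equal(out$label, ">16")
  # censored control: undefined, with a warning
  ctrl_cens <- make_record(dose = 0, censored = TRUE)
  expect_warning(und <- normalize_lag(rec, ctrl_cens), "undefined")
  expect_false(und$defined)
  # pairing violations
  expect_error(normalize_lag(rec, make_record(strain = "S2", dose = 0)),
               "strain")
  expect_error(normalize_lag(rec, make_record(dose = 0.05)), "dose 0")
  expect_error(normalize_lag(make_record(dose = 0.1, residence_time = 7),
                             make_record(dose = 0, residence_time = 14)),
               "residence")
})

test_that("table-level normalization uses the YPD and wine pairing keys", {
  recs <- rbind(make_record("S1", 0, lag = 3), make_record("S1", 0.05, lag = 8),
                make_record("S2", 0, lag = 4), make_record("S2", 0.05, lag = 5))
  out <- normalize_lags(recs, mode = "ypd")
  expect_equal(out$normalized_lag_days[out$strain == "S1" & out$dose == 0.05], 5)
  expect_equal(out$normalized_lag_days[out$strain == "S2" & out$dose == 0.05], 1)
  expect_equal(out$normalized_lag_days[out$dose == 0], c(0, 0))
  # wine mode: control is the original-wine record at the same residence time
  wine <- rbind(
    make_record("S1", 0, lag = 5, modality = "original", residence_time = 7),
    make_record("S1", 0, lag = 7, modality = "original", residence_time = 14),
    make_record("S1", 0.5, lag = 14, modality = "ethanol14.5", residence_time = 7))
  wout <- normalize_lags(wine, mode = "wine")
  expect_equal(wout$normalized_lag_days[wout$modality == "ethanol14.5"], 9)
  # unmatched record flagged via message
  lone <- rbind(make_record("S3", 0.5, lag = 10))
  expect_message(normalize_lags(lone, mode = "ypd"), "lack a matched")
})

test_that("normalize_lag of any record with itself is zero", {
  set.seed(11)
  for (i in 1:10) {
    r <- make_record(lag = sample(c(3, 6, 8, 10, 14), 1), dose = 0)
    expect_equal(normalize_lag(r, r)$value, 0)
  }
})

test_that("profile classification reproduces the three archetypes", {
  doses <- c(0, 0.05, 0.1, 0.25, 0.5)
  # censored at the two highest doses: low tolerance
  low <- do.call(rbind, lapply(doses, function(d) {
    make_record("A", d, lag = if (d <= 0.1) 3 + 20 * d else NA,
                censored = d > 0.1, amax = 2000)
  }))
  expect_equal(classify_profile(low), "low_tolerance")
  # growth everywhere but 8 extra days and shrunken Amax at the top dose
  mid <- do.call(rbind, lapply(doses, function(d) {
    make_record("B", d, lag = 3 + 16 * d, amax = 2000 * (1 - 0.8 * d))
  }))
  expect_equal(classify_profile(mid), "intermediate")
  # small delay, Amax retained
  res <- do.call(rbind, lapply(doses, function(d) {
    make_record("C", d, lag = 3 + 2 * d, amax = 2000 * (1 - 0.1 * d))
  }))
  expect_equal(classify_profile(res), "resistant")
  # classification is invariant to record order
  expect_equal(classify_profile(mid[sample(nrow(mid)), ]), "intermediate")
  # missing dose-0 curve
  expect_error(classify_profile(mid[mid$dose > 0, ]), "dose")
  # every strain gets exactly one class
  tab <- classify_profiles(rbind(low, mid, res))
  expect_equal(sort(tab$profile),
               c("intermediate", "low_tolerance", "resistant"))
})

test_that("replicate summaries take medians and flag discordant lags", {
  recs <- rbind(make_record("S1", 0.05, lag = 6, replicate = 1L),
                make_record("S1", 0.05, lag = 8, replicate = 2L),
                make_record("S1", 0.05, lag = 20, replicate = 3L))
  out <- summarize_replicates(recs, imaging_days = c(3, 6, 8, 10, 14, 17, 20))
  expect_equal(out$lag_days, 8)
  expect_true(out$lag_flagged)
  agree <- rbind(make_record("S1", 0.05, lag = 6, replicate = 1L),
                 make_record("S1", 0.05, lag = 8, replicate = 2L))
  expect_false(summarize_replicates(agree, c(3, 6, 8, 10, 14, 17, 20))$lag_flagged)
})

test_that("lag-class distributions count censored records separately and sum to 1", {
  recs <- do.call(rbind, lapply(1:10, function(i) {
    make_record("S1", 0.05, lag = 3, replicate = 1L)
  }))
  recs$drop_id <- paste0("d", 1:10)
  dist <- summarize_lag_distribution(recs, bin_edges = c(0, 4, 7, 21))
  expect_equal(sum(dist$count), 10)
  expect_equal(dist$count[dist$lag_class == "[0,4)"], 10)
  expect_equal(sum(dist$fraction), 1)
  mixed <- rbind(recs,
                 do.call(rbind, lapply(1:4, function(i) {
                   r <- make_record("S1", 0.05, censored = TRUE)
                   r$drop_id <- paste0("c", i); r
                 })))
  dist2 <- summarize_lag_distribution(mixed, bin_edges = c(0, 4, 7, 21))
  expect_equal(dist2$count[dist2$lag_class == "censored"], 4)
  for (g in split(dist2, paste(dist2$genetic_group, dist2$dose))) {
    expect_equal(sum(g$fraction), 1)
  }
})

test_that("observed lag-class fractions track a known sampling distribution", {
  set.seed(21)
  probs <- c(0.5, 0.3, 0.2)
  lag_values <- c(3, 6, 10)
  n <- 400
  draw <- sample(lag_values, n, replace = TRUE, prob = probs)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- make_record("S1", 0.05, lag = draw[i]); r$drop_id <- paste0("d", i); r
  }))
  dist <- summarize_lag_distribution(recs, bin_edges = c(0, 4, 7, 21))
  obs <- dist$fraction[match(c("[0,4)", "[4,7)", "[7,21)"), dist$lag_class)]
  half_width <- 1.96 * sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(obs - probs) <= half_width + 1e-9))
})
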