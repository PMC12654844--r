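# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

# 4 strains x 3 doses x 2 densities on 600 px plates, clean rendering
small_clean_sim <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- simulate_experiment(
      n_strains = 4, doses = c(0, 0.05, 0.5),
      density_classes = c("low", "high"), seed = 42,
      noise_sd = 0, jitter = FALSE, frame_px = 600)
  }
  .fixture_env$clean
}

# same design with default noise and per-frame jitter
small_noisy_sim <- function() {
  if (is.null(.fixture_env$noisy)) {
    .fixture_env$noisy <- simulate_experiment(
      n_strains = 4, doses = c(0, 0.05, 0.5),
      density_classes = c("low", "high"), seed = 42,
      noise_sd = 0.05, jitter = TRUE, frame_px = 600)
  }
  .fixture_env$noisy
}

small_clean_kinetics <- function() {
  if (is.null(.fixture_env$clean_kin)) {
    sim <- small_clean_sim()
    .fixture_env$clean_kin <-
      quantify_experiment(sim$series, sim$design, register = FALSE)
  }
  .fixture_env$clean_kin
}

# first imaging day strictly after the continuous crossing, NA if beyond grid
grid_lag_from_truth <- function(true_lag, imaging_days) {
  vapply(true_lag, function(t) {
    d <- imaging_days[imaging_days > t]
    if (length(d)) d[1] else NA_real_
  }, numeric(1))
}

# a frame with exactly `n_px` foreground pixels around a center, plus value
# checks: intensities fg on bg
disk_frame <- function(nr = 200, nc = 200, cx = 100, cy = 100, r = 30,
                       n_px = NULL, bg = 0.2, fg = 0.8) {
  img <- matrix(bg, nr, nc)
  idx <- spotlag:::roi_pixel_indices(c(nr, nc), cx, cy, r)
  if (!is.null(n_px)) {
    px <- (idx - 1) %/% nr; py <- (idx - 1) %% nr
    idx <- idx[order((px - cx)^2 + (py - cy)^2, idx)][seq_len(n_px)]
  }
  img[idx] <- fg
  img
}

# single-drop layout matching disk_frame geometry
disk_layout <- function(nr = 200, nc = 200, cx = 100, cy = 100, r = 40) {
  plate_layout("T", nc, nr,
               corners = matrix(c(10, 10, nc - 11, 10, nc - 11, nr - 11,
                                  10, nr - 11), 4, 2, byrow = TRUE),
               drops = drop_table("d1", cx, cy, roi_radius = r),
               validate = FALSE)
}

# hand-built kinetics row set for one drop
make_curve <- function(days, areas, density_class = "high") {
  data.frame(plate_id = "T", drop_id = "d1", strain = "S1",
             genetic_group = "A1", dose = 0, density_class = density_class,
             modality = "YPD", residence_time = NA_real_, replicate = 1L,
             day = days, area_px = as.integer(areas),
             stringsAsFactors = FALSE)
}

# phenotype-record row for normalization / classification tests
make_record <- function(strain = "S1", dose = 0, lag = 3, censored = FALSE,
                        horizon = 20, amax = 2000, density_class = "low",
                        replicate = 1L, modality = "YPD",
                        residence_time = NA_real_,
                        genetic_group = "A1") {
  data.frame(plate_id = "T", drop_id = paste0(strain, "_", dose, "_", replicate),
             strain = strain, genetic_group = genetic_group, dose = dose,
             density_class = density_class, modality = modality,
             residence_time = residence_time, replicate = replicate,
             lag_days = if (censored) NA_real_ else lag, censored = censored,
             lag_label = if (censored) paste0(">", horizon) else format(lag),
             horizon = horizon, amax_px = amax, stringsAsFactors = FALSE)
}
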