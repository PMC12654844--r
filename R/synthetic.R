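#' @title Synthetic plate-image generator with known ground truth
#' @name synthetic-data
#'
#' @description
#' Emulates the screening assay end to end: strains drawn from three
#' tolerance archetypes (low tolerance / intermediate / resistant), logistic
#' area kinetics whose lag extends with cycloheximide dose and shortens with
#' inoculum density, colonies rendered as intensity disks inside each drop
#' ROI, corner fiducials, per-frame geometric jitter, additive Gaussian noise
#' and a linear illumination gradient. Every drop's true continuous lag,
#' Amax and colony count are recorded in a truth table so each pipeline
#' stage can be verified against known parameters.
NULL

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# ---- strain models ----------------------------------------------------------

#' Sample strain kinetic models from the three tolerance archetypes
#'
#' Each strain gets a logistic-growth parameter set. The baseline detection
#' lag spans roughly 3-8 days across the collection; dose sensitivity,
#' complete-inhibition dose and Amax suppression differ by archetype:
#' low-tolerance strains are fully inhibited at one of the upper doses,
#' intermediate strains grow at all doses with a strong delay and 35-55 %
#' Amax loss at the top dose, resistant strains show at most ~2 extra days
#' of lag and little Amax loss.
#'
#' @param n Number of strains.
#' @param seed RNG seed; the draw is deterministic given `seed`.
#' @param proportions Archetype proportions, in the order low tolerance /
#'   intermediate / resistant (default `c(0.15, 0.60, 0.25)`).
#' @return `data.frame` of class `strain_models`, one row per strain:
#'   `strain`, `genetic_group`, `archetype`, `base_lag` (d), `growth_rate`
#'   (1/d), `dose_sensitivity` (d per log10 dose unit),
#'   `max_inhibitory_dose` (g/L, `Inf` when growth occurs at every dose),
#'   `amax_base` (px), `amax_dose_slope` (fractional loss at 0.5 g/L),
#'   `density_effect` (d per 10x density), `lag_offset_top` (wine-stress
#'   extra lag at 0.5 g/L, 0 for plain YPD).
#' @export
sample_strain_models <- function(n, seed = 1,
                                 proportions = c(low_tolerance = 0.15,
                                                 intermediate = 0.60,
                                                 resistant = 0.25)) {
  stopifnot(n >= 1, length(proportions) == 3, all(proportions >= 0))
  proportions <- proportions / sum(proportions)
  .with_seed(seed, {
    archetype <- sample(c("low_tolerance", "intermediate", "resistant"), n,
                        replace = TRUE, prob = proportions)
    base_lag <- stats::runif(n, 2.2, 7.5)
    growth_rate <- stats::runif(n, 0.8, 1.5)
    dose_sensitivity <- ifelse(archetype == "low_tolerance",
                               stats::runif(n, 2, 4),
                        ifelse(archetype == "intermediate",
                               stats::runif(n, 3, 6),
                               stats::runif(n, 0.2, 0.9)))
    max_inhibitory_dose <- ifelse(
      archetype == "low_tolerance",
      sample(c(0.1, 0.25, 0.5), n, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
      Inf)
    amax_base <- stats::runif(n, 1800, 3200)
    amax_dose_slope <- ifelse(archetype == "low_tolerance",
                              stats::runif(n, 0.30, 0.50),
                       ifelse(archetype == "intermediate",
                              stats::runif(n, 0.35, 0.55),
                              stats::runif(n, 0.05, 0.15)))
    density_effect <- stats::runif(n, 0.3, 0.8)
    out <- data.frame(strain = sprintf("S%03d", seq_len(n)),
                      genetic_group = sample(GENETIC_GROUPS, n, replace = TRUE),
                      archetype = archetype, base_lag = base_lag,
                      growth_rate = growth_rate,
                      dose_sensitivity = dose_sensitivity,
                      max_inhibitory_dose = max_inhibitory_dose,
                      amax_base = amax_base, amax_dose_slope = amax_dose_slope,
                      density_effect = density_effect, lag_offset_top = 0,
                      stringsAsFactors = FALSE)
    class(out) <- c("strain_models", "data.frame")
    out
  })
}

# dose scale of the lag response; the tested doses span two orders of
# magnitude, so lag extension enters through log10(1 + dose/d0)
.dose_scale <- 0.005
# reference threshold anchoring base_lag to the continuous detection crossing
# at dose 0 and the lowest density
.lag_ref_threshold <- 250

.model_amax <- function(model, dose) {
  a <- model$amax_base * (1 - model$amax_dose_slope * pmin(dose, 0.5) / 0.5)
  ifelse(dose >= model$max_inhibitory_dose, 0, a)
}

.model_tmid <- function(model, dose, density_class) {
  density <- DENSITY_CLASSES[[density_class]]
  shape_offset <- log(model$amax_base / .lag_ref_threshold - 1) / model$growth_rate
  model$base_lag + shape_offset +
    model$dose_sensitivity * log10(1 + dose / .dose_scale) +
    model$lag_offset_top * pmin(dose, 0.5) / 0.5 -
    model$density_effect * log10(density / 5)
}

#' Expected drop growth area at time t
#'
#' Logistic area kinetics
#' `A(t) = Amax(dose) / (1 + exp(-k (t - t_mid)))` with the dose shrinking
#' `Amax` linearly (fraction `amax_dose_slope` at 0.5 g/L), the lag midpoint
#' extended by `dose_sensitivity * log10(1 + dose/0.005)` days and shortened
#' by `density_effect` days per tenfold inoculum density. Doses at or above
#' the strain's complete-inhibition dose give zero area at all times.
#'
#' @param model One row of a [sample_strain_models()] table.
#' @param dose Cycloheximide dose in g/L.
#' @param density_class One of `names(DENSITY_CLASSES)`.
#' @param t Time(s) in days.
#' @return Expected area in pixels (vectorized over `t`).
#' @export
drop_area_curve <- function(model, dose, density_class, t) {
  stopifnot(all(t >= 0), nrow(model) == 1)
  amax <- .model_amax(model, dose)
  if (amax <= 0) return(rep(0, length(t)))
  tmid <- .model_tmid(model, dose, density_class)
  amax / (1 + exp(-model$growth_rate * (t - tmid)))
}

#' Continuous detection-crossing time of a synthetic drop
#'
#' Closed-form solution of `A(t) = threshold` for the logistic curve;
#' `Inf` when the plateau never exceeds the threshold.
#'
#' @inheritParams drop_area_curve
#' @param threshold Detection threshold in pixels.
#' @return Crossing time in days, or `Inf`.
#' @export
crossing_time <- function(model, dose, density_class, threshold) {
  amax <- .model_amax(model, dose)
  if (amax <= threshold) return(Inf)
  tmid <- .model_tmid(model, dose, density_class)
  tmid - log(amax / threshold - 1) / model$growth_rate
}

# ---- wine stress scenarios --------------------------------------------------

#' Adjust strain models for a wine stress modality
#'
#' Residence in stressed wine extends the cycloheximide-induced lag: at the
#' top dose (0.5 g/L) high ethanol adds 3-5 days, sulfite-containing
#' modalities 2-3 days and acidification alone 0-1 day, scaling linearly
#' down at lower doses. The stress hierarchy
#' ethanol > SO2 > pH 3.0 > original wine is preserved at every dose.
#'
#' @param base_models A [sample_strain_models()] table.
#' @param modality One of `r paste0('"', WINE_MODALITIES, '"', collapse = ", ")`.
#' @param seed RNG seed for the per-strain offset draws.
#' @return The models with `lag_offset_top` set for the modality.
#' @export
make_wine_stress_scenario <- function(base_models, modality, seed = 1) {
  if (!modality %in% WINE_MODALITIES) {
    stop(sprintf("unknown modality '%s' (known: %s)", modality,
                 paste(WINE_MODALITIES, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(base_models)
  rng <- switch(modality,
                "original" = c(0, 0),
                "pH3.0" = c(0, 1),
                "pH3.0+SO2" = c(2, 3),
                "SO2" = c(2, 3),
                "ethanol14.5" = c(3, 5))
  out <- base_models
  out$lag_offset_top <- if (rng[2] > rng[1]) {
    .with_seed(seed, stats::runif(n, rng[1], rng[2]))
  } else rep(rng[1], n)
  out$modality <- modality
  out
}

# ---- plate layout synthesis -------------------------------------------------

#' Lay out drops on synthetic 1200 x 1200 plates
#'
#' Places drops on a regular grid (pitch 110 px, ROI radius 40 px at a
#' 10 px/mm scale, i.e. a 12 x 12 cm plate) with fiducial anchors 60 px in
#' from each corner, splitting the assignment table across as many plates
#' as needed.
#'
#' @param assignments `data.frame` with one row per drop: `strain`,
#'   `genetic_group`, `dose`, `density_class`, `replicate`, `modality`,
#'   `residence_time` (missing columns get defaults).
#' @param frame_px Plate image side in pixels (default 1200).
#' @param roi_radius ROI radius (default 40).
#' @param pitch Grid pitch in pixels (default 110).
#' @return List of [plate_layout()] objects.
#' @export
synthetic_layouts <- function(assignments, frame_px = 1200, roi_radius = 40,
                              pitch = 110) {
  defaults <- list(genetic_group = NA_character_, dose = 0,
                   density_class = "low", replicate = 1L, modality = "YPD",
                   residence_time = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(assignments)) assignments[[nm]] <- defaults[[nm]]
  }
  # clearance keeps every ROI outside the 110 px corner-fiducial search
  # windows even under maximal frame jitter
  margin <- 120 + roi_radius
  per_row <- floor((frame_px - 2 * margin) / pitch) + 1
  per_plate <- per_row^2
  n <- nrow(assignments)
  n_plates <- ceiling(n / per_plate)
  corners <- matrix(c(60, 60, frame_px - 60, 60,
                      frame_px - 60, frame_px - 60, 60, frame_px - 60),
                    4, 2, byrow = TRUE)
  lapply(seq_len(n_plates), function(p) {
    idx <- ((p - 1) * per_plate + 1):min(p * per_plate, n)
    k <- seq_along(idx) - 1
    gx <- margin + (k %% per_row) * pitch
    gy <- margin + (k %/% per_row) * pitch
    a <- assignments[idx, , drop = FALSE]
    drops <- drop_table(drop_id = sprintf("P%02d_d%03d", p, seq_along(idx)),
                        cx = gx, cy = gy, roi_radius = roi_radius,
                        strain = a$strain, genetic_group = a$genetic_group,
                        dose = a$dose, density_class = a$density_class,
                        replicate = a$replicate, modality = a$modality,
                        residence_time = a$residence_time)
    plate_layout(sprintf("P%02d", p), frame_px, frame_px, corners, drops)
  })
}

# ---- rendering --------------------------------------------------------------

.place_colonies <- function(n, cx, cy, r_place, min_dist = 6, max_try = 200) {
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    for (try in seq_len(max_try)) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- r_place * sqrt(stats::runif(1))
      p <- c(cx + rr * cos(a), cy + rr * sin(a))
      if (!nrow(centers) ||
          min(sqrt(rowSums((centers - rep(p, each = nrow(centers)))^2))) >= min_dist) {
        centers <- rbind(centers, p)
        break
      }
    }
    if (nrow(centers) < i) centers <- rbind(centers, c(cx, cy))  # fallback
  }
  centers
}

.jitter_transform <- function(frame_px, max_shift = 5, max_rot_deg = 2,
                              max_proj = 5e-6) {
  th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  dx <- stats::runif(1, -max_shift, max_shift)
  dy <- stats::runif(1, -max_shift, max_shift)
  p1 <- stats::runif(1, -max_proj, max_proj)
  p2 <- stats::runif(1, -max_proj, max_proj)
  c0 <- (frame_px - 1) / 2
  rot <- matrix(c(cos(th), -sin(th), c0 - c0 * cos(th) + c0 * sin(th),
                  sin(th), cos(th), c0 - c0 * sin(th) - c0 * cos(th),
                  0, 0, 1), 3, 3, byrow = TRUE)
  shift <- matrix(c(1, 0, dx, 0, 1, dy, 0, 0, 1), 3, 3, byrow = TRUE)
  proj <- diag(3); proj[3, 1] <- p1; proj[3, 2] <- p2
  # maps jittered-frame coordinates back onto the template grid; this is the
  # transform registration must recover
  plane_transform(shift %*% rot %*% proj)
}

#' Render a synthetic plate-image time series with ground truth
#'
#' For every plate of the design, draws colony counts (Poisson at the
#' nominal density of each drop's class), places colony centers inside the
#' ROI, and renders each imaging day by switching on exactly
#' `ceiling(A(t))` ROI pixels grown outward from the colony centers (so
#' rendered pixel area tracks the model curve to within its integer
#' ceiling, and drop masks are nested over time). Corner fiducials are
#' drawn, a per-frame random jitter homography is applied to every frame
#' except the reference (last) one, and Gaussian noise plus a linear
#' illumination gradient are added. Fully deterministic for a fixed seed.
#'
#' @param design An [experiment_design()] whose drops name strains present
#'   in `models`.
#' @param models A [sample_strain_models()] table.
#' @param seed RNG seed.
#' @param noise_sd Additive Gaussian pixel noise sd (default 0.02).
#' @param jitter Apply per-frame geometric jitter (default `TRUE`); the
#'   reference frame is never jittered.
#' @param gradient_amplitude Peak-to-center amplitude of the linear
#'   illumination gradient (default 0.03).
#' @param background,foreground,fiducial_intensity Rendering intensities
#'   (defaults 0.2 / 0.8 / 0.9).
#' @param fiducial_radius Fiducial disk radius in pixels (default 10).
#' @return List with `series` (list of [plate_image_series()]), `truth`
#'   (data.frame: one row per drop with `colony_count`, `true_lag`
#'   continuous crossing of that drop's threshold, `true_amax`,
#'   `threshold`), `transforms` (per plate and frame, the frame-to-template
#'   transform that registration must recover) and `colony_centers` (list
#'   per drop).
#' @export
render_series <- function(design, models, seed = 1, noise_sd = 0.02,
                          jitter = TRUE, gradient_amplitude = 0.03,
                          background = 0.2, foreground = 0.8,
                          fiducial_intensity = 0.9, fiducial_radius = 10) {
  .with_seed(seed, {
    days <- design$imaging_days
    all_series <- list()
    truth_rows <- list()
    transforms <- list()
    centers_out <- list()
    for (layout in design$plates) {
      nr <- layout$height_px; nc <- layout$width_px
      d <- layout$drops
      mi <- match(d$strain, models$strain)
      if (anyNA(mi)) {
        stop(sprintf("no model for strain(s): %s",
                     paste(unique(d$strain[is.na(mi)]), collapse = ", ")),
             call. = FALSE)
      }
      # static scaffold: background + gradient + fiducials
      gx <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
      base_img <- background + gradient_amplitude * (2 * gx / (nc - 1) - 1)
      fid_idx <- unlist(lapply(seq_len(4), function(i) {
        roi_pixel_indices(c(nr, nc), layout$corners[i, 1],
                          layout$corners[i, 2], fiducial_radius)
      }))
      # per-drop colony placement and outward pixel ordering
      n_drops <- nrow(d)
      pix_order <- vector("list", n_drops)
      capacity <- integer(n_drops)
      colony_count <- integer(n_drops)
      thresholds <- detection_threshold(design, d$density_class)
      true_lag <- numeric(n_drops); true_amax <- numeric(n_drops)
      plate_centers <- vector("list", n_drops)
      for (j in seq_len(n_drops)) {
        nominal <- DENSITY_CLASSES[[d$density_class[j]]]
        cnt <- stats::rpois(1, nominal)
        colony_count[j] <- cnt
        n_centers <- min(cnt, 60L)
        roi_idx <- roi_pixel_indices(c(nr, nc), d$cx[j], d$cy[j],
                                     d$roi_radius[j])
        capacity[j] <- length(roi_idx)
        m <- models[mi[j], , drop = FALSE]
        if (n_centers > 0) {
          cent <- .place_colonies(n_centers, d$cx[j], d$cy[j],
                                  d$roi_radius[j] * 0.7)
          px <- ((roi_idx - 1) %/% nr)      # 0-based x
          py <- ((roi_idx - 1) %% nr)       # 0-based y
          dmin <- rep(Inf, length(roi_idx))
          for (cc in seq_len(nrow(cent))) {
            dmin <- pmin(dmin, (px - cent[cc, 1])^2 + (py - cent[cc, 2])^2)
          }
          pix_order[[j]] <- roi_idx[order(dmin, roi_idx)]
          plate_centers[[j]] <- cent
          # Amax is the area reached by the end of incubation, not the
          # logistic plateau: slow strains may still be growing at day 20
          true_amax[j] <- min(ceiling(drop_area_curve(m, d$dose[j],
                                                      d$density_class[j],
                                                      max(days))),
                              capacity[j])
          true_lag[j] <- crossing_time(m, d$dose[j], d$density_class[j],
                                       thresholds[j])
        } else {
          pix_order[[j]] <- integer(0)
          plate_centers[[j]] <- matrix(numeric(0), 0, 2)
          true_amax[j] <- 0
          true_lag[j] <- Inf
        }
      }
      # frames
      images <- vector("list", length(days))
      plate_tf <- vector("list", length(days))
      clipped <- FALSE
      for (k in seq_along(days)) {
        img <- base_img
        img[fid_idx] <- fiducial_intensity
        for (j in seq_len(n_drops)) {
          if (!length(pix_order[[j]])) next
          m <- models[mi[j], , drop = FALSE]
          a <- drop_area_curve(m, d$dose[j], d$density_class[j], days[k])
          target <- ceiling(a)
          if (target > capacity[j]) { target <- capacity[j]; clipped <- TRUE }
          if (target > 0) img[pix_order[[j]][seq_len(target)]] <- foreground
        }
        is_ref <- k == length(days)
        if (jitter && !is_ref) {
          tf <- .jitter_transform(nc)
          img <- apply_transform(img, invert_transform(tf))
          plate_tf[[k]] <- tf
        } else {
          plate_tf[[k]] <- plane_transform(diag(3))
        }
        if (noise_sd > 0) {
          img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
        }
        images[[k]] <- pmin(pmax(img, 0), 1)
      }
      if (clipped) warning(sprintf("plate %s: drop area clipped to ROI capacity",
                                   layout$plate_id), call. = FALSE)
      all_series[[layout$plate_id]] <-
        plate_image_series(layout$plate_id, days, images)
      transforms[[layout$plate_id]] <- plate_tf
      truth_rows[[layout$plate_id]] <- data.frame(
        plate_id = layout$plate_id, drop_id = d$drop_id, strain = d$strain,
        genetic_group = d$genetic_group, dose = d$dose,
        density_class = d$density_class, modality = d$modality,
        residence_time = d$residence_time, replicate = d$replicate,
        colony_count = colony_count, threshold = thresholds,
        true_lag = true_lag, true_amax = true_amax,
        stringsAsFactors = FALSE)
      centers_out[[layout$plate_id]] <- stats::setNames(plate_centers, d$drop_id)
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(series = all_series, truth = truth, transforms = transforms,
         colony_centers = centers_out)
  })
}

# ---- top-level simulation convenience ---------------------------------------

#' Simulate a full screening experiment
#'
#' Builds the dose x density x replicate assignment for `n_strains` sampled
#' strains, lays the drops out on synthetic plates, renders the image series
#' and returns everything needed to run and check the pipeline.
#'
#' @param n_strains Number of strains (default 20).
#' @param doses Dose series (default [STANDARD_DOSES]).
#' @param density_classes Density classes spotted (default
#'   `c("low", "high")`).
#' @param replicates Replicates per condition (default 1).
#' @param seed RNG seed controlling both strain sampling and rendering.
#' @param imaging_days Imaging grid (default `c(3, 6, 8, 10, 14, 17, 20)`).
#' @param modality Modality label; a wine modality applies
#'   [make_wine_stress_scenario()] to the models.
#' @param models Optional pre-sampled models (default: sampled here).
#' @param frame_px Plate image side in pixels (default 1200).
#' @param ... Passed to [render_series()] (noise, jitter, intensities).
#' @return List: `design`, `models`, `series`, `truth`, `transforms`.
#' @export
simulate_experiment <- function(n_strains = 20, doses = STANDARD_DOSES,
                                density_classes = c("low", "high"),
                                replicates = 1, seed = 1,
                                imaging_days = c(3, 6, 8, 10, 14, 17, 20),
                                modality = "YPD", models = NULL,
                                frame_px = 1200, ...) {
  if (is.null(models)) models <- sample_strain_models(n_strains, seed = seed)
  if (modality != "YPD") {
    models <- make_wine_stress_scenario(models, modality, seed = seed + 1)
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      density_class = density_classes, dose = doses,
                      strain = models$strain, stringsAsFactors = FALSE)
  grid$genetic_group <- models$genetic_group[match(grid$strain, models$strain)]
  grid$modality <- modality
  grid$residence_time <- NA_real_
  layouts <- synthetic_layouts(grid, frame_px = frame_px)
  design <- experiment_design(layouts, imaging_days = imaging_days)
  rendered <- render_series(design, models, seed = seed + 2, ...)
  c(list(design = design, models = models), rendered)
}

# ---- image and manifest I/O -------------------------------------------------

#' Read a plate photograph as a grayscale intensity matrix
#'
#' PNG via the png package; TIFF via the tiff package when installed. RGB
#' images are converted by Rec. 709 luminance.
#'
#' @param path Image path.
#' @return Intensity matrix in `[0, 1]`.
#' @export
read_plate_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE)) {
                    stop("reading TIFF requires the 'tiff' package", call. = FALSE)
                  }
                  tiff::readTIFF(path)
                },
                stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE))
  to_grayscale(img)
}

#' Write a series of plate frames plus a manifest
#'
#' Frames are written as 8-bit grayscale PNGs named `<plate>_d<day>.png`
#' with a `manifest.csv` (`plate_id`, `day`, `path`) alongside.
#'
#' @param series A [plate_image_series()] or list of them.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest, invisibly.
#' @export
write_series <- function(series, dir) {
  if (inherits(series, "plate_image_series")) series <- list(series)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in series) {
    for (i in seq_along(s$days)) {
      fn <- sprintf("%s_d%g.png", s$plate_id, s$days[i])
      png::writePNG(s$images[[i]], file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(plate_id = s$plate_id,
                                             day = s$days[i], path = fn,
                                             stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Load plate image series from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_series()]
#'   (or hand-made, columns `plate_id`, `day`, `path`; relative paths are
#'   resolved against the manifest's directory).
#' @return Named list of [plate_image_series()].
#' @export
load_series <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(split(man, man$plate_id), function(g) {
    g <- g[order(g$day), ]
    if (anyDuplicated(g$day)) {
      stop(sprintf("plate %s: duplicated day in manifest", g$plate_id[1]),
           call. = FALSE)
    }
    paths <- ifelse(file.exists(g$path), g$path, file.path(base, g$path))
    plate_image_series(g$plate_id[1], g$day, lapply(paths, read_plate_image))
  })
}
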