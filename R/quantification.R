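#' @title Foreground segmentation and growth-area quantification
#' @name quantification
#'
#' @description
#' Colony growth is read as the number of foreground pixels inside each
#' drop's circular ROI. Foreground is separated from agar background per
#' frame by a two-component Gaussian mixture fitted to the pixel-intensity
#' histogram; pixels are hard-assigned by maximum posterior responsibility
#' and the colony component is the brighter one under the default dark-field
#' polarity.
NULL

# Weighted EM for a two-component 1-D Gaussian mixture over histogram bins.
# Deterministic: initialized from the modal bin (background) and the extreme
# intensity on the colony side; no RNG involved.
.gmm2_histogram <- function(x, polarity = c("bright", "dark"),
                            bins = 512, max_iter = 100, tol = 1e-6) {
  polarity <- match.arg(polarity)
  rng <- range(x)
  if (rng[2] - rng[1] < 1e-9) {
    return(list(mu = c(rng[1], rng[1]), sigma = c(0, 0), lambda = c(1, 0),
                separable = FALSE))
  }
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                      plot = FALSE)
  v <- h$mids; w <- h$counts
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  # initialize at the intensity extremes: robust whether background or
  # foreground dominates the histogram
  mu <- c(min(v), max(v))
  s0 <- max(stats::sd(x) / 2, 1e-3)
  sigma <- c(s0, s0)
  lambda <- c(0.5, 0.5)
  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- lambda[1] * stats::dnorm(v, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(v, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(w * r1); n2 <- sum(w * r2); n <- n1 + n2
    mu <- c(sum(w * r1 * v) / max(n1, 1e-12),
            sum(w * r2 * v) / max(n2, 1e-12))
    sigma <- c(sqrt(sum(w * r1 * (v - mu[1])^2) / max(n1, 1e-12)),
               sqrt(sum(w * r2 * (v - mu[2])^2) / max(n2, 1e-12)))
    sigma <- pmax(sigma, 1e-4)
    lambda <- c(n1, n2) / n
    loglik <- sum(w * log(tot))
    if (abs(loglik - loglik_old) < tol * abs(loglik_old + 1e-12)) break
    loglik_old <- loglik
  }
  # order so component 1 = background, 2 = colony side
  ord <- if (polarity == "bright") order(mu) else order(mu, decreasing = TRUE)
  list(mu = mu[ord], sigma = sigma[ord], lambda = lambda[ord],
       separable = TRUE, iterations = iter)
}

#' Segment colony foreground by a two-component intensity mixture
#'
#' Fits a two-component Gaussian mixture to the frame's intensity histogram
#' (weighted EM over 512 bins, tolerance 1e-6, at most 100 iterations) and
#' hard-assigns each pixel to the component with the larger posterior
#' responsibility. If the component means are separated by less than
#' `separability_floor` the frame is declared free of detectable growth and
#' an empty mask is returned; likewise (with a warning) when the nominal
#' foreground would cover more than 90 percent of the frame, which indicates
#' a saturated or degenerate image rather than colonies.
#'
#' @param image Registered intensity matrix with values in `[0, 1]`.
#' @param polarity `"bright"` (colonies brighter than agar, default) or
#'   `"dark"`.
#' @param separability_floor Minimum `|mu_fg - mu_bg|` for a credible
#'   foreground component (default 0.05).
#' @param max_foreground_fraction Cap above which the mask is zeroed with a
#'   warning (default 0.9).
#' @return Object of class `foreground_mask`: logical matrix `mask` plus
#'   `method_stats` (component means, sds, mixing weights, separability).
#' @export
subtract_background <- function(image, polarity = c("bright", "dark"),
                                separability_floor = 0.05,
                                max_foreground_fraction = 0.9) {
  polarity <- match.arg(polarity)
  if (any(!is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  fit <- .gmm2_histogram(as.vector(image), polarity)
  empty <- function(reason) {
    structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                   method_stats = c(fit, list(reason = reason))),
              class = "foreground_mask")
  }
  if (!fit$separable || abs(fit$mu[2] - fit$mu[1]) < separability_floor) {
    return(empty("components not separable: no detectable growth"))
  }
  d1 <- fit$lambda[1] * stats::dnorm(image, fit$mu[1], max(fit$sigma[1], 1e-4))
  d2 <- fit$lambda[2] * stats::dnorm(image, fit$mu[2], max(fit$sigma[2], 1e-4))
  mask <- d2 > d1
  # posterior boundaries can invert in the far tail opposite the colony side;
  # clamp assignment to the colony side of the background mean
  if (polarity == "bright") mask <- mask & image > fit$mu[1]
  else mask <- mask & image < fit$mu[1]
  frac <- mean(mask)
  if (frac > max_foreground_fraction) {
    warning(sprintf("foreground fraction %.2f exceeds cap %.2f; returning empty mask",
                    frac, max_foreground_fraction), call. = FALSE)
    return(empty("foreground fraction cap exceeded"))
  }
  structure(list(mask = mask, method_stats = fit), class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("foreground_mask: %d x %d, foreground fraction %.4f\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}

#' Count foreground pixels inside one drop's ROI
#'
#' Counts mask pixels whose Euclidean distance from the drop center does not
#' exceed the drop's ROI radius. Deterministic integer count.
#'
#' @param mask A [subtract_background()] result or a logical matrix.
#' @param layout The plate's [plate_layout()].
#' @param drop_id Identifier of the drop to measure.
#' @return Integer pixel count.
#' @export
measure_area <- function(mask, layout, drop_id) {
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  i <- match(drop_id, layout$drops$drop_id)
  if (is.na(i)) stop(sprintf("unknown drop_id '%s'", drop_id), call. = FALSE)
  cx <- layout$drops$cx[i]; cy <- layout$drops$cy[i]
  r <- layout$drops$roi_radius[i]
  cols <- max(1, floor(cx - r) + 1):min(ncol(m), ceiling(cx + r) + 1)
  rows <- max(1, floor(cy - r) + 1):min(nrow(m), ceiling(cy + r) + 1)
  dx2 <- (cols - 1 - cx)^2
  dy2 <- (rows - 1 - cy)^2
  inroi <- outer(dy2, dx2, `+`) <= r^2
  sum(m[rows, cols] & inroi)
}

#' Indices of all pixels inside a drop ROI
#'
#' Linear indices (column-major) of the pixels whose centers lie within
#' `roi_radius` of `(cx, cy)`, ordered by row-then-column scan.
#'
#' @param dim_img `c(nrow, ncol)` of the image.
#' @param cx,cy Drop center (0-based pixel coordinates).
#' @param r ROI radius in pixels.
#' @return Integer vector of linear indices.
#' @keywords internal
roi_pixel_indices <- function(dim_img, cx, cy, r) {
  cols <- max(1, floor(cx - r) + 1):min(dim_img[2], ceiling(cx + r) + 1)
  rows <- max(1, floor(cy - r) + 1):min(dim_img[1], ceiling(cy + r) + 1)
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$col - 1 - cx)^2 + (grid$row - 1 - cy)^2
  keep <- d2 <= r^2
  (grid$col[keep] - 1L) * dim_img[1] + grid$row[keep]
}

#' Assemble per-drop growth kinetics from a registered series
#'
#' Segments every frame, measures each drop's ROI and returns the long-format
#' kinetics table (one row per drop x day) carrying the full drop metadata.
#' Frames listed in the design but absent from the series yield explicit
#' `NA` area rows rather than silently dropped points.
#'
#' @param series A registered [plate_image_series()].
#' @param layout The plate's [plate_layout()].
#' @param imaging_days Expected imaging days (defaults to the series' days);
#'   a frame day outside this set, or a duplicated day, is a consistency
#'   error.
#' @param ... Passed to [subtract_background()].
#' @return A `data.frame` of class `spot_kinetics`.
#' @export
assemble_kinetics <- function(series, layout, imaging_days = series$days, ...) {
  if (anyDuplicated(series$days)) {
    stop("duplicated imaging day in series", call. = FALSE)
  }
  if (!all(series$days %in% imaging_days)) {
    stop(sprintf("frame day(s) %s not in the design's imaging days",
                 paste(setdiff(series$days, imaging_days), collapse = ", ")),
         call. = FALSE)
  }
  d <- layout$drops
  res <- vector("list", length(imaging_days))
  for (k in seq_along(imaging_days)) {
    day <- imaging_days[k]
    i <- match(day, series$days)
    if (is.na(i)) {
      area <- rep(NA_integer_, nrow(d))
    } else {
      fg <- subtract_background(series$images[[i]], ...)
      area <- vapply(d$drop_id, function(id) measure_area(fg, layout, id),
                     numeric(1))
    }
    res[[k]] <- data.frame(plate_id = layout$plate_id, drop_id = d$drop_id,
                           strain = d$strain, genetic_group = d$genetic_group,
                           dose = d$dose, density_class = d$density_class,
                           modality = d$modality,
                           residence_time = d$residence_time,
                           replicate = d$replicate, day = day,
                           area_px = as.integer(area),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$drop_id, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("spot_kinetics", "data.frame")
  out
}

#' Extract one drop's growth curve from a kinetics table
#'
#' @param kinetics A `spot_kinetics` table.
#' @param drop_id Drop identifier.
#' @return A `data.frame` (class `growth_curve`) of that drop's rows, day
#'   ascending.
#' @export
growth_curve <- function(kinetics, drop_id) {
  rows <- kinetics[kinetics$drop_id == drop_id, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("unknown drop_id '%s'", drop_id), call. = FALSE)
  rows <- rows[order(rows$day), ]
  rownames(rows) <- NULL
  class(rows) <- c("growth_curve", "data.frame")
  rows
}

#' @export
plot.spot_kinetics <- function(x, drop_ids = unique(x$drop_id), ...) {
  cols <- grDevices::hcl.colors(max(2L, length(drop_ids)), "Dark 3")
  graphics::plot(NA, xlim = range(x$day), ylim = range(x$area_px, na.rm = TRUE),
                 xlab = "day", ylab = "growth area (px)", ...)
  for (i in seq_along(drop_ids)) {
    cur <- x[x$drop_id == drop_ids[i], ]
    graphics::lines(cur$day, cur$area_px, col = cols[i], type = "b", pch = 16)
  }
  invisible(x)
}
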