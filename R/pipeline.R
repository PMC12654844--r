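#' Run the full quantification pipeline on one plate
#'
#' Registration (corner detection, homography, resampling onto the template
#' grid) followed by per-frame background segmentation and per-drop area
#' measurement.
#'
#' @param series A [plate_image_series()].
#' @param layout The plate's [plate_layout()].
#' @param design The [experiment_design()] (supplies imaging days).
#' @param register Register frames before quantifying (default `TRUE`); set
#'   `FALSE` for series already on the template grid.
#' @param ... Passed to [subtract_background()].
#' @return A `spot_kinetics` table.
#' @export
quantify_series <- function(series, layout, design, register = TRUE, ...) {
  if (register) series <- register_series(series, layout)
  assemble_kinetics(series, layout, imaging_days = design$imaging_days, ...)
}

#' Quantify every plate of a simulated or loaded experiment
#'
#' @param series_list Named list of [plate_image_series()] (names = plate
#'   ids present in the design).
#' @param design The [experiment_design()].
#' @param register Register frames first (default `TRUE`).
#' @param ... Passed to [subtract_background()].
#' @return A combined `spot_kinetics` table across plates.
#' @export
quantify_experiment <- function(series_list, design, register = TRUE, ...) {
  out <- lapply(names(series_list), function(pid) {
    layout <- design$plates[[pid]]
    if (is.null(layout)) stop(sprintf("plate '%s' absent from design", pid),
                              call. = FALSE)
    quantify_series(series_list[[pid]], layout, design, register = register, ...)
  })
  res <- do.call(rbind, out)
  class(res) <- c("spot_kinetics", "data.frame")
  res
}
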