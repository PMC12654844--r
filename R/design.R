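#' @title Experiment-design containers
#' @name design-containers
#'
#' @description
#' The pipeline's static description of an assay: where the drops sit on each
#' plate (`plate_layout`), what was spotted in them (the drop table), when the
#' plates were photographed, which area thresholds define colony detection,
#' and which wine conditions the sampled cultures came from
#' (`wine_condition`). All pixel coordinates are 0-based with the origin at
#' the top-left corner, x rightward and y downward, matching raster
#' conventions.
NULL

# canonical vocabularies ------------------------------------------------------

#' @export
GENETIC_GROUPS <- c("A1", "A2", "A3", "Admixed", "Admixed D1/D2", "D1", "D2")

#' Inoculum density classes and their nominal colony counts per 2 uL drop
#' @export
DENSITY_CLASSES <- c(low = 5, medium = 50, high = 500, undiluted = 5000)

#' Cycloheximide doses used by the screening design (g/L)
#' @export
STANDARD_DOSES <- c(0, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5)

#' Wine stress modality labels understood by the stress generator
#' @export
WINE_MODALITIES <- c("original", "pH3.0", "pH3.0+SO2", "SO2", "ethanol14.5")

.known_modalities <- function() c("YPD", WINE_MODALITIES)

# drop table ------------------------------------------------------------------

.drop_columns <- c("drop_id", "cx", "cy", "roi_radius", "strain",
                   "genetic_group", "dose", "density_class", "replicate",
                   "modality", "residence_time")

#' Build a drop-specification table
#'
#' One row per spotted drop. `cx`/`cy` are the ROI center in template pixels,
#' `roi_radius` the radius of the circular region quantified for that drop.
#'
#' @param drop_id Character vector of unique drop identifiers.
#' @param cx,cy Numeric ROI center coordinates (pixels, 0-based).
#' @param roi_radius Positive ROI radius in pixels (default 40, i.e. 4 mm at
#'   10 px/mm).
#' @param strain Strain identifiers.
#' @param genetic_group One of [GENETIC_GROUPS], or `NA`.
#' @param dose Cycloheximide dose in g/L, non-negative.
#' @param density_class One of `names(DENSITY_CLASSES)`.
#' @param replicate Replicate number, 1..3.
#' @param modality Medium/condition label, `"YPD"` for the plain screening.
#' @param residence_time Days of residence in wine (0/7/14/21) or `NA`.
#' @return A `data.frame` with one row per drop.
#' @export
drop_table <- function(drop_id, cx, cy, roi_radius = 40, strain = "S1",
                       genetic_group = NA_character_, dose = 0,
                       density_class = "low", replicate = 1L,
                       modality = "YPD", residence_time = NA_real_) {
  data.frame(drop_id = as.character(drop_id), cx = as.numeric(cx),
             cy = as.numeric(cy), roi_radius = as.numeric(roi_radius),
             strain = as.character(strain),
             genetic_group = as.character(genetic_group),
             dose = as.numeric(dose),
             density_class = as.character(density_class),
             replicate = as.integer(replicate),
             modality = as.character(modality),
             residence_time = as.numeric(residence_time),
             stringsAsFactors = FALSE)
}

# plate layout ----------------------------------------------------------------

#' Construct a plate layout
#'
#' A plate layout ties a plate identifier to its pixel dimensions, the four
#' corner anchor points used for registration (clockwise from top-left), and
#' the drop table. Validation enforces corner convexity, drop containment
#' within the corner quadrilateral, ROI disjointness and identifier
#' uniqueness.
#'
#' @param plate_id Plate identifier.
#' @param width_px,height_px Image dimensions in pixels.
#' @param corners 4x2 numeric matrix of (x, y) anchors, clockwise from
#'   top-left.
#' @param drops A drop table as returned by [drop_table()].
#' @param validate Run [validate_layout()] (default `TRUE`).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(plate_id, width_px, height_px, corners, drops,
                         validate = TRUE) {
  corners <- as.matrix(corners)
  storage.mode(corners) <- "double"
  layout <- structure(
    list(plate_id = as.character(plate_id), width_px = as.integer(width_px),
         height_px = as.integer(height_px), corners = corners, drops = drops),
    class = "plate_layout")
  if (validate) validate_layout(layout)
  layout
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout '%s': %d x %d px, %d drops\n",
              x$plate_id, x$width_px, x$height_px, nrow(x$drops)))
  invisible(x)
}

# 2 * signed area of a polygon; positive for clockwise order in y-down coords
.signed_area2 <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

.is_convex_cw <- function(p) {
  if (nrow(p) != 4) return(FALSE)
  n <- 4L
  cr <- vapply(seq_len(n), function(i) {
    a <- p[i, ]; b <- p[i %% n + 1, ]; c <- p[(i + 1) %% n + 1, ]
    (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }, numeric(1))
  all(cr > 0) && .signed_area2(p) > 0
}

# signed distance of point(s) to each quad edge; all positive <=> strictly
# inside a clockwise quad (y-down convention)
.edge_distances <- function(quad, x, y) {
  n <- nrow(quad)
  sapply(seq_len(n), function(i) {
    a <- quad[i, ]; b <- quad[i %% n + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    (e[1] * (y - a[2]) - e[2] * (x - a[1])) / len
  })
}

#' Validate a plate layout
#'
#' @param layout A `plate_layout`.
#' @return The layout, invisibly; signals a classed validation error
#'   identifying the offending plate/drop otherwise.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  fail <- function(msg) {
    stop(sprintf("plate '%s': %s", layout$plate_id, msg), call. = FALSE)
  }
  if (!is.matrix(layout$corners) || !all(dim(layout$corners) == c(4, 2))) {
    fail("corners must be a 4x2 matrix")
  }
  if (!.is_convex_cw(layout$corners)) {
    fail("corners must form a convex quadrilateral listed clockwise from top-left")
  }
  d <- layout$drops
  required <- setdiff(.drop_columns, "residence_time")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    fail(paste("drop table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(d$drop_id)) {
    fail(sprintf("duplicated drop_id: %s",
                 paste(unique(d$drop_id[duplicated(d$drop_id)]), collapse = ", ")))
  }
  if (any(d$roi_radius <= 0)) fail("roi_radius must be > 0")
  if (any(d$dose < 0)) fail("dose must be >= 0")
  bad_density <- setdiff(unique(d$density_class), names(DENSITY_CLASSES))
  if (length(bad_density)) {
    fail(paste("unknown density_class:", paste(bad_density, collapse = ", ")))
  }
  unknown_mod <- setdiff(unique(d$modality), .known_modalities())
  if (length(unknown_mod)) {
    message(sprintf("plate '%s': unrecognised modality label(s) %s (kept as-is)",
                    layout$plate_id, paste(unknown_mod, collapse = ", ")))
  }
  # every ROI disk strictly inside the corner quadrilateral
  dist <- .edge_distances(layout$corners, d$cx, d$cy)
  if (nrow(d) == 1L) dist <- matrix(dist, nrow = 1)
  inside <- dist > d$roi_radius
  if (!all(inside)) {
    bad <- d$drop_id[!apply(inside, 1, all)]
    fail(sprintf("drop ROI(s) not strictly inside the corner quadrilateral: %s",
                 paste(bad, collapse = ", ")))
  }
  # pairwise ROI disjointness
  if (nrow(d) > 1) {
    dd <- as.matrix(stats::dist(cbind(d$cx, d$cy)))
    rr <- outer(d$roi_radius, d$roi_radius, `+`)
    diag(dd) <- Inf
    if (any(dd < rr)) {
      i <- which(dd < rr, arr.ind = TRUE)[1, ]
      fail(sprintf("overlapping ROIs: %s and %s", d$drop_id[i[1]], d$drop_id[i[2]]))
    }
  }
  invisible(layout)
}

# wine conditions -------------------------------------------------------------

#' Characterize a wine condition
#'
#' Computes the molecular SO2 of the condition from its free SO2, pH,
#' temperature and ethanol via [compute_molecular_so2()].
#'
#' @param label Condition label (e.g. `"pH3.0+SO2"`).
#' @param pH Wine pH.
#' @param free_so2 Free SO2, mg/L.
#' @param ethanol Ethanol, percent by volume.
#' @param temperature Temperature in degrees Celsius.
#' @return An object of class `wine_condition` with a `molecular_so2` field.
#' @export
wine_condition <- function(label, pH, free_so2 = 0, ethanol = 12.91,
                           temperature = 20) {
  mso2 <- compute_molecular_so2(free_so2, pH, temperature, ethanol)
  structure(list(label = label, pH = pH, free_so2 = free_so2,
                 ethanol = ethanol, temperature = temperature,
                 molecular_so2 = mso2),
            class = "wine_condition")
}

#' @export
print.wine_condition <- function(x, ...) {
  cat(sprintf("wine_condition '%s': pH %.2f, %.3g%% vol, free SO2 %.3g mg/L -> mSO2 %.2f mg/L\n",
              x$label, x$pH, x$ethanol, x$free_so2, x$molecular_so2))
  invisible(x)
}

# experiment design -----------------------------------------------------------

#' Assemble an experiment design
#'
#' @param plates List of [plate_layout()] objects.
#' @param imaging_days Strictly increasing vector of imaging day numbers,
#'   maximum 30 (the assay photographs every 2-3 days for 20 days).
#' @param t_high Detection threshold in pixels for all but the lowest
#'   inoculum density (default 500).
#' @param t_low Detection threshold for the lowest density class (default
#'   250).
#' @param conditions Optional list of [wine_condition()] objects.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(plates, imaging_days = c(3, 6, 8, 10, 14, 17, 20),
                              t_high = 500, t_low = 250, conditions = list()) {
  if (!length(imaging_days) || is.unsorted(imaging_days, strictly = TRUE)) {
    stop("imaging_days must be non-empty and strictly increasing", call. = FALSE)
  }
  if (max(imaging_days) > 30) stop("imaging_days must not exceed 30", call. = FALSE)
  if (!(t_high > t_low && t_low > 0)) {
    stop("detection thresholds must satisfy t_high > t_low > 0", call. = FALSE)
  }
  if (inherits(plates, "plate_layout")) plates <- list(plates)
  for (p in plates) validate_layout(p)
  ids <- vapply(plates, `[[`, character(1), "plate_id")
  if (anyDuplicated(ids)) stop("duplicated plate_id in design", call. = FALSE)
  structure(list(plates = stats::setNames(plates, ids),
                 imaging_days = as.numeric(imaging_days),
                 t_high = t_high, t_low = t_low, conditions = conditions),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  ndrop <- sum(vapply(x$plates, function(p) nrow(p$drops), integer(1)))
  cat(sprintf(paste0("experiment_design: %d plate(s), %d drops, imaging days {%s},",
                     " thresholds %g/%g px\n"),
              length(x$plates), ndrop, paste(x$imaging_days, collapse = ", "),
              x$t_high, x$t_low))
  invisible(x)
}

#' Detection threshold applicable to a density class
#'
#' The lowest inoculum density uses the lower threshold; all other classes
#' use the higher one.
#'
#' @param design An `experiment_design`.
#' @param density_class Character vector of density classes.
#' @return Numeric vector of thresholds (pixels).
#' @export
detection_threshold <- function(design, density_class) {
  ifelse(density_class == "low", design$t_low, design$t_high)
}

# YAML I/O --------------------------------------------------------------------

.layout_to_list <- function(p) {
  list(plate_id = p$plate_id, width_px = p$width_px, height_px = p$height_px,
       corners = lapply(seq_len(4), function(i) as.numeric(p$corners[i, ])),
       drops = lapply(seq_len(nrow(p$drops)), function(i) {
         row <- as.list(p$drops[i, , drop = FALSE])
         row <- lapply(row, function(v) if (is.factor(v)) as.character(v) else v)
         if (is.na(row$residence_time)) row$residence_time <- NULL
         if (is.na(row$genetic_group)) row$genetic_group <- NULL
         row
       }))
}

.layout_from_list <- function(lst) {
  corners <- do.call(rbind, lapply(lst$corners, as.numeric))
  drops <- do.call(rbind, lapply(lst$drops, function(row) {
    drop_table(drop_id = row$drop_id, cx = row$cx, cy = row$cy,
               roi_radius = row$roi_radius %||% 40,
               strain = row$strain %||% "S1",
               genetic_group = row$genetic_group %||% NA_character_,
               dose = row$dose %||% 0,
               density_class = row$density_class %||% "low",
               replicate = row$replicate %||% 1L,
               modality = row$modality %||% "YPD",
               residence_time = row$residence_time %||% NA_real_)
  }))
  plate_layout(lst$plate_id, lst$width_px, lst$height_px, corners, drops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment design from a YAML file
#'
#' @param path Path to a YAML design file.
#' @return A validated [experiment_design()].
#' @export
load_design <- function(path) {
  if (!file.exists(path)) stop(sprintf("design file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("cannot parse design file %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(raw$plates)) stop("design file has no 'plates' section", call. = FALSE)
  plates <- lapply(raw$plates, .layout_from_list)
  conditions <- lapply(raw$conditions %||% list(), function(cc) {
    wine_condition(cc$label, cc$pH, cc$free_so2 %||% 0,
                   cc$ethanol %||% 12.91, cc$temperature %||% 20)
  })
  experiment_design(plates,
                    imaging_days = as.numeric(raw$imaging_days %||% c(3, 6, 8, 10, 14, 17, 20)),
                    t_high = raw$t_high %||% 500, t_low = raw$t_low %||% 250,
                    conditions = conditions)
}

#' Write an experiment design to a YAML file
#'
#' Inverse of [load_design()]: `load_design(save_design(d, f))` preserves the
#' design's semantic content.
#'
#' @param design An `experiment_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_design <- function(design, path) {
  lst <- list(imaging_days = design$imaging_days, t_high = design$t_high,
              t_low = design$t_low,
              conditions = lapply(design$conditions, function(cc) {
                list(label = cc$label, pH = cc$pH, free_so2 = cc$free_so2,
                     ethanol = cc$ethanol, temperature = cc$temperature)
              }),
              plates = lapply(design$plates, .layout_to_list))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Collect all drops of a design into one table
#'
#' @param design An `experiment_design`.
#' @return Drop table with a `plate_id` column prepended.
#' @export
design_drops <- function(design) {
  do.call(rbind, lapply(design$plates, function(p) {
    cbind(plate_id = p$plate_id, p$drops, stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}
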