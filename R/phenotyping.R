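#' @title Phenotype extraction from growth kinetics
#' @name phenotyping
#'
#' @description
#' Two phenotypes summarize each drop's kinetics: the lag phase, the first
#' imaging day on which the growth area strictly exceeds the detection
#' threshold (500 px for all but the lowest inoculum density, 250 px for the
#' lowest), right-censored at the final incubation day when never exceeded;
#' and Amax, the maximum growth area reached over the series. Lags are
#' normalized against the matched no-drug control of the same strain (and,
#' in the wine design, the same residence time in the unmodified wine), and
#' strains are classified into low-tolerance / intermediate / resistant
#' profiles from their behaviour across the dose series.
NULL

#' Extract the lag phase of one growth curve
#'
#' Returns the earliest imaging day whose area strictly exceeds the
#' detection threshold; when no day does, the lag is right-censored at the
#' last observed day. Lags live on the discrete imaging grid: no
#' interpolation between photographs.
#'
#' @param curve A [growth_curve()] (or any data.frame with `day`, `area_px`
#'   and `density_class` columns; `NA` areas are treated as not exceeding).
#' @param t_high,t_low Detection thresholds in pixels (defaults 500/250).
#' @return A list with `lag_days` (numeric, `NA` when censored), `censored`
#'   (logical), `horizon` (last observed day) and `label` (e.g. `"8"` or
#'   `">20"`).
#' @export
extract_lag <- function(curve, t_high = 500, t_low = 250) {
  stopifnot(nrow(curve) >= 1)
  thr <- if (curve$density_class[1] == "low") t_low else t_high
  ord <- order(curve$day)
  day <- curve$day[ord]; area <- curve$area_px[ord]
  hit <- which(!is.na(area) & area > thr)
  horizon <- max(day)
  if (length(hit)) {
    list(lag_days = day[hit[1]], censored = FALSE, horizon = horizon,
         label = format(day[hit[1]]))
  } else {
    list(lag_days = NA_real_, censored = TRUE, horizon = horizon,
         label = paste0(">", format(horizon)))
  }
}

#' Extract the maximum growth area of one curve
#'
#' @param curve A [growth_curve()] (or data.frame with `area_px`).
#' @return Maximum `area_px` over the series (0 for an all-`NA` curve).
#' @export
extract_amax <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  a <- curve$area_px[!is.na(curve$area_px)]
  if (!length(a)) 0L else max(a)
}

#' Build the per-drop phenotype table from kinetics
#'
#' @param kinetics A `spot_kinetics` long table.
#' @param design The [experiment_design()] supplying detection thresholds.
#' @return A `data.frame` of class `phenotype_table`: one row per drop with
#'   drop metadata, `lag_days`, `censored`, `lag_label`, `horizon`,
#'   `amax_px`.
#' @export
phenotype_table <- function(kinetics, design) {
  meta_cols <- c("plate_id", "drop_id", "strain", "genetic_group", "dose",
                 "density_class", "modality", "residence_time", "replicate")
  ids <- unique(kinetics$drop_id)
  rows <- lapply(ids, function(id) {
    cur <- kinetics[kinetics$drop_id == id, , drop = FALSE]
    cur <- cur[order(cur$day), ]
    lag <- extract_lag(cur, t_high = design$t_high, t_low = design$t_low)
    cbind(cur[1, meta_cols, drop = FALSE],
          data.frame(lag_days = lag$lag_days, censored = lag$censored,
                     lag_label = lag$label, horizon = lag$horizon,
                     amax_px = extract_amax(cur)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Normalize one record's lag against its matched control
#'
#' Subtracts the control lag from the record lag. A censored record yields a
#' censored normalized value (`> horizon - control lag`); a censored control
#' makes the normalized lag undefined (with a warning), since no finite
#' baseline exists.
#'
#' @param record,control Single-row phenotype records sharing the pairing
#'   key: same strain (and same residence time in the wine design); the
#'   control must be the 0-dose (and, in wine mode, original-wine) record.
#' @return List with `value`, `censored`, `defined`, `label`.
#' @export
normalize_lag <- function(record, control) {
  if (record$strain != control$strain) {
    stop("record and control must share the strain", call. = FALSE)
  }
  if (!is.na(record$residence_time) && !is.na(control$residence_time) &&
      record$residence_time != control$residence_time) {
    stop("record and control must share the residence time", call. = FALSE)
  }
  if (control$dose != 0) stop("control must have dose 0", call. = FALSE)
  if (control$censored) {
    warning("control lag is censored; normalized lag undefined", call. = FALSE)
    return(list(value = NA_real_, censored = FALSE, defined = FALSE,
                label = NA_character_))
  }
  if (record$censored) {
    v <- record$horizon - control$lag_days
    return(list(value = v, censored = TRUE, defined = TRUE,
                label = paste0(">", format(v))))
  }
  v <- record$lag_days - control$lag_days
  list(value = v, censored = FALSE, defined = TRUE, label = format(v))
}

#' Normalize all lags of a phenotype table against matched controls
#'
#' In the plain screening (`mode = "ypd"`) the control for a record is the
#' same strain, density class and replicate at dose 0. In the wine design
#' (`mode = "wine"`) it is the same strain, residence time and density class
#' sampled from the unmodified (original) wine and plated without drug.
#' Replicates are paired by replicate number when possible.
#'
#' @param records A [phenotype_table()].
#' @param mode `"ypd"` or `"wine"`.
#' @return The table with `normalized_lag_days`, `norm_censored`,
#'   `norm_defined` and `norm_label` columns appended.
#' @export
normalize_lags <- function(records, mode = c("ypd", "wine")) {
  mode <- match.arg(mode)
  key <- function(df) {
    if (mode == "ypd") paste(df$strain, df$density_class, df$replicate, sep = "|")
    else paste(df$strain, df$residence_time, df$density_class, df$replicate,
               sep = "|")
  }
  is_ctrl <- records$dose == 0 &
    (mode == "ypd" | records$modality %in% c("original", "YPD"))
  ctrl <- records[is_ctrl, , drop = FALSE]
  ctrl_key <- key(ctrl)
  idx <- match(key(records), ctrl_key)
  n <- nrow(records)
  records$normalized_lag_days <- NA_real_
  records$norm_censored <- FALSE
  records$norm_defined <- FALSE
  records$norm_label <- NA_character_
  n_ctrl_censored <- 0L
  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) next
    if (ctrl$censored[j]) { n_ctrl_censored <- n_ctrl_censored + 1L; next }
    nl <- suppressWarnings(normalize_lag(records[i, ], ctrl[j, ]))
    records$normalized_lag_days[i] <- nl$value
    records$norm_censored[i] <- nl$censored
    records$norm_defined[i] <- nl$defined
    records$norm_label[i] <- nl$label
  }
  if (n_ctrl_censored > 0) {
    message(sprintf("%d record(s) have a censored control: normalized lag undefined",
                    n_ctrl_censored))
  }
  unmatched <- sum(is.na(idx))
  if (unmatched > 0) {
    message(sprintf("%d record(s) lack a matched dose-0 control", unmatched))
  }
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' Classify a strain's cycloheximide tolerance profile
#'
#' Three descriptive classes summarize the dose response:
#' `low_tolerance` when any tested dose fully suppresses detectable growth
#' (censored lag); `resistant` when at the maximum dose the normalized lag
#' is at most `r_max` days and Amax is retained to at least `amax_ratio_min`
#' of the no-drug value; `intermediate` otherwise (growth at all doses but
#' clearly delayed or reduced).
#'
#' @param records Phenotype rows of one strain (single density class and
#'   replicate, or replicate medians) spanning at least three doses
#'   including 0 and the maximum.
#' @param r_max Resistance cutoff on normalized lag at the top dose, days
#'   (default 2).
#' @param amax_ratio_min Minimum Amax retention at the top dose for the
#'   resistant class (default 0.8).
#' @return One of `"low_tolerance"`, `"intermediate"`, `"resistant"`.
#' @export
classify_profile <- function(records, r_max = 2, amax_ratio_min = 0.8) {
  doses <- sort(unique(records$dose))
  if (length(doses) < 3 || doses[1] != 0) {
    stop("need curves for >= 3 doses including 0 and the maximum dose",
         call. = FALSE)
  }
  agg <- function(x) stats::median(x, na.rm = TRUE)
  per_dose <- lapply(doses, function(d) {
    r <- records[records$dose == d, , drop = FALSE]
    list(dose = d, censored = all(r$censored), lag = agg(r$lag_days),
         amax = agg(r$amax_px), horizon = max(r$horizon))
  })
  ctrl <- per_dose[[1]]
  if (ctrl$censored) stop("dose-0 curve is censored: cannot classify", call. = FALSE)
  if (any(vapply(per_dose, `[[`, logical(1), "censored"))) {
    return("low_tolerance")
  }
  top <- per_dose[[length(per_dose)]]
  norm_lag_top <- top$lag - ctrl$lag
  amax_ratio <- if (ctrl$amax > 0) top$amax / ctrl$amax else 0
  if (norm_lag_top <= r_max && amax_ratio >= amax_ratio_min) "resistant"
  else "intermediate"
}

#' Classify every strain of a phenotype table
#'
#' Records are grouped by strain (optionally within a density class) and
#' replicate medians are taken per dose before classification.
#'
#' @param records A [phenotype_table()].
#' @param density_class Restrict to one density class (default `"low"`, the
#'   class whose curves the taxonomy describes); `NULL` uses all.
#' @param ... Passed to [classify_profile()].
#' @return `data.frame` with `strain` and `profile` columns.
#' @export
classify_profiles <- function(records, density_class = "low", ...) {
  if (!is.null(density_class)) {
    records <- records[records$density_class == density_class, , drop = FALSE]
  }
  strains <- unique(records$strain)
  profile <- vapply(strains, function(s) {
    classify_profile(records[records$strain == s, , drop = FALSE], ...)
  }, character(1))
  data.frame(strain = strains, profile = profile, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Median-summarize replicates of a phenotype table
#'
#' Collapses the `n = 3` replicate drops of each condition to their median
#' lag and median Amax. Conditions whose replicate lags disagree by more
#' than one imaging interval are flagged in the `lag_flagged` column.
#'
#' @param records A [phenotype_table()].
#' @param imaging_days Imaging grid used to define "one imaging interval".
#' @return Summarized `phenotype_table` with one row per condition.
#' @export
summarize_replicates <- function(records, imaging_days) {
  keycols <- c("strain", "genetic_group", "dose", "density_class", "modality",
               "residence_time")
  key <- do.call(paste, c(records[keycols], sep = "|"))
  max_gap <- max(diff(sort(unique(imaging_days))))
  rows <- lapply(split(records, key), function(g) {
    obs <- g$lag_days[!g$censored]
    flagged <- length(obs) > 1 && diff(range(obs)) > max_gap
    cens <- sum(g$censored) > length(g$censored) / 2
    out <- g[1, c("plate_id", keycols), drop = FALSE]
    out$replicates <- nrow(g)
    out$lag_days <- if (cens || !length(obs)) NA_real_ else stats::median(obs)
    out$censored <- cens || !length(obs)
    out$horizon <- max(g$horizon)
    out$amax_px <- stats::median(g$amax_px)
    out$lag_flagged <- flagged
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Tabulate lag-class distributions
#'
#' Bins observed lags into day classes, with censored records in a dedicated
#' class, per grouping cell (by default genetic group x dose).
#'
#' @param records A [phenotype_table()].
#' @param bin_edges Increasing numeric lag-class boundaries; a lag `l` falls
#'   in class `i` when `bin_edges[i] <= l < bin_edges[i+1]` (default
#'   `c(0, 4, 7, 9, 15, 21)`).
#' @param by Character vector of grouping columns (default
#'   `c("genetic_group", "dose")`).
#' @return `data.frame` of class `lag_distribution`: one row per group x
#'   class with `count` and within-group `fraction` (fractions sum to 1 per
#'   group).
#' @export
summarize_lag_distribution <- function(records, bin_edges = c(0, 4, 7, 9, 15, 21),
                                       by = c("genetic_group", "dose")) {
  stopifnot(nrow(records) >= 1, !is.unsorted(bin_edges, strictly = TRUE))
  labs <- paste0("[", utils::head(bin_edges, -1), ",", bin_edges[-1], ")")
  classes <- c(labs, "censored")
  key <- do.call(paste, c(records[by], sep = "|"))
  rows <- lapply(split(records, key), function(g) {
    bin <- pmin(pmax(findInterval(g$lag_days, bin_edges), 1L), length(labs))
    cls <- ifelse(g$censored, "censored", labs[bin])
    counts <- table(factor(cls, levels = classes))
    cbind(g[rep(1, length(classes)), by, drop = FALSE],
          data.frame(lag_class = classes, count = as.integer(counts),
                     fraction = as.integer(counts) / nrow(g)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lag_distribution", "data.frame")
  out
}
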