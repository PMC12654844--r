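#' Write a machine-readable report bundle with figures
#'
#' Collects phenotypes, group comparisons and variance partitions into CSV /
#' JSON files and draws the standard figure families: Amax distributions by
#' dose, normalized-lag boxplots by genetic group and dose, and a lag-class
#' bubble chart. Compact-letter annotations on the figures are taken
#' verbatim from the supplied comparisons.
#'
#' @param phenotypes A [phenotype_table()] (ideally after
#'   [normalize_lags()]).
#' @param comparisons Named list of `group_comparison` objects (may be
#'   empty; the name states what was compared).
#' @param partitions Named list of `variance_partition` objects (may be
#'   empty).
#' @param out_dir Output directory, created if needed.
#' @param format Figure device: `"png"` (default) or `"svg"`.
#' @return Invisibly, the paths written.
#' @export
spot_report <- function(phenotypes, comparisons = list(), partitions = list(),
                        out_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(as.data.frame(phenotypes), "phenotypes.csv")
  if (length(comparisons)) {
    comp_df <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cc <- comparisons[[nm]]
      data.frame(comparison = nm, level = names(cc$letters),
                 letters = unname(cc$letters), H = cc$H, p_value = cc$p_value,
                 stringsAsFactors = FALSE)
    }))
    wr(comp_df, "comparisons.csv")
  }
  if (length(partitions)) {
    part_df <- do.call(rbind, lapply(names(partitions), function(nm) {
      cbind(partition = nm, as.data.frame(partitions[[nm]]))
    }))
    wr(part_df, "partition.csv")
  }
  summary_json <- list(
    n_records = nrow(phenotypes),
    n_censored = sum(phenotypes$censored),
    comparisons = lapply(comparisons, function(cc) {
      list(H = cc$H, df = cc$df, p_value = cc$p_value,
           letters = as.list(cc$letters))
    }),
    partitions = lapply(partitions, function(vp) {
      stats::setNames(as.list(vp$fraction_pct), vp$term)
    }))
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)

  dev_open <- function(name, w = 7, h = 5) {
    p <- file.path(out_dir, paste0(name, ".", format))
    if (format == "png") grDevices::png(p, width = w * 100, height = h * 100)
    else grDevices::svg(p, width = w, height = h)
    paths <<- c(paths, p)
  }
  # Amax distribution by dose
  if (length(unique(phenotypes$dose)) > 1) {
    dev_open("amax_by_dose")
    fdose <- factor(phenotypes$dose)
    graphics::boxplot(amax_px ~ fdose, data = phenotypes,
                      xlab = "cycloheximide (g/L)", ylab = "Amax (px)",
                      col = "grey85")
    cc <- comparisons[["amax_by_dose"]]
    if (!is.null(cc)) {
      graphics::mtext(cc$letters[levels(fdose)], side = 3,
                      at = seq_along(levels(fdose)), line = 0.2)
    }
    grDevices::dev.off()
  }
  # normalized lag by genetic group x dose
  has_norm <- "normalized_lag_days" %in% names(phenotypes) &&
    any(is.finite(phenotypes$normalized_lag_days))
  if (has_norm) {
    dev_open("normalized_lag_by_group_dose", w = 9)
    ok <- is.finite(phenotypes$normalized_lag_days) & !phenotypes$norm_censored
    dat <- phenotypes[ok & phenotypes$dose > 0, , drop = FALSE]
    if (nrow(dat)) {
      grp <- interaction(dat$genetic_group, dat$dose, sep = " @ ", drop = TRUE)
      graphics::boxplot(dat$normalized_lag_days ~ grp, las = 2,
                        xlab = "", ylab = "normalized lag (d)", col = "grey85")
    }
    grDevices::dev.off()
  }
  # lag-class bubble chart
  dist <- summarize_lag_distribution(phenotypes)
  dev_open("lag_class_bubble", w = 8)
  dist$xi <- as.integer(factor(dist$lag_class,
                               levels = unique(dist$lag_class)))
  grp_lab <- do.call(paste, c(dist[setdiff(names(dist),
                                           c("lag_class", "count", "fraction",
                                             "xi"))], sep = " @ "))
  dist$yi <- as.integer(factor(grp_lab, levels = unique(grp_lab)))
  graphics::plot(dist$xi, dist$yi, cex = 3 * sqrt(dist$fraction), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.7),
                 xaxt = "n", yaxt = "n", xlab = "lag class (d)", ylab = "")
  graphics::axis(1, at = unique(dist$xi),
                 labels = unique(dist$lag_class), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = unique(dist$yi), labels = unique(grp_lab), las = 2,
                 cex.axis = 0.6)
  grDevices::dev.off()
  invisible(paths)
}
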