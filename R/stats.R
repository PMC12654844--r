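#' @title Group statistics: Kruskal-Wallis / Dunn and ANOVA variance partition
#' @name stats-report
#'
#' @description
#' Phenotype groups (doses, genetic groups, modalities) are compared by the
#' non-parametric Kruskal-Wallis test followed by Dunn's pairwise post hoc
#' comparisons on the same midranks, summarized as a compact-letter display.
#' The sources of normalized-lag variance are partitioned by a multifactorial
#' ANOVA (main effects and interactions), reporting each term's share of the
#' total sum of squares.
NULL

# ---- Kruskal-Wallis + Dunn --------------------------------------------------

#' Kruskal-Wallis test with Dunn post hoc comparisons and letters
#'
#' The H statistic is computed on midranks with the usual tie correction;
#' Dunn's pairwise z statistics reuse the same pooled ranks. Pairwise p
#' values are adjusted (Benjamini-Hochberg by default) and condensed into a
#' compact-letter display: two levels share no letter exactly when their
#' adjusted p value is below `alpha`.
#'
#' @param values Numeric response vector (censored lags must be excluded
#'   upstream).
#' @param groups Grouping factor (>= 2 levels, each with >= 2 observations).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Adjustment method for Dunn p values: `"BH"` (default),
#'   `"holm"` or `"none"`.
#' @return Object of class `group_comparison`: `H`, `df`, `p_value`,
#'   `pairwise` (data.frame with z, p, p_adj), `letters` (named character),
#'   `mean_ranks`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05,
                         p_adjust = c("BH", "holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  keep <- is.finite(values) & !is.na(groups)
  if (sum(!keep)) message(sprintf("%d non-finite value(s) excluded", sum(!keep)))
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  n_i <- table(groups)
  if (length(n_i) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(n_i < 2)) {
    stop(sprintf("degenerate group(s) with < 2 observations: %s",
                 paste(names(n_i)[n_i < 2], collapse = ", ")), call. = FALSE)
  }
  N <- length(values)
  r <- rank(values)                     # midranks
  rbar <- tapply(r, groups, mean)
  H_raw <- 12 / (N * (N + 1)) * sum(n_i * rbar^2) - 3 * (N + 1)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  C <- 1 - tie_sum / (N^3 - N)
  H <- if (C > 0) H_raw / C else 0
  df <- length(n_i) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  # Dunn pairwise z on the same ranks
  lev <- names(n_i)
  pairs <- utils::combn(lev, 2)
  sigma2 <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(sigma2 * (1 / n_i[pr[1]] + 1 / n_i[pr[2]]))
  })
  p_pair <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_pair, method = p_adjust)
  pairwise <- data.frame(level1 = pairs[1, ], level2 = pairs[2, ],
                         z = as.numeric(z), p = as.numeric(p_pair),
                         p_adj = as.numeric(p_adj), row.names = NULL,
                         stringsAsFactors = FALSE)
  letters <- compact_letters(pairwise, lev, alpha = alpha,
                             order_by = -as.numeric(rbar))
  structure(list(H = as.numeric(H), df = df, p_value = p,
                 pairwise = pairwise, letters = letters,
                 mean_ranks = rbar, n = n_i, alpha = alpha,
                 p_adjust = p_adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n", x$H, x$df,
              x$p_value))
  cat("letters:", paste(sprintf("%s=%s", names(x$letters), x$letters),
                        collapse = "  "), "\n")
  invisible(x)
}

#' Compact-letter display by insert-and-absorb
#'
#' Builds letter codes such that two levels share a letter if and only if
#' their difference is not significant at `alpha`, using the
#' insert-and-absorb algorithm over the significance graph.
#'
#' @param pairwise `data.frame` with `level1`, `level2`, `p_adj`.
#' @param levels Character vector of all level names.
#' @param alpha Significance threshold.
#' @param order_by Optional numeric used to order letter assignment (e.g.
#'   decreasing mean rank); purely cosmetic.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(pairwise, levels, alpha = 0.05, order_by = NULL) {
  cols <- list(levels)                      # start: one column with all levels
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$level1[i]; b <- sig$level2[i]
    for (k in rev(seq_along(cols))) {
      if (a %in% cols[[k]] && b %in% cols[[k]]) {
        cols[[length(cols) + 1]] <- setdiff(cols[[k]], a)
        cols[[k]] <- setdiff(cols[[k]], b)
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (k in seq_along(cols)) for (m in seq_along(cols)) {
      if (k != m && keep[k] && keep[m] && all(cols[[k]] %in% cols[[m]]) &&
          length(cols[[k]]) < length(cols[[m]])) keep[k] <- FALSE
    }
    # identical duplicates: keep the first
    sig_cols <- vapply(cols, function(cc) paste(sort(cc), collapse = "/"),
                       character(1))
    keep <- keep & !duplicated(sig_cols)
    cols <- cols[keep]
  }
  if (!is.null(order_by)) {
    ord <- order(vapply(cols, function(cc) {
      min(order_by[match(cc, levels)])
    }, numeric(1)))
    cols <- cols[ord]
  }
  out <- stats::setNames(rep("", length(levels)), levels)
  for (k in seq_along(cols)) {
    for (lv in cols[[k]]) out[lv] <- paste0(out[lv], letters[k])
  }
  out
}

# ---- ANOVA variance partition -----------------------------------------------

#' Partition normalized-lag variance by multifactorial ANOVA
#'
#' Fits a linear model of the response on the listed factor terms (main
#' effects and interactions, e.g. `c("dose", "strain", "dose:strain")`) and
#' reports each term's sum of squares as a percentage of the total (terms
#' plus residual). Type II sums of squares are the default because the
#' screening design becomes unbalanced once censored lags are dropped; Type
#' I (sequential) is available for legacy comparison.
#'
#' @param records `data.frame` holding the response and factor columns;
#'   rows with a non-finite response are excluded (count logged).
#' @param response Response column name (default `"normalized_lag_days"`).
#' @param terms Character vector of model terms; `:` denotes interaction.
#' @param ss_type 2 (default) or 1.
#' @return Object of class `variance_partition`: `data.frame` with `term`,
#'   `df`, `sum_sq`, `fraction_pct` (sums to 100).
#' @export
anova_partition <- function(records, response = "normalized_lag_days",
                            terms = c("dose", "strain", "dose:strain"),
                            ss_type = 2) {
  y <- records[[response]]
  keep <- is.finite(y)
  if (sum(!keep)) {
    message(sprintf("%d record(s) with undefined/censored response excluded",
                    sum(!keep)))
  }
  dat <- records[keep, , drop = FALSE]
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(dat))
  if (length(missing_vars)) {
    stop(paste("missing factor column(s):", paste(missing_vars, collapse = ", ")),
         call. = FALSE)
  }
  for (v in vars) dat[[v]] <- factor(dat[[v]])
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = dat)
  al <- stats::alias(fit)
  if (!is.null(al$Complete) && nrow(al$Complete)) {
    stop(paste("rank-deficient design; aliased coefficients:",
               paste(rownames(al$Complete), collapse = ", ")), call. = FALSE)
  }
  # Type II requires a positive residual SS; a saturated/perfect fit reduces
  # to the sequential decomposition, which is then exact
  if (ss_type == 2 && stats::deviance(fit) < 1e-10 * sum((y[keep] - mean(y[keep]))^2)) {
    ss_type <- 1
  }
  if (ss_type == 2) {
    tab <- car::Anova(fit, type = 2)
    term_names <- rownames(tab)
    ss <- tab[["Sum Sq"]]; dfree <- tab[["Df"]]
  } else {
    tab <- stats::anova(fit)
    term_names <- rownames(tab)
    ss <- tab[["Sum Sq"]]; dfree <- tab[["Df"]]
  }
  resid_i <- which(term_names %in% c("Residuals", "Residual"))
  term_names[resid_i] <- "residuals"
  out <- data.frame(term = term_names, df = dfree, sum_sq = ss,
                    fraction_pct = 100 * ss / sum(ss), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("variance_partition", "data.frame"),
            ss_type = ss_type, n = nrow(dat))
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("ANOVA variance partition (type %s SS, n = %d):\n",
              attr(x, "ss_type"), attr(x, "n")))
  df <- as.data.frame(x)
  df$fraction_pct <- sprintf("%.1f%%", df$fraction_pct)
  print(df, row.names = FALSE)
  invisible(x)
}
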