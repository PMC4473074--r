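# Group-level inference on ratio records and cell-count tables: one-way
# ANOVA with Tukey HSD post-hoc per ion per timepoint, and percent-reduction
# summaries. alpha defaults to 0.05; no additional multiplicity correction
# is applied across ions (each channel is analyzed independently, a
# documented limitation).

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Runs an independent one-way ANOVA across group cells for each ion x
#' timepoint stratum, followed by Tukey's honestly-significant-difference
#' test for all group pairs.
#'
#' @param records Data frame with columns `group`, the measure, and the
#'   stratification columns in `by` (defaults suit the ratio table from
#'   [quantify_cohort()]; set `by = NULL` for a plain one-factor table).
#' @param measure Name of the response column (default `"ratio"`).
#' @param by Character vector of stratification columns; an ANOVA is run
#'   within each stratum.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param log_scale If `TRUE`, analyze `log(measure)`; ratio distributions
#'   are right-skewed and the log option symmetrizes them. Default `FALSE`
#'   (ratios are analyzed on the natural scale).
#' @return An object of class `"tukey_results"`: a data frame of pairwise
#'   comparisons (`group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`, plus the `by` columns) with the per-stratum ANOVA table
#'   (`F`, `df1`, `df2`, `p_overall`, `n`) in attribute `"anova"`.
#' @export
anova_tukey <- function(records, measure = "ratio",
                        by = c("ion", "timepoint_days"),
                        alpha = 0.05, log_scale = FALSE) {
  stopifnot(is.data.frame(records), measure %in% names(records),
            "group" %in% names(records))
  by <- intersect(by, names(records))
  records <- records[!is.na(records[[measure]]), , drop = FALSE]
  strata <- if (length(by)) {
    split(records, records[by], drop = TRUE, sep = " | ")
  } else {
    list(all = records)
  }
  comp <- list()
  anov <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    y <- d[[measure]]
    if (log_scale) {
      if (any(y <= 0)) stop("log scale requires positive values", call. = FALSE)
      y <- log(y)
    }
    g <- factor(d$group)
    if (nlevels(g) < 2L) {
      stop("stratum '", s, "' has fewer than 2 groups", call. = FALSE)
    }
    tab <- table(g)
    if (any(tab < 2L)) {
      stop("group '", names(tab)[tab < 2L][1L], "' in stratum '", s,
           "' has fewer than 2 observations", call. = FALSE)
    }
    fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
    av <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$g
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    res <- data.frame(
      group1 = vapply(pair, `[`, "", 1L),
      group2 = vapply(pair, `[`, "", 2L),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    res$significant <- res$p_adj < alpha
    if (length(by)) {
      for (j in seq_along(by)) res[[by[j]]] <- d[[by[j]]][1L]
      res <- res[, c(by, setdiff(names(res), by))]
    }
    comp[[s]] <- res
    an <- data.frame(F = av[1L, "F value"], df1 = av[1L, "Df"],
                     df2 = av[2L, "Df"], p_overall = av[1L, "Pr(>F)"],
                     n = length(y), stringsAsFactors = FALSE)
    if (length(by)) for (j in seq_along(by)) an[[by[j]]] <- d[[by[j]]][1L]
    anov[[s]] <- an
  }
  out <- do.call(rbind, comp)
  rownames(out) <- NULL
  structure(out,
            anova = do.call(rbind, c(anov, list(make.row.names = FALSE))),
            alpha = alpha, measure = measure,
            class = c("tukey_results", "data.frame"))
}

#' @export
print.tukey_results <- function(x, ...) {
  cat(sprintf(
    "Tukey HSD comparisons on '%s' (alpha = %g): %d pairs, %d significant\n",
    attr(x, "measure"), attr(x, "alpha"), nrow(x), sum(x$significant)))
  df <- as.data.frame(x)
  df$p_adj <- signif(df$p_adj, 3)
  df$diff <- signif(df$diff, 3)
  df$stars <- ifelse(x$significant, "*", "")
  print.data.frame(df[, setdiff(names(df), c("lwr", "upr"))],
                   row.names = FALSE)
  invisible(x)
}

#' Percent reduction in mean cell counts from 3 d to 21 d
#'
#' `100 * (mean_3d - mean_21d) / mean_3d` for one group and stain.
#'
#' @param table Cell-count data frame (see [read_cellcounts()]).
#' @param group Group label.
#' @param stain `"FJB"` or `"NeuN"`.
#' @return Percent reduction (positive when counts fell).
#' @export
percent_reduction <- function(table, group, stain = "FJB") {
  stopifnot(is.data.frame(table))
  d <- table[table$group == group & table$stain == stain, , drop = FALSE]
  m3 <- mean(d$count[d$timepoint_days == 3L])
  m21 <- mean(d$count[d$timepoint_days == 21L])
  if (!is.finite(m3) || !is.finite(m21)) {
    stop("both timepoints (3 d, 21 d) must be present for group '", group,
         "', stain '", stain, "'", call. = FALSE)
  }
  if (m3 == 0) {
    stop("mean count at 3 d is zero; percent reduction undefined",
         call. = FALSE)
  }
  100 * (m3 - m21) / m3
}

#' Test one group's 3 d vs 21 d contrast
#'
#' Fits a single one-way ANOVA over all group x timepoint cells and reports
#' the Tukey-adjusted comparison between the named group's two timepoints.
#' Treating each group x timepoint combination as one cell of a one-way
#' layout is an interpretive choice for cross-timepoint inference.
#'
#' @param records Ratio table restricted by `ion`.
#' @param ion Ion label to test.
#' @param group Group whose timecourse is tested.
#' @param measure Response column (default `"ratio"`).
#' @param alpha Significance level.
#' @return A one-row data frame: `ion`, `group`, `diff`, `p_adj`,
#'   `significant`.
#' @export
timecourse_test <- function(records, ion, group, measure = "ratio",
                            alpha = 0.05) {
  stopifnot(is.data.frame(records))
  d <- records[records$ion == ion & !is.na(records[[measure]]), ,
               drop = FALSE]
  if (!all(c(3L, 21L) %in% d$timepoint_days[d$group == group])) {
    stop("group '", group, "' needs observations at both 3 d and 21 d",
         call. = FALSE)
  }
  d$cell <- paste(d$group, d$timepoint_days, sep = ".")
  res <- anova_tukey(transform(d, group = cell), measure = measure,
                     by = NULL, alpha = alpha)
  want <- c(paste0(group, ".3"), paste0(group, ".21"))
  hit <- (res$group1 == want[1L] & res$group2 == want[2L]) |
         (res$group1 == want[2L] & res$group2 == want[1L])
  row <- res[hit, , drop = FALSE]
  data.frame(ion = ion, group = group, diff = row$diff,
             p_adj = row$p_adj, significant = row$significant,
             stringsAsFactors = FALSE)
}
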