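# Pipeline orchestration: validated configuration, file-driven
# quantification, group statistics and rendering.

.pipeline_defaults <- function() {
  list(
    panel = NULL,                 # NULL = default panel configuration
    baseline_window = 5,
    baseline_percentile = 0.10,
    detection_floor = "auto",
    alpha = 0.05,
    design = "design.csv",
    roi = "roi.csv",
    data_dir = ".",
    out_dir = "results",
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' A YAML file (or list) with any of the keys: `panel` (panel configuration
#' or path), `baseline_window`, `baseline_percentile`, `detection_floor`
#' (`"auto"` or a number), `alpha`, `design`, `roi`, `data_dir`, `out_dir`,
#' `seed`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or a named list; `NULL` gives the
#'   defaults.
#' @return Validated configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- .pipeline_defaults()
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (!identical(cfg$detection_floor, "auto")) {
    stopifnot(is.numeric(cfg$detection_floor), cfg$detection_floor >= 0)
  }
  stopifnot(cfg$baseline_window > 0,
            cfg$baseline_percentile >= 0, cfg$baseline_percentile <= 0.5,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Quantify a cohort from files
#'
#' Reads the design table, ROI file and each section's imzML, quantifies
#' every section ([quantify_section()]), applies the cohort-wide detection
#' filter, and writes the tidy ratio table. Deterministic for fixed inputs.
#'
#' @param config A [pipeline_config()] (list or YAML path). `design` and
#'   `roi` paths are resolved relative to `data_dir`, as are the
#'   `section_file` entries of the design.
#' @param write If `TRUE` (default when `out_dir` exists in the config),
#'   write `ratios.csv` under `out_dir`.
#' @return The ratio table (invisibly writes `ratios.csv`).
#' @export
run_quantify <- function(config = NULL, write = TRUE) {
  cfg <- pipeline_config(config)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(cfg$data_dir, p)
  }
  design_path <- resolve(cfg$design)
  if (!file.exists(design_path)) {
    stop("design file not found: ", design_path, call. = FALSE)
  }
  roi_path <- resolve(cfg$roi)
  if (!file.exists(roi_path)) {
    stop("ROI file not found: ", roi_path, call. = FALSE)
  }
  design <- read_design(design_path)
  rois <- read_roi(roi_path)
  panel <- if (is.null(cfg$panel)) build_panel() else build_panel(cfg$panel)
  recs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sec <- resolve(design$section_file[i])
    if (!file.exists(sec)) {
      stop("section file not found: ", sec, " (animal ",
           design$animal_id[i], ")", call. = FALSE)
    }
    message("quantifying section ", design$animal_id[i], " (", i, "/",
            nrow(design), ")")
    img <- read_imzml(sec, meta = list(
      animal_id = design$animal_id[i],
      group = design$group[i],
      timepoint_days = design$timepoint_days[i]))
    recs[[i]] <- tryCatch(
      quantify_section(img, rois, panel,
                       baseline_window = cfg$baseline_window,
                       baseline_percentile = cfg$baseline_percentile,
                       floor = cfg$detection_floor),
      error = function(e) {
        stop("section ", design$animal_id[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out <- detection_filter(out)
  if (write && !is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(cfg$out_dir, "ratios.csv"),
                     row.names = FALSE)
  }
  out
}

#' Group statistics and figures for a ratio table
#'
#' Runs the per-ion, per-timepoint one-way ANOVA with Tukey post-hoc
#' ([anova_tukey()]), writes the comparison table, and renders one bar
#' chart per ion x timepoint with significance asterisks over groups that
#' differ from both control and sham.
#'
#' @param records Ratio table from [run_quantify()] / [quantify_cohort()].
#' @param alpha Significance level.
#' @param out_dir Output directory for `comparisons.csv` and figures;
#'   `NULL` skips writing.
#' @param fig_format `"pdf"` (default) or `"png"`.
#' @return The `"tukey_results"` object, invisibly when writing.
#' @export
run_stats <- function(records, alpha = 0.05, out_dir = NULL,
                      fig_format = c("pdf", "png")) {
  fig_format <- match.arg(fig_format)
  if (length(unique(records$group)) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  res <- anova_tukey(records, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res),
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(res, "anova"), file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    for (ion in unique(records$ion)) {
      for (tp in unique(records$timepoint_days[records$ion == ion])) {
        safe <- gsub("[^A-Za-z0-9]+", "_", paste0(ion, "_", tp, "d"))
        f <- file.path(out_dir, paste0(safe, ".", fig_format))
        if (fig_format == "pdf") {
          grDevices::pdf(f, width = 5, height = 4)
        } else {
          grDevices::png(f, width = 500, height = 400)
        }
        tryCatch(plot_ratio_bars(records, res, ion, tp),
                 finally = grDevices::dev.off())
      }
    }
    return(invisible(res))
  }
  res
}

#' Bar chart of group ratios with significance asterisks
#'
#' Mean +/- SEM of the ipsi/contra ratio per group for one ion and
#' timepoint. An asterisk marks groups whose Tukey comparison against both
#' control and sham (or against all reference groups present) is
#' significant.
#'
#' @param records Ratio table.
#' @param results `"tukey_results"` from [anova_tukey()].
#' @param ion Ion label.
#' @param timepoint_days Timepoint to plot.
#' @param ref_groups Reference groups an asterisked group must differ from;
#'   intersected with the groups present.
#' @export
plot_ratio_bars <- function(records, results, ion, timepoint_days,
                            ref_groups = c("control", "sham")) {
  d <- records[records$ion == ion &
                 records$timepoint_days == timepoint_days &
                 !is.na(records$ratio), , drop = FALSE]
  if (!nrow(d)) stop("no data for ", ion, " at ", timepoint_days, " d",
                     call. = FALSE)
  groups <- intersect(.group_levels, unique(d$group))
  m <- vapply(groups, function(g) mean(d$ratio[d$group == g]), numeric(1))
  s <- vapply(groups, function(g) {
    x <- d$ratio[d$group == g]
    stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  r <- as.data.frame(results)
  r <- r[r$ion == ion & r$timepoint_days == timepoint_days, , drop = FALSE]
  refs <- intersect(ref_groups, groups)
  starred <- vapply(groups, function(g) {
    if (g %in% refs || !length(refs)) return(FALSE)
    all(vapply(refs, function(ref) {
      hit <- (r$group1 == g & r$group2 == ref) |
             (r$group1 == ref & r$group2 == g)
      any(hit & r$significant)
    }, logical(1)))
  }, logical(1))
  ylim <- c(0, max(m + s) * 1.25)
  bp <- graphics::barplot(m, names.arg = groups, ylim = ylim,
                          ylab = "ipsilateral / contralateral ratio",
                          main = sprintf("%s, %d d", ion, timepoint_days),
                          col = "grey80", las = 2)
  has_bar <- is.finite(s) & s > 0
  if (any(has_bar)) {
    graphics::arrows(bp[has_bar], (m - s)[has_bar], bp[has_bar],
                     (m + s)[has_bar], angle = 90, code = 3, length = 0.04)
  }
  graphics::abline(h = 1, lty = 3)
  if (any(starred)) {
    graphics::text(bp[starred], (m + s)[starred] + 0.06 * ylim[2L], "*",
                   cex = 1.5)
  }
  invisible(data.frame(group = groups, mean = m, sem = s,
                       starred = starred))
}
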