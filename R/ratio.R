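# The per-animal, per-ion ipsilateral/contralateral ratio: the unit of all
# downstream statistics. Averaging over the ROI first and integrating the
# averaged spectrum follows the depicted workflow order; with a
# percentile-0 baseline the two orders commute.

#' Quantify one section: per-ion ipsi/contra AUC ratios
#'
#' For each panel ion, averages the spectra inside the ipsilateral and the
#' (mirrored) contralateral ROI, subtracts the moving low-percentile
#' baseline from each averaged spectrum, integrates the ion window on both,
#' and records the ipsilateral / contralateral area ratio. Because each
#' lesioned region is compared against the same animal's own contralateral
#' tissue, per-section multiplicative factors (matrix application,
#' ion-suppression scale, detector gain) cancel from the ratio.
#'
#' Ions whose contralateral or ipsilateral area falls below the detection
#' floor are flagged `"below_detection"` and their ratio is set to `NA`;
#' [detection_filter()] removes such ions cohort-wide.
#'
#' @param image A continuous-mode [msi_image()]; metadata (`animal_id`,
#'   `group`, `timepoint_days`) is read from `image$meta`.
#' @param rois An `"roi_pair"` from [roi_pair()] or [read_roi()].
#' @param panel An `"ion_panel"` from [build_panel()].
#' @param baseline_window,baseline_percentile Baseline parameters, see
#'   [subtract_baseline()].
#' @param floor Detection floor on the area scale; `"auto"` (default)
#'   estimates it as 3 x MAD of the baseline-subtracted contralateral
#'   spectrum in signal-free regions ([detection_floor()]); a number uses
#'   that value; 0 disables flagging.
#' @return A data frame with one row per ion: `animal_id`, `group`,
#'   `timepoint_days`, `ion`, `species`, `ceramide`, `adduct`, `mz`,
#'   `ipsi_area`, `contra_area`, `ratio`, `flag`.
#' @export
quantify_section <- function(image, rois, panel,
                             baseline_window = 5,
                             baseline_percentile = 0.10,
                             floor = "auto") {
  stopifnot(inherits(image, "msi_image"), inherits(rois, "roi_pair"),
            inherits(panel, "ion_panel"))
  ipsi_idx <- roi_mask(image, rois$ipsi)
  contra_idx <- roi_mask(image, rois$contra)
  if (length(intersect(ipsi_idx, contra_idx))) {
    stop("ipsilateral and contralateral masks overlap", call. = FALSE)
  }
  ipsi <- subtract_baseline(average_spectrum(image, ipsi_idx),
                            baseline_window, baseline_percentile)
  contra <- subtract_baseline(average_spectrum(image, contra_idx),
                              baseline_window, baseline_percentile)
  if (identical(floor, "auto")) {
    floor <- detection_floor(contra, panel)
  }
  stopifnot(is.numeric(floor), floor >= 0)

  meta <- image$meta
  pick <- function(k) if (is.null(meta[[k]])) NA else meta[[k]]
  out <- panel
  class(out) <- "data.frame"
  out$ipsi_area <- vapply(seq_len(nrow(panel)), function(i) {
    integrate_peak(ipsi, panel[i, ])
  }, numeric(1))
  out$contra_area <- vapply(seq_len(nrow(panel)), function(i) {
    integrate_peak(contra, panel[i, ])
  }, numeric(1))
  below <- out$ipsi_area < floor | out$contra_area < floor
  out$ratio <- ifelse(below, NA_real_, out$ipsi_area / out$contra_area)
  out$flag <- ifelse(below, "below_detection", "")
  cbind(
    data.frame(animal_id = pick("animal_id"),
               group = pick("group"),
               timepoint_days = pick("timepoint_days"),
               stringsAsFactors = FALSE),
    out[, c("ion", "species", "ceramide", "adduct", "mz",
            "ipsi_area", "contra_area", "ratio", "flag")]
  )
}

#' Drop ions below the detection threshold cohort-wide
#'
#' Removes every ion whose ipsilateral or contralateral area fell below the
#' floor in any animal of the cohort, and reports which ions were dropped.
#' This mirrors the treatment of channels whose signal does not rise above
#' noise in any animal (e.g. a d20:1 channel of a low-abundance species).
#'
#' @param records Ratio table from [quantify_section()] /
#'   [quantify_cohort()] rows bound together.
#' @param floor Optional numeric floor re-applied to the stored areas; by
#'   default the `"below_detection"` flags set at quantification time are
#'   used. `floor = 0` is the identity.
#' @return The records with below-detection ions removed entirely.
#' @export
detection_filter <- function(records, floor = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(floor)) {
    below <- records$flag == "below_detection"
  } else {
    stopifnot(is.numeric(floor), floor >= 0)
    below <- records$ipsi_area < floor | records$contra_area < floor
  }
  bad_ions <- unique(records$ion[below])
  if (length(bad_ions)) {
    message("below detection in at least one animal, dropped: ",
            paste(bad_ions, collapse = "; "))
  }
  out <- records[!records$ion %in% bad_ions, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all ions fell below the detection floor", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Quantify a cohort of sections
#'
#' Applies [quantify_section()] to each section and binds the tidy records.
#'
#' @param images List of [msi_image()] objects with populated metadata.
#' @param rois A single `"roi_pair"` shared by all sections, or a list of
#'   pairs (one per section).
#' @param panel An `"ion_panel"`.
#' @param ... Passed to [quantify_section()].
#' @param filter If `TRUE` (default), apply [detection_filter()] to the
#'   combined records.
#' @return The combined ratio table.
#' @export
quantify_cohort <- function(images, rois, panel, ..., filter = TRUE) {
  stopifnot(is.list(images), length(images) > 0L)
  shared <- inherits(rois, "roi_pair")
  recs <- lapply(seq_along(images), function(i) {
    r <- if (shared) rois else rois[[i]]
    quantify_section(images[[i]], r, panel, ...)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (filter) out <- detection_filter(out)
  out
}
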