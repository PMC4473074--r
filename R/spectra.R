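# ROI spectral averaging, moving low-percentile baseline subtraction, and
# windowed trapezoidal peak integration.

#' Construct a mass spectrum
#'
#' @param mz Strictly increasing m/z axis (Da).
#' @param intensity Non-negative intensities, same length.
#' @return An object of class `"mass_spectrum"`.
#' @export
mass_spectrum <- function(mz, intensity) {
  .check_spectrum(mz, intensity)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d bins, %.4f - %.4f Da, TIC %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Average the spectra of a set of pixels
#'
#' Arithmetic mean of intensities per m/z bin over the masked pixels; the
#' shared axis is unchanged. Continuous-mode images only: processed-mode
#' images must be resampled onto a common axis first.
#'
#' @param image An [msi_image()] in continuous mode.
#' @param mask Integer pixel indices, e.g. from [roi_mask()].
#' @return A [mass_spectrum()].
#' @export
average_spectrum <- function(image, mask) {
  stopifnot(inherits(image, "msi_image"))
  if (image$mode != "continuous") {
    stop("average_spectrum needs a shared m/z axis; resample the ",
         "processed-mode image onto a common axis first", call. = FALSE)
  }
  if (!length(mask)) stop("empty pixel mask", call. = FALSE)
  stopifnot(all(mask >= 1L), all(mask <= nrow(image$coords)))
  mass_spectrum(image$mz, colMeans(image$intensities[mask, , drop = FALSE]))
}

# Rolling quantile with partial edge windows. The quantile is evaluated on
# a decimated set of anchor positions (every k/8 bins) and linearly
# interpolated: the baseline is a slowly varying curve by definition, so
# anchor spacing well below the window width loses nothing.
.rolling_percentile <- function(x, k, p) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  stride <- max(1L, k %/% 8L)
  pos <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(pos, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = p, names = FALSE, type = 7)
  }, numeric(1))
  if (length(pos) == n) q else stats::approx(pos, q, xout = seq_len(n))$y
}

# O(n) centered moving average with shrinking edge windows
.rolling_mean <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Subtract a moving low-percentile baseline
#'
#' The baseline is estimated as the running `percentile` quantile of the
#' intensities within a `window`-Da moving window, smoothed once with a
#' moving average of the same width; the result is
#' `max(0, intensity - baseline)`, so output never exceeds input and is
#' never negative. This tracks the slowly varying MALDI matrix/chemical
#' baseline while ignoring isolated analyte peaks.
#'
#' @param spectrum A [mass_spectrum()].
#' @param window Baseline window width in Da (default 5).
#' @param percentile Quantile tracked as baseline, in `[0, 0.5]`
#'   (default 0.10).
#' @return A [mass_spectrum()] with attribute `"baseline"` holding the
#'   estimate that was subtracted.
#' @export
subtract_baseline <- function(spectrum, window = 5, percentile = 0.10) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (percentile < 0 || percentile > 0.5) {
    stop("percentile must be in [0, 0.5]", call. = FALSE)
  }
  step <- stats::median(diff(spectrum$mz))
  k <- max(1L, round(window / step))
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L) {
    stop("baseline window narrower than 3 bins at this axis spacing",
         call. = FALSE)
  }
  base <- .rolling_mean(.rolling_percentile(spectrum$intensity, k,
                                            percentile), k)
  out <- pmax(0, spectrum$intensity - base)
  structure(mass_spectrum(spectrum$mz, out), baseline = base)
}

#' Integrate the area under a peak window
#'
#' Trapezoidal area of the (already baseline-subtracted) intensity over
#' `[mz - window, mz + window]` on the native axis; no peak fitting.
#'
#' @param spectrum A [mass_spectrum()].
#' @param mz Window center (Da), or a one-row ion record from
#'   [build_panel()] (in which case `window` is taken from it).
#' @param window Half-width (Da).
#' @return Area in intensity * Da (non-negative for non-negative input).
#' @export
integrate_peak <- function(spectrum, mz, window = 0.5) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (is.data.frame(mz)) {
    stopifnot(nrow(mz) == 1L)
    window <- mz$window
    mz <- mz$mz
  }
  lo <- mz - window
  hi <- mz + window
  ax <- spectrum$mz
  if (lo < ax[1L] || hi > ax[length(ax)]) {
    stop(sprintf(
      "integration window [%.4f, %.4f] outside spectrum axis [%.4f, %.4f]",
      lo, hi, ax[1L], ax[length(ax)]), call. = FALSE)
  }
  idx <- which(ax >= lo & ax <= hi)
  if (length(idx) < 2L) {
    stop("integration window spans fewer than 2 axis points", call. = FALSE)
  }
  pracma::trapz(ax[idx], spectrum$intensity[idx])
}

#' Estimate the detection floor from signal-free regions
#'
#' Computes 3 x the median absolute deviation of the baseline-subtracted
#' intensity outside all panel integration windows (each widened by
#' `margin` Da), scaled by the panel window width so the floor is on the
#' area scale (intensity * Da).
#'
#' @param spectrum A baseline-subtracted [mass_spectrum()].
#' @param panel An `"ion_panel"` from [build_panel()].
#' @param margin Extra exclusion around each window (Da); default 2.
#' @param k Multiplier on the MAD; default 3.
#' @return The detection floor (area units).
#' @export
detection_floor <- function(spectrum, panel, margin = 2, k = 3) {
  stopifnot(inherits(spectrum, "mass_spectrum"), inherits(panel, "ion_panel"))
  quiet <- rep(TRUE, length(spectrum$mz))
  for (i in seq_len(nrow(panel))) {
    quiet <- quiet & (spectrum$mz < panel$mz[i] - panel$window[i] - margin |
                      spectrum$mz > panel$mz[i] + panel$window[i] + margin)
  }
  if (!any(quiet)) {
    stop("no signal-free region left to estimate the detection floor",
         call. = FALSE)
  }
  k * stats::mad(spectrum$intensity[quiet], center = 0) *
    2 * stats::median(panel$window)
}

#' Per-pixel ion intensity map
#'
#' Baseline-subtracted window area of one ion channel computed pixel by
#' pixel. For speed the per-pixel baseline is estimated on the spectrum
#' cropped to the window plus two baseline windows on each side.
#'
#' @param image A continuous-mode [msi_image()].
#' @param ion One-row ion record from [build_panel()], or a numeric m/z
#'   (with `window`).
#' @param window Half-width (Da) when `ion` is numeric.
#' @param baseline_window,baseline_percentile Baseline parameters as in
#'   [subtract_baseline()].
#' @return A numeric matrix (rows = y, columns = x, NA where no pixel was
#'   acquired) of class `"ion_map"`, with attributes `mz` and `ion`.
#' @export
ion_image <- function(image, ion, window = 0.5, baseline_window = 5,
                      baseline_percentile = 0.10) {
  stopifnot(inherits(image, "msi_image"))
  if (image$mode != "continuous") {
    stop("ion_image needs a continuous-mode image", call. = FALSE)
  }
  label <- NULL
  if (is.data.frame(ion)) {
    stopifnot(nrow(ion) == 1L)
    label <- ion$ion
    window <- ion$window
    ion <- ion$mz
  }
  ax <- image$mz
  lo <- ion - window - 2 * baseline_window
  hi <- ion + window + 2 * baseline_window
  keep <- which(ax >= max(lo, ax[1L]) & ax <= min(hi, ax[length(ax)]))
  sub_ax <- ax[keep]
  areas <- vapply(seq_len(nrow(image$coords)), function(i) {
    sp <- mass_spectrum(sub_ax, image$intensities[i, keep])
    sp <- subtract_baseline(sp, baseline_window, baseline_percentile)
    integrate_peak(sp, ion, window)
  }, numeric(1))
  nx <- max(image$coords[, "x"]) + 1L
  ny <- max(image$coords[, "y"]) + 1L
  m <- matrix(NA_real_, nrow = ny, ncol = nx)
  m[cbind(image$coords[, "y"] + 1L, image$coords[, "x"] + 1L)] <- areas
  structure(m, class = c("ion_map", "matrix"), mz = ion, ion = label)
}

#' Render an ion map
#'
#' Grey-scale rendering with low intensities dark and high intensities
#' light, plus an intensity bar.
#'
#' @param x An `"ion_map"`.
#' @param main Plot title; defaults to the ion label.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ion_map <- function(x, main = attr(x, "ion"), ...) {
  m <- unclass(x)
  rng <- range(m, na.rm = TRUE)
  pal <- grDevices::gray.colors(256, start = 0, end = 1)
  old <- graphics::par(mar = c(2, 2, 3, 5))
  on.exit(graphics::par(old))
  graphics::image(
    x = seq_len(ncol(m)) - 1L, y = seq_len(nrow(m)) - 1L,
    z = t(m), col = pal, zlim = rng, useRaster = TRUE,
    xlab = "x", ylab = "y", main = if (is.null(main)) "" else main,
    ylim = c(nrow(m) - 0.5, -0.5), asp = 1, ...)
  # intensity bar
  usr <- graphics::par("usr")
  xl <- usr[2] + 0.02 * diff(usr[1:2])
  xr <- usr[2] + 0.06 * diff(usr[1:2])
  yy <- seq(usr[3], usr[4], length.out = 257)
  graphics::rect(xl, yy[-257], xr, yy[-1], col = pal, border = NA, xpd = NA)
  graphics::text(xr, c(usr[3], usr[4]),
                 labels = sprintf("%.3g", c(rng[2], rng[1])),
                 pos = 4, xpd = NA, cex = 0.7)
  invisible(x)
}

#' Export a spectrum as two-column delimited text
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path (tab-separated, columns `mz`, `intensity`).
#' @return Invisibly, the path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  utils::write.table(
    data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
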