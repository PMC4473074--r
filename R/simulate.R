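# Synthetic spectral-image generator. Emulates 10 um-section, 100 um-pitch
# negative-mode acquisitions of a unilateral striatal lesion: Gaussian
# ganglioside peaks at the panel m/z values, a smooth polynomial chemical
# baseline, one multiplicative log-normal gain per section (tissue
# heterogeneity / sample preparation / ion suppression acting on the whole
# section), and additive Gaussian detector noise. Inside the lesion ellipse
# each ion's peak amplitude is multiplied by its configured fold change;
# contralateral tissue is always at fold 1, the anchor of the ratio design.

#' Default effect table: qualitative lesion findings as fold changes
#'
#' Encodes which ions are elevated or reduced ipsilaterally in which group
#' at which timepoint. Directions follow the biology the generator emulates;
#' the magnitudes (`fold_up` = 1.8, `fold_down` = 0.6) are generator
#' defaults, not measured values. Groups without entries (control, sham,
#' abeta alone) are 1 everywhere.
#'
#' @param fold_up,fold_down Fold changes used for "elevated" and "reduced".
#' @return Data frame with columns `ion`, `group`, `timepoint_days`,
#'   `fold`.
#' @export
default_fold_table <- function(fold_up = 1.8, fold_down = 0.6) {
  e <- function(ion, group, tp, fold) {
    expand.grid(ion = ion, group = group, timepoint_days = tp,
                fold = fold, stringsAsFactors = FALSE)
  }
  rbind(
    # GM2, both ceramides: up at 3 d after stroke with or without abeta;
    # still up at 21 d only with combined insult
    e(c("GM2 d18:1 [M-H]-", "GM2 d20:1 [M-H]-"),
      c("et1", "abeta_et1"), 3L, fold_up),
    e(c("GM2 d18:1 [M-H]-", "GM2 d20:1 [M-H]-"), "abeta_et1", 21L, fold_up),
    # GM3 d18:1: up at 3 d only in the combined group; at 21 d also in
    # stroke alone
    e("GM3 d18:1 [M-H]-", "abeta_et1", 3L, fold_up),
    e("GM3 d18:1 [M-H]-", c("et1", "abeta_et1"), 21L, fold_up),
    # GM1: d18:1 up at 3 d in the combined group; d20:1 up at both
    # timepoints in the combined group
    e("GM1 d18:1 [M-H]-", "abeta_et1", 3L, fold_up),
    e("GM1 d20:1 [M-H]-", "abeta_et1", c(3L, 21L), fold_up),
    # GD1a sodium adduct d18:1: up at 3 d in the combined group
    e("GD1a d18:1 [M-2H+Na]-", "abeta_et1", 3L, fold_up),
    # GD1a potassium adduct, both ceramides: down at 3 d after stroke
    # alone, recovered by 21 d
    e(c("GD1a d18:1 [M-2H+K]-", "GD1a d20:1 [M-2H+K]-"),
      "et1", 3L, fold_down)
  )
}

#' Default synthetic-acquisition configuration
#'
#' The shipped generator settings: a 40 x 26 pixel grid at 100 um pitch
#' (a striatal field of view), m/z axis 1160-1920 Da sampled every 0.1 Da,
#' Gaussian peaks of width sigma = 0.15 Da (reflectron-TOF-like), a
#' quadratic chemical baseline falling from 28 to 8 counts across the axis,
#' per-ion peak amplitudes between 45 and 110 counts with GM3 d20:1 at 0.4
#' (deliberately below the detection floor), additive noise sigma = 6, and
#' a per-section log-normal gain with sdlog = 0.3. The lesion is an ellipse
#' in the left hemisphere; the shipped ROI is the lesion ellipse padded by
#' one pixel, mirrored about the sagittal midline for the contralateral ROI.
#'
#' @param sigma_noise Additive Gaussian noise SD (counts); 0 for noiseless
#'   sections.
#' @param sigma_gain sdlog of the per-section log-normal gain.
#' @param fold_table Effect table, see [default_fold_table()].
#' @param nx,ny Grid size (pixels).
#' @param mz_step Axis spacing (Da).
#' @return A list of class `"effect_config"`.
#' @export
default_effect_config <- function(sigma_noise = 6, sigma_gain = 0.3,
                                  fold_table = default_fold_table(),
                                  nx = 40L, ny = 26L, mz_step = 0.1) {
  panel <- build_panel()
  amps <- c(
    "GM3 d18:1 [M-H]-"      = 60,
    "GM3 d20:1 [M-H]-"      = 0.4,   # below the detection floor by design
    "GM2 d18:1 [M-H]-"      = 80,
    "GM2 d20:1 [M-H]-"      = 55,
    "GM1 d18:1 [M-H]-"      = 110,
    "GM1 d20:1 [M-H]-"      = 70,
    "GD1a d18:1 [M-2H+Na]-" = 75,
    "GD1a d18:1 [M-2H+K]-"  = 65,
    "GD1a d20:1 [M-2H+Na]-" = 50,
    "GD1a d20:1 [M-2H+K]-"  = 45
  )
  stopifnot(all(panel$ion %in% names(amps)))
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), pitch_um = 100,
    mz_range = c(1160, 1920), mz_step = mz_step,
    panel = panel,
    amplitudes = amps,
    peak_sd = 0.15,
    baseline_coef = c(28, -30, 10),  # quadratic in (mz - lo) / (hi - lo)
    sigma_noise = sigma_noise,
    sigma_gain = sigma_gain,
    shot_noise = FALSE,
    lesion = list(cx = 10, cy = 12.5, rx = 5, ry = 6.5),
    midline_x = (nx - 1) / 2,
    roi_margin = 0,
    fold_table = fold_table
  ), class = "effect_config")
}

.mz_axis <- function(config) {
  seq(config$mz_range[1L], config$mz_range[2L], by = config$mz_step)
}

.baseline_curve <- function(config, mz) {
  u <- (mz - config$mz_range[1L]) / diff(config$mz_range)
  cf <- config$baseline_coef
  b <- rowSums(outer(u, seq_along(cf) - 1, `^`) *
               matrix(cf, length(u), length(cf), byrow = TRUE))
  if (any(b < 0)) stop("baseline model dips below zero", call. = FALSE)
  b
}

.fold_for <- function(config, ion, group, timepoint_days) {
  ft <- config$fold_table
  hit <- ft$ion == ion & ft$group == group &
    ft$timepoint_days == timepoint_days
  if (any(hit)) ft$fold[hit][1L] else 1
}

# 28-vertex polygon tracing the lesion ellipse (plus margin); this same
# polygon defines both the lesion mask and the shipped ipsilateral ROI, so
# the region averaged is exactly the region carrying the fold change.
.lesion_polygon <- function(config, margin = 0) {
  les <- config$lesion
  th <- seq(0, 2 * pi, length.out = 29L)[-29L]
  roi_polygon("ipsilateral",
              les$cx + (les$rx + margin) * cos(th),
              les$cy + (les$ry + margin) * sin(th))
}

#' The shipped ROI pair for a synthetic section
#'
#' The ipsilateral ROI traces the lesion boundary polygon (padded by
#' `roi_margin` pixels, default 0); the contralateral ROI is its mirror
#' about the sagittal midline. A positive margin mixes non-lesioned tissue
#' into the ipsilateral average and dilutes the recovered fold change
#' (partial-volume effect).
#'
#' @param config An `"effect_config"`.
#' @return An `"roi_pair"`.
#' @export
default_roi <- function(config) {
  ipsi <- .lesion_polygon(config, config$roi_margin)
  roi_pair(ipsi, config$midline_x,
           mirror_roi(ipsi, config$midline_x, xmax = config$nx))
}

#' Simulate one spectral image section
#'
#' Per-pixel spectrum: `gain * (baseline(mz) + sum_ions amplitude *
#' fold^(pixel in lesion) * Gaussian(mz; ion mz, peak_sd)) + noise`,
#' truncated at zero. The lesion mask, fold map, gain and seed are returned
#' as ground truth in attribute `"truth"`.
#'
#' @param config An `"effect_config"` from [default_effect_config()].
#' @param animal_id,group,timepoint_days Section metadata; `group` and
#'   `timepoint_days` select the fold changes from the effect table.
#' @param seed Optional integer seed for reproducibility.
#' @return An [msi_image()] with attribute `"truth"`.
#' @export
simulate_section <- function(config, animal_id = "a1", group = "control",
                             timepoint_days = 3L, seed = NULL) {
  stopifnot(inherits(config, "effect_config"))
  group <- match.arg(group, .group_levels)
  if (!is.null(seed)) set.seed(seed)
  les <- config$lesion
  if (les$cx - les$rx < 0 || les$cx + les$rx > config$nx - 1 ||
      les$cy - les$ry < 0 || les$cy + les$ry > config$ny - 1) {
    stop("lesion ellipse extends outside the pixel grid", call. = FALSE)
  }
  coords <- as.matrix(expand.grid(x = 0:(config$nx - 1L),
                                  y = 0:(config$ny - 1L)))
  n <- nrow(coords)
  mz <- .mz_axis(config)
  m <- length(mz)
  lesion <- .points_in_polygon(coords[, "x"], coords[, "y"],
                               .lesion_polygon(config)$vertices)

  intens <- matrix(.baseline_curve(config, mz), n, m, byrow = TRUE)
  folds <- numeric(nrow(config$panel))
  names(folds) <- config$panel$ion
  for (i in seq_len(nrow(config$panel))) {
    ion <- config$panel$ion[i]
    center <- config$panel$mz[i]
    f <- .fold_for(config, ion, group, timepoint_days)
    stopifnot(f > 0)
    folds[i] <- f
    amp <- config$amplitudes[[ion]]
    cols <- which(abs(mz - center) <= 5 * config$peak_sd)
    shape <- exp(-0.5 * ((mz[cols] - center) / config$peak_sd)^2)
    height <- amp * ifelse(lesion, f, 1)
    intens[, cols] <- intens[, cols] + outer(height, shape)
  }
  gain <- if (config$sigma_gain > 0) {
    stats::rlnorm(1L, meanlog = 0, sdlog = config$sigma_gain)
  } else 1
  intens <- gain * intens
  if (config$sigma_noise > 0) {
    intens <- intens + matrix(stats::rnorm(n * m, sd = config$sigma_noise),
                              n, m)
  }
  if (isTRUE(config$shot_noise)) {
    intens <- intens + matrix(stats::rnorm(n * m), n, m) *
      sqrt(pmax(intens, 0))
  }
  intens[intens < 0] <- 0
  img <- msi_image(
    coords, mz, intens, pitch_um = config$pitch_um, polarity = "negative",
    meta = list(section_id = paste0("sec_", animal_id),
                animal_id = animal_id, group = group,
                timepoint_days = as.integer(timepoint_days)))
  attr(img, "truth") <- list(lesion = lesion, folds = folds, gain = gain,
                             seed = seed)
  img
}

#' Default cohort design
#'
#' At 3 d all five groups (control, sham, abeta, et1, abeta_et1) are
#' acquired; at 21 d the three treatment groups (abeta, et1, abeta_et1).
#' `n` animals per group (default 4).
#'
#' @param timepoint_days 3 or 21.
#' @param n Animals per group.
#' @param groups Optional explicit group vector.
#' @return A design data frame (see [read_design()]).
#' @export
cohort_design <- function(timepoint_days = 3L, n = 4L, groups = NULL) {
  timepoint_days <- as.integer(timepoint_days)
  stopifnot(timepoint_days %in% .timepoint_levels)
  if (is.null(groups)) {
    groups <- if (timepoint_days == 3L) .group_levels else
      c("abeta", "et1", "abeta_et1")
  }
  if (n == 0L) {
    return(data.frame(animal_id = character(), group = character(),
                      timepoint_days = integer(),
                      section_file = character(),
                      stringsAsFactors = FALSE))
  }
  animal <- paste0(rep(groups, each = n), "_", timepoint_days, "d_",
                   rep(seq_len(n), length(groups)))
  data.frame(animal_id = animal,
             group = rep(groups, each = n),
             timepoint_days = timepoint_days,
             section_file = paste0("sec_", animal, ".imzML"),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of sections
#'
#' One section per design row, with per-animal seeds derived from the
#' master seed. With `dir` set, writes each section as imzML next to the
#' shared ROI table (`roi.csv`), the design table (`design.csv`) and a
#' ground-truth echo (`truth.yaml`); otherwise returns the images in
#' memory.
#'
#' @param config An `"effect_config"`.
#' @param design Design table; default [cohort_design()] at 3 d.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return Invisibly (with `dir`) or visibly, a list with `design`, `rois`
#'   and either `images` (in-memory) or `dir`.
#' @export
simulate_cohort <- function(config, design = cohort_design(),
                            seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "effect_config"))
  design <- validate_design(design)
  set.seed(seed)
  n <- nrow(design)
  seeds <- if (n) sample.int(.Machine$integer.max, n) else integer()
  rois <- default_roi(config)
  truths <- list()
  images <- if (is.null(dir)) vector("list", n) else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    img <- simulate_section(config, design$animal_id[i], design$group[i],
                            design$timepoint_days[i], seed = seeds[i])
    truths[[design$animal_id[i]]] <- list(
      folds = as.list(attr(img, "truth")$folds),
      gain = attr(img, "truth")$gain,
      seed = seeds[i])
    if (is.null(dir)) {
      images[[i]] <- img
    } else {
      write_imzml(img, file.path(dir, design$section_file[i]))
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
    write_roi(rois, file.path(dir, "roi.csv"))
    yaml::write_yaml(list(master_seed = seed, animals = truths),
                     file.path(dir, "truth.yaml"))
    invisible(list(design = design, rois = rois, dir = dir))
  } else {
    list(design = design, rois = rois, images = images, truth = truths)
  }
}

#' Default cell-count generator configuration
#'
#' Mean counts per (group, stain, timepoint) cell chosen so that FJB counts
#' fall 35% from 3 d to 21 d in the combined abeta_et1 group and 65% in the
#' et1 group, and NeuN counts are equal across the two groups at 3 d but
#' lower in the combined group at 21 d. Counts are negative binomial with
#' dispersion `size` (larger = closer to Poisson); n = 6 animals per cell.
#'
#' @param n Animals per cell.
#' @param size Negative-binomial dispersion; `Inf` gives Poisson.
#' @return A list of class `"cellcount_config"`.
#' @export
default_cellcount_config <- function(n = 6L, size = 40) {
  means <- rbind(
    data.frame(group = "et1",       stain = "FJB",  timepoint_days = 3L,
               mean = 250),
    data.frame(group = "et1",       stain = "FJB",  timepoint_days = 21L,
               mean = 87.5),
    data.frame(group = "abeta_et1", stain = "FJB",  timepoint_days = 3L,
               mean = 250),
    data.frame(group = "abeta_et1", stain = "FJB",  timepoint_days = 21L,
               mean = 162.5),
    data.frame(group = "et1",       stain = "NeuN", timepoint_days = 3L,
               mean = 150),
    data.frame(group = "et1",       stain = "NeuN", timepoint_days = 21L,
               mean = 110),
    data.frame(group = "abeta_et1", stain = "NeuN", timepoint_days = 3L,
               mean = 150),
    data.frame(group = "abeta_et1", stain = "NeuN", timepoint_days = 21L,
               mean = 60)
  )
  structure(list(means = means, n = as.integer(n), size = size,
                 deterministic = FALSE),
            class = "cellcount_config")
}

#' Simulate a cell-count table
#'
#' Draws counts from a negative binomial with the configured means and
#' dispersion (`size = Inf` gives Poisson; `deterministic = TRUE` returns
#' the configured means exactly, the zero-variance mode).
#'
#' @param config A `"cellcount_config"` from [default_cellcount_config()].
#' @param seed Optional integer seed.
#' @return A cell-count data frame (animal_id, group, timepoint_days,
#'   stain, count).
#' @export
simulate_cellcounts <- function(config = default_cellcount_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "cellcount_config"))
  if (!is.null(seed)) set.seed(seed)
  if (any(config$means$mean <= 0)) {
    stop("cell-count means must be positive", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(config$means)), function(i) {
    cell <- config$means[i, ]
    counts <- if (isTRUE(config$deterministic)) {
      rep(cell$mean, config$n)
    } else if (is.infinite(config$size)) {
      stats::rpois(config$n, cell$mean)
    } else {
      stats::rnbinom(config$n, size = config$size, mu = cell$mean)
    }
    data.frame(
      animal_id = paste0(cell$group, "_", cell$timepoint_days, "d_",
                         seq_len(config$n)),
      group = cell$group, timepoint_days = cell$timepoint_days,
      stain = cell$stain, count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
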