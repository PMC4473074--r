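test_that("ROI averaging is idempotent, linear, and matches a naive loop", {
  mz <- seq(1000, 1020, by = 0.1)
  base <- abs(sin(mz)) + 1
  img <- flat_image(4, 4, mz = mz)
  # two identical spectra average to themselves
  img$intensities <- matrix(rep(base, each = 16), 16, length(mz))
  avg <- average_spectrum(img, c(1L, 2L))
  expect_equal(avg$intensity, base)
  # spectra a and 3a average to 2a
  img$intensities[2L, ] <- 3 * base
  expect_equal(average_spectrum(img, c(1L, 2L))$intensity, 2 * base)
  # 9-pixel mask against a brute-force per-bin mean
  set.seed(5)
  img$intensities <- matrix(runif(16 * length(mz)), 16, length(mz))
  mask <- c(1L, 2L, 3L, 5L, 6L, 7L, 9L, 10L, 11L)
  naive <- vapply(seq_along(mz), function(j) {
    s <- 0
    for (i in mask) s <- s + img$intensities[i, j]
    s / length(mask)
  }, numeric(1))
  expect_equal(average_spectrum(img, mask)$intensity, naive,
               tolerance = 1e-12)
})

test_that("averaging requires a shared axis and a non-empty mask", {
  proc <- msi_image(cbind(x = 0:1, y = c(0L, 0L)),
                    list(c(1, 2), c(1, 2)), list(c(0, 1), c(1, 0)))
  expect_error(average_spectrum(proc, 1L), "resample")
  expect_error(average_spectrum(flat_image(), integer(0)), "empty")
})

test_that("baseline subtraction removes a flat offset entirely at percentile 0", {
  mz <- seq(1000, 1050, by = 0.1)
  sp <- mass_spectrum(mz, rep(7.5, length(mz)))
  out <- subtract_baseline(sp, window = 5, percentile = 0)
  expect_equal(out$intensity, rep(0, length(mz)))
  expect_equal(attr(out, "baseline"), rep(7.5, length(mz)))
})

test_that("baseline subtraction preserves isolated peak areas within 5%", {
  mz <- seq(1000, 1100, by = 0.05)
  peak <- 40 * exp(-0.5 * ((mz - 1050) / 0.2)^2)
  injected <- pracma::trapz(mz, peak)
  # on a zero baseline
  sp0 <- subtract_baseline(mass_spectrum(mz, peak), window = 10,
                           percentile = 0.1)
  got0 <- integrate_peak(sp0, 1050, 2)
  expect_lt(abs(got0 - injected) / injected, 0.05)
  # on a linear ramp baseline with a slope typical of the slowly varying
  # MALDI chemical background (tens of counts over hundreds of Da)
  ramp <- 5 + 0.06 * (mz - 1000)
  spr <- subtract_baseline(mass_spectrum(mz, ramp + peak), window = 5,
                           percentile = 0.1)
  gotr <- integrate_peak(spr, 1050, 2)
  expect_lt(abs(gotr - injected) / injected, 0.05)
})

test_that("baseline subtraction never increases intensities or goes negative", {
  set.seed(42)
  for (rep in 1:5) {
    mz <- seq(1000, 1030, by = 0.1)
    y <- abs(rnorm(length(mz), 10, 3)) +
      30 * exp(-0.5 * ((mz - sample(1005:1025, 1)) / 0.2)^2)
    out <- subtract_baseline(mass_spectrum(mz, y), window = 4,
                             percentile = runif(1, 0, 0.5))
    expect_true(all(out$intensity >= 0))
    expect_true(all(out$intensity <= y + 1e-12))
  }
})

test_that("too-narrow baseline windows are rejected", {
  sp <- mass_spectrum(seq(1000, 1010, by = 1), rep(1, 11))
  expect_error(subtract_baseline(sp, window = 1), "3 bins")
  expect_error(subtract_baseline(sp, window = -2), "positive")
  expect_error(subtract_baseline(sp, window = 5, percentile = 0.9),
               "0, 0.5")
})

test_that("peak integration matches analytic areas", {
  mz <- seq(999, 1001, by = 0.001)
  # zero spectrum
  expect_equal(integrate_peak(mass_spectrum(mz, rep(0, length(mz))),
                              1000, 0.5), 0)
  # unit rectangle of width w integrated over exactly its support
  w <- 0.4
  y <- as.numeric(mz >= 1000 - w / 2 & mz <= 1000 + w / 2)
  expect_equal(integrate_peak(mass_spectrum(mz, y), 1000, w / 2), w,
               tolerance = 1e-9)
  # Gaussian amplitude A, sd s fully inside the window: area A*s*sqrt(2*pi)
  A <- 12; s <- 0.05
  g <- A * exp(-0.5 * ((mz - 1000) / s)^2)
  got <- integrate_peak(mass_spectrum(mz, g), 1000, 0.5)
  expect_lt(abs(got - A * s * sqrt(2 * pi)) / (A * s * sqrt(2 * pi)), 0.01)
  # windows outside the axis are an error
  expect_error(integrate_peak(mass_spectrum(mz, g), 1001, 0.5), "outside")
})

test_that("integration is linear and commutes with ROI averaging", {
  cfg <- tiny_config()
  img <- simulate_section(cfg, "a", "et1", 3L, seed = 2)
  panel <- cfg$panel
  mask <- roi_mask(img, default_roi(cfg)$ipsi)
  # area of the mean equals the mean of per-pixel areas (shared axis, no
  # baseline subtraction: both are linear in the intensities)
  for (i in seq_len(nrow(panel))) {
    mean_area <- integrate_peak(average_spectrum(img, mask), panel[i, ])
    per_pixel <- vapply(mask, function(px) {
      integrate_peak(mass_spectrum(img$mz, img$intensities[px, ]),
                     panel[i, ])
    }, numeric(1))
    expect_equal(mean_area, mean(per_pixel), tolerance = 1e-9)
  }
  # k-fold intensity scaling scales areas k-fold (percentile-0 baseline)
  sp <- average_spectrum(img, mask)
  a1 <- integrate_peak(subtract_baseline(sp, percentile = 0), panel[1, ])
  sp3 <- mass_spectrum(sp$mz, 3 * sp$intensity)
  a3 <- integrate_peak(subtract_baseline(sp3, percentile = 0), panel[1, ])
  expect_equal(a3, 3 * a1, tolerance = 1e-9)
})

test_that("ion images are linear and light up the lesion", {
  cfg <- tiny_config()
  img <- simulate_section(cfg, "a", "et1", 3L, seed = 3)
  gm2 <- cfg$panel[cfg$panel$species == "GM2", ]
  map <- ion_image(img, gm2)
  truth <- attr(img, "truth")
  les <- img$coords[truth$lesion, , drop = FALSE]
  ctr <- img$coords[!truth$lesion, , drop = FALSE]
  les_vals <- map[cbind(les[, "y"] + 1L, les[, "x"] + 1L)]
  ctr_vals <- map[cbind(ctr[, "y"] + 1L, ctr[, "x"] + 1L)]
  expect_gt(min(les_vals), max(0, stats::median(ctr_vals)))
  expect_gt(mean(les_vals) / mean(ctr_vals), 1.5)

  # zero image maps to zero everywhere
  zero <- img
  zero$intensities[] <- 0
  expect_true(all(ion_image(zero, gm2) == 0))

  # scaling all intensities by k scales the map by k (percentile-0 baseline)
  m1 <- ion_image(img, gm2, baseline_percentile = 0)
  imgk <- img
  imgk$intensities <- img$intensities * 2
  m2 <- ion_image(imgk, gm2, baseline_percentile = 0)
  expect_equal(unclass(m2), 2 * unclass(m1), tolerance = 1e-9)

  # rendering runs on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(map))
})

test_that("spectra export as two-column text", {
  sp <- mass_spectrum(c(1, 2, 3), c(0, 5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read.delim(path)
  expect_equal(back$mz, sp$mz)
  expect_equal(back$intensity, sp$intensity)
})
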