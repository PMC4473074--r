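test_that("sections are reproducible under a fixed seed", {
  cfg <- tiny_config(sigma_noise = 4, sigma_gain = 0.3)
  a <- simulate_section(cfg, "a1", "et1", 3L, seed = 77)
  b <- simulate_section(cfg, "a1", "et1", 3L, seed = 77)
  expect_identical(a$intensities, b$intensities)
  expect_identical(attr(a, "truth")$gain, attr(b, "truth")$gain)
  # and the written imzML is byte-identical
  p1 <- withr::local_tempfile(fileext = ".imzML")
  p2 <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(a, p1)
  write_imzml(b, p2)
  expect_identical(unname(tools::md5sum(sub("imzML$", "ibd", p1))),
                   unname(tools::md5sum(sub("imzML$", "ibd", p2))))
})

test_that("the ground truth matches the generative model", {
  cfg <- tiny_config()
  img <- simulate_section(cfg, "a1", "et1", 3L, seed = 5)
  truth <- attr(img, "truth")
  # noiseless, gain 1: reconstruct one lesion and one contralateral pixel
  les_px <- which(truth$lesion)[1]
  ctr_px <- which(!truth$lesion)[1]
  f <- truth$folds[["GM2 d18:1 [M-H]-"]]
  expect_equal(f, 1.8)
  gm2 <- cfg$panel[cfg$panel$species == "GM2", ]
  i_peak <- which.min(abs(img$mz - gm2$mz))
  ctr_h <- img$intensities[ctr_px, i_peak]
  les_h <- img$intensities[les_px, i_peak]
  # noiseless, gain 1: the pixel difference is amplitude * (f - 1) * shape
  shape <- exp(-0.5 * ((img$mz[i_peak] - gm2$mz) / cfg$peak_sd)^2)
  amp <- cfg$amplitudes[["GM2 d18:1 [M-H]-"]]
  expect_equal(1 + (les_h - ctr_h) / (amp * shape), f, tolerance = 1e-9)
})

test_that("groups without configured effects stay at fold 1", {
  cfg <- tiny_config()
  for (g in c("control", "sham", "abeta")) {
    img <- simulate_section(cfg, "a", g, 3L, seed = 2)
    expect_true(all(attr(img, "truth")$folds == 1), label = g)
  }
})

test_that("the default effect table encodes the lesion response pattern", {
  ft <- default_fold_table()
  fold_of <- function(ion, group, tp) {
    hit <- ft$ion == ion & ft$group == group & ft$timepoint_days == tp
    if (any(hit)) ft$fold[hit] else 1
  }
  # stroke-alone GM2 elevation resolves by 21 d; combined persists
  expect_gt(fold_of("GM2 d18:1 [M-H]-", "et1", 3L), 1)
  expect_equal(fold_of("GM2 d18:1 [M-H]-", "et1", 21L), 1)
  expect_gt(fold_of("GM2 d20:1 [M-H]-", "abeta_et1", 21L), 1)
  # GM3 d18:1 appears in stroke-alone only at 21 d
  expect_equal(fold_of("GM3 d18:1 [M-H]-", "et1", 3L), 1)
  expect_gt(fold_of("GM3 d18:1 [M-H]-", "et1", 21L), 1)
  # potassiated GD1a dips at 3 d after stroke alone and recovers
  expect_lt(fold_of("GD1a d18:1 [M-2H+K]-", "et1", 3L), 1)
  expect_equal(fold_of("GD1a d18:1 [M-2H+K]-", "et1", 21L), 1)
  # amyloid alone never deviates from 1
  expect_false(any(ft$group %in% c("abeta", "control", "sham")))
  expect_true(all(ft$fold > 0))
})

test_that("cohorts have one section per design row and derived seeds", {
  cfg <- tiny_config(sigma_noise = 2)
  des <- cohort_design(3L, n = 1)
  out1 <- simulate_cohort(cfg, des, seed = 50)
  out2 <- simulate_cohort(cfg, des, seed = 50)
  expect_length(out1$images, 5L)
  expect_identical(out1$images[[3]]$intensities,
                   out2$images[[3]]$intensities)
  # different animals get different noise
  expect_false(identical(out1$images[[1]]$intensities,
                         out1$images[[2]]$intensities))
  # empty design: valid empty cohort
  empty <- simulate_cohort(cfg, cohort_design(3L, n = 0), seed = 1)
  expect_length(empty$images, 0L)
  expect_equal(nrow(empty$design), 0L)
})

test_that("cohorts written to disk carry design, ROI and ground truth", {
  cfg <- tiny_config(sigma_noise = 2)
  dir <- withr::local_tempdir()
  des <- cohort_design(3L, n = 1, groups = c("control", "et1"))
  simulate_cohort(cfg, des, seed = 3, dir = dir)
  expect_setequal(
    list.files(dir),
    c(des$section_file, sub("imzML$", "ibd", des$section_file),
      "design.csv", "roi.csv", "truth.yaml"))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$master_seed, 3)
  expect_setequal(names(truth$animals), des$animal_id)
  # the on-disk cohort reloads into the same spectra
  mem <- simulate_cohort(cfg, des, seed = 3)
  back <- read_imzml(file.path(dir, des$section_file[2]))
  expect_equal(back$intensities, unname(mem$images[[2]]$intensities))
})

test_that("cell counts follow the configured means", {
  cc <- default_cellcount_config()
  # zero-variance mode returns the configured means exactly
  det <- cc
  det$deterministic <- TRUE
  tab <- simulate_cellcounts(det)
  expect_equal(percent_reduction(tab, "abeta_et1", "FJB"), 35)
  expect_equal(percent_reduction(tab, "et1", "FJB"), 65)
  # NeuN: equal at 3 d, lower in the combined group at 21 d
  m <- function(g, tp) mean(tab$count[tab$group == g & tab$stain == "NeuN" &
                                        tab$timepoint_days == tp])
  expect_equal(m("et1", 3L), m("abeta_et1", 3L))
  expect_lt(m("abeta_et1", 21L), m("et1", 21L))

  # Poisson limit, large n: reduction converges to the configured 35%
  pois <- default_cellcount_config(n = 10000L, size = Inf)
  pois$means <- data.frame(group = "abeta_et1", stain = "FJB",
                           timepoint_days = c(3L, 21L), mean = c(100, 65))
  big <- simulate_cellcounts(pois, seed = 99)
  expect_lt(abs(percent_reduction(big, "abeta_et1", "FJB") - 35), 1)

  # invalid configuration
  bad <- cc
  bad$means$mean[1] <- 0
  expect_error(simulate_cellcounts(bad), "positive")
})

test_that("default-config cell counts reproduce the reductions in expectation", {
  reds <- vapply(1:200, function(i) {
    tab <- simulate_cellcounts(seed = 1000 + i)
    c(percent_reduction(tab, "et1", "FJB"),
      percent_reduction(tab, "abeta_et1", "FJB"))
  }, numeric(2))
  expect_lt(abs(mean(reds[1, ]) - 65), 1.5)
  expect_lt(abs(mean(reds[2, ]) - 35), 1.5)
})

test_that("a lesion outside the grid is rejected", {
  cfg <- tiny_config()
  cfg$lesion <- list(cx = 1, cy = 4, rx = 3, ry = 2)
  expect_error(simulate_section(cfg, seed = 1), "outside the pixel grid")
})
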