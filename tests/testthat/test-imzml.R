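grid_image <- function(nx = 4, ny = 4, drop_pixel = NULL, seed = 11) {
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)))
  if (!is.null(drop_pixel)) coords <- coords[-drop_pixel, , drop = FALSE]
  mz <- seq(1000, 1010, by = 0.25)
  ints <- matrix(round(abs(rnorm(nrow(coords) * length(mz))), 6),
                 nrow(coords), length(mz))
  msi_image(coords, mz, ints, pitch_um = 100)
}

test_that("continuous-mode imzML round-trips bit-exactly", {
  for (img in list(grid_image(1, 1), grid_image(4, 4),
                   grid_image(4, 4, drop_pixel = 7))) {
    path <- withr::local_tempfile(fileext = ".imzML")
    write_imzml(img, path)
    back <- read_imzml(path)
    expect_identical(back$mode, "continuous")
    expect_identical(back$coords, img$coords)
    expect_identical(back$mz, img$mz)
    expect_identical(back$intensities, unname(img$intensities))
    expect_identical(back$pitch_um, img$pitch_um)
    expect_identical(back$polarity, img$polarity)
  }
})

test_that("written imzML bytes are deterministic for fixed input", {
  img <- grid_image(3, 2)
  p1 <- withr::local_tempfile(fileext = ".imzML")
  p2 <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(img, p1)
  write_imzml(img, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_identical(
    unname(tools::md5sum(sub("imzML$", "ibd", p1))),
    unname(tools::md5sum(sub("imzML$", "ibd", p2))))
})

test_that("processed mode round-trips, including an empty spectrum", {
  coords <- cbind(x = c(0L, 1L, 2L), y = c(0L, 0L, 0L))
  mz <- list(c(1000, 1001.5, 1003), numeric(0), c(999.5, 1002))
  ints <- list(c(5, 0, 2.25), numeric(0), c(1, 7))
  img <- msi_image(coords, mz, ints)
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(img, path)
  back <- read_imzml(path)
  expect_identical(back$mode, "processed")
  expect_identical(back$coords, img$coords)
  expect_equal(back$mz, img$mz)
  expect_equal(back$intensities, img$intensities)
})

test_that("32-bit float encoding is read back at float precision", {
  img <- grid_image(2, 2)
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(img, path, mz_dtype = "32-bit float",
              intensity_dtype = "32-bit float")
  back <- read_imzml(path)
  expect_equal(back$mz, img$mz, tolerance = 1e-6)
  expect_equal(back$intensities, unname(img$intensities),
               tolerance = 1e-6)
  # re-writing the float32-truncated values round-trips exactly
  path2 <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(back, path2, mz_dtype = "32-bit float",
              intensity_dtype = "32-bit float")
  back2 <- read_imzml(path2)
  expect_identical(back2$intensities, back$intensities)
})

test_that("corrupt or missing companion files raise format errors", {
  img <- grid_image(2, 2)
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(img, path)
  ibd <- sub("imzML$", "ibd", path)
  # truncate the binary companion
  raw <- readBin(ibd, "raw", n = file.info(ibd)$size)
  writeBin(raw[1:(length(raw) - 40L)], ibd)
  expect_error(read_imzml(path), "truncated")
  unlink(ibd)
  expect_error(read_imzml(path), "missing binary companion")
  expect_error(read_imzml(withr::local_tempfile(fileext = ".imzML")),
               "no such file")
})

test_that("pyimzml parses our continuous-mode output identically", {
  img <- grid_image(3, 3)
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(img, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "for i, (x, y, z) in enumerate(p.coordinates):",
    "    mz, ii = p.getspectrum(i)",
    "    print(x, y, '%.9g' % sum(mz), '%.9g' % sum(ii))"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L,
              info = paste(out, collapse = "\n"))
  got <- read.table(text = out)
  expect_equal(nrow(got), nrow(img$coords))
  # pyimzml positions are 1-based
  expect_equal(got$V1, img$coords[, "x"] + 1L)
  expect_equal(got$V2, img$coords[, "y"] + 1L)
  expect_equal(got$V3, rep(sum(img$mz), nrow(img$coords)),
               tolerance = 1e-8)
  expect_equal(got$V4, unname(rowSums(img$intensities)), tolerance = 1e-8)
})

test_that("the design reader validates labels, duplicates and emptiness", {
  d <- cohort_design(3L)
  expect_equal(nrow(d), 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  back <- read_design(path)
  expect_equal(back$animal_id, d$animal_id)
  expect_equal(back$timepoint_days, d$timepoint_days)

  empty <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[0, ], empty, row.names = FALSE)
  expect_error(read_design(empty), "empty")

  dup <- rbind(d, d[1, ])
  pd <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, pd, row.names = FALSE)
  expect_error(read_design(pd), "duplicated")

  bad <- d
  bad$group[1] <- "lesion"
  pb <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, pb, row.names = FALSE)
  expect_error(read_design(pb), "control, sham, abeta, et1, abeta_et1")
})

test_that("cell-count tables are validated on read", {
  tab <- simulate_cellcounts(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read_cellcounts(path)
  expect_equal(back$count, tab$count)
  bad <- tab
  bad$count[1] <- -4L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cellcounts(path), "non-negative")
})
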