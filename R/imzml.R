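# imzML 1.1 reader/writer. Continuous mode stores one shared m/z axis and one
# intensity block per pixel; processed mode stores a (mz, intensity) pair per
# pixel. The binary companion (.ibd) starts with the 16-byte UUID echoed in
# the XML. Coordinates are written 1-based per the standard and exposed
# 0-based (x rightward, y downward).

#' Construct a spectral image
#'
#' A pixel grid of mass spectra with physical pitch and section metadata.
#' In continuous mode all pixels share one m/z axis and intensities form an
#' n_pixels x n_bins matrix; in processed mode each pixel carries its own
#' sorted axis.
#'
#' @param coords Integer matrix (n x 2) of 0-based pixel coordinates
#'   (columns x, y); x increases rightward, y downward. Rows must be unique.
#' @param mz Numeric ascending m/z axis (continuous mode) or a list of such
#'   axes, one per pixel (processed mode).
#' @param intensities Matrix n x length(mz) of non-negative intensities
#'   (continuous), or a list of vectors (processed).
#' @param pitch_um Physical pixel spacing in micrometres; default 100.
#' @param polarity `"negative"` or `"positive"`.
#' @param meta Named list of section metadata (`section_id`, `animal_id`,
#'   `group`, `timepoint_days`); kept outside the imzML file, normally
#'   populated from the study design table.
#' @return An object of class `"msi_image"`.
#' @export
msi_image <- function(coords, mz, intensities, pitch_um = 100,
                      polarity = c("negative", "positive"), meta = list()) {
  polarity <- match.arg(polarity)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (anyDuplicated(coords)) stop("duplicate pixel coordinates", call. = FALSE)
  if (any(coords < 0L)) stop("coordinates must be >= 0", call. = FALSE)
  if (!is.numeric(pitch_um) || pitch_um <= 0) {
    stop("pitch_um must be positive", call. = FALSE)
  }
  if (is.list(mz)) {
    mode <- "processed"
    stopifnot(length(mz) == nrow(coords), is.list(intensities),
              length(intensities) == nrow(coords))
    for (i in seq_along(mz)) {
      .check_spectrum(mz[[i]], intensities[[i]], where = paste("pixel", i))
    }
  } else {
    mode <- "continuous"
    intensities <- as.matrix(intensities)
    if (nrow(intensities) != nrow(coords) ||
        ncol(intensities) != length(mz)) {
      stop("intensity matrix must be n_pixels x length(mz)", call. = FALSE)
    }
    .check_spectrum(mz, intensities[1L, ], where = "shared axis")
    if (any(intensities < 0)) stop("negative intensities", call. = FALSE)
  }
  structure(
    list(coords = coords, mz = mz, intensities = intensities,
         pitch_um = pitch_um, polarity = polarity, mode = mode, meta = meta),
    class = "msi_image"
  )
}

.check_spectrum <- function(mz, intensity, where = "spectrum") {
  if (length(mz) != length(intensity)) {
    stop("m/z and intensity lengths differ (", where, ")", call. = FALSE)
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("m/z axis not strictly increasing (", where, ")", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("negative intensities (", where, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.msi_image <- function(x, ...) {
  cat(sprintf(
    "msi_image: %d pixels (%s mode), pitch %g um, %s polarity\n",
    nrow(x$coords), x$mode, x$pitch_um, x$polarity))
  if (x$mode == "continuous") {
    cat(sprintf("  m/z axis: %d bins, %.4f - %.4f Da\n",
                length(x$mz), min(x$mz), max(x$mz)))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

.ibd_sizes <- c("32-bit float" = 4L, "64-bit float" = 8L)
.ms_dtype_acc <- c("32-bit float" = "MS:1000521", "64-bit float" = "MS:1000523")

.uuid_from_payload <- function(payload_file) {
  hex <- unname(tools::md5sum(payload_file))
  bytes <- as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  fmt <- paste0("{", substr(hex, 1, 8), "-", substr(hex, 9, 12), "-",
                substr(hex, 13, 16), "-", substr(hex, 17, 20), "-",
                substr(hex, 21, 32), "}")
  list(bytes = bytes, text = fmt)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a spectral image as imzML
#'
#' Writes a standard-conformant imzML/ibd file pair. Output bytes are
#' deterministic for a fixed input: the UUID is derived from an MD5 digest
#' of the binary payload rather than drawn at random.
#'
#' @param image An [msi_image()].
#' @param path Output path; `".imzML"` is appended if missing, and the
#'   binary companion gets the same stem with `".ibd"`.
#' @param mz_dtype,intensity_dtype Binary encodings, `"64-bit float"`
#'   (default) or `"32-bit float"`. 64-bit round-trips bit-exactly.
#' @return Invisibly, the imzML path.
#' @export
write_imzml <- function(image, path, mz_dtype = "64-bit float",
                        intensity_dtype = "64-bit float") {
  stopifnot(inherits(image, "msi_image"))
  mz_dtype <- match.arg(mz_dtype, names(.ibd_sizes))
  intensity_dtype <- match.arg(intensity_dtype, names(.ibd_sizes))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE)) {
    path <- paste0(path, ".imzML")
  }
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  n <- nrow(image$coords)
  continuous <- image$mode == "continuous"

  # assemble binary payload and per-spectrum offsets (offsets include the
  # 16-byte UUID header that precedes the payload in the .ibd file)
  payload <- file.path(tempdir(), paste0("gangliomsi-ibd-", Sys.getpid()))
  con <- file(payload, "wb")
  pos <- 16L
  wr <- function(x, dtype) {
    writeBin(as.numeric(x), con, size = .ibd_sizes[[dtype]],
             endian = "little")
  }
  mz_off <- integer(n); mz_len <- integer(n)
  int_off <- integer(n); int_len <- integer(n)
  if (continuous) {
    m <- length(image$mz)
    wr(image$mz, mz_dtype)
    mz_off[] <- pos; mz_len[] <- m
    pos <- pos + m * .ibd_sizes[[mz_dtype]]
    for (i in seq_len(n)) {
      wr(image$intensities[i, ], intensity_dtype)
      int_off[i] <- pos; int_len[i] <- m
      pos <- pos + m * .ibd_sizes[[intensity_dtype]]
    }
  } else {
    for (i in seq_len(n)) {
      m <- length(image$mz[[i]])
      wr(image$mz[[i]], mz_dtype)
      mz_off[i] <- pos; mz_len[i] <- m
      pos <- pos + m * .ibd_sizes[[mz_dtype]]
      wr(image$intensities[[i]], intensity_dtype)
      int_off[i] <- pos; int_len[i] <- m
      pos <- pos + m * .ibd_sizes[[intensity_dtype]]
    }
  }
  close(con)
  uuid <- .uuid_from_payload(payload)

  ibd <- file(ibd_path, "wb")
  writeBin(uuid$bytes, ibd)
  writeBin(readBin(payload, "raw", n = file.info(payload)$size), ibd)
  close(ibd)
  unlink(payload)

  cv <- function(acc, name, value = NULL, unit = NULL) {
    ref <- sub(":.*", "", acc)
    s <- sprintf('<cvParam cvRef="%s" accession="%s" name="%s"',
                 ref, acc, .xml_escape(name))
    if (!is.null(value)) s <- paste0(s, sprintf(' value="%s"', value))
    if (!is.null(unit)) {
      s <- paste0(s, sprintf(
        ' unitCvRef="UO" unitAccession="%s" unitName="%s"',
        unit[1], unit[2]))
    }
    paste0(s, "/>")
  }
  mode_cv <- if (continuous) {
    cv("IMS:1000030", "continuous")
  } else {
    cv("IMS:1000031", "processed")
  }
  pol_cv <- if (image$polarity == "negative") {
    cv("MS:1000129", "negative scan")
  } else {
    cv("MS:1000130", "positive scan")
  }
  max_x <- max(image$coords[, "x"]) + 1L
  max_y <- max(image$coords[, "y"]) + 1L

  spectra <- character(n)
  for (i in seq_len(n)) {
    ml <- if (continuous) length(image$mz) else length(image$mz[[i]])
    spectra[i] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, ml),
      '<referenceableParamGroupRef ref="spectrum1"/>',
      '<scanList count="1">', cv("MS:1000795", "no combination"),
      '<scan>',
      cv("IMS:1000050", "position x", image$coords[i, "x"] + 1L),
      cv("IMS:1000051", "position y", image$coords[i, "y"] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv("IMS:1000102", "external offset", mz_off[i]),
      cv("IMS:1000103", "external array length", mz_len[i]),
      cv("IMS:1000104", "external encoded length",
         mz_len[i] * .ibd_sizes[[mz_dtype]]),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv("IMS:1000102", "external offset", int_off[i]),
      cv("IMS:1000103", "external array length", int_len[i]),
      cv("IMS:1000104", "external encoded length",
         int_len[i] * .ibd_sizes[[intensity_dtype]]),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv("MS:1000579", "MS1 spectrum"),
    mode_cv,
    cv("IMS:1000080", "universally unique identifier", uuid$text),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="3">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS:1000514", "m/z array", unit = c("MS:1000040", "m/z")),
    cv(.ms_dtype_acc[[mz_dtype]], mz_dtype),
    cv("MS:1000576", "no compression"),
    cv("IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS:1000515", "intensity array",
       unit = c("MS:1000131", "number of detector counts")),
    cv(.ms_dtype_acc[[intensity_dtype]], intensity_dtype),
    cv("MS:1000576", "no compression"),
    cv("IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="spectrum1">',
    cv("MS:1000579", "MS1 spectrum"),
    cv("MS:1000511", "ms level", "1"),
    pol_cv,
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1">',
    '<software id="gangliomsi" version="0.1.0"/>',
    '</softwareList>',
    '<scanSettingsList count="1">',
    '<scanSettings id="scanSettings1">',
    cv("IMS:1000042", "max count of pixels x", max_x),
    cv("IMS:1000043", "max count of pixels y", max_y),
    cv("IMS:1000046", "pixel size (x)", image$pitch_um,
       unit = c("UO:0000017", "micrometer")),
    cv("IMS:1000047", "pixel size y", image$pitch_um,
       unit = c("UO:0000017", "micrometer")),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1">',
    '<dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="gangliomsi">',
    cv("MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', n),
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>\n')

  writeLines(xml, path, sep = "", useBytes = TRUE)
  invisible(path)
}

.xp <- function(node, path) {
  xml2::xml_find_all(node, path)
}

.cv_value <- function(node, accession) {
  v <- xml2::xml_attr(
    .xp(node, sprintf('.//*[local-name()="cvParam"][@accession="%s"]',
                      accession)),
    "value")
  if (length(v)) v[1L] else NA_character_
}

.has_cv <- function(node, accession) {
  length(.xp(node, sprintf('.//*[local-name()="cvParam"][@accession="%s"]',
                           accession))) > 0L
}

#' Read an imzML spectral image
#'
#' Parses the XML index and binary companion into an [msi_image()]. Both
#' continuous and processed binary modes, and both 32-bit and 64-bit float
#' encodings, are supported.
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @param meta Optional named list of section metadata to attach (study
#'   design does not travel inside imzML).
#' @return An [msi_image()].
#' @export
read_imzml <- function(path, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) {
    stop("missing binary companion: ", ibd_path, call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  fc <- .xp(doc, '//*[local-name()="fileContent"]')[[1L]]
  continuous <- .has_cv(fc, "IMS:1000030")
  if (!continuous && !.has_cv(fc, "IMS:1000031")) {
    stop("imzML file declares neither continuous nor processed mode",
         call. = FALSE)
  }

  # array dtypes from the referenceable param groups
  dtype_of <- function(group_has) {
    grps <- .xp(doc, '//*[local-name()="referenceableParamGroup"]')
    for (g in grps) {
      if (.has_cv(g, group_has)) {
        if (.has_cv(g, "MS:1000523")) return("64-bit float")
        if (.has_cv(g, "MS:1000521")) return("32-bit float")
      }
    }
    "64-bit float"
  }
  grp_id_of <- function(group_has) {
    grps <- .xp(doc, '//*[local-name()="referenceableParamGroup"]')
    for (g in grps) {
      if (.has_cv(g, group_has)) return(xml2::xml_attr(g, "id"))
    }
    NA_character_
  }
  mz_dtype <- dtype_of("MS:1000514")
  int_dtype <- dtype_of("MS:1000515")
  mz_grp <- grp_id_of("MS:1000514")
  int_grp <- grp_id_of("MS:1000515")

  polarity <- "negative"
  if (length(.xp(doc, '//*[local-name()="cvParam"][@accession="MS:1000130"]'))) {
    polarity <- "positive"
  }
  pitch <- .cv_value(doc, "IMS:1000046")
  pitch_um <- if (is.na(pitch)) 100 else as.numeric(pitch)

  spectra <- .xp(doc, '//*[local-name()="spectrum"]')
  n <- length(spectra)
  if (n == 0L) stop("imzML file contains no spectra", call. = FALSE)

  ibd_size <- file.info(ibd_path)$size
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))

  coords <- matrix(0L, n, 2L, dimnames = list(NULL, c("x", "y")))
  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  read_arr <- function(off, len, dtype, what) {
    bytes <- len * .ibd_sizes[[dtype]]
    if (off + bytes > ibd_size) {
      stop("truncated .ibd file while reading ", what, call. = FALSE)
    }
    seek(ibd, off)
    out <- readBin(ibd, "numeric", n = len, size = .ibd_sizes[[dtype]],
                   endian = "little")
    if (length(out) != len) {
      stop("truncated .ibd file while reading ", what, call. = FALSE)
    }
    out
  }
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    px <- as.integer(.cv_value(sp, "IMS:1000050"))
    py <- as.integer(.cv_value(sp, "IMS:1000051"))
    if (is.na(px) || is.na(py)) {
      stop("spectrum ", i, " lacks pixel coordinates", call. = FALSE)
    }
    coords[i, ] <- c(px - 1L, py - 1L)
    arrays <- .xp(sp, './/*[local-name()="binaryDataArray"]')
    got_mz <- FALSE; got_int <- FALSE
    for (a in arrays) {
      ref <- xml2::xml_attr(
        .xp(a, './/*[local-name()="referenceableParamGroupRef"]')[[1L]], "ref")
      off <- as.numeric(.cv_value(a, "IMS:1000102"))
      len <- as.integer(.cv_value(a, "IMS:1000103"))
      if (is.na(off) || is.na(len)) {
        stop("spectrum at pixel (", px - 1L, ",", py - 1L,
             ") lacks external offset/length", call. = FALSE)
      }
      where <- sprintf("pixel (%d,%d)", px - 1L, py - 1L)
      if (identical(ref, mz_grp)) {
        mz_list[[i]] <- read_arr(off, len, mz_dtype, where)
        got_mz <- TRUE
      } else if (identical(ref, int_grp)) {
        int_list[[i]] <- read_arr(off, len, int_dtype, where)
        got_int <- TRUE
      }
    }
    if (!got_mz || !got_int) {
      stop("spectrum at pixel (", px - 1L, ",", py - 1L,
           ") lacks m/z or intensity array", call. = FALSE)
    }
    if (length(mz_list[[i]]) != length(int_list[[i]])) {
      stop("axis-length mismatch at pixel (", px - 1L, ",", py - 1L, ")",
           call. = FALSE)
    }
  }

  if (continuous) {
    axis <- mz_list[[1L]]
    for (i in seq_len(n)) {
      if (!identical(length(mz_list[[i]]), length(axis)) ||
          any(mz_list[[i]] != axis)) {
        stop("continuous-mode file with non-uniform m/z axes (pixel (",
             coords[i, 1L], ",", coords[i, 2L], "))", call. = FALSE)
      }
    }
    msi_image(coords, axis, do.call(rbind, int_list),
              pitch_um = pitch_um, polarity = polarity, meta = meta)
  } else {
    msi_image(coords, mz_list, int_list,
              pitch_um = pitch_um, polarity = polarity, meta = meta)
  }
}
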