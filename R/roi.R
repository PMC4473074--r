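# Polygonal regions of interest in pixel space (0-based coordinates, x
# rightward, y downward) and the mirrored-contralateral construction.

#' Define a polygonal region of interest
#'
#' @param label ROI label: `"ipsilateral"`, `"contralateral"` or `"other"`.
#' @param x,y Ordered vertex coordinates in pixel space (numeric; vertices
#'   need not lie on pixel centers). At least 3 vertices; the polygon must
#'   not self-intersect.
#' @return An object of class `"roi_polygon"`.
#' @export
roi_polygon <- function(label, x, y) {
  label <- match.arg(label, c("ipsilateral", "contralateral", "other"))
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA vertex coordinates", call. = FALSE)
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (.self_intersects(v)) {
    stop("polygon '", label, "' is self-intersecting", call. = FALSE)
  }
  structure(list(label = label, vertices = v), class = "roi_polygon")
}

# proper-crossing test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections
.self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)  # a triangle cannot self-intersect
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n - 1L && i == 1L) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd (crossing number) point-in-polygon, vectorized over points.
# Points exactly on an edge are treated as outside ("strictly inside").
.points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1L]; yi <- vertices[i, 2L]
    xj <- vertices[j, 1L]; yj <- vertices[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Pixels of an image inside a polygon
#'
#' Selects the pixels whose centers fall strictly inside the polygon under
#' the even-odd rule.
#'
#' @param image An [msi_image()].
#' @param polygon An [roi_polygon()].
#' @return Integer vector of pixel indices (rows of `image$coords`).
#' @export
roi_mask <- function(image, polygon) {
  stopifnot(inherits(image, "msi_image"), inherits(polygon, "roi_polygon"))
  inside <- .points_in_polygon(image$coords[, "x"], image$coords[, "y"],
                               polygon$vertices)
  idx <- which(inside)
  if (!length(idx)) {
    stop("ROI '", polygon$label, "' covers no pixel centers", call. = FALSE)
  }
  idx
}

#' Mirror a region of interest about the sagittal midline
#'
#' Reflects each vertex x -> 2 * midline_x - x; y is unchanged. On a grid
#' symmetric about the midline the mirrored mask has the same size as the
#' original.
#'
#' @param polygon An [roi_polygon()], typically the ipsilateral ROI.
#' @param midline_x Pixel x-coordinate of the sagittal axis (may be
#'   half-integer, e.g. 19.5 on a 40-wide grid).
#' @param xmax Optional grid width; if given, reflected vertices outside
#'   `[0, xmax - 1]` are an error.
#' @return The mirrored [roi_polygon()], labelled `"contralateral"` if the
#'   input was ipsilateral (and vice versa).
#' @export
mirror_roi <- function(polygon, midline_x, xmax = NULL) {
  stopifnot(inherits(polygon, "roi_polygon"), is.numeric(midline_x))
  rx <- 2 * midline_x - polygon$vertices[, "x"]
  if (!is.null(xmax) && (any(rx < 0) || any(rx > xmax - 1))) {
    stop("mirrored polygon falls outside the pixel grid", call. = FALSE)
  }
  new_label <- switch(polygon$label,
                      ipsilateral = "contralateral",
                      contralateral = "ipsilateral",
                      polygon$label)
  roi_polygon(new_label, rx, polygon$vertices[, "y"])
}

#' Pair an ipsilateral ROI with its mirrored contralateral ROI
#'
#' @param ipsi The ipsilateral [roi_polygon()].
#' @param midline_x Sagittal midline pixel x-coordinate.
#' @param contra Optional explicitly drawn contralateral polygon; by default
#'   the mirror of `ipsi`.
#' @return A list of class `"roi_pair"` with elements `ipsi`, `contra`,
#'   `midline_x`.
#' @export
roi_pair <- function(ipsi, midline_x, contra = NULL) {
  stopifnot(inherits(ipsi, "roi_polygon"))
  if (is.null(contra)) contra <- mirror_roi(ipsi, midline_x)
  structure(list(ipsi = ipsi, contra = contra, midline_x = midline_x),
            class = "roi_pair")
}

#' Read ROI polygons from a vertex table
#'
#' The file is a delimited table with columns `label`, `x`, `y`: one row per
#' vertex, in order, in 0-based pixel coordinates. A row with label
#' `"midline"` supplies the sagittal midline x in its `x` column. If only an
#' ipsilateral polygon and a midline are present the contralateral ROI is
#' constructed by mirroring.
#'
#' @param path CSV file path.
#' @return An object of class `"roi_pair"`.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("no such ROI file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y")
  if (!all(need %in% names(df))) {
    stop("ROI file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  midline_x <- NA_real_
  mid <- df$label == "midline"
  if (any(mid)) midline_x <- as.numeric(df$x[mid][1L])
  df <- df[!mid, , drop = FALSE]
  polys <- lapply(split(df, factor(df$label, unique(df$label))),
                  function(d) roi_polygon(d$label[1L], d$x, d$y))
  ipsi <- polys[["ipsilateral"]]
  if (is.null(ipsi)) {
    stop("ROI file lacks an 'ipsilateral' polygon", call. = FALSE)
  }
  contra <- polys[["contralateral"]]
  if (is.null(contra)) {
    if (is.na(midline_x)) {
      stop("ROI file has no 'contralateral' polygon and no 'midline' row",
           call. = FALSE)
    }
    contra <- mirror_roi(ipsi, midline_x)
  }
  roi_pair(ipsi, midline_x, contra)
}

#' Write an ROI pair as a vertex table
#'
#' @param pair An `"roi_pair"` object.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_roi <- function(pair, path) {
  stopifnot(inherits(pair, "roi_pair"))
  rows <- rbind(
    data.frame(label = pair$ipsi$label,
               x = pair$ipsi$vertices[, "x"],
               y = pair$ipsi$vertices[, "y"]),
    data.frame(label = pair$contra$label,
               x = pair$contra$vertices[, "x"],
               y = pair$contra$vertices[, "y"]))
  if (!is.na(pair$midline_x)) {
    rows <- rbind(rows,
                  data.frame(label = "midline", x = pair$midline_x, y = NA))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
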