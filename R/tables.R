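# Study-design and cell-count tables. Metadata travels in these tables, not
# inside imzML, which has no standard slot for study design.

.group_levels <- c("control", "sham", "abeta", "et1", "abeta_et1")
.timepoint_levels <- c(3L, 21L)
.stain_levels <- c("FJB", "NeuN")

#' Read and validate a group-design table
#'
#' One row per animal section: columns `animal_id`, `group` (one of
#' control, sham, abeta, et1, abeta_et1), `timepoint_days` (3 or 21) and
#' `section_file` (the imzML file for that animal's section, relative to the
#' design file unless absolute).
#'
#' @param path CSV file path.
#' @return A validated data frame; duplicate animal/section pairs are
#'   rejected.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such design file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("design table is empty", call. = FALSE)
  need <- c("animal_id", "group", "timepoint_days", "section_file")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_design(df)
}

#' @rdname read_design
#' @param design A design data frame to validate in place.
#' @export
validate_design <- function(design) {
  bad <- setdiff(unique(design$group), .group_levels)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.group_levels, collapse = ", "), call. = FALSE)
  }
  if (!all(design$timepoint_days %in% .timepoint_levels)) {
    stop("timepoint_days must be one of: ",
         paste(.timepoint_levels, collapse = ", "), call. = FALSE)
  }
  key <- paste(design$animal_id, design$section_file, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated animal/section pair(s) in design: ",
         design$animal_id[duplicated(key)][1L], call. = FALSE)
  }
  design$timepoint_days <- as.integer(design$timepoint_days)
  design
}

#' Read a cell-count table
#'
#' Rows of (animal_id, group, timepoint_days, stain, count) where stain is
#' `"FJB"` (degenerating cells) or `"NeuN"` (mature neurons) and count is a
#' non-negative integer.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_cellcounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "timepoint_days", "stain", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cell-count table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$stain %in% .stain_levels)) {
    stop("stain must be one of: ", paste(.stain_levels, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$count < 0) || any(df$count != floor(df$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(unique(df$group), .group_levels)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$timepoint_days <- as.integer(df$timepoint_days)
  df$count <- as.integer(df$count)
  df
}
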