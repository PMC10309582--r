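#' ROI label map
#'
#' Integer-labelled soma segmentation: `0` = background, `1..N` = ROIs. The
#' per-ROI geometry table is derived from the label image, so the two can
#' never disagree. Coordinates follow the image convention: `y` = row index,
#' `x` = column index, both 1-based; centroids are pixel-index means.
#'
#' @param labels Integer `H x W` matrix of ROI labels. Labels must be the
#'   contiguous range `1..N` (plus background 0).
#' @return An object of class `"roi_map"` with elements `labels` and `table`
#'   (columns `label`, `area_px`, `centroid_x`, `centroid_y`, `touches_edge`).
#' @seealso [segment_somata()], [write_rois()], [read_rois()]
#' @export
roi_map <- function(labels) {
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels != round(labels)) ||
      any(labels < 0))
    stop("'labels' must be a matrix of nonnegative integers")
  storage.mode(labels) <- "integer"
  n <- max(labels)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n)))
    stop("ROI labels must be contiguous 1..N")
  structure(list(labels = labels, table = .roi_table(labels)),
            class = "roi_map")
}

.roi_table <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      touches_edge = logical()))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, n)
  cy <- as.numeric(rowsum(as.numeric(rr), lab)) / area
  cx <- as.numeric(rowsum(as.numeric(cc), lab)) / area
  edge <- rr == 1L | rr == nrow(labels) | cc == 1L | cc == ncol(labels)
  touches <- as.logical(tabulate(lab[edge], n) > 0L)
  data.frame(label = seq_len(n), area_px = area,
             centroid_x = cx, centroid_y = cy, touches_edge = touches)
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> %d x %d px, %d ROI(s)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$table)))
  if (nrow(x$table))
    cat(sprintf("  area range [%d, %d] px\n",
                min(x$table$area_px), max(x$table$area_px)))
  invisible(x)
}

#' Write an ROI map to disk
#'
#' Emits `<prefix>_labels.tif` (16-bit label image) and `<prefix>_rois.csv`
#' (the geometry table). [read_rois()] on the same prefix reconstructs the
#' map exactly.
#'
#' @param rois A [roi_map()].
#' @param path_prefix Output path prefix (directory must exist).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_rois <- function(rois, path_prefix) {
  stopifnot(inherits(rois, "roi_map"))
  if (max(rois$labels) > 65535L)
    stop("more than 65535 ROIs cannot be stored in a 16-bit label image")
  tif <- paste0(path_prefix, "_labels.tif")
  csv <- paste0(path_prefix, "_rois.csv")
  tiff::writeTIFF(rois$labels / 65535, tif, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  utils::write.csv(rois$table, csv, row.names = FALSE, quote = FALSE)
  invisible(c(labels = tif, table = csv))
}

#' Read an ROI map written by [write_rois()]
#'
#' @param path_prefix The prefix passed to [write_rois()].
#' @return A [roi_map()].
#' @export
read_rois <- function(path_prefix) {
  tif <- paste0(path_prefix, "_labels.tif")
  if (!file.exists(tif)) stop("cannot read label image: ", tif)
  labels <- tiff::readTIFF(tif, as.is = TRUE)
  roi_map(labels)
}
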