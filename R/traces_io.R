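#' Raw fluorescence trace matrix
#'
#' Mean-gray fluorescence per cell and time frame, as produced by
#' [extract_traces()] or [simulate_traces()].
#'
#' @param values Numeric `n_cells x T` matrix of raw fluorescence F.
#' @param cell_ids Character vector of unique cell identifiers (default
#'   `"cell_1"..`).
#' @param group Per-cell label such as the cell line (recycled if length 1).
#' @param time_s Strictly increasing vector of acquisition times in seconds
#'   (default `0, 1, ..., T-1`).
#' @return An object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(values, cell_ids = NULL, group = NULL, time_s = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("trace values must be finite")
  n <- nrow(values); n_t <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) stop("'cell_ids' must have one entry per cell")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (is.null(group)) group <- "all"
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) stop("'group' must have one entry per cell")
  if (is.null(time_s)) time_s <- seq_len(n_t) - 1
  if (length(time_s) != n_t) stop("'time_s' must have one entry per frame")
  if (n_t > 1L && any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing")
  dimnames(values) <- NULL
  structure(list(values = values, cell_ids = cell_ids, group = group,
                 time_s = as.numeric(time_s)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d frames, %d group(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$group))))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Baseline-normalized (dF/F0) trace matrix
#'
#' @param values `n_cells x T` matrix of dF/F0 values (dimensionless).
#' @param f0 Per-cell baseline fluorescence F0 (must be > 0).
#' @param stimulus_frame 1-based index of the last pre-stimulus frame.
#' @param n_baseline Number of pre-stimulus frames averaged into F0.
#' @inheritParams trace_matrix
#' @return An object of class `"dff_matrix"`.
#' @seealso [normalize_dff()]
#' @export
dff_matrix <- function(values, f0, stimulus_frame, n_baseline,
                       cell_ids = NULL, group = NULL, time_s = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("dF/F0 values must be finite")
  if (length(f0) != nrow(values)) stop("'f0' must have one entry per cell")
  if (any(f0 <= 0)) stop("all baselines F0 must be positive")
  stimulus_frame <- as.integer(stimulus_frame)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline > stimulus_frame)
    stop("'n_baseline' cannot exceed the number of pre-stimulus frames")
  tm <- trace_matrix(values, cell_ids, group, time_s)
  structure(list(values = tm$values, f0 = as.numeric(f0),
                 stimulus_frame = stimulus_frame, n_baseline = n_baseline,
                 cell_ids = tm$cell_ids, group = tm$group, time_s = tm$time_s),
            class = "dff_matrix")
}

#' @export
print.dff_matrix <- function(x, ...) {
  cat(sprintf(
    "<dff_matrix> %d cells x %d frames, stimulus after frame %d (F0 over %d frames)\n",
    nrow(x$values), ncol(x$values), x$stimulus_frame, x$n_baseline))
  invisible(x)
}

#' @export
dim.dff_matrix <- function(x) dim(x$values)

#' Read a trace CSV
#'
#' Expected layout: header `cell_id,group,<t0>,<t1>,...` where the remaining
#' column names are the acquisition times in seconds, then one row per cell.
#' The dialect is fixed: comma-separated, UTF-8, `.` decimal mark.
#'
#' @param path CSV file path.
#' @return A [trace_matrix()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("cannot read CSV file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("cell_id", "group")))
    stop("trace CSV must start with columns 'cell_id', 'group'")
  time_s <- suppressWarnings(as.numeric(colnames(df)[-(1:2)]))
  if (any(is.na(time_s)))
    stop("trace CSV header must contain numeric times after 'cell_id','group'")
  vals <- suppressWarnings(
    vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d, frame column %d",
                 bad[1L], bad[2L]))
  }
  trace_matrix(vals, cell_ids = df$cell_id, group = df$group, time_s = time_s)
}

#' Write a trace matrix as CSV
#'
#' Inverse of [read_traces()] up to floating-point formatting (15 significant
#' digits are written).
#'
#' @param traces A [trace_matrix()] or [dff_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, c("trace_matrix", "dff_matrix")))
  vals <- format(traces$values, digits = 15, trim = TRUE, scientific = FALSE)
  df <- data.frame(cell_id = traces$cell_ids, group = traces$group,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", "group",
                    format(traces$time_s, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
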