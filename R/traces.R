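#' Extract mean-gray traces from a stack
#'
#' For every ROI, the raw trace is the arithmetic mean of each frame over the
#' ROI's pixel set. Cells are ordered by ROI label, and the trace operator is
#' linear in the stack.
#'
#' @param stack An [image_stack()].
#' @param rois A [roi_map()] with the same `H x W` shape.
#' @param group Optional per-cell group label (recycled if length 1).
#' @return A [trace_matrix()] with cell ids `"roi_<label>"`; its `time_s` grid
#'   comes from the stack's frame interval. An empty ROI map yields an empty
#'   matrix with a warning.
#' @export
extract_traces <- function(stack, rois, group = "all") {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_map"))
  d <- dim(stack$frames)
  if (!identical(d[1:2], dim(rois$labels)))
    stop("stack is ", d[1L], " x ", d[2L], " but ROI map is ",
         nrow(rois$labels), " x ", ncol(rois$labels))
  n <- max(rois$labels)
  time_s <- (seq_len(d[3L]) - 1) * stack$frame_interval_s
  if (n == 0L) {
    warning("ROI map is empty; returning an empty trace matrix")
    return(trace_matrix(matrix(numeric(), 0L, d[3L]),
                        cell_ids = character(0), group = character(0),
                        time_s = time_s))
  }
  idx <- which(rois$labels > 0L)
  lab <- rois$labels[idx]
  flat <- matrix(stack$frames, d[1L] * d[2L], d[3L])
  sums <- rowsum(flat[idx, , drop = FALSE], lab)
  vals <- sums / tabulate(lab, n)
  trace_matrix(vals, cell_ids = paste0("roi_", seq_len(n)),
               group = group, time_s = time_s)
}

#' Baseline (dF/F0) normalization
#'
#' For each cell, the baseline `F0` is the mean of the last `n_baseline`
#' frames before the stimulus, and every time point is expressed as
#' `(F - F0) / F0`. The result is invariant to any positive gain applied to
#' the raw fluorescence, and the mean dF/F0 over the baseline window is 0 by
#' construction.
#'
#' @param traces A [trace_matrix()].
#' @param stimulus_frame 1-based index of the last pre-stimulus frame.
#' @param n_baseline Number of pre-stimulus frames averaged into F0
#'   (default 20, i.e. the 20 time points preceding stimulus addition).
#' @return A [dff_matrix()].
#' @export
normalize_dff <- function(traces, stimulus_frame, n_baseline = 20L) {
  stopifnot(inherits(traces, "trace_matrix"))
  n_t <- ncol(traces$values)
  stimulus_frame <- as.integer(stimulus_frame)
  n_baseline <- as.integer(n_baseline)
  if (stimulus_frame < 1L || stimulus_frame >= n_t)
    stop("'stimulus_frame' must satisfy 0 < stimulus_frame < T")
  if (n_baseline < 1L || n_baseline > stimulus_frame)
    stop("'n_baseline' must be between 1 and the number of pre-stimulus frames (",
         stimulus_frame, ")")
  win <- (stimulus_frame - n_baseline + 1L):stimulus_frame
  f0 <- rowMeans(traces$values[, win, drop = FALSE])
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("baseline F0 is not positive for cell(s): ",
         paste(traces$cell_ids[bad], collapse = ", "),
         " (check segmentation)")
  vals <- sweep(traces$values, 1L, f0, "-") / f0
  dff_matrix(vals, f0 = f0, stimulus_frame = stimulus_frame,
             n_baseline = n_baseline, cell_ids = traces$cell_ids,
             group = traces$group, time_s = traces$time_s)
}

#' Post-stimulus peak amplitudes
#'
#' Per-cell maximum dF/F0 over all post-stimulus frames, plus a per-group
#' summary (sample mean and n-1 standard deviation), the form in which peak
#' responses of cell lines are usually reported.
#'
#' @param norm A [dff_matrix()].
#' @return A list with `cells` (data frame: `cell_id`, `group`, `peak`) and
#'   `groups` (data frame: `group`, `n`, `mean`, `sd`).
#' @export
peak_amplitudes <- function(norm) {
  stopifnot(inherits(norm, "dff_matrix"))
  n_t <- ncol(norm$values)
  win <- (norm$stimulus_frame + 1L):n_t
  if (norm$stimulus_frame >= n_t) stop("no post-stimulus frames")
  peak <- apply(norm$values[, win, drop = FALSE], 1L, max)
  cells <- data.frame(cell_id = norm$cell_ids, group = norm$group,
                      peak = peak, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(cells$peak, cells$group), function(p)
    data.frame(n = length(p), mean = mean(p),
               sd = if (length(p) > 1L) stats::sd(p) else 0)))
  groups <- data.frame(group = rownames(groups), groups,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(cells = cells, groups = groups)
}

#' Random per-group subsample of cells
#'
#' Uniform sampling without replacement of `n_per_group` cells from every
#' group, reproducible under `seed` (e.g. 52 cells per cell line across six
#' lines gives 312 cells).
#'
#' @param norm A [dff_matrix()].
#' @param n_per_group Cells to keep per group.
#' @param seed RNG seed.
#' @return A [dff_matrix()] with `n_per_group x n_groups` cells, in original
#'   relative order.
#' @export
sample_cells <- function(norm, n_per_group, seed = 2023L) {
  stopifnot(inherits(norm, "dff_matrix"))
  groups <- unique(norm$group)
  sizes <- table(norm$group)[groups]
  small <- groups[sizes < n_per_group]
  if (length(small))
    stop("group(s) with fewer than ", n_per_group, " cells: ",
         paste(small, collapse = ", "))
  keep <- with_local_seed(seed, {
    sort(unlist(lapply(groups, function(g) {
      members <- which(norm$group == g)
      members[sample.int(length(members), n_per_group)]
    })))
  })
  dff_matrix(norm$values[keep, , drop = FALSE], f0 = norm$f0[keep],
             stimulus_frame = norm$stimulus_frame,
             n_baseline = norm$n_baseline,
             cell_ids = norm$cell_ids[keep], group = norm$group[keep],
             time_s = norm$time_s)
}

#' Heatmap-ready ordering of a dF/F0 matrix
#'
#' Orders cells by group and, within group, by descending post-stimulus peak
#' amplitude (`order_by = "peak"`), or keeps the input order
#' (`order_by = "input"`). Values are dF/F0, untransformed; the ordering is a
#' permutation, so the multiset of rows is preserved.
#'
#' @param norm A [dff_matrix()].
#' @param order_by `"peak"` or `"input"`.
#' @return A list with `values` (ordered matrix) and `meta` (data frame of
#'   `cell_id`, `group`, `peak` in the same order).
#' @export
heatmap_matrix <- function(norm, order_by = c("peak", "input")) {
  stopifnot(inherits(norm, "dff_matrix"))
  order_by <- match.arg(order_by)
  peak <- peak_amplitudes(norm)$cells$peak
  ord <- switch(order_by,
                peak = order(match(norm$group, unique(norm$group)), -peak),
                input = seq_len(nrow(norm$values)))
  vals <- norm$values[ord, , drop = FALSE]
  rownames(vals) <- norm$cell_ids[ord]
  list(values = vals,
       meta = data.frame(cell_id = norm$cell_ids[ord],
                         group = norm$group[ord], peak = peak[ord],
                         stringsAsFactors = FALSE))
}
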