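#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full [run_declutter()]
#' analysis. Exactly one input mode must be used: a movie (`stack`) that is
#' registered, segmented and trace-extracted, or a pre-extracted trace table
#' (`traces`) that enters at the normalization stage.
#'
#' @param stack A movie input: an [image_stack()] or a TIFF path.
#' @param traces A trace input: a [trace_matrix()] or a CSV path readable by
#'   [read_traces()].
#' @param stimulus_frame Last pre-stimulus frame (default 60).
#' @param n_baseline Baseline frames averaged into F0 (default 20).
#' @param frame_interval_s Seconds per frame for TIFF input (default 1).
#' @param register Run drift correction on movie input (default `TRUE`).
#' @param seg A [seg_params()] for movie input.
#' @param n_per_group Optional per-group random subsample size (e.g. 52);
#'   `NULL` keeps all cells.
#' @param fve_threshold Cumulative FVE at which FPC scores are truncated
#'   (default 0.95).
#' @param k Cluster count; `NULL` (default) uses the [elbow_select()]
#'   suggestion over `k_range`.
#' @param k_range Candidate cluster counts for the elbow scan.
#' @param n_neighbors,min_dist UMAP display parameters.
#' @param seed Seed used for every stochastic stage (default 2023).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(stack = NULL, traces = NULL,
                       stimulus_frame = 60L, n_baseline = 20L,
                       frame_interval_s = 1, register = TRUE,
                       seg = seg_params(), n_per_group = NULL,
                       fve_threshold = 0.95, k = NULL, k_range = 1:8,
                       n_neighbors = 15L, min_dist = 0.1, seed = 2023L) {
  if (is.null(stack) == is.null(traces))
    stop("exactly one input mode must be set: 'stack' (movie) or 'traces'")
  if (is.character(stack) && !file.exists(stack))
    stop("stack file does not exist: ", stack)
  if (is.character(traces) && !file.exists(traces))
    stop("trace file does not exist: ", traces)
  stopifnot(inherits(seg, "seg_params"))
  structure(list(stack = stack, traces = traces,
                 stimulus_frame = as.integer(stimulus_frame),
                 n_baseline = as.integer(n_baseline),
                 frame_interval_s = frame_interval_s,
                 register = isTRUE(register), seg = seg,
                 n_per_group = n_per_group,
                 fve_threshold = fve_threshold, k = k,
                 k_range = as.integer(k_range),
                 n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Scalar fields map 1:1 onto [run_config()] arguments; the `seg` block maps
#' onto [seg_params()].
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext))
  if (!is.null(cfg$seg)) cfg$seg <- do.call(seg_params, cfg$seg)
  if (!is.null(cfg$k_range)) cfg$k_range <- do.call(seq, as.list(cfg$k_range))
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages register -> segment -> extract -> normalize ->
#' (sample) -> fPCA -> 95%-FVE truncation -> elbow scan -> k-means -> UMAP ->
#' cluster profiles, writing every numeric result as CSV, the figures that
#' display them, and a JSON run manifest recording all parameters, seeds and
#' per-stage warnings. Every number appearing in a figure is also present in
#' a CSV, and two runs with the same configuration produce byte-identical
#' CSV output.
#'
#' @param config A [run_config()] or a path readable by [read_run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main intermediate objects (`rois`,
#'   `dff`, `fpca`, `n_components`, `elbow`, `clusters`, `embedding`,
#'   `profiles`) and `out_dir`.
#' @export
run_declutter <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$warnings <- list()
  stage <- function(name, expr) {
    msgs <- character(0)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (length(msgs)) state$warnings[[name]] <- msgs
    res
  }
  used <- list()
  rois <- NULL

  if (!is.null(config$stack)) {
    stk <- stage("read_stack", {
      if (inherits(config$stack, "image_stack")) config$stack
      else read_stack(config$stack,
                      frame_interval_s = config$frame_interval_s,
                      stimulus_frame = config$stimulus_frame)
    })
    if (config$register) {
      drift <- stage("register", estimate_drift(stk))
      stk <- stage("register", apply_drift(stk, drift))
      utils::write.csv(
        data.frame(frame = seq_len(nrow(drift$shifts)), drift$shifts),
        file.path(out_dir, "drift.csv"), row.names = FALSE, quote = FALSE)
    }
    rois <- stage("segment", segment_somata(stk, config$seg))
    write_rois(rois, file.path(out_dir, "segmentation"))
    traces <- stage("extract", extract_traces(stk, rois))
  } else {
    traces <- stage("read_traces", {
      if (inherits(config$traces, "trace_matrix")) config$traces
      else read_traces(config$traces)
    })
  }
  write_traces(traces, file.path(out_dir, "traces.csv"))

  dff <- stage("normalize", normalize_dff(traces, config$stimulus_frame,
                                          config$n_baseline))
  if (!is.null(config$n_per_group))
    dff <- stage("sample", sample_cells(dff, config$n_per_group,
                                        seed = config$seed))
  write_traces(dff, file.path(out_dir, "dff.csv"))
  hm <- heatmap_matrix(dff, "peak")
  utils::write.csv(hm$meta, file.path(out_dir, "heatmap_order.csv"),
                   row.names = FALSE, quote = FALSE)

  fit <- stage("fpca", fpca(dff))
  n_comp <- stage("fpca", select_k(fit, config$fve_threshold))
  used$n_components <- n_comp
  fv <- fraction_variance(fit)
  utils::write.csv(
    data.frame(component = seq_along(fv$fve), eigenvalue = fit$eigenvalues,
               fve = fv$fve, cumulative_fve = fv$cumulative),
    file.path(out_dir, "fve.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(time_s = fit$time_s, mean_fn = fit$mean_fn,
               stats::setNames(as.data.frame(fit$eigenfunctions),
                               paste0("phi_", seq_along(fit$eigenvalues)))),
    file.path(out_dir, "fpca_eigenfunctions.csv"),
    row.names = FALSE, quote = FALSE)
  scores <- fit$scores[, seq_len(n_comp), drop = FALSE]
  utils::write.csv(
    data.frame(cell_id = fit$cell_ids, group = fit$group,
               stats::setNames(as.data.frame(scores),
                               paste0("xi_", seq_len(n_comp)))),
    file.path(out_dir, "fpca_scores.csv"), row.names = FALSE, quote = FALSE)

  elbow <- stage("elbow", elbow_select(scores, config$k_range,
                                       seed = config$seed))
  utils::write.csv(data.frame(k = elbow$k_range, wss = elbow$wss),
                   file.path(out_dir, "elbow.csv"),
                   row.names = FALSE, quote = FALSE)
  k_used <- if (is.null(config$k)) elbow$k else as.integer(config$k)
  used$k <- k_used
  clusters <- stage("cluster", kmeans_cluster(scores, k_used,
                                              seed = config$seed))
  emb <- stage("embed", embed_umap(scores, config$n_neighbors,
                                   config$min_dist, seed = config$seed))
  utils::write.csv(
    data.frame(cell_id = fit$cell_ids, group = fit$group,
               cluster = clusters$labels, emb$coords),
    file.path(out_dir, "clusters.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(cell_id = fit$cell_ids, emb$coords),
    file.path(out_dir, "embedding.csv"), row.names = FALSE, quote = FALSE)

  prof <- stage("profiles", cluster_profiles(dff, clusters$labels))
  utils::write.csv(
    data.frame(cluster = rownames(prof$profiles), prof$profiles,
               check.names = FALSE),
    file.path(out_dir, "cluster_profiles.csv"),
    row.names = FALSE, quote = FALSE)
  comp_df <- data.frame(group = rownames(prof$composition),
                        as.data.frame.matrix(prof$composition),
                        check.names = FALSE)
  utils::write.csv(comp_df, file.path(out_dir, "cluster_composition.csv"),
                   row.names = FALSE, quote = FALSE)

  stage("figures", .pipeline_figures(out_dir, hm, fit, n_comp, elbow,
                                     clusters, emb, dff, prof))

  manifest <- list(
    package_version = as.character(utils::packageVersion("declutter")),
    input_mode = if (is.null(config$stack)) "traces" else "movie",
    parameters = list(
      stimulus_frame = config$stimulus_frame,
      n_baseline = config$n_baseline,
      frame_interval_s = config$frame_interval_s,
      register = config$register,
      segmentation = unclass(config$seg),
      n_per_group = config$n_per_group,
      fve_threshold = config$fve_threshold,
      k_requested = config$k,
      k_range = config$k_range,
      n_neighbors = emb$n_neighbors,
      n_neighbors_adjusted = emb$adjusted,
      min_dist = config$min_dist),
    seed = config$seed,
    n_cells = nrow(dff$values),
    n_frames = ncol(dff$values),
    n_rois = if (is.null(rois)) NULL else nrow(rois$table),
    n_components = n_comp,
    k_suggested = elbow$k,
    k_used = k_used,
    warnings = state$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(rois = rois, dff = dff, fpca = fit, n_components = n_comp,
                 elbow = elbow, clusters = clusters, embedding = emb,
                 profiles = prof, out_dir = out_dir))
}

## All display output of a run; every plotted number also lives in a CSV.
.pipeline_figures <- function(out_dir, hm, fit, n_comp, elbow, clusters,
                              emb, dff, prof) {
  png_dev <- function(name, width = 900, height = 600)
    grDevices::png(file.path(out_dir, name), width = width, height = height)

  png_dev("heatmap.png", 800, 700)
  graphics::image(x = dff$time_s, y = seq_len(nrow(hm$values)),
                  z = t(hm$values[rev(seq_len(nrow(hm$values))), ,
                                  drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "cell (ordered by group, peak)",
                  main = expression(Delta * F / F[0]))
  grDevices::dev.off()

  png_dev("eigenfunctions.png")
  plot(fit, n_show = min(3L, length(fit$eigenvalues)))
  grDevices::dev.off()

  png_dev("elbow.png", 600, 450)
  graphics::plot(elbow$k_range, elbow$wss, type = "b", pch = 19,
                 xlab = "k", ylab = "total within-cluster SS",
                 main = "Elbow scan")
  graphics::abline(v = elbow$k, lty = 2)
  grDevices::dev.off()

  cols <- grDevices::hcl.colors(max(3L, clusters$k), "Dark 3")
  png_dev("umap_clusters.png", 650, 600)
  graphics::plot(emb$coords, col = cols[clusters$labels], pch = 19,
                 cex = 0.7, main = "UMAP (colored by cluster)")
  graphics::legend("topright", bty = "n", pch = 19,
                   col = cols[seq_len(clusters$k)],
                   legend = paste("cluster", seq_len(clusters$k)))
  grDevices::dev.off()

  grp <- factor(dff$group)
  gcols <- grDevices::hcl.colors(max(3L, nlevels(grp)), "Set 2")
  png_dev("umap_groups.png", 650, 600)
  graphics::plot(emb$coords, col = gcols[as.integer(grp)], pch = 19,
                 cex = 0.7, main = "UMAP (colored by group)")
  graphics::legend("topright", bty = "n", pch = 19,
                   col = gcols[seq_len(nlevels(grp))], legend = levels(grp))
  grDevices::dev.off()

  png_dev("cluster_profiles.png", 900, 350 * nrow(prof$profiles))
  graphics::par(mfrow = c(nrow(prof$profiles), 1L),
                mar = c(4, 4, 2, 1))
  for (k in seq_len(nrow(prof$profiles))) {
    members <- which(prof$labels == k)
    graphics::matplot(dff$time_s, t(dff$values[members, , drop = FALSE]),
                      type = "l", lty = 1,
                      col = grDevices::adjustcolor(
                        gcols[as.integer(grp)[members]], 0.35),
                      xlab = "time (s)", ylab = expression(Delta * F / F[0]),
                      main = sprintf("cluster %d (n = %d)", k,
                                     length(members)))
    graphics::lines(dff$time_s, prof$profiles[k, ], col = "black", lwd = 2.5)
  }
  grDevices::dev.off()
  invisible(NULL)
}
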