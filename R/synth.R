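#' Simulation configuration
#'
#' Ground-truthed generator settings for synthetic calcium recordings. The
#' defaults emulate a Fluo-4-AM time-lapse experiment: 60 pre-stimulus frames
#' plus 600 post-stimulus frames at 1 frame/s (a 1-min baseline series
#' followed by a 10-min series after ATP addition), with three response
#' archetypes — non-responders, low responders and high responders — whose
#' stimulus-locked transients follow a peak-normalized double-exponential
#' shape.
#'
#' Amplitudes are drawn per cell from the archetype's truncated-at-zero
#' normal distribution; `noise_sd` is the additive Gaussian noise on F
#' expressed relative to the cell's baseline F0, so its value is directly
#' comparable to dF/F0 units.
#'
#' @param n_cells Total number of cells (split evenly across `groups`).
#' @param groups Character vector of group (cell line) names.
#' @param archetype_props Archetype mixture proportions, either a named
#'   vector `(non, low, high)` shared by all groups or a matrix with one row
#'   per group. Each row must sum to 1; realized counts use largest-remainder
#'   rounding, so proportions are met exactly.
#' @param t_total Total number of frames (default 660).
#' @param stimulus_frame Last pre-stimulus frame (default 60).
#' @param frame_interval_s Seconds per frame (default 1).
#' @param tau_rise,tau_decay Transient rise/decay time constants in seconds
#'   (defaults 5 and 30).
#' @param amp_mean,amp_sd Named vectors `(non, low, high)` of amplitude mean
#'   and cell-to-cell standard deviation in dF/F0 units.
#' @param f0_mean,f0_cv Baseline fluorescence level and its cell-to-cell
#'   coefficient of variation.
#' @param noise_sd Gaussian noise on F, relative to each cell's F0.
#' @param bleach_rate Shared photobleaching rate (1/s; 0 disables).
#' @param seed RNG seed; every simulation is fully reproducible under it.
#' @param h,w Movie height/width in pixels.
#' @param soma_radius_px Range `c(min, max)` of soma Gaussian radii (sigma).
#' @param min_separation_px Minimum center-to-center soma distance.
#' @param background Flat background intensity of the movie.
#' @param read_noise_sd Per-pixel Gaussian read noise of the movie (absolute
#'   units; negative pixels are clamped at the sensor floor 0).
#' @param drift_amplitude_px Amplitude of the sinusoidal stage drift
#'   (0 disables).
#' @param drift_period_frames Period of the sinusoidal drift.
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_traces()], [simulate_movie()]
#' @export
sim_config <- function(n_cells = 300L,
                       groups = "sim",
                       archetype_props = c(non = 1/3, low = 1/3, high = 1/3),
                       t_total = 660L,
                       stimulus_frame = 60L,
                       frame_interval_s = 1,
                       tau_rise = 5,
                       tau_decay = 30,
                       amp_mean = c(non = 0, low = 0.3, high = 1.2),
                       amp_sd = c(non = 0, low = 0.05, high = 0.15),
                       f0_mean = 100,
                       f0_cv = 0.1,
                       noise_sd = 0.05,
                       bleach_rate = 0,
                       seed = 2023L,
                       h = 224L, w = 224L,
                       soma_radius_px = c(4, 7),
                       min_separation_px = 30,
                       background = 5,
                       read_noise_sd = 1,
                       drift_amplitude_px = 0,
                       drift_period_frames = 200L) {
  arch <- c("non", "low", "high")
  if (is.null(dim(archetype_props)))
    archetype_props <- matrix(archetype_props, length(groups), 3L,
                              byrow = TRUE,
                              dimnames = list(groups, arch))
  if (!identical(colnames(archetype_props), arch))
    stop("'archetype_props' columns must be (non, low, high)")
  if (any(archetype_props < 0) ||
      any(abs(rowSums(archetype_props) - 1) > 1e-8))
    stop("archetype proportions of every group must be nonnegative and sum to 1")
  if (stimulus_frame >= t_total)
    stop("'stimulus_frame' must be smaller than 't_total'")
  if (any(c(tau_rise, tau_decay, noise_sd, bleach_rate, f0_cv) < 0) ||
      tau_rise >= tau_decay)
    stop("rates must be nonnegative and tau_rise < tau_decay")
  if (!all(arch %in% names(amp_mean)) || !all(arch %in% names(amp_sd)))
    stop("'amp_mean' and 'amp_sd' must be named (non, low, high)")
  structure(list(
    n_cells = as.integer(n_cells), groups = groups,
    archetype_props = archetype_props,
    t_total = as.integer(t_total), stimulus_frame = as.integer(stimulus_frame),
    frame_interval_s = frame_interval_s,
    tau_rise = tau_rise, tau_decay = tau_decay,
    amp_mean = amp_mean[arch], amp_sd = amp_sd[arch],
    f0_mean = f0_mean, f0_cv = f0_cv, noise_sd = noise_sd,
    bleach_rate = bleach_rate, seed = as.integer(seed),
    h = as.integer(h), w = as.integer(w),
    soma_radius_px = soma_radius_px,
    min_separation_px = min_separation_px,
    background = background, read_noise_sd = read_noise_sd,
    drift_amplitude_px = drift_amplitude_px,
    drift_period_frames = as.integer(drift_period_frames)),
    class = "sim_config")
}

#' Stimulus-locked transient shape
#'
#' Peak-normalized double-exponential response sampled on the acquisition
#' grid: `g(u) = exp(-u/tau_decay) - exp(-u/tau_rise)` for `u > 0` seconds
#' after the stimulus, zero before, scaled so its maximum over the sampled
#' frames is exactly 1 (so an amplitude `a` produces a peak dF/F0 of `a`).
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `t_total`.
#' @export
transient_shape <- function(config) {
  u <- pmax(0, seq_len(config$t_total) - config$stimulus_frame) *
    config$frame_interval_s
  g <- ifelse(u > 0, exp(-u / config$tau_decay) - exp(-u / config$tau_rise), 0)
  if (max(g) > 0) g <- g / max(g)
  g
}

## Largest-remainder rounding of n * props to integer counts summing to n.
## Ties in the remainders go to the earlier category.
largest_remainder <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-(raw - counts), seq_along(props))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Simulate ground-truthed calcium traces
#'
#' Per cell: `F(t) = F0 * bleach(t) * (1 + a * g(t)) + F0 * noise_sd * eps(t)`
#' with `g` the shared [transient_shape()] and `a = 0` for non-responders.
#' Archetype counts per group are allocated by largest-remainder rounding of
#' the configured proportions (so they are exact, not just expected) and then
#' shuffled under the seed.
#'
#' @param config A [sim_config()].
#' @return List with `traces` (a [trace_matrix()]) and `truth` (data frame:
#'   `cell_id`, `group`, `archetype`, `amplitude`, `f0`).
#' @export
simulate_traces <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, .simulate_traces_impl(config))
}

.simulate_traces_impl <- function(config) {
  g <- transient_shape(config)
  t_s <- (seq_len(config$t_total) - 1) * config$frame_interval_s
  bleach <- exp(-config$bleach_rate * t_s)
  n_groups <- length(config$groups)
  per_group <- largest_remainder(rep(1 / n_groups, n_groups), config$n_cells)
  arch_names <- c("non", "low", "high")

  cell_id <- character(0); grp <- character(0); archetype <- character(0)
  for (gi in seq_len(n_groups)) {
    counts <- largest_remainder(config$archetype_props[gi, ], per_group[gi])
    a <- sample(rep(arch_names, counts))
    archetype <- c(archetype, a)
    grp <- c(grp, rep(config$groups[gi], per_group[gi]))
  }
  n <- length(archetype)
  cell_id <- paste0("cell_", seq_len(n))
  amplitude <- rnorm_pos(n, config$amp_mean[archetype],
                         config$amp_sd[archetype])
  amplitude[archetype == "non"] <- 0
  f0 <- rnorm_pos(n, config$f0_mean, config$f0_cv * config$f0_mean)
  f0 <- pmax(f0, 0.05 * config$f0_mean)     # keep baselines physical

  clean <- outer(f0, bleach) * (1 + outer(amplitude, g))
  noise <- matrix(stats::rnorm(n * config$t_total), n) *
    (f0 * config$noise_sd)
  values <- clean + noise
  list(traces = trace_matrix(values, cell_ids = cell_id, group = grp,
                             time_s = t_s),
       truth = data.frame(cell_id = cell_id, group = grp,
                          archetype = archetype, amplitude = amplitude,
                          f0 = f0, stringsAsFactors = FALSE))
}

#' Simulate a ground-truthed calcium movie
#'
#' Renders each simulated cell as a 2-D Gaussian soma (random radius within
#' `soma_radius_px`) on a flat background, modulated over time by its
#' simulated trace, with optional sinusoidal stage drift and per-pixel read
#' noise. Soma centers are placed by rejection sampling at the configured
#' minimum separation (up to 1e4 attempts). The truth label map marks each
#' soma's 2-sigma footprint (~86% of its fluorescence); truth drift shifts
#' are recorded relative to the first frame.
#'
#' @param config A [sim_config()] (use a small `n_cells` for movies).
#' @return List with `stack` ([image_stack()]), `rois` (truth [roi_map()]),
#'   `drift` (truth [drift_track()]), `traces` (generating soma time courses
#'   as a [trace_matrix()]) and `truth` (archetype table).
#' @export
simulate_movie <- function(config = sim_config(n_cells = 30L)) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, .simulate_movie_impl(config))
}

.simulate_movie_impl <- function(config) {
  sim <- .simulate_traces_impl(config)
  n <- nrow(sim$traces$values)
  h <- config$h; w <- config$w
  radii <- stats::runif(n, config$soma_radius_px[1L], config$soma_radius_px[2L])
  margin <- 2 * radii + 2
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(1e4)) {
      cand <- c(stats::runif(1, 1 + margin[i], h - margin[i]),
                stats::runif(1, 1 + margin[i], w - margin[i]))
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      if (!nrow(prev) ||
          all((prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 >=
              config$min_separation_px^2)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " somata at separation ",
           config$min_separation_px,
           " px; use fewer or smaller cells or a larger field")
  }

  ## truth labels: disjoint 2-sigma discs (separation > 4*max radius)
  labels <- matrix(0L, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n)) {
    d2 <- (yy - centers[i, 1L])^2 + (xx - centers[i, 2L])^2
    labels[d2 <= (2 * radii[i])^2] <- i
  }

  t_total <- config$t_total
  if (config$drift_amplitude_px > 0) {
    ph <- 2 * pi * (seq_len(t_total) - 1L) / config$drift_period_frames
    dy <- config$drift_amplitude_px * sin(ph)
    dx <- config$drift_amplitude_px * sin(ph + pi / 2)
    dy <- dy - dy[1L]; dx <- dx - dx[1L]
  } else {
    dy <- dx <- numeric(t_total)
  }

  f_mat <- sim$traces$values                       # n x T soma time courses
  if (all(dy == 0) && all(dx == 0)) {
    profiles <- matrix(0, h * w, n)
    for (i in seq_len(n)) {
      d2 <- (yy - centers[i, 1L])^2 + (xx - centers[i, 2L])^2
      profiles[, i] <- exp(-d2 / (2 * radii[i]^2))
    }
    movie <- profiles %*% f_mat + config$background
  } else {
    movie <- matrix(config$background, h * w, t_total)
    for (t in seq_len(t_total)) {
      frame <- matrix(0, h, w)
      for (i in seq_len(n)) {
        cy <- centers[i, 1L] + dy[t]; cx <- centers[i, 2L] + dx[t]
        d2 <- (yy - cy)^2 + (xx - cx)^2
        frame <- frame + exp(-d2 / (2 * radii[i]^2)) * f_mat[i, t]
      }
      movie[, t] <- movie[, t] + as.numeric(frame)
    }
  }
  if (config$read_noise_sd > 0)
    movie <- movie + stats::rnorm(length(movie), 0, config$read_noise_sd)
  movie[movie < 0] <- 0                            # sensor floor

  stack <- image_stack(array(movie, c(h, w, t_total)),
                       frame_interval_s = config$frame_interval_s,
                       stimulus_frame = config$stimulus_frame,
                       metadata = list(simulated = TRUE, seed = config$seed))
  list(stack = stack,
       rois = roi_map(labels),
       drift = drift_track(cbind(dy, dx), reference_frame = 1L),
       traces = sim$traces,
       truth = cbind(sim$truth,
                     center_y = centers[, 1L], center_x = centers[, 2L],
                     radius_px = radii))
}
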