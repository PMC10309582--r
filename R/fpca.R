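#' Functional principal component analysis of dense trace data
#'
#' Fits the dense regular-grid functional PCA estimator to a set of curves
#' observed on a common time grid: the mean function is the cross-sectional
#' mean, and the eigenfunctions/eigenvalues come from the eigendecomposition
#' of the quadrature-weighted sample covariance surface,
#' `W^{1/2} C W^{1/2}` with `C` the `T x T` sample covariance (n-1
#' denominator) and `W = diag(w)` the quadrature weights. Eigenfunctions are
#' normalized to unit L2 norm under the quadrature inner product
#' (`sum(w * phi^2) = 1`) and oriented so that the value of largest magnitude
#' is positive; scores are the weighted projections of the centered curves.
#'
#' On a uniform grid the weights are `w = dt`, which makes the eigenvalues
#' exactly `dt` times those of the plain sample covariance matrix and the
#' scores ordinary PCA scores scaled by `sqrt(dt)`. A non-uniform grid gets
#' trapezoid weights and a warning. No covariance smoothing is applied
#' (`smooth` is reserved and must be `FALSE`): at one frame per second with
#' every cell fully observed, the raw estimator is deterministic and directly
#' checkable against matrix PCA.
#'
#' Eigenvalues below `1e-12` times the leading eigenvalue are treated as
#' numerically zero and dropped, so the number of retained components is at
#' most `min(n_cells - 1, T)`.
#'
#' @param x Curves to decompose: a [dff_matrix()] (rows = cells) or a plain
#'   numeric matrix `n x T`.
#' @param ... Passed between methods.
#' @return An object of class `"fpca"` with elements `time_s`, `mean_fn`,
#'   `eigenfunctions` (`T x K` matrix), `eigenvalues`, `scores` (`n x K`),
#'   `fve`, `weights`, `n`, plus the cell metadata when `x` is a
#'   [dff_matrix()]. Methods: [print()], [summary()], [fitted()],
#'   [predict()], [plot()], [screeplot()].
#' @examples
#' shapes <- rbind(sin(seq(0, pi, length.out = 50)))
#' x <- outer(c(-1, 1, -1, 1), shapes[1, ]) + 0.2
#' fit <- fpca(x, time_s = seq(0, 49))
#' summary(fit)
#' @export
fpca <- function(x, ...) UseMethod("fpca")

#' @rdname fpca
#' @param time_s Time grid (defaults to `0..T-1` seconds).
#' @param smooth Reserved flag for a covariance pre-smoother; only `FALSE` is
#'   implemented.
#' @export
fpca.default <- function(x, time_s = NULL, smooth = FALSE, ...) {
  x <- as.matrix(x)
  n <- nrow(x); n_t <- ncol(x)
  if (n < 2L) stop("functional PCA needs at least 2 cells")
  if (!all(is.finite(x))) stop("curves must be finite")
  if (isTRUE(smooth)) stop("covariance smoothing is reserved, not implemented")
  if (is.null(time_s)) time_s <- seq_len(n_t) - 1
  if (length(time_s) != n_t || any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing with one entry per frame")
  w <- .quad_weights(time_s)

  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  cc <- crossprod(xc) / (n - 1)
  sw <- sqrt(w)
  m <- cc * tcrossprod(sw)
  eig <- eigen(m, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  k_max <- min(n - 1L, n_t)
  lam <- lam[seq_len(k_max)]
  lam[lam < 1e-12 * lam[1L]] <- 0
  keep <- which(lam > 0)
  lam <- lam[keep]
  phi <- eig$vectors[, keep, drop = FALSE] / sw
  ## orient each eigenfunction so its largest-magnitude value is positive
  for (k in seq_along(keep)) {
    v <- phi[, k]
    if (v[which.max(abs(v))] < 0) phi[, k] <- -v
  }
  scores <- xc %*% (phi * w)
  fve <- if (length(lam)) lam / sum(lam) else numeric(0)
  structure(list(time_s = as.numeric(time_s), mean_fn = mu,
                 eigenfunctions = phi, eigenvalues = lam, scores = scores,
                 fve = fve, weights = w, n = n),
            class = "fpca")
}

#' @rdname fpca
#' @export
fpca.dff_matrix <- function(x, smooth = FALSE, ...) {
  fit <- fpca.default(x$values, time_s = x$time_s, smooth = smooth)
  fit$cell_ids <- x$cell_ids
  fit$group <- x$group
  fit$f0 <- x$f0
  fit$stimulus_frame <- x$stimulus_frame
  fit$n_baseline <- x$n_baseline
  fit
}

## Quadrature weights: uniform Riemann weights on a (numerically) uniform
## grid -- this makes the estimator coincide exactly with scaled matrix PCA --
## and trapezoid weights (with a warning) otherwise.
.quad_weights <- function(time_s) {
  n_t <- length(time_s)
  if (n_t == 1L) return(1)
  d <- diff(time_s)
  dt <- mean(d)
  if (max(abs(d - dt)) <= 1e-8 * dt) return(rep(dt, n_t))
  warning("non-uniform time grid: using trapezoid quadrature weights")
  c(d[1L] / 2, (d[-1L] + d[-(n_t - 1L)]) / 2, d[n_t - 1L] / 2)
}

#' @export
print.fpca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("<fpca> %d curves on %d time points, %d component(s)\n",
              x$n, length(x$time_s), k))
  if (k) {
    kshow <- seq_len(min(3L, k))
    cat(sprintf("  leading FVE: %s\n",
                paste(sprintf("%.1f%%", 100 * x$fve[kshow]), collapse = ", ")))
    cat(sprintf("  components for 95%% FVE: %d\n", select_k(x, 0.95)))
  } else {
    cat("  all eigenvalues are zero (identical curves)\n")
  }
  invisible(x)
}

#' @export
summary.fpca <- function(object, ...) {
  k <- length(object$eigenvalues)
  tab <- data.frame(component = seq_len(k),
                    eigenvalue = object$eigenvalues,
                    fve = object$fve, cumulative_fve = cumsum(object$fve))
  structure(list(table = tab, n = object$n, n_time = length(object$time_s)),
            class = "summary.fpca")
}

#' @export
print.summary.fpca <- function(x, ...) {
  cat(sprintf("Functional PCA: %d curves, %d time points\n", x$n, x$n_time))
  print(utils::head(x$table, 10L), row.names = FALSE, digits = 4)
  if (nrow(x$table) > 10L)
    cat("  ... (", nrow(x$table) - 10L, " more components)\n", sep = "")
  invisible(x)
}

#' Fraction of variance explained
#'
#' @param model A fitted [fpca()] model.
#' @return List with `fve` (per component, `lambda_k / sum(lambda)`) and
#'   `cumulative` (non-decreasing to 1). A model whose eigenvalues are all
#'   zero has no defined FVE and raises an error.
#' @export
fraction_variance <- function(model) {
  stopifnot(inherits(model, "fpca"))
  if (!length(model$eigenvalues) || sum(model$eigenvalues) == 0)
    stop("all eigenvalues are zero: fraction of variance is undefined")
  list(fve = model$fve, cumulative = cumsum(model$fve))
}

#' Number of components for a variance target
#'
#' The smallest `K` whose cumulative fraction of variance explained reaches
#' the threshold (default 95%, the usual truncation level for denoising).
#'
#' @param model A fitted [fpca()] model, or a numeric vector of per-component
#'   FVE values.
#' @param threshold Target cumulative FVE in `(0, 1]`.
#' @return Integer `K`.
#' @export
select_k <- function(model, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  fve <- if (inherits(model, "fpca")) fraction_variance(model)$fve
         else as.numeric(model)
  cum <- cumsum(fve)
  k <- which(cum >= threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(fve)
  as.integer(k)
}

#' Truncated reconstruction (denoising)
#'
#' Rebuilds every curve from its first `k` component scores:
#' `mu(t) + sum_{j<=k} xi_j phi_j(t)`. With all components the centered data
#' are recovered (completeness); truncating at the 95%-FVE cut acts as a
#' denoiser.
#'
#' @param model A fitted [fpca()] model.
#' @param k Number of components to keep (`1..K_max`).
#' @return If the model was fitted to a [dff_matrix()], a denoised
#'   [dff_matrix()]; otherwise a plain `n x T` matrix.
#' @export
reconstruct <- function(model, k) {
  stopifnot(inherits(model, "fpca"))
  k_max <- length(model$eigenvalues)
  k <- as.integer(k)
  if (k < 1L || k > k_max)
    stop("'k' must be between 1 and ", k_max)
  vals <- fitted(model, k = k)
  if (is.null(model$cell_ids)) return(vals)
  dff_matrix(vals, f0 = model$f0, stimulus_frame = model$stimulus_frame,
             n_baseline = model$n_baseline, cell_ids = model$cell_ids,
             group = model$group, time_s = model$time_s)
}

#' @export
#' @rdname fpca
#' @param object,k Fitted model and number of components (default: all).
fitted.fpca <- function(object, k = length(object$eigenvalues), ...) {
  if (k == 0L)
    return(matrix(object$mean_fn, object$n, length(object$time_s),
                  byrow = TRUE))
  sel <- seq_len(k)
  sweep(object$scores[, sel, drop = FALSE] %*%
          t(object$eigenfunctions[, sel, drop = FALSE]),
        2L, object$mean_fn, "+")
}

#' @export
#' @rdname fpca
#' @param newdata Matrix of new curves on the model's time grid.
predict.fpca <- function(object, newdata, k = length(object$eigenvalues), ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$time_s))
    stop("'newdata' must be observed on the model's time grid")
  sel <- seq_len(k)
  sweep(newdata, 2L, object$mean_fn) %*%
    (object$eigenfunctions[, sel, drop = FALSE] * object$weights)
}

#' @export
#' @rdname fpca
#' @param n_show Number of eigenfunctions to draw.
plot.fpca <- function(x, n_show = min(3L, length(x$eigenvalues)), ...) {
  if (!n_show) stop("no components to plot")
  graphics::matplot(x$time_s, x$eigenfunctions[, seq_len(n_show), drop = FALSE],
                    type = "l", lty = 1, lwd = 2,
                    xlab = "time (s)", ylab = expression(phi[k](t)),
                    main = "Leading eigenfunctions", ...)
  graphics::legend("topright", bty = "n", lty = 1, lwd = 2,
                   col = seq_len(n_show),
                   legend = sprintf("phi%d (%.1f%%)", seq_len(n_show),
                                    100 * x$fve[seq_len(n_show)]))
  invisible(x)
}

#' @export
#' @rdname fpca
#' @param npcs Components shown in the scree plot.
screeplot.fpca <- function(x, npcs = min(10L, length(x$eigenvalues)), ...) {
  graphics::barplot(100 * x$fve[seq_len(npcs)],
                    names.arg = seq_len(npcs),
                    xlab = "component", ylab = "FVE (%)", ...)
  invisible(x)
}
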