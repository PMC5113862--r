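#' Spatiotemporal stimulus container
#'
#' @param frames X x Y x T numeric array of contrast values (binary
#'   checkerboard noise is +/- 1), one frame per raster time bin.
#' @return Object of class `stimulus`.
#' @export
stimulus <- function(frames) {
  if (length(dim(frames)) != 3) stop("frames must be an X x Y x T array")
  if (!all(is.finite(frames))) stop("frames must be finite")
  structure(list(frames = frames, dims = dim(frames)), class = "stimulus")
}

#' Binary white-noise checkerboard stimulus
#'
#' Each check is independently +/- 1, redrawn every frame.
#' @param nx,ny Spatial dimensions in checks.
#' @param T_ Number of frames (= raster bins).
#' @param seed Integer seed.
#' @return A [stimulus()].
#' @export
checkerboard_stimulus <- function(nx, ny, T_, seed = 1L) {
  frames <- with_seed(seed,
                      array(sample(c(-1, 1), nx * ny * T_, replace = TRUE),
                            dim = c(nx, ny, T_)))
  stimulus(frames)
}

#' Spike-triggered average
#'
#' Averages the stimulus history preceding (and including) each spike bin.
#' Lag 1 of the third dimension is the spike bin itself; lags increase into
#' the past. Spikes earlier than `n_lags` bins into the recording are
#' skipped so every average uses a complete history.
#'
#' @param spike_row Binary vector of length T (one cell's raster row).
#' @param stim A [stimulus()] aligned with the raster.
#' @param n_lags Number of history frames (default 10).
#' @return X x Y x n_lags array.
#' @export
compute_sta <- function(spike_row, stim, n_lags = 10) {
  stopifnot(inherits(stim, "stimulus"))
  if (n_lags < 1) stop("n_lags must be >= 1")
  T_ <- stim$dims[3]
  if (length(spike_row) != T_) stop("raster/stimulus length mismatch")
  trig <- which(spike_row == 1 & seq_along(spike_row) >= n_lags)
  if (!length(trig)) stop("no spikes")
  sta_from_triggers(trig, stim, n_lags)
}

sta_from_triggers <- function(trig, stim, n_lags) {
  X <- stim$dims[1]; Y <- stim$dims[2]
  S <- matrix(stim$frames, X * Y, stim$dims[3])
  out <- array(0, dim = c(X, Y, n_lags))
  for (lag in seq_len(n_lags)) {
    out[, , lag] <- matrix(rowMeans(S[, trig - lag + 1, drop = FALSE]), X, Y)
  }
  out
}

#' Mask a filter to a square patch around its peak
#'
#' Finds the spatial location with maximal absolute filter value over all
#' lags and zeroes every check outside the centered `patch` x `patch`
#' window (the window is clipped at array edges), suppressing estimation
#' noise away from the receptive field.
#'
#' @param sta X x Y x tau array (e.g. from [compute_sta()]).
#' @param patch Odd window size in checks (default 7).
#' @return Array of the same dimensions, plus attributes `peak` (x, y) and
#'   `mask` (logical X x Y).
#' @export
mask_sta <- function(sta, patch = 7) {
  if (patch %% 2 != 1) stop("patch must be odd")
  d <- dim(sta)
  flat <- apply(abs(sta), c(1, 2), max)
  peak <- which(flat == max(flat), arr.ind = TRUE)[1, ]
  half <- (patch - 1) / 2
  mask <- matrix(FALSE, d[1], d[2])
  xr <- max(1, peak[1] - half):min(d[1], peak[1] + half)
  yr <- max(1, peak[2] - half):min(d[2], peak[2] + half)
  mask[xr, yr] <- TRUE
  out <- sta
  for (lag in seq_len(d[3])) out[, , lag][!mask] <- 0
  attr(out, "peak") <- peak
  attr(out, "mask") <- mask
  out
}

# Filtered drive u(t) = sum_x sum_tau K(x, tau) s(x, t - tau + 1); bins with
# incomplete history get NA.
filter_drive <- function(filter, stim) {
  d <- dim(filter)
  X <- d[1]; Y <- d[2]; n_lags <- d[3]
  T_ <- stim$dims[3]
  S <- matrix(stim$frames, X * Y, T_)
  K <- matrix(filter, X * Y, n_lags)
  nz <- which(rowSums(abs(K)) > 0)
  u <- rep(NA_real_, T_)
  idx <- n_lags:T_
  acc <- numeric(length(idx))
  for (lag in seq_len(n_lags)) {
    acc <- acc + as.numeric(crossprod(K[nz, lag, drop = FALSE],
                                      S[nz, idx - lag + 1, drop = FALSE]))
  }
  u[idx] <- acc
  u
}

#' Fit the logistic LN nonlinearity parameters
#'
#' With the linear filter fixed (typically the masked STA), fits the gain
#' and offset of the logistic nonlinearity
#' \deqn{p(t) = \frac{1}{1 + \exp(\alpha\, (K*s)(t) - \theta)}}
#' by maximum likelihood under per-bin Bernoulli spiking. This is logistic
#' regression in disguise (linear predictor theta - alpha u), so the fit is
#' convex and deterministic.
#'
#' @param spike_row Binary vector of length T.
#' @param stim A [stimulus()].
#' @param filter Fixed X x Y x tau filter.
#' @return List with `gain` (alpha), `offset` (theta), `loglik`, and
#'   `drive` (the filtered stimulus).
#' @export
fit_ln <- function(spike_row, stim, filter) {
  u <- filter_drive(filter, stim)
  ok <- !is.na(u)
  y <- spike_row[ok]
  x <- u[ok]
  fit <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  if (!fit$converged) stop("LN fit did not converge")
  co <- fit$coefficients
  # linear predictor b0 + b1 u = theta - alpha u
  list(gain = -co[[2]], offset = co[[1]],
       loglik = -fit$deviance / 2, drive = u)
}

#' LN model container
#' @param filter X x Y x tau linear filter (zero outside the mask).
#' @param gain alpha of the logistic nonlinearity.
#' @param offset theta of the logistic nonlinearity.
#' @return Object of class `ln_model`.
#' @export
ln_model <- function(filter, gain, offset) {
  structure(list(filter = filter, gain = gain, offset = offset),
            class = "ln_model")
}

#' LN spiking probability time series
#' @param model An [ln_model()].
#' @param stim A [stimulus()].
#' @return Length-T vector of Bernoulli probabilities (NA where the filter
#'   history is incomplete).
#' @export
ln_probability <- function(model, stim) {
  u <- filter_drive(model$filter, stim)
  1 / (1 + exp(model$gain * u - model$offset))
}

#' Simulate a conditionally independent LN population
#'
#' Draws each cell's spikes as independent Bernoulli samples at its LN
#' probability given the shared stimulus. Cells with overlapping filters
#' acquire stimulus-driven (signal) correlations despite the conditional
#' independence.
#'
#' @param models List of [ln_model()] sharing the stimulus geometry.
#' @param stim A [stimulus()].
#' @param seed Integer seed.
#' @param bin_width Raster bin width in seconds.
#' @return A [binary_raster()] (bins with incomplete history are silent).
#' @export
simulate_ln_population <- function(models, stim, seed = 1L, bin_width = 0.02) {
  probs <- vapply(models, ln_probability, numeric(stim$dims[3]), stim = stim)
  probs[is.na(probs)] <- 0
  data <- with_seed(seed,
                    matrix(as.integer(stats::runif(length(probs)) < probs),
                           nrow = nrow(probs)))
  binary_raster(t(data), bin_width)
}

#' Mode-triggered stimulus average
#'
#' Same averaging rule as [compute_sta()], but triggered on the bins where
#' a decoded mode is active.
#'
#' @param path A [mode_path()] (or integer vector) aligned with the
#'   stimulus.
#' @param mode 1-based mode index.
#' @param stim A [stimulus()].
#' @param n_lags Number of history frames.
#' @return X x Y x n_lags array.
#' @export
mode_triggered_average <- function(path, mode, stim, n_lags = 10) {
  p <- if (inherits(path, "mode_path")) path$path else as.integer(path)
  trig <- which(p == mode & seq_along(p) >= n_lags)
  if (!length(trig)) stop("mode never active (with complete history)")
  sta_from_triggers(trig, stim, n_lags)
}

#' Best separable (rank-1) approximation of a spatiotemporal field
#'
#' Least-squares space (x) time factorization via the leading singular
#' triplet of the space-by-time unfolding. The sign ambiguity is resolved
#' by making the temporal factor's largest-magnitude sample positive; the
#' spatial factor absorbs the overall sign, so an OFF-dominated field has a
#' negative spatial peak.
#'
#' @param field X x Y x tau array.
#' @return List with `spatial` (X x Y), `temporal` (length tau),
#'   `residual_fraction` (1 - leading singular value^2 / total energy), and
#'   `on_off` ("ON" or "OFF" from the sign of the spatial peak).
#' @export
separable_approximation <- function(field) {
  d <- dim(field)
  A <- matrix(field, d[1] * d[2], d[3])
  if (all(A == 0)) stop("all-zero field")
  sv <- svd(A)
  spatial <- sv$u[, 1] * sv$d[1]
  temporal <- sv$v[, 1]
  sgn <- sign(temporal[which.max(abs(temporal))])
  if (sgn == 0) sgn <- 1
  temporal <- temporal * sgn
  spatial <- spatial * sgn
  peak <- spatial[which.max(abs(spatial))]
  list(spatial = matrix(spatial, d[1], d[2]),
       temporal = temporal,
       residual_fraction = 1 - sv$d[1]^2 / sum(sv$d^2),
       on_off = if (peak >= 0) "ON" else "OFF")
}

#' Write / read a stimulus as plain-text TSV
#'
#' Text container for the X x Y x T contrast array: a header line
#' `# dims=X,Y,T` followed by one line per frame of X*Y tab-separated
#' values in column-major order.
#' @param stim A [stimulus()].
#' @param path File path (`.gz` suffix for compression).
#' @export
write_stimulus_tsv <- function(stim, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  d <- stim$dims
  writeLines(sprintf("# dims=%d,%d,%d", d[1], d[2], d[3]), con)
  utils::write.table(t(matrix(stim$frames, d[1] * d[2], d[3])), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_tsv
#' @export
read_stimulus_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  d <- as.integer(strsplit(sub("^# dims=", "", header), ",")[[1]])
  m <- as.matrix(utils::read.table(con, sep = "\t"))
  stimulus(array(t(m), dim = d))
}
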