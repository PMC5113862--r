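#' Transition entropy of each mode
#'
#' Entropy (bits) of the outgoing transition distribution of each mode,
#' \eqn{H_{trans}(\beta) = -\sum_\alpha p(\alpha|\beta)\log_2
#' p(\alpha|\beta)}; roughly \eqn{2^{H}} modes are accessible from mode
#' beta. Because self-transitions dominate decoded sequences, the
#' off-diagonal variant renormalizes after removing the self-transition:
#' \eqn{\tilde p(\alpha|\beta) = p(\alpha|\beta) / (1 - p(\beta|\beta))},
#' \eqn{\alpha \neq \beta}.
#'
#' @param model An [hmm_params()].
#' @param off_diagonal_only If `TRUE`, use the renormalized off-diagonal
#'   transition probabilities.
#' @return Numeric vector of length M (bits).
#' @export
transition_entropy <- function(model, off_diagonal_only = FALSE) {
  P <- model$transition
  M <- ncol(P)
  out <- numeric(M)
  for (b in seq_len(M)) {
    p <- P[, b]
    if (off_diagonal_only) {
      if (1 - p[b] <= 0)
        stop(sprintf("mode %d has self-transition 1; off-diagonal entropy undefined", b))
      p <- p[-b] / (1 - p[b])
    }
    out[b] <- entropy_bits(p)
  }
  out
}

#' Dwell-time statistics of a decoded mode path
#'
#' Splits the path into maximal constant runs and reports per-mode run
#' lengths and mean dwell times (run length times bin width).
#'
#' @param path A [mode_path()] (or integer vector).
#' @param bin_width Bin width in seconds (taken from the path object when
#'   available).
#' @return List with `runs` (per-mode list of run lengths in bins),
#'   `mean_dwell_s` (per-mode mean dwell in seconds, NA for unvisited
#'   modes), and `n_modes`.
#' @export
dwell_times <- function(path, bin_width = NULL) {
  if (inherits(path, "mode_path")) {
    bin_width <- bin_width %||% path$bin_width
    M <- path$n_modes
    p <- path$path
  } else {
    p <- as.integer(path)
    M <- max(p)
    bin_width <- bin_width %||% 0.02
  }
  if (length(p) == 0) stop("empty path")
  r <- rle(p)
  runs <- lapply(seq_len(M), function(a) r$lengths[r$values == a])
  mean_dwell <- vapply(runs, function(x)
    if (length(x)) mean(x) * bin_width else NA_real_, numeric(1))
  list(runs = runs, mean_dwell_s = mean_dwell, n_modes = M)
}

#' Mode participation at a firing-probability threshold
#'
#' Cell i participates in mode alpha when its mode-conditional spiking
#' probability exceeds theta times its across-mode average:
#' \eqn{m_{i\alpha} / \bar m_i \geq \theta}, with \eqn{\bar m_i} the
#' unweighted mean of \eqn{m_{i\alpha}} over modes. At theta = 0 every cell
#' participates in every mode.
#'
#' @param emissions List of [tree_emission()] (or an [hmm_params()]).
#' @param theta Non-negative threshold.
#' @return List with `member` (N x M logical), `cells_per_mode`,
#'   `modes_per_cell`, and their means.
#' @export
mode_participation <- function(emissions, theta) {
  if (inherits(emissions, "hmm_params")) emissions <- emissions$emissions
  if (theta < 0) stop("theta must be >= 0")
  m <- vapply(emissions, function(e) e$marginals,
              numeric(emissions[[1]]$n_cells))
  m <- matrix(m, ncol = length(emissions))
  mbar <- rowMeans(m)
  ok <- mbar > 0
  if (!all(ok)) warning("cells with zero mean rate excluded")
  member <- matrix(FALSE, nrow(m), ncol(m))
  member[ok, ] <- m[ok, , drop = FALSE] / mbar[ok] >= theta
  list(member = member,
       cells_per_mode = colSums(member),
       modes_per_cell = rowSums(member),
       mean_cells_per_mode = mean(colSums(member)),
       mean_modes_per_cell = mean(rowSums(member)))
}

#' Pairwise mode discriminability by Fisher LDA
#'
#' For each mode pair, projects the two modes' word sets onto the Fisher
#' discriminant direction (shrinkage-regularized pooled covariance) and
#' reports \eqn{d' = |\mu_1 - \mu_2| / \sqrt{(s_1^2 + s_2^2)/2}} along that
#' axis. Each mode's word set contains the unique words assigned to it by
#' the decoded path; words within one bin of a mode transition can be
#' excluded.
#'
#' @param raster A [binary_raster()].
#' @param path A [mode_path()] aligned with the raster.
#' @param exclude_transition_bins Drop bins adjacent to a mode switch
#'   (default TRUE).
#' @param shuffle_control If `TRUE`, permute the bin-to-mode assignment
#'   (preserving per-mode counts) before computing d'.
#' @param seed Seed for the shuffle control.
#' @param lambda_scale Shrinkage scale for the pooled covariance
#'   regularizer lambda = lambda_scale * trace(Sigma) / N.
#' @return Object of class `discriminability_report`: `dprime` (M x M
#'   symmetric, 0 on the diagonal, NA for excluded modes),
#'   `nearest_neighbor` (data.frame per mode: partner, dprime).
#' @export
lda_dprime <- function(raster, path, exclude_transition_bins = TRUE,
                       shuffle_control = FALSE, seed = 1L,
                       lambda_scale = 1e-3) {
  stopifnot(inherits(raster, "binary_raster"))
  p <- if (inherits(path, "mode_path")) path$path else as.integer(path)
  M <- if (inherits(path, "mode_path")) path$n_modes else max(p)
  T_ <- ncol(raster$data)
  if (length(p) != T_) stop("path length must match raster")
  keep <- rep(TRUE, T_)
  if (exclude_transition_bins && T_ > 1) {
    switch_after <- which(diff(p) != 0)      # transition between t and t+1
    keep[unique(c(switch_after, switch_after + 1))] <- FALSE
  }
  if (shuffle_control) p <- with_seed(seed, sample(p))
  word_sets <- lapply(seq_len(M), function(a) {
    idx <- which(p == a & keep)
    if (!length(idx)) return(matrix(0, nrow(raster$data), 0))
    w <- raster$data[, idx, drop = FALSE]
    w[, !duplicated(word_strings(binary_raster(w, raster$bin_width))),
      drop = FALSE]
  })
  usable <- vapply(word_sets, ncol, integer(1)) >= 2
  if (any(!usable))
    warning("modes with fewer than 2 unique words excluded from LDA")
  dp <- matrix(NA_real_, M, M)
  diag(dp) <- 0
  for (a in seq_len(M - 1)) for (b in (a + 1):M) {
    if (!usable[a] || !usable[b]) next
    dp[a, b] <- dp[b, a] <- fisher_dprime(t(word_sets[[a]]), t(word_sets[[b]]),
                                          lambda_scale)
  }
  nn <- data.frame(mode = seq_len(M), partner = NA_integer_,
                   dprime = NA_real_)
  for (a in seq_len(M)) {
    row <- dp[a, ]
    row[a] <- NA
    if (all(is.na(row))) next
    nn$partner[a] <- which.min(row)
    nn$dprime[a] <- min(row, na.rm = TRUE)
  }
  structure(list(dprime = dp, nearest_neighbor = nn),
            class = "discriminability_report")
}

# d' between two word clouds (observations in rows) along the Fisher axis.
fisher_dprime <- function(x1, x2, lambda_scale = 1e-3) {
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  S <- (stats::cov(x1) * (nrow(x1) - 1) + stats::cov(x2) * (nrow(x2) - 1)) /
    (nrow(x1) + nrow(x2) - 2)
  N <- ncol(x1)
  lambda <- lambda_scale * sum(diag(S)) / N
  if (lambda <= 0) lambda <- lambda_scale
  wdir <- solve(S + diag(lambda, N), mu1 - mu2)
  z1 <- as.numeric(x1 %*% wdir)
  z2 <- as.numeric(x2 %*% wdir)
  s2 <- (stats::var(z1) + stats::var(z2)) / 2
  if (s2 <= 0) return(if (abs(mean(z1) - mean(z2)) < 1e-12) 0 else Inf)
  abs(mean(z1) - mean(z2)) / sqrt(s2)
}
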