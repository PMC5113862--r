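#' Activation matrix of one mode (or word) across stimulus repeats
#'
#' @param active R x T 0/1 matrix: whether the event (mode active / word
#'   occurred) happened in each bin of each repeat.
#' @param bin_width Bin width in seconds.
#' @return Object of class `activation_matrix`.
#' @export
activation_matrix <- function(active, bin_width = 0.02) {
  active <- as.matrix(active)
  if (!all(active %in% c(0L, 1L))) stop("entries must be 0/1")
  storage.mode(active) <- "integer"
  structure(list(active = active, n_repeats = nrow(active),
                 n_bins = ncol(active), bin_width = bin_width),
            class = "activation_matrix")
}

#' Per-mode activation matrices from decoded repeat paths
#'
#' Decodes each repeat with the Viterbi path of `model` and returns, for
#' each mode, the R x T activation matrix (mode active = decoded in that
#' bin).
#'
#' @param model An [hmm_params()].
#' @param repeats A [repeat_set()].
#' @return List of M [activation_matrix()] objects.
#' @export
mode_activations <- function(model, repeats) {
  stopifnot(inherits(repeats, "repeat_set"))
  paths <- lapply(repeats$rasters, function(r) viterbi(model, r)$path)
  pm <- do.call(rbind, paths)
  bw <- repeats$rasters[[1]]$bin_width
  lapply(seq_len(model$n_modes), function(a)
    activation_matrix((pm == a) * 1L, bw))
}

#' Information efficiency of an activation pattern across repeats
#'
#' With r(t) the fraction of repeats on which the event was active at bin
#' t, and \eqn{\bar r} its time average, the output entropy is the binary
#' entropy of \eqn{\bar r}, the noise entropy is the time-averaged binary
#' entropy of r(t), and the information efficiency is their normalized
#' difference \eqn{(S_{out} - S_{noise}) / S_{out}} (mutual information
#' about time-in-stimulus over output entropy); defined as 0 when
#' \eqn{S_{out} = 0}.
#'
#' @param act An [activation_matrix()] with at least 2 repeats.
#' @return List with `S_out`, `S_noise` (bits) and `efficiency`.
#' @export
information_efficiency <- function(act) {
  stopifnot(inherits(act, "activation_matrix"))
  if (act$n_repeats < 2) stop("need at least 2 repeats")
  r <- colMeans(act$active)
  S_out <- binary_entropy(mean(r))
  S_noise <- mean(binary_entropy(r))
  eff <- if (S_out > 0) (S_out - S_noise) / S_out else 0
  list(S_out = S_out, S_noise = S_noise, efficiency = eff)
}

#' Windowed event reproducibility across repeats
#'
#' For every occurrence of the event (a given mode or word being active at
#' some bin of some repeat), computes the fraction of the other repeats
#' that contain an occurrence within +/- `window` seconds of that bin, and
#' averages over all occurrences. Default window 80 ms (+/- 4 bins at
#' 20 ms).
#'
#' @param act An [activation_matrix()].
#' @param window Half-window in seconds (inclusive, two-sided).
#' @return Mean fraction in `[0, 1]`.
#' @export
event_reproducibility <- function(act, window = 0.08) {
  stopifnot(inherits(act, "activation_matrix"))
  if (window < 0) stop("window must be >= 0")
  A <- act$active
  R <- nrow(A); T_ <- ncol(A)
  if (sum(A) == 0) stop("event never occurs; reproducibility undefined")
  wb <- as.integer(round(window / act$bin_width))
  # near[r, t] = does repeat r have an occurrence within wb bins of t
  near <- A
  if (wb > 0) {
    for (r in seq_len(R)) {
      occ <- which(A[r, ] == 1L)
      hit <- logical(T_)
      for (o in occ) hit[max(1, o - wb):min(T_, o + wb)] <- TRUE
      near[r, ] <- as.integer(hit)
    }
  }
  total <- 0; count <- 0
  for (r in seq_len(R)) {
    occ <- which(A[r, ] == 1L)
    if (!length(occ)) next
    others <- near[-r, occ, drop = FALSE]
    total <- total + sum(colMeans(others))
    count <- count + length(occ)
  }
  total / count
}

#' Trial-to-trial Hamming noise
#'
#' Average Hamming distance between the population words of all unordered
#' repeat pairs at each time bin; optionally aggregated against the mean
#' spike count of the bin.
#'
#' @param repeats A [repeat_set()] with at least 2 repeats.
#' @return List with `per_bin` (length-T mean Hamming distance),
#'   `mean_k` (length-T mean spike count across repeats), and `by_k`
#'   (data.frame aggregating `per_bin` over rounded `mean_k`).
#' @export
hamming_noise <- function(repeats) {
  stopifnot(inherits(repeats, "repeat_set"))
  R <- repeats$n_repeats
  if (R < 2) stop("need at least 2 repeats")
  T_ <- ncol(repeats$rasters[[1]]$data)
  per_bin <- numeric(T_)
  ksum <- numeric(T_)
  for (a in seq_len(R - 1)) for (b in (a + 1):R) {
    per_bin <- per_bin + colSums(abs(repeats$rasters[[a]]$data -
                                       repeats$rasters[[b]]$data))
  }
  per_bin <- per_bin / (R * (R - 1) / 2)
  for (a in seq_len(R)) ksum <- ksum + colSums(repeats$rasters[[a]]$data)
  mean_k <- ksum / R
  kr <- round(mean_k)
  by_k <- stats::aggregate(per_bin, list(k = kr), mean)
  names(by_k)[2] <- "mean_hamming"
  list(per_bin = per_bin, mean_k = mean_k, by_k = by_k)
}

#' Shuffled-means null model
#'
#' Control for whether reliability depends on the placement of the mode
#' means in word space. Starting from an HMM with independent (edge-free)
#' emissions, the entries of each mode's mean vector are randomly permuted
#' across cells, independently per mode; the transition matrix and initial
#' distribution are then re-optimized by EM with the emissions frozen.
#'
#' @param model An [hmm_params()] with independent emissions (no tree
#'   edges), e.g. from `baum_welch_fit(..., tree = FALSE)`.
#' @param raster The [binary_raster()] to re-fit transitions on.
#' @param seed Integer seed for the permutations.
#' @param max_iter,tol EM controls for the partial re-fit.
#' @return A control [hmm_params()].
#' @export
shuffled_means_control <- function(model, raster, seed = 1L,
                                   max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(model, "hmm_params"))
  if (any(vapply(model$emissions, function(e) nrow(e$edges), integer(1)) > 0))
    stop("shuffled-means control requires independent (edge-free) emissions")
  N <- model$n_cells
  perms <- with_seed(seed, lapply(seq_len(model$n_modes),
                                  function(a) sample.int(N)))
  emissions <- lapply(seq_len(model$n_modes), function(a)
    tree_emission(model$emissions[[a]]$marginals[perms[[a]]]))
  par <- list(transition = model$transition, initial = model$initial,
              emissions = emissions)
  data <- raster$data
  logB <- vapply(emissions, emission_loglik, numeric(ncol(data)),
                 raster = data)
  logB <- matrix(logB, ncol = model$n_modes)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- .fb_core(logB, par$transition, par$initial, FALSE)
    if (is.finite(ll_prev) && (fb$loglik - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- fb$loglik
    par <- m_step(data, fb$gamma, fb$xi_sum, model$eta, 1e-6, FALSE,
                  NULL, NULL, fixed_emissions = emissions)
  }
  hmm_params(par$transition, par$initial, emissions, model$eta,
             meta = c(model$meta[c("bin_width")],
                      list(control = "shuffled_means", seed = seed)))
}

#' Random-partition null assignment of words to modes
#'
#' Deterministic word-to-mode map matched in mode count and probability
#' mass to the true modes: each mode starts with a capacity equal to its
#' stationary weight; words are visited in decreasing probability order and
#' assigned uniformly at random among modes whose remaining capacity is at
#' least the word's probability, decrementing the chosen mode's capacity.
#' When no mode qualifies the word is assigned uniformly at random.
#'
#' @param word_table Data frame from [word_frequencies()] (columns `word`,
#'   `frequency`).
#' @param weights Mode weights (e.g. `stationary_weights(model)$weights`).
#' @param seed Integer seed.
#' @return Named integer vector: mode index per word (names = word
#'   strings).
#' @export
random_partition_control <- function(word_table, weights, seed = 1L) {
  w <- as.numeric(weights)
  if (abs(sum(w) - 1) > 0.01) stop("weights must sum to ~1")
  tab <- word_table[order(-word_table$frequency, word_table$word), ]
  with_seed(seed, {
    cap <- w
    assign_ <- integer(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      p <- tab$frequency[i]
      ok <- which(cap >= p)
      if (length(ok)) {
        a <- if (length(ok) == 1) ok else sample(ok, 1)
        cap[a] <- cap[a] - p
      } else {
        a <- sample.int(length(w), 1)
      }
      assign_[i] <- a
    }
    stats::setNames(assign_, tab$word)
  })
}

#' Chance baseline: efficiency after within-repeat time permutation
#'
#' Independently permutes the time bins of each repeat's activation row
#' (preserving each repeat's activation count) and recomputes
#' [information_efficiency()].
#'
#' @param act An [activation_matrix()].
#' @param seed Integer seed.
#' @return As [information_efficiency()].
#' @export
chance_baseline <- function(act, seed = 1L) {
  stopifnot(inherits(act, "activation_matrix"))
  A <- act$active
  A <- with_seed(seed, t(apply(A, 1, sample)))
  information_efficiency(activation_matrix(A, act$bin_width))
}
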