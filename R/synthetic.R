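#' Synthetic ground-truth mode HMM
#'
#' Builds an HMM emulating the structure reported for retinal population
#' recordings: a dominant near-silent mode plus active modes in which a
#' small subset (~10) of cells fires with elevated probability, chain-tree
#' emissions with mild positive edge correlations, and a transition matrix
#' with a controllable self-transition (dwell) probability.
#'
#' `separation` interpolates the active-cell firing probability between the
#' silent baseline (separation 0: all modes identical to the silent mode)
#' and a strongly active level (0.5 at separation 1).
#'
#' @param n_cells N.
#' @param n_modes M (mode 1 is the near-silent mode).
#' @param separation Mode separation in `[0, 1]`.
#' @param self_transition Diagonal transition probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param cells_per_mode Number of active cells per active mode (default
#'   `min(10, n_cells)`).
#' @param baseline Silent-mode firing probability (default 0.005 per bin,
#'   i.e. 0.25 Hz at 20 ms bins).
#' @param edge_corr Pearson correlation on chain-tree edges (default 0.2).
#' @param bin_width Bin width stored in the model meta (default 20 ms).
#' @return An [hmm_params()] passing all container invariants.
#' @export
make_ground_truth_model <- function(n_cells, n_modes, separation = 0.8,
                                    self_transition = 0.7, seed = 1L,
                                    cells_per_mode = NULL, baseline = 0.005,
                                    edge_corr = 0.2, bin_width = 0.02) {
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (separation < 0 || separation > 1) stop("separation must lie in [0, 1]")
  if (self_transition < 0 || self_transition >= 1)
    stop("self_transition must lie in [0, 1)")
  cells_per_mode <- cells_per_mode %||% min(10L, n_cells)
  with_seed(seed, {
    emissions <- vector("list", n_modes)
    for (a in seq_len(n_modes)) {
      m <- rep(baseline, n_cells)
      if (a > 1) {
        cells <- sample.int(n_cells, cells_per_mode)
        m[cells] <- baseline + separation * (0.5 - baseline) *
          stats::runif(cells_per_mode, 0.7, 1)
      }
      if (n_cells > 1) {
        chain <- sample.int(n_cells)
        edges <- cbind(pmin(chain[-n_cells], chain[-1]),
                       pmax(chain[-n_cells], chain[-1]))
        ord <- order(edges[, 1], edges[, 2])
        edges <- edges[ord, , drop = FALSE]
        mi <- m[edges[, 1]]; mj <- m[edges[, 2]]
        c11 <- mi * mj + edge_corr * sqrt(mi * (1 - mi) * mj * (1 - mj))
        emissions[[a]] <- make_tree_emission(m, edges, c11)
      } else {
        emissions[[a]] <- make_tree_emission(m)
      }
    }
    if (n_modes == 1) {
      transition <- matrix(1, 1, 1)
    } else {
      transition <- matrix(0, n_modes, n_modes)
      for (b in seq_len(n_modes)) {
        off <- stats::runif(n_modes - 1, 0.2, 1)
        off <- off / sum(off) * (1 - self_transition)
        transition[-b, b] <- off
        transition[b, b] <- self_transition
      }
    }
    initial <- rep(1 / n_modes, n_modes)
    hmm_params(transition, initial, emissions, eta = 0.002,
               meta = list(bin_width = bin_width, seed = seed,
                           separation = separation,
                           self_transition = self_transition))
  })
}

#' Simulate stimulus-locked repeats from a ground-truth HMM
#'
#' Emulates repeated presentations of an identical stimulus: one master
#' mode path is drawn from the chain; each repeat reuses the master path,
#' but at every bin, with probability `jitter`, the mode is instead
#' resampled from the transition distribution conditioned on the repeat's
#' previous bin. Words are then drawn independently from the per-mode
#' emissions. `jitter = 0` gives identical mode paths across repeats
#' (emission noise only); `jitter = 1` gives independent chain draws.
#'
#' @param model An [hmm_params()].
#' @param T_ Bins per repeat.
#' @param n_repeats R.
#' @param jitter Per-bin path resampling probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: `model`, `mode_paths` (list of
#'   [mode_path()]), `repeats` ([repeat_set()]), `master_path`, and
#'   `provenance`.
#' @export
simulate_repeats <- function(model, T_, n_repeats, jitter = 0.1, seed = 1L) {
  stopifnot(inherits(model, "hmm_params"))
  if (n_repeats < 1) stop("need at least one repeat")
  if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]")
  bw <- model$meta$bin_width %||% 0.02
  with_seed(seed, {
    master <- sample_mode_chain(model, T_)
    paths <- vector("list", n_repeats)
    rasters <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      p <- master
      resample <- stats::runif(T_) < jitter
      if (resample[1]) p[1] <- sample.int(model$n_modes, 1,
                                          prob = model$initial)
      for (t in seq_len(T_ - 1) + 1) {
        if (resample[t])
          p[t] <- sample.int(model$n_modes, 1,
                             prob = model$transition[, p[t - 1]])
      }
      paths[[r]] <- mode_path(p, model$n_modes, bw)
      rasters[[r]] <- binary_raster(sample_words_for_path(model, p), bw)
    }
    structure(list(model = model, mode_paths = paths,
                   repeats = repeat_set(rasters), master_path = master,
                   provenance = list(seed = seed, T_ = T_,
                                     n_repeats = n_repeats, jitter = jitter)),
              class = "ground_truth")
  })
}

#' Match fitted modes to ground-truth modes by greedy mean-vector matching
#'
#' Utility for parameter-recovery checks: finds the permutation of fitted
#' modes minimizing (greedily) the L-infinity distance between matched mean
#' vectors.
#'
#' @param fit,truth [hmm_params()] objects with equal M and N.
#' @return Integer vector `perm` such that fitted mode `perm[a]` matches
#'   truth mode `a`.
#' @export
match_modes <- function(fit, truth) {
  M <- truth$n_modes
  if (fit$n_modes != M) stop("mode counts differ")
  mf <- vapply(fit$emissions, function(e) e$marginals, numeric(fit$n_cells))
  mt <- vapply(truth$emissions, function(e) e$marginals, numeric(fit$n_cells))
  cost <- matrix(0, M, M)
  for (a in seq_len(M)) for (b in seq_len(M))
    cost[a, b] <- max(abs(mt[, a] - mf[, b]))
  perm <- integer(M)
  used <- logical(M)
  for (step in seq_len(M)) {
    cost2 <- cost
    cost2[perm > 0, ] <- Inf
    cost2[, used] <- Inf
    ij <- which(cost2 == min(cost2), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
  }
  perm
}
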