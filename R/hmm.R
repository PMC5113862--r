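#' Hidden Markov model over collective modes
#'
#' Parameters of the mode HMM: M modes, a column-stochastic transition
#' matrix with entry (alpha, beta) = P(alpha at t | beta at t-1), an initial
#' mode distribution, and one [tree_emission()] per mode. `eta` records the
#' shrinkage regularization strength used during fitting.
#'
#' @param transition M x M column-stochastic matrix.
#' @param initial Length-M probability vector.
#' @param emissions List of M [tree_emission()] objects sharing N.
#' @param eta Regularization strength in `[0, 1]`.
#' @param meta Optional list of provenance fields (bin_width, seed, ...).
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(transition, initial, emissions, eta = 0.002,
                       meta = list()) {
  transition <- as.matrix(transition)
  M <- length(emissions)
  if (M < 1) stop("need at least one mode")
  if (!all(dim(transition) == c(M, M))) stop("transition must be M x M")
  if (any(transition < 0)) stop("transition entries must be non-negative")
  if (any(abs(colSums(transition) - 1) > 1e-8))
    stop("transition columns must sum to 1")
  initial <- as.numeric(initial)
  if (length(initial) != M || abs(sum(initial) - 1) > 1e-8 || any(initial < 0))
    stop("initial must be a length-M probability vector")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  N <- emissions[[1]]$n_cells
  for (em in emissions) {
    if (!inherits(em, "tree_emission")) stop("emissions must be tree_emission")
    if (em$n_cells != N) stop("emissions must share N")
  }
  structure(list(n_modes = M, n_cells = N, transition = transition,
                 initial = initial, emissions = emissions, eta = eta,
                 meta = meta),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d modes over %d cells (eta = %g)\n",
              x$n_modes, x$n_cells, x$eta))
  invisible(x)
}

# T x M matrix of per-bin emission log-likelihoods.
emission_loglik_matrix <- function(model, raster) {
  data <- if (inherits(raster, "binary_raster")) raster$data else raster
  if (nrow(data) != model$n_cells) stop("raster N does not match emissions")
  vapply(model$emissions, emission_loglik, numeric(ncol(data)), raster = data)
}

#' Forward-backward posteriors and sequence log-likelihood
#'
#' Exact scaled forward-backward pass. The returned log-likelihood is
#' \eqn{\log \sum_{\alpha(\cdot)} \prod_t Q_{\alpha(t)}(\sigma(t))
#' P(\alpha(t)|\alpha(t-1))}, the full sum over mode sequences.
#'
#' @param model An [hmm_params()].
#' @param raster A [binary_raster()].
#' @param keep_xi If `TRUE`, also return the full pairwise posterior array
#'   `xi` of dimension (T-1) x M x M with `xi[t, a, b]` = P(mode a at t+1,
#'   mode b at t | data). Off by default to save memory; the summed
#'   `xi_sum` needed by the M-step is always returned.
#' @return Object of class `hmm_posteriors`: `gamma` (T x M), `xi_sum`
#'   (M x M), `loglik`, and optionally `xi`.
#' @export
forward_backward <- function(model, raster, keep_xi = FALSE) {
  stopifnot(inherits(model, "hmm_params"))
  logB <- emission_loglik_matrix(model, raster)
  fb <- .fb_core(logB, model$transition, model$initial, keep_xi)
  out <- list(gamma = fb$gamma, xi_sum = fb$xi_sum, loglik = fb$loglik)
  if (keep_xi) {
    Tm1 <- nrow(logB) - 1L
    out$xi <- array(fb$xi, dim = c(Tm1, model$n_modes, model$n_modes))
  }
  class(out) <- "hmm_posteriors"
  out
}

#' Viterbi decoding of the mode sequence
#'
#' Returns the single mode path maximizing the joint probability of path
#' and observations; ties are broken toward the lower mode index.
#'
#' @inheritParams forward_backward
#' @return Object of class `mode_path`: integer vector `path` (1-based mode
#'   indices, length T) plus `n_modes` and `bin_width`.
#' @export
viterbi <- function(model, raster) {
  stopifnot(inherits(model, "hmm_params"))
  logB <- emission_loglik_matrix(model, raster)
  path <- .viterbi_core(logB, log(model$transition), log(model$initial))
  mode_path(path, model$n_modes,
            if (inherits(raster, "binary_raster")) raster$bin_width else 0.02)
}

#' Decoded mode path
#' @param path Integer vector of 1-based mode indices.
#' @param n_modes M.
#' @param bin_width Bin width in seconds.
#' @export
mode_path <- function(path, n_modes, bin_width = 0.02) {
  path <- as.integer(path)
  if (any(path < 1 | path > n_modes)) stop("path entries out of range")
  structure(list(path = path, n_modes = as.integer(n_modes),
                 bin_width = bin_width),
            class = "mode_path")
}

#' Stationary mixture weights of the mode chain
#'
#' Solves \eqn{w = P w} (the stationarity / detailed-balance condition of
#' the printed model) for the unique normalized weight vector, via the
#' leading eigenvector of the transition matrix.
#'
#' @param model An [hmm_params()].
#' @return Object of class `stationary_mixture`: `weights` (length M,
#'   summing to 1) and `emissions`.
#' @export
stationary_weights <- function(model) {
  stopifnot(inherits(model, "hmm_params"))
  P <- model$transition
  ev <- eigen(P)
  on_circle <- sum(abs(abs(ev$values) - 1) < 1e-8)
  if (on_circle > 1) stop("no unique stationary distribution")
  w <- Re(ev$vectors[, which.max(Re(ev$values))])
  w <- w / sum(w)
  if (any(w < -1e-10)) stop("no unique stationary distribution")
  w <- pmax(w, 0)
  w <- w / sum(w)
  structure(list(weights = w, emissions = model$emissions),
            class = "stationary_mixture")
}

#' Static mixture log-likelihood over words
#'
#' Evaluates the time-independent mixture \eqn{P_{mix}(w) = \sum_\alpha
#' w_\alpha Q_\alpha(w)} on the empirical word distribution of a raster and
#' returns \eqn{L = \sum_w f_{emp}(w) \ln P_{mix}(w)} restricted to words
#' occurring at least `min_count` times. With `min_count = 1`, L is the
#' mean per-bin log-likelihood (natural log).
#'
#' @param mixture A [stationary_weights()] result (or any list with
#'   `weights` and `emissions`).
#' @param raster A [binary_raster()].
#' @param min_count Minimum word count to include (1 = full L; 2 = the
#'   truncated convention restricted to repeated words).
#' @return List with `words` (data.frame: word, count, frequency,
#'   p_model, logp_model) and `L`.
#' @export
static_log_likelihood <- function(mixture, raster, min_count = 1) {
  if (min_count < 1) stop("min_count must be >= 1")
  tab <- word_frequencies(raster)
  U <- do.call(cbind, lapply(strsplit(tab$word, ""), as.integer))
  ll <- vapply(mixture$emissions, emission_loglik, numeric(ncol(U)), raster = U)
  ll <- matrix(ll, ncol = length(mixture$emissions))
  pm <- as.numeric(exp(ll) %*% mixture$weights)
  tab$p_model <- pm
  tab$logp_model <- log(pm)
  keep <- tab$count >= min_count
  list(words = tab, L = sum(tab$frequency[keep] * tab$logp_model[keep]))
}

# ---- Baum-Welch ------------------------------------------------------------

# One M-step: from posteriors to new parameters. Shrinks each mode's
# marginal and pairwise tables toward the global tables with weight eta,
# then reselects the Chow-Liu tree.
m_step <- function(data, gamma, xi_sum, eta, eps, tree,
                   global_m, global_P11, fixed_emissions = NULL) {
  M <- ncol(gamma)
  cs <- colSums(xi_sum)
  transition <- xi_sum
  for (b in seq_len(M)) {
    transition[, b] <- if (cs[b] > 0) xi_sum[, b] / cs[b] else rep(1 / M, M)
  }
  initial <- pmax(gamma[1, ], 1e-12)
  initial <- initial / sum(initial)
  if (!is.null(fixed_emissions)) {
    return(list(transition = transition, initial = initial,
                emissions = fixed_emissions))
  }
  emissions <- vector("list", M)
  sw <- colSums(gamma)
  Gm <- data %*% gamma  # N x M weighted spike counts
  for (a in seq_len(M)) {
    if (sw[a] <= 0) {
      m <- global_m
      P11 <- global_P11
    } else {
      m <- (1 - eta) * (Gm[, a] / sw[a]) + eta * global_m
      wa <- gamma[, a]
      P11 <- (1 - eta) * (tcrossprod(sweep(data, 2, wa, "*"), data) / sw[a]) +
        eta * global_P11
    }
    if (tree && length(m) > 1) {
      stats <- pairwise_mi(m, P11, eps)
      edges <- max_spanning_tree(stats$mi)
      c11 <- stats$c11[cbind(edges[, 1], edges[, 2])]
      emissions[[a]] <- make_tree_emission(m, edges, c11, eps)
    } else {
      emissions[[a]] <- make_tree_emission(m, eps = eps)
    }
  }
  list(transition = transition, initial = initial, emissions = emissions)
}

# Random one-hot responsibilities: each bin assigned a uniform random mode.
init_from_random_assignment <- function(data, M, eta, eps, tree,
                                        global_m, global_P11) {
  T_ <- ncol(data)
  assign_ <- sample.int(M, T_, replace = TRUE)
  gamma <- matrix(0, T_, M)
  gamma[cbind(seq_len(T_), assign_)] <- 1
  # transition counts of the random assignment path
  xi_sum <- matrix(0, M, M)
  for (t in 2:T_) xi_sum[assign_[t], assign_[t - 1]] <-
    xi_sum[assign_[t], assign_[t - 1]] + 1
  xi_sum <- xi_sum + 1  # Laplace smoothing so all transitions are possible
  m_step(data, gamma, xi_sum, eta, eps, tree, global_m, global_P11)
}

#' Fit the mode HMM by Baum-Welch EM
#'
#' Expectation-maximization with a modified M-step: per-mode
#' responsibility-weighted marginal and pairwise tables are shrunk toward
#' the global (mode-independent) tables with weight `eta`, after which each
#' mode's Chow-Liu tree is reselected. Several random restarts are run and
#' the fit with the best training log-likelihood kept.
#'
#' @param raster A [binary_raster()].
#' @param n_modes Number of modes M (>= 1).
#' @param eta Shrinkage strength in `[0, 1]`; default 0.002.
#' @param seed Integer seed (controls restarts deterministically).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood improvement threshold (default 1e-6).
#' @param n_restarts Number of random restarts (default 5).
#' @param tree If `FALSE`, fit independent (edge-free) emissions.
#' @param eps Probability floor for emission tables.
#' @return An [hmm_params()] whose `meta` holds `loglik` (final training
#'   log-likelihood), `loglik_trace`, `n_iter`, `seed`, `bin_width`.
#' @export
baum_welch_fit <- function(raster, n_modes, eta = 0.002, seed = 1L,
                           max_iter = 500L, tol = 1e-6, n_restarts = 5L,
                           tree = TRUE, eps = 1e-6) {
  stopifnot(inherits(raster, "binary_raster"))
  data <- raster$data
  T_ <- ncol(data)
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (T_ <= n_modes) stop("need more bins than modes")
  n_words <- nrow(unique(t(data)))
  if (n_modes > n_words)
    warning("more modes than distinct observed words; degenerate modes likely")
  global_m <- rowMeans(data)
  global_P11 <- tcrossprod(data) / T_
  restart_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                              n_restarts))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(restart_seeds[r],
                     bw_single_run(data, n_modes, eta, max_iter, tol, tree,
                                   eps, global_m, global_P11))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  hmm_params(best$par$transition, best$par$initial, best$par$emissions, eta,
             meta = list(loglik = best$loglik, loglik_trace = best$trace,
                         n_iter = length(best$trace), seed = seed,
                         bin_width = raster$bin_width))
}

bw_single_run <- function(data, M, eta, max_iter, tol, tree, eps,
                          global_m, global_P11) {
  par <- init_from_random_assignment(data, M, eta, eps, tree,
                                     global_m, global_P11)
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- vapply(par$emissions, emission_loglik, numeric(ncol(data)),
                   raster = data)
    logB <- matrix(logB, ncol = M)
    fb <- .fb_core(logB, par$transition, par$initial, FALSE)
    trace <- c(trace, fb$loglik)
    if (is.finite(ll_prev) &&
        (fb$loglik - ll_prev) < tol * abs(ll_prev)) {
      ll_prev <- fb$loglik
      break
    }
    ll_prev <- fb$loglik
    par <- m_step(data, fb$gamma, fb$xi_sum, eta, eps, tree,
                  global_m, global_P11)
  }
  list(par = par, loglik = ll_prev, trace = trace)
}

#' Select the number of modes by cross-validated likelihood
#'
#' Splits the raster into `n_folds` contiguous time blocks; for each
#' candidate M and fold, fits on the remaining blocks and evaluates the
#' held-out mean per-bin static mixture log-likelihood
#' ([static_log_likelihood()] with `min_count = 1`). Returns the candidate
#' maximizing the mean held-out log-likelihood.
#'
#' @param raster A [binary_raster()].
#' @param candidates Integer vector of candidate M values.
#' @param n_folds Number of contiguous folds (default 2).
#' @param eta Shrinkage strength passed to the fits.
#' @param seed Integer seed.
#' @param n_restarts Restarts per fit (default 2; fewer than
#'   [baum_welch_fit()]'s default to keep cross-validation tractable).
#' @param max_iter Maximum EM iterations per fit.
#' @return List with `table` (data.frame: n_modes, cv_loglik and per-fold
#'   columns) and `chosen` (the argmax M; ties toward the smaller M).
#' @export
select_num_modes <- function(raster, candidates, n_folds = 2, eta = 0.002,
                             seed = 1L, n_restarts = 2L, max_iter = 300L) {
  stopifnot(inherits(raster, "binary_raster"))
  if (length(candidates) < 1) stop("no candidates")
  if (n_folds < 2) stop("need at least 2 folds")
  T_ <- ncol(raster$data)
  bounds <- round(seq(0, T_, length.out = n_folds + 1))
  if (any(diff(bounds) < 2)) stop("folds would be shorter than 2 bins")
  fold_ll <- matrix(NA_real_, length(candidates), n_folds)
  fit_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max %/% 2,
                                                 length(candidates) * n_folds),
                                      length(candidates), n_folds))
  for (f in seq_len(n_folds)) {
    test_idx <- (bounds[f] + 1):bounds[f + 1]
    train <- binary_raster(raster$data[, -test_idx, drop = FALSE],
                           raster$bin_width, raster$cell_ids)
    test <- binary_raster(raster$data[, test_idx, drop = FALSE],
                          raster$bin_width, raster$cell_ids)
    for (ci in seq_along(candidates)) {
      fit <- baum_welch_fit(train, candidates[ci], eta = eta,
                            seed = fit_seeds[ci, f], max_iter = max_iter,
                            n_restarts = n_restarts)
      mix <- stationary_weights(fit)
      fold_ll[ci, f] <- static_log_likelihood(mix, test, min_count = 1)$L
    }
  }
  tab <- data.frame(n_modes = candidates, cv_loglik = rowMeans(fold_ll))
  for (f in seq_len(n_folds)) tab[[paste0("fold", f)]] <- fold_ll[, f]
  list(table = tab, chosen = candidates[which.max(tab$cv_loglik)])
}

#' Sample a raster (and its mode path) from an HMM
#'
#' @param model An [hmm_params()].
#' @param T_ Number of time bins.
#' @param seed Integer seed.
#' @param bin_width Bin width for the returned raster (default from
#'   `model$meta$bin_width`, else 20 ms).
#' @return List with `raster` ([binary_raster()]) and `path`
#'   ([mode_path()]).
#' @export
sample_hmm <- function(model, T_, seed = 1L, bin_width = NULL) {
  stopifnot(inherits(model, "hmm_params"))
  if (T_ < 1) stop("T_ must be >= 1")
  bin_width <- bin_width %||% (model$meta$bin_width %||% 0.02)
  with_seed(seed, {
    path <- sample_mode_chain(model, T_)
    data <- sample_words_for_path(model, path)
    list(raster = binary_raster(data, bin_width),
         path = mode_path(path, model$n_modes, bin_width))
  })
}

sample_mode_chain <- function(model, T_) {
  M <- model$n_modes
  path <- integer(T_)
  path[1] <- sample.int(M, 1, prob = model$initial)
  for (t in seq_len(T_ - 1) + 1)
    path[t] <- sample.int(M, 1, prob = model$transition[, path[t - 1]])
  path
}

sample_words_for_path <- function(model, path) {
  N <- model$n_cells
  data <- matrix(0L, N, length(path))
  for (a in seq_len(model$n_modes)) {
    idx <- which(path == a)
    if (length(idx))
      data[, idx] <- t(sample_emission_impl(model$emissions[[a]], length(idx)))
  }
  data
}

# ---- serialization ---------------------------------------------------------

#' Write / read an HMM as JSON
#'
#' The JSON holds `n_modes`, `eta`, `transition` (column-stochastic,
#' row-major), `initial`, `emissions` (per mode: `marginals`, `edges` as
#' 0-based pairs, `edge_joints` as p00,p01,p10,p11 per edge), and `meta`.
#'
#' @param model An [hmm_params()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns an [hmm_params()].
#' @export
write_model_json <- function(model, path) {
  em <- lapply(model$emissions, function(e) {
    list(marginals = e$marginals,
         edges = if (nrow(e$edges)) unname(e$edges) - 1L else list(),
         edge_joints = lapply(e$edge_joints, function(tab)
           c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])))
  })
  meta <- model$meta
  meta$loglik_trace <- NULL
  obj <- list(n_modes = model$n_modes, eta = model$eta,
              transition = model$transition, initial = model$initial,
              emissions = em, meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  M <- obj$n_modes
  emissions <- lapply(obj$emissions, function(e) {
    marg <- as.numeric(unlist(e$marginals))
    if (length(e$edges) == 0) return(tree_emission(marg))
    edges <- do.call(rbind, lapply(e$edges, function(p) as.integer(unlist(p)))) + 1L
    jt <- lapply(e$edge_joints, function(v) {
      v <- as.numeric(unlist(v))  # stored p00, p01, p10, p11
      matrix(c(v[1], v[3], v[2], v[4]), 2, 2)
    })
    tree_emission(marg, edges, jt)
  })
  transition <- do.call(rbind, lapply(obj$transition,
                                      function(r) as.numeric(unlist(r))))
  hmm_params(transition, as.numeric(unlist(obj$initial)), emissions,
             obj$eta, meta = lapply(obj$meta, unlist))
}
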