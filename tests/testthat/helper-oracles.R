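# Brute-force oracles kept independent of the package internals they check.

# All binary words of length n, one word per row.
all_words <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# Exact word probabilities of a tree emission by enumeration.
enum_word_probs <- function(model) {
  W <- all_words(model$n_cells)
  p <- exp(apply(W, 1, function(w) emission_logprob(model, w)))
  list(words = W, p = p)
}

# Brute-force HMM sequence log-likelihood: explicit sum over all M^T mode
# sequences, using only emission_logprob and the raw parameters.
brute_hmm_loglik <- function(model, data) {
  M <- model$n_modes
  T_ <- ncol(data)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), T_)))
  logem <- sapply(seq_len(M), function(a)
    apply(data, 2, function(w) emission_logprob(model$emissions[[a]], w)))
  logem <- matrix(logem, nrow = T_)
  total <- -Inf
  for (s in seq_len(nrow(seqs))) {
    z <- seqs[s, ]
    lp <- log(model$initial[z[1]]) + logem[1, z[1]]
    for (t in seq_len(T_ - 1) + 1)
      lp <- lp + log(model$transition[z[t], z[t - 1]]) + logem[t, z[t]]
    total <- max(total, lp) + log1p(exp(min(total, lp) - max(total, lp)))
  }
  total
}

# Brute-force Viterbi: argmax over all mode sequences, ties toward the
# lexicographically smallest sequence.
brute_viterbi <- function(model, data) {
  M <- model$n_modes
  T_ <- ncol(data)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), T_)))
  # expand.grid varies the first column fastest; order rows lexicographically
  seqs <- seqs[do.call(order, as.data.frame(seqs)), , drop = FALSE]
  best <- -Inf; bestseq <- NULL
  for (s in seq_len(nrow(seqs))) {
    z <- seqs[s, ]
    lp <- log(model$initial[z[1]]) +
      emission_logprob(model$emissions[[z[1]]], data[, 1])
    for (t in seq_len(T_ - 1) + 1)
      lp <- lp + log(model$transition[z[t], z[t - 1]]) +
        emission_logprob(model$emissions[[z[t]]], data[, t])
    if (lp > best + 1e-12) { best <- lp; bestseq <- z }
  }
  as.integer(bestseq)
}

# All labeled trees on n nodes via Prufer sequences (n >= 2).
all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 1, 2)))
  prufers <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(prufers)), function(i) prufer_decode(prufers[i, ], n))
}

prufer_decode <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0
  for (v in pr) {
    leaf <- min(which(degree == 1L))
    k <- k + 1
    edges[k, ] <- sort(c(leaf, v))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1, ] <- sort(which(degree == 1L))
  edges
}

# Max log-likelihood of 0/1 data (cells in rows) under a *given* tree
# topology, with empirical (floored) parameter estimates.
tree_loglik_for_topology <- function(data, edges, eps = 1e-6) {
  m <- rowMeans(data)
  c11 <- apply(edges, 1, function(e) mean(data[e[1], ] * data[e[2], ]))
  em <- make_tree_emission(m, edges, c11, eps)
  sum(emission_loglik(em, data))
}

# Random valid tree emission for property tests.
random_tree_emission <- function(n, seed) {
  with_seed_local(seed, {
    m <- runif(n, 0.05, 0.95)
    if (n == 1) return(make_tree_emission(m))
    perm <- sample.int(n)
    edges <- cbind(pmin(perm[-n], perm[-1]), pmax(perm[-n], perm[-1]))
    c11 <- numeric(n - 1)
    for (e in seq_len(n - 1)) {
      lo <- max(0, m[edges[e, 1]] + m[edges[e, 2]] - 1)
      hi <- min(m[edges[e, 1]], m[edges[e, 2]])
      c11[e] <- runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
    }
    make_tree_emission(m, edges, c11)
  })
}

# Random valid HMM for property tests.
random_hmm <- function(n_cells, n_modes, seed) {
  with_seed_local(seed, {
    emissions <- lapply(seq_len(n_modes), function(a)
      random_tree_emission(n_cells, seed * 131 + a))
    P <- matrix(runif(n_modes^2, 0.1, 1), n_modes)
    P <- sweep(P, 2, colSums(P), "/")
    init <- runif(n_modes, 0.1, 1)
    hmm_params(P, init / sum(init), emissions)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
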