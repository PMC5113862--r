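#' Tree-structured emission distribution over binary words
#'
#' One collective mode's distribution over binary population words
#' \eqn{\{\sigma_i\}}: a product of per-cell marginals times per-edge
#' pairwise correction factors,
#' \deqn{Q(\sigma) = \prod_i p(\sigma_i) \prod_{\langle i,j\rangle}
#'       \frac{p(\sigma_i,\sigma_j)}{p(\sigma_i)p(\sigma_j)},}
#' where the edges form a tree (the Chow-Liu dependence tree). The tree
#' constraint guarantees the factorized form is a normalized distribution.
#'
#' @param marginals Length-N vector of spiking probabilities
#'   \eqn{m_i = p(\sigma_i = 1)}.
#' @param edges Integer matrix with 2 columns (1-based cell indices,
#'   `edges[, 1] < edges[, 2]`), acyclic; may have zero rows (independent
#'   cells).
#' @param edge_joints List of 2x2 probability tables, one per edge; rows
#'   index \eqn{\sigma_i \in \{0,1\}} (the lower cell index), columns
#'   \eqn{\sigma_j}. Each table sums to 1 and its marginals must agree with
#'   `marginals` to 1e-12.
#' @return Object of class `tree_emission`.
#' @seealso [chow_liu_fit()], [make_tree_emission()]
#' @export
tree_emission <- function(marginals, edges = matrix(0L, 0, 2),
                          edge_joints = list()) {
  marginals <- as.numeric(marginals)
  N <- length(marginals)
  if (N == 0) stop("need at least one cell")
  if (any(marginals <= 0 | marginals >= 1))
    stop("marginals must lie strictly inside (0, 1); apply a floor first")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) != length(edge_joints)) stop("one joint table per edge")
  if (nrow(edges) > 0) {
    if (any(edges[, 1] >= edges[, 2])) stop("edges must satisfy i < j")
    if (any(edges < 1 | edges > N)) stop("edge index out of range")
    if (has_cycle(edges, N)) stop("edge set must be acyclic")
    for (e in seq_len(nrow(edges))) {
      tab <- edge_joints[[e]]
      if (!all(dim(tab) == c(2, 2))) stop("edge_joints must be 2x2")
      if (abs(sum(tab) - 1) > 1e-10) stop("edge table must sum to 1")
      if (any(tab <= 0)) stop("edge table entries must be positive")
      i <- edges[e, 1]; j <- edges[e, 2]
      if (abs(sum(tab[2, ]) - marginals[i]) > 1e-12 ||
          abs(sum(tab[, 2]) - marginals[j]) > 1e-12)
        stop("edge table marginals inconsistent with `marginals`")
    }
  }
  structure(list(marginals = marginals, edges = edges,
                 edge_joints = edge_joints, n_cells = N),
            class = "tree_emission")
}

# Cycle check by union-find.
has_cycle <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a == b) return(TRUE)
    parent[a] <- b
  }
  FALSE
}

#' Build a tree emission from marginals and edge pairwise probabilities
#'
#' Applies the probability floor: marginals are clamped to
#' `[eps, 1 - eps]` and each edge's joint spiking probability
#' \eqn{C_{ij} = p(\sigma_i = 1, \sigma_j = 1)} is clamped strictly inside
#' its Frechet feasibility interval so that all four table entries are
#' positive while the table marginals stay exactly consistent with the
#' clamped `marginals`.
#'
#' @param marginals Length-N spiking probabilities (any values in `[0, 1]`).
#' @param edges Edge matrix as in [tree_emission()].
#' @param c11 Vector of \eqn{C_{ij}} values, one per edge.
#' @param eps Probability floor (default 1e-6).
#' @return A valid [tree_emission()].
#' @export
make_tree_emission <- function(marginals, edges = matrix(0L, 0, 2),
                               c11 = numeric(0), eps = 1e-6) {
  m <- clamp(as.numeric(marginals), eps, 1 - eps)
  edges <- matrix(as.integer(edges), ncol = 2)
  joints <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    joints[[e]] <- edge_table(m[i], m[j], c11[e], eps)
  }
  tree_emission(m, edges, joints)
}

# 2x2 table from marginals (mi, mj) and joint-1 probability c, with all
# entries positive and marginals exactly (mi, mj).
edge_table <- function(mi, mj, c, eps) {
  lo <- max(0, mi + mj - 1)
  hi <- min(mi, mj)
  d <- min(eps^2, (hi - lo) / 3)
  c <- clamp(c, lo + d, hi - d)
  matrix(c(1 - mi - mj + c, mi - c, mj - c, c), 2, 2)
}

#' Fit a Chow-Liu tree emission to weighted binary words
#'
#' Computes weight-weighted empirical marginals and pairwise joints, then
#' selects the spanning tree maximizing total pairwise mutual information
#' (the maximum-likelihood tree). Ties are broken toward lexicographically
#' smaller edges, so the fit is deterministic.
#'
#' @param raster A [binary_raster()] (or plain 0/1 N x T matrix).
#' @param weights Length-T non-negative weights (e.g. HMM responsibilities);
#'   default all 1.
#' @param eps Probability floor.
#' @param tree If `FALSE`, return an independent (edge-free) emission.
#' @return A [tree_emission()].
#' @examples
#' r <- binary_raster(matrix(rbinom(200, 1, 0.3), 4, 50))
#' fit <- chow_liu_fit(r)
#' @export
chow_liu_fit <- function(raster, weights = NULL, eps = 1e-6, tree = TRUE) {
  data <- if (inherits(raster, "binary_raster")) raster$data else raster
  N <- nrow(data); T_ <- ncol(data)
  if (N == 0) stop("no cells")
  if (is.null(weights)) weights <- rep(1, T_)
  if (length(weights) != T_) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  W <- sum(weights)
  if (W <= 0) stop("weights must have positive sum")
  m <- as.numeric(data %*% weights) / W
  if (!tree || N == 1)
    return(make_tree_emission(m, eps = eps))
  P11 <- tcrossprod(sweep(data, 2, weights, "*"), data) / W
  stats <- pairwise_mi(m, P11, eps)
  edges <- max_spanning_tree(stats$mi)
  c11 <- stats$c11[cbind(edges[, 1], edges[, 2])]
  make_tree_emission(m, edges, c11, eps)
}

# Pairwise MI matrix (bits) and clamped C11 for all cell pairs, from clamped
# marginals m and raw joint-1 matrix P11.
pairwise_mi <- function(m, P11, eps) {
  N <- length(m)
  m <- clamp(m, eps, 1 - eps)
  Mi <- matrix(m, N, N)
  Mj <- t(Mi)
  lo <- pmax(0, Mi + Mj - 1)
  hi <- pmin(Mi, Mj)
  d <- pmin(eps^2, (hi - lo) / 3)
  C <- clamp(P11, lo + d, hi - d)
  p11 <- C
  p10 <- Mi - C
  p01 <- Mj - C
  p00 <- 1 - Mi - Mj + C
  mi <- p11 * log2(p11 / (Mi * Mj)) + p10 * log2(p10 / (Mi * (1 - Mj))) +
    p01 * log2(p01 / ((1 - Mi) * Mj)) + p00 * log2(p00 / ((1 - Mi) * (1 - Mj)))
  diag(mi) <- 0
  list(mi = mi, c11 = C)
}

# Maximum spanning tree by Kruskal with deterministic lexicographic
# tie-break. Returns an edge matrix with i < j.
max_spanning_tree <- function(w) {
  N <- nrow(w)
  if (N < 2) return(matrix(0L, 0, 2))
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- matrix(0L, N - 1, 2)
  k <- 0
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1
      edges[k, ] <- c(idx[e, 1], idx[e, 2])
      if (k == N - 1) break
    }
  }
  storage.mode(edges) <- "integer"
  edges[seq_len(k), , drop = FALSE]
}

#' Log-probability of a binary word under a tree emission
#'
#' @param model A [tree_emission()].
#' @param word Binary vector of length N.
#' @return Finite log-probability (natural log).
#' @export
emission_logprob <- function(model, word) {
  stopifnot(inherits(model, "tree_emission"))
  word <- as.integer(word)
  if (length(word) != model$n_cells) stop("word length mismatch")
  if (!all(word %in% c(0L, 1L))) stop("word entries must be 0/1")
  as.numeric(emission_loglik(model, matrix(word, ncol = 1)))
}

#' Per-bin log-likelihood of a raster under a tree emission
#'
#' Vectorized evaluation of [emission_logprob()] across all columns.
#' @param model A [tree_emission()].
#' @param raster A [binary_raster()] or 0/1 matrix with N rows.
#' @return Numeric vector of length T (natural log).
#' @export
emission_loglik <- function(model, raster) {
  data <- if (inherits(raster, "binary_raster")) raster$data else raster
  if (nrow(data) != model$n_cells) stop("raster N mismatch")
  logp1 <- log(model$marginals)
  logp0 <- log1p(-model$marginals)
  E <- nrow(model$edges)
  ledge <- matrix(0, max(E, 1), 4)
  if (E > 0) {
    for (e in seq_len(E)) {
      tab <- model$edge_joints[[e]]
      i <- model$edges[e, 1]; j <- model$edges[e, 2]
      lp <- c(logp0[i], logp1[i])  # indexed by si
      lq <- c(logp0[j], logp1[j])
      for (si in 0:1) for (sj in 0:1)
        ledge[e, 2 * si + sj + 1] <- log(tab[si + 1, sj + 1]) - lp[si + 1] - lq[sj + 1]
    }
  }
  .tree_loglik_core(data, logp1, logp0,
                    if (E > 0) model$edges[, 1] - 1L else integer(0),
                    if (E > 0) model$edges[, 2] - 1L else integer(0),
                    ledge)
}

# Root each tree component at its smallest node; BFS orders. Returns list
# with parent (0 = root), order (BFS), and for each non-root the conditional
# table P(child state | parent state) as a 2x2 matrix [parent+1, child+1].
tree_rooting <- function(model) {
  N <- model$n_cells
  adj <- vector("list", N)
  E <- nrow(model$edges)
  for (e in seq_len(E)) {
    i <- model$edges[e, 1]; j <- model$edges[e, 2]
    adj[[i]] <- c(adj[[i]], e)
    adj[[j]] <- c(adj[[j]], e)
  }
  parent <- integer(N)
  cond <- vector("list", N)
  visited <- logical(N)
  order <- integer(0)
  for (root in seq_len(N)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order <- c(order, v)
      for (e in adj[[v]]) {
        i <- model$edges[e, 1]; j <- model$edges[e, 2]
        u <- if (i == v) j else i
        if (visited[u]) next
        visited[u] <- TRUE
        parent[u] <- v
        tab <- model$edge_joints[[e]]
        if (i != v) tab <- t(tab)  # orient rows = parent state
        cond[[u]] <- tab / rowSums(tab)
        queue <- c(queue, u)
      }
    }
  }
  list(parent = parent, order = order, cond = cond)
}

#' Sample binary words from a tree emission
#'
#' Exact ancestral sampling: each tree component is rooted, the root state
#' drawn from its marginal, and children drawn from the conditional tables.
#'
#' @param model A [tree_emission()].
#' @param n Number of words.
#' @param seed Integer seed.
#' @return n x N 0/1 matrix (words in rows).
#' @export
sample_emission <- function(model, n, seed = 1L) {
  with_seed(seed, sample_emission_impl(model, n))
}

sample_emission_impl <- function(model, n) {
  rt <- tree_rooting(model)
  N <- model$n_cells
  out <- matrix(0L, n, N)
  for (v in rt$order) {
    if (rt$parent[v] == 0L) {
      out[, v] <- as.integer(stats::runif(n) < model$marginals[v])
    } else {
      p1 <- rt$cond[[v]][out[, rt$parent[v]] + 1L, 2]
      out[, v] <- as.integer(stats::runif(n) < p1)
    }
  }
  out
}

#' Entropy of a tree emission distribution
#'
#' Closed-form entropy of the factorized distribution,
#' \deqn{S = -\sum_i \sum_{\sigma_i} p(\sigma_i)\log_2 p(\sigma_i)
#'  - \sum_{\langle ij\rangle} \sum_{\sigma_i,\sigma_j}
#'    p(\sigma_i,\sigma_j)\log_2
#'    \frac{p(\sigma_i,\sigma_j)}{p(\sigma_i)p(\sigma_j)}.}
#'
#' @param model A [tree_emission()].
#' @return Entropy in bits.
#' @export
emission_entropy <- function(model) {
  s <- sum(binary_entropy(model$marginals))
  for (e in seq_len(nrow(model$edges))) {
    i <- model$edges[e, 1]; j <- model$edges[e, 2]
    tab <- model$edge_joints[[e]]
    prod_tab <- outer(c(1 - model$marginals[i], model$marginals[i]),
                      c(1 - model$marginals[j], model$marginals[j]))
    s <- s - sum(tab * log2(tab / prod_tab))
  }
  s
}

#' Maximum entropy of a word distribution at fixed mean spike count
#'
#' The entropy of the uniform distribution over all words with spike count
#' k, \eqn{\log_2 \binom{N}{k}}, extended to non-integer k via the Gamma
#' function:
#' \deqn{S_{max}(k) = \log_2 \frac{\Gamma(N+1)}{\Gamma(N-k+1)\Gamma(k+1)}.}
#'
#' @param n_cells N.
#' @param k Mean spike count, in `[0, N]` (non-integer allowed).
#' @return Bits.
#' @examples
#' max_entropy_bound(10, 3)  # log2 choose(10, 3)
#' @export
max_entropy_bound <- function(n_cells, k) {
  if (any(k < 0 | k > n_cells)) stop("k must lie in [0, n_cells]")
  (lgamma(n_cells + 1) - lgamma(n_cells - k + 1) - lgamma(k + 1)) / log(2)
}

#' Exact population spike-count distribution of a tree emission
#'
#' Computes P(k), k = 0..N, of the summed word \eqn{k = \sum_i \sigma_i}
#' under the tree model by dynamic programming on the tree
#' (count-convolution messages); no sampling involved.
#'
#' @param model A [tree_emission()].
#' @return Numeric vector of length N + 1 (probabilities of k = 0..N).
#' @export
spike_count_distribution <- function(model) {
  rt <- tree_rooting(model)
  N <- model$n_cells
  # h[[v]]: 2 x (size_v + 1) matrix, h[s+1, k+1] = P(subtree count = k | state s)
  h <- vector("list", N)
  children <- split(seq_len(N)[rt$parent > 0], rt$parent[rt$parent > 0])
  for (v in rev(rt$order)) {
    hv <- rbind(c(1), c(1))  # count from v itself added at the end
    for (c_ in children[[as.character(v)]] %||% integer(0)) {
      # message from child: msg[sp+1, ] = sum_sc P(sc | sp) * h_child[sc+1, ]
      hc <- h[[c_]]
      msg <- rt$cond[[c_]] %*% hc
      hv <- rbind(convolve_vec(hv[1, ], msg[1, ]),
                  convolve_vec(hv[2, ], msg[2, ]))
    }
    # account for v's own spike: state 1 shifts counts by one
    h[[v]] <- rbind(c(hv[1, ], 0), c(0, hv[2, ]))
  }
  dist <- 1
  for (v in rt$order) {
    if (rt$parent[v] != 0L) next
    pv <- c(1 - model$marginals[v], model$marginals[v])
    comp <- pv[1] * h[[v]][1, ] + pv[2] * h[[v]][2, ]
    dist <- convolve_vec(dist, comp)
  }
  length(dist) <- N + 1
  dist[is.na(dist)] <- 0
  dist
}

# Plain polynomial convolution of two coefficient vectors.
convolve_vec <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}
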