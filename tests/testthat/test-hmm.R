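test_that("forward_backward matches brute-force sequence enumeration", {
  for (seed in 1:5) {
    M <- 2 + seed %% 2
    model <- random_hmm(n_cells = 3, n_modes = M, seed = seed)
    data <- t(sample_emission(model$emissions[[1]], 3 + seed %% 3,
                              seed = seed + 70))
    fb <- forward_backward(model, binary_raster(data), keep_xi = TRUE)
    expect_equal(fb$loglik, brute_hmm_loglik(model, data), tolerance = 1e-10)
    # posterior consistency invariants
    expect_equal(rowSums(fb$gamma), rep(1, ncol(data)), tolerance = 1e-10)
    for (t in seq_len(ncol(data) - 1)) {
      expect_equal(sum(fb$xi[t, , ]), 1, tolerance = 1e-8)
      expect_equal(rowSums(fb$xi[t, , ]), fb$gamma[t + 1, ], tolerance = 1e-8)
      expect_equal(colSums(fb$xi[t, , ]), fb$gamma[t, ], tolerance = 1e-8)
    }
  }
})

test_that("forward_backward degenerate cases factorize", {
  em <- random_tree_emission(4, seed = 81)
  m1 <- hmm_params(matrix(1, 1, 1), 1, list(em))
  data <- t(sample_emission(em, 20, seed = 82))
  fb <- forward_backward(m1, binary_raster(data))
  expect_equal(as.numeric(fb$gamma), rep(1, 20))
  expect_equal(fb$loglik, sum(emission_loglik(em, data)), tolerance = 1e-10)
  # uniform chain: gamma rows proportional to per-bin emission likelihoods
  ems <- lapply(1:3, function(a) random_tree_emission(4, seed = 82 + a))
  mu <- hmm_params(matrix(1 / 3, 3, 3), rep(1 / 3, 3), ems)
  fbu <- forward_backward(mu, binary_raster(data))
  lik <- sapply(ems, function(e) exp(emission_loglik(e, data)))
  expect_equal(fbu$gamma, lik / rowSums(lik), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("loglik is invariant to mode relabeling", {
  model <- random_hmm(4, 3, seed = 90)
  data <- t(sample_emission(model$emissions[[2]], 30, seed = 91))
  perm <- c(3, 1, 2)
  permuted <- hmm_params(model$transition[perm, perm], model$initial[perm],
                         model$emissions[perm], model$eta)
  r <- binary_raster(data)
  expect_equal(forward_backward(model, r)$loglik,
               forward_backward(permuted, r)$loglik, tolerance = 1e-10)
})

test_that("viterbi matches brute-force argmax and breaks ties low", {
  for (seed in 1:4) {
    model <- random_hmm(3, 3, seed = 200 + seed)
    data <- t(sample_emission(model$emissions[[1]], 5, seed = 210 + seed))
    v <- viterbi(model, binary_raster(data))
    expect_identical(v$path, brute_viterbi(model, data))
  }
  # identical emissions, diagonal-dominant transitions -> constant path
  em <- random_tree_emission(3, seed = 220)
  P <- matrix(0.1, 2, 2); diag(P) <- 0.9
  m <- hmm_params(P, c(0.5, 0.5), list(em, em))
  d <- t(sample_emission(em, 10, seed = 221))
  expect_equal(unique(viterbi(m, binary_raster(d))$path), 1L)
  # M = 1 -> constant path
  m1 <- hmm_params(matrix(1, 1, 1), 1, list(em))
  expect_equal(unique(viterbi(m1, binary_raster(d))$path), 1L)
})

test_that("viterbi path beats random alternative paths", {
  model <- random_hmm(4, 3, seed = 230)
  data <- t(sample_emission(model$emissions[[1]], 40, seed = 231))
  path_logp <- function(z) {
    lp <- log(model$initial[z[1]]) +
      emission_logprob(model$emissions[[z[1]]], data[, 1])
    for (t in 2:length(z))
      lp <- lp + log(model$transition[z[t], z[t - 1]]) +
        emission_logprob(model$emissions[[z[t]]], data[, t])
    lp
  }
  vit <- path_logp(viterbi(model, binary_raster(data))$path)
  set.seed(232)
  rand <- replicate(1000, path_logp(sample.int(3, 40, replace = TRUE)))
  expect_true(all(vit >= rand))
})

test_that("stationary_weights solves w = P w", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)  # columns (0.9,0.1), (0.2,0.8)
  em <- lapply(1:2, function(a) random_tree_emission(2, seed = 240 + a))
  m <- hmm_params(P, c(0.5, 0.5), em)
  w <- stationary_weights(m)$weights
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(as.numeric(P %*% w), w, tolerance = 1e-10)
  # uniform transition -> uniform weights
  mu <- hmm_params(matrix(1 / 3, 3, 3), rep(1 / 3, 3),
                   lapply(1:3, function(a) random_tree_emission(2, a)))
  expect_equal(stationary_weights(mu)$weights, rep(1 / 3, 3))
  # identity transition is reducible
  mid <- hmm_params(diag(2), c(0.5, 0.5), em)
  expect_error(stationary_weights(mid), "no unique stationary")
})

test_that("static_log_likelihood matches direct evaluation", {
  set.seed(250)
  data <- matrix(rbinom(60, 1, 0.4), 3, 20)
  r <- binary_raster(data)
  em <- lapply(1:2, function(a) random_tree_emission(3, seed = 250 + a))
  mix <- list(weights = c(0.7, 0.3), emissions = em)
  res <- static_log_likelihood(mix, r, min_count = 1)
  # brute force: mean over bins of log mixture probability
  direct <- mean(apply(data, 2, function(w)
    log(0.7 * exp(emission_logprob(em[[1]], w)) +
          0.3 * exp(emission_logprob(em[[2]], w)))))
  expect_equal(res$L, direct, tolerance = 1e-12)
  # mixture equal to the empirical distribution -> L = -H_emp (nats)
  tab <- word_frequencies(r)
  res2 <- static_log_likelihood(mix, r, min_count = 2)
  keep <- tab$count >= 2
  expect_lt(res2$L, 0)
  expect_equal(nrow(res$words), nrow(tab))
})

test_that("baum_welch M = 1 recovers empirical marginals", {
  set.seed(260)
  r <- binary_raster(matrix(rbinom(5 * 400, 1, 0.3), 5, 400))
  fit <- baum_welch_fit(r, 1, seed = 261, n_restarts = 1, max_iter = 20)
  expect_equal(fit$emissions[[1]]$marginals, rowMeans(r$data),
               tolerance = 1e-9)
})

test_that("eta = 1 collapses all modes onto the global table", {
  set.seed(262)
  r <- binary_raster(matrix(rbinom(4 * 300, 1, 0.25), 4, 300))
  fit <- baum_welch_fit(r, 3, eta = 1, seed = 263, n_restarts = 1,
                        max_iter = 3)
  for (a in 2:3) {
    expect_equal(fit$emissions[[a]]$marginals, fit$emissions[[1]]$marginals,
                 tolerance = 1e-10)
    expect_equal(fit$emissions[[a]]$edges, fit$emissions[[1]]$edges)
  }
  expect_equal(fit$emissions[[1]]$marginals, rowMeans(r$data),
               tolerance = 1e-6)
})

test_that("EM training log-likelihood is monotone on seeded data", {
  for (seed in 1:6) {
    gt <- make_ground_truth_model(8, 2, separation = 0.6, seed = seed)
    sim <- sample_hmm(gt, 400, seed = seed + 500)
    fit <- baum_welch_fit(sim$raster, 2, seed = seed, n_restarts = 1,
                          max_iter = 60)
    expect_true(all(diff(fit$meta$loglik_trace) >= -1e-8))
  }
})

test_that("sample_hmm obeys the geometric dwell law and ergodicity", {
  gt <- make_ground_truth_model(6, 3, self_transition = 0.7, seed = 270)
  sim <- sample_hmm(gt, 30000, seed = 271)
  runs <- rle(sim$path$path)
  expect_equal(mean(runs$lengths), 1 / 0.3, tolerance = 0.05)
  occ <- tabulate(sim$path$path, 3) / 30000
  w <- stationary_weights(gt)$weights
  expect_true(all(abs(occ - w) < 0.02))
  # M = 1: constant path, word statistics match the emission
  m1 <- hmm_params(matrix(1, 1, 1), 1,
                   list(random_tree_emission(4, seed = 272)))
  s1 <- sample_hmm(m1, 5000, seed = 273)
  expect_equal(unique(s1$path$path), 1L)
  expect_equal(rowMeans(s1$raster$data), m1$emissions[[1]]$marginals,
               tolerance = 0.03)
})

test_that("model JSON round-trips", {
  gt <- make_ground_truth_model(7, 3, seed = 280)
  tmp <- tempfile(fileext = ".json")
  write_model_json(gt, tmp)
  back <- read_model_json(tmp)
  expect_equal(back$transition, gt$transition, tolerance = 1e-12)
  expect_equal(back$initial, gt$initial, tolerance = 1e-12)
  for (a in 1:3) {
    expect_equal(back$emissions[[a]]$marginals, gt$emissions[[a]]$marginals,
                 tolerance = 1e-12)
    expect_equal(back$emissions[[a]]$edges, gt$emissions[[a]]$edges)
    expect_equal(back$emissions[[a]]$edge_joints, gt$emissions[[a]]$edge_joints,
                 tolerance = 1e-12)
  }
  r <- sample_hmm(gt, 50, seed = 281)$raster
  expect_equal(forward_backward(back, r)$loglik,
               forward_backward(gt, r)$loglik, tolerance = 1e-10)
})

test_that("select_num_modes trivial cases", {
  set.seed(290)
  r <- binary_raster(matrix(rbinom(4 * 400, 1, 0.2), 4, 400))
  sel <- select_num_modes(r, candidates = 1, seed = 291, max_iter = 30)
  expect_equal(sel$chosen, 1)
  expect_error(select_num_modes(r, candidates = c(1, 2), n_folds = 300),
               "shorter")
})

test_that("parametric bootstrap closure: refit explains held-out data", {
  gt <- make_ground_truth_model(10, 2, separation = 0.8, seed = 295)
  sim <- sample_hmm(gt, 4000, seed = 296)
  fit <- baum_welch_fit(sim$raster, 2, seed = 297, n_restarts = 2,
                        max_iter = 100)
  boot <- sample_hmm(fit, 4000, seed = 298)
  refit <- baum_welch_fit(boot$raster, 2, seed = 299, n_restarts = 2,
                          max_iter = 100)
  held <- sample_hmm(gt, 4000, seed = 300)$raster
  ll_fit <- forward_backward(fit, held)$loglik / 4000
  ll_refit <- forward_backward(refit, held)$loglik / 4000
  expect_lt(abs(ll_fit - ll_refit), 0.05)
})
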