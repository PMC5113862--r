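# Small localized spatiotemporal filter inside an nx x ny grid.
toy_filter <- function(nx, ny, n_lags, cx, cy) {
  K <- array(0, dim = c(nx, ny, n_lags))
  prof <- exp(-((seq_len(n_lags) - 2)^2) / 2)
  for (dx in -1:1) for (dy in -1:1) {
    K[cx + dx, cy + dy, ] <- -prof * exp(-(dx^2 + dy^2))
  }
  K
}

test_that("compute_sta: single spike returns its history; linearity holds", {
  stim <- checkerboard_stimulus(5, 5, 30, seed = 800)
  spikes <- rep(0, 30); spikes[12] <- 1
  sta <- compute_sta(spikes, stim, n_lags = 4)
  for (lag in 1:4) {
    expect_equal(sta[, , lag], stim$frames[, , 12 - lag + 1])
  }
  # linearity in the stimulus
  stim2 <- stimulus(stim$frames * 2.5)
  spikes2 <- rep(0, 30); spikes2[c(12, 20)] <- 1
  expect_equal(compute_sta(spikes2, stim2, 4),
               2.5 * compute_sta(spikes2, stim, 4), tolerance = 1e-12)
  expect_error(compute_sta(rep(0, 30), stim, 4), "no spikes")
})

test_that("STA of stimulus-independent spiking vanishes", {
  stim <- checkerboard_stimulus(4, 4, 20000, seed = 801)
  spikes <- with_seed_local(802, rbinom(20000, 1, 0.2))
  sta <- compute_sta(spikes, stim, n_lags = 3)
  se <- 1 / sqrt(sum(spikes[3:20000]))
  expect_true(all(abs(sta) < 4 * se))
})

test_that("mask_sta keeps a 7x7 patch around the peak", {
  set.seed(810)
  sta <- array(rnorm(11 * 11 * 3, sd = 0.01), dim = c(11, 11, 3))
  sta[6, 6, 2] <- -1  # peak well inside
  masked <- mask_sta(sta, patch = 7)
  expect_equal(sum(attr(masked, "mask")), 49)
  expect_equal(masked[6, 6, 2], -1)
  expect_true(all(masked[1, , ] == 0))
  # filter already inside a 7x7 region is unchanged
  K <- toy_filter(11, 11, 3, 6, 6)
  expect_equal(mask_sta(K, 7), K, ignore_attr = TRUE)
  # peak at the edge clips the window
  sta2 <- array(0, dim = c(11, 11, 2)); sta2[1, 1, 1] <- 1
  expect_lt(sum(attr(mask_sta(sta2, 7), "mask")), 49)
  expect_error(mask_sta(sta, patch = 6), "odd")
})

test_that("fit_ln recovers closed-form constant-rate limits", {
  stim <- checkerboard_stimulus(4, 4, 20000, seed = 820)
  K <- array(0, dim = c(4, 4, 2)); K[2, 2, 1] <- 1
  # constant p = 0.5 independent of the stimulus
  spikes <- with_seed_local(821, rbinom(20000, 1, 0.5))
  fit <- fit_ln(spikes, stim, K)
  expect_equal(fit$gain, 0, tolerance = 0.1)
  expect_equal(fit$offset, 0, tolerance = 0.1)
  # constant p = 0.9 -> offset ln 9 at gain ~ 0
  spikes9 <- with_seed_local(822, rbinom(20000, 1, 0.9))
  fit9 <- fit_ln(spikes9, stim, K)
  expect_equal(fit9$offset, log(9), tolerance = 0.15)
  expect_equal(fit9$gain, 0, tolerance = 0.1)
})

test_that("LN parameter and filter recovery from simulated data", {
  nx <- 9; ny <- 9; n_lags <- 5
  stim <- checkerboard_stimulus(nx, ny, 60000, seed = 830)
  K <- toy_filter(nx, ny, n_lags, 5, 5)
  truth <- ln_model(K, gain = -2, offset = 1)
  r <- simulate_ln_population(list(truth), stim, seed = 831)
  spikes <- r$data[1, ]
  # STA recovers the filter direction
  sta <- compute_sta(spikes, stim, n_lags)
  cosine <- sum(sta * K) / sqrt(sum(sta^2) * sum(K^2))
  expect_gte(cosine, 0.9)
  # (gain, offset) recovered within +/- 0.1 given the true filter,
  # normalized to unit energy as in the STA pipeline
  Kn <- K / sqrt(sum(K^2))
  fit <- fit_ln(spikes, stim, Kn)
  expect_equal(fit$gain, -2 * sqrt(sum(K^2)), tolerance = 0.1 * sqrt(sum(K^2)))
  expect_equal(fit$offset, 1, tolerance = 0.1)
  # optimum beats the intercept-only model
  rate <- mean(spikes[n_lags:length(spikes)])
  ll0 <- sum(spikes[-(1:(n_lags - 1))] * log(rate) +
               (1 - spikes[-(1:(n_lags - 1))]) * log(1 - rate))
  expect_gte(fit$loglik, ll0)
})

test_that("conditionally independent LN cells show signal correlations", {
  nx <- 7; ny <- 7
  stim <- checkerboard_stimulus(nx, ny, 20000, seed = 840)
  K <- toy_filter(nx, ny, 3, 4, 4)
  cell <- ln_model(K, gain = -3, offset = 0.5)
  r <- simulate_ln_population(list(cell, cell), stim, seed = 841)
  expect_gt(cor(r$data[1, ], r$data[2, ]), 0.1)
  # per-cell rate matches the mean LN probability within binomial error
  p <- ln_probability(cell, stim)
  p[is.na(p)] <- 0
  expect_equal(mean(r$data[1, ]), mean(p),
               tolerance = 4 * sqrt(mean(p) / 20000) + 1e-3)
  # gain 0 with huge offset silences the population
  mute <- ln_model(K, gain = 0, offset = -50)
  expect_equal(sum(simulate_ln_population(list(mute), stim,
                                          seed = 842)$data), 0)
})

test_that("mode_triggered_average equals the STA on the same trigger set", {
  stim <- checkerboard_stimulus(5, 5, 500, seed = 850)
  spikes <- with_seed_local(851, rbinom(500, 1, 0.2))
  path <- ifelse(spikes == 1, 2, 1)  # mode 2 fires exactly with the cell
  mta <- mode_triggered_average(path, 2, stim, n_lags = 4)
  sta <- compute_sta(spikes, stim, n_lags = 4)
  expect_identical(mta, sta)
  expect_error(mode_triggered_average(rep(1, 500), 2, stim, 4),
               "never active")
})

test_that("separable_approximation factorizes rank-1 and rank-2 fields", {
  nx <- 6; ny <- 5; nt <- 8
  f <- matrix(0, nx, ny); f[3, 3] <- -2; f[3, 4] <- -1
  g <- sin(seq_len(nt))
  field <- array(outer(as.numeric(f), g), dim = c(nx, ny, nt))
  sep <- separable_approximation(field)
  expect_equal(sep$residual_fraction, 0, tolerance = 1e-12)
  # factors proportional to truth; reconstruction is exact
  recon <- array(outer(as.numeric(sep$spatial), sep$temporal),
                 dim = dim(field))
  expect_equal(recon, field, tolerance = 1e-10)
  expect_equal(abs(cor(as.numeric(sep$spatial), as.numeric(f))), 1,
               tolerance = 1e-10)
  expect_equal(sep$on_off, "OFF")
  # orthogonal rank-2 with energies 9 and 1 -> residual fraction 0.1
  u1 <- c(1, rep(0, nx * ny - 1)); u2 <- c(0, 1, rep(0, nx * ny - 2))
  v1 <- c(1, rep(0, nt - 1)); v2 <- c(0, 1, rep(0, nt - 2))
  A <- 3 * outer(u1, v1) + 1 * outer(u2, v2)  # energies 9 and 1
  sep2 <- separable_approximation(array(A, dim = c(nx, ny, nt)))
  expect_equal(sep2$residual_fraction, 0.1, tolerance = 1e-12)
  # reconstruction error identity
  recon2 <- array(outer(as.numeric(sep2$spatial), sep2$temporal),
                  dim = c(nx, ny, nt))
  expect_equal(sum((array(A, dim = c(nx, ny, nt)) - recon2)^2),
               sep2$residual_fraction * sum(A^2), tolerance = 1e-10)
  expect_error(separable_approximation(array(0, dim = c(2, 2, 2))),
               "all-zero")
})

test_that("stimulus TSV round-trips", {
  stim <- checkerboard_stimulus(4, 3, 11, seed = 860)
  tmp <- tempfile(fileext = ".tsv.gz")
  write_stimulus_tsv(stim, tmp)
  back <- read_stimulus_tsv(tmp)
  expect_equal(back$frames, stim$frames)
})
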