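---
title: "Collective modes of population spiking: model, fitting, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective modes of population spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmodes)
```

## The model

A population of N neurons, binned at width $\Delta$ (default 20 ms), yields a
sequence of binary *words* $\sigma(t) = (\sigma_1(t), \dots, \sigma_N(t))$,
where $\sigma_i(t) = 1$ if cell $i$ fired at least once in bin $t$.
`popmodes` models this sequence as a hidden Markov model whose latent states
are *collective modes*: discrete population-wide activity patterns. The
sequence likelihood is

$$P(\{\sigma(t)\}) = \sum_{\alpha(\cdot)} \prod_t
  Q_{\alpha(t)}(\sigma(t))\, P(\alpha(t) \mid \alpha(t-1)),$$

summing over all mode sequences. The transition matrix is stationary and
column-stochastic: entry $(\alpha, \beta)$ is the probability of mode
$\alpha$ given mode $\beta$ one bin earlier.

Each mode's emission distribution is a **Chow-Liu dependence tree**

$$Q_\alpha(\sigma) = \prod_i p_\alpha(\sigma_i)
  \prod_{\langle i,j\rangle \in \mathcal T_\alpha}
  \frac{p_\alpha(\sigma_i, \sigma_j)}{p_\alpha(\sigma_i)\,p_\alpha(\sigma_j)},$$

with the edges $\mathcal T_\alpha$ forming a spanning tree. The tree
constraint makes this factorization an exactly normalized distribution, and
the maximum-likelihood tree is the maximum spanning tree on pairwise mutual
information — so both the parameters *and* the topology are fit from data,
separately for each mode. The mode-conditional firing probabilities
$m_{i\alpha} = p_\alpha(\sigma_i = 1)$ and per-edge joint probabilities
$C_{ij\alpha} = p_\alpha(\sigma_i = 1, \sigma_j = 1)$ give $M(2N-1)$ emission
parameters.

Reducing the HMM to a static distribution uses the stationary mixture
$P_{mix}(\sigma) = \sum_\alpha w_\alpha Q_\alpha(\sigma)$ with weights
solving $w = Pw$ (the stationarity condition; the printed "detailed balance"
equation is implemented literally as this eigenvector problem, which is what
the formula states — it is not pairwise detailed balance).

## Fitting

`baum_welch_fit()` runs EM with a modified M-step. The E-step is a scaled
forward-backward pass (per-bin scaling constants; implemented in C++ for
speed, exactness is enumeration-tested). The M-step:

1. re-estimates the transition matrix from summed pairwise posteriors;
2. computes responsibility-weighted marginal and pairwise tables per mode;
3. **shrinks** each mode's tables toward the global, mode-independent tables
   with weight $\eta$: $(1-\eta)\cdot\hat\theta_\alpha +
   \eta\cdot\hat\theta_{global}$, with $\eta = 0.002$ by default;
4. reselects each mode's Chow-Liu tree on the shrunk tables.

The shrinkage regularizes rarely-occupied modes: at $\eta = 1$ every mode
collapses onto the global table, at $\eta = 0$ the M-step is exact maximum
likelihood. Because the published account of $\eta$ describes only its role
and range, the convex-combination form above is this package's design
choice; it reproduces the stated limits and monotone complexity behavior.
With this form the EM objective is MAP-like rather than pure ML; in
practice the training log-likelihood remains non-decreasing to 1e-8 at the
default $\eta$, and the test suite asserts that on twenty seeded datasets.

Initialization assigns each bin a uniform-random mode (seeded), builds
parameters from those one-hot responsibilities, and re-runs from 5 random
restarts (2 during cross-validation, for tractability), keeping the best
training likelihood. Convergence: relative log-likelihood improvement below
1e-6 or 500 iterations.

**Numerical flooring.** Finite data produce zero counts. Marginals are
clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$, and
each edge's $C_{ij}$ is clamped strictly inside its Fréchet interval
$[\max(0, m_i + m_j - 1), \min(m_i, m_j)]$ (shrunk by
$\min(\varepsilon^2, \text{width}/3)$). This keeps every 2×2 table entry
positive while the tables stay *exactly* consistent with the stored
marginals — an alternative (flooring all four entries and renormalizing)
would break that consistency invariant.

**Ties.** Maximum-spanning-tree ties are broken lexicographically by edge;
Viterbi ties toward the lower mode index. Both are deterministic.

## Choosing the number of modes

`select_num_modes()` performs n-fold cross-validation (default n = 2, the
published choice) over contiguous time blocks — contiguous rather than
interleaved, because the HMM models adjacent-bin dependence and interleaved
splits would leak temporal structure. Each held-out block is scored by the
mean per-bin log-likelihood of the *static mixture* $P_{mix}$, and the
candidate M maximizing the mean held-out score is chosen. On data with no
cross-cell correlations (e.g. circularly shuffled rasters) this selects
M = 1; on synthetic data from a 3-mode ground truth it recovers M = 3.

## Downstream analyses

- `emission_entropy()`: the closed-form tree entropy $S_\alpha$ (bits);
  `max_entropy_bound()` gives the fixed-count reference
  $\log_2 \binom{N}{k}$ (Gamma-continuous in $k$). Note this reference is
  the entropy of the uniform fixed-count distribution, not an upper bound
  for arbitrary emissions: independent cells at $p = 0.5$ have entropy $N$
  bits, above $\log_2\binom{N}{N/2}$.
- `spike_count_distribution()`: exact P(k) by count-convolution message
  passing on the tree.
- `transition_entropy()`: $H_{trans}(\beta)$ per mode, with the
  off-diagonal renormalized variant
  $\tilde p(\alpha|\beta) = p(\alpha|\beta)/(1 - p(\beta|\beta))$.
- `dwell_times()`: maximal-run statistics of the Viterbi path.
- `mode_participation()`: cell i belongs to mode $\alpha$ when
  $m_{i\alpha}/\bar m_i \ge \theta$, with $\bar m_i$ the *unweighted* mean
  over modes (the stated definition mentions no weighting).
- `lda_dprime()`: Fisher LDA between the unique word sets of each mode
  pair; $d' = |\Delta\mu| / \sqrt{(s_1^2 + s_2^2)/2}$ along the
  discriminant (symmetric pooled-SD convention). The pooled covariance of
  binary word sets is rank-deficient, so it is shrunk by
  $\lambda I$ with $\lambda = 10^{-3}\,\mathrm{tr}(\Sigma)/N$ before
  inversion. Bins within one bin of a mode switch can be excluded, and a
  label-shuffling control is built in.

## Repeat-based reliability

For repeated presentations of an identical stimulus, each mode's activation
across repeats (from per-repeat Viterbi paths — a deterministic choice;
posterior-threshold activation would be an alternative) gives $r(t)$, the
fraction of repeats active at bin t. Then
$S_{out} = h(\bar r)$, $S_{noise} = \langle h(r(t))\rangle_t$ with $h$ the
binary entropy, and the **information efficiency** is
$(S_{out} - S_{noise})/S_{out}$ — the fraction of the mode's output entropy
that is information about time-in-stimulus (defined as 0 when
$S_{out} = 0$). `event_reproducibility()` applies the ±80 ms window rule
(two-sided, inclusive, ±4 bins at 20 ms; the published text does not state
sidedness). Controls:

- `shuffled_means_control()`: permute each independent-emission mode's mean
  vector across cells, refit only transitions;
- `random_partition_control()`: deterministic word-to-mode map via the
  greedy capacity algorithm, matching mode count and probability mass;
- `chance_baseline()`: within-repeat time permutation.

On synthetic stimulus-locked data the acceptance suite verifies the
qualitative ordering: true modes > shuffled-means > random-partition ≈
chance.

## Stimulus side: STA and the logistic LN model

`compute_sta()` averages the stimulus history over spike bins (lag 1 = the
spike bin; spikes with incomplete history are skipped). `mask_sta()` zeroes
everything outside a 7×7 patch around the spatiotemporal peak.
`fit_ln()` fixes the filter and fits the remaining two parameters of

$$p_i = \frac{1}{1 + \exp(\alpha\, K_i \!*\! s - \theta)}$$

by maximum likelihood — a convex logistic regression (note the printed sign
convention: *negative* $\alpha$ means more filtered drive → more spiking).
`simulate_ln_population()` draws conditionally independent Bernoulli spikes,
the construction used to test whether shared stimulus filtering alone
explains mode structure. `mode_triggered_average()` applies the STA rule to
mode-active bins, and `separable_approximation()` returns the best rank-1
space × time factorization (leading SVD triplet; sign fixed by making the
temporal factor's largest sample positive, so OFF-dominated fields have a
negative spatial peak).

## The synthetic world

`make_ground_truth_model()` builds the stated world used throughout the
tests: mode 1 near-silent (baseline 0.005 per bin ≈ 0.25 Hz), each active
mode elevating a random subset of ~10 cells (the reported scale of
synchronously active groups) to a firing probability interpolated by
`separation` between baseline and 0.5, chain trees with edge correlation
0.2 (mild positive pairwise correlation, as in retinal data), and a
configurable self-transition (default 0.7, the reported median).
`simulate_repeats()` adds repeat structure by reusing one master mode path
and resampling each bin's mode with probability `jitter` (default 0.1) —
the minimal mechanism producing both stimulus-locking and trial-to-trial
noise, since the real repeat structure comes from the physical stimulus and
has no published generative form.

What a green test does **not** establish: the generator has no
stimulus-driven rate modulation within modes, no refractoriness or bursting,
no slow drift, and emission noise is exactly tree-structured — so passing
recovery tests shows the estimator is correct under the model's own
assumptions, not that real retinas satisfy them.

## Worked example

```{r example, eval = FALSE}
gt <- make_ground_truth_model(n_cells = 20, n_modes = 3, separation = 0.8,
                              self_transition = 0.7, seed = 11)
sim <- sample_hmm(gt, T_ = 20000, seed = 12)
fit <- baum_welch_fit(sim$raster, n_modes = 3, seed = 13)
path <- viterbi(fit, sim$raster)
dwell_times(path)$mean_dwell_s
transition_entropy(fit)
```

## Known limitations

- The EM objective with $\eta > 0$ is not exactly the penalized likelihood
  whose M-step the shrinkage would solve; monotonicity is verified
  empirically, not guaranteed.
- Cross-validation scores the static mixture, not the sequence likelihood,
  so temporal information does not contribute to model selection (this
  matches the stated procedure).
- `select_num_modes()` concatenates the non-held-out blocks, creating one
  artificial junction bin per fold.
- The Viterbi decode conditions on the full sequence; a causal
  (filtering-based) decode would differ near the end of the data.
- Mode counts beyond ~100 and populations beyond a few hundred cells are
  untested for speed; the M-step is O(M N² T) per iteration.
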