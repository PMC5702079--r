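# pobds

Estimation and identification of **partially-observed Boolean dynamical
systems** (POBDS): gene regulatory networks modeled as Boolean circuits
whose ON/OFF state is never measured directly, only through noisy
expression data (binarized calls, microarray/imaging intensities, or
RNA-seq counts).

The hidden state evolves as

    X_k = f(X_{k-1}) ⊕ n_k

where `f` is a synchronous Boolean network over d genes, `⊕` is bitwise
XOR, and the transition noise `n_k` flips each gene independently with
probability `p`. Observations `Y_k` are drawn gene-wise from one of four
channels: Bernoulli (flip probability `q`), Gaussian
(`N(mu0, sigma0²)` / `N(mu1, sigma1²)` for OFF/ON genes), or
Poisson / negative binomial RNA-seq counts with mean
`λ_j(x) = s·exp(mu + delta_j·x_j)` (and NB variance `λ + λ²/phi_j`).
A POBDS is thus a hidden Markov model over the 2^d Boolean states, and
the package provides:

- a parser for the standard `"targets, factors"` Boolean-network text
  dialect, plus exhaustive synchronous attractor analysis
  (`parse_boolnet`, `load_network`, `find_attractors`);
- simulation of paired state/observation series with reproducible,
  stream-separated seeding (`simulate_network`, `write_trajectory`);
- the **Boolean Kalman filter** and **smoother** — the exact MMSE state
  estimators, computed as normalized forward (and backward) recursions
  over the enumerated state space, with per-gene posterior marginals
  thresholded at 1/2 (`run_bkf`, `run_bks`);
- a **sequential importance resampling particle filter** for networks too
  large to enumerate, with ESS-triggered systematic resampling
  (`run_sir_bkf`);
- **multiple model adaptive estimation** for identifying the network
  topology and the process-noise intensity from data: a bank of BKFs whose
  posterior model probabilities are updated from the filters' predictive
  likelihoods, stopping when one model crosses a threshold (`run_mmae`);
- trajectory and posterior plotting (`plot_trajectory`,
  `plot_mmae_posterior`).

The four-gene p53-MDM2 negative feedback loop is bundled in two variants
(`p53_network(0)` and `p53_network(1)`, DNA-damage input fixed to 0/1) as
the standard test system.

## Worked example

```r
library(pobds)

net <- p53_network(1)                      # DNA-damage variant
find_attractors(net)
#> Attractors (synchronous, noiseless): 0 fixed point(s), 1 cycle(s)
#>   cycle of length 6: 0001 -> 1000 -> 1100 -> 1110 -> 0110 -> 0011

spec <- obs_gaussian(1, 2, 5, 2)           # OFF ~ N(1,4), ON ~ N(5,4)
traj <- simulate_network(net, 100, p = 0.01, obs_model = spec, seed = 11)

fit <- run_bkf(net, p = 0.01, spec, traj$Y)
fit
#> BKF result: 100 time points, 4 genes; log marginal likelihood = -830.3419
mean(fit$Xhat == traj$X)
#> [1] 0.9875

bank <- make_model_bank(list(p53net_DNAdsb0 = p53_network(0),
                             p53net_DNAdsb1 = net),
                        c(0.01, 0.05, 0.10))
run_mmae(bank, spec, traj$Y, threshold = 0.8)
#> MMAE: model [4] p53net_DNAdsb1,p=0.01 crossed threshold 0.80 at time 22 (posterior 0.819)
```

The attractor report shows the oscillatory damage response (p53 pulses
around a six-state cycle; without damage, `p53_network(0)` has the
all-zero fixed point instead). The filter tracks ~99% of gene-time states
from the noisy intensities, and the six-model identification run selects
the generating model (damage network, `p = 0.01`) once its posterior
passes 0.8. `plot_trajectory(list(traj$X, fit$Xhat), c("true", "BKF"))`
overlays the true and estimated step functions per gene.

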