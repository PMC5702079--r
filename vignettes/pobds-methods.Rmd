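---
title: "State estimation and model identification for partially-observed Boolean dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State estimation and model identification for partially-observed Boolean dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pobds)
```

## The signal model

A Boolean network describes a gene regulatory circuit as d binary switches:
gene j is ON (1, transcribed at a functional level) or OFF (0), and all
genes update synchronously through logic rules of the current state. The
deterministic model cannot absorb unmodeled biology, and — more importantly
for data analysis — the Boolean state is never measured directly: microarray
intensities, RNA-seq counts or imaging readouts are noisy functions of it.

A partially-observed Boolean dynamical system (POBDS) addresses both. The
hidden state is

$$\mathbf{X}_k = \mathbf{f}(\mathbf{X}_{k-1}) \oplus \mathbf{n}_k,$$

where $\mathbf{f}:\{0,1\}^d \to \{0,1\}^d$ is the network function,
$\oplus$ is componentwise modulo-2 addition, and the transition noise
$\mathbf{n}_k$ has i.i.d. Bernoulli($p$) components: each gene's planned
update is flipped independently with probability $p \in [0, 0.5]$. At
$p = 0$ the trajectories are governed entirely by the network; as
$p \to 0.5$ the chain approaches an unstructured random walk on
$\{0,1\}^d$. The data are $\mathbf{Y}_k$, drawn gene-wise independently
from an observation channel given $\mathbf{X}_k$. A POBDS is therefore a
hidden Markov model with $2^d$ states and special structure, and the
package exploits both facts: the exact algorithms are HMM recursions over
the enumerated state space, and all state arithmetic is expressed through
the Boolean network.

The indexing convention is fixed once: gene 1 is the most significant bit,
so state $(x_1,\dots,x_d)$ has index $\sum_j x_j 2^{d-j}$ (0-based). Every
posterior distribution vector (PDV) in the package is ordered this way,
which makes PDVs comparable across functions and runs.

## Observation channels

Four channels cover the common technologies; all parameters are on the
scale of the measured data.

| channel | parameters | gene j's law given $x_j$ |
|---|---|---|
| Bernoulli | $q \in [0, 0.5]$ | $y_j = x_j$ flipped w.p. $q$ |
| Gaussian | $\mu_0, \sigma_0, \mu_1, \sigma_1$ | $N(\mu_{x_j}, \sigma_{x_j}^2)$ |
| Poisson | $s > 0$, $\mu$, $\delta_j > 0$ | Poisson$(\lambda_j)$ |
| negative binomial | as Poisson plus $\phi_j > 0$ | NB, mean $\lambda_j$, var $\lambda_j + \lambda_j^2/\phi_j$ |

The count channels use the log-linear RNA-seq mean
$\lambda_j(x) = s\,e^{\mu + \delta_j x_j}$: $s$ is the sequencing depth,
$\mu$ the baseline log-expression of an inactive gene, $\delta_j$ the
differential expression of gene j when active, and $\phi_j$ the inverse
dispersion ($\phi_j \to \infty$ recovers Poisson). $\delta$ and $\phi$ are
per-gene vectors; the other parameters are shared scalars. Missing genes —
`NA` observations or an explicit mask — simply drop out of the likelihood,
which is the natural treatment of incomplete measurements in this model.

Likelihoods are computed and combined exclusively in log space;
exponentiation happens only inside normalized updates after subtracting
the running maximum (log-sum-exp). Count likelihoods across tens of genes
underflow double precision quickly otherwise.

## Exact filtering and smoothing

The Boolean Kalman filter (BKF) is the exact minimum mean-squared-error
(MMSE) state estimator: a forward recursion propagating the PDV through
the transition matrix $M$ ($M_{ji} = p^{h}(1-p)^{d-h}$ with $h$ the
Hamming distance between $s_j$ and $f(s_i)$, so every column sums to 1),
followed by the likelihood update and renormalization. The per-step
normalizers are the predictive likelihoods $P(\mathbf{Y}_k \mid
\mathbf{Y}_{1:k-1})$; their logs sum to the log marginal likelihood, which
is what the model-identification layer consumes. The MMSE Boolean estimate
thresholds each gene's posterior marginal at 1/2; a marginal of exactly
1/2 maps to 1 — any fixed tie rule is MMSE-optimal, and a deterministic
one keeps runs reproducible.

The Boolean Kalman smoother (BKS) adds a backward likelihood recursion
(rescaled each step for stability) and returns the full fixed-interval
result: smoothed PDVs at every instant, with the final one equal to the
filtered PDV by construction. Smoothing can only sharpen the posterior on
average, and the test suite checks exactly that (posterior entropy,
paired over replicates) rather than pointwise dominance, which does not
hold path by path.

Defaults: the initial PDV is uniform over the $2^d$ states (the filters
take no informative prior argument in the original interface, and uniform
is the uninformative choice); dense matrix-vector products are used up to
$d = 12$, beyond which exact filtering is refused with a pointer to the
particle filter — at $d = 12$ the matrix already holds $2^{24}$ doubles.

## Particle approximation

For larger networks `run_sir_bkf()` implements the bootstrap sequential
importance resampling filter: N particles initialized uniformly (each
gene an independent fair coin, so no state enumeration is ever needed),
propagated through the noisy transition kernel (the proposal), reweighted
by the observation likelihood, and resampled when the effective sample
size $1/\sum_i w_i^2$ drops below $\alpha N$. Choices that the SIR
framework leaves open were fixed as follows:

* **Resampling scheme** — systematic resampling (one uniform draw,
  stratified positions): lowest variance among the simple schemes and a
  single RNG draw per trigger.
* **Trigger** — ESS below $\alpha N$, the standard reading of a
  resampling threshold $\alpha \in [0,1]$; $\alpha = 0$ never resamples
  (pure SIS) and $\alpha = 1$ resamples every step.
* **After resampling** log-weights are reset to exactly $-\log N$.
* **Proposal** — the transition kernel itself; no observation-informed
  proposal is attempted, matching the bootstrap-filter design.

Estimates use weighted per-gene marginals with the same tie rule as the
exact filter. On the four-gene p53 system with N = 5000 the per-step
total-variation distance to the exact PDV is well below 0.05 in median,
and it decreases with N (both properties are in the test suite).

## Multiple-model identification

When the network topology or the noise intensity is unknown, candidate
models $\{\theta_1,\dots,\theta_M\}$ — the Cartesian product of candidate
networks and candidate $p$ values, networks outer — are filtered in
parallel, one BKF each. After every observation each model's weight is
multiplied by its predictive likelihood and the weights are renormalized
(in log space: per-step likelihoods on count data span hundreds of orders
of magnitude across models). The run stops at the first step whose
maximum posterior reaches the threshold, checked after the update; if the
threshold is never crossed the filters run to the end and the final
argmax is reported without a selection. Ties break to the lowest model
index. The posterior after k steps equals, up to normalization,
$\text{prior}_m \times P(\mathbf{Y}_{1:k} \mid \theta_m)$, and the test
suite verifies this identity against independently recomputed
whole-sequence marginal likelihoods.

`run_mmae(..., stop_on_threshold = FALSE)` disables the stop while keeping
the full posterior history, which is how the replication script measures
when the *generating* model's own posterior first crosses the threshold.

## The p53-MDM2 test system

The bundled four-gene network (ATM, p53, WIP1, MDM2) is the p53-MDM2
negative feedback loop, with the DNA double-strand-break input baked into
two fixture variants as a constant. Its rules are

```
ATM  <- !WIP1 & dna_dsb      p53  <- ATM & !MDM2
WIP1 <- p53                  MDM2 <- !ATM & (p53 | WIP1)
```

Without damage (`dna_dsb = 0`) every state funnels to the all-zero fixed
point — the quiescent cell. Under damage (`dna_dsb = 1`) the noiseless
dynamics is a six-state cycle in which p53 pulses, the classic
oscillatory damage response. Both facts are asserted in the tests via
exhaustive attractor analysis, and they are the reason this small circuit
is a good identification benchmark: the two variants differ strongly in
dynamics while sharing the gene set.

## Simulation and the scope of what the tests show

`simulate_network()` draws the initial state uniformly over the $2^d$
states unless `x0` is given — matching the filters' uninformative prior —
and one seed drives the initial state/process noise and the observation
noise through separate sub-streams, so changing the observation channel
never perturbs the hidden path. Trajectories serialize to tab-separated
text (one file of states, one of observations, reals at full precision,
plus a JSON sidecar of parameters and seed) so runs are diff-able and
language-neutral.

The demonstration conditions used throughout the tests and the
replication script are those of the p53 case study: 100-point series,
process noise $p = 0.01$, and the well-separated Gaussian channel
$\mu_0 = 1, \sigma_0 = 2, \mu_1 = 5, \sigma_1 = 2$ (a two-standard-
deviation separation between the OFF and ON intensity distributions). The
model-identification experiment uses the six-model bank
$\{$no-stress, damage$\} \times p \in \{0.01, 0.05, 0.10\}$, uniform
prior, threshold 0.8, 100 replicates.

What the generator emulates — synchronous updates, gene-wise independent
noise on both layers, time-constant parameters — bounds what passing
tests can show. Real expression series have asynchronous and variable
sampling, correlated technical noise across genes, drifting sequencing
depth, and networks that are at best approximations; none of that is
represented here, so the oracle-agreement and tracking results certify
the estimators, not the biology.

Two quantitative notes from the demonstration conditions. BKF tracking
accuracy on the damage network averages well above 90% per gene-time
entry. Model identification is fast in its network axis (the damage
network is typically separated from the no-stress one within a handful of
steps) but intrinsically slow in its noise axis: distinguishing
$p = 0.01$ from $p = 0.05$ on four genes yields only about
$d \cdot \mathrm{KL}(\text{Bern}(0.01)\,\|\,\text{Bern}(0.05)) \approx
0.15$ nats per step even with perfectly observed states, so reaching a
0.8 posterior typically takes on the order of 15–25 time points, and the
median stopping time sits near the upper end of that range under
observation noise. Single runs routinely stop by 15 points; the median
across replicates is a harder summary of the same behavior.

## Numerical choices and problem sizes

* PDVs are renormalized at every step and checked to sum to 1 within
  1e-10 in the tests.
* Zero-likelihood situations (a noiseless Bernoulli channel contradicting
  every reachable state, or a fully degenerate particle ensemble) raise
  explicit errors rather than returning NaNs.
* The backward smoother messages are rescaled to sum to 1 at every step;
  only ratios matter, so this is free of bias.
* Attractor analysis walks the functional graph iteratively (no
  recursion), so basins of any shape are handled; it is guarded at
  $d \le 20$.
* Test problem sizes were chosen so the whole suite runs in well under a
  minute of filtering work: oracle comparisons at $d \le 4$, $n \le 50$
  (path-enumeration smoothing checks at $d = 2$, $n = 6$, where the
  $4^6$ paths are enumerable exactly), Monte-Carlo transition checks at
  $10^6$ draws, particle-filter consistency at $N$ up to $10^4$, and 100
  identification replicates.

## Known limitations

Asynchronous and probabilistic Boolean network classes are rejected at
parse time rather than approximated. Observation noise is independent
across genes; correlated channels are out of scope. Observation-model
parameters are taken as known by all estimators — the identification
layer searches over networks and process noise only, not over channel
parameters. The particle filter estimates filtered quantities only; there
is no particle smoother.
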