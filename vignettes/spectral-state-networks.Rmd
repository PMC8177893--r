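---
title: "Dynamic spectral brain networks with time-delay embedded HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spectral brain networks with time-delay embedded HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdehmm)
```

## The problem

Combined cortical (MEG source) and subthalamic (LFP) recordings allow
cortico-subthalamic communication to be studied as a *dynamic* process:
rather than estimating one static connectivity matrix per recording, one
asks which recurrent whole-brain coupling configurations ("states") the
system visits, what their spectral content is, and how their occurrence
changes between experimental conditions (in the motivating application,
a dopaminergic medication ON/OFF contrast in Parkinson's disease).

`tdehmm` implements that analysis chain end to end:

1. **Preprocessing** — region time series are leakage-corrected by
   symmetric orthogonalisation (cortical channels only), z-scored per
   subject, concatenated over subjects, and sign-aligned across
   subjects.
2. **Time-delay embedding (TDE) + PCA** — each sample is replaced by a
   window of lagged copies (15 lags for 60 ms at 250 Hz), and the
   `N * L`-dimensional embedding is reduced to `2N` principal
   components. Covariance in this space encodes spectral power *and*
   cross-channel phase coupling, so Gaussian states become spectral
   network states.
3. **Variational-Bayes Gaussian HMM** — `K = 6` zero-mean states with
   full covariances under an inverse-Wishart prior and a persistent
   Dirichlet transition prior; batch VB with a stochastic (minibatch)
   option.
4. **State spectra** — multitaper PSD/coherence (7 Slepian tapers,
   time–bandwidth 4, 0.5 Hz bins, 1–45 Hz) from the samples assigned to
   each state.
5. **Frequency modes** — robust NNMF of the group-level STN–cortex
   coherence into 4 non-negative spectral modes, replacing fixed band
   definitions; coherence is projected onto the modes.
6. **Network statistics** — within condition, a two-component Gaussian
   mixture on demeaned projected coherence separates genuine edges from
   background; between conditions, matched states are compared per
   cluster pair by two-sided t-tests, all with multiple-comparison
   correction at `alpha = 0.05`.
7. **State matching** — states of two independently fitted HMMs are
   paired by minimising summed affine-invariant Riemannian distances
   between state covariances (Munkres assignment).
8. **Temporal statistics** — fractional occupancy, lifetimes (> 100 ms
   filter) and intervals, compared by two-way repeated-measures ANOVA
   (occupancy, subject level) and two-way fixed-effects ANOVA
   (lifetimes/intervals, visit level) with post hoc tests.

## The observation model and its priors

After embedding and PCA, each sample $x_t \in \mathbb{R}^P$ is modelled
as $x_t \mid z_t = k \sim \mathcal{N}(0, \Sigma_k)$. Means are pinned at
zero so that state switching is driven by second-order structure only.
Conjugate priors make the variational updates closed form:

* $\Sigma_k \sim \mathcal{IW}(\Psi_0, \nu_0)$ with $\Psi_0$ the
  empirical covariance of the embedded data and $\nu_0 = P + 2$, i.e.
  the prior mean *is* the empirical covariance and is as weak as it can
  be while keeping that interpretation. The reference analysis names
  the prior family but not its hyperparameters; this choice is the
  package's own.
* Transition rows $A_{k\cdot} \sim \mathrm{Dir}(\alpha_0)$ with
  $\alpha_0 = 10$ on the diagonal and 1 off it, encoding temporal
  persistence.
* The free energy reported per iteration is the exact negative evidence
  lower bound of this conjugate model (forward–backward under expected
  log-parameters, minus the Wishart and Dirichlet KL terms); it is
  non-increasing over batch iterations and is checked against the
  closed-form single-Gaussian marginal likelihood when `K = 1`.

**Initialisation.** The toolbox-style initialisation referenced by the
source analysis is not fully specified, so the package uses its own
reproducible stand-in: k-means on log-power features of short windows,
followed by a few VB iterations on a temporal subsample, best of five
seeded restarts by free energy. **Stochastic mode** uses subject-level
minibatches with step size $\rho_t = (t + 5)^{-0.6}$ on the natural
parameters; batch VB is the default and the reference for tests.

**Numerical choices.** Covariance scale matrices are floored at
$10^{-8}$ of their mean eigenvalue before Cholesky factorisation;
forward–backward uses per-sample scaling in C++; Viterbi ties break
toward the lower state index; the embedded-space PCA is computed from
lagged cross-products without materialising the `N·L x T` matrix, and
is tested to agree with the naive path to `1e-10`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fs` | 250 Hz | sampling rate of the region time series |
| `window_ms` | 60 ms | TDE window; 15 lags at 250 Hz |
| `n_components` | `2N` (96 for 48 channels) | PCA retention |
| `K` | 6 | number of HMM states |
| `transition_diag` | 10 | Dirichlet prior diagonal |
| `n_tapers`, `time_bandwidth` | 7, 4 | multitaper configuration |
| `resolution_hz` | 0.5 Hz | spectral grid |
| `band` | 1–45 Hz | analysis band-pass |
| `n_modes` | 4 | NNMF frequency modes |
| `alpha` | 0.05 | corrected significance level |
| `min_lifetime_ms` | 100 ms | lifetime filter (strictly greater) |

## State spectra on short visits

State visits are brief (a few hundred milliseconds), while a 0.5 Hz
grid requires 2 s windows. Estimating a multitaper per visit would
inflate the spectral bandwidth to `time_bandwidth / visit length`
(±8 Hz for a 500 ms visit) and smear narrowband coupling far outside
its band. The package therefore **concatenates each state's visits**
(after band-pass filtering the continuous data, which avoids filter
transients on short snippets) and tiles full 2 s windows across the
concatenation; windows may span visit boundaries. The phase
discontinuities at boundaries add a broadband leakage floor but
preserve the nominal ±2 Hz resolution, which is the better trade and
standard practice for state-wise spectra. Gamma-weighted estimation is
deliberately not the default: the hard "state visit" definition
(probability higher than all other states) is used throughout.

## Robust NNMF and the sparsity choice

NNMF is not unique: any broadband background common to all coherence
columns can be shared arbitrarily between a dedicated background mode
and the narrowband modes without changing the reconstruction. The
"robust" variant implemented here resolves this in three ways: a
deterministic NNDSVD-initialised first run plus seeded random restarts;
a consensus step that keeps the lowest-error run whose modes agree
(correlation > 0.9) with the across-restart consensus; and a mild L1
penalty on the mode shapes (`sparsity = 0.1`, scaled by the mean column
mass) with per-iteration renormalisation of the modes to unit 1-norm.
The penalty biases the fixed point toward parts-based solutions in
which the coherence-estimation bias floor collects in one broad
residual mode and the oscillatory peaks stay in their own modes; the
reconstruction error it costs is well under 1%. Modes are labelled
automatically by the canonical band holding most of their mass — the
reference analysis did this step by visual inspection.

## Matching states across fits

Two HMMs fitted on different datasets live in different PCA subspaces,
so their `P x P` covariances are not directly comparable. Mapping a
state covariance back to the full channel × lag space through its own
projection gives a rank-`P` matrix in a 720-dimensional space, on which
the affine-invariant Riemannian metric degenerates (most eigenvalue
ratios are floor-against-floor). The package instead compares the
**zero-lag channel-space blocks** (`N x N`, full rank): the lag-0 block
of `W Σ W'` read from each model's own projection. This is the only
well-conditioned construction that needs no shared subspace, and it
retains the metric's congruence invariance. Matching minimises the
summed distances with a hand-written O(K³) Munkres/Jonker–Volgenant
solver, verified against exhaustive enumeration of all 720 pairings for
K = 6.

## Network statistics

For the within-condition analysis the projected group coherence is
demeaned per edge across states (so "significant" means *above this
edge's typical level*), absolute values are standardised per
state × mode and fitted with a two-component EM mixture whose component
variances are fixed at 1; the component with the smaller mean is the
background. Edge p-values are upper-tail probabilities under the
background component, corrected by Benjamini–Hochberg within each
state × mode family (the correction scope and procedure are
configurable; the source analysis says only "corrected"). The
between-condition t-tests are independent-sample by default to mirror
the reference analysis, with a paired option available — statistically
preferable when the same subjects are measured in both conditions.

Occupancy is analysed at the subject level (two-way repeated measures:
state × condition within subject); lifetimes and intervals at the visit
level (two-way fixed effects on pooled visits, so residual degrees of
freedom run into the number of visits). Post hoc comparisons use
Tukey's HSD at the visit level and Bonferroni-corrected paired t-tests
for occupancy. The 100 ms filter applies to lifetimes only, not
intervals.

## The synthetic cohort generator

Real recordings of this kind are not publicly distributable, so the
package ships a generator whose outputs have *known* answers. Each
state is a set of coherent edges: the two channels of an edge share a
band-limited Gaussian latent built directly in the frequency domain
(flat spectral top with cosine roll-off), mixed with independent
channel noise so that the magnitude-squared coherence at the centre
frequency is exactly `r / (r + 1)` with `r = g² c / (1 - c)` — the
closed form every coherence test is checked against. A Markov chain
(optionally semi-Markov via a truncated geometric dwell) switches
states; two conditions can permute state labels and rescale edge gains,
which is what the matching and between-condition tests recover.

The default geometry mirrors the study this package replays: 48
channels of which 6 are tagged "STN", 250 Hz, and canonical-band edges
(delta/theta ≈ 4–5 Hz, alpha at 10 Hz with a deliberately narrow
envelope representing a sharp oscillatory peak, beta ≈ 20–24 Hz). The
bundled `three_band_state_specs()` gives each state a small network of
six edges (four STN–cortex, two cortico-cortical) with coherence
targets 0.8–0.9: strong, spatially distributed coupling consistent
with whole-network states, and enough second-order contrast that state
discovery is limited by the embedding window rather than by the state
definitions. The validation cohort used by the tests and the
acceptance script is 3 states, 4 subjects, 5 minutes each, two
conditions with the planted permutation (3, 1, 2), and a 500 ms
expected dwell.

What the generator does **not** emulate: 1/f spectral backgrounds,
volume conduction / source leakage (so the recovery suites disable
orthogonalisation, which would partially remove planted zero-lag-ish
coupling), nonstationary artefacts, inter-subject anatomical
variability, and realistic MEG noise floors. Passing the recovery
suites therefore demonstrates correctness of the inference machinery
under the stated signal model, not robustness to real-data pathologies.

## Problem sizes and determinism

The test and acceptance problem sizes are chosen so each property is
measured at the smallest scale where it is meaningful: exhaustive
oracles at `T = 6`, `K = 2` (64 paths) and `K = 6` assignment (720
permutations); Monte-Carlo calibration with 200–500 replicates at the
statistic level (with effect sizes taken from the generator's closed
form rather than re-simulating full cohorts per replicate); and one
criterion-scale cohort run (above) for end-to-end recovery. Every
stochastic step — sequence generation, signal synthesis, k-means
restarts, NNMF restarts, minibatch order — is seeded, and the pipeline
is byte-reproducible under a fixed configuration.

## Known limitations

* The HMM assumes zero-mean Gaussian emissions in embedded space;
  heavy-tailed artefacts will be absorbed into extra states rather
  than rejected.
* Free energies are comparable only across runs on the same dataset
  and embedding.
* The stochastic mode trades monotonicity for speed; its free energy
  is checked against batch VB on small problems only.
* `K` selection is out of scope: the package reports free energy but
  implements no model-order search.
* With very short dwell times (a few tens of milliseconds) the
  embedding window itself bounds achievable frame accuracy, and
  cross-visit multitaper windows mix neighbouring states into the
  leakage floor.
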