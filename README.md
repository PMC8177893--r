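# tdehmm

Discovery and characterisation of recurrent spectral-connectivity states
in multichannel electrophysiological recordings (e.g. combined MEG
source + subthalamic LFP data), for researchers studying dynamic
cortico-subcortical communication.

Static connectivity analysis averages over network configurations that
the brain visits transiently. `tdehmm` instead models the recording as a
sequence of visits to a small number of recurrent states. Each sample of
the `N`-channel series is time-delay embedded (a 60 ms lag window, 15
lags at 250 Hz), reduced to `2N` principal components, and modelled by a
hidden Markov model with zero-mean Gaussian states,

&nbsp;&nbsp;&nbsp;&nbsp;*x*<sub>t</sub> | *z*<sub>t</sub> = *k* ~
N(0, Σ<sub>k</sub>),&nbsp;&nbsp; Σ<sub>k</sub> ~ IW(Ψ₀, ν₀),&nbsp;&nbsp;
*z*<sub>t</sub> a Markov chain with Dirichlet-prior transitions,

fitted by variational Bayes. Because embedded-space covariance encodes
spectral power and cross-channel phase coupling, each state is a
spectral network. Downstream, the package estimates state-wise
multitaper coherence (7 Slepian tapers, TW = 4, 0.5 Hz bins, 1–45 Hz),
factorises group STN–cortex coherence into data-driven frequency modes
by robust NNMF, thresholds edges with a two-component Gaussian mixture
(corrected p < 0.05), pairs states across independently fitted models by
affine-invariant Riemannian distance + Munkres assignment, and compares
fractional occupancy, lifetimes (> 100 ms) and intervals across
conditions by two-way ANOVAs. A Markov-switching oscillatory cohort
simulator with closed-form coherence targets provides ground truth for
every stage.

## Worked example

Simulate a small two-condition cohort whose second condition permutes
the state labels, run the pipeline, and recover the structure:

```r
library(tdehmm)

specs <- three_band_state_specs()          # delta/theta, alpha, beta states
cs <- cohort_spec(n_subjects = 4, duration_s = 300,
                  transition_matrix = default_transition(3, dwell_s = 0.5),
                  condition_map = list(A = list(),
                                       B = list(permutation = c(3, 1, 2))),
                  seed = 7)
coh <- generate_cohort(cs, specs)

res <- run_pipeline(coh$data,
                    pipeline_config(K = 3, orthogonalise = FALSE,
                                    sign_flip = FALSE, seed = 11))

res$A$modes
#> <frequency_modes> 4 modes on 89 bins (1.0-45.0 Hz)
#>   mode 1 [beta]: band mass delta/theta=0.00 alpha=0.00 beta=0.99
#>   mode 2 [alpha]: band mass delta/theta=0.18 alpha=0.79 beta=0.06
#>   mode 3 [delta/theta]: band mass delta/theta=0.94 alpha=0.09 beta=0.01
#>   mode 4 [residual]: band mass delta/theta=0.18 alpha=0.11 beta=0.26

res$match
#> <state_match> 3 states, total distance 21.9701
#>   pairing: 1 -> 3, 2 -> 1, 3 -> 2
```

The mode printout shows the NNMF recovering the three canonical bands
from the data (the fourth mode absorbs the broadband coherence floor);
`band mass` is the fraction of each mode's weight inside the named band.
The matching pairs each condition-A state with the condition-B state
whose covariance is closest in the Riemannian metric — composing the
pairing with each fit's label alignment recovers the planted permutation
`(3, 1, 2)` exactly. Per-subject state paths sit in
`res$A$hmm$posterior`; argmax-gamma frame accuracy against the ground
truth `coh$truth$state_sequences` is 0.935–0.941 across subjects at
these settings, and significant STN–cortex edges (in
`res$A$network$edges`) contain every planted edge of the matching state
and mode.

(Exact numbers above are from this configuration and seed; other seeds
move them slightly.)

## Package layout

| Path | Contents |
|---|---|
| `R/simulate.R` | cohort generator with closed-form coherence ground truth |
| `R/preprocess.R` | first-PC reduction, symmetric orthogonalisation, sign-flip, z-score/concatenate |
| `R/tde.R` | time-delay embedding, memory-efficient PCA, channel-space back-projection |
| `R/hmm.R`, `src/fb.cpp` | variational-Bayes Gaussian HMM; C++ forward–backward/Viterbi |
| `R/spectra.R` | Slepian tapers, state segment extraction, multitaper cross-spectra |
| `R/modes.R` | robust NNMF frequency modes and projections |
| `R/network.R` | mixture edge thresholding, between-condition cluster t-tests |
| `R/matching.R` | Riemannian distance, Munkres assignment, state matching |
| `R/temporal.R` | occupancy/lifetime/interval metrics and ANOVAs |
| `R/io.R` | TSV/JSON readers and writers, `pipeline_config()`, `run_pipeline()` |
| `vignettes/spectral-state-networks.Rmd` | the methods vignette |

See the vignette for the model, the assumptions behind each stage, and
the design decisions taken where the underlying methods literature
leaves choices open.
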