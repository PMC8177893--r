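#' Specify one synthetic connectivity state
#'
#' A state is a set of coherent edges on top of independent channel noise.
#' Each edge binds two channels through a shared band-limited latent
#' oscillation centred on `f0` Hz, mixed so that the coherence (the
#' magnitude of the coherency, the quantity the multitaper estimator
#' reports) between the two channels at `f0` equals `coherence`.
#'
#' @param state_id integer state label (1-based).
#' @param edges data frame with columns `i`, `j` (channel indices), `f0`
#'   (centre frequency, Hz), `coherence` (target in `[0, 1]`), and
#'   optionally `bw_flat`, `bw_roll` (half-widths, Hz, of the flat top and
#'   cosine roll-off of the latent's spectral envelope).
#' @param psd_background noise variance per channel (scalar recycled, or a
#'   vector of length `n_channels`).
#' @return An object of class `state_spec`.
#' @export
state_spec <- function(state_id, edges = NULL, psd_background = 1) {
  if (is.null(edges)) {
    edges <- data.frame(i = integer(), j = integer(), f0 = numeric(),
                        coherence = numeric())
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (!all(c("i", "j", "f0", "coherence") %in% names(edges)))
      stopf("edges must have columns i, j, f0, coherence")
    if (any(edges$coherence < 0 | edges$coherence > 1))
      stopf("coherence_target must lie in [0, 1]")
    if (is.null(edges$bw_flat)) edges$bw_flat <- 1.5
    if (is.null(edges$bw_roll)) edges$bw_roll <- 1.0
  }
  structure(list(state_id = as.integer(state_id), edges = edges,
                 psd_background = psd_background),
            class = "state_spec")
}

#' Specify a synthetic two-condition cohort
#'
#' Defaults mirror the study geometry this package targets: 48 channels of
#' which the last 6 are tagged as STN contacts, 250 Hz sampling, and a
#' Markov chain whose expected dwell time is 500 ms per state.
#'
#' @param n_subjects number of virtual subjects per condition.
#' @param n_channels total channels (cortical + STN).
#' @param n_stn how many trailing channels carry the `"STN"` group tag;
#'   the rest are tagged `"cortical"`.
#' @param fs sampling rate in Hz.
#' @param duration_s seconds of data per subject per condition.
#' @param transition_matrix K x K row-stochastic matrix of the latent chain.
#' @param min_dwell_samples if `> 1`, dwell lengths are drawn from a
#'   geometric truncated below at this value (semi-Markov option).
#' @param condition_map named list of conditions; each element is a list
#'   with `permutation` (length-K state relabelling: condition state `k`
#'   behaves like base state `permutation[k]`) and optional `edge_gain`
#'   (named list mapping base state id to a per-edge amplitude multiplier).
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 17, n_channels = 48, n_stn = 6,
                        fs = 250, duration_s = 600,
                        transition_matrix = default_transition(3, fs = fs),
                        min_dwell_samples = 0,
                        condition_map = list(
                          A = list(permutation = NULL, edge_gain = NULL),
                          B = list(permutation = NULL, edge_gain = NULL)),
                        seed = 1L) {
  assert_row_stochastic(transition_matrix)
  if (fs <= 0) stopf("fs must be positive")
  if (n_subjects < 1) stopf("need at least one subject")
  K <- nrow(transition_matrix)
  for (nm in names(condition_map)) {
    p <- condition_map[[nm]]$permutation
    if (!is.null(p) && !identical(sort(as.integer(p)), seq_len(K)))
      stopf("condition '%s': permutation must permute 1..%d", nm, K)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 n_stn = as.integer(n_stn), fs = fs,
                 duration_s = duration_s,
                 transition_matrix = transition_matrix,
                 min_dwell_samples = as.integer(min_dwell_samples),
                 condition_map = condition_map, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Uniform-dwell transition matrix
#'
#' K-state chain with self-transition probability chosen so the expected
#' dwell time is `dwell_s` seconds at sampling rate `fs`, and uniform
#' off-diagonal jumps.
#' @param K number of states.
#' @param dwell_s expected dwell in seconds.
#' @param fs sampling rate, Hz.
#' @export
default_transition <- function(K, dwell_s = 0.5, fs = 250) {
  if (K == 1) return(matrix(1, 1, 1))
  p_self <- 1 - 1 / (dwell_s * fs)
  P <- matrix((1 - p_self) / (K - 1), K, K)
  diag(P) <- p_self
  P
}

#' Stationary distribution of a Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to sum to one.
#' @param P row-stochastic matrix.
#' @export
stationary_distribution <- function(P) {
  assert_row_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a latent state sequence
#'
#' Draws run lengths from the geometric dwell distribution implied by the
#' self-transition probabilities (truncated below at `min_dwell_samples`
#' when requested) and jump targets from the renormalised off-diagonal
#' rows. Equivalent in law to stepping the chain sample by sample when
#' `min_dwell_samples <= 1`.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param n_samples length of the sequence.
#' @param min_dwell_samples minimum dwell enforced by truncation (0 or 1
#'   disables it).
#' @param seed integer seed (reproducible).
#' @param init initial state (integer) or probability vector; defaults to
#'   the stationary distribution (uniform if not unique).
#' @return integer vector of states in `1..K`.
#' @export
generate_state_sequence <- function(transition_matrix, n_samples,
                                    min_dwell_samples = 0, seed = 1L,
                                    init = NULL) {
  assert_row_stochastic(transition_matrix)
  if (n_samples <= 0) stopf("n_samples must be positive")
  K <- nrow(transition_matrix)
  set.seed(as.integer(seed))
  if (is.null(init)) {
    init <- tryCatch(stationary_distribution(transition_matrix),
                     error = function(e) rep(1 / K, K))
  }
  state <- if (length(init) == 1) as.integer(init)
           else sample.int(K, 1, prob = init)
  out <- integer(n_samples)
  pos <- 0L
  while (pos < n_samples) {
    p_self <- transition_matrix[state, state]
    if (p_self >= 1) {
      dwell <- n_samples - pos
    } else {
      dwell <- stats::rgeom(1, 1 - p_self) + 1L
      if (min_dwell_samples > 1 && dwell < min_dwell_samples)
        dwell <- min_dwell_samples + stats::rgeom(1, 1 - p_self)
    }
    dwell <- min(dwell, n_samples - pos)
    out[(pos + 1L):(pos + dwell)] <- state
    pos <- pos + dwell
    if (pos < n_samples) {
      jump <- transition_matrix[state, ]
      jump[state] <- 0
      state <- sample.int(K, 1, prob = jump)
    }
  }
  out
}

## Spectral envelope of an edge's latent: flat top with cosine roll-off.
edge_envelope <- function(f, f0, bw_flat, bw_roll) {
  d <- abs(f - f0)
  env <- numeric(length(f))
  env[d <= bw_flat] <- 1
  ramp <- d > bw_flat & d < bw_flat + bw_roll
  env[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - bw_flat) / bw_roll))
  env
}

#' Closed-form coherence of a shared-latent edge
#'
#' With channel `i` receiving `sqrt(r) * sd_i * s(t)` plus independent
#' noise of variance `sd_i^2` per frequency bin, the coherence
#' (coherency magnitude) at the latent's peak is `r / (r + 1)` where
#' `r = gain^2 * c / (1 - c)`. `gain = 1` returns the nominal target `c`.
#' @param coherence nominal edge target in `[0, 1)`.
#' @param gain amplitude multiplier applied to the shared latent.
#' @export
edge_coherence_after_gain <- function(coherence, gain = 1) {
  r <- gain^2 * coherence / (1 - coherence)
  r / (r + 1)
}

#' Synthesise a multichannel series from a state sequence
#'
#' For every maximal single-state run, independent Gaussian channel noise
#' is added to per-edge shared latents built directly in the frequency
#' domain, so that the coherency magnitude at each edge's centre
#' frequency hits its target exactly in expectation (see
#' [edge_coherence_after_gain()]).
#' An edge with `coherence == 1` duplicates the source channel's signal.
#'
#' @param state_specs list of [state_spec()] objects covering every state
#'   in the sequence (position k = state k).
#' @param state_sequence integer vector from [generate_state_sequence()].
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param n_channels total channel count.
#' @param labels,groups,subject_id,condition metadata for the result.
#' @return A [region_timeseries()] object.
#' @export
generate_coherent_timeseries <- function(state_specs, state_sequence, fs,
                                         seed = 1L, n_channels = NULL,
                                         labels = NULL, groups = NULL,
                                         subject_id = "S01",
                                         condition = "A") {
  if (is.null(n_channels)) {
    n_channels <- max(1L, vapply(state_specs, function(s)
      if (nrow(s$edges)) max(s$edges$i, s$edges$j) else 1L, numeric(1)))
  }
  for (s in state_specs) {
    if (nrow(s$edges)) {
      if (any(s$edges$i > n_channels | s$edges$j > n_channels |
              s$edges$i < 1 | s$edges$j < 1))
        stopf("state %d: edge channel index out of range", s$state_id)
      if (any(s$edges$f0 <= 0 | s$edges$f0 >= fs / 2))
        stopf("state %d: centre frequency outside (0, fs/2)", s$state_id)
    }
  }
  used <- sort(unique(state_sequence))
  if (max(used) > length(state_specs))
    stopf("state sequence references state %d but only %d specs given",
          max(used), length(state_specs))
  set.seed(as.integer(seed))
  n_total <- length(state_sequence)
  X <- matrix(0, n_channels, n_total)
  runs <- rle(state_sequence)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$values)) {
    k <- runs$values[r]
    n <- runs$lengths[r]
    sp <- state_specs[[k]]
    sdv <- sqrt(rep_len(sp$psd_background, n_channels))
    seg <- matrix(rnorm(n_channels * n), n_channels, n) * sdv
    if (nrow(sp$edges) > 0 && n >= 8) {
      freqs <- (seq_len(n) - 1) * fs / n
      half <- 2:(floor((n - 1) / 2) + 1)  # positive-frequency bins, no DC
      for (e in seq_len(nrow(sp$edges))) {
        ed <- sp$edges[e, ]
        if (ed$coherence >= 1) next  # handled after noise, below
        env <- edge_envelope(freqs[half], ed$f0, ed$bw_flat, ed$bw_roll)
        nz <- which(env > 0)
        if (!length(nz)) next
        S <- complex(length.out = n)
        eps <- complex(real = rnorm(length(nz), sd = sqrt(0.5)),
                       imaginary = rnorm(length(nz), sd = sqrt(0.5)))
        S[half[nz]] <- sqrt(n) * env[nz] * eps
        S[n - half[nz] + 2L] <- Conj(S[half[nz]])
        s_t <- Re(fft(S, inverse = TRUE)) / n
        g <- sqrt(ed$coherence / (1 - ed$coherence))
        seg[ed$i, ] <- seg[ed$i, ] + g * sdv[ed$i] * s_t
        seg[ed$j, ] <- seg[ed$j, ] + g * sdv[ed$j] * s_t
      }
      dup <- sp$edges[sp$edges$coherence >= 1, , drop = FALSE]
      for (e in seq_len(nrow(dup))) seg[dup$j[e], ] <- seg[dup$i[e], ]
    }
    X[, starts[r]:ends[r]] <- seg
  }
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n_channels))
  if (is.null(groups)) groups <- rep("cortical", n_channels)
  region_timeseries(X, fs = fs, labels = labels, groups = groups,
                    subject_id = subject_id, condition = condition)
}

## Apply a condition's permutation and edge gains to the base state specs.
condition_specs <- function(state_specs, cond) {
  K <- length(state_specs)
  perm <- cond$permutation %||% seq_len(K)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    base <- state_specs[[perm[k]]]
    gains <- cond$edge_gain[[as.character(base$state_id)]]
    if (!is.null(gains) && nrow(base$edges)) {
      g <- rep_len(gains, nrow(base$edges))
      base$edges$coherence <-
        edge_coherence_after_gain(base$edges$coherence, g)
    }
    out[[k]] <- base
  }
  out
}

#' Generate a multi-subject, multi-condition cohort with ground truth
#'
#' Every subject in every condition gets an independent state sequence from
#' the shared chain and a signal realisation from the condition's
#' (possibly permuted / gain-adjusted) state specs. The returned ground
#' truth records sequences, true per-state edge coherences per condition,
#' the condition permutations, and per-subject temporal statistics of the
#' true sequences.
#'
#' @param spec a [cohort_spec()].
#' @param state_specs list of [state_spec()], one per chain state.
#' @return list with `data` (per condition: list of region time series)
#'   and `truth` (class `ground_truth`).
#' @export
generate_cohort <- function(spec, state_specs) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- nrow(spec$transition_matrix)
  if (length(state_specs) != K)
    stopf("need %d state specs, got %d", K, length(state_specs))
  n_samples <- round(spec$duration_s * spec$fs)
  groups <- c(rep("cortical", spec$n_channels - spec$n_stn),
              rep("STN", spec$n_stn))
  labels <- c(sprintf("ctx%02d", seq_len(spec$n_channels - spec$n_stn)),
              sprintf("stn%02d", seq_len(spec$n_stn)))
  data <- list()
  sequences <- list()
  true_specs <- list()
  for (ci in seq_along(spec$condition_map)) {
    cname <- names(spec$condition_map)[ci]
    cond <- spec$condition_map[[ci]]
    cspecs <- condition_specs(state_specs, cond)
    true_specs[[cname]] <- cspecs
    subj <- vector("list", spec$n_subjects)
    seqs <- vector("list", spec$n_subjects)
    for (si in seq_len(spec$n_subjects)) {
      sseed <- derive_seed(spec$seed, ci * 101L + si)
      z <- generate_state_sequence(spec$transition_matrix, n_samples,
                                   spec$min_dwell_samples, seed = sseed)
      subj[[si]] <- generate_coherent_timeseries(
        cspecs, z, spec$fs, seed = sseed + 1L,
        n_channels = spec$n_channels, labels = labels, groups = groups,
        subject_id = sprintf("S%02d", si), condition = cname)
      seqs[[si]] <- z
    }
    data[[cname]] <- subj
    sequences[[cname]] <- seqs
  }
  temporal <- lapply(sequences, function(seqs)
    lapply(seqs, compute_temporal_metrics, fs = spec$fs, n_states = K))
  fo <- lapply(temporal, function(tm)
    t(vapply(tm, function(m) m$fractional_occupancy, numeric(K))))
  truth <- structure(list(
    state_sequences = sequences,
    state_specs = true_specs,
    permutations = lapply(spec$condition_map, function(cond)
      cond$permutation %||% seq_len(K)),
    fractional_occupancy = fo,
    temporal = temporal,
    K = K, fs = spec$fs), class = "ground_truth")
  list(data = data, truth = truth)
}

#' Canonical three-band example states
#'
#' Three connectivity states in the default 48-channel geometry (42
#' cortical + 6 STN), one per canonical band: delta/theta (~4 Hz),
#' alpha (10 Hz, narrower envelope), and beta (~21 Hz). Each state
#' couples two STN contacts to cortical regions plus one
#' cortico-cortical edge, with coherence targets in the 0.6-0.85 range
#' typical of strong synthetic coupling.
#'
#' @param n_channels,n_stn cohort geometry; STN contacts are the last
#'   `n_stn` channels.
#' @return list of three [state_spec()] objects.
#' @export
three_band_state_specs <- function(n_channels = 48, n_stn = 6) {
  stn <- (n_channels - n_stn + 1):n_channels
  list(
    state_spec(1, data.frame(
      i = c(stn[1], stn[2], stn[3], stn[4], 2, 6),
      j = c(1, 5, 7, 9, 3, 8),
      f0 = c(4, 5, 4.5, 5.5, 4.5, 5),
      coherence = c(0.9, 0.88, 0.85, 0.85, 0.8, 0.8),
      bw_flat = 1.5, bw_roll = 1)),
    state_spec(2, data.frame(
      i = c(stn[3], stn[4], stn[5], stn[6], 11, 15),
      j = c(10, 12, 14, 16, 13, 17),
      f0 = c(10, 10, 10, 10, 10, 10),
      coherence = c(0.9, 0.88, 0.85, 0.85, 0.8, 0.8),
      bw_flat = 0.5, bw_roll = 0.5)),
    state_spec(3, data.frame(
      i = c(stn[5], stn[6], stn[1], stn[2], 21, 25),
      j = c(20, 22, 24, 26, 23, 27),
      f0 = c(21, 24, 20, 22, 21, 23),
      coherence = c(0.9, 0.88, 0.85, 0.85, 0.8, 0.8),
      bw_flat = 2, bw_roll = 1.5)))
}
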