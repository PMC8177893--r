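## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Small two-regime single-subject cohort with strong, well-separated
## covariance structure (several high-coherence edges per state).
two_regime_fit <- function() {
  if (!is.null(.fixtures$two_regime)) return(.fixtures$two_regime)
  specs <- list(
    state_spec(1, data.frame(i = c(1, 2), j = c(2, 3), f0 = c(8, 10),
                             coherence = c(0.95, 0.9))),
    state_spec(2, data.frame(i = c(4, 5), j = c(5, 6), f0 = c(22, 25),
                             coherence = c(0.95, 0.9))))
  P <- default_transition(2, dwell_s = 0.5)
  z <- generate_state_sequence(P, 250 * 300, seed = 5)
  ts <- generate_coherent_timeseries(specs, z, 250, seed = 6,
                                     n_channels = 6)
  cc <- standardise_and_concatenate(list(ts))
  emb <- tde_embed_pca(cc, 60, n_components = 12)
  fit <- hmm_fit(emb, K = 2, seed = 1, max_iter = 25, restarts = 3)
  .fixtures$two_regime <- list(specs = specs, P = P, z = z, ts = ts,
                               cc = cc, emb = emb, fit = fit)
  .fixtures$two_regime
}

## Brute-force path enumeration oracle for FB / Viterbi checks.
enumerate_paths <- function(loglik, A, pi0) {
  T_ <- nrow(loglik); K <- ncol(loglik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1, function(p) {
    s <- log(pi0[p[1]]) + loglik[1, p[1]]
    for (t in 2:T_) s <- s + log(A[p[t - 1], p[t]]) + loglik[t, p[t]]
    s
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  gamma <- vapply(seq_len(T_), function(t)
    vapply(seq_len(K), function(k) sum(w[paths[, t] == k]), 0),
    numeric(K))
  xi <- matrix(0, K, K)
  for (r in seq_len(nrow(paths)))
    for (t in 2:T_)
      xi[paths[r, t - 1], paths[r, t]] <-
        xi[paths[r, t - 1], paths[r, t]] + w[r]
  list(log_evidence = log(sum(exp(lp - max(lp)))) + max(lp),
       gamma = t(gamma), xi = xi,
       viterbi = paths[which.max(lp), ])
}

## All permutations of 1..n (for brute-force assignment checks).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

random_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.5
}
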