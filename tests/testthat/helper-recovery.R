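## Criterion-scale recovery fixture: two-condition cohort (3 states,
## 48 channels, 250 Hz, 5 min/subject, 4 subjects) with a planted state
## permutation, run through the full pipeline once per test session.
recovery_fixture <- function() {
  if (!is.null(.fixtures$recovery)) return(.fixtures$recovery)
  specs <- three_band_state_specs()
  cs <- cohort_spec(n_subjects = 4, duration_s = 300,
                    transition_matrix = default_transition(3, dwell_s = 0.5),
                    condition_map = list(
                      A = list(permutation = NULL),
                      B = list(permutation = c(3, 1, 2))),
                    seed = 7)
  coh <- generate_cohort(cs, specs)
  res <- suppressWarnings(run_pipeline(
    coh$data,
    pipeline_config(K = 3, orthogonalise = FALSE, sign_flip = FALSE,
                    seed = 11)))
  aligns <- list(); accs <- list(); fo_errs <- list()
  for (cond in c("A", "B")) {
    post <- res[[cond]]$hmm$posterior
    a <- c(); fe <- c()
    for (s in seq_along(post$boundaries)) {
      eb <- post$boundaries[[s]]
      est <- max.col(post$gamma[eb[1]:eb[2], , drop = FALSE],
                     ties.method = "first")
      zt <- coh$truth$state_sequences[[cond]][[s]]
      zt <- zt[(post$centre_shift + 1):(post$centre_shift + length(est))]
      al <- align_to_truth(est, zt, 3)
      a <- c(a, al$accuracy)
      if (s == 1) aligns[[cond]] <- al$perm
      fo_est <- tabulate(al$perm[est], 3) / length(est)
      fo_true <- tabulate(zt, 3) / length(zt)
      fe <- c(fe, max(abs(fo_est - fo_true)))
    }
    accs[[cond]] <- a
    fo_errs[[cond]] <- fe
  }
  .fixtures$recovery <- list(specs = specs, coh = coh, res = res,
                             aligns = aligns, accs = accs,
                             fo_errs = fo_errs)
  .fixtures$recovery
}
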