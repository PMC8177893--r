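test_that("state sequences are reproducible and follow the chain law", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  z1 <- generate_state_sequence(P, 5000, seed = 42)
  z2 <- generate_state_sequence(P, 5000, seed = 42)
  expect_identical(z1, z2)

  ## absorbing chain stays put
  za <- generate_state_sequence(diag(2), 100, seed = 1, init = 1)
  expect_true(all(za == 1))

  ## geometric dwell: self-transition 0.9 -> mean dwell 10
  z <- generate_state_sequence(P, 200000, seed = 2)
  expect_lt(abs(mean(rle(z)$lengths) - 10) / 10, 0.05)

  ## FO matches the stationary distribution (eigen oracle) within 2%
  P3 <- default_transition(3, dwell_s = 0.1, fs = 250)
  z3 <- generate_state_sequence(P3, 300000, seed = 3)
  fo <- tabulate(z3, 3) / length(z3)
  expect_equal(max(abs(fo - stationary_distribution(P3))), 0,
               tolerance = 0.02)

  ## min-dwell truncation is honoured
  zmd <- generate_state_sequence(default_transition(2, 0.2), 50000,
                                 min_dwell_samples = 30, seed = 4)
  runs <- rle(zmd)$lengths
  expect_true(all(head(runs, -1) >= 30))
})

test_that("malformed specifications are rejected", {
  expect_error(generate_state_sequence(matrix(c(0.5, 0.2, 0.5, 0.2), 2),
                                       100), "sum to 1")
  expect_error(state_spec(1, data.frame(i = 1, j = 2, f0 = 10,
                                        coherence = 1.2)), "\\[0, 1\\]")
  expect_error(
    generate_coherent_timeseries(
      list(state_spec(1, data.frame(i = 1, j = 2, f0 = 200,
                                    coherence = 0.5))),
      rep(1L, 100), fs = 250, n_channels = 2),
    "fs/2")
  expect_error(
    generate_coherent_timeseries(
      list(state_spec(1, data.frame(i = 1, j = 9, f0 = 10,
                                    coherence = 0.5))),
      rep(1L, 100), fs = 250, n_channels = 4),
    "out of range")
})

test_that("shared-latent edges hit their closed-form coherence target", {
  sp <- state_spec(1, data.frame(i = 1, j = 2, f0 = 20, coherence = 0.9))
  ts <- generate_coherent_timeseries(list(sp), rep(1L, 250 * 120),
                                     fs = 250, seed = 3, n_channels = 3)
  mt <- multitaper_spectra(list(ts$data), fs = 250)
  f20 <- which.min(abs(mt$freqs - 20))
  expect_gt(mt$coherence[f20, 1, 2], 0.8)
  expect_lt(mt$coherence[f20, 1, 2], 0.95)

  ## channels without an edge stay below twice the estimator bias floor
  msc_floor <- 1 / mt$n_avg
  expect_lt(mean(mt$coherence[, 1, 3]^2), 2 * msc_floor)
  expect_lt(mean(mt$coherence[, 2, 3]^2), 2 * msc_floor)

  ## degenerate duplicated channel: coherence 1 everywhere
  spd <- state_spec(1, data.frame(i = 1, j = 2, f0 = 10, coherence = 1))
  tsd <- generate_coherent_timeseries(list(spd), rep(1L, 5000), fs = 250,
                                      seed = 4, n_channels = 2)
  mtd <- multitaper_spectra(list(tsd$data), fs = 250)
  expect_equal(max(abs(mtd$coherence[, 1, 2] - 1)), 0, tolerance = 1e-10)
})

test_that("cohorts record consistent ground truth and condition maps", {
  ## single state, single subject: FO is exactly 1
  cs1 <- cohort_spec(n_subjects = 1, n_channels = 3, n_stn = 1, fs = 100,
                     duration_s = 5, transition_matrix = matrix(1, 1, 1),
                     condition_map = list(A = list()), seed = 9)
  coh1 <- generate_cohort(cs1, list(state_spec(1)))
  expect_equal(unname(coh1$truth$fractional_occupancy$A[1, ]), 1)

  ## permutation is recorded and data are reproducible under the seed
  cs <- cohort_spec(n_subjects = 2, n_channels = 4, n_stn = 1, fs = 100,
                    duration_s = 10,
                    transition_matrix = default_transition(3, 0.5, 100),
                    condition_map = list(A = list(),
                                         B = list(permutation = c(3, 1, 2))),
                    seed = 11)
  specs <- lapply(1:3, function(k)
    state_spec(k, data.frame(i = 1, j = 2, f0 = 5 * k, coherence = 0.7)))
  coh <- generate_cohort(cs, specs)
  expect_equal(coh$truth$permutations$B, c(3, 1, 2))
  coh2 <- generate_cohort(cs, specs)
  expect_identical(coh$data$A[[1]]$data, coh2$data$A[[1]]$data)
  expect_identical(coh$truth$state_sequences, coh2$truth$state_sequences)

  ## FO in the truth matches the emitted sequences
  fo <- tabulate(coh$truth$state_sequences$A[[1]], 3) /
    length(coh$truth$state_sequences$A[[1]])
  expect_equal(unname(coh$truth$fractional_occupancy$A[1, ]), fo)
})

test_that("edge gain multipliers lower coherence by the closed form", {
  ## closed form: target 0.9 with amplitude gain 0.5 -> MSC 9/13
  expect_equal(edge_coherence_after_gain(0.9, 0.5), 2.25 / 3.25)
  expect_equal(edge_coherence_after_gain(0.9, 1), 0.9)

  sp <- state_spec(1, data.frame(i = 1, j = 2, f0 = 20, coherence = 0.9))
  cs <- cohort_spec(n_subjects = 1, n_channels = 2, n_stn = 0, fs = 250,
                    duration_s = 120, transition_matrix = matrix(1, 1, 1),
                    condition_map = list(
                      A = list(),
                      B = list(edge_gain = list(`1` = 0.5))),
                    seed = 5)
  coh <- generate_cohort(cs, list(sp))
  est <- function(x) {
    mt <- multitaper_spectra(list(x$data), fs = 250)
    mt$coherence[which.min(abs(mt$freqs - 20)), 1, 2]
  }
  ca <- est(coh$data$A[[1]])
  cb <- est(coh$data$B[[1]])
  expect_gt(ca, cb + 0.05)
  ## estimator reports the coherency magnitude the target calibrates
  expect_equal(cb, 2.25 / 3.25, tolerance = 0.05)
  ## truth records the adjusted target
  expect_equal(coh$truth$state_specs$B[[1]]$edges$coherence, 2.25 / 3.25)
})
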