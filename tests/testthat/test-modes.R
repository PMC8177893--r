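## Minimal state_spectra-shaped object with known coherence arrays.
fake_spectra <- function(coh_by_subject_state, freqs, n_stn = 2,
                         n_ctx = 3) {
  N <- n_stn + n_ctx
  structure(list(
    spectra = coh_by_subject_state, freqs = freqs,
    labels = sprintf("ch%d", 1:N),
    groups = c(rep("cortical", n_ctx), rep("STN", n_stn)),
    subject_ids = sprintf("S%02d", seq_along(coh_by_subject_state)),
    K = length(coh_by_subject_state[[1]]), fs = 250),
    class = "state_spectra")
}

rand_coh <- function(nf, N, seed) {
  set.seed(seed)
  arr <- array(runif(nf * N * N, 0, 0.5), c(nf, N, N))
  for (f in seq_len(nf)) {
    m <- arr[f, , ]
    m <- (m + t(m)) / 2
    diag(m) <- 1
    arr[f, , ] <- m
  }
  list(coherence = arr)
}

test_that("group coherence layout follows the STN x cortical block scheme", {
  nf <- 10
  s1 <- list(rand_coh(nf, 5, 1), rand_coh(nf, 5, 2))
  s2 <- list(rand_coh(nf, 5, 3), rand_coh(nf, 5, 4))
  sp <- fake_spectra(list(s1, s2), freqs = seq(1, 5.5, by = 0.5))
  gc_ <- build_group_coherence(sp)
  expect_equal(gc_$block, 2 * 3)
  expect_equal(dim(gc_$group), c(nf, 6 * 2))   # block * K columns
  ## identical subjects: group equals either subject
  gc_same <- build_group_coherence(fake_spectra(list(s1, s1),
                                                seq(1, 5.5, by = 0.5)))
  expect_equal(gc_same$group, gc_same$subject[[1]])
  ## vectorisation order: STN index fastest
  expect_equal(gc_$subject[[1]][, 1],
               s1[[1]]$coherence[, 4, 1])       # stn ch4, ctx ch1
  expect_equal(gc_$subject[[1]][, 2],
               s1[[1]]$coherence[, 5, 1])       # stn ch5, ctx ch1
})

test_that("NNMF recovers planted non-overlapping spectral modes", {
  set.seed(5)
  nf <- 40
  freqs <- seq(1, 20.5, by = 0.5)
  W_true <- cbind(c(dnorm(1:20, 6, 1.5), rep(0, 20)),
                  c(rep(0, 20), dnorm(1:20, 12, 1.5)))
  W_true <- sweep(W_true, 2, colSums(W_true), "/")
  H_true <- matrix(runif(2 * 30), 2, 30)
  V <- W_true %*% H_true + matrix(runif(nf * 30, 0, 1e-3), nf)
  fm <- nnmf_frequency_modes(V, freqs, n_modes = 2, restarts = 6, seed = 1)
  cors <- abs(cor(t(fm$modes), W_true))
  perm <- solve_assignment(-cors)$pairing
  expect_gt(min(cors[cbind(1:2, perm)]), 0.95)
  ## unit 1-norm convention
  expect_equal(rowSums(fm$modes), c(1, 1), tolerance = 1e-8)

  ## rank-1 input with one mode: exact reconstruction
  V1 <- outer(runif(nf, 0.1, 1), runif(12, 0.1, 1))
  fm1 <- nnmf_frequency_modes(V1, freqs, n_modes = 1, restarts = 3,
                              seed = 2)
  expect_lt(fm1$reconstruction_error / sum(V1^2), 1e-6)

  ## nested models: more modes never fit worse
  fm4 <- nnmf_frequency_modes(V, freqs, n_modes = 4, restarts = 4, seed = 3)
  fm1b <- nnmf_frequency_modes(V, freqs, n_modes = 1, restarts = 4,
                               seed = 3)
  expect_lte(fm4$reconstruction_error, fm1b$reconstruction_error)

  ## determinism under seed, negativity guard
  fm_a <- nnmf_frequency_modes(V, freqs, n_modes = 2, restarts = 3, seed = 7)
  fm_b <- nnmf_frequency_modes(V, freqs, n_modes = 2, restarts = 3, seed = 7)
  expect_identical(fm_a$modes, fm_b$modes)
  expect_error(nnmf_frequency_modes(-V, freqs, n_modes = 2), "negative")
})

test_that("mode projections are exact inner products", {
  set.seed(6)
  nf <- 20
  freqs <- seq(1, 10.5, by = 0.5)
  mat <- matrix(runif(nf * 8), nf, 8)
  ## one-hot mode selects a single bin
  onehot <- matrix(0, 1, nf); onehot[1, 7] <- 1
  expect_equal(drop(project_onto_modes(mat, onehot)), mat[7, ])
  ## uniform mode over a band equals the scaled band mean
  band <- freqs >= 3 & freqs <= 6
  unif <- matrix(0, 1, nf); unif[1, band] <- 1 / sum(band)
  expect_equal(drop(project_onto_modes(mat, unif)),
               colMeans(mat[band, ]))
  ## linearity: group projection equals mean of subject projections
  mats <- lapply(1:4, function(i) matrix(runif(nf * 8), nf, 8))
  modes <- matrix(runif(2 * nf), 2, nf)
  group <- Reduce(`+`, mats) / 4
  pg <- project_onto_modes(group, modes)
  ps <- Reduce(`+`, lapply(mats, project_onto_modes, modes = modes)) / 4
  expect_equal(pg, ps, tolerance = 1e-12)
  ## grid mismatch guard
  fmobj <- structure(list(modes = modes, freqs = freqs + 1),
                     class = "frequency_modes")
  expect_error(project_onto_modes(mat, fmobj, freqs = freqs), "grids")
})
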