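test_that("first-PC reduction maximises explained variance", {
  set.seed(1)
  x <- rnorm(500)
  ## single vertex: same waveform up to sign/scale
  expect_equal(abs(cor(reduce_region_to_first_pc(matrix(x, 1)), x)), 1)
  ## duplicated vertices: still the shared waveform
  expect_equal(abs(cor(reduce_region_to_first_pc(rbind(x, x)), x)), 1)
  ## constant input is rejected
  expect_error(reduce_region_to_first_pc(matrix(1, 3, 100)), "variance")

  ## random 5-vertex input: beats 1000 random unit projections
  V <- matrix(rnorm(5 * 400), 5, 400)
  pc_var <- var(reduce_region_to_first_pc(V))
  Vc <- V - rowMeans(V)
  rand_var <- replicate(1000, {
    w <- rnorm(5); w <- w / sqrt(sum(w^2))
    var(drop(w %*% Vc))
  })
  expect_true(all(pc_var >= rand_var - 1e-10))
})

test_that("symmetric orthogonalisation yields the closest uncorrelated rows", {
  set.seed(2)
  X <- matrix(rnorm(3 * 1000), 3, 1000)
  O <- symmetric_orthogonalise(X)
  ## defining property: exactly orthogonal rows (zero sample correlation
  ## once centred rows; Gram is diagonal)
  G <- tcrossprod(O)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)

  ## already-orthogonal input passes through
  Q <- qr.Q(qr(matrix(rnorm(200 * 3), 200, 3)))
  Xo <- t(Q) * c(3, 1, 2)
  expect_equal(symmetric_orthogonalise(Xo), Xo, tolerance = 1e-6)

  ## least-squares optimality: no worse than sequential Gram-Schmidt
  gs <- function(X) {
    Y <- X
    for (i in 2:nrow(X)) for (j in 1:(i - 1)) {
      Y[i, ] <- Y[i, ] - sum(Y[i, ] * Y[j, ]) / sum(Y[j, ]^2) * Y[j, ]
    }
    Y
  }
  d_sym <- sqrt(sum((X - O)^2))
  d_gs <- sqrt(sum((X - gs(X))^2))
  expect_lte(d_sym, d_gs + 1e-8)

  ## rank-deficient input: error naming the collinear channels
  Xr <- rbind(X[1, ], X[1, ] * 2, X[3, ])
  expect_error(symmetric_orthogonalise(Xr), "rank-deficient")
})

test_that("sign-flip correction recovers planted channel sign flips", {
  set.seed(3)
  base <- matrix(rnorm(4 * 2000), 4, 2000)
  base <- t(apply(base, 1, function(x) as.numeric(stats::filter(
    x, rep(1 / 5, 5), sides = 2, circular = TRUE))))
  s1 <- base + matrix(rnorm(4 * 2000, sd = 0.2), 4)
  s2 <- base + matrix(rnorm(4 * 2000, sd = 0.2), 4)

  ## single subject: identity
  one <- sign_flip_correct(list(s1))
  expect_true(all(one$signs == 1))

  ## planted flip on channel 3 of subject 2 is recovered (up to a
  ## global sign per subject)
  s2f <- s2; s2f[3, ] <- -s2f[3, ]
  res <- sign_flip_correct(list(s1, s2f))
  rec <- res$signs[2, ] * res$signs[2, 1]   # normalise global sign
  expect_equal(unname(rec), c(1, 1, -1, 1))

  ## aligned cohort: identity signs are a fixed point
  res2 <- sign_flip_correct(list(s1, s2))
  expect_true(all(res2$signs[2, ] * res2$signs[2, 1] == 1))
  ## objective is non-decreasing across sweeps
  expect_true(all(diff(res$objective) >= -1e-9))
})

test_that("standardisation and concatenation keep exact bookkeeping", {
  set.seed(4)
  mk <- function(n, id) region_timeseries(matrix(rnorm(3 * n), 3), fs = 100,
                                          labels = c("a", "b", "c"),
                                          subject_id = id)
  cc <- standardise_and_concatenate(list(mk(1000, "S1"), mk(2000, "S2")))
  expect_equal(ncol(cc$data), 3000)
  expect_equal(cc$boundaries, list(c(1, 1000), c(1001, 3000)))
  for (b in cc$boundaries) {
    blk <- cc$data[, b[1]:b[2]]
    expect_lt(max(abs(rowMeans(blk))), 1e-12)
    expect_equal(apply(blk, 1, sd), rep(1, 3), tolerance = 1e-12)
  }
  ## z-scoring is idempotent
  again <- standardise_and_concatenate(list(region_timeseries(
    cc$data[, 1:1000], fs = 100, labels = c("a", "b", "c"))))
  expect_equal(again$data, cc$data[, 1:1000], tolerance = 1e-12)

  ## mismatched labels are rejected
  bad <- mk(100, "S3"); bad$labels <- c("x", "b", "c")
  expect_error(standardise_and_concatenate(list(mk(100, "S1"), bad)),
               "labels")
})

test_that("preprocessing pipeline orthogonalises cortical channels only", {
  set.seed(5)
  mats <- lapply(1:2, function(s) {
    region_timeseries(matrix(rnorm(5 * 3000), 5), fs = 250,
                      groups = c(rep("cortical", 3), rep("STN", 2)),
                      subject_id = sprintf("S%d", s))
  })
  cc <- preprocess_cohort(mats, orthogonalise = TRUE, sign_flip = TRUE)
  for (b in cc$boundaries) {
    blk <- cc$data[, b[1]:b[2]]
    C <- cor(t(blk[1:3, ]))
    expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
  }
})
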