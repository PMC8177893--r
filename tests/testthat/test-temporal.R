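test_that("temporal metrics match hand-counted values", {
  ## path 1 1 1 2 2 1 1 at 1000 Hz
  m <- compute_temporal_metrics(c(1, 1, 1, 2, 2, 1, 1), fs = 1000)
  expect_equal(m$fractional_occupancy, c(5 / 7, 2 / 7))
  expect_equal(m$lifetimes[[1]], c(3, 2))
  expect_equal(m$lifetimes[[2]], 2)
  expect_equal(m$intervals[[1]], 2)
  expect_equal(m$intervals[[2]], numeric(0))
  expect_equal(m$n_visits, c(2L, 1L))

  ## constant path: one lifetime, no intervals, FO 1
  mc <- compute_temporal_metrics(rep(1L, 500), fs = 250)
  expect_equal(mc$fractional_occupancy, 1)
  expect_equal(mc$lifetimes[[1]], 2000)
  expect_length(mc$intervals[[1]], 0)

  expect_error(compute_temporal_metrics(integer(0), 250), "empty")
})

test_that("the 100 ms lifetime filter excludes exactly sub-threshold runs", {
  ## at 250 Hz: 25 samples = 100 ms (excluded, strict >), 26 = 104 ms
  path <- c(rep(1, 25), rep(2, 50), rep(1, 26), rep(2, 50), rep(1, 24))
  m <- compute_temporal_metrics(path, fs = 250)
  expect_equal(m$lifetimes[[1]], c(100, 104, 96))
  expect_equal(m$lifetimes_filtered[[1]], 104)
  expect_equal(m$lifetimes_filtered[[2]], c(200, 200))
  ## intervals are not filtered
  expect_equal(m$intervals[[1]], c(200, 200))
  ## pre-filter lifetimes partition the recording exactly
  expect_equal(sum(unlist(m$lifetimes)), length(path) / 250 * 1000)
})

test_that("mean lifetimes track the chain's geometric dwell", {
  P <- default_transition(3, dwell_s = 0.4, fs = 250)
  z <- generate_state_sequence(P, 250 * 1200, seed = 8)
  m <- compute_temporal_metrics(z, fs = 250)
  for (k in 1:3)
    expect_lt(abs(mean(m$lifetimes[[k]]) - 400) / 400, 0.1)
})

## Fabricate a temporal_metrics object from given per-state lifetimes.
fake_metrics <- function(lifetimes, intervals = lifetimes, fo = NULL) {
  K <- length(lifetimes)
  fo <- fo %||% rep(1 / K, K)
  structure(list(
    fractional_occupancy = fo / sum(fo),
    lifetimes = lifetimes,
    lifetimes_filtered = lapply(lifetimes, function(x) x[x > 100]),
    intervals = intervals,
    n_visits = lengths(lifetimes), fs = 250, min_lifetime_ms = 100),
    class = "temporal_metrics")
}

test_that("two-way ANOVA matches the explicit sums-of-squares oracle", {
  ## balanced 2 states x 2 conditions x 2 subjects x 4 visits table
  set.seed(9)
  vals <- array(rnorm(2 * 2 * 2 * 4, mean = 200, sd = 20), c(2, 2, 2, 4))
  mk_cond <- function(c_) lapply(1:2, function(s)
    fake_metrics(list(vals[1, c_, s, ] + 0, vals[2, c_, s, ] + 0),
                 fo = runif(2, 0.3, 0.7)))
  res <- suppressWarnings(
    anova_temporal(mk_cond(1), mk_cond(2), conditions = c("A", "B")))
  tab <- res$lifetime$anova

  ## oracle: textbook two-way fixed-effects sums of squares on the
  ## pooled visit table (subjects pooled within cells)
  y <- as.vector(vals)
  state <- rep(1:2, times = 16)
  cond <- rep(rep(1:2, each = 2), times = 8)
  g <- mean(y)
  ss_state <- sum(tapply(y, state, function(v) length(v) * (mean(v) - g)^2))
  ss_cond <- sum(tapply(y, cond, function(v) length(v) * (mean(v) - g)^2))
  cellm <- tapply(y, list(state, cond), mean)
  n_cell <- 8
  ss_int <- n_cell * sum((cellm - outer(tapply(y, state, mean),
                                        tapply(y, cond, mean), `+`) + g)^2)
  ss_res <- sum((y - cellm[cbind(state, cond)])^2)
  df_res <- length(y) - 4
  F_state <- (ss_state / 1) / (ss_res / df_res)
  F_cond <- (ss_cond / 1) / (ss_res / df_res)
  F_int <- (ss_int / 1) / (ss_res / df_res)
  expect_equal(tab$F[tab$term == "state"], F_state, tolerance = 1e-10)
  expect_equal(tab$F[tab$term == "condition"], F_cond, tolerance = 1e-10)
  expect_equal(tab$F[tab$term == "state:condition"], F_int,
               tolerance = 1e-10)
  expect_equal(tab$df_resid[tab$term == "state"], df_res)
})

test_that("visit-level ANOVA keeps its nominal type-I rate on null data", {
  reject <- vapply(1:500, function(seed) {
    set.seed(seed)
    mk <- function() lapply(1:3, function(s)
      fake_metrics(lapply(1:3, function(k) 150 + rexp(40, 1 / 200)),
                   fo = runif(3, 0.2, 0.5)))
    res <- suppressWarnings(anova_temporal(mk(), mk()))
    res$lifetime$anova$p[res$lifetime$anova$term == "state"] < 0.05
  }, TRUE)
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("state-dependent dwell differences are detected with high power", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    mk <- function() lapply(1:17, function(s)
      fake_metrics(list(110 + rexp(50, 1 / 300), 110 + rexp(50, 1 / 150)),
                   fo = runif(2, 0.3, 0.7)))
    res <- suppressWarnings(anova_temporal(mk(), mk()))
    res$lifetime$anova$p[res$lifetime$anova$term == "state"] < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})
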