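## Two-component 1-D Gaussian mixture EM with both variances fixed at 1.
## Values are expected to be standardised by the caller.
gmm2_unit_em <- function(x, max_iter = 200, tol = 1e-8) {
  mu <- stats::quantile(x, c(0.25, 0.9), names = FALSE)
  w <- c(0.8, 0.2)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], 1)
    d2 <- w[2] * stats::dnorm(x, mu[2], 1)
    tot <- d1 + d2
    r2 <- d2 / tot
    ll <- sum(log(tot))
    w[2] <- mean(r2); w[1] <- 1 - w[2]
    mu[1] <- sum((1 - r2) * x) / sum(1 - r2)
    mu[2] <- sum(r2 * x) / sum(r2)
    if (ll - ll_old < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); w <- rev(w) }
  list(mu = mu, w = w)
}

#' Map vectorised STN-cortex block entries to channel indices
#'
#' The block from [build_group_coherence()] is vectorised with the STN
#' index running fastest.
#' @param gc the list returned by [build_group_coherence()].
#' @return data frame with `edge`, `stn_channel`, `cortical_channel`.
#' @export
edge_table <- function(gc) {
  n_stn <- length(gc$stn)
  data.frame(edge = seq_len(gc$block),
             stn_channel = gc$stn[((seq_len(gc$block) - 1) %% n_stn) + 1],
             cortical_channel =
               gc$cortical[((seq_len(gc$block) - 1) %/% n_stn) + 1])
}

#' Threshold projected coherence edges with a two-Gaussian mixture
#'
#' Within each frequency mode, edge values are first normalised by
#' subtracting the per-edge mean across states; per state and mode the
#' absolute normalised values are standardised and modelled as a
#' two-component Gaussian mixture with unit component variances (one
#' component for background noise, one for genuine connections). Edge
#' p-values are upper-tail probabilities under the noise component,
#' corrected across edges within the state x mode family.
#'
#' @param group_projection n_modes x (block * K) matrix from
#'   [project_onto_modes()] applied to the group coherence matrix.
#' @param K number of states.
#' @param block edges per state (STN x cortical pairs).
#' @param alpha significance level after correction.
#' @param correction `p.adjust` method; `"BH"` (default) or
#'   `"bonferroni"`.
#' @return object of class `network_result`: `edges` data frame (state,
#'   mode, edge, value, p, p_adj, significant) and `offsets` (per-edge
#'   means removed, n_modes x block x ... per mode).
#' @export
gmm_threshold <- function(group_projection, K, block, alpha = 0.05,
                          correction = "BH") {
  M <- as.matrix(group_projection)
  if (ncol(M) != K * block) stopf("projection has %d columns, expected %d",
                                  ncol(M), K * block)
  if (any(!is.finite(M))) stopf("non-finite projection values")
  if (K < 2) stopf("need >= 2 states to demean across states")
  n_modes <- nrow(M)
  rows <- list()
  offsets <- array(NA_real_, c(n_modes, block))
  for (m in seq_len(n_modes)) {
    vals <- matrix(M[m, ], nrow = K, ncol = block, byrow = TRUE)
    off <- colMeans(vals)
    offsets[m, ] <- off
    dem <- sweep(vals, 2, off)
    for (k in seq_len(K)) {
      x <- abs(dem[k, ])
      s <- stats::sd(x)
      if (!is.finite(s) || s < 1e-14) {
        warning(sprintf("state %d mode %d: degenerate edge values; no significant edges", k, m))
        p <- rep(1, block)
      } else {
        z <- x / s
        fit <- gmm2_unit_em(z)
        p <- stats::pnorm(z - fit$mu[1], lower.tail = FALSE)
      }
      p_adj <- p.adjust(p, method = correction)
      rows[[length(rows) + 1L]] <- data.frame(
        state = k, mode = m, edge = seq_len(block),
        value = dem[k, ], p = p, p_adj = p_adj,
        significant = p_adj < alpha)
    }
  }
  structure(list(edges = do.call(rbind, rows), offsets = offsets,
                 alpha = alpha, correction = correction),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  n_sig <- sum(x$edges$significant)
  cat(sprintf("<network_result> %d edge tests, %d significant at corrected p < %g\n",
              nrow(x$edges), n_sig, x$alpha))
  invisible(x)
}

#' Between-condition comparison of matched-state coherence
#'
#' For every matched state pair, frequency mode, and cluster pair
#' (STN cluster x cortical cluster), subject-level mean projected
#' coherence is compared between the two conditions with a two-sided
#' independent-sample t-test (a paired option is available for
#' within-subject designs). P-values are corrected over all tested
#' combinations.
#'
#' @param proj_a,proj_b per-condition lists of subject projection
#'   matrices (n_modes x block * K each).
#' @param edge_index data frame from [edge_table()].
#' @param clusters character vector: cluster label per channel.
#' @param pairing state pairing from [match_states()] (condition A state
#'   `k` corresponds to condition B state `pairing[k]`); identity when
#'   `NULL`.
#' @param K,block state count and edges per state.
#' @param alpha significance level after correction.
#' @param correction `p.adjust` method (default `"bonferroni"`).
#' @param paired use paired t-tests.
#' @return object of class `cluster_comparison` with a `tests` data
#'   frame: state_a, state_b, mode, cluster pair, t, df, p, p_adj,
#'   significant, direction (`"A>B"` / `"B>A"`).
#' @export
intermed_ttests <- function(proj_a, proj_b, edge_index, clusters,
                            pairing = NULL, K, block, alpha = 0.05,
                            correction = "bonferroni", paired = FALSE) {
  if (is.null(pairing)) pairing <- seq_len(K)
  if (length(proj_a) < 2 || length(proj_b) < 2)
    stopf("need at least 2 subjects per condition")
  n_modes <- nrow(proj_a[[1]])
  pair_lab <- paste(clusters[edge_index$stn_channel],
                    clusters[edge_index$cortical_channel], sep = "-")
  pairs <- unique(pair_lab)
  rows <- list()
  for (k in seq_len(K)) {
    kb <- pairing[k]
    for (m in seq_len(n_modes)) {
      cols_a <- (k - 1) * block + seq_len(block)
      cols_b <- (kb - 1) * block + seq_len(block)
      for (cp in pairs) {
        sel <- pair_lab == cp
        if (!any(sel)) next
        va <- vapply(proj_a, function(P)
          mean(P[m, cols_a[sel]], na.rm = TRUE), 0)
        vb <- vapply(proj_b, function(P)
          mean(P[m, cols_b[sel]], na.rm = TRUE), 0)
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (length(va) < 2 || length(vb) < 2) {
          warning(sprintf("cluster pair %s: too few subjects, skipped", cp))
          next
        }
        tt <- t.test(va, vb, paired = paired)
        rows[[length(rows) + 1L]] <- data.frame(
          state_a = k, state_b = kb, mode = m, clusters = cp,
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value,
          direction = if (mean(va) >= mean(vb)) "A>B" else "B>A")
      }
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adj <- p.adjust(tests$p, method = correction)
  tests$significant <- tests$p_adj < alpha
  structure(list(tests = tests, alpha = alpha, correction = correction,
                 paired = paired), class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat(sprintf("<cluster_comparison> %d tests, %d significant at corrected p < %g\n",
              nrow(x$tests), sum(x$tests$significant), x$alpha))
  invisible(x)
}
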