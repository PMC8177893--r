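#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `d(A, B) = sqrt(sum(log(lambda_i)^2))` over the generalised
#' eigenvalues of `(A, B)`. Zero iff `A == B`, symmetric, and invariant
#' under congruence `A -> M A M'`, `B -> M B M'` for invertible `M`.
#'
#' @param A,B symmetric positive definite matrices.
#' @return non-negative scalar.
#' @export
riemannian_distance <- function(A, B) {
  for (nm in list(list(A, "A"), list(B, "B"))) {
    ev_min <- min(eigen((nm[[1]] + t(nm[[1]])) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min <= 0)
      stopf("matrix %s is not positive definite (min eigenvalue %.3g)",
            nm[[2]], ev_min)
  }
  R <- chol(A)
  M <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)),
                 transpose = TRUE)          # A^{-1/2} B A^{-1/2} (chol-based)
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Minimum-cost linear assignment (Munkres / Jonker-Volgenant)
#'
#' Solves `min_perm sum_i cost[i, perm[i]]` by the O(n^3) shortest
#' augmenting path algorithm with dual potentials.
#'
#' @param cost square numeric cost matrix.
#' @return list with `pairing` (row i matched to column `pairing[i]`)
#'   and `total` cost.
#' @export
solve_assignment <- function(cost) {
  a <- as.matrix(cost)
  n <- nrow(a)
  if (ncol(a) != n) stopf("cost matrix must be square")
  if (any(!is.finite(a))) stopf("cost matrix must be finite")
  INF <- sum(abs(a)) + 1
  ## arrays indexed 0..n for the virtual column 0 (offset +1)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  pairing <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) pairing[p[j + 1]] <- j
  list(pairing = pairing, total = sum(a[cbind(seq_len(n), pairing)]))
}

#' Match states across two independently fitted HMMs
#'
#' State covariances from each fit are mapped back to the shared channel
#' space (the zero-lag block of the channel x lag covariance, via each
#' model's own PCA projection), pairwise affine-invariant Riemannian
#' distances are computed, and the assignment minimising the total
#' distance is found with the Munkres algorithm. Covariances are
#' eigenvalue-floored before the metric if needed.
#'
#' @param model_a,model_b `hmm_model` objects with equal `K`, or plain
#'   lists of SPD matrices already in a common space.
#' @return object of class `state_match`: `distance_matrix` (K x K,
#'   rows = model A states), `pairing` (A state k matched to B state
#'   `pairing[k]`), `total_distance`.
#' @export
match_states <- function(model_a, model_b) {
  covs <- lapply(list(model_a, model_b), function(m) {
    if (inherits(m, "hmm_model")) {
      emb <- m$embedding
      lapply(m$state_covariances, function(S)
        spd_floor(state_cov_to_channel(S, emb), rel = 1e-10))
    } else {
      lapply(m, spd_floor, rel = 1e-10)
    }
  })
  A <- covs[[1]]; B <- covs[[2]]
  if (length(A) != length(B))
    stopf("models have different state counts (%d vs %d)",
          length(A), length(B))
  K <- length(A)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    D[i, j] <- riemannian_distance(A[[i]], B[[j]])
  sol <- solve_assignment(D)
  structure(list(distance_matrix = D, pairing = sol$pairing,
                 total_distance = sol$total), class = "state_match")
}

#' @export
print.state_match <- function(x, ...) {
  cat(sprintf("<state_match> %d states, total distance %.4f\n",
              length(x$pairing), x$total_distance))
  cat("  pairing:", paste(seq_along(x$pairing), "->", x$pairing,
                          collapse = ", "), "\n")
  invisible(x)
}

#' Align estimated state labels to a reference path
#'
#' Finds the label permutation maximising frame agreement between an
#' estimated hard path and a reference path (assignment problem on the
#' K x K overlap-count matrix). Returns `perm` such that
#' `perm[est_label]` is the matched reference label, plus the achieved
#' frame accuracy.
#'
#' @param est_path,ref_path equal-length integer paths in `1..K`.
#' @param K number of states.
#' @export
align_to_truth <- function(est_path, ref_path, K) {
  stopifnot(length(est_path) == length(ref_path))
  overlap <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    overlap[i, j] <- sum(est_path == i & ref_path == j)
  sol <- solve_assignment(-overlap)
  list(perm = sol$pairing,
       accuracy = sum(overlap[cbind(seq_len(K), sol$pairing)]) /
         length(est_path))
}
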