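## Symmetric lag offsets for an L-point window: 0-centred, e.g. L = 15
## gives -7..7.
lag_offsets <- function(L) seq_len(L) - 1L - (L %/% 2L)

#' Number of embedding lags for a window length
#'
#' @param window_ms embedding window in milliseconds.
#' @param fs sampling rate, Hz.
#' @return integer lag count `L = round(window_ms * fs / 1000)`.
#' @export
embedding_lags <- function(window_ms, fs) {
  L <- as.integer(round(window_ms * fs / 1000))
  if (L < 1) stopf("window of %g ms at %g Hz gives no lags", window_ms, fs)
  L
}

#' Time-delay embed a multichannel matrix
#'
#' Stacks lagged copies of the channel matrix into an `N*L x T'` matrix,
#' `T' = T - L + 1`. Row block `a` (rows `(a-1)*N + 1 .. a*N`) holds the
#' channels delayed by the `a`-th symmetric lag offset; columns are
#' indexed by the centre sample of the window.
#'
#' @param data channels x samples matrix.
#' @param window_ms embedding window, ms.
#' @param fs sampling rate, Hz.
#' @return `N*L x (T - L + 1)` matrix with attributes `offsets` and
#'   `centre_shift` (offset of embedded column 1 into the original time
#'   axis).
#' @export
tde_embed <- function(data, window_ms, fs) {
  X <- as.matrix(data)
  N <- nrow(X); T_ <- ncol(X)
  L <- embedding_lags(window_ms, fs)
  if (T_ <= L) stopf("need more than %d samples, got %d", L, T_)
  offs <- lag_offsets(L)
  h_lo <- -min(offs); h_hi <- max(offs)
  centres <- (1L + h_lo):(T_ - h_hi)
  E <- matrix(0, N * L, length(centres))
  for (a in seq_len(L)) {
    E[((a - 1L) * N + 1L):(a * N), ] <- X[, centres + offs[a], drop = FALSE]
  }
  attr(E, "offsets") <- offs
  attr(E, "centre_shift") <- h_lo
  E
}

#' PCA reduction of an embedded matrix
#'
#' Rows (embedded dimensions) are mean-centred; the covariance is
#' eigen-decomposed and the data projected on the leading
#' `n_components` eigenvectors. The discarded variance equals the sum of
#' the discarded eigenvalues.
#'
#' @param embedded matrix from [tde_embed()] (or any dims x samples
#'   matrix).
#' @param n_components number of components retained; default `2 * N` when
#'   `n_channels` is supplied, otherwise all.
#' @param n_channels,fs,labels,groups,boundaries optional metadata carried
#'   into the result.
#' @return Object of class `embedded_ts`: `data` (P x T'), `projection`
#'   (N*L x P, orthonormal columns), `mean`, `evals` (all eigenvalues,
#'   decreasing), `explained_variance` (retained), plus metadata.
#' @export
pca_reduce <- function(embedded, n_components = NULL, n_channels = NULL,
                       fs = NULL, labels = NULL, groups = NULL,
                       boundaries = NULL) {
  D <- nrow(embedded); T_ <- ncol(embedded)
  if (is.null(n_components))
    n_components <- if (!is.null(n_channels)) 2L * n_channels else D
  if (n_components > D)
    stopf("n_components (%d) exceeds embedded dimension (%d)",
          n_components, D)
  mu <- rowMeans(embedded)
  C <- tcrossprod(embedded - mu) / (T_ - 1)
  e <- eigen(C, symmetric = TRUE)
  W <- e$vectors[, seq_len(n_components), drop = FALSE]
  scores <- crossprod(W, embedded - mu)
  new_embedded(scores, W, mu, e$values, attr(embedded, "offsets"),
               attr(embedded, "centre_shift") %||% 0L,
               n_channels, fs, labels, groups,
               boundaries %||% list(c(1L, T_)))
}

new_embedded <- function(scores, W, mu, evals, offsets, centre_shift,
                         n_channels, fs, labels, groups, boundaries) {
  structure(list(data = scores, projection = W, mean = mu, evals = evals,
                 explained_variance = evals[seq_len(ncol(W))],
                 offsets = offsets, centre_shift = centre_shift,
                 n_channels = n_channels, fs = fs, labels = labels,
                 groups = groups, boundaries = boundaries),
            class = "embedded_ts")
}

#' @export
print.embedded_ts <- function(x, ...) {
  cat(sprintf(
    "<embedded_ts> %d components x %d samples (N=%s, L=%d lags)\n",
    nrow(x$data), ncol(x$data), x$n_channels %||% "?", length(x$offsets)))
  invisible(x)
}

#' Embed and PCA-reduce a concatenated dataset
#'
#' Equivalent to [tde_embed()] + [pca_reduce()] applied per subject block
#' and pooled, but never materialises the full `N*L x T'` matrix: the
#' lag-covariance is accumulated from `N x N` lagged cross-products and
#' the PC scores are formed lag-block by lag-block. Embedding never
#' crosses a subject boundary.
#'
#' @param concat a `concat_ts` from [standardise_and_concatenate()].
#' @param window_ms embedding window, ms (default 60).
#' @param n_components retained components; default `2 * N`.
#' @return An `embedded_ts` with per-subject `boundaries` in embedded
#'   column indices.
#' @export
tde_embed_pca <- function(concat, window_ms = 60, n_components = NULL) {
  X <- concat$data
  N <- nrow(X)
  L <- embedding_lags(window_ms, concat$fs)
  if (is.null(n_components)) n_components <- 2L * N
  if (n_components > N * L)
    stopf("n_components (%d) exceeds embedded dimension (%d)",
          n_components, N * L)
  offs <- lag_offsets(L)
  h_lo <- -min(offs); h_hi <- max(offs)

  M <- matrix(0, N * L, N * L)
  mu <- numeric(N * L)
  Ttot <- 0L
  blocks <- lapply(concat$boundaries, function(b) {
    s <- b[1]; e <- b[2]
    if (e - s + 1L <= L)
      stopf("subject block of %d samples too short for %d lags",
            e - s + 1L, L)
    c(s, e, s + h_lo, e - h_hi)  # block start/end, centre start/end
  })
  for (b in blocks) {
    s <- b[1]; e <- b[2]; c0 <- b[3]; c1 <- b[4]
    Tp <- c1 - c0 + 1L
    Ttot <- Ttot + Tp
    for (a in seq_len(L)) {
      idx <- ((a - 1L) * N + 1L):(a * N)
      mu[idx] <- mu[idx] + rowSums(X[, (c0 + offs[a]):(c1 + offs[a]),
                                     drop = FALSE])
    }
    for (d in 0:(L - 1L)) {
      ## widest-range lagged cross-product once per lag difference d,
      ## then trim per pair by cheap edge corrections
      G_full <- tcrossprod(X[, s:(e - d), drop = FALSE],
                           X[, (s + d):e, drop = FALSE])
      for (a in seq_len(L - d)) {
        bcol <- a + d
        u0 <- c0 + offs[a]; u1 <- c1 + offs[a]
        G <- G_full
        if (u0 > s) {
          cols <- s:(u0 - 1L)
          G <- G - tcrossprod(X[, cols, drop = FALSE],
                              X[, cols + d, drop = FALSE])
        }
        if (u1 < e - d) {
          cols <- (u1 + 1L):(e - d)
          G <- G - tcrossprod(X[, cols, drop = FALSE],
                              X[, cols + d, drop = FALSE])
        }
        ri <- ((a - 1L) * N + 1L):(a * N)
        ci <- ((bcol - 1L) * N + 1L):(bcol * N)
        M[ri, ci] <- M[ri, ci] + G
        if (d > 0) M[ci, ri] <- M[ci, ri] + t(G)
      }
    }
  }
  mu <- mu / Ttot
  C <- (M - Ttot * tcrossprod(mu)) / (Ttot - 1)
  e <- eigen(C, symmetric = TRUE)
  W <- e$vectors[, seq_len(n_components), drop = FALSE]

  scores <- matrix(0, n_components, Ttot)
  emb_bounds <- vector("list", length(blocks))
  pos <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    c0 <- b[3]; c1 <- b[4]
    Tp <- c1 - c0 + 1L
    sc <- matrix(0, n_components, Tp)
    for (a in seq_len(L)) {
      idx <- ((a - 1L) * N + 1L):(a * N)
      sc <- sc + crossprod(W[idx, , drop = FALSE],
                           X[, (c0 + offs[a]):(c1 + offs[a]), drop = FALSE])
    }
    scores[, (pos + 1L):(pos + Tp)] <- sc - drop(crossprod(W, mu))
    emb_bounds[[bi]] <- c(pos + 1L, pos + Tp)
    pos <- pos + Tp
  }
  new_embedded(scores, W, mu, e$values, offs, h_lo, N, concat$fs,
               concat$labels, concat$groups, emb_bounds)
}

#' Map a state covariance back to channel space
#'
#' Projects a P x P covariance in PC space to the channel x lag space via
#' the PCA projection and reads out one lag-offset block (the zero-lag
#' block by default), giving an `N x N` channel-space covariance. The
#' result is symmetrised; it is positive semi-definite by construction.
#'
#' @param sigma P x P covariance in PC space.
#' @param embedding the `embedded_ts` whose projection defines the map.
#' @param lag lag offset of the block to read (default 0).
#' @return `N x N` symmetric matrix.
#' @export
state_cov_to_channel <- function(sigma, embedding, lag = 0) {
  offs <- embedding$offsets
  a <- which(offs == lag)
  if (!length(a)) stopf("lag %d not in the embedding window", lag)
  N <- embedding$n_channels
  idx <- ((a - 1L) * N + 1L):(a * N)
  W0 <- embedding$projection[idx, , drop = FALSE]
  B <- W0 %*% sigma %*% t(W0)
  (B + t(B)) / 2
}
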