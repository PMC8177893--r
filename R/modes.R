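#' Assemble subject- and group-level STN-cortex coherence matrices
#'
#' For each subject and state, the STN x cortical block of the coherence
#' array is vectorised (length `n_stn * n_cortical`, 252 in the default
#' 6 x 42 geometry) and the states are concatenated along columns,
#' giving a `bins x (block * K)` subject-level matrix. The group-level
#' matrix is the subject average.
#'
#' @param spectra a `state_spectra` from [compute_state_spectra()].
#' @return list with `subject` (list of bins x (block*K) matrices),
#'   `group` (their mean), `freqs`, `stn`, `cortical` (channel indices),
#'   `block` (block length), `K`.
#' @export
build_group_coherence <- function(spectra) {
  stn <- which(spectra$groups == "STN")
  ctx <- which(spectra$groups == "cortical")
  if (!length(stn) || !length(ctx))
    stopf("channel groups must tag both STN and cortical channels")
  nf <- length(spectra$freqs)
  block <- length(stn) * length(ctx)
  K <- spectra$K
  subj_mats <- list()
  for (s in seq_along(spectra$spectra)) {
    M <- matrix(NA_real_, nf, block * K)
    for (k in seq_len(K)) {
      sp <- spectra$spectra[[s]][[k]]
      if (is.null(sp)) next
      blk <- sp$coherence[, stn, ctx, drop = FALSE]
      M[, ((k - 1) * block + 1):(k * block)] <-
        matrix(blk, nf, block)
    }
    subj_mats[[s]] <- M
  }
  arr <- simplify2array(subj_mats)           # nf x cols x subjects
  group <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  group[!is.finite(group)] <- 0
  list(subject = subj_mats, group = group, freqs = spectra$freqs,
       stn = stn, cortical = ctx, block = block, K = K)
}

## Non-negative double SVD initialisation (deterministic, parts-based).
nndsvd_init <- function(V, r) {
  sv <- svd(V, nu = r, nv = r)
  W <- matrix(0, nrow(V), r); H <- matrix(0, r, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(r)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      s <- sqrt(sv$d[j] * nup * nvp)
      W[, j] <- s * up / max(nup, 1e-12)
      H[j, ] <- s * vp / max(nvp, 1e-12)
    } else {
      s <- sqrt(sv$d[j] * nun * nvn)
      W[, j] <- s * un / max(nun, 1e-12)
      H[j, ] <- s * vn / max(nvn, 1e-12)
    }
  }
  W[W < 1e-9] <- 1e-9; H[H < 1e-9] <- 1e-9
  list(W = W, H = H)
}

## One multiplicative-update NNMF run (Lee-Seung, Frobenius objective)
## with an L1 penalty on the spectral factor W. Sparsity on W resolves
## the additive non-uniqueness of NNMF (it stops broadband background
## mass from leaking into narrowband modes); W columns are renormalised
## to unit 1-norm each iteration with the scale moved into H, so the
## penalty acts on the mode shapes only. A single mode (r = 1) is
## unique up to scale, so no penalty is applied there.
nnmf_once <- function(V, r, max_iter = 1000, tol = 1e-12, init = NULL,
                      sparsity = 0.05) {
  n <- nrow(V); m <- ncol(V)
  if (is.null(init)) {
    W <- matrix(runif(n * r, 0.1, 1), n, r)
    H <- matrix(runif(r * m, 0.1, 1), r, m)
  } else {
    W <- init$W; H <- init$H
  }
  lam <- if (r > 1) sparsity * mean(colSums(V)) else 0
  err_old <- Inf
  eps <- 1e-12
  errs <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) + eps) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H) + eps) / (W %*% tcrossprod(H) + lam + eps)
    s <- pmax(colSums(W), eps)
    W <- sweep(W, 2, s, "/")
    H <- H * s
    if (it %% 50 == 0 || it == max_iter) {
      err <- sum((V - W %*% H)^2)
      errs <- c(errs, err)
      ## the sparsity bias needs long runs: only stop once the fit is
      ## essentially stationary
      if (abs(err_old - err) < tol * (err + 1e-30)) break
      err_old <- err
    }
  }
  list(W = W, H = H, error = sum((V - W %*% H)^2), trace = errs)
}

#' Data-driven frequency modes by robust NNMF
#'
#' Factorises the non-negative group-level coherence matrix
#' (`bins x columns`) into `n_modes` spectral modes (columns of `W`).
#' Robustness: `restarts` seeded multiplicative-update runs (the first
#' NNDSVD-initialised); cross-restart agreement with the consensus mode
#' set is reported as a stability diagnostic, and the returned fit is
#' the most frequency-specific run (largest mean Hoyer sparsity of the
#' mode shapes) among those fitting within 2% of the best
#' reconstruction error — mixed and parts-based factorisations fit
#' near-identically, so specificity is the right tie-break. Modes are
#' normalised to unit 1-norm and labelled by the canonical band holding
#' most of their mass.
#'
#' @param group_matrix non-negative bins x columns matrix.
#' @param freqs frequency grid (Hz) matching the rows.
#' @param n_modes number of modes (default 4).
#' @param restarts seeded restarts (default 10).
#' @param seed integer seed.
#' @param consensus_r correlation threshold used in the stability
#'   diagnostic (`n_stable`: how many restarts agree with the
#'   consensus at this level).
#' @param sparsity strength of the L1 penalty on the mode shapes,
#'   relative to the mean column mass of the input (see Details in the
#'   source); 0 disables it.
#' @param bands named list of band edges used only for labelling.
#' @return object of class `frequency_modes`: `modes`
#'   (n_modes x bins, unit 1-norm rows), `labels`, `freqs`,
#'   `reconstruction_error`, `stability` (pairwise mode correlations
#'   across restarts), `band_mass`.
#' @export
nnmf_frequency_modes <- function(group_matrix, freqs, n_modes = 4,
                                 restarts = 10, seed = 1L,
                                 consensus_r = 0.9, sparsity = 0.1,
                                 bands = list(`delta/theta` = c(1, 8),
                                              alpha = c(8, 12),
                                              beta = c(13, 30))) {
  V <- as.matrix(group_matrix)
  if (any(V < 0)) stopf("group coherence matrix has negative entries")
  if (nrow(V) != length(freqs)) stopf("frequency grid mismatch")
  set.seed(as.integer(seed))
  ## first restart from the deterministic NNDSVD decomposition, the
  ## rest from random non-negative starts
  runs <- lapply(seq_len(restarts), function(r)
    nnmf_once(V, n_modes, sparsity = sparsity,
              init = if (r == 1 && min(dim(V)) >= n_modes)
                nndsvd_init(V, n_modes)))
  errs <- vapply(runs, `[[`, 0, "error")
  ## normalise each run's modes to unit 1-norm columns of W
  norm_modes <- lapply(runs, function(rn) {
    W <- rn$W
    sweep(W, 2, pmax(colSums(W), 1e-300), "/")
  })
  ## consensus diagnostics: align every run's modes to the best run's
  ref <- norm_modes[[which.min(errs)]]
  aligned <- lapply(norm_modes, function(W) {
    cost <- -abs(stats::cor(ref, W))
    perm <- solve_assignment(cost)$pairing
    W[, perm, drop = FALSE]
  })
  consensus <- Reduce(`+`, aligned) / length(aligned)
  min_cor <- vapply(aligned, function(W)
    min(diag(stats::cor(W, consensus))), 0)
  ## selection: mixed and parts-based factorisations fit almost equally
  ## well, so among runs within 2% of the best error take the most
  ## frequency-specific one (largest mean Hoyer sparsity of the modes)
  hoyer <- function(w) {
    n <- length(w)
    (sqrt(n) - sum(w) / sqrt(sum(w^2))) / (sqrt(n) - 1)
  }
  sparseness <- vapply(norm_modes, function(W)
    mean(apply(W, 2, hoyer)), 0)
  cand <- which(errs <= 1.02 * min(errs))
  pick <- cand[which.max(sparseness[cand])]
  W <- norm_modes[[pick]]
  stability <- min_cor

  modes <- t(W)                               # n_modes x bins
  bm <- band_mass(modes, freqs, bands)
  lab <- label_modes(bm)
  structure(list(modes = modes, labels = lab, freqs = freqs,
                 reconstruction_error = errs[pick],
                 errors = errs, stability = stability,
                 n_stable = sum(min_cor > consensus_r),
                 band_mass = bm, n_modes = n_modes),
            class = "frequency_modes")
}

## Fraction of each mode's 1-norm inside each canonical band.
band_mass <- function(modes, freqs, bands) {
  out <- matrix(0, nrow(modes), length(bands),
                dimnames = list(NULL, names(bands)))
  for (b in seq_along(bands)) {
    inb <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
    out[, b] <- rowSums(modes[, inb, drop = FALSE]) / rowSums(modes)
  }
  out
}

## Greedy unique band labels by mass; leftover modes become "residual".
label_modes <- function(bm) {
  lab <- rep("residual", nrow(bm))
  taken_mode <- rep(FALSE, nrow(bm))
  for (b in colnames(bm)[order(-apply(bm, 2, max))]) {
    cand <- order(-bm[, b])
    for (m in cand) {
      if (!taken_mode[m]) { lab[m] <- b; taken_mode[m] <- TRUE; break }
    }
  }
  lab
}

#' @export
print.frequency_modes <- function(x, ...) {
  cat(sprintf("<frequency_modes> %d modes on %d bins (%.1f-%.1f Hz)\n",
              x$n_modes, length(x$freqs), min(x$freqs), max(x$freqs)))
  for (m in seq_len(x$n_modes))
    cat(sprintf("  mode %d [%s]: band mass %s\n", m, x$labels[m],
                paste(sprintf("%s=%.2f", colnames(x$band_mass),
                              x$band_mass[m, ]), collapse = " ")))
  invisible(x)
}

#' Project coherence matrices onto frequency modes
#'
#' Inner product along the frequency axis between a `bins x columns`
#' coherence matrix and each mode: the result is one value per column
#' per mode. Linear in the input, so the group projection equals the
#' mean of the subject projections.
#'
#' @param mat bins x columns matrix (subject- or group-level).
#' @param modes a `frequency_modes` object (or n_modes x bins matrix).
#' @param freqs frequency grid of `mat`; checked against the modes'.
#' @return n_modes x columns matrix.
#' @export
project_onto_modes <- function(mat, modes, freqs = NULL) {
  M <- if (inherits(modes, "frequency_modes")) modes$modes else as.matrix(modes)
  if (inherits(modes, "frequency_modes") && !is.null(freqs) &&
      !isTRUE(all.equal(freqs, modes$freqs)))
    stopf("frequency grids differ between data and modes")
  if (ncol(M) != nrow(mat)) stopf("frequency grid mismatch")
  M %*% mat
}
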