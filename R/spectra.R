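.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; the
#' `k` most concentrated tapers are returned with unit energy. Results
#' are memoised per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers (default 7).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  if (n < k + 1) stopf("taper length %d too short for %d tapers", n, k)
  W <- nw / n
  t_ <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * W)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  H <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h <- H[, j]
    h <- h / sqrt(sum(h^2))
    if (sum(h) < 0) h <- -h            # even tapers: positive mean
    if (abs(sum(h)) < 1e-8 && h[2] < h[1]) h <- -h
    H[, j] <- h
  }
  .taper_cache[[key]] <- H
  H
}

#' Extract single-state data segments
#'
#' Returns the maximal contiguous runs of columns during which `path`
#' equals `state`. `offset` shifts the path onto the data's time axis
#' (e.g. the embedding's centre shift).
#'
#' @param data channels x samples matrix (or `region_ts`).
#' @param path integer state path; `path[i]` labels data column
#'   `i + offset`.
#' @param state state whose visits to extract.
#' @param min_len drop runs shorter than this many samples.
#' @param offset alignment shift (default 0).
#' @return list of channels x run-length matrices (possibly empty).
#' @export
extract_state_segments <- function(data, path, state, min_len = 2,
                                   offset = 0) {
  X <- if (inherits(data, "region_ts")) data$data else as.matrix(data)
  runs <- rle(as.integer(path))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values == state & runs$lengths >= min_len
  out <- list()
  for (r in which(keep)) {
    cols <- (starts[r] + offset):(ends[r] + offset)
    cols <- cols[cols >= 1 & cols <= ncol(X)]
    if (length(cols) >= min_len)
      out[[length(out) + 1L]] <- X[, cols, drop = FALSE]
  }
  out
}

#' Multitaper power and coherence from state segments
#'
#' The state's visits are concatenated and windows of
#' `fs / resolution_hz` samples (2 s at the default 0.5 Hz grid) are
#' tiled across the concatenation, so the spectral bandwidth stays at
#' `time_bandwidth / window` even when individual visits are short;
#' windows spanning a visit boundary are accepted, as is standard for
#' state-wise spectra of brief visits. A remainder (or a total shorter
#' than one window) forms a final zero-padded window. Cross-spectra are
#' averaged over Slepian tapers and windows with duration weighting.
#' Coherence is `|S_ij| / sqrt(S_ii S_jj)`.
#'
#' @param segments list of channels x samples matrices (one state's
#'   visits).
#' @param fs sampling rate, Hz.
#' @param n_tapers,time_bandwidth Slepian taper count and time-bandwidth
#'   product.
#' @param resolution_hz frequency bin width.
#' @param fmin,fmax analysed band edges, Hz.
#' @param state label used in error messages.
#' @return list with `freqs`, `psd` (bins x N), `coherence`
#'   (bins x N x N), `n_avg` (taper-window count), `config`.
#' @export
multitaper_spectra <- function(segments, fs, n_tapers = 7,
                               time_bandwidth = 4, resolution_hz = 0.5,
                               fmin = 1, fmax = 45, state = NA) {
  nfft <- round(fs / resolution_hz)
  min_win <- max(16L, n_tapers + 1L)
  segments <- Filter(function(s) ncol(s) >= min_win, segments)
  if (!length(segments))
    stopf("state %s: no segment of at least %d samples", state, min_win)
  N <- nrow(segments[[1]])
  freqs_all <- (0:(nfft %/% 2)) * fs / nfft
  sel <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9)
  nf <- length(sel)
  S <- array(0 + 0i, c(nf, N, N))
  wtot <- 0
  n_avg <- 0L
  ## concatenate the visits, then tile full windows across the result
  X <- do.call(cbind, segments)
  len <- ncol(X)
  nw_full <- len %/% nfft
  wins <- lapply(seq_len(nw_full), function(w)
    X[, ((w - 1) * nfft + 1):(w * nfft), drop = FALSE])
  rem <- len - nw_full * nfft
  if (rem >= min_win)
    wins <- c(wins, list(X[, (nw_full * nfft + 1):len, drop = FALSE]))
  for (Xw in wins) {
    lw <- ncol(Xw)
    H <- dpss_tapers(lw, time_bandwidth, n_tapers)
    Z <- matrix(0 + 0i, nf, 0)
    pad <- matrix(0, nfft - lw, N)
    for (tp in seq_len(n_tapers)) {
      tap <- t(Xw) * H[, tp]
      Z <- cbind(Z, stats::mvfft(rbind(tap, pad))[sel, , drop = FALSE])
    }
    ## Z is nf x (N * n_tapers); accumulate per-bin outer products
    w <- lw
    for (f in seq_len(nf)) {
      M <- matrix(Z[f, ], N, n_tapers)
      S[f, , ] <- S[f, , ] + w * tcrossprod(M, Conj(M)) / n_tapers
    }
    wtot <- wtot + w
    n_avg <- n_avg + n_tapers
  }
  S <- S / wtot
  psd <- matrix(0, nf, N)
  for (f in seq_len(nf)) psd[f, ] <- Re(diag(S[f, , ])) * 2 / fs
  coh <- array(0, c(nf, N, N))
  for (f in seq_len(nf)) {
    d <- sqrt(pmax(Re(diag(S[f, , ])), 1e-300))
    coh[f, , ] <- abs(S[f, , ]) / outer(d, d)
    diag(coh[f, , ]) <- 1
  }
  list(freqs = freqs_all[sel], psd = psd, coherence = pmin(coh, 1),
       n_avg = n_avg,
       config = list(n_tapers = n_tapers, time_bandwidth = time_bandwidth,
                     resolution_hz = resolution_hz, fs = fs))
}

#' Band-pass a multichannel matrix
#'
#' Zero-phase Butterworth (order 4, applied forwards and backwards) with
#' the pipeline's default 1-45 Hz pass band.
#' @param data channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param band length-2 pass band in Hz.
#' @export
bandpass_filter <- function(data, fs, band = c(1, 45)) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  t(apply(data, 1, function(x) signal::filtfilt(bf, x)))
}

#' State- and subject-resolved multitaper spectra
#'
#' For every subject and state: band-pass the subject's continuous data,
#' cut out that state's visits (maximal runs of highest posterior
#' probability), and estimate multitaper PSD and coherence. States a
#' subject never visits yield `NULL` entries.
#'
#' @param concat the preprocessed `concat_ts` the model was fitted on.
#' @param posterior a `state_posterior` from [hmm_fit()].
#' @param K number of states.
#' @param band band-pass applied before estimation (Hz).
#' @param min_len minimum segment length in samples.
#' @param ... passed to [multitaper_spectra()].
#' @return object of class `state_spectra`: `spectra[[subject]][[state]]`,
#'   plus `freqs`, `labels`, `groups`, `subject_ids`.
#' @export
compute_state_spectra <- function(concat, posterior, K,
                                  band = c(1, 45), min_len = 16, ...) {
  nsub <- length(concat$boundaries)
  out <- vector("list", nsub)
  freqs <- NULL
  for (s in seq_len(nsub)) {
    ob <- concat$boundaries[[s]]
    eb <- posterior$boundaries[[s]]
    gam <- posterior$gamma[eb[1]:eb[2], , drop = FALSE]
    path <- max.col(gam, ties.method = "first")
    Xs <- bandpass_filter(concat$data[, ob[1]:ob[2], drop = FALSE],
                          concat$fs, band)
    out[[s]] <- vector("list", K)
    for (k in seq_len(K)) {
      segs <- extract_state_segments(Xs, path, k, min_len = min_len,
                                     offset = posterior$centre_shift)
      if (!length(segs)) next
      sp <- tryCatch(
        multitaper_spectra(segs, concat$fs, fmin = band[1], fmax = band[2],
                           state = k, ...),
        error = function(e) NULL)
      out[[s]][[k]] <- sp
      if (is.null(freqs) && !is.null(sp)) freqs <- sp$freqs
    }
  }
  structure(list(spectra = out, freqs = freqs, labels = concat$labels,
                 groups = concat$groups, subject_ids = concat$subject_ids,
                 K = K, fs = concat$fs), class = "state_spectra")
}
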