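#' Region-level multichannel time series
#'
#' The basic data container: a channels x samples matrix with sampling
#' rate, channel labels, channel group tags (e.g. `"cortical"` vs `"STN"`),
#' and subject/condition identifiers.
#'
#' @param data numeric matrix, channels in rows.
#' @param fs sampling rate, Hz.
#' @param labels character vector of channel names.
#' @param groups character vector of channel group tags.
#' @param subject_id,condition identifiers.
#' @return Object of class `region_ts`.
#' @export
region_timeseries <- function(data, fs, labels = NULL, groups = NULL,
                              subject_id = "S01", condition = "A") {
  data <- as.matrix(data)
  if (fs <= 0) stopf("fs must be positive")
  if (any(!is.finite(data))) stopf("data contains non-finite values")
  n <- nrow(data)
  labels <- labels %||% sprintf("ch%02d", seq_len(n))
  groups <- groups %||% rep("cortical", n)
  if (length(labels) != n || length(groups) != n)
    stopf("labels/groups must have one entry per channel")
  structure(list(data = data, fs = fs, labels = labels, groups = groups,
                 subject_id = subject_id, condition = condition),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %s/%s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Collapse a region's vertex series to its first principal component
#'
#' Reduces a vertices x samples matrix to the single series explaining the
#' largest variance share. The sign is fixed so the component correlates
#' positively with the mean vertex series.
#'
#' @param vertex_series numeric matrix, vertices in rows.
#' @return numeric vector of length `ncol(vertex_series)`.
#' @export
reduce_region_to_first_pc <- function(vertex_series) {
  X <- as.matrix(vertex_series)
  if (ncol(X) < 2) stopf("need at least 2 samples")
  if (all(apply(X, 1, stats::sd) < 1e-14))
    stopf("degenerate (constant) vertex input: zero variance")
  Xc <- X - rowMeans(X)
  if (nrow(X) == 1) {
    pc <- drop(Xc)
  } else {
    sv <- svd(Xc, nu = 1, nv = 1)
    pc <- drop(sv$d[1] * sv$v[, 1])
  }
  m <- colMeans(Xc)
  if (sum(pc * m) < 0) pc <- -pc
  pc
}

#' Symmetric (least-squares) orthogonalisation of channel rows
#'
#' Returns the matrix closest in Frobenius norm to the input whose rows
#' are mutually orthogonal (zero pairwise zero-lag correlation), via the
#' alternating polar-decomposition scheme: rows are written as
#' `d_i * o_i` with orthonormal `o_i`, solving for the orthonormal frame
#' by SVD and the magnitudes by projection until convergence. Unlike
#' sequential Gram-Schmidt this treats all channels symmetrically.
#'
#' @param data channels x samples matrix (samples >= channels, full row
#'   rank).
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @return matrix of the same shape with exactly orthogonal rows.
#' @export
symmetric_orthogonalise <- function(data, tol = 1e-12, max_iter = 200) {
  X <- as.matrix(data)
  N <- nrow(X); T_ <- ncol(X)
  if (T_ < N) stopf("need at least as many samples as channels")
  sv0 <- svd(X, nu = 0, nv = 0)
  if (sv0$d[N] < 1e-10 * sv0$d[1]) {
    g <- X %*% t(X)
    cc <- abs(stats::cov2cor(g)); diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stopf("rank-deficient input; channels %d and %d are (near-)collinear",
          worst[1], worst[2])
  }
  d <- sqrt(rowSums(X^2))
  obj_old <- Inf
  O <- X / d
  for (it in seq_len(max_iter)) {
    ## orthonormal frame closest to the magnitude-weighted target
    sv <- svd(t(X) * rep(d, each = T_), nu = N, nv = N)
    O <- tcrossprod(sv$v, sv$u)       # N x T, orthonormal rows
    d <- rowSums(X * O)               # optimal magnitudes
    obj <- sum((X - d * O)^2)
    if (abs(obj_old - obj) < tol * (1 + obj)) break
    obj_old <- obj
  }
  d * O
}

## Lagged autocovariance stack used by the sign-flip objective.
lagged_autocov <- function(X, n_lags) {
  T_ <- ncol(X)
  Xc <- X - rowMeans(X)
  out <- array(0, c(nrow(X), nrow(X), n_lags + 1L))
  for (l in 0:n_lags) {
    out[, , l + 1L] <- tcrossprod(Xc[, 1:(T_ - l), drop = FALSE],
                                  Xc[, (1 + l):T_, drop = FALSE]) / (T_ - l)
  }
  out
}

#' Sign-flip correction across subjects
#'
#' Source-reconstructed channels carry an arbitrary sign per subject.
#' This greedy search flips individual channel signs per subject to
#' maximise the cross-subject agreement (inner product) of lagged
#' autocovariance structures; the objective is non-decreasing across
#' sweeps and the first subject is held as reference so the global sign
#' is anchored.
#'
#' @param subjects list of `region_ts` (or plain matrices) with equal
#'   channel counts.
#' @param n_lags number of autocovariance lags in the objective; defaults
#'   to 14 so the window matches a 15-sample embedding.
#' @param max_sweeps sweep cap.
#' @return list with `signs` (subjects x channels matrix of +-1),
#'   `subjects` (flipped inputs), and `objective` trace.
#' @export
sign_flip_correct <- function(subjects, n_lags = 14, max_sweeps = 20) {
  mats <- lapply(subjects, function(s) if (inherits(s, "region_ts")) s$data else as.matrix(s))
  S <- length(mats)
  N <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != N)) stopf("unequal channel counts")
  signs <- matrix(1, S, N)
  if (S == 1) {
    return(list(signs = signs, subjects = subjects, objective = numeric(0)))
  }
  covs <- lapply(mats, lagged_autocov, n_lags = n_lags)
  adj <- function(C, s) {
    for (l in seq_len(dim(C)[3])) C[, , l] <- (s %o% s) * C[, , l]
    C
  }
  total_obj <- function(acovs) {
    tot <- 0
    for (a in 1:(S - 1)) for (b in (a + 1):S)
      tot <- tot + sum(acovs[[a]] * acovs[[b]])
    tot
  }
  acovs <- covs
  trace <- total_obj(acovs)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (s in 2:S) for (ch in seq_len(N)) {
      cand <- signs[s, ]
      cand[ch] <- -cand[ch]
      old_c <- acovs[[s]]
      new_c <- adj(covs[[s]], cand)
      others <- Reduce(`+`, acovs[-s])
      if (sum(new_c * others) > sum(old_c * others) + 1e-12) {
        signs[s, ] <- cand
        acovs[[s]] <- new_c
        changed <- TRUE
      }
    }
    trace <- c(trace, total_obj(acovs))
    if (!changed) break
  }
  flipped <- Map(function(s, i) {
    if (inherits(s, "region_ts")) { s$data <- signs[i, ] * s$data; s }
    else signs[i, ] * s
  }, subjects, seq_len(S))
  list(signs = signs, subjects = flipped, objective = trace)
}

#' Z-score per subject and concatenate along time
#'
#' Each subject's channels are standardised to mean 0, sd 1 before the
#' subject blocks are joined along the temporal dimension. Boundaries of
#' the blocks are recorded so posteriors can be sliced back per subject.
#'
#' @param subjects list of `region_ts` with identical labels/groups.
#' @return Object of class `concat_ts`: `data` (N x total samples),
#'   `boundaries` (per subject `c(start, end)`, 1-based inclusive),
#'   `labels`, `groups`, `fs`, `subject_ids`, `condition`.
#' @export
standardise_and_concatenate <- function(subjects) {
  stopifnot(length(subjects) >= 1)
  ref <- subjects[[1]]
  for (s in subjects) {
    if (!identical(s$labels, ref$labels))
      stopf("subject %s: channel labels differ from first subject",
            s$subject_id)
  }
  zs <- lapply(subjects, function(s) {
    m <- rowMeans(s$data)
    sdv <- apply(s$data, 1, stats::sd)
    if (any(sdv < 1e-14))
      stopf("subject %s: constant channel(s): %s", s$subject_id,
            paste(s$labels[sdv < 1e-14], collapse = ", "))
    (s$data - m) / sdv
  })
  lens <- vapply(zs, ncol, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  structure(list(
    data = do.call(cbind, zs),
    boundaries = Map(c, starts, ends),
    labels = ref$labels, groups = ref$groups, fs = ref$fs,
    subject_ids = vapply(subjects, function(s) s$subject_id, ""),
    condition = ref$condition), class = "concat_ts")
}

#' @export
print.concat_ts <- function(x, ...) {
  cat(sprintf("<concat_ts> %d channels x %d samples, %d subjects @ %g Hz\n",
              nrow(x$data), ncol(x$data), length(x$boundaries), x$fs))
  invisible(x)
}

#' Full preprocessing chain for one condition
#'
#' Fixed order: (optional) leakage correction by symmetric
#' orthogonalisation of the cortical channels only (STN contacts bypass
#' the step), per-subject z-scoring and concatenation, then sign-flip
#' correction across subjects. Inputs are region-level series, i.e. any
#' vertex-to-region reduction has already happened.
#'
#' @param subjects list of `region_ts` for one condition.
#' @param orthogonalise apply symmetric orthogonalisation to channels
#'   tagged `"cortical"`. Set `FALSE` for data known to be leakage-free
#'   (e.g. simulations).
#' @param sign_flip apply the cross-subject sign-flip correction.
#' @return A `concat_ts`.
#' @export
preprocess_cohort <- function(subjects, orthogonalise = TRUE,
                              sign_flip = TRUE) {
  out <- lapply(subjects, function(s) {
    if (orthogonalise) {
      ctx <- which(s$groups == "cortical")
      if (length(ctx) > 1) {
        ## centre rows first: the orthogonal frame lives in the row space,
        ## so it stays zero-mean and the later z-scoring preserves the
        ## exact zero correlation between cortical channels
        blk <- s$data[ctx, , drop = FALSE]
        s$data[ctx, ] <- symmetric_orthogonalise(blk - rowMeans(blk))
      }
    }
    ## z-score here so the sign-flip sees the standardised cohort; the
    ## final standardisation inside the concatenation is then a no-op
    ## (flipping a zero-mean unit-sd row preserves both moments).
    s$data <- (s$data - rowMeans(s$data)) /
      apply(s$data, 1, stats::sd)
    if (any(!is.finite(s$data)))
      stopf("subject %s: constant channel after preprocessing", s$subject_id)
    s
  })
  if (sign_flip && length(out) > 1) out <- sign_flip_correct(out)$subjects
  standardise_and_concatenate(out)
}
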