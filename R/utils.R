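#' @useDynLib tdehmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft prcomp kmeans sd var aov t.test
#'   p.adjust pnorm qnorm TukeyHSD pairwise.t.test complete.cases
#' @importFrom utils head tail modifyList read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_row_stochastic <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stopf("transition matrix must be square, got %d x %d", nrow(P), ncol(P))
  if (any(P < -tol))
    stopf("transition matrix has negative entries")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8))
    stopf("transition matrix rows must sum to 1 (max deviation %.3g)",
          max(abs(rs - 1)))
  invisible(P)
}

## Per-stream seeds derived from a master seed; kept well below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

is_spd <- function(A, tol = 1e-10) {
  if (!isSymmetric(A, tol = 1e-8)) return(FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

## Symmetrise and floor eigenvalues so downstream log-dets stay finite.
spd_floor <- function(A, rel = 1e-8) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  floor_val <- rel * sum(abs(e$values)) / nrow(A)
  lam <- pmax(e$values, floor_val)
  e$vectors %*% (lam * t(e$vectors))
}

logdet_chol <- function(A) 2 * sum(log(diag(chol(A))))

## Multivariate log-gamma and digamma (sums over p dimensions).
lmvgamma <- function(a, p) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}
mvdigamma <- function(a, p) sum(digamma(a + (1 - seq_len(p)) / 2))
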