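#' Default priors for the embedded-space Gaussian HMM
#'
#' States are zero-mean Gaussians with full covariance under an
#' inverse-Wishart prior; the prior scale is the empirical covariance of
#' the embedded data and the degrees of freedom `P + 2`, so the prior
#' mean equals the empirical covariance. Transition rows carry a
#' Dirichlet prior with diagonal concentration `transition_diag` (10 by
#' default) and 1 off the diagonal, favouring temporally persistent
#' states.
#'
#' @param X P x T matrix of embedded observations.
#' @param K number of states.
#' @param transition_diag diagonal of the transition Dirichlet prior.
#' @return list with `Psi0`, `nu0`, `alpha0`, `pi0`.
#' @export
hmm_priors <- function(X, K, transition_diag = 10) {
  P <- nrow(X)
  Psi0 <- spd_floor(tcrossprod(X) / ncol(X))
  alpha0 <- matrix(1, K, K)
  diag(alpha0) <- transition_diag
  list(Psi0 = Psi0, nu0 = P + 2, alpha0 = alpha0, pi0 = rep(1, K))
}

## Expected log-likelihood matrix T x K under the Wishart posteriors.
## st: list per state with chol_Psi (upper), nu, Eldet.
expected_loglik <- function(X, st) {
  P <- nrow(X); T_ <- ncol(X); K <- length(st)
  llk <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    Y <- backsolve(st[[k]]$chol_Psi, X, transpose = TRUE)
    qf <- st[[k]]$nu * colSums(Y^2)
    llk[, k] <- -0.5 * P * log(2 * pi) + 0.5 * st[[k]]$Eldet - 0.5 * qf
  }
  llk
}

state_from_Psi <- function(Psi, nu, P) {
  Psi <- spd_floor(Psi)
  R <- chol(Psi)
  Eldet <- mvdigamma(nu / 2, P) + P * log(2) - 2 * sum(log(diag(R)))
  list(Psi = Psi, nu = nu, chol_Psi = R, Eldet = Eldet)
}

kl_wishart <- function(Psi, nu, Psi0, nu0, P) {
  Eldet <- mvdigamma(nu / 2, P) + P * log(2) - logdet_chol(Psi)
  tr <- sum(diag(solve(Psi, Psi0)))
  (nu - nu0) / 2 * Eldet + nu / 2 * (tr - P) +
    (nu0 * P / 2) * log(2) - (nu0 / 2) * logdet_chol(Psi0) +
    lmvgamma(nu0 / 2, P) -
    ((nu * P / 2) * log(2) - (nu / 2) * logdet_chol(Psi) +
       lmvgamma(nu / 2, P))
}

kl_dirichlet <- function(a, b) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

## E-step over all subject blocks: returns gamma, xi, logZ, first-sample
## responsibilities, negative ELBO for the parameters used.
estep <- function(X, boundaries, st, alpha, pi_a, priors) {
  K <- length(st)
  ElogA <- digamma(alpha) - digamma(rowSums(alpha))
  Elogpi <- digamma(pi_a) - digamma(sum(pi_a))
  llk <- expected_loglik(X, st)
  T_ <- ncol(X)
  gamma <- matrix(0, T_, K)
  xi <- matrix(0, K, K)
  logZ <- 0
  g1 <- rep(0, K)
  for (b in boundaries) {
    idx <- b[1]:b[2]
    fb <- fb_cpp(llk[idx, , drop = FALSE], ElogA, Elogpi)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    logZ <- logZ + fb$log_evidence
    g1 <- g1 + fb$gamma[1, ]
  }
  P <- nrow(X)
  kl <- sum(vapply(st, function(s)
    kl_wishart(s$Psi, s$nu, priors$Psi0, priors$nu0, P), 0)) +
    sum(vapply(seq_len(K), function(k)
      kl_dirichlet(alpha[k, ], priors$alpha0[k, ]), 0)) +
    kl_dirichlet(pi_a, priors$pi0)
  list(gamma = gamma, xi = xi, logZ = logZ, g1 = g1,
       free_energy = -(logZ - kl))
}

## M-step sufficient statistics -> posterior parameters.
mstep <- function(X, gamma, xi, g1, priors) {
  K <- ncol(gamma)
  P <- nrow(X)
  tX <- t(X)
  st <- vector("list", K)
  for (k in seq_len(K)) {
    g <- gamma[, k]
    S <- X %*% (tX * g)
    st[[k]] <- state_from_Psi(priors$Psi0 + S, priors$nu0 + sum(g), P)
  }
  list(st = st, alpha = priors$alpha0 + xi, pi_a = priors$pi0 + g1)
}

## k-means initial responsibilities from short-window power features.
init_gamma_kmeans <- function(X, boundaries, K, seed, win = 16) {
  set.seed(seed)
  P <- nrow(X)
  nf <- min(P, 24)
  gam <- matrix(0, ncol(X), K)
  feats <- list(); wins <- list()
  for (bi in seq_along(boundaries)) {
    b <- boundaries[[bi]]
    idx <- b[1]:b[2]
    nw <- length(idx) %/% win
    if (nw < 1) next
    F_ <- matrix(0, nw, nf)
    for (w in seq_len(nw)) {
      cols <- idx[((w - 1) * win + 1):(w * win)]
      F_[w, ] <- log(rowMeans(X[seq_len(nf), cols, drop = FALSE]^2) + 1e-12)
    }
    feats[[bi]] <- F_
    wins[[bi]] <- b
  }
  Fall <- do.call(rbind, feats)
  km <- suppressWarnings(kmeans(Fall, centers = min(K, nrow(Fall)),
                                nstart = 1, iter.max = 20))
  cl <- km$cluster
  if (max(cl) < K) cl <- ((cl - 1) %% K) + 1
  pos <- 0
  for (bi in seq_along(feats)) {
    b <- wins[[bi]]
    idx <- b[1]:b[2]
    nw <- nrow(feats[[bi]])
    soft <- matrix(if (K > 1) 0.1 / (K - 1) else 1, length(idx), K)
    for (w in seq_len(nw)) {
      rows <- ((w - 1) * win + 1):(w * win)
      soft[rows, cl[pos + w]] <- 0.9
    }
    extra <- length(idx) - nw * win
    if (extra > 0)
      soft[(nw * win + 1):length(idx), cl[pos + nw]] <- 0.9
    if (K == 1) soft[] <- 1
    gam[idx, ] <- soft / rowSums(soft)
    pos <- pos + nw
  }
  gam
}

## Evenly subsample subject blocks down to ~cap columns for cheap restarts.
subsample_blocks <- function(X, boundaries, cap) {
  Ttot <- ncol(X)
  if (Ttot <= cap) return(list(X = X, boundaries = boundaries))
  frac <- cap / Ttot
  Xs <- list(); bnd <- list(); pos <- 0L
  for (b in boundaries) {
    len <- b[2] - b[1] + 1L
    keep <- max(32L, floor(len * frac))
    cols <- b[1]:(b[1] + keep - 1L)
    Xs[[length(Xs) + 1L]] <- X[, cols, drop = FALSE]
    bnd[[length(bnd) + 1L]] <- c(pos + 1L, pos + keep)
    pos <- pos + keep
  }
  list(X = do.call(cbind, Xs), boundaries = bnd)
}

#' Fit a variational-Bayes Gaussian HMM on embedded data
#'
#' Observation model: zero-mean Gaussian with full state covariance under
#' an inverse-Wishart prior; transitions under a Dirichlet prior with a
#' heavy diagonal. Inference is batch variational Bayes (coordinate
#' ascent, free energy non-increasing); an optional stochastic
#' variational mode processes subject-level minibatches with a decaying
#' step size. Initialisation is k-means on short-window power features
#' followed by a few VB iterations on a temporal subsample, best of
#' `restarts` seeded restarts by free energy.
#'
#' @param embedded an `embedded_ts` from [tde_embed_pca()] (or
#'   [pca_reduce()]).
#' @param K number of states (default 6).
#' @param priors from [hmm_priors()]; computed from the data when `NULL`.
#' @param stochastic `NULL` for batch VB, or a list with any of
#'   `minibatch` (subjects per update), `kappa` (forgetting exponent,
#'   default 0.6), `delay` (default 5), `epochs`.
#' @param seed integer seed controlling initialisation.
#' @param max_iter,tol batch iteration cap and relative free-energy
#'   convergence tolerance.
#' @param restarts,restart_iter,restart_cap number of seeded restarts,
#'   VB iterations per restart, and column cap of the restart subsample.
#' @param init_gamma optional T' x K matrix of initial responsibilities,
#'   bypassing the k-means restarts (used e.g. to test label-permutation
#'   equivariance).
#' @param verbose print free energy per iteration.
#' @return list with `model` (class `hmm_model`) and `posterior` (class
#'   `state_posterior`).
#' @export
hmm_fit <- function(embedded, K = 6, priors = NULL, stochastic = NULL,
                    seed = 1L, max_iter = 30, tol = 1e-6, restarts = 5,
                    restart_iter = 3, restart_cap = 20000,
                    init_gamma = NULL, verbose = FALSE) {
  X <- embedded$data
  boundaries <- embedded$boundaries
  P <- nrow(X)
  if (K < 1) stopf("K must be >= 1")
  if (P >= ncol(X)) stopf("need more samples than dimensions")
  if (is.null(priors)) priors <- hmm_priors(X, K)
  if (!is_spd(priors$Psi0)) stopf("prior scale matrix is not positive definite")
  if (nrow(priors$alpha0) != K) {
    alpha0 <- matrix(1, K, K); diag(alpha0) <- diag(priors$alpha0)[1]
    priors$alpha0 <- alpha0; priors$pi0 <- rep(1, K)
  }

  ## --- initialisation ---
  if (!is.null(init_gamma)) {
    stopifnot(nrow(init_gamma) == ncol(X), ncol(init_gamma) == K)
    gam <- init_gamma / rowSums(init_gamma)
    par <- mstep(X, gam, crossprod(gam[-nrow(gam), ], gam[-1, ]),
                 colSums(gam[vapply(boundaries, function(b) b[1], 0), , drop = FALSE]),
                 priors)
  } else if (K == 1) {
    gam <- matrix(1, ncol(X), 1)
    par <- mstep(X, gam, matrix(0, 1, 1), length(boundaries), priors)
  } else {
    sub <- subsample_blocks(X, boundaries, restart_cap)
    sub_priors <- hmm_priors(sub$X, K,
                             transition_diag = diag(priors$alpha0)[1])
    best <- NULL
    for (r in seq_len(restarts)) {
      gam <- init_gamma_kmeans(sub$X, sub$boundaries, K,
                               seed = derive_seed(seed, r))
      pr <- mstep(sub$X, gam,
                  crossprod(gam[-nrow(gam), ], gam[-1, ]),
                  colSums(gam[vapply(sub$boundaries, function(b) b[1], 0), ,
                              drop = FALSE]),
                  sub_priors)
      fe <- NA
      for (it in seq_len(restart_iter)) {
        es <- estep(sub$X, sub$boundaries, pr$st, pr$alpha, pr$pi_a,
                    sub_priors)
        fe <- es$free_energy
        pr <- mstep(sub$X, es$gamma, es$xi, es$g1, sub_priors)
      }
      if (is.null(best) || fe < best$fe) best <- list(fe = fe, pr = pr)
      if (verbose) message(sprintf("restart %d: F = %.4f", r, fe))
    }
    ## carry restart posteriors to the full data via one E/M pass
    es <- estep(X, boundaries, best$pr$st, best$pr$alpha, best$pr$pi_a,
                priors)
    par <- mstep(X, es$gamma, es$xi, es$g1, priors)
  }

  ## --- main VB loop ---
  fe_trace <- numeric(0)
  es <- NULL
  if (is.null(stochastic)) {
    for (it in seq_len(max_iter)) {
      es <- estep(X, boundaries, par$st, par$alpha, par$pi_a, priors)
      fe_trace <- c(fe_trace, es$free_energy)
      if (verbose) message(sprintf("iter %d: F = %.4f", it, es$free_energy))
      if (it > 1 && abs(fe_trace[it - 1] - fe_trace[it]) <
            tol * abs(fe_trace[it]))
        break
      par <- mstep(X, es$gamma, es$xi, es$g1, priors)
    }
  } else {
    kappa <- stochastic$kappa %||% 0.6
    delay <- stochastic$delay %||% 5
    mb <- stochastic$minibatch %||% 1
    epochs <- stochastic$epochs %||% max_iter
    S <- length(boundaries)
    Ttot <- ncol(X)
    tstep <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(S)
      for (start in seq(1, S, by = mb)) {
        sel <- ord[start:min(start + mb - 1, S)]
        bnd <- boundaries[sel]
        Tb <- sum(vapply(bnd, function(b) b[2] - b[1] + 1L, 0L))
        w <- Ttot / Tb
        gam_b <- list(); xi_b <- matrix(0, K, K); g1_b <- rep(0, K)
        ElogA <- digamma(par$alpha) - digamma(rowSums(par$alpha))
        Elogpi <- digamma(par$pi_a) - digamma(sum(par$pi_a))
        Psis <- vector("list", K); nus <- numeric(K)
        Shat <- lapply(seq_len(K), function(k) matrix(0, P, P))
        Nhat <- rep(0, K)
        for (b in bnd) {
          idx <- b[1]:b[2]
          llk <- expected_loglik(X[, idx, drop = FALSE], par$st)
          fb <- fb_cpp(llk, ElogA, Elogpi)
          xi_b <- xi_b + fb$xi
          g1_b <- g1_b + fb$gamma[1, ]
          Xb <- X[, idx, drop = FALSE]
          tXb <- t(Xb)
          for (k in seq_len(K)) {
            Shat[[k]] <- Shat[[k]] + Xb %*% (tXb * fb$gamma[, k])
            Nhat[k] <- Nhat[k] + sum(fb$gamma[, k])
          }
        }
        rho <- (tstep + delay)^(-kappa)
        tstep <- tstep + 1
        for (k in seq_len(K)) {
          Psi_new <- (1 - rho) * par$st[[k]]$Psi +
            rho * (priors$Psi0 + w * Shat[[k]])
          nu_new <- (1 - rho) * par$st[[k]]$nu +
            rho * (priors$nu0 + w * Nhat[k])
          par$st[[k]] <- state_from_Psi(Psi_new, nu_new, P)
        }
        par$alpha <- (1 - rho) * par$alpha +
          rho * (priors$alpha0 + w * xi_b)
        par$pi_a <- (1 - rho) * par$pi_a +
          rho * (priors$pi0 + length(boundaries) / length(bnd) * g1_b)
      }
      es <- estep(X, boundaries, par$st, par$alpha, par$pi_a, priors)
      fe_trace <- c(fe_trace, es$free_energy)
      if (verbose) message(sprintf("epoch %d: F = %.4f", ep, es$free_energy))
    }
    par <- mstep(X, es$gamma, es$xi, es$g1, priors)
    es <- estep(X, boundaries, par$st, par$alpha, par$pi_a, priors)
    fe_trace <- c(fe_trace, es$free_energy)
  }
  if (is.null(es))
    es <- estep(X, boundaries, par$st, par$alpha, par$pi_a, priors)

  ## hard path with the final expected parameters
  ElogA <- digamma(par$alpha) - digamma(rowSums(par$alpha))
  Elogpi <- digamma(par$pi_a) - digamma(sum(par$pi_a))
  llk <- expected_loglik(X, par$st)
  path <- integer(ncol(X))
  for (b in boundaries) {
    idx <- b[1]:b[2]
    path[idx] <- viterbi_cpp(llk[idx, , drop = FALSE], ElogA, Elogpi)
  }

  covs <- lapply(par$st, function(s) s$Psi / (s$nu - P - 1))
  model <- structure(list(
    K = K,
    state_covariances = covs,
    Psi = lapply(par$st, `[[`, "Psi"),
    nu = vapply(par$st, `[[`, 0, "nu"),
    transition = par$alpha / rowSums(par$alpha),
    trans_alpha = par$alpha,
    initial = par$pi_a / sum(par$pi_a),
    pi_alpha = par$pi_a,
    free_energy_trace = fe_trace,
    priors = priors,
    embedding = embedded[c("projection", "mean", "offsets", "centre_shift",
                           "n_channels", "fs", "labels", "groups")],
    config = list(seed = seed, stochastic = !is.null(stochastic))),
    class = "hmm_model")
  posterior <- structure(list(
    gamma = es$gamma, xi = es$xi, viterbi_path = path,
    boundaries = boundaries,
    centre_shift = embedded$centre_shift,
    free_energy = tail(fe_trace, 1)), class = "state_posterior")
  list(model = model, posterior = posterior)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K=%d states, P=%d dims, final F=%.2f\n",
              x$K, nrow(x$state_covariances[[1]]),
              tail(x$free_energy_trace, 1)))
  invisible(x)
}

#' Forward-backward smoothing
#'
#' Exact posterior state marginals, summed pairwise transition
#' posteriors, and the log-evidence of one segment under known
#' parameters.
#'
#' @param log_likelihoods T x K matrix of per-sample state
#'   log-likelihoods.
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K initial distribution.
#' @return list with `gamma` (T x K, rows sum to 1), `xi` (K x K summed
#'   pairwise posteriors), `log_evidence`.
#' @export
hmm_forward_backward <- function(log_likelihoods, transition, initial) {
  assert_row_stochastic(transition)
  fb_cpp(as.matrix(log_likelihoods), log(transition), log(initial))
}

#' Viterbi decoding
#'
#' Most probable state path; ties are broken toward the lower state
#' index.
#' @inheritParams hmm_forward_backward
#' @return integer path in `1..K`.
#' @export
hmm_viterbi <- function(log_likelihoods, transition, initial) {
  assert_row_stochastic(transition)
  viterbi_cpp(as.matrix(log_likelihoods), log(transition), log(initial))
}

#' Variational free energy of a fitted model
#'
#' Recomputes the negative evidence lower bound (lower is better) for a
#' model on its embedded data, using the model's own posterior
#' parameters. At convergence this equals the last entry of the model's
#' free-energy trace.
#'
#' @param model an `hmm_model`.
#' @param embedded the `embedded_ts` the model was fitted on.
#' @return scalar free energy.
#' @export
hmm_free_energy <- function(model, embedded) {
  P <- nrow(embedded$data)
  st <- Map(function(Psi, nu) state_from_Psi(Psi, nu, P),
            model$Psi, as.list(model$nu))
  es <- estep(embedded$data, embedded$boundaries, st, model$trans_alpha,
              model$pi_alpha, model$priors)
  es$free_energy
}
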