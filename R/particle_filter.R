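#' Particle ensemble constructor and effective sample size
#'
#' A particle ensemble approximates a PDV by N weighted Boolean states. The
#' effective sample size `ESS = 1 / sum(w_i^2)` of the normalized weights
#' ranges from N (all weights equal) down to 1 (all mass on one particle)
#' and is the standard degeneracy diagnostic: the SIR filter resamples when
#' it drops below `alpha * N`.
#'
#' @param particles N x d Boolean matrix, one particle state per row.
#' @param log_weights Length-N log-weights (unnormalized).
#' @return `particle_ensemble()` an ensemble object; `ess()` a scalar in
#'   \[1, N\].
#' @export
particle_ensemble <- function(particles, log_weights = NULL) {
  particles <- as_state_matrix(particles, ncol(as.matrix(particles)), "particles")
  n <- nrow(particles)
  if (n < 1L) stop("ensemble needs at least one particle")
  if (is.null(log_weights)) log_weights <- rep(-log(n), n)
  if (length(log_weights) != n) stop("'log_weights' must match the particle count")
  structure(list(particles = particles, log_weights = log_weights),
            class = "particle_ensemble")
}

#' @rdname particle_ensemble
#' @param ensemble A `particle_ensemble` (or a numeric vector of weights).
#' @export
ess <- function(ensemble) {
  w <- if (inherits(ensemble, "particle_ensemble"))
    normalized_weights(ensemble$log_weights)
  else {
    if (any(ensemble < 0)) stop("weights must be non-negative")
    ensemble / sum(ensemble)
  }
  1 / sum(w^2)
}

normalized_weights <- function(log_weights) {
  mx <- max(log_weights)
  if (!is.finite(mx)) stop("particle degeneracy: all particle weights are zero")
  w <- exp(log_weights - mx)
  w / sum(w)
}

# systematic resampling: one uniform draw, N stratified positions
systematic_resample <- function(w) {
  n <- length(w)
  pos <- (stats::runif(1) + 0:(n - 1L)) / n
  cw <- cumsum(w)
  cw <- cw / cw[n]  # rescale so the grid is exactly non-decreasing up to 1
  findInterval(pos, cw, left.open = TRUE) + 1L
}

#' One sequential-importance-resampling step
#'
#' Bootstrap-filter update: every particle is propagated through the noisy
#' state transition (the proposal is the transition kernel itself), its
#' log-weight is incremented by the observation log-likelihood, and if the
#' effective sample size of the normalized weights falls below `alpha * N`
#' the ensemble is rebuilt by systematic resampling with all log-weights
#' reset to `-log(N)`. `alpha = 0` never resamples (pure sequential
#' importance sampling); `alpha = 1` resamples at every step.
#'
#' @param ensemble A `particle_ensemble`.
#' @param net A `boolean_network`.
#' @param p Process-noise intensity in \[0, 0.5\].
#' @param spec An `obs_model`.
#' @param y Observation vector at this time point.
#' @param alpha Resampling threshold in \[0, 1\].
#' @return The updated `particle_ensemble`, with attribute `"resampled"`.
#' @export
sir_step <- function(ensemble, net, p, spec, y, alpha) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  spec <- as_obs_model(spec)
  n <- nrow(ensemble$particles)
  d <- ncol(ensemble$particles)
  xs <- sample_transition(net, p, ensemble$particles)
  bits <- obs_bits_loglik(spec, y, d)
  ll <- sum(bits$ll0) + as.vector(xs %*% (bits$ll1 - bits$ll0))
  lw <- ensemble$log_weights + ll
  # with normalized incoming weights this is the particle estimate of the
  # predictive likelihood P(y_k | y_{1:k-1})
  log_pred <- logsumexp(lw)
  w <- normalized_weights(lw)  # errors on total degeneracy
  resampled <- FALSE
  if (1 / sum(w^2) < alpha * n) {
    idx <- systematic_resample(w)
    xs <- xs[idx, , drop = FALSE]
    lw <- rep(-log(n), n)
    resampled <- TRUE
  } else {
    lw <- log(w)  # keep weights normalized in log space
  }
  out <- particle_ensemble(xs, lw)
  attr(out, "resampled") <- resampled
  attr(out, "log_pred_lik") <- log_pred
  out
}

#' SIR particle approximation of the Boolean Kalman filter
#'
#' For networks too large to enumerate 2^d states, the filtering
#' distribution is approximated by N particles: initialized uniformly over
#' the Boolean state space (each gene an independent fair coin, so no
#' enumeration is needed), propagated by [sir_step()], and summarized at
#' every time point by weighted per-gene marginals with the same MMSE
#' thresholding and tie rule as the exact filter. As N grows the particle
#' marginals converge to the exact BKF marginals.
#'
#' @inheritParams run_bkf
#' @param N Number of particles (>= 1).
#' @param alpha Resampling threshold in \[0, 1\]; resample when
#'   ESS < `alpha * N`.
#' @param track_pdv When `TRUE` (and d <= 12) also tabulate the weighted
#'   empirical PDV over the enumerated states at every step, for comparison
#'   against the exact filter.
#' @return A `pobds_filter` with `Xhat`, `marginals`, per-step `ess`, and
#'   (optionally) `pdvs`. `log_normalizers` holds the per-step log average
#'   incremental weights, the particle estimate of the predictive
#'   likelihood.
#' @export
run_sir_bkf <- function(net, p, spec, Y, N, alpha = 0.5, track_pdv = FALSE) {
  stopifnot(inherits(net, "boolean_network"))
  spec <- as_obs_model(spec)
  d <- length(net$genes)
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L) stop("'N' must be a positive integer")
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  if (ncol(Y) != d) stop(sprintf("'Y' must have %d columns", d))
  n <- nrow(Y)
  if (track_pdv && d > 12) stop("'track_pdv' needs an enumerable state space (d <= 12)")

  particles <- matrix(as.integer(stats::runif(N * d) < 0.5), N, d)
  colnames(particles) <- net$genes
  ens <- particle_ensemble(particles)

  Xhat <- matrix(0L, n, d, dimnames = list(NULL, net$genes))
  marg <- matrix(0, n, d, dimnames = list(NULL, net$genes))
  essv <- numeric(n)
  logz <- numeric(n)
  pdvs <- if (track_pdv) matrix(0, n, 2L^d) else NULL
  cod <- if (track_pdv) state_codec(d) else NULL

  for (k in seq_len(n)) {
    ens <- sir_step(ens, net, p, spec, Y[k, ], alpha)
    w <- normalized_weights(ens$log_weights)
    marg[k, ] <- as.vector(crossprod(ens$particles, w))
    Xhat[k, ] <- as.integer(marg[k, ] >= 0.5)
    essv[k] <- 1 / sum(w^2)
    logz[k] <- attr(ens, "log_pred_lik")
    if (track_pdv) {
      idx <- encode_state(cod, ens$particles) + 1L
      pdvs[k, ] <- as.vector(tapply(w, factor(idx, levels = seq_len(2L^d)), sum,
                                    default = 0))
    }
  }

  filter_result(Xhat, pdvs, logz, net$genes, method = "SIR-BKF",
                extra = list(marginals = marg, ess = essv, N = N, alpha = alpha,
                             p = p, obs_model = spec))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
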