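#' Observation models for the POBDS measurement channel
#'
#' Given the hidden Boolean state x, the observed expression vector y has
#' conditionally independent components, one per gene. Four channels cover
#' the common expression technologies:
#'
#' * **Bernoulli** — binarized data; each observed bit equals the state bit
#'   flipped independently with probability `q`.
#' * **Gaussian** — microarray / imaging intensities; gene j is drawn from
#'   N(`mu0`, `sigma0`^2) when inactive and N(`mu1`, `sigma1`^2) when active.
#' * **Poisson** — RNA-seq counts with mean `lambda_j(x) = s * exp(mu +
#'   delta_j * x_j)`: `s` is the sequencing depth, `mu` the baseline
#'   log-expression of an inactivated gene, and `delta_j > 0` the
#'   differential expression of gene j when activated.
#' * **Negative binomial** — over-dispersed RNA-seq counts with the same
#'   mean and variance `lambda + lambda^2 / phi_j`; `phi_j > 0` is the
#'   inverse dispersion of gene j.
#'
#' `delta` and `phi` are per-gene vectors (scalars are recycled to length d
#' at evaluation time); the remaining parameters are scalars shared across
#' genes.
#'
#' @param q Flip probability, in \[0, 0.5\]. `q = 0` is the noiseless channel.
#' @param mu0,sigma0,mu1,sigma1 Means and standard deviations (positive) of
#'   the inactive- and active-state Gaussians.
#' @param s Sequencing depth, > 0.
#' @param mu Baseline log-expression (scalar).
#' @param delta Per-gene differential expression, entries > 0.
#' @param phi Per-gene inverse dispersion, entries > 0.
#' @return An `obs_model` object.
#' @name obs_models
NULL

new_obs_model <- function(type, params) {
  structure(c(list(type = type), params), class = c(paste0("obs_", tolower(type)), "obs_model"))
}

#' @rdname obs_models
#' @export
obs_bernoulli <- function(q) {
  if (length(q) != 1L || q < 0 || q > 0.5) stop("'q' must be a scalar in [0, 0.5]")
  new_obs_model("Bernoulli", list(q = q))
}

#' @rdname obs_models
#' @export
obs_gaussian <- function(mu0, sigma0, mu1, sigma1) {
  for (nm in c("mu0", "sigma0", "mu1", "sigma1"))
    if (length(get(nm)) != 1L) stop(sprintf("'%s' must be a scalar", nm))
  if (sigma0 <= 0 || sigma1 <= 0) stop("'sigma0' and 'sigma1' must be positive")
  new_obs_model("Gaussian", list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1))
}

#' @rdname obs_models
#' @export
obs_poisson <- function(s, mu, delta) {
  if (length(s) != 1L || s <= 0) stop("'s' (sequencing depth) must be a positive scalar")
  if (length(mu) != 1L) stop("'mu' must be a scalar")
  if (any(delta <= 0)) stop("'delta' entries must be positive")
  new_obs_model("Poisson", list(s = s, mu = mu, delta = delta))
}

#' @rdname obs_models
#' @export
obs_nbinom <- function(s, mu, delta, phi) {
  if (length(s) != 1L || s <= 0) stop("'s' (sequencing depth) must be a positive scalar")
  if (length(mu) != 1L) stop("'mu' must be a scalar")
  if (any(delta <= 0)) stop("'delta' entries must be positive")
  if (any(phi <= 0)) stop("'phi' entries must be positive")
  new_obs_model("NegativeBinomial", list(s = s, mu = mu, delta = delta, phi = phi))
}

#' Coerce an `obsModel`-style list to an observation model
#'
#' Accepts the `list("Bernoulli", q)` / `list("Gaussian", c(mu0, sigma0,
#' mu1, sigma1))` / `list("Poisson", list(s, mu, delta))` /
#' `list("NB", list(s, mu, delta, phi))` configuration convention, with
#' parameters given positionally as a vector or list after the model name.
#' An existing `obs_model` passes through unchanged.
#'
#' @param x An `obs_model` or a list of (name, parameters).
#' @return An `obs_model`.
#' @export
as_obs_model <- function(x) {
  if (inherits(x, "obs_model")) return(x)
  if (!is.list(x) || length(x) < 2L || !is.character(x[[1]]))
    stop("expected list(<model name>, <parameters...>)")
  name <- tolower(x[[1]])
  # flatten positional parameters
  flat <- unlist(lapply(x[-1], function(p) if (is.list(p)) unlist(p) else p),
                 use.names = FALSE)
  switch(name,
    bernoulli = obs_bernoulli(flat[1]),
    gaussian  = obs_gaussian(flat[1], flat[2], flat[3], flat[4]),
    poisson   = {
      if (length(flat) < 3L) stop("Poisson model needs s, mu, delta")
      obs_poisson(flat[1], flat[2], flat[-(1:2)])
    },
    nb = , negbinomial = , negativebinomial = {
      if (length(flat) < 4L || length(flat) %% 2 != 0)
        stop("negative binomial model needs s, mu, delta (length d), phi (length d)")
      d <- (length(flat) - 2L) / 2L
      obs_nbinom(flat[1], flat[2], flat[2 + seq_len(d)], flat[2 + d + seq_len(d)])
    },
    stop(sprintf("unknown observation model '%s'", x[[1]]))
  )
}

#' @export
print.obs_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "type")]
  cat(sprintf("%s observation model: %s\n", x$type,
              paste(sprintf("%s = %s", names(pars),
                            vapply(pars, function(p) paste(format(p), collapse = ","), "")),
                    collapse = ", ")))
  invisible(x)
}

recycle_d <- function(v, d, what) {
  if (length(v) == 1L) return(rep(v, d))
  if (length(v) != d) stop(sprintf("'%s' must have length 1 or %d", what, d))
  v
}

validate_obs_support <- function(spec, y) {
  bad <- switch(spec$type,
    Bernoulli = !all(y[!is.na(y)] %in% c(0, 1)),
    Gaussian  = FALSE,
    any(y[!is.na(y)] < 0) || any(y[!is.na(y)] != round(y[!is.na(y)])))
  if (bad)
    stop(sprintf("observation outside the support of the %s model", spec$type))
  invisible(TRUE)
}

# Per-gene log density/mass of y under x_j = 0 and x_j = 1.
# Returns list(ll0, ll1), each length d; missing genes (NA in y, or masked)
# contribute 0 to both, i.e. their factor is dropped.
obs_bits_loglik <- function(spec, y, d, miss = NULL) {
  if (length(y) != d) stop(sprintf("'y' must have length %d, got %d", d, length(y)))
  m <- is.na(y)
  if (!is.null(miss)) {
    miss <- as.logical(miss)
    if (length(miss) != d) stop("'miss' mask must have length d")
    m <- m | miss
  }
  validate_obs_support(spec, y[!m])
  yy <- ifelse(m, 0, y)  # placeholder values under the mask
  ll <- switch(spec$type,
    Bernoulli = {
      q <- spec$q
      list(ll0 = ifelse(yy == 0, log1p(-q), log(q)),
           ll1 = ifelse(yy == 1, log1p(-q), log(q)))
    },
    Gaussian = list(
      ll0 = stats::dnorm(yy, spec$mu0, spec$sigma0, log = TRUE),
      ll1 = stats::dnorm(yy, spec$mu1, spec$sigma1, log = TRUE)),
    Poisson = {
      delta <- recycle_d(spec$delta, d, "delta")
      list(ll0 = stats::dpois(yy, spec$s * exp(spec$mu), log = TRUE),
           ll1 = stats::dpois(yy, spec$s * exp(spec$mu + delta), log = TRUE))
    },
    NegativeBinomial = {
      delta <- recycle_d(spec$delta, d, "delta")
      phi <- recycle_d(spec$phi, d, "phi")
      list(ll0 = stats::dnbinom(yy, size = phi, mu = spec$s * exp(spec$mu), log = TRUE),
           ll1 = stats::dnbinom(yy, size = phi, mu = spec$s * exp(spec$mu + delta), log = TRUE))
    },
    stop("unknown observation model type"))
  ll$ll0[m] <- 0
  ll$ll1[m] <- 0
  ll
}

#' Observation log-likelihood
#'
#' Log-probability (density or mass) of an observed expression vector given a
#' Boolean state, summed over the conditionally independent genes. All
#' likelihood arithmetic in the package stays in log space; count models
#' underflow quickly otherwise.
#'
#' @param spec An `obs_model`.
#' @param y Numeric observation vector of length d. `NA` entries are treated
#'   as missing and contribute nothing (the POBDS model explicitly allows
#'   incomplete measurements).
#' @param x Boolean state vector of length d.
#' @param miss Optional logical mask of genes to treat as unobserved.
#' @return Scalar log-likelihood.
#' @export
obs_loglik <- function(spec, y, x, miss = NULL) {
  spec <- as_obs_model(spec)
  d <- length(x)
  xm <- as_state_matrix(x, d)
  ll <- obs_bits_loglik(spec, y, d, miss)
  sum(ifelse(xm[1L, ] == 1L, ll$ll1, ll$ll0))
}

# log-likelihood of y for every row of the state matrix S (2^d x d or N x d)
obs_loglik_states <- function(spec, y, S, miss = NULL) {
  ll <- obs_bits_loglik(spec, y, ncol(S), miss)
  sum(ll$ll0) + as.vector(S %*% (ll$ll1 - ll$ll0))
}

#' Draw an observation vector given the hidden state
#'
#' Samples each gene independently from the channel whose density
#' [obs_loglik()] evaluates. Uses R's global random number generator.
#'
#' @inheritParams obs_loglik
#' @param x Boolean state vector, or an n x d matrix to draw one observation
#'   row per state row.
#' @return Numeric vector (or matrix) shaped like `x`.
#' @export
sample_observation <- function(spec, x) {
  spec <- as_obs_model(spec)
  vec <- is.null(dim(x))
  d <- if (vec) length(x) else ncol(x)
  xm <- as_state_matrix(x, d)
  n <- nrow(xm)
  y <- switch(spec$type,
    Bernoulli = {
      flips <- matrix(stats::runif(n * d) < spec$q, n, d)
      (xm + flips) %% 2
    },
    Gaussian = {
      mu <- ifelse(xm == 1L, spec$mu1, spec$mu0)
      sd <- ifelse(xm == 1L, spec$sigma1, spec$sigma0)
      matrix(stats::rnorm(n * d, mu, sd), n, d)
    },
    Poisson = {
      delta <- recycle_d(spec$delta, d, "delta")
      lam <- spec$s * exp(spec$mu + xm * rep(delta, each = n))
      matrix(stats::rpois(n * d, lam), n, d)
    },
    NegativeBinomial = {
      delta <- recycle_d(spec$delta, d, "delta")
      phi <- recycle_d(spec$phi, d, "phi")
      lam <- spec$s * exp(spec$mu + xm * rep(delta, each = n))
      matrix(stats::rnbinom(n * d, size = rep(phi, each = n), mu = lam), n, d)
    })
  colnames(y) <- colnames(xm)
  if (vec) y[1L, ] else y
}
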