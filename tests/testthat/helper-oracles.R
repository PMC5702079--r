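# Independent oracles, deliberately written as plain loops over enumerated
# states so they share no code path with the package internals.

# per-state observation log-likelihood, direct per-gene formulas
oracle_state_loglik <- function(spec, y, x) {
  d <- length(x)
  tot <- 0
  for (j in seq_len(d)) {
    if (is.na(y[j])) next
    tot <- tot + switch(spec$type,
      Bernoulli = if (y[j] != x[j]) log(spec$q) else log(1 - spec$q),
      Gaussian = {
        mu <- if (x[j] == 1) spec$mu1 else spec$mu0
        sd <- if (x[j] == 1) spec$sigma1 else spec$sigma0
        -0.5 * log(2 * pi) - log(sd) - (y[j] - mu)^2 / (2 * sd^2)
      },
      Poisson = {
        del <- if (length(spec$delta) == 1) spec$delta else spec$delta[j]
        lam <- spec$s * exp(spec$mu + del * x[j])
        y[j] * log(lam) - lam - lgamma(y[j] + 1)
      },
      NegativeBinomial = {
        del <- if (length(spec$delta) == 1) spec$delta else spec$delta[j]
        ph <- if (length(spec$phi) == 1) spec$phi else spec$phi[j]
        lam <- spec$s * exp(spec$mu + del * x[j])
        lgamma(y[j] + ph) - lgamma(ph) - lgamma(y[j] + 1) +
          ph * log(ph / (ph + lam)) + y[j] * log(lam / (ph + lam))
      })
  }
  tot
}

# enumerate all 2^d states, gene 1 = most significant bit (loop-built)
oracle_states <- function(d) {
  S <- matrix(0L, 2^d, d)
  for (i in 0:(2^d - 1)) {
    k <- i
    for (j in d:1) { S[i + 1, j] <- k %% 2; k <- k %/% 2 }
  }
  S
}

# transition matrix by double loop over state pairs
oracle_transition_matrix <- function(net, p) {
  d <- length(net$genes)
  S <- oracle_states(d)
  M <- matrix(0, 2^d, 2^d)
  for (i in seq_len(2^d)) {
    fx <- network_step(net, S[i, ])
    for (j in seq_len(2^d)) {
      h <- sum(S[j, ] != fx)
      M[j, i] <- p^h * (1 - p)^(d - h)
    }
  }
  M
}

# classic scaled HMM forward pass, loops only; returns filtered posteriors,
# per-step log normalizers
oracle_hmm_forward <- function(net, p, spec, Y, prior = NULL) {
  d <- length(net$genes)
  ns <- 2^d
  S <- oracle_states(d)
  M <- oracle_transition_matrix(net, p)
  if (is.null(prior)) prior <- rep(1 / ns, ns)
  n <- nrow(Y)
  post <- matrix(0, n, ns)
  logz <- numeric(n)
  cur <- prior
  for (k in seq_len(n)) {
    pred <- numeric(ns)
    for (j in seq_len(ns)) pred[j] <- sum(M[j, ] * cur)
    lik <- vapply(seq_len(ns),
                  function(j) exp(oracle_state_loglik(spec, Y[k, ], S[j, ])), 0)
    un <- lik * pred
    z <- sum(un)
    post[k, ] <- un / z
    logz[k] <- log(z)
    cur <- post[k, ]
  }
  list(post = post, logz = logz)
}

# exhaustive joint enumeration over all state paths (small d, small n):
# smoothed marginals P(X_k = s | Y_{1:n}) and log marginal likelihood
oracle_path_enumeration <- function(net, p, spec, Y, prior = NULL) {
  d <- length(net$genes)
  ns <- 2^d
  S <- oracle_states(d)
  M <- oracle_transition_matrix(net, p)
  n <- nrow(Y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), n)))
  logp <- numeric(nrow(paths))
  if (is.null(prior)) prior <- rep(1 / ns, ns)
  lik <- matrix(0, n, ns)  # per-(time, state) log-likelihood table
  for (k in seq_len(n)) for (j in seq_len(ns))
    lik[k, j] <- oracle_state_loglik(spec, Y[k, ], S[j, ])
  for (r in seq_len(nrow(paths))) {
    idx <- paths[r, ]
    # marginalize the unobserved time-0 state under the prior
    lp <- log(sum(M[idx[1], ] * prior))
    if (n > 1) for (k in 2:n) lp <- lp + log(M[idx[k], idx[k - 1]])
    logp[r] <- lp + sum(lik[cbind(seq_len(n), idx)])
  }
  mx <- max(logp)
  w <- exp(logp - mx)
  marg <- matrix(0, n, ns)
  for (k in seq_len(n))
    for (j in seq_len(ns))
      marg[k, j] <- sum(w[paths[, k] == j])
  marg <- marg / sum(w)
  list(marg = marg, logml = mx + log(sum(w)))
}

# small random Boolean network: each gene's rule is a random expression over
# one to three (not necessarily distinct) genes
random_network <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- LETTERS[seq_len(d)]
  rand_expr <- function(depth) {
    if (depth <= 0 || runif(1) < 0.35) {
      if (runif(1) < 0.1) as.character(sample(0:1, 1)) else sample(genes, 1)
    } else {
      op <- sample(c("!", "&", "|"), 1)
      if (op == "!") paste0("!(", rand_expr(depth - 1), ")")
      else paste0("(", rand_expr(depth - 1), " ", op, " ", rand_expr(depth - 1), ")")
    }
  }
  rules <- vapply(genes, function(g) rand_expr(2), "")
  parse_boolnet(c("targets, factors", paste0(genes, ", ", rules)))
}

# random observation model of each family, parameters drawn to be moderately
# informative
random_obs_model <- function(type, d) {
  switch(type,
    Bernoulli = obs_bernoulli(runif(1, 0.02, 0.3)),
    Gaussian = obs_gaussian(runif(1, 0, 2), runif(1, 0.5, 2),
                            runif(1, 3, 6), runif(1, 0.5, 2)),
    Poisson = obs_poisson(runif(1, 5, 20), runif(1, 0, 1), runif(d, 0.5, 2)),
    NegativeBinomial = obs_nbinom(runif(1, 5, 20), runif(1, 0, 1),
                                  runif(d, 0.5, 2), runif(d, 2, 8)))
}

tv_dist <- function(a, b) 0.5 * sum(abs(a - b))

pdv_entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
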