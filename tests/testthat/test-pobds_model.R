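test_that("transition matrix obeys the Hamming-distance formula and its limits", {
  net <- p53_network(1)
  for (p in c(0, 0.05, 0.3, 0.5)) {
    tm <- build_transition_matrix(net, p)
    expect_equal(colSums(tm$M), rep(1, 16), tolerance = 1e-12)
    expect_equal(tm$M, oracle_transition_matrix(net, p), tolerance = 1e-14)
  }
  # p = 0: deterministic map, columns are unit vectors on f(s_i)
  tm0 <- build_transition_matrix(net, 0)
  cod <- state_codec(4)
  nxt <- encode_state(cod, network_step(net, oracle_states(4))) + 1
  for (i in 1:16) {
    expect_equal(tm0$M[nxt[i], i], 1)
    expect_equal(sum(tm0$M[, i]), 1)
  }
  # p = 0.5: fully chaotic, every entry 2^-d
  tm5 <- build_transition_matrix(net, 0.5)
  expect_equal(unname(tm5$M), matrix(1 / 16, 16, 16), tolerance = 1e-14)
  expect_error(build_transition_matrix(net, 0.6), "0, 0.5")
})

test_that("two-gene identity network has the textbook flip-probability entries", {
  net <- parse_boolnet("targets, factors\nA, A\nB, B")
  tm <- build_transition_matrix(net, 0.1)
  S <- oracle_states(2)
  for (i in 1:4) for (j in 1:4) {
    h <- sum(S[i, ] != S[j, ])
    expect_equal(tm$M[j, i], c(0.81, 0.09, 0.01)[h + 1])
  }
})

test_that("relabeling genes conjugates the transition matrix by the state permutation", {
  for (seed in 21:23) {
    net <- random_network(3, seed = seed)
    perm <- sample(3)
    # permuted network: reordered rule lines (rule bodies are unchanged)
    txt <- write_boolnet(net)
    net_p <- parse_boolnet(c(txt[1], txt[-1][perm]))
    p <- 0.13
    M <- build_transition_matrix(net, p)$M
    Mp <- build_transition_matrix(net_p, p)$M
    cod <- state_codec(3)
    S <- oracle_states(3)
    sigma <- encode_state(cod, S[, perm]) + 1  # state index under the relabeling
    expect_equal(Mp[sigma, sigma], M, tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("sample_transition follows the network exactly when noiseless", {
  net <- p53_network(1)
  x <- c(0, 1, 1, 0)
  for (i in 1:10) expect_equal(sample_transition(net, 0, x), network_step(net, x))
  # near-zero noise: almost every draw equals f(x)
  set.seed(31)
  draws <- sample_transition(net, 1e-9, matrix(rep(x, each = 1e4), 1e4, 4))
  fx <- network_step(net, x)
  expect_gte(mean(apply(draws, 1, function(r) all(r == fx))), 0.99)
})

test_that("Monte-Carlo transition frequencies match the matrix column", {
  net <- parse_boolnet("targets, factors\nA, A\nB, B")
  p <- 0.1
  tm <- build_transition_matrix(net, p)
  x <- c(1, 0)
  n <- 1e5
  set.seed(32)
  draws <- sample_transition(net, p, matrix(rep(x, each = n), n, 2))
  idx <- encode_state(state_codec(2), draws) + 1
  freq <- tabulate(idx, 4) / n
  col <- tm$M[, encode_state(state_codec(2), x) + 1]
  se <- sqrt(col * (1 - col) / n)
  expect_true(all(abs(freq - col) <= 3.5 * se))
})

test_that("observation log-likelihoods match direct per-gene formulas", {
  # Bernoulli, y == x
  b <- obs_bernoulli(0.05)
  x <- c(1, 0, 1, 1)
  expect_equal(obs_loglik(b, x, x), 4 * log(0.95))
  expect_equal(obs_loglik(b, c(1, 1, 1, 1), x), 3 * log(0.95) + log(0.05))

  # Gaussian with identical components is uninformative about the state
  gu <- obs_gaussian(2, 1.5, 2, 1.5)
  y <- c(1.2, -0.4, 3.3, 2.0)
  S <- oracle_states(4)
  lls <- apply(S, 1, function(s) obs_loglik(gu, y, s))
  expect_equal(max(lls) - min(lls), 0)

  # Poisson validated against the textbook pmf at lambda = s exp(mu + delta)
  po <- obs_poisson(10, 0.5, c(1, 1, 1))
  yv <- c(40, 12, 55)
  xv <- c(1, 0, 1)
  lam <- 10 * exp(0.5 + c(1, 0, 1))
  expect_equal(obs_loglik(po, yv, xv),
               sum(yv * log(lam) - lam - lgamma(yv + 1)))

  # negative binomial against the gamma-function mass
  nb <- obs_nbinom(10, 0.5, c(1, 1), c(3, 5))
  ynb <- c(7, 30); xnb <- c(0, 1)
  expect_equal(obs_loglik(nb, ynb, xnb),
               oracle_state_loglik(nb, ynb, xnb))

  # random cross-family agreement with the loop oracle
  set.seed(33)
  for (type in c("Bernoulli", "Gaussian", "Poisson", "NegativeBinomial")) {
    spec <- random_obs_model(type, 4)
    x <- as.integer(runif(4) < 0.5)
    y <- sample_observation(spec, x)
    expect_equal(obs_loglik(spec, y, x), oracle_state_loglik(spec, y, x),
                 tolerance = 1e-12)
  }
})

test_that("Bernoulli likelihood normalizes over the observation space", {
  spec <- obs_bernoulli(0.2)
  Sy <- oracle_states(3)
  for (i in seq_len(8)) {
    x <- Sy[i, ]
    tot <- sum(apply(Sy, 1, function(y) exp(obs_loglik(spec, y, x))))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("missing genes drop out of the likelihood", {
  spec <- obs_gaussian(1, 2, 5, 2)
  x <- c(1, 0, 1, 0)
  y <- c(4.8, 1.1, 5.2, 0.4)
  full <- obs_loglik(spec, y, x)
  # masking gene 3 equals summing over the other genes only
  expect_equal(obs_loglik(spec, y, x, miss = c(FALSE, FALSE, TRUE, FALSE)),
               full - dnorm(y[3], 5, 2, log = TRUE))
  # NA in y behaves like a mask
  y2 <- y; y2[3] <- NA
  expect_equal(obs_loglik(spec, y2, x), full - dnorm(y[3], 5, 2, log = TRUE))
})

test_that("sampled observations have the moments the likelihood implies", {
  set.seed(34)
  g <- obs_gaussian(1, 2, 5, 2)
  n <- 1e5
  y <- sample_observation(g, matrix(1L, n, 1))
  expect_lt(abs(mean(y) - 5), 3 * 2 / sqrt(n))
  # Bernoulli q = 0 is the identity channel
  x <- matrix(c(1L, 0L, 1L), 1)
  expect_equal(unname(sample_observation(obs_bernoulli(0), c(1, 0, 1))), c(1, 0, 1))
  # negative binomial approaches the Poisson variance as phi grows
  nb <- obs_nbinom(10, 0.2, 1, 1e6)
  ynb <- sample_observation(nb, matrix(1L, n, 1))
  lam <- 10 * exp(1.2)
  expect_equal(var(as.vector(ynb)) / lam, 1, tolerance = 0.05)
})

test_that("obsModel-style configuration lists are accepted", {
  expect_equal(as_obs_model(list("Bernoulli", 0.05))$q, 0.05)
  g <- as_obs_model(list("Gaussian", c(1, 2, 5, 2)))
  expect_equal(c(g$mu0, g$sigma0, g$mu1, g$sigma1), c(1, 2, 5, 2))
  po <- as_obs_model(list("Poisson", list(10, 0.5, c(1, 2, 3))))
  expect_equal(po$delta, c(1, 2, 3))
  nb <- as_obs_model(list("NB", c(10, 0.5, 1, 2, 3, 4)))
  expect_equal(nb$delta, c(1, 2))
  expect_equal(nb$phi, c(3, 4))
  expect_error(as_obs_model(list("Weibull", 1)), "unknown observation model")
})

test_that("parameter and support validation", {
  expect_error(obs_bernoulli(0.7), "0, 0.5")
  expect_error(obs_gaussian(0, -1, 1, 1), "positive")
  expect_error(obs_poisson(-1, 0, 1), "positive")
  expect_error(obs_nbinom(1, 0, 1, -2), "positive")
  expect_error(obs_loglik(obs_bernoulli(0.1), c(0.5, 1), c(0, 1)), "support")
  expect_error(obs_loglik(obs_poisson(10, 0, c(1, 1)), c(-3, 2), c(0, 1)), "support")
  expect_error(obs_loglik(obs_gaussian(1, 2, 5, 2), c(1, 2), c(0, 1, 1)), "length")
})
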