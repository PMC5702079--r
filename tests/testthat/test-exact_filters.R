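test_that("bkf_step recovers the state under near-noiseless binary observations", {
  net <- p53_network(1)
  tm <- build_transition_matrix(net, 0.05)
  cod <- state_codec(4)
  y <- network_step(net, c(0, 0, 1, 1))  # a reachable state
  st <- bkf_step(rep(1 / 16, 16), tm, obs_bernoulli(1e-12), y)
  expect_equal(st$posterior[encode_state(cod, y) + 1], 1, tolerance = 1e-9)
})

test_that("uninformative observations reduce the update to pure prediction", {
  net <- p53_network(1)
  tm <- build_transition_matrix(net, 0.1)
  prior <- runif(16); prior <- prior / sum(prior)
  st <- bkf_step(prior, tm, obs_gaussian(2, 1, 2, 1), c(0.3, 1.2, -0.5, 2.2))
  expect_equal(st$posterior, as.vector(tm$M %*% prior), tolerance = 1e-14)
})

test_that("contradictory noiseless observations raise a zero-likelihood error", {
  net <- parse_boolnet("targets, factors\nA, 1\nB, 1")
  tm <- build_transition_matrix(net, 0)
  # after one deterministic step the state is (1,1); observing (0,0) under q=0
  expect_error(bkf_step(rep(0.25, 4), tm, obs_bernoulli(0), c(0, 0)),
               "zero-likelihood")
})

test_that("BKF equals the brute-force HMM forward pass on random models", {
  set.seed(51)
  types <- c("Bernoulli", "Gaussian", "Poisson", "NegativeBinomial")
  for (i in 1:4) {
    d <- sample(2:3, 1)
    net <- random_network(d)
    p <- runif(1, 0.01, 0.3)
    spec <- random_obs_model(types[i], d)
    traj <- simulate_network(net, 20, p, spec)
    fit <- run_bkf(net, p, spec, traj$Y)
    orc <- oracle_hmm_forward(net, p, spec, traj$Y)
    expect_lt(max(abs(fit$pdvs - orc$post)), 1e-12)
    expect_lt(max(abs(fit$log_normalizers - orc$logz)), 1e-10)
  }
})

test_that("a full BKF run composes from single steps", {
  net <- p53_network(1)
  spec <- obs_gaussian(1, 2, 5, 2)
  traj <- simulate_network(net, 15, 0.05, spec, seed = 52)
  fit <- run_bkf(net, 0.05, spec, traj$Y)
  tm <- build_transition_matrix(net, 0.05)
  cur <- rep(1 / 16, 16)
  for (k in 1:15) {
    st <- bkf_step(cur, tm, spec, traj$Y[k, ])
    expect_equal(fit$pdvs[k, ], st$posterior)
    expect_equal(fit$log_normalizers[k], st$log_normalizer)
    cur <- st$posterior
  }
})

test_that("every filtered and smoothed PDV stays normalized", {
  net <- p53_network(1)
  spec <- obs_poisson(10, 0.5, c(1, 2, 1.5, 1))
  traj <- simulate_network(net, 40, 0.05, spec, seed = 53)
  for (fit in list(run_bkf(net, 0.05, spec, traj$Y),
                   run_bks(net, 0.05, spec, traj$Y))) {
    expect_true(all(fit$pdvs >= 0))
    expect_equal(rowSums(fit$pdvs), rep(1, 40), tolerance = 1e-10)
  }
})

test_that("smoother boundary, oracle, and no-information properties", {
  net <- random_network(2, seed = 54)
  p <- 0.15
  spec <- obs_gaussian(0, 1, 2, 1)
  traj <- simulate_network(net, 6, p, spec, seed = 55)
  fit <- run_bkf(net, p, spec, traj$Y)
  sm <- run_bks(net, p, spec, traj$Y)

  # final smoothed PDV is the final filtered PDV
  expect_lt(max(abs(sm$pdvs[6, ] - fit$pdvs[6, ])), 1e-12)

  # all smoothed marginals match exhaustive path enumeration
  orc <- oracle_path_enumeration(net, p, spec, traj$Y)
  expect_lt(max(abs(sm$pdvs - orc$marg)), 1e-10)

  # total log marginal likelihood agrees with the joint enumeration
  expect_equal(sum(fit$log_normalizers), orc$logml, tolerance = 1e-10)

  # with uninformative observations the smoothed PDVs are the prior chain marginals
  flat <- obs_gaussian(1, 2, 1, 2)
  smf <- run_bks(net, p, flat, traj$Y)
  M <- build_transition_matrix(net, p)$M
  cur <- rep(0.25, 4)
  for (k in 1:6) {
    cur <- as.vector(M %*% cur)
    expect_equal(smf$pdvs[k, ], cur, tolerance = 1e-12)
  }
})

test_that("smoothing is at least as sharp as filtering on average", {
  net <- p53_network(1)
  spec <- obs_gaussian(1, 2, 5, 2)
  set.seed(56)
  gap <- replicate(200, {
    traj <- simulate_network(net, 10, 0.05, spec)
    f <- run_bkf(net, 0.05, spec, traj$Y)
    s <- run_bks(net, 0.05, spec, traj$Y)
    ks <- 1:9  # interior instants
    mean(vapply(ks, function(k) pdv_entropy(f$pdvs[k, ]) - pdv_entropy(s$pdvs[k, ]), 0))
  })
  expect_gt(mean(gap), 0)
})

test_that("MMSE thresholding of a PDV", {
  cod <- state_codec(4)
  point <- rep(0, 16); point[encode_state(cod, c(1, 0, 1, 1)) + 1] <- 1
  expect_equal(mmse_from_pdv(point, cod), c(1L, 0L, 1L, 1L))
  # uniform PDV: every marginal exactly 1/2, ties map to 1
  expect_equal(mmse_from_pdv(rep(1 / 16, 16), cod), c(1L, 1L, 1L, 1L))
  # random PDV against direct marginal summation
  set.seed(57)
  pdv <- runif(16); pdv <- pdv / sum(pdv)
  S <- oracle_states(4)
  marg <- vapply(1:4, function(j) sum(pdv[S[, j] == 1]), 0)
  expect_equal(mmse_from_pdv(pdv, cod), as.integer(marg >= 0.5))
})

test_that("exact filtering refuses unenumerable networks", {
  genes <- paste0("G", 1:13)
  txt <- c("targets, factors", paste0(genes, ", ", c(genes[-1], genes[1])))
  big <- parse_boolnet(txt)
  expect_error(build_transition_matrix(big, 0.01), "run_sir_bkf")
})
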