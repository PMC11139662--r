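# variational message passing, action selection, free energy

test_that("single-observation inference matches exact Bayes by enumeration", {
  for (s in 1:6) {
    set.seed(s)
    D <- softmax(rnorm(2))
    counts <- matrix(rexp(4) + 0.3, 2)
    m <- soft_two_state(D = D, counts = counts)
    o <- onehot(sample(2, 1), 2)
    b <- infer_states(m, new_beliefs(m), list(list(signal = o)))
    # brute-force oracle over the two states
    lik <- as.vector(t(dirichlet_mean(counts)) %*% o)
    oracle <- D * lik / sum(D * lik)
    expect_equal(b$s[[1]][, 1], oracle, tolerance = 1e-6)
  }
})

test_that("degenerate likelihoods behave as expected", {
  m <- make_fixture("two_state")
  b <- infer_states(m, new_beliefs(m), list(list(signal = onehot(2, 2))))
  expect_gt(b$s[[1]][2, 1], 0.99)
  # uniform likelihood: posterior equals the prior
  mu <- soft_two_state(D = c(0.3, 0.7), counts = matrix(1, 2, 2))
  bu <- infer_states(mu, new_beliefs(mu), list(list(signal = onehot(1, 2))))
  expect_equal(bu$s[[1]][, 1], c(0.3, 0.7), tolerance = 1e-9)
})

test_that("likelihood messages match their closed forms in both modes", {
  a_id <- fedinf:::.det_counts(array(diag(3), c(3, 3)), 4096)
  msg <- likelihood_message(a_id, onehot(2, 3), list(rep(1 / 3, 3)), 1)
  expect_equal(which.max(msg), 2L)
  a_u <- array(1, c(3, 3))
  msg_u <- likelihood_message(a_u, onehot(1, 3), list(rep(1 / 3, 3)), 1)
  expect_equal(max(msg_u) - min(msg_u), 0)
  a_11 <- array(1, c(2, 2))
  msg_d <- likelihood_message(a_11, onehot(1, 2), list(c(0.5, 0.5)), 1,
                              mode = "digamma")
  expect_equal(as.vector(msg_d), c(-1, -1), tolerance = 1e-12)
})

test_that("permutation dynamics propagate beliefs forward", {
  m <- make_fixture("permutation_world")
  b <- new_beliefs(m)
  b$s[[1]] <- matrix(onehot(1, 4), 4, 1)
  b$paths[[1]] <- c(0, 1)  # cyclic shift certain
  pred <- predictive_posterior(b, m, 1)
  # beliefs propagate through the volatility-hedged transition: almost all
  # mass moves with the permutation, a small uniform residue hedges it
  expect_equal(which.max(pred), 2L)
  expect_gt(pred[2], 0.96)
  # uniform path posterior mixes still and shift
  b$paths[[1]] <- c(0.5, 0.5)
  expect_lt(max(abs(predictive_posterior(b, m, 1) - c(0.5, 0.5, 0, 0))),
            0.02)
})

test_that("uncontrolled paths are inferred from successive state posteriors", {
  m <- make_fixture("permutation_world")
  b <- new_beliefs(m)
  b$s[[1]] <- cbind(onehot(1, 4), onehot(2, 4))  # a shift happened
  b <- infer_paths(m, b)
  expect_gt(b$paths[[1]][2], 0.95)
})

test_that("policy posterior follows softmax(precision * (ln E - G))", {
  m <- make_fixture("mini_sentinel")
  m$E[[2]] <- rep(1 / 3, 3)
  m$policy_precision <- 1
  b <- new_beliefs(m)
  b$s <- list(matrix(rep(1 / 3, 3), 3, 1), matrix(onehot(2, 3), 3, 1))
  b <- infer_paths(m, b, efe = c(0, 1, 1))
  expect_equal(b$policy, softmax(-c(0, 1, 1)), tolerance = 1e-9)
  expect_equal(round(b$policy, 3), c(0.576, 0.212, 0.212))
})

test_that("action selection is argmax with lowest-index tie-break or seeded sampling", {
  expect_equal(select_action(c(0.2, 0.5, 0.3)), 2L)
  expect_equal(select_action(c(0.5, 0.5)), 1L)
  expect_equal(select_action(c(0, 1, 0), mode = "sample", seed = 42), 2L)
})

test_that("free energy matches closed forms on degenerate models", {
  # posterior = prior = one-hot consistent with a deterministic likelihood
  m <- soft_two_state(D = c(1, 0),
                      counts = fedinf:::.det_counts(diag(2), 65536))
  b <- infer_states(m, new_beliefs(m), list(list(signal = onehot(1, 2))))
  expect_lt(abs(b$F_last), 1e-3)
  # uniform prior, uniform likelihood over 9 outcomes: F = ln 9
  m9 <- gen_model(
    factors = list(factor_spec("state", 9)),
    modalities = list(modality_spec("signal", 9, 1L)),
    A = list(matrix(1, 9, 9)),
    B = list(array(diag(9), c(9, 9, 1))))
  b9 <- infer_states(m9, new_beliefs(m9), list(list(signal = onehot(3, 9))))
  expect_equal(b9$F_last, log(9), tolerance = 1e-6)
})

test_that("free energy does not increase across fixed-point sweeps", {
  w0 <- init_world(1, "clockwise", "near", "foe")
  m <- silence(build_sentinel_agent(2))
  b <- new_beliefs(m)
  obs <- list()
  w <- w0
  for (t in 1:6) {
    obs[[t]] <- sentinel_obs(m, w, 2)
    b <- infer_states(m, b, obs)
    ft <- b$F_trace
    b$actions <- c(b$actions, 2L)
    w <- step_world(w, c(2, 2, 2))
  }
  # within every epoch's call the converged free energy does not exceed
  # the first sweep's beyond a small slack: the interleaved path
  # re-estimation makes sweeps only approximately monotone
  starts <- cumsum(c(1, head(b$sweeps, -1)))
  net <- numeric(0)
  for (k in seq_along(b$sweeps)) {
    tr <- b$F_trace[seq(starts[k], length.out = b$sweeps[k])]
    net <- c(net, tr[length(tr)] - tr[1])
  }
  expect_true(all(net < 0.05))
  # and where there is real uncertainty to resolve (first contact), the
  # sweeps buy a substantial decrease
  expect_lt(min(net), -0.5)
})

test_that("identical agents with identical observations agree exactly", {
  m <- silence(build_sentinel_agent(1))
  w <- init_world(3, "anticlockwise", "close", "friend")
  obs <- list(sentinel_obs(m, w, 1))
  b1 <- infer_states(m, new_beliefs(m), obs)
  b2 <- infer_states(m, new_beliefs(m), obs)
  expect_identical(b1$s, b2$s)
  expect_identical(b1$F_last, b2$F_last)
})
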