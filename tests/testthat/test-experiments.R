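# scheduler mechanics and reported metrics

test_that("mapping divergence matches closed forms and shrinks under interpolation", {
  id9 <- fedinf:::.det_counts(array(diag(9), c(9, 9)), 1e8, 1e-8)
  expect_equal(mapping_divergence(id9, id9), 0)
  u9 <- matrix(1, 9, 9)
  expect_equal(mapping_divergence(id9, u9), 9 * log(9), tolerance = 1e-3)
  mid <- 0.5 * id9 + 0.5 * u9
  expect_lt(mapping_divergence(mid, id9), mapping_divergence(u9, id9))
  expect_error(mapping_divergence(id9, matrix(1, 3, 3)), "mismatch")
})

test_that("structural complexity accumulates Dirichlet KL and never decreases", {
  a <- matrix(c(2, 1), 2)
  b <- matrix(c(1, 1), 2)
  expect_equal(structural_complexity(b, b, 0), 0)
  expect_equal(structural_complexity(a, b, 0), log(2) - 0.5, tolerance = 1e-12)
  acc <- 0
  set.seed(8)
  cur <- matrix(rexp(9) + 0.5, 3)
  trace <- numeric(5)
  for (k in 1:5) {
    nxt <- cur + matrix(runif(9), 3) * 0.3
    acc <- structural_complexity(nxt, cur, acc)
    trace[k] <- acc
    cur <- nxt
  }
  expect_true(all(diff(trace) >= 0))
})

test_that("low-free-energy incidence thresholds at one nat per observation", {
  expect_true(low_F_incidence(matrix(0, 4, 8)))
  expect_false(low_F_incidence(matrix(log(9), 4, 8)))
  with_na <- matrix(0.5, 4, 8)
  with_na[2, ] <- NA
  expect_true(low_F_incidence(with_na))
})

test_that("electrophysiological summaries follow the belief trace", {
  states <- cbind(c(0.5, 0.5), c(0.5, 0.5), c(0.9, 0.1))
  policy <- cbind(rep(1 / 3, 3), onehot(2, 3))
  ep <- electrophysiology(list(states = states, policy = policy))
  expect_equal(ep$lfp[, 1], c(0, 0))
  expect_equal(ep$lfp[, 2], c(0.4, -0.4))
  expect_equal(ep$dopamine, c(-log(3), 0), tolerance = 1e-12)
})

test_that("an epoch keeps posteriors normalised and silencing equals muting", {
  w0 <- init_world(4, "still", "near", "friend")
  models <- lapply(1:3, build_sentinel_agent)
  ens <- init_ensemble(lapply(models, ens_agent), w0)
  ens <- run_epoch(ens)
  for (ag in ens$agents) {
    for (f in 1:4) expect_equal(colSums(ag$beliefs$s[[f]]), 1, tolerance = 1e-9)
  }
  # silenced channel delivers the same posterior as no channel at all
  sil <- run_episode(lapply(models, function(m) ens_agent(silence(m))),
                     w0, n_epochs = 3, communication = TRUE)
  mute <- run_episode(lapply(models, function(m) ens_agent(silence(m))),
                      w0, n_epochs = 3, communication = FALSE)
  for (i in 1:3) {
    expect_equal(sil$agents[[i]]$beliefs$s[[1]],
                 mute$agents[[i]]$beliefs$s[[1]], tolerance = 1e-6)
  }
})

test_that("convergence summaries behave on synthetic traces", {
  kl <- matrix(1, 10, 3)
  kl[6:10, ] <- 0.05
  expect_equal(convergence_episode(kl), 6L)
  kl[9, 2] <- 0.5   # a late excursion resets the criterion
  expect_equal(convergence_episode(kl), 10L)
  expect_true(is.na(convergence_episode(matrix(1, 4, 3))))
  Fm <- cbind(rep(2, 30), rep(2, 30), c(rep(6, 3), rep(2.05, 27)))
  # the smoothing window must fully clear the naive early episodes
  expect_equal(supervision_convergence(Fm, run_length = 8), 11L)
  expect_true(is.na(supervision_convergence(Fm[1:15, ], run_length = 8)))
})

test_that("experiment configs have protocol defaults and reject bad values", {
  cfg <- default_config("acquisition")
  expect_equal(cfg$eta, 32)
  expect_equal(cfg$n_episodes, 32)
  expect_equal(cfg$n_epochs, 16)
  expect_equal(default_config("emergence")$n_episodes, 512)
  expect_error(run_experiment("nonsense"), "arg")
})
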