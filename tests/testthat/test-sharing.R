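# the communication channel: speaking, the chorus, silencing, consensus

test_that("speak maps predictive beliefs through the auditory likelihood", {
  m <- make_fixture("permutation_world")
  m$E[[1]] <- c(1, 0)   # static world
  b <- new_beliefs(m)
  b$s[[1]] <- matrix(onehot(3, 4), 4, 1)
  b$paths[[1]] <- c(1, 0)
  w <- speak(m, b, 1)
  expect_gt(w[3], 0.95)
  expect_equal(which.max(w), 3L)
  # an uncertain speaker is quiet (flat word)
  b$s[[1]] <- matrix(rep(1 / 4, 4), 4, 1)
  expect_equal(speak(m, b, 1), rep(1 / 4, 4), tolerance = 1e-3)
  # a permutation mapping permutes the word
  mp <- m
  mp$A[[2]] <- fedinf:::.det_counts(array(diag(4)[, c(2, 3, 4, 1)], c(4, 4)))
  mp <- refresh_model(mp)
  b$s[[1]] <- matrix(onehot(1, 4), 4, 1)
  expect_gt(speak(mp, b, 1)[2], 0.95)
})

test_that("the chorus is an order-invariant product of the other speakers", {
  expect_equal(chorus(list(c(0.8, 0.2), c(0.5, 0.5)), listener_index = 0),
               c(0.8, 0.2), tolerance = 1e-9)
  h <- chorus(list(c(0.8, 0.2), c(0.6, 0.4)), listener_index = 0)
  expect_equal(h, c(0.48, 0.08) / 0.56, tolerance = 1e-9)
  expect_equal(round(h, 3), c(0.857, 0.143))
  # sensory attenuation: the listener's own word is excluded
  expect_equal(chorus(list(c(0.9, 0.1), c(0.6, 0.4)), listener_index = 1),
               c(0.6, 0.4), tolerance = 1e-9)
  set.seed(6)
  ws <- lapply(1:4, function(i) softmax(rnorm(5)))
  expect_equal(chorus(ws, 2), chorus(rev(ws), 3), tolerance = 1e-12)
  # a lone listener hears an uninformative (flagged) word
  empty <- chorus(list(c(1, 0)), listener_index = 1)
  expect_equal(as.vector(empty), c(0.5, 0.5))
  expect_true(attr(empty, "empty"))
  # mixture mode averages instead
  expect_equal(chorus(list(c(0.8, 0.2), c(0.6, 0.4)), 0, mode = "mixture"),
               c(0.7, 0.3), tolerance = 1e-9)
})

test_that("silencing makes the channel uninformative and is idempotent", {
  m <- build_sentinel_agent(1)
  ms <- silence(m)
  for (g in 6:8) {
    cols <- dirichlet_mean(ms$A[[g]])
    expect_equal(max(cols) - min(cols), 0)
  }
  b <- new_beliefs(ms)
  b$s[[1]] <- matrix(onehot(4, 9), 9, 1)
  b$paths[[1]] <- c(1, 0, 0)
  expect_equal(speak(ms, b, 1), rep(1 / 9, 9), tolerance = 1e-12)
  expect_equal(silence(silence(m))$A[[6]], silence(m)$A[[6]])
  # a silenced heard word yields a constant likelihood message
  msg <- likelihood_message(ms$A[[6]], softmax(rnorm(9)), list(rep(1 / 9, 9)), 1)
  expect_lt(max(msg) - min(msg), 1e-9)
})

test_that("one exchange round drives agents with different priors to consensus", {
  mw <- make_fixture("permutation_world")
  mw$E[[1]] <- c(1, 0)
  # very precise identity words so the channel itself adds no distortion
  mw$A[[2]] <- fedinf:::.det_counts(array(diag(4), c(4, 4)), 65536, 1 / 256)
  mw <- refresh_model(mw)
  Ds <- list(c(.6, .2, .1, .1), c(.1, .5, .2, .2), c(.25, .25, .25, .25))
  ms <- lapply(Ds, function(d) { m <- mw; m$D[[1]] <- d; refresh_model(m) })
  agents <- lapply(ms, new_beliefs)
  words <- lapply(1:3, function(i) speak(ms[[i]], agents[[i]], 1))
  post <- lapply(1:3, function(i) {
    h <- chorus(words, i)
    b <- infer_states(ms[[i]], agents[[i]],
                      list(list(signal = NULL, word = h)))
    b$s[[1]][, 1]
  })
  tv <- function(p, q) sum(abs(p - q)) / 2
  expect_lt(tv(post[[1]], post[[2]]), 1e-3)
  expect_lt(tv(post[[1]], post[[3]]), 1e-3)
  expect_lt(tv(post[[2]], post[[3]]), 1e-3)
  # and the consensus is the normalised product of all three priors
  target <- Reduce(`*`, Ds)
  target <- target / sum(target)
  expect_lt(tv(post[[1]], target), 1e-2)
})
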