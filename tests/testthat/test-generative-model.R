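# sentinel model factory and the true world process

test_that("sentinel agent has the declared structure and identity auditory maps", {
  m <- build_sentinel_agent(1)
  expect_length(m$factors, 4)
  expect_length(m$modalities, 8)
  a_loc <- m$A[[6]]
  expect_equal(dim(a_loc), c(9L, 9L))
  mean_loc <- dirichlet_mean(a_loc)
  expect_true(all(diag(mean_loc) > 0.99))
  # every B path slice is a permutation (deterministic dynamics)
  for (f in seq_along(m$B)) {
    for (u in seq_len(dim(m$B[[f]])[3])) {
      s <- m$B[[f]][, , u]
      expect_true(all(s %in% c(0, 1)))
      expect_equal(colSums(s), rep(1, ncol(s)))
    }
  }
})

test_that("naive and uniform auditory options set the stated counts", {
  m0 <- build_sentinel_agent(2, naive_auditory = TRUE, init_noise_sd = 0)
  for (g in 6:8) {
    expect_true(all(m0$A[[g]] == 1))
    expect_true(m0$modalities[[g]]$learnable)
  }
  set.seed(5)
  m1 <- build_sentinel_agent(2, naive_auditory = TRUE, init_noise_sd = 1)
  expect_true(all(m1$A[[6]] >= 1))
  expect_gt(stats::sd(m1$A[[6]]), 0)
  m64 <- build_sentinel_agent(3, uniform_auditory_counts = 64)
  for (g in 6:8) {
    expect_true(all(m64$A[[g]] == 64))
    cols <- dirichlet_mean(m64$A[[g]])
    expect_equal(max(cols) - min(cols), 0)
  }
})

test_that("the world process is cyclic and static where it should be", {
  w <- init_world(1, "clockwise", "near", "foe")
  expect_equal(w$location, 1L)
  expect_equal(w$gaze, rep(2L, 3))
  expect_equal(step_world(w)$location, 2L)
  w9 <- init_world(9, "clockwise", "close", "friend")
  expect_equal(step_world(w9)$location, 1L)
  for (k in 1:4) w <- step_world(w)
  expect_equal(w$location, 5L)
  expect_equal(w$proximity, 2L)  # unchanged within an episode
  ws <- init_world(5, "still", "close", "friend")
  for (k in 1:3) ws <- step_world(ws)
  expect_equal(ws$location, 5L)
  expect_error(init_world(10), "1..9")
  expect_error(init_world(3, motion = "sideways"), "expected one of")
})

test_that("visual geometry generates the described observations", {
  m <- build_sentinel_agent(1)  # home centre 2, gaze ahead fovea 2
  w <- init_world(2, "still", "near", "foe")
  o <- observe_environment(w, 1, m)
  expect_equal(o$foveal, onehot(3, 4))           # someone in the distance
  expect_equal(o$contrast_centre, onehot(2, 3))  # near contrast at centre
  expect_equal(o$contrast_left, onehot(3, 3))
  expect_equal(o$contrast_right, onehot(3, 3))
  expect_equal(o$proprioceptive, onehot(2, 3))
  # close subject at the fovea reveals the pose
  wc <- init_world(2, "still", "close", "foe")
  expect_equal(observe_environment(wc, 1, m)$foveal, onehot(2, 4))
  # subject outside the whole window: everything reads none
  wf <- init_world(6, "still", "close", "foe")
  of <- observe_environment(wf, 1, m)
  expect_equal(of$foveal, onehot(4, 4))
  expect_equal(of$contrast_centre, onehot(3, 3))
})

test_that("the three agents' reachable windows jointly cover the circle", {
  covered <- sort(unique(unlist(lapply(1:3, function(i) {
    m <- build_sentinel_agent(i)
    unlist(lapply(1:3, function(g) {
      fedinf:::.window(m$meta$home_centre, g, m$meta$gaze_shift,
                       m$meta$orientation)
    }))
  }))))
  expect_equal(covered, 1:9)
})

test_that("model validation catches malformed tensors", {
  expect_error(factor_spec("x", 2, 1, controllable = TRUE), "more than one")
  expect_error(modality_spec("w", 2, c(1, 2), channel = "communicative"),
               "exactly one parent")
  B_bad <- array(c(0.5, 0.4, 0.5, 0.6), c(2, 2, 1))
  B_bad[1, 1, 1] <- 0.7   # columns no longer sum to one
  expect_error(
    gen_model(list(factor_spec("s", 2)),
              list(modality_spec("o", 2, 1L)),
              A = list(matrix(1, 2, 2)), B = list(B_bad)),
    "sum to 1")
})
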