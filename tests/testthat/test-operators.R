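# elementary probabilistic operators

test_that("softmax normalises, matches closed forms and is shift-invariant", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(0, -1)), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(softmax(c(5, -3, 2), precision = 0), rep(1 / 3, 3))
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(6)
    expect_equal(softmax(x), softmax(x + 17.3), tolerance = 1e-12)
    expect_equal(sum(softmax(x, precision = runif(1, 0.1, 4))), 1)
  }
  expect_error(softmax(c(0, Inf)), "finite")
})

test_that("expected_log applies the digamma rule column-wise", {
  expect_equal(expected_log(matrix(c(1, 1), 2)), matrix(-1, 2),
               tolerance = 1e-12)
  expect_equal(expected_log(matrix(c(2, 2), 2)), matrix(-5 / 6, 2),
               tolerance = 1e-12)
  expect_equal(expected_log(matrix(7, 1)), matrix(0, 1))
  expect_error(expected_log(matrix(c(1, 0), 2)), "positive")
})

test_that("dirichlet_mean normalises columns and approaches exp(expected_log)", {
  expect_equal(dirichlet_mean(matrix(c(2, 6), 2)), matrix(c(0.25, 0.75), 2))
  a <- array(c(5, 0.5, 0.5, 5), c(2, 2))
  expect_equal(colSums(dirichlet_mean(a)), c(1, 1))
  # equality with exp(phi) only holds in the large-count limit
  gap <- function(k) {
    max(abs(dirichlet_mean(k * a) - exp(expected_log(k * a))))
  }
  expect_gt(gap(1), gap(100))
  expect_lt(gap(100), 0.01)
})

test_that("contract performs the generalised inner product", {
  expect_equal(contract(diag(2), list(c(0.3, 0.7)), skip_axis = 1),
               c(0.3, 0.7))
  u <- matrix(1 / 3, 3, 5)
  expect_equal(contract(u, list(rep(0.2, 5))), rep(1 / 3, 3))
  p <- diag(4)[, c(2, 3, 4, 1)]      # permutation
  expect_equal(contract(p, list(onehot(1, 4))), onehot(2, 4))
  expect_error(contract(diag(2), list(c(1, 0, 0))), "length")
})

test_that("outer_product builds unit-mass coincidence tensors", {
  x <- outer_product(list(onehot(1, 2), onehot(2, 3)))
  expect_equal(x[1, 2], 1)
  expect_equal(sum(x), 1)
  expect_equal(outer_product(list(c(0.5, 0.5), c(0.5, 0.5))),
               matrix(0.25, 2, 2))
  for (s in 1:4) {
    set.seed(s)
    vs <- lapply(c(2, 3, 4), function(n) softmax(rnorm(n)))
    expect_equal(sum(outer_product(vs)), 1, tolerance = 1e-12)
  }
})

test_that("categorical_kl is a proper divergence", {
  expect_equal(categorical_kl(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(categorical_kl(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  p <- c(0.7, 0.3); q <- c(0.4, 0.6)
  expect_gt(categorical_kl(p, q), 0)
  expect_false(isTRUE(all.equal(categorical_kl(p, q), categorical_kl(q, p))))
  expect_error(categorical_kl(c(0.5, 0.5), c(1, 0)), "support")
})

test_that("joint mutual information matches closed forms", {
  expect_equal(joint_mutual_information(matrix(1, 4, 4)), 0)
  expect_equal(joint_mutual_information(array(diag(9), c(9, 9))), log(9),
               tolerance = 1e-12)
  # 9 states onto 8 outcomes, states 5 and 6 sharing an outcome, uniform mass
  a <- matrix(0, 8, 9)
  for (j in 1:9) a[if (j <= 5) j else j - 1, j] <- 1
  expect_equal(sum(a), 9)
  expect_equal(joint_mutual_information(a), log(9) - (2 / 9) * log(2),
               tolerance = 1e-12)
  # invariant under permuting outcome labels
  set.seed(7)
  b <- matrix(rexp(36), 6)
  expect_equal(joint_mutual_information(b),
               joint_mutual_information(b[sample(6), ]), tolerance = 1e-12)
})

test_that("log_beta matches Gamma identities and is additive over columns", {
  expect_equal(log_beta(matrix(c(1, 1), 2)), 0)
  expect_equal(log_beta(matrix(c(5, 1), 2)), log(1 / 5), tolerance = 1e-12)
  expect_equal(log_beta(matrix(c(6, 1), 2)), log(1 / 6), tolerance = 1e-12)
  set.seed(2)
  c1 <- matrix(rexp(3) + 0.1, 3)
  c2 <- matrix(rexp(3) + 0.1, 3)
  expect_equal(log_beta(cbind(c1, c2)), log_beta(c1) + log_beta(c2),
               tolerance = 1e-12)
})

test_that("dirichlet_kl matches the standard closed form", {
  expect_equal(dirichlet_kl(matrix(c(2, 1), 2), matrix(c(1, 1), 2)),
               log(2) - 0.5, tolerance = 1e-12)
  set.seed(3)
  a <- matrix(rexp(6) + 0.2, 3)
  expect_equal(dirichlet_kl(a, a), 0, tolerance = 1e-12)
  expect_gt(dirichlet_kl(a, a + 0.5), 0)
})
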