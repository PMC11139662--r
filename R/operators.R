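#' Log floor used throughout the package
#'
#' Logarithms of probabilities are floored at `exp(-32)` so that exact zeros
#' in sparse likelihood tensors never produce `-Inf` inside fixed-point
#' sweeps. All information measures are reported in natural units (nats).
#'
#' @keywords internal
.eps <- exp(-32)

#' Floored natural logarithm
#' @param x numeric vector or array of non-negative values.
#' @return `log(pmax(x, exp(-32)))`, preserving dimensions.
#' @export
ln_eps <- function(x) {
  out <- log(pmax(x, .eps))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

.check_counts <- function(a, what = "counts") {
  if (!is.numeric(a) || length(a) == 0) {
    stop(what, " must be a non-empty numeric array", call. = FALSE)
  }
  if (any(!is.finite(a))) stop(what, " must be finite", call. = FALSE)
  if (any(a <= 0)) stop(what, " must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

# flatten an array to (outcome levels) x (parent combinations)
.as_mat <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  matrix(a, nrow = d[1L])
}

#' Softmax (normalised exponential)
#'
#' The sigma operator mapping log-probabilities (or negative expected free
#' energies) to a categorical distribution. Invariant under adding a constant
#' to `logits`; `precision` scales the logits before exponentiation, with
#' `precision -> 0` giving the uniform distribution.
#'
#' @param logits finite numeric vector.
#' @param precision positive scalar inverse temperature.
#' @return probability vector summing to one.
#' @examples
#' softmax(c(0, -1))
#' @export
softmax <- function(logits, precision = 1) {
  if (any(!is.finite(logits))) stop("logits must be finite", call. = FALSE)
  if (!is.numeric(precision) || length(precision) != 1 || precision < 0) {
    stop("precision must be a non-negative scalar", call. = FALSE)
  }
  x <- precision * logits
  x <- x - max(x)
  p <- exp(x)
  p / sum(p)
}

# internal fast softmax (no validation)
.softmax <- function(x) {
  x <- x - max(x)
  p <- exp(x)
  p / sum(p)
}

#' Expected log-likelihood of a Dirichlet count array
#'
#' The phi operator: for each column (over the outcome axis, always axis 1),
#' `digamma(a) - digamma(colsum(a))`, i.e. the expectation of the log of a
#' categorical parameter under its Dirichlet posterior.
#'
#' @param a strictly positive count array; axis 1 indexes outcome levels.
#' @return array of the same shape.
#' @export
expected_log <- function(a) {
  .check_counts(a)
  m <- .as_mat(a)
  out <- digamma(m) - rep(digamma(colSums(m)), each = nrow(m))
  dim(out) <- if (is.null(dim(a))) NULL else dim(a)
  out
}

#' Column-wise mean of a Dirichlet count array
#'
#' The mu operator: normalises each column (over the outcome axis) to sum to
#' one, giving the expected categorical likelihood.
#'
#' @inheritParams expected_log
#' @return array of the same shape with unit column sums.
#' @export
dirichlet_mean <- function(a) {
  .check_counts(a)
  m <- .as_mat(a)
  out <- m / rep(colSums(m), each = nrow(m))
  dim(out) <- if (is.null(dim(a))) NULL else dim(a)
  out
}

#' Tensor contraction against categorical distributions
#'
#' The generalised inner product: sums `tensor` weighted by the product of
#' the supplied distributions over all axes except `skip_axis`, returning the
#' vector along the skipped axis.
#'
#' @param tensor numeric array.
#' @param dists list of probability vectors, one per contracted axis. May be
#'   of length `ndim(tensor)` with the entry at `skip_axis` ignored (`NULL`),
#'   or of length `ndim(tensor) - 1` matching the non-skipped axes in order.
#' @param skip_axis axis to keep (default 1, the outcome axis).
#' @return numeric vector along `skip_axis`.
#' @export
contract <- function(tensor, dists, skip_axis = 1) {
  d <- dim(tensor)
  if (is.null(d)) d <- length(tensor)
  k <- length(d)
  if (skip_axis < 1 || skip_axis > k) stop("invalid skip_axis", call. = FALSE)
  if (length(dists) == k) dists <- dists[-skip_axis]
  if (length(dists) != k - 1) stop("dists must match contracted axes", call. = FALSE)
  other <- setdiff(seq_len(k), skip_axis)
  for (i in seq_along(other)) {
    if (length(dists[[i]]) != d[other[i]]) {
      stop("distribution length does not match axis ", other[i], call. = FALSE)
    }
  }
  if (k == 1) return(as.vector(tensor))
  m <- matrix(aperm(tensor, c(other, skip_axis)), ncol = d[skip_axis])
  w <- Reduce(function(x, y) as.vector(outer(x, y)), dists)
  as.vector(crossprod(m, w))
}

#' Outer product of probability vectors
#'
#' Builds the rank-1 tensor of joint coincidences; for normalised inputs the
#' entries sum to one, so a single observation contributes exactly one count.
#'
#' @param vectors list of numeric vectors (at least one).
#' @return array with one axis per vector.
#' @export
outer_product <- function(vectors) {
  if (!length(vectors)) stop("need at least one vector", call. = FALSE)
  out <- Reduce(`%o%`, vectors)
  if (is.null(dim(out))) dim(out) <- length(out)
  out
}

#' Kullback-Leibler divergence between categorical distributions
#'
#' @param p,q probability vectors of equal length; `q` must be positive
#'   wherever `p` is.
#' @return non-negative divergence in nats.
#' @export
categorical_kl <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  if (any(p > 0 & q <= 0)) stop("q must have support wherever p does", call. = FALSE)
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(q[i])))
}

.entropy <- function(p) {
  i <- p > 0
  -sum(p[i] * log(p[i]))
}

#' Mutual information of the joint distribution encoded by Dirichlet counts
#'
#' Normalises the count array over all elements, recovering the joint
#' distribution over outcomes and (combinations of) parent states, and
#' returns `I(o; s) = H(o) + H(s) - H(o, s)` in nats.
#'
#' @inheritParams expected_log
#' @return non-negative mutual information (nats).
#' @export
joint_mutual_information <- function(a) {
  # zeros are admissible here (0 log 0 = 0 in the entropies)
  if (any(!is.finite(a)) || any(a < 0) || sum(a) <= 0) {
    stop("counts must be non-negative with positive total", call. = FALSE)
  }
  m <- .as_mat(a)
  p <- m / sum(m)
  .entropy(rowSums(p)) + .entropy(colSums(p)) - .entropy(as.vector(p))
}

#' Sum of log-Beta functions over columns of a count array
#'
#' For each column of the outcome axis, `sum(lgamma(a_i)) - lgamma(sum(a_i))`,
#' summed over columns: the log normalising constant of the factorised
#' Dirichlet distribution.
#'
#' @inheritParams expected_log
#' @return scalar.
#' @export
log_beta <- function(a) {
  .check_counts(a)
  m <- .as_mat(a)
  sum(lgamma(m)) - sum(lgamma(colSums(m)))
}

#' KL divergence between factorised Dirichlet distributions
#'
#' Column-wise Dirichlet-to-Dirichlet KL divergence, summed over columns.
#' Used to score learning increments and structural complexity.
#'
#' @param a,b strictly positive count arrays of identical shape.
#' @return non-negative divergence (nats).
#' @export
dirichlet_kl <- function(a, b) {
  .check_counts(a); .check_counts(b)
  if (!identical(dim(a), dim(b)) && length(a) != length(b)) {
    stop("count arrays must share a shape", call. = FALSE)
  }
  ma <- .as_mat(a); mb <- .as_mat(b)
  a0 <- colSums(ma); b0 <- colSums(mb)
  sum(lgamma(a0)) - sum(lgamma(ma)) - sum(lgamma(b0)) + sum(lgamma(mb)) +
    sum((ma - mb) * (digamma(ma) - rep(digamma(a0), each = nrow(ma))))
}
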