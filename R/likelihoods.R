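#' Per-block minus log-likelihoods, gradients and likelihood anchors
#'
#' Each omics block contributes a data-type-specific minus log-likelihood of
#' the observations given its parameter matrix, with normalization constants
#' dropped:
#' \itemize{
#'   \item gaussian: \eqn{\frac{1}{2}(X - \Theta)^2} (unit variance),
#'   \item binary:   \eqn{-[X\Theta - \ln(1 + e^{\Theta})]} (Bernoulli-logit),
#'   \item poisson:  \eqn{-(X\Theta - e^{\Theta})} (Poisson with rate
#'     \eqn{e^{\Theta}}; the \eqn{\ln X!} term is dropped).
#' }
#' Masked entries contribute zero. Because constants are dropped, the
#' explained-variation statistic built from these quantities is invariant to
#' the convention.
#'
#' @param block An [omics_block()].
#' @param theta Numeric matrix of natural parameters, same shape as the
#'   block's data.
#'
#' @return `block_nll()` a finite scalar (non-negative for gaussian blocks);
#'   `block_nll_grad()` a matrix of the same shape as `theta` with zeros at
#'   masked entries.
#' @seealso [saturated_loglik()], [null_loglik()] for the anchors used by
#'   [explained_variation()].
#' @export
block_nll <- function(block, theta) {
  check_theta(block, theta)
  X <- block$data
  m <- block$mask
  val <- switch(block$type,
    gaussian = 0.5 * (X - theta)^2,
    binary   = -(X * theta - log1pexp(theta)),
    poisson  = -(X * theta - exp_clipped(theta))
  )
  sum(val[m])
}

#' @rdname block_nll
#' @export
block_nll_grad <- function(block, theta) {
  check_theta(block, theta)
  X <- block$data
  g <- switch(block$type,
    gaussian = theta - X,
    binary   = stats::plogis(theta) - X,
    poisson  = exp_clipped(theta) - X
  )
  g[!block$mask] <- 0
  g
}

#' Saturated and null log-likelihood anchors
#'
#' `saturated_loglik()` returns the unconstrained entry-wise maximum of the
#' (constant-dropped) log-likelihood: 0 for gaussian (attained at
#' \eqn{\Theta = X}), 0 for binary (the limit \eqn{\Theta \to \pm\infty}
#' matching the observation) and \eqn{X \ln X - X} (0 when \eqn{X = 0}) for
#' poisson, attained at \eqn{\Theta = \ln X}. `null_loglik()` evaluates the
#' log-likelihood at \eqn{\Theta = 0}, the rank-zero model. Both sum over
#' observed entries only and anchor the explained-variation statistic.
#'
#' @param block An [omics_block()].
#' @return A scalar log-likelihood (not negated).
#' @export
saturated_loglik <- function(block) {
  X <- block$data[block$mask]
  switch(block$type,
    gaussian = 0,
    binary   = 0,
    poisson  = {
      pos <- X > 0
      sum(X[pos] * log(X[pos]) - X[pos])
    }
  )
}

#' @rdname saturated_loglik
#' @export
null_loglik <- function(block) {
  X <- block$data[block$mask]
  n <- length(X)
  switch(block$type,
    gaussian = -0.5 * sum(X^2),
    binary   = -n * log(2),
    poisson  = -n
  )
}

# ---- stacked (multi-block) versions -----------------------------------------

stacked_nll <- function(blocks, theta, offsets) {
  s <- 0
  for (k in seq_along(blocks))
    s <- s + block_nll(blocks[[k]], theta[offsets[[k]], , drop = FALSE])
  s
}

stacked_grad <- function(blocks, theta, offsets) {
  g <- matrix(0, nrow(theta), ncol(theta))
  for (k in seq_along(blocks))
    g[offsets[[k]], ] <- block_nll_grad(blocks[[k]], theta[offsets[[k]], , drop = FALSE])
  g
}

# ---- internal helpers -------------------------------------------------------

check_theta <- function(block, theta) {
  if (!is.matrix(theta) || !identical(dim(theta), dim(block$data)))
    stop("theta shape ", paste(dim(theta), collapse = "x"),
         " does not match block '", block$name, "' shape ",
         paste(dim(block$data), collapse = "x"))
  if (!all(is.finite(theta)))
    stop("non-finite entries in theta for block '", block$name, "'")
  invisible(TRUE)
}

# Numerically stable ln(1 + e^x): x + log1p(e^-x) for large x.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

# e^x with the exponent clipped at 50 to avoid overflow; the shrinkage solver
# keeps parameters moderate so the clip is a guard, not an operating regime.
exp_clipped <- function(x, cap = 50) {
  if (any(x > cap)) {
    warning("natural parameter exceeds ", cap, "; exponent clipped",
            call. = FALSE)
    x <- pmin(x, cap)
  }
  exp(x)
}
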