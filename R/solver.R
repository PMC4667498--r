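#' Singular value shrinkage operator
#'
#' Soft-thresholds the singular values of a matrix: with \eqn{M = U\Sigma V^T},
#' returns \eqn{U D_\mu(\Sigma) V^T} where each singular value \eqn{\lambda}
#' maps to \eqn{\lambda - \mu} if \eqn{\lambda > \mu} and to 0 otherwise.
#' This is the proximal operator of the nuclear norm: the unique minimizer of
#' \eqn{\frac{1}{2}\|Z - M\|_F^2 + \mu \|Z\|_*}.
#'
#' @param M Numeric matrix with finite entries.
#' @param mu Non-negative shrinkage level.
#' @return Matrix of the same shape as `M`.
#' @export
svt_shrink <- function(M, mu) {
  if (!all(is.finite(M))) stop("non-finite entries in matrix passed to svt_shrink")
  if (mu < 0) stop("mu must be non-negative")
  sv <- tryCatch(svd(M), error = function(e)
    stop("SVD failed in svt_shrink: ", conditionMessage(e)))
  svt_reconstruct(sv, mu)
}

# Rebuild U D_mu(Sigma) V^T from a precomputed SVD.
svt_reconstruct <- function(sv, mu) {
  d <- pmax(sv$d - mu, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(sv$u), nrow(sv$v)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Choose the shrinkage level from the current singular spectrum
#'
#' The shrinkage level is the (rank + 1)-th largest singular value, so that
#' after shrinkage the matrix has rank at most `rank` while the retained
#' singular values are perturbed as little as possible. When fewer than
#' rank + 1 singular values exist the level is 0 (no shrinkage needed).
#' Ties (\eqn{\sigma_r = \sigma_{r+1}}) are applied verbatim, so the shrunken
#' rank can fall below `rank`.
#'
#' @param singular_values Numeric vector sorted in descending order, all
#'   non-negative.
#' @param rank Target rank, a positive integer.
#' @return Non-negative scalar shrinkage level.
#' @export
select_mu <- function(singular_values, rank) {
  if (rank < 1) stop("rank must be at least 1")
  if (is.unsorted(rev(singular_values)))
    stop("singular_values must be sorted in descending order")
  if (length(singular_values) <= rank) return(0)
  max(singular_values[rank + 1], 0)
}

#' Fit the nuclear-norm-regularized low-rank model
#'
#' Minimizes the stacked minus log-likelihood over all blocks plus a nuclear
#' norm penalty, \eqn{L(\Theta) + \mu |\Theta|_*}, by a singular value
#' thresholding scheme: starting from \eqn{\Theta = 0}, each iteration takes
#' one gradient step of length `step` on the unpenalized likelihood, then
#' applies the singular value shrinkage operator with \eqn{\mu} re-chosen as
#' the (rank + 1)-th largest singular value of the post-gradient-step matrix.
#' The objective is convex, so any starting point reaches the global optimum;
#' step lengths in \[0.5, 2\] guarantee convergence and the default is 0.5.
#'
#' @param blocks A single [omics_block()] or a list of blocks sharing an
#'   identical, identically ordered sample set.
#' @param rank Target rank r of the parameter matrix, also the dimension of
#'   the reduced subspace. Must satisfy
#'   `1 <= rank <= min(total features, samples)`; at the upper limit no
#'   shrinkage is applied and the model is unconstrained.
#' @param step Gradient step length \eqn{\delta}; a warning is raised outside
#'   \[0.5, 2\].
#' @param tol Convergence threshold on the relative change of the penalized
#'   objective between iterations.
#' @param max_iter Iteration cap.
#' @param center Logical: center each gaussian feature (row) at its observed
#'   mean before fitting. Off by default; real-valued inputs are modeled with
#'   unit variance as supplied.
#' @param scale. Logical: additionally standardize gaussian rows to unit
#'   standard deviation. Off by default.
#' @param verbose Print per-iteration objective and shrinkage level.
#'
#' @return An object of class `"lra_fit"` with elements:
#'   \item{theta}{fitted stacked parameter matrix (features x samples);}
#'   \item{rank}{the target rank;}
#'   \item{offsets}{row indices of each block within `theta`;}
#'   \item{objective_trace, mu_trace, ev_trace, rank_trace}{per-iteration
#'     penalized objective, shrinkage level, explained variation, and
#'     numerical rank of the shrunken parameter matrix;}
#'   \item{loglik, loglik_sat, loglik_null}{the model log-likelihood at the
#'     optimum and its saturated / rank-zero anchors;}
#'   \item{explained_variation}{scalar in \[0, 1\];}
#'   \item{singular_values}{top rank + 1 singular values of `theta` at
#'     convergence;}
#'   \item{n_iter, converged}{iterations used and convergence flag.}
#'
#' @examples
#' sim <- simulate_multiomics(simulation_spec(n_samples = 30,
#'   block_specs = list(expr = c(40, "gaussian")), true_rank = 2, seed = 1))
#' fit <- lra_fit(sim$blocks, rank = 2)
#' fit$explained_variation
#' @export
lra_fit <- function(blocks, rank, step = 0.5, tol = 1e-6, max_iter = 100,
                    center = FALSE, scale. = FALSE, verbose = FALSE) {
  blocks <- check_blocks(blocks)
  if (center || scale.) blocks <- lapply(blocks, standardize_block,
                                         center = center, scale. = scale.)
  n <- ncol(blocks[[1]]$data)
  p <- sum(vapply(blocks, function(b) nrow(b$data), integer(1)))
  if (rank < 1 || rank != round(rank)) stop("rank must be a positive integer")
  if (rank > min(p, n))
    stop("rank must be at most min(total features, samples) = ", min(p, n))
  if (step < 0.5 || step > 2)
    warning("step length ", step, " is outside [0.5, 2], the range with ",
            "guaranteed convergence", call. = FALSE)
  if (tol <= 0 || max_iter < 1) stop("tol must be > 0 and max_iter >= 1")

  offsets <- block_offsets(blocks)
  ll_sat <- sum(vapply(blocks, saturated_loglik, numeric(1)))
  ll_null <- sum(vapply(blocks, null_loglik, numeric(1)))

  theta <- matrix(0, p, n)
  obj_trace <- mu_trace <- ev_trace <- numeric(max_iter)
  rank_trace <- integer(max_iter)
  obj_prev <- Inf
  converged <- FALSE
  n_iter <- 0L

  for (t in seq_len(max_iter)) {
    n_iter <- t
    g <- stacked_grad(blocks, theta, offsets)
    theta1 <- theta - step * g
    sv <- svd(theta1)
    mu <- select_mu(sv$d, rank)
    theta <- svt_reconstruct(sv, mu)
    d_shr <- pmax(sv$d - mu, 0)
    rank_trace[t] <- sum(d_shr > 1e-8 * max(d_shr[1], .Machine$double.eps))

    nll <- stacked_nll(blocks, theta, offsets)
    obj <- nll + mu * sum(pmax(sv$d - mu, 0))
    obj_trace[t] <- obj
    mu_trace[t] <- mu
    ev_trace[t] <- explained_variation(-nll, ll_sat, ll_null)
    if (verbose)
      message(sprintf("iter %3d  objective %.6g  mu %.6g  ev %.4f",
                      t, obj, mu, ev_trace[t]))
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) / max(1, abs(obj_prev)) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  sv_final <- svd(theta, nu = 0, nv = 0)$d
  loglik <- -stacked_nll(blocks, theta, offsets)
  rownames(theta) <- unlist(lapply(blocks, `[[`, "feature_ids"))
  colnames(theta) <- blocks[[1]]$sample_ids

  structure(
    list(theta = theta, rank = rank, offsets = offsets,
         block_names = vapply(blocks, `[[`, character(1), "name"),
         sample_ids = blocks[[1]]$sample_ids,
         objective_trace = obj_trace[seq_len(n_iter)],
         mu_trace = mu_trace[seq_len(n_iter)],
         ev_trace = ev_trace[seq_len(n_iter)],
         rank_trace = rank_trace[seq_len(n_iter)],
         loglik = loglik, loglik_sat = ll_sat, loglik_null = ll_null,
         explained_variation = explained_variation(loglik, ll_sat, ll_null),
         singular_values = sv_final[seq_len(min(rank + 1, length(sv_final)))],
         n_iter = n_iter, converged = converged,
         step = step, tol = tol),
    class = "lra_fit"
  )
}

#' @export
print.lra_fit <- function(x, ...) {
  cat(sprintf(paste0("low-rank multi-omics fit: rank %d, %d x %d parameter ",
                     "matrix\n  blocks: %s\n  explained variation %.4f, ",
                     "%d iterations (%s)\n"),
              x$rank, nrow(x$theta), ncol(x$theta),
              paste(x$block_names, collapse = ", "),
              x$explained_variation, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Explained variation of a rank-r fit
#'
#' Normalizes the model log-likelihood between the rank-zero anchor
#' (\eqn{\Theta = 0}) and the saturated (unconstrained) anchor:
#' \deqn{1 - \frac{\mathcal{L}_{sat} - \mathcal{L}_r}{\mathcal{L}_{sat} -
#'   \mathcal{L}_0}}
#' so the rank-zero model scores 0 and the saturated model scores 1. The
#' statistic guides the choice of rank: its curve over r typically rises
#' steeply up to the intrinsic rank of the data and flattens beyond it. A
#' degenerate denominator (constant data, saturated equal to null) is defined
#' as 1. Tiny numeric excursions outside \[0, 1\] are clipped.
#'
#' @param loglik_r Log-likelihood of the rank-r fit.
#' @param loglik_sat,loglik_null Saturated and rank-zero anchors, see
#'   [saturated_loglik()] and [null_loglik()].
#' @return Scalar in \[0, 1\].
#' @export
explained_variation <- function(loglik_r, loglik_sat, loglik_null) {
  vals <- c(loglik_r, loglik_sat, loglik_null)
  if (!all(is.finite(vals))) stop("non-finite log-likelihood input")
  den <- loglik_sat - loglik_null
  if (den <= 0) return(1)
  min(max((loglik_r - loglik_null) / den, 0), 1)
}

#' Explained-variation curve over candidate ranks
#'
#' Fits the model once per candidate rank and returns the explained-variation
#' curve. The desirable rank is read off the curve's elbow (the point after
#' which the gain in model fitness slows markedly); [elbow_rank()] locates the
#' maximum-curvature point, but visual inspection of the curve is equally
#' valid and no automatic choice is imposed.
#'
#' @param blocks Blocks as for [lra_fit()].
#' @param ranks Positive integer vector of candidate ranks, sorted ascending.
#' @inheritParams lra_fit
#' @param ... Further arguments passed to [lra_fit()].
#' @return A data.frame with columns `rank`, `explained_variation`, `loglik`,
#'   `n_iter` and `converged`, one row per candidate rank.
#' @export
scan_rank <- function(blocks, ranks, step = 0.5, tol = 1e-6, max_iter = 100,
                      ...) {
  if (!length(ranks) || any(ranks < 1) || is.unsorted(ranks, strictly = TRUE))
    stop("ranks must be positive integers sorted in strictly ascending order")
  rows <- lapply(ranks, function(r) {
    fit <- tryCatch(
      lra_fit(blocks, rank = r, step = step, tol = tol, max_iter = max_iter,
              ...),
      error = function(e) stop("rank ", r, ": ", conditionMessage(e)))
    data.frame(rank = r, explained_variation = fit$explained_variation,
               loglik = fit$loglik, n_iter = fit$n_iter,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Locate the elbow of an explained-variation curve
#'
#' Prepends the rank-zero anchor (explained variation 0) and returns the rank
#' with the largest negative second difference of the curve, i.e. the point
#' of maximum curvature where the fitness gain slows.
#'
#' @param scan A data.frame from [scan_rank()] with consecutive integer ranks
#'   starting at 1.
#' @return The elbow rank (integer).
#' @export
elbow_rank <- function(scan) {
  r <- scan$rank
  if (r[1] != 1 || any(diff(r) != 1))
    stop("elbow detection needs consecutive ranks starting at 1")
  ev <- c(0, scan$explained_variation) # rank-0 anchor
  if (length(ev) < 3) stop("need at least two ranks to locate an elbow")
  gains <- diff(ev)
  # drop in slope after each rank; the elbow maximizes it
  curv <- gains[-length(gains)] - gains[-1]
  r[which.max(curv)]
}

# Optional per-feature centering / standardization of gaussian blocks, using
# observed entries only. Non-gaussian blocks pass through untouched.
standardize_block <- function(block, center = TRUE, scale. = FALSE) {
  if (block$type != "gaussian") return(block)
  X <- block$data
  for (i in seq_len(nrow(X))) {
    o <- block$mask[i, ]
    if (!any(o)) next
    if (center) X[i, o] <- X[i, o] - mean(X[i, o])
    if (scale.) {
      s <- stats::sd(X[i, o])
      if (is.finite(s) && s > 0) X[i, o] <- X[i, o] / s
    }
  }
  omics_block(X, block$type, name = block$name, mask = block$mask)
}
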