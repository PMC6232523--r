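#' Generate a balanced Q-matrix
#'
#' Builds the balanced item-by-attribute designs of the recovery study: with
#' 3 attributes the items split as evenly as possible between one- and
#' two-attribute items; with 4 or 5 attributes between two- and
#' three-attribute items.  Within each complexity level the attribute
#' combinations are cycled so every attribute appears in (near-)equal counts,
#' and the cycling start and row order are shuffled under the current RNG
#' state (or `seed`).  The result always satisfies the Q-matrix invariants;
#' an infeasible request (fewer items than attributes, or a draw that leaves
#' an attribute unmeasured) is an error.
#'
#' @param A number of attributes.
#' @param I number of items (default 30).
#' @param seed optional seed.
#' @return validated I x A Q-matrix.
#' @export
sim_q_matrix <- function(A, I = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (I < A) {
    stop(sprintf("cannot cover %d attributes with %d items", A, I),
         call. = FALSE)
  }
  sizes <- if (A == 1) c(1L, 1L) else if (A <= 3) c(1L, 2L) else c(2L, 3L)
  n1 <- ceiling(I / 2)
  n2 <- I - n1
  combos <- function(k) {
    cmb <- utils::combn(A, min(k, A))
    lst <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    lst[sample.int(length(lst))]
  }
  pick <- function(lst, n) lst[((seq_len(n) - 1L) %% length(lst)) + 1L]
  rows <- c(pick(combos(sizes[1L]), n1), pick(combos(sizes[2L]), n2))
  rows <- rows[sample.int(I)]
  q <- matrix(0, I, A, dimnames = list(NULL, paste0("A", seq_len(A))))
  for (i in seq_len(I)) q[i, rows[[i]]] <- 1
  if (any(colSums(q) == 0)) {
    stop("generated Q-matrix leaves an attribute unmeasured; increase I",
         call. = FALSE)
  }
  as_qmatrix(q)
}

#' Generate correlated binary attribute profiles
#'
#' Person profiles are produced by thresholding a multivariate normal draw at
#' zero: latent scores come from \eqn{MV(0, \Sigma)} with unit diagonal and
#' off-diagonal correlations drawn uniformly from `corr_range`, and attribute
#' \eqn{a} is mastered when the latent score is positive.  If a drawn
#' \eqn{\Sigma} is not positive definite it is projected to the nearest
#' correlation matrix (a rare event for 4-5 attributes with correlations in
#' `[0.7, 0.9]`).
#'
#' @param N number of persons.
#' @param A number of attributes.
#' @param corr_range range of the pairwise latent correlations.
#' @param seed optional seed.
#' @return list with `alpha` (N x A binary profile matrix) and `sigma` (the
#'   latent correlation matrix actually used).
#' @export
sim_attributes <- function(N, A, corr_range = c(0.7, 0.9), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(corr_range > -1), all(corr_range < 1))
  sigma <- NULL
  for (try in 1:10) {
    s <- diag(A)
    if (A > 1) {
      rho <- stats::runif(A * (A - 1) / 2, corr_range[1L], corr_range[2L])
      s[upper.tri(s)] <- rho
      s[lower.tri(s)] <- t(s)[lower.tri(s)]
    }
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
      sigma <- s
      break
    }
    proj <- tryCatch(
      as.matrix(Matrix::nearPD(s, corr = TRUE)$mat),
      error = function(e) NULL)
    if (!is.null(proj)) {
      sigma <- proj
      break
    }
  }
  if (is.null(sigma)) stop("could not build a positive-definite correlation matrix",
                           call. = FALSE)
  z <- MASS::mvrnorm(N, mu = rep(0, A), Sigma = sigma)
  z <- matrix(z, nrow = N)
  alpha <- (z > 0) * 1
  colnames(alpha) <- paste0("A", seq_len(A))
  list(alpha = alpha, sigma = sigma)
}

#' Data-generating item parameters of the recovery study
#'
#' High-quality items set main effects to 2, intercepts to -1.5 and every
#' interaction effect (any order) to 0.5; low-quality items use 0.2, -0.5,
#' and 0.1.
#'
#' @param q Q-matrix.
#' @param quality `"high"` or `"low"`.
#' @return per-item parameter list in the package's canonical layout.
#' @export
true_item_params <- function(q, quality = c("high", "low")) {
  quality <- match.arg(quality)
  val <- switch(quality,
                high = c(intercept = -1.5, main = 2, interaction = 0.5),
                low = c(intercept = -0.5, main = 0.2, interaction = 0.1))
  lcdm_start_params(q, intercept = val[["intercept"]], main = val[["main"]],
                    interaction = val[["interaction"]])
}

#' Simulate item responses from an LCDM
#'
#' Responses are independent Bernoulli draws with success probability given
#' by the item response function at each person's attribute profile.
#'
#' @param params per-item parameter list.
#' @param q Q-matrix.
#' @param alpha N x A binary profile matrix.
#' @param seed optional seed.
#' @return N x I binary response matrix.
#' @export
sim_responses <- function(params, q, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- as_qmatrix(q)
  profiles <- attribute_profiles(ncol(q))
  pi <- compute_pi(params, lcdm_designs(q, profiles))
  # map each person's profile to its class index (attribute 1 = MSB)
  cls <- drop(alpha %*% 2^((ncol(q) - 1):0)) + 1L
  p <- pi[cls, , drop = FALSE]
  y <- matrix(as.numeric(stats::runif(length(p)) < p), nrow = nrow(alpha))
  colnames(y) <- paste0("I", seq_len(nrow(q)))
  y
}

#' Relative bias and root mean squared error of parameter estimates
#'
#' `rbias()` is `scale * mean((estimate - truth) / truth)`; parameters with
#' zero truth cannot be scaled and are dropped (with a warning).  `rmse()` is
#' `scale * sqrt(mean((estimate - truth)^2))`.  The default `scale = 100`
#' reports both on a percent-like scale; pass `scale = 1` for the raw scale.
#'
#' @param estimate,truth numeric vectors of equal length (estimates pooled
#'   over replications and parameters of one type).
#' @param scale reporting scale factor.
#' @return scalar.
#' @export
rbias <- function(estimate, truth, scale = 100) {
  stopifnot(length(estimate) == length(truth))
  keep <- truth != 0
  if (!all(keep)) {
    warning(sprintf("%d parameter(s) with zero truth dropped from RBIAS",
                    sum(!keep)))
  }
  scale * mean((estimate[keep] - truth[keep]) / truth[keep])
}

#' @rdname rbias
#' @export
rmse <- function(estimate, truth, scale = 100) {
  stopifnot(length(estimate) == length(truth))
  scale * sqrt(mean((estimate - truth)^2))
}
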