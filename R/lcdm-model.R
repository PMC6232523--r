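#' Enumerate all attribute profiles
#'
#' Lists the \eqn{2^A} binary mastery profiles defining the latent classes of
#' a diagnostic classification model.  Row \eqn{c} (1-based) is the
#' \eqn{A}-bit binary expansion of \eqn{c - 1} with attribute 1 as the most
#' significant bit, so the first row is the all-zero profile and the last row
#' the all-ones profile.  This order is fixed throughout the package so class
#' labels are stable across runs.
#'
#' @param A number of attributes (positive integer).
#' @return a \eqn{2^A \times A} binary matrix with columns `A1`, ..., `AA`.
#' @examples
#' attribute_profiles(2)
#' @export
attribute_profiles <- function(A) {
  stopifnot(length(A) == 1L, A >= 1, A == round(A))
  C <- 2L^A
  c_idx <- 0:(C - 1L)
  prof <- vapply(seq_len(A), function(a) (c_idx %/% 2L^(A - a)) %% 2L, numeric(C))
  prof <- matrix(prof, nrow = C, ncol = A)
  colnames(prof) <- paste0("A", seq_len(A))
  prof
}

#' Validate a Q-matrix
#'
#' A Q-matrix is the item-by-attribute binary incidence matrix declaring which
#' attributes each item measures.  Every entry must be 0 or 1, every item must
#' measure at least one attribute, and every attribute must be measured by at
#' least one item.
#'
#' @param q matrix or data frame, items in rows, attributes in columns.
#' @return the validated numeric matrix with attribute column names.
#' @export
as_qmatrix <- function(q) {
  q <- as_binary_matrix(q, "Q-matrix")
  zr <- which(rowSums(q) == 0)
  if (length(zr)) {
    stop(sprintf("Q-matrix row %d measures no attribute", zr[1L]), call. = FALSE)
  }
  zc <- which(colSums(q) == 0)
  if (length(zc)) {
    stop(sprintf("Q-matrix column %d is measured by no item", zc[1L]), call. = FALSE)
  }
  if (is.null(colnames(q))) colnames(q) <- paste0("A", seq_len(ncol(q)))
  q
}

# canonical subset order for the attributes measured by one item:
# singletons in ascending attribute index, then pairs in lexicographic
# order, then triples, ...  Returns a list of integer vectors.
item_subsets <- function(attrs) {
  attrs <- sort(as.integer(attrs))
  K <- length(attrs)
  if (K == 1L) return(list(attrs))
  out <- list()
  for (k in seq_len(K)) {
    cmb <- utils::combn(attrs, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

subset_label <- function(s) paste(s, collapse = "x")

# parameter labels for one item: "0" (intercept) then subset labels
item_param_labels <- function(attrs) {
  c("0", vapply(item_subsets(attrs), subset_label, character(1)))
}

#' Build the design vector of one latent class on one item
#'
#' The linear predictor of the LCDM for class profile \eqn{\alpha} on item
#' \eqn{i} is \eqn{\lambda_{i,0} + \lambda_i^\top h(\alpha, q_i)}.  This
#' returns \eqn{h(\alpha, q_i)}: one binary element per nonempty subset of the
#' attributes measured by the item (canonical order: singletons ascending,
#' then pairs, ...), equal to 1 iff the profile masters every attribute of the
#' subset.
#'
#' @param profile binary mastery vector of length \eqn{A}.
#' @param q_row binary Q-matrix row of length \eqn{A}.
#' @return named binary vector over the item's effect labels (no intercept).
#' @examples
#' build_design_vector(c(0, 1, 1), c(0, 1, 1))
#' @export
build_design_vector <- function(profile, q_row) {
  if (length(profile) != length(q_row)) {
    stop("profile and q_row must have the same length", call. = FALSE)
  }
  attrs <- which(q_row == 1)
  if (!length(attrs)) stop("item measures no attribute", call. = FALSE)
  subsets <- item_subsets(attrs)
  h <- vapply(subsets, function(s) prod(profile[s] * q_row[s]), numeric(1))
  names(h) <- vapply(subsets, subset_label, character(1))
  h
}

# full design matrix of one item over a profile space: C x 2^K, first
# column the intercept, remaining columns the canonical subsets
item_design <- function(attrs, profiles) {
  subsets <- item_subsets(attrs)
  X <- cbind(1, vapply(subsets, function(s) {
    apply(profiles[, s, drop = FALSE], 1L, prod)
  }, numeric(nrow(profiles))))
  colnames(X) <- c("0", vapply(subsets, subset_label, character(1)))
  X
}

# design matrices for all items (list of C x 2^{K_i} matrices)
lcdm_designs <- function(q, profiles = attribute_profiles(ncol(q))) {
  lapply(seq_len(nrow(q)), function(i) item_design(which(q[i, ] == 1), profiles))
}

#' Default starting item parameters
#'
#' Intercepts at -1, main effects at +1, interaction effects at 0: a weakly
#' monotone start in the style of common diagnostic-model software.
#'
#' @param q Q-matrix.
#' @param intercept,main,interaction starting values by parameter type.
#' @return list with one named numeric vector per item (label `"0"` is the
#'   intercept; effect labels such as `"2"` or `"2x3"` name attribute subsets).
#' @export
lcdm_start_params <- function(q, intercept = -1, main = 1, interaction = 0) {
  q <- as_qmatrix(q)
  lapply(seq_len(nrow(q)), function(i) {
    labs <- item_param_labels(which(q[i, ] == 1))
    val <- ifelse(labs == "0", intercept,
                  ifelse(grepl("x", labs, fixed = TRUE), interaction, main))
    stats::setNames(val, labs)
  })
}

# parameter type by label: intercept / main / interaction
param_type <- function(labels) {
  ifelse(labels == "0", "intercept",
         ifelse(grepl("x", labels, fixed = TRUE), "interaction", "main"))
}

# pack a per-item parameter list into one named vector (items ascending,
# canonical subset order within item) and back
pack_params <- function(params) {
  v <- unlist(lapply(seq_along(params), function(i) {
    stats::setNames(params[[i]], paste0("i", i, ".", names(params[[i]])))
  }))
  v
}

unpack_params <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (i in seq_along(skeleton)) {
    p <- length(skeleton[[i]])
    out[[i]][] <- vec[pos + seq_len(p)]
    pos <- pos + p
  }
  out
}

#' Item response probability of the LCDM
#'
#' Evaluates \eqn{\pi = \mathrm{logistic}(\lambda_0 + \lambda^\top h)} for one
#' item, one class.
#'
#' @param params_i named parameter vector of the item (intercept label `"0"`
#'   first, then effects in canonical subset order).
#' @param design design vector as returned by [build_design_vector()].
#' @return probability strictly inside (0, 1).
#' @examples
#' h <- build_design_vector(c(1, 0, 0), c(1, 0, 0))
#' item_response_probability(c("0" = -1.5, "1" = 2), h)
#' @export
item_response_probability <- function(params_i, design) {
  if (any(!is.finite(params_i))) stop("non-finite item parameters", call. = FALSE)
  if (length(design) != length(params_i) - 1L) {
    stop("design vector does not match the item's parameter layout", call. = FALSE)
  }
  eta <- unname(params_i[1L]) + sum(params_i[-1L] * design)
  clip_prob(stats::plogis(eta))
}

#' Class-by-item response probability matrix
#'
#' @param params per-item parameter list (see [lcdm_start_params()]).
#' @param q Q-matrix.
#' @param profiles profile space; defaults to [attribute_profiles()].
#' @return \eqn{C \times I} matrix of correct-response probabilities.
#' @export
class_item_probability_matrix <- function(params, q,
                                          profiles = attribute_profiles(ncol(q))) {
  designs <- lcdm_designs(q, profiles)
  compute_pi(params, designs)
}

# internal fast path: pi from params + precomputed designs
compute_pi <- function(params, designs) {
  C <- nrow(designs[[1L]])
  pi <- vapply(seq_along(params), function(i) {
    stats::plogis(clip_logit(drop(designs[[i]] %*% params[[i]])))
  }, numeric(C))
  clip_prob(matrix(pi, nrow = C))
}

# N x C matrix of per-class response log-likelihoods
class_loglik <- function(y, pi) {
  lp <- log(pi)
  lq <- log1p(-pi)
  L <- y %*% t(lp - lq)
  sweep(L, 2L, rowSums(lq), "+")
}

#' Marginal log-likelihood of an LCDM
#'
#' Sums, over persons, the log of the class-probability-weighted response
#' likelihoods.  Computed in log-sum-exp form for numerical stability; the
#' result is identical (to ~1e-10) to the direct product form on small
#' problems and stays finite for response probabilities inside (0, 1).  A
#' person with zero likelihood under every class yields `-Inf`, not an error.
#'
#' @param y N x I binary response matrix.
#' @param pi C x I class-by-item probability matrix.
#' @param v class-probability vector of length C.
#' @return scalar log-likelihood (always <= 0).
#' @export
marginal_log_likelihood <- function(y, pi, v) {
  y <- as_binary_matrix(y, "response matrix")
  if (ncol(y) != ncol(pi)) stop("item counts of y and pi differ", call. = FALSE)
  if (length(v) != nrow(pi)) stop("length of v must match classes of pi", call. = FALSE)
  L <- class_loglik(y, clip_prob(pi))
  A <- sweep(L, 2L, log(v), "+")
  sum(row_log_sum_exp(A))
}
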