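#' Posterior attribute classification
#'
#' Turns posterior latent-class probabilities into person-level attribute
#' calls.  `marginal` holds the posterior mastery probability of each
#' attribute (\eqn{\sum_c H_{pc} \alpha_{ca}}).  The MAP profile is the
#' profile of the posterior-modal class (ties broken toward the lowest class
#' index); the EAP profile thresholds the marginal probabilities at 0.5, with
#' exact ties called as mastery.
#'
#' @param x an `lcdm` fit or an N x C posterior matrix.
#' @param profiles profile space (taken from the fit when `x` is one).
#' @return list of class `lcdm_classification` with `marginal`, `map`, and
#'   `eap` N x A matrices.
#' @export
lcdm_classify <- function(x, profiles = NULL) {
  if (inherits(x, "lcdm")) {
    profiles <- x$profiles
    x <- x$posterior
  }
  if (is.null(profiles)) stop("profiles must be supplied", call. = FALSE)
  if (ncol(x) != nrow(profiles)) {
    stop("posterior columns must match the number of profiles", call. = FALSE)
  }
  marginal <- x %*% profiles
  map <- profiles[max.col(x, ties.method = "first"), , drop = FALSE]
  eap <- (marginal >= 0.5) * 1
  structure(list(marginal = marginal, map = map, eap = eap),
            class = "lcdm_classification")
}

#' Attribute- and profile-level classification accuracy
#'
#' `attribute_accuracy()` is the mean agreement over all person-by-attribute
#' cells; `profile_accuracy()` the proportion of persons whose entire
#' attribute profile is recovered.  Profile accuracy can never exceed
#' attribute accuracy.
#'
#' @param truth,estimate N x A binary profile matrices.
#' @return proportion in `[0, 1]`.
#' @export
attribute_accuracy <- function(truth, estimate) {
  if (!all(dim(truth) == dim(estimate))) {
    stop("profile matrices must have the same shape", call. = FALSE)
  }
  mean(truth == estimate)
}

#' @rdname attribute_accuracy
#' @export
profile_accuracy <- function(truth, estimate) {
  if (!all(dim(truth) == dim(estimate))) {
    stop("profile matrices must have the same shape", call. = FALSE)
  }
  mean(rowSums(truth != estimate) == 0)
}
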