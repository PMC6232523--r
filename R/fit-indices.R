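# model-implied inter-item correlation matrix, by exact summation over the
# latent classes: E[Y_i] = sum_c v_c pi_ci, E[Y_i Y_j] = sum_c v_c pi_ci pi_cj
implied_correlations <- function(pi, v) {
  mu <- drop(crossprod(pi, v))
  eyy <- crossprod(pi * v, pi)
  covm <- eyy - tcrossprod(mu)
  sdv <- sqrt(mu * (1 - mu))
  corm <- covm / tcrossprod(sdv)
  diag(corm) <- 1
  corm
}

#' Global model-fit indices MADcor and SRMSR
#'
#' Compares observed and model-implied inter-item Pearson correlations over
#' all item pairs.  MADcor is the mean absolute deviation of the two
#' correlations; SRMSR the square root of the mean squared deviation.  The
#' model-implied moments are computed by exact summation over the latent
#' classes.  Items with zero observed variance cannot enter a correlation and
#' are excluded with a warning.
#'
#' @param object an `lcdm` fit, or a C x I probability matrix (then `v` and
#'   `y` must be given).
#' @param y response matrix (defaults to the one stored in the fit).
#' @param v class-probability vector when `object` is a probability matrix.
#' @return list of class `lcdm_fit_indices` with `madcor`, `srmsr`, and
#'   `excluded` (indices of zero-variance items).
#' @export
lcdm_fit_indices <- function(object, y = NULL, v = NULL) {
  if (inherits(object, "lcdm")) {
    pi <- object$pi
    v <- object$v
    if (is.null(y)) y <- object$y
  } else {
    pi <- object
    if (is.null(y) || is.null(v)) {
      stop("y and v are required when object is a probability matrix",
           call. = FALSE)
    }
  }
  y <- as_binary_matrix(y, "response matrix")
  keep <- which(apply(y, 2L, stats::var) > 0)
  excluded <- setdiff(seq_len(ncol(y)), keep)
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance item(s) from fit indices: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  if (length(keep) < 2L) stop("need at least two items with variance", call. = FALSE)
  obs <- stats::cor(y[, keep, drop = FALSE])
  imp <- implied_correlations(pi[, keep, drop = FALSE], v)
  d <- (obs - imp)[upper.tri(obs)]
  structure(list(madcor = mean(abs(d)), srmsr = sqrt(mean(d^2)),
                 excluded = excluded),
            class = "lcdm_fit_indices")
}

#' @export
print.lcdm_fit_indices <- function(x, ...) {
  cat(sprintf("MADcor %.4f | SRMSR %.4f\n", x$madcor, x$srmsr))
  invisible(x)
}
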