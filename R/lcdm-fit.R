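#' Control parameters for LCDM estimation
#'
#' @param max_iter iteration cap for the EM cycle (default 1000).
#' @param tol EM stop rule: absolute change of the marginal log-likelihood
#'   below `tol` (default 0.001) terminates the classical EM.
#' @param start optional per-item starting parameter list (see
#'   [lcdm_start_params()]); defaults to intercepts -1, main effects +1,
#'   interactions 0.
#' @param monotone if `TRUE`, the EM M-step clamps main effects to be
#'   non-negative (off by default).
#' @param gens DE generations run inside each M-step of the hybrid estimator.
#' @param stall,stall_tol hybrid stop rule: the marginal log-likelihood
#'   unchanged within `stall_tol` for `stall` consecutive EM iterations.
#' @param objective hybrid M-step objective: `"expected"` maximizes the
#'   expected complete-data log-likelihood per item (separable, one
#'   low-dimensional DE search per item); `"marginal"` maximizes the marginal
#'   log-likelihood with the class probabilities held fixed, over the joint
#'   parameter vector.
#' @param persist keep DE populations across EM iterations (default `TRUE`).
#' @param bound box constraint half-width for the DE search (default 20, i.e.
#'   every item parameter is kept inside \eqn{[-20, 20]}).
#' @param de a [de_control()] list for the M-step optimizer.
#' @return list of class `lcdm_control`.
#' @export
lcdm_control <- function(max_iter = 1000, tol = 0.001, start = NULL,
                         monotone = FALSE, gens = 20, stall = 10,
                         stall_tol = 1e-8,
                         objective = c("expected", "marginal"),
                         persist = TRUE, bound = 20, de = de_control()) {
  objective <- match.arg(objective)
  stopifnot(max_iter >= 1, tol > 0, gens >= 1, stall >= 1, bound > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol, start = start,
                 monotone = monotone, gens = as.integer(gens),
                 stall = as.integer(stall), stall_tol = stall_tol,
                 objective = objective, persist = persist, bound = bound,
                 de = de),
            class = "lcdm_control")
}

#' Fit a log-linear cognitive diagnostic model
#'
#' Estimates the LCDM — a logistic restricted latent class model whose linear
#' predictor contains an intercept plus main and interaction effects of the
#' attributes an item measures — by marginal maximum likelihood.  Two
#' estimators are available: the classical EM algorithm with a guarded Newton
#' M-step (`"em"`), and a hybrid (`"em-de"`) that keeps the EM structure but
#' performs the M-step item-parameter update with a derivative-free
#' Differential Evolution search inside a \eqn{\pm}`bound` box.  The hybrid
#' never suffers the vanishing-curvature failures of derivative-based
#' M-steps; the classical EM reports them as a structured non-convergence
#' instead of crashing.
#'
#' @param y binary response matrix (persons x items) or data frame.
#' @param q binary Q-matrix (items x attributes).
#' @param method `"em"` or `"em-de"`.
#' @param control list of [lcdm_control()] settings.
#' @param seed optional integer seed; with a fixed seed the `"em-de"` fit is
#'   fully reproducible (the `"em"` path is deterministic anyway).
#' @return object of class `lcdm` with components `params` (per-item named
#'   parameter vectors), `v` (class probabilities), `pi` (class-by-item
#'   response probabilities), `posterior`, `loglik`, `trace`, `niter`,
#'   `converged`, `reason`, and `failure` (structured M-step failure record
#'   or `NULL`).
#' @examples
#' set.seed(1)
#' q <- matrix(c(1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
#' truth <- true_item_params(q, "high")
#' alpha <- attribute_profiles(2)[sample(1:4, 150, replace = TRUE), ]
#' y <- sim_responses(truth, q, alpha)
#' fit <- lcdm(y, q, method = "em")
#' coef(fit)
#' @export
lcdm <- function(y, q, method = c("em", "em-de"), control = list(),
                 seed = NULL) {
  method <- match.arg(method)
  q <- as_qmatrix(q)
  y <- as_binary_matrix(y, "response matrix")
  if (ncol(y) != nrow(q)) {
    stop(sprintf("response matrix has %d items but the Q-matrix has %d",
                 ncol(y), nrow(q)), call. = FALSE)
  }
  ctrl <- if (inherits(control, "lcdm_control")) control
          else do.call(lcdm_control, control)
  if (!is.null(seed)) set.seed(seed)
  fit <- switch(method,
                em = fit_lcdm_em(y, q, ctrl),
                `em-de` = fit_lcdm_emde(y, q, ctrl))
  fit$call <- match.call()
  fit$method <- method
  fit$q <- q
  fit$y <- y
  fit$N <- nrow(y)
  fit$I <- nrow(q)
  fit$A <- ncol(q)
  fit$npar <- length(unlist(fit$params)) + nrow(fit$profiles) - 1L
  fit$control <- ctrl
  fit$seed <- seed
  class(fit) <- "lcdm"
  fit
}

#' @export
print.lcdm <- function(x, ...) {
  cat(sprintf("Log-linear cognitive diagnostic model (%s estimator)\n",
              x$method))
  cat(sprintf("  %d persons, %d items, %d attributes (%d latent classes)\n",
              x$N, x$I, x$A, nrow(x$profiles)))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)\n",
              x$loglik, x$niter, x$reason))
  if (!is.null(x$failure)) {
    cat(sprintf("  M-step failure: %s\n", x$failure$message))
  }
  invisible(x)
}

#' @export
coef.lcdm <- function(object, simplify = TRUE, ...) {
  if (simplify) pack_params(object$params) else object$params
}

#' @export
logLik.lcdm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' @export
summary.lcdm <- function(object, ...) {
  tabs <- lapply(seq_along(object$params), function(i) {
    b <- object$params[[i]]
    data.frame(item = i, label = names(b), type = param_type(names(b)),
               estimate = unname(b))
  })
  idx <- tryCatch(lcdm_fit_indices(object), warning = function(w) {
    suppressWarnings(lcdm_fit_indices(object))
  })
  out <- list(coefficients = do.call(rbind, tabs), v = object$v,
              loglik = object$loglik, npar = object$npar,
              aic = -2 * object$loglik + 2 * object$npar,
              bic = -2 * object$loglik + log(object$N) * object$npar,
              fit = idx, method = object$method, niter = object$niter,
              converged = object$converged, reason = object$reason,
              N = object$N, I = object$I, A = object$A)
  class(out) <- "summary.lcdm"
  out
}

#' @export
print.summary.lcdm <- function(x, digits = 3, ...) {
  cat(sprintf("LCDM (%s): %d persons, %d items, %d attributes\n",
              x$method, x$N, x$I, x$A))
  cat(sprintf("logLik %.3f on %d parameters | AIC %.1f | BIC %.1f\n",
              x$loglik, x$npar, x$aic, x$bic))
  cat(sprintf("%d iterations (%s)\n", x$niter, x$reason))
  cat(sprintf("fit: MADcor %.3f, SRMSR %.3f\n", x$fit$madcor, x$fit$srmsr))
  cat("\nItem parameters:\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat("\nClass probabilities:\n")
  print(round(x$v, digits))
  invisible(x)
}

#' @export
predict.lcdm <- function(object, newdata = NULL,
                         type = c("posterior", "mastery", "profile",
                                  "expected"),
                         rule = c("map", "eap"), ...) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  y <- if (is.null(newdata)) object$y else as_binary_matrix(newdata, "newdata")
  H <- e_step(y, object$pi, object$v)
  attr(H, "loglik") <- NULL
  switch(type,
    posterior = H,
    mastery = H %*% object$profiles,
    profile = {
      cls <- lcdm_classify(H, object$profiles)
      if (rule == "map") cls$map else cls$eap
    },
    expected = H %*% object$pi)
}

#' @export
plot.lcdm <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "EM iteration", ylab = "marginal log-likelihood",
                 main = sprintf("LCDM %s estimation trace", x$method), ...)
  invisible(x)
}

#' @export
simulate.lcdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(object$profiles)
  lapply(seq_len(nsim), function(s) {
    cls <- sample.int(C, object$N, replace = TRUE, prob = object$v)
    p <- object$pi[cls, , drop = FALSE]
    matrix(as.numeric(stats::runif(length(p)) < p), nrow = object$N)
  })
}

#' @export
residuals.lcdm <- function(object, ...) {
  obs <- suppressWarnings(stats::cor(object$y))
  imp <- implied_correlations(object$pi, object$v)
  res <- obs - imp
  diag(res) <- NA_real_
  res
}
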