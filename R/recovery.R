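#' Define a Monte-Carlo recovery study condition
#'
#' The defaults reproduce the study conditions of the package's simulation
#' design: 30 items, 300 persons, a balanced Q-matrix, attribute correlations
#' drawn from U(0.7, 0.9), and 200 replications.
#'
#' @param A number of attributes (3, 4, or 5 in the original design).
#' @param I number of items.
#' @param N number of persons.
#' @param quality `"high"` or `"low"` item quality.
#' @param corr_range latent attribute correlation range.
#' @param replications number of Monte-Carlo replications.
#' @param fresh_q draw a fresh Q-matrix every replication (default) or freeze
#'   one for the whole condition.
#' @param seed master seed; per-replication seeds are derived from it so the
#'   replications are independent and the run is reproducible.
#' @return list of class `lcdm_sim_design`.
#' @export
lcdm_sim_design <- function(A = 3, I = 30, N = 300,
                            quality = c("high", "low"),
                            corr_range = c(0.7, 0.9), replications = 200,
                            fresh_q = TRUE, seed = 1) {
  quality <- match.arg(quality)
  stopifnot(A >= 1, I >= A, N >= 1, replications >= 1)
  structure(list(A = A, I = I, N = N, quality = quality,
                 corr_range = corr_range,
                 replications = as.integer(replications),
                 fresh_q = fresh_q, seed = seed),
            class = "lcdm_sim_design")
}

#' Run a parameter-recovery study
#'
#' For each replication: draw a balanced Q-matrix, correlated attribute
#' profiles, and item responses under the condition's true parameters; fit
#' each requested estimator; classify persons from the posterior (MAP by
#' default); and accumulate attribute/profile classification accuracy against
#' the generating profiles, RBIAS and RMSE of the item-parameter estimates by
#' parameter type, and estimator failure counts.  An estimator failure (the
#' classical EM's curvature degeneracies) is counted and the replication
#' continues; failed fits are excluded from the accuracy and recovery
#' summaries.
#'
#' @param design an [lcdm_sim_design()].
#' @param estimators character vector among `"em"` and `"em-de"`.
#' @param rule classification rule, `"map"` (default) or `"eap"`.
#' @param control optional [lcdm_control()] overrides shared by the
#'   estimators.
#' @param progress print a line per replication.
#' @return object of class `lcdm_recovery`: per-estimator accuracy means,
#'   RBIAS/RMSE by parameter type (percent scale and raw), failure counts,
#'   and the per-replication accuracy draws.
#' @export
lcdm_recovery <- function(design, estimators = c("em", "em-de"),
                          rule = c("map", "eap"), control = list(),
                          progress = FALSE) {
  stopifnot(inherits(design, "lcdm_sim_design"))
  estimators <- match.arg(estimators, c("em", "em-de"), several.ok = TRUE)
  rule <- match.arg(rule)
  seeds <- derive_seeds(design$seed, design$replications)
  ctrl <- if (inherits(control, "lcdm_control")) control
          else do.call(lcdm_control, control)

  frozen_q <- if (!design$fresh_q) sim_q_matrix(design$A, design$I,
                                                seed = design$seed) else NULL
  acc <- list()
  dev <- list()
  rel <- list()
  failures <- stats::setNames(integer(length(estimators)), estimators)
  used <- stats::setNames(integer(length(estimators)), estimators)
  for (est in estimators) {
    acc[[est]] <- matrix(NA_real_, design$replications, 2,
                         dimnames = list(NULL, c("attribute", "profile")))
    dev[[est]] <- list(intercept = numeric(0), main = numeric(0),
                       interaction = numeric(0))
    rel[[est]] <- list(intercept = numeric(0), main = numeric(0),
                       interaction = numeric(0))
  }

  for (r in seq_len(design$replications)) {
    set.seed(seeds[r])
    q <- if (design$fresh_q) sim_q_matrix(design$A, design$I) else frozen_q
    att <- sim_attributes(design$N, design$A, design$corr_range)
    truth <- true_item_params(q, design$quality)
    y <- sim_responses(truth, q, att$alpha)
    for (est in estimators) {
      fit <- lcdm(y, q, method = est, control = ctrl, seed = seeds[r])
      if (!is.null(fit$failure)) {
        failures[est] <- failures[est] + 1L
        next
      }
      used[est] <- used[est] + 1L
      cls <- lcdm_classify(fit)
      estp <- if (rule == "map") cls$map else cls$eap
      acc[[est]][r, "attribute"] <- attribute_accuracy(att$alpha, estp)
      acc[[est]][r, "profile"] <- profile_accuracy(att$alpha, estp)
      tv <- unlist(truth)
      ev <- unlist(fit$params)
      ty <- param_type(sub("^i[0-9]+\\.", "", names(pack_params(truth))))
      for (tp in c("intercept", "main", "interaction")) {
        sel <- ty == tp
        if (!any(sel)) next
        dev[[est]][[tp]] <- c(dev[[est]][[tp]], ev[sel] - tv[sel])
        rel[[est]][[tp]] <- c(rel[[est]][[tp]], (ev[sel] - tv[sel]) / tv[sel])
      }
    }
    if (progress) {
      message(sprintf("replication %d/%d done", r, design$replications))
    }
  }

  summarize <- function(est) {
    a <- acc[[est]]
    types <- names(dev[[est]])
    rb <- vapply(types, function(tp) {
      if (length(rel[[est]][[tp]])) 100 * mean(rel[[est]][[tp]]) else NA_real_
    }, numeric(1))
    rm100 <- vapply(types, function(tp) {
      if (length(dev[[est]][[tp]])) 100 * sqrt(mean(dev[[est]][[tp]]^2)) else NA_real_
    }, numeric(1))
    list(attribute_accuracy = mean(a[, "attribute"], na.rm = TRUE),
         profile_accuracy = mean(a[, "profile"], na.rm = TRUE),
         rbias = rb, rmse = rm100, rmse_raw = rm100 / 100,
         failures = failures[[est]], replications_used = used[[est]])
  }
  structure(list(design = design, rule = rule,
                 estimators = stats::setNames(lapply(estimators, summarize),
                                              estimators),
                 accuracy_draws = acc),
            class = "lcdm_recovery")
}

#' @export
print.lcdm_recovery <- function(x, digits = 3, ...) {
  d <- x$design
  cat(sprintf("Recovery study: A=%d, I=%d, N=%d, %s quality, %d replications\n",
              d$A, d$I, d$N, d$quality, d$replications))
  cat(sprintf("classification rule: %s\n\n", toupper(x$rule)))
  for (est in names(x$estimators)) {
    s <- x$estimators[[est]]
    cat(sprintf("[%s] attribute accuracy %.3f | profile accuracy %.3f | failures %d/%d\n",
                est, s$attribute_accuracy, s$profile_accuracy, s$failures,
                d$replications))
    cat("  RBIAS (x100): ",
        paste(sprintf("%s %.2f", names(s$rbias), s$rbias), collapse = ", "),
        "\n", sep = "")
    cat("  RMSE  (x100): ",
        paste(sprintf("%s %.2f", names(s$rmse), s$rmse), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
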