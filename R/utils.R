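# Internal numeric helpers shared across estimators.

# probabilities are clipped away from 0/1 so log terms stay finite
.PROB_EPS <- 1e-10
.LOGIT_CAP <- 23.025850929940457  # logit(1 - 1e-10)

clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

clip_logit <- function(x) pmin(pmax(x, -.LOGIT_CAP), .LOGIT_CAP)

# row-wise log-sum-exp of a matrix; -Inf rows stay -Inf instead of NaN
row_log_sum_exp <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- -Inf
  out
}

as_binary_matrix <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("%s must be binary: entry [%d, %d] is %s",
                 what, i, j, format(x[bad[1L]])), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

# condition used when the Newton M-step loses curvature
convergence_failure <- function(message, item, iteration) {
  structure(
    class = c("lcdm_convergence_failure", "error", "condition"),
    list(message = message, call = NULL, item = item, iteration = iteration)
  )
}

# replication seeds derived from one master seed; reproducible and
# independent of how many replications have already run
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# small stable FNV-1a hash for config manifests (hex string)
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
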