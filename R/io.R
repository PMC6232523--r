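#' Read a Q-matrix or response matrix from CSV
#'
#' Q-matrices are CSV files with a header row (`A1`, ..., `Ak`) and one 0/1
#' row per item.  Response files hold one 0/1 row per person; an optional
#' person-ID first column (any non-binary or character column) is dropped.
#' Malformed cells are reported with their row and column.
#'
#' @param path file path.
#' @return validated matrix.
#' @export
read_qmatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty Q-matrix file: %s", path), call. = FALSE)
  as_qmatrix(as.matrix(df))
}

#' @rdname read_qmatrix
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    stop(sprintf("empty response file: %s", path), call. = FALSE)
  }
  has_header <- !grepl("^[01][,01]*$", gsub("[[:space:]\"]", "", first))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE)
  if (ncol(df) > 1L) {
    col1 <- df[[1L]]
    if (is.character(col1) || is.factor(col1) || !all(col1 %in% c(0, 1))) {
      df <- df[, -1L, drop = FALSE]
    }
  }
  as_binary_matrix(as.matrix(df), "response matrix")
}

#' Write / read item parameters as JSON
#'
#' The JSON document is keyed by item (`"item_1"`, ...), each with an
#' `intercept` and an `effects` map keyed by attribute-subset label (`"1"`,
#' `"2x3"`, ...).  Reading the file back restores the canonical per-item
#' parameter list bit-exactly (values are serialized at full precision).
#'
#' @param params per-item parameter list.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()` the
#'   parameter list.
#' @export
write_params <- function(params, path) {
  doc <- stats::setNames(lapply(params, function(b) {
    list(intercept = unname(b[["0"]]),
         effects = as.list(b[names(b) != "0"]))
  }), paste0("item_", seq_along(params)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(unname(doc), function(it) {
    eff <- unlist(it$effects)
    stats::setNames(c(it$intercept, eff), c("0", names(it$effects)))
  })
}

#' Write the outputs of a fit to a directory
#'
#' Writes the parameter JSON, posterior CSV, classification CSV, fit-index
#' JSON, a run log with the iteration trace, and a manifest listing every
#' file together with a hash of the fit configuration.
#'
#' @param fit an `lcdm` object.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(params = file.path(dir, "parameters.json"),
             posterior = file.path(dir, "posterior.csv"),
             classification = file.path(dir, "classification.csv"),
             indices = file.path(dir, "fit_indices.json"),
             v = file.path(dir, "class_probabilities.csv"),
             log = file.path(dir, "run.log"),
             manifest = file.path(dir, "manifest.json"))
  write_params(fit$params, paths[["params"]])
  utils::write.csv(fit$posterior, paths[["posterior"]], row.names = FALSE)
  cls <- lcdm_classify(fit)
  utils::write.csv(cls$map, paths[["classification"]], row.names = FALSE)
  idx <- suppressWarnings(lcdm_fit_indices(fit))
  jsonlite::write_json(list(madcor = idx$madcor, srmsr = idx$srmsr),
                       paths[["indices"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(class = seq_along(fit$v), v = fit$v),
                   paths[["v"]], row.names = FALSE)
  writeLines(c(sprintf("method: %s", fit$method),
               sprintf("converged: %s (%s) after %d iterations",
                       fit$converged, fit$reason, fit$niter),
               sprintf("loglik trace: %s",
                       paste(format(fit$trace, digits = 10), collapse = " "))),
             paths[["log"]])
  manifest <- list(
    files = as.list(basename(paths[names(paths) != "manifest"])),
    config_hash = config_hash(list(method = fit$method,
                                   control = unclass(fit$control),
                                   seed = fit$seed)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE)
  invisible(manifest)
}

#' Write built-in example datasets
#'
#' `kind = "ols_example"` writes the 8-point regression data used to
#' demonstrate the DE optimizer (x = 22, 14, 15, 12, 10, 26, 11, 28 and
#' y = 44, 29, 30, 27, 24, 51, 25, 56).  `"table1_q"` writes the 4-item,
#' 3-skill example Q-matrix; `"table2_items"` the 3-item Q-matrix whose rows
#' measure one, two, and three attributes.  `"tiny_lcdm"` simulates a small
#' 2-attribute, 6-item, 200-person dataset (with the generating truth) for
#' smoke tests.
#'
#' @param kind one of `"ols_example"`, `"table1_q"`, `"table2_items"`,
#'   `"tiny_lcdm"`.
#' @param dir output directory.
#' @param seed seed for `"tiny_lcdm"`.
#' @return character vector of written file paths, invisibly.
#' @export
make_fixture <- function(kind, dir = ".", seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(kind,
    ols_example = {
      p <- file.path(dir, "ols_example.csv")
      utils::write.csv(data.frame(
        x = c(22, 14, 15, 12, 10, 26, 11, 28),
        y = c(44, 29, 30, 27, 24, 51, 25, 56)), p, row.names = FALSE)
      p
    },
    table1_q = {
      p <- file.path(dir, "table1_q.csv")
      q <- matrix(c(1, 0, 0,
                    1, 0, 1,
                    0, 1, 1,
                    1, 1, 0), 4, 3, byrow = TRUE,
                  dimnames = list(NULL, c("A1", "A2", "A3")))
      utils::write.csv(as.data.frame(q), p, row.names = FALSE)
      p
    },
    table2_items = {
      p <- file.path(dir, "table2_q.csv")
      q <- matrix(c(1, 0, 0,
                    0, 1, 1,
                    1, 1, 1), 3, 3, byrow = TRUE,
                  dimnames = list(NULL, c("A1", "A2", "A3")))
      utils::write.csv(as.data.frame(q), p, row.names = FALSE)
      p
    },
    tiny_lcdm = {
      set.seed(seed)
      q <- sim_q_matrix(2, 6)
      att <- sim_attributes(200, 2)
      truth <- true_item_params(q, "high")
      y <- sim_responses(truth, q, att$alpha)
      pq <- file.path(dir, "tiny_q.csv")
      py <- file.path(dir, "tiny_responses.csv")
      pa <- file.path(dir, "tiny_alpha.csv")
      pp <- file.path(dir, "tiny_truth.json")
      utils::write.csv(as.data.frame(q), pq, row.names = FALSE)
      utils::write.csv(as.data.frame(y), py, row.names = FALSE)
      utils::write.csv(as.data.frame(att$alpha), pa, row.names = FALSE)
      write_params(truth, pp)
      c(pq, py, pa, pp)
    },
    stop(sprintf("unknown fixture kind: %s", kind), call. = FALSE))
  invisible(out)
}
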