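#' Read a samples-by-variables matrix from delimited text
#'
#' Expects a rectangular numeric table with a header row; rows are samples.
#' Negative entries are rejected for orthant models and zeros are rejected
#' when the model has `b = 0` (the gamma-type families need strictly
#' positive data), with a message naming the offending cell.
#'
#' @param path File path.
#' @param delimiter `","` or `"\t"` (guessed from the extension when `NULL`).
#' @param spec Optional [model_spec()] used for domain validation.
#' @return Numeric matrix with column names.
#' @export
read_sm_matrix <- function(path, delimiter = NULL, spec = NULL) {
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "\t" else ","
  df <- read.csv(path, sep = delimiter, header = TRUE,
                 check.names = FALSE, colClasses = "numeric")
  x <- as_data_matrix(df)
  if (!is.null(spec) && spec$family != "gaussian_rm") {
    if (any(x < 0)) {
      idx <- which(x < 0, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "negative value at row %d, column '%s': orthant models need non-negative data",
        idx[1], colnames(x)[idx[2]]))
    }
    if (spec$b == 0 && any(x == 0)) {
      idx <- which(x == 0, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "zero value at row %d, column '%s': b = 0 models need strictly positive data (consider a pseudocount or a different family)",
        idx[1], colnames(x)[idx[2]]))
    }
  }
  x
}

#' Write estimation results to an output directory
#'
#' Emits `K_hat.csv` (named rows/columns), `edges.tsv` (undirected,
#' upper-triangle only: `node_i`, `node_j`, `kappa_hat`), `eta_hat.csv`
#' when present, and `metadata.json` (model, h, penalties, convergence,
#' column scales, seed).
#'
#' @param fit An `sm_fit`.
#' @param outdir Output directory (created if missing).
#' @param system Optional `sm_system` (for column scales).
#' @param seed Optional seed to record.
#' @return Invisibly, the paths written.
#' @export
write_sm_results <- function(fit, outdir, system = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(K = file.path(outdir, "K_hat.csv"),
             edges = file.path(outdir, "edges.tsv"),
             meta = file.path(outdir, "metadata.json"))
  write.csv(as.data.frame(fit$K), paths["K"], row.names = TRUE)
  ed <- tidy(fit)
  utils::write.table(ed, paths["edges"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(fit$eta)) {
    paths <- c(paths, eta = file.path(outdir, "eta_hat.csv"))
    write.csv(data.frame(variable = fit$var_names, eta_hat = fit$eta),
              paths["eta"], row.names = FALSE)
  }
  meta <- list(
    model = list(family = fit$spec$family, a = fit$spec$a, b = fit$spec$b,
                 centered = fit$spec$centered),
    h = unclass(if (is.null(system)) NULL else system$h),
    lambda_K = fit$lambda_K, lambda_eta = fit$lambda_eta,
    penalize_diag = fit$penalize_diag,
    multiplier = if (is.null(system)) NULL else system$delta,
    converged = fit$converged, iterations = fit$iterations,
    objective = fit$objective,
    column_scales = if (is.null(system)) NULL else system$column_scales,
    n = fit$n, m = fit$m, seed = seed,
    package_version = as.character(utils::packageVersion("hscore")))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
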