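#' Write a response matrix to CSV
#'
#' Comma-separated, UTF-8, mandatory header row of voxel ids; one row
#' per trial. The companion of [read_responses()].
#'
#' @param responses numeric matrix (n_trials, n_voxels).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_responses <- function(responses, path) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("v%04d", seq_len(ncol(responses)))
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' @param path CSV file with a header row of voxel ids (trials x voxels).
#' @param n_trials optional expected trial count (e.g. the paired image
#'   count); a mismatch is an error.
#' @return numeric matrix with voxel ids as column names.
#' @export
read_responses <- function(path, n_trials = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("response file contains non-numeric columns")
  bad <- colnames(m)[colSums(!is.finite(m)) > 0]
  if (length(bad))
    stop("non-finite responses in voxel(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!is.null(n_trials) && nrow(m) != n_trials)
    stop("response file has ", nrow(m), " trials; expected ", n_trials)
  m
}

#' Save / load fitted models
#'
#' Persists a fitted [fit_encoding()] model (or a trained [scnn()]) to a
#' single file with a format tag and version, so that
#' `load_model(save_model(m, f))` reproduces predictions bit-exactly.
#'
#' @param model an `"scnn_encoding"` or `"scnn"` object.
#' @param path file path.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("scnn_encoding", "scnn")))
    stop("model must be an 'scnn_encoding' or 'scnn' object")
  saveRDS(list(format = "scnnenc_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "scnnenc_model"))
    stop("file is not a saved model (missing format tag): ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported model file version: ", obj$version)
  obj$model
}
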