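#' Root mean squared error of proportion estimates
#'
#' Square root of the mean squared elementwise difference over all
#' spot x cell-type entries. Symmetric in its arguments and invariant to
#' a consistent reordering of spots or types.
#'
#' @param v_hat,v_true Spots x types proportion matrices of identical
#'   shape; rows of each are expected to sum to 1.
#' @param check_rows Verify the row-sum contract (default TRUE).
#' @return Non-negative scalar.
#' @export
rmse <- function(v_hat, v_true, check_rows = TRUE) {
  v_hat <- as.matrix(v_hat); v_true <- as.matrix(v_true)
  if (!identical(dim(v_hat), dim(v_true))) stop("shapes must match")
  if (check_rows) {
    # tolerance admits proportions rounded to 6 decimals on disk
    if (any(abs(rowSums(v_hat) - 1) > 1e-4) ||
        any(abs(rowSums(v_true) - 1) > 1e-4)) {
      stop("proportion rows must sum to 1")
    }
  }
  sqrt(mean((v_hat - v_true)^2))
}

#' Pearson correlation of inferred and true log2 fold changes
#'
#' @param fc_hat,fc_true Per-gene log2 fold changes (layer 1 over
#'   layer 2), at least 3 finite values.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
log2fc_correlation <- function(fc_hat, fc_true) {
  if (length(fc_hat) != length(fc_true)) stop("lengths must match")
  if (length(fc_hat) < 3) stop("at least 3 genes are required")
  if (any(!is.finite(fc_hat)) || any(!is.finite(fc_true))) {
    stop("fold changes must be finite")
  }
  stats::cor(fc_hat, fc_true, method = "pearson")
}

#' Score a deconvolution fit against simulation truth
#'
#' Computes the overall and per-type RMSE of the fitted proportions
#' against the true composition, matching spots and cell types by name.
#'
#' @param fit A `spatial_fit` (or a spots x types proportion matrix).
#' @param v_true True spots x types proportions.
#' @return A list of class `eval_report`: `rmse`, `rmse_per_type`,
#'   `n_spots`, `n_types`.
#' @export
evaluate_deconvolution <- function(fit, v_true) {
  v_hat <- if (inherits(fit, "spatial_fit")) proportions(fit)
           else as.matrix(fit)
  v_true <- as.matrix(v_true)
  if (!is.null(rownames(v_hat)) && !is.null(rownames(v_true))) {
    common <- intersect(rownames(v_hat), rownames(v_true))
    v_hat <- v_hat[common, , drop = FALSE]
    v_true <- v_true[common, colnames(v_hat), drop = FALSE]
  }
  per_type <- sqrt(colMeans((v_hat - v_true)^2))
  structure(list(rmse = rmse(v_hat, v_true),
                 rmse_per_type = per_type,
                 n_spots = nrow(v_hat), n_types = ncol(v_hat)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$n_spots, "spots x", x$n_types, "types; RMSE =",
      format(x$rmse, digits = 6), "\n")
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row for the overall RMSE followed by one row per cell type.
#'
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  df <- data.frame(
    metric = c("rmse", paste0("rmse_", names(report$rmse_per_type))),
    value = c(report$rmse, unname(report$rmse_per_type)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
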