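# JSON serialisation of fitted models. Matrices are stored flat in
# column-major order with explicit dimensions, which survives jsonlite's
# scalar unboxing for any shape.

flat_mat <- function(m) list(dim = dim(m), values = as.vector(m))

unflat_mat <- function(x, rn, cn) {
  m <- matrix(as.numeric(unlist(x$values)), nrow = x$dim[1],
              ncol = x$dim[2])
  dimnames(m) <- list(rn, cn)
  m
}

#' Serialise a fitted reference model to JSON
#'
#' Versioned text schema (`spotlayer-ref/1`) holding `theta`
#' (column-major flat with dimensions), `o`, gene ids and cell-type
#' names at full double precision; round-trips exactly through
#' [read_ref_model()].
#'
#' @param model A `ref_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ref_model <- function(model, path) {
  stopifnot(inherits(model, "ref_model"))
  obj <- list(schema = "spotlayer-ref/1",
              gene_ids = model$gene_ids,
              cell_types = model$cell_types,
              theta = flat_mat(model$theta),
              o = unname(model$o),
              logLik = model$logLik,
              objective_trace = model$objective_trace,
              dropped_genes = model$dropped_genes,
              converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialised reference model
#'
#' @param path JSON path written by [write_ref_model()].
#' @return A `ref_model`.
#' @export
read_ref_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "spotlayer-ref/1")) {
    stop("unrecognised reference-model schema: ", obj$schema)
  }
  theta <- unflat_mat(obj$theta, obj$gene_ids, obj$cell_types)
  o <- stats::setNames(as.numeric(obj$o), obj$gene_ids)
  structure(list(theta = theta, o = o, P = sigmoid(o),
                 gene_ids = obj$gene_ids, cell_types = obj$cell_types,
                 logLik = obj$logLik,
                 objective_trace = as.numeric(obj$objective_trace),
                 dropped_genes = as.character(obj$dropped_genes %||% character(0)),
                 converged = obj$converged),
            class = "ref_model")
}

#' Serialise a spatial fit to JSON
#'
#' Versioned text schema (`spotlayer-fit/1`) holding the fitted cell
#' counts, layer shifts, platform bias, identifiers and objective trace
#' at full double precision.
#'
#' @param fit A `spatial_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_spatial_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spatial_fit"))
  obj <- list(schema = "spotlayer-fit/1",
              gene_ids = fit$gene_ids,
              cell_types = colnames(fit$n),
              spot_ids = fit$spot_ids,
              layer_names = rownames(fit$T),
              spot_layers = as.character(fit$layers),
              n = flat_mat(fit$n),
              T = flat_mat(fit$T),
              beta = unname(fit$beta),
              theta = flat_mat(fit$theta),
              P = unname(fit$P),
              objective_trace = fit$objective_trace,
              logPosterior = fit$logPosterior,
              dropped_spots = fit$dropped_spots,
              t_prior_sd = fit$prior$t_prior_sd,
              converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialised spatial fit
#'
#' @param path JSON path written by [write_spatial_fit()].
#' @return A `spatial_fit`.
#' @export
read_spatial_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "spotlayer-fit/1")) {
    stop("unrecognised spatial-fit schema: ", obj$schema)
  }
  structure(list(
    n = unflat_mat(obj$n, obj$spot_ids, obj$cell_types),
    T = unflat_mat(obj$T, obj$layer_names, obj$gene_ids),
    beta = stats::setNames(as.numeric(obj$beta), obj$gene_ids),
    theta = unflat_mat(obj$theta, obj$gene_ids, obj$cell_types),
    P = stats::setNames(as.numeric(obj$P), obj$gene_ids),
    gene_ids = obj$gene_ids, spot_ids = obj$spot_ids,
    layers = stats::setNames(
      factor(obj$spot_layers, levels = obj$layer_names), obj$spot_ids),
    objective_trace = as.numeric(obj$objective_trace),
    logPosterior = obj$logPosterior,
    dropped_spots = as.character(obj$dropped_spots %||% character(0)),
    prior = prior_spec(obj$t_prior_sd),
    converged = obj$converged),
    class = "spatial_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
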