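#' Bundle a single-cell reference dataset
#'
#' Pairs a gene-by-cell count matrix with per-cell cell-type labels and
#' library sizes. Library sizes default to each cell's total count divided
#' by the median total across cells, so they are dimensionless with median
#' 1 and the fitted expression levels are on a per-typical-cell scale.
#'
#' @param counts Gene x cell count matrix (see [count_matrix()]).
#' @param cell_types Per-cell labels: either named by cell id or in column
#'   order. Coerced to factor; every cell must be labelled.
#' @param library_sizes Optional positive per-cell scalars overriding the
#'   default normalisation.
#' @return A list of class `reference_data` with elements `counts`,
#'   `cell_types` (factor) and `library_sizes`.
#' @export
reference_data <- function(counts, cell_types, library_sizes = NULL) {
  assert_count_matrix(counts)
  cells <- colnames(counts)
  if (!is.null(names(cell_types))) {
    if (!all(cells %in% names(cell_types))) {
      stop("every cell in `counts` needs a label in `cell_types`")
    }
    cell_types <- cell_types[cells]
  } else if (length(cell_types) != ncol(counts)) {
    stop("`cell_types` must have one label per cell")
  }
  if (anyNA(cell_types)) stop("missing cell-type labels")
  # a factor's declared levels are kept, so empty declared types are
  # detectable downstream
  if (!is.factor(cell_types)) cell_types <- factor(as.character(cell_types))
  if (is.null(library_sizes)) {
    tot <- Matrix::colSums(counts)
    med <- stats::median(tot)
    if (med <= 0) stop("median cell total count is zero")
    library_sizes <- tot / med
  } else {
    if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
      stop("`library_sizes` must be positive, one per cell")
    }
  }
  names(library_sizes) <- cells
  structure(list(counts = counts, cell_types = cell_types,
                 library_sizes = library_sizes),
            class = "reference_data")
}

#' @export
print.reference_data <- function(x, ...) {
  cat("reference_data:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells,", nlevels(x$cell_types), "cell types\n")
  invisible(x)
}

#' Fit the cell-type expression model to a single-cell reference
#'
#' Maximum-likelihood estimation of the negative binomial reference model:
#' the count of gene g in cell c is NB with size
#' `S_c * softplus(theta[g, z_c])` and success probability
#' `P_g = sigmoid(o_g)`, where `z_c` is the cell's type and `S_c` its
#' library size. `theta` (genes x types, pre-link location) and `o`
#' (gene-wise pre-link dispersion) are estimated jointly by bounded
#' quasi-Newton ascent of the exact log-likelihood with analytic
#' gradients. Because the reference carries no layer information, any
#' layer structure present in the cells is absorbed into `theta`; layer
#' shifts are estimated later, from the spatial data only.
#'
#' Genes with zero counts in every cell have no finite location MLE and
#' are dropped with a warning before fitting.
#'
#' @param ref A [reference_data()] object.
#' @param control Optimiser settings, see [fit_control()].
#' @return A list of class `ref_model`: `theta` (genes x types), `o`,
#'   `P = sigmoid(o)`, `gene_ids`, `cell_types` (type names), `logLik`,
#'   `objective_trace`, `dropped_genes`, `converged`.
#' @export
fit_reference <- function(ref, control = fit_control()) {
  stopifnot(inherits(ref, "reference_data"))
  z <- ref$cell_types
  n_per_type <- table(z)
  if (any(n_per_type == 0)) {
    stop("cell type(s) with zero cells: ",
         paste(names(n_per_type)[n_per_type == 0], collapse = ", "))
  }
  counts <- ref$counts
  nnz <- Matrix::rowSums(counts > 0)
  dropped <- rownames(counts)[nnz == 0]
  if (length(dropped) > 0) {
    warning(length(dropped),
            " gene(s) with all-zero counts dropped before fitting: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    counts <- counts[nnz > 0, , drop = FALSE]
  }
  X <- dense_counts(counts)
  G <- nrow(X); C <- ncol(X); Z <- nlevels(z)
  S <- as.numeric(ref$library_sizes)
  zc <- as.integer(z)
  # cell -> type indicator for gradient pooling
  Mz <- Matrix::sparseMatrix(i = seq_len(C), j = zc, x = 1,
                             dims = c(C, Z))
  rsX <- rowSums(X)
  lfact <- sum(lfactorial(X))

  # type-wise mean expression per typical cell, for initialization
  Xs <- sweep(X, 2, S, "/")
  m <- as.matrix((Xs %*% Mz) %*% Matrix::Diagonal(x = 1 / as.numeric(n_per_type)))
  theta0 <- softplus_inv(pmin(pmax(m, 1e-3), 1e6))
  par0 <- c(pmin(pmax(theta0, -20), 20), rep(0, G))

  unpack <- function(par) {
    list(theta = matrix(par[seq_len(G * Z)], G, Z),
         o = par[G * Z + seq_len(G)])
  }
  Xi <- X
  storage.mode(Xi) <- "integer"
  fngr <- function(par) {
    pr <- unpack(par)
    sp <- softplus(pr$theta)                       # G x Z
    p <- sigmoid(pr$o)
    log_p <- -softplus(-pr$o)
    log_1mp <- -softplus(pr$o)
    k <- ref_nb_kernel(sp, zc, S, Xi, log_1mp)
    obj <- k$objective - lfact + sum(rsX * log_p)
    g_theta <- k$g_theta * sigmoid(pr$theta)
    g_o <- rsX * (1 - p) - k$rs_r * p
    list(objective = obj, gradient = c(g_theta, g_o))
  }

  lower <- c(rep(-20, G * Z), rep(-15, G))
  upper <- c(rep(20, G * Z), rep(15, G))
  res <- maximize_lbfgs(par0, fngr, lower, upper, control)
  pr <- unpack(res$par)
  dimnames(pr$theta) <- list(rownames(counts), levels(z))
  names(pr$o) <- rownames(counts)
  structure(list(theta = pr$theta, o = pr$o, P = sigmoid(pr$o),
                 gene_ids = rownames(counts), cell_types = levels(z),
                 logLik = res$objective, objective_trace = res$trace,
                 dropped_genes = dropped, converged = res$converged),
            class = "ref_model")
}

#' @export
print.ref_model <- function(x, ...) {
  cat("ref_model:", length(x$gene_ids), "genes x",
      length(x$cell_types), "cell types; logLik =",
      format(x$logLik, digits = 8),
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}
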