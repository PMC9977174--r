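#' Filter genes by spot presence
#'
#' Keeps genes detected (nonzero) in at least `ceiling(min_frac * n)` of
#' the n units, the recommended guard against excessive zeros (default:
#' present in at least 2% of spots). A gene in exactly the threshold
#' fraction of units is kept.
#'
#' @param counts Gene x unit count matrix.
#' @param min_frac Minimum detection fraction in `[0, 1]`.
#' @return List with `counts` (filtered, original ordering preserved) and
#'   `report` (a `filter_report`).
#' @export
filter_gene_presence <- function(counts, min_frac = 0.02) {
  assert_count_matrix(counts)
  if (min_frac < 0 || min_frac > 1) stop("`min_frac` must be in [0, 1]")
  need <- ceiling(min_frac * ncol(counts))
  keep <- Matrix::rowSums(counts > 0) >= need
  out <- counts[keep, , drop = FALSE]
  report <- filter_report(
    rules = data.frame(
      rule = "gene_presence",
      axis = "genes",
      threshold = paste0(">=", need, " of ", ncol(counts), " units"),
      removed = sum(!keep), stringsAsFactors = FALSE),
    input_dim = dim(counts), output_dim = dim(out))
  list(counts = out, report = report)
}

#' Quality-control filtering of reference and spatial counts
#'
#' Applies the four standard thresholds and then intersects the gene
#' sets: reference genes must be expressed in at least `min_cells_per_gene`
#' cells and cells must express at least `min_genes_per_cell` genes;
#' spatial genes must be expressed in at least `min_spots_per_gene` spots
#' and spots must express at least `min_genes_per_spot` genes; finally
#' only genes present in both filtered matrices are kept (in reference
#' gene order). Within each modality the gene and unit masks are computed
#' on the input matrix and applied simultaneously.
#'
#' @param ref_counts Gene x cell reference counts.
#' @param st_counts Gene x spot spatial counts.
#' @param min_cells_per_gene,min_genes_per_cell Reference thresholds
#'   (defaults 3 and 200).
#' @param min_spots_per_gene,min_genes_per_spot Spatial thresholds
#'   (defaults 3 and 100).
#' @return List with filtered `ref_counts`, `st_counts` and `report`.
#' @export
filter_qc <- function(ref_counts, st_counts, min_cells_per_gene = 3,
                      min_genes_per_cell = 200, min_spots_per_gene = 3,
                      min_genes_per_spot = 100) {
  assert_count_matrix(ref_counts)
  assert_count_matrix(st_counts)
  keep_g_ref <- Matrix::rowSums(ref_counts > 0) >= min_cells_per_gene
  keep_c <- Matrix::colSums(ref_counts > 0) >= min_genes_per_cell
  keep_g_st <- Matrix::rowSums(st_counts > 0) >= min_spots_per_gene
  keep_s <- Matrix::colSums(st_counts > 0) >= min_genes_per_spot
  ref2 <- ref_counts[keep_g_ref, keep_c, drop = FALSE]
  st2 <- st_counts[keep_g_st, keep_s, drop = FALSE]
  common <- intersect(rownames(ref2), rownames(st2))
  ref_removed_isect <- nrow(ref2) - length(common)
  st_removed_isect <- nrow(st2) - length(common)
  ref3 <- ref2[common, , drop = FALSE]
  st3 <- st2[rownames(st2)[rownames(st2) %in% common], , drop = FALSE]
  report <- filter_report(
    rules = data.frame(
      rule = c("ref_gene_min_cells", "ref_cell_min_genes",
               "st_gene_min_spots", "st_spot_min_genes",
               "ref_gene_intersection", "st_gene_intersection"),
      axis = c("genes", "cells", "genes", "spots", "genes", "genes"),
      threshold = c(paste0(">=", min_cells_per_gene, " cells"),
                    paste0(">=", min_genes_per_cell, " genes"),
                    paste0(">=", min_spots_per_gene, " spots"),
                    paste0(">=", min_genes_per_spot, " genes"),
                    "shared with ST", "shared with reference"),
      removed = c(sum(!keep_g_ref), sum(!keep_c), sum(!keep_g_st),
                  sum(!keep_s), ref_removed_isect, st_removed_isect),
      stringsAsFactors = FALSE),
    input_dim = c(dim(ref_counts), dim(st_counts)),
    output_dim = c(dim(ref3), dim(st3)))
  list(ref_counts = ref3, st_counts = st3, report = report)
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes with the variance-stabilising procedure popularised by
#' single-cell toolkits: per-gene mean and variance of the raw counts are
#' computed; a loess curve (span 0.3, degree 2) of log10 variance on
#' log10 mean predicts each gene's expected standard deviation; counts
#' are standardised with the predicted sd and clipped at `sqrt(n)`; the
#' variance of the clipped standardised values is the ranking statistic.
#' Zero-variance genes receive a statistic of 0 and rank last; ties break
#' by input gene order.
#'
#' @param counts Gene x unit count matrix.
#' @param k Number of genes to return (default 2000; must not exceed the
#'   gene count).
#' @param span Loess span for the mean-variance trend.
#' @return Character vector of the top `k` gene ids (in decreasing
#'   statistic order) with the per-gene statistics attached as attribute
#'   `"stats"`.
#' @export
select_hvg <- function(counts, k = 2000L, span = 0.3) {
  assert_count_matrix(counts)
  G <- nrow(counts)
  if (k > G) stop("`k` must not exceed the number of genes")
  X <- dense_counts(counts)
  n <- ncol(X)
  mu <- rowMeans(X)
  v <- apply(X, 1, stats::var)
  stat <- numeric(G)
  use <- v > 0 & mu > 0
  if (sum(use) >= 2) {
    fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    Zu <- (X[use, , drop = FALSE] - mu[use]) / sd_exp
    Zu <- pmin(Zu, clip)
    stat[use] <- apply(Zu, 1, stats::var)
  }
  ord <- order(-stat, seq_len(G))
  out <- rownames(counts)[ord[seq_len(k)]]
  attr(out, "stats") <- data.frame(gene = rownames(counts), mean = mu,
                                   variance = v, standardized_variance = stat,
                                   stringsAsFactors = FALSE)
  out
}

#' Construct a filtering report
#'
#' Records per-rule removal counts plus input/output dimensions so that
#' `removed + surviving = input` reconciles per axis.
#'
#' @param rules Data frame with columns rule, axis, threshold, removed.
#' @param input_dim,output_dim Integer dimension vectors.
#' @return A list of class `filter_report`.
#' @export
filter_report <- function(rules, input_dim, output_dim) {
  structure(list(rules = rules, input_dim = input_dim,
                 output_dim = output_dim), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print(x$rules, row.names = FALSE)
  cat("input dim:", paste(x$input_dim, collapse = " x "),
      "-> output dim:", paste(x$output_dim, collapse = " x "), "\n")
  invisible(x)
}

#' Write a filtering report as CSV
#'
#' @param report A `filter_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$rules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
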