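#' Between-layer fold change of expression location parameters
#'
#' For each layer L and gene g, computes within each cell type z the ratio
#' of `softplus(theta[g, z] + T[L, g])` to the average of
#' `softplus(theta[g, z] + T[L', g])` over the other layers, then takes
#' the maximum of that ratio over cell types. With two layers this is the
#' layer-1-over-layer-2 (and vice versa) location ratio. Note the maximum
#' is over the fold change itself, not its magnitude, so detection of
#' down-regulated genes relies on the `|log2 FC|` gate applied downstream.
#'
#' @param theta Genes x cell-types pre-link location matrix.
#' @param T_mat Layers x genes shift matrix (at least 2 layers).
#' @return Layers x genes matrix of positive fold changes.
#' @export
fold_change <- function(theta, T_mat) {
  theta <- as.matrix(theta)
  T_mat <- as.matrix(T_mat)
  G <- nrow(theta); Z <- ncol(theta); L <- nrow(T_mat)
  if (ncol(T_mat) != G) stop("`T_mat` must be layers x genes")
  if (L < 2) stop("fold change is undefined with a single layer")
  sp <- lapply(seq_len(L), function(l) {
    softplus(theta + rep(T_mat[l, ], times = Z))   # G x Z
  })
  tot <- Reduce(`+`, sp)
  out <- matrix(NA_real_, L, G)
  for (l in seq_len(L)) {
    denom <- (tot - sp[[l]]) / (L - 1)
    out[l, ] <- apply(sp[[l]] / denom, 1, max)
  }
  dimnames(out) <- list(rownames(T_mat), rownames(theta))
  out
}

#' Configuration of the layer-wise differential expression test
#'
#' @param n_permutations Number of layer-label permutations N (paper-scale
#'   default 10,000; reduce for exploratory runs).
#' @param alpha Family-wise significance level before Bonferroni division
#'   by the gene count (default 0.05).
#' @param log2fc_threshold Minimum `|log2 fold change|` for a call
#'   (default 1).
#' @param seed Integer seed controlling the permutations.
#' @param warm_start Reuse the observed fit's cell counts and platform
#'   bias (with shifts reset to zero) to initialise each permutation
#'   refit. Cold and warm starts give matching p-values; warm starting
#'   only saves iterations.
#' @return A list of class `lde_config`.
#' @export
lde_config <- function(n_permutations = 10000L, alpha = 0.05,
                       log2fc_threshold = 1, seed = NULL,
                       warm_start = TRUE) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1,
            log2fc_threshold > 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha = alpha, log2fc_threshold = log2fc_threshold,
                 seed = seed, warm_start = isTRUE(warm_start)),
            class = "lde_config")
}

#' Permutation p-value for one layer shift
#'
#' Fraction of permutation replicates whose `|T|` strictly exceeds the
#' observed `|T|`: `#(|t_sims| > |t_obs|) / N`, with no pseudo-count, so
#' a p-value of exactly 0 is attainable. P-values are multiples of `1/N`.
#'
#' @param t_obs Observed shift (scalar).
#' @param t_sims Vector of N permutation shifts.
#' @return P-value in `[0, 1]`.
#' @export
lde_pvalue <- function(t_obs, t_sims) {
  if (length(t_sims) < 1) stop("`t_sims` must be non-empty")
  if (anyNA(t_obs) || anyNA(t_sims)) stop("missing values in shifts")
  mean(abs(t_sims) > abs(t_obs))
}

#' Apply the layer-wise differential expression decision rule
#'
#' A (layer, gene) pair is called if its permutation p-value is below
#' `alpha / G` (Bonferroni over the G tested genes) and its
#' `|log2 fold change|` exceeds the threshold.
#'
#' @param p_values Layers x genes (or vector of) permutation p-values.
#' @param log2fc Matching log2 fold changes.
#' @param n_genes Number of genes tested, G (Bonferroni divisor).
#' @param config An [lde_config()] providing `alpha` and the threshold.
#' @return Logical matrix/vector of calls.
#' @export
call_lde <- function(p_values, log2fc, n_genes, config = lde_config()) {
  if (n_genes < 1) stop("`n_genes` must be at least 1")
  if (!identical(dim(p_values), dim(log2fc)) ||
      length(p_values) != length(log2fc)) {
    stop("`p_values` and `log2fc` must have matching shapes")
  }
  (p_values < config$alpha / n_genes) &
    (abs(log2fc) > config$log2fc_threshold)
}

#' Null distribution of layer shifts by label permutation
#'
#' Re-runs the spot-level MAP fit under `n_permutations` uniformly random
#' permutations of the spot layer labels (labels are resampled without
#' replacement, preserving the number of spots per layer) and records the
#' fitted shift matrix of each replicate. Only gene expression enters the
#' refits. Seeded and reproducible via `config$seed`.
#'
#' @param st A [spatial_data()] object.
#' @param ref_model Fitted reference model.
#' @param config An [lde_config()].
#' @param fit Observed fit used for warm starts (computed if `NULL`).
#' @param prior,control Passed to [fit_spatial()].
#' @return 3-d array N x layers x genes of permutation shifts.
#' @export
permutation_null <- function(st, ref_model, config = lde_config(),
                             fit = NULL, prior = prior_spec(),
                             control = fit_control()) {
  stopifnot(inherits(config, "lde_config"))
  if (is.null(fit)) fit <- fit_spatial(st, ref_model, prior, control)
  N <- config$n_permutations
  if (!is.null(config$seed)) set.seed(config$seed)
  layers <- st$layers
  init <- if (config$warm_start) {
    list(n = fit$n, beta = fit$beta, T = matrix(0, nrow(fit$T), ncol(fit$T)))
  } else NULL
  sims <- array(NA_real_, dim = c(N, nrow(fit$T), ncol(fit$T)),
                dimnames = list(NULL, rownames(fit$T), colnames(fit$T)))
  st_perm <- st
  for (i in seq_len(N)) {
    perm <- sample(length(layers))
    st_perm$layers <- stats::setNames(layers[perm], names(layers))
    fit_i <- fit_spatial(st_perm, ref_model, prior, control, init = init)
    sims[i, , ] <- fit_i$T[rownames(fit$T), colnames(fit$T)]
  }
  sims
}

#' Identify layer-wise differentially expressed genes
#'
#' Full inference path: fits (or reuses) the observed spot-level model,
#' computes between-layer fold changes from the fitted locations and
#' shifts, builds the permutation null of the shifts, and applies the
#' Bonferroni + fold-change decision rule.
#'
#' @param st A [spatial_data()] object with layer labels.
#' @param ref_model Fitted reference model.
#' @param config An [lde_config()].
#' @param fit Optional pre-computed observed [fit_spatial()] result.
#' @param prior,control Passed to [fit_spatial()].
#' @param keep_null Keep the full N x layers x genes null array in the
#'   result (memory permitting).
#' @return A list of class `lde_result`: `fold_change`,
#'   `log2_fold_change`, `p_values`, `is_lde` (all layers x genes),
#'   `t_obs`, `n_genes`, `config`, `fit`, optionally `null_t`.
#' @export
run_lde <- function(st, ref_model, config = lde_config(), fit = NULL,
                    prior = prior_spec(), control = fit_control(),
                    keep_null = FALSE) {
  if (is.null(fit)) fit <- fit_spatial(st, ref_model, prior, control)
  fc <- fold_change(fit$theta, fit$T)
  log2fc <- log2(fc)
  sims <- permutation_null(st, ref_model, config, fit = fit,
                           prior = prior, control = control)
  p <- fit$T
  for (l in seq_len(nrow(p))) {
    for (g in seq_len(ncol(p))) {
      p[l, g] <- lde_pvalue(fit$T[l, g], sims[, l, g])
    }
  }
  G <- ncol(p)
  res <- list(fold_change = fc, log2_fold_change = log2fc, p_values = p,
              is_lde = call_lde(p, log2fc, G, config), t_obs = fit$T,
              n_genes = G, config = config, fit = fit)
  if (keep_null) res$null_t <- sims
  structure(res, class = "lde_result")
}

#' @export
print.lde_result <- function(x, ...) {
  cat("lde_result:", x$n_genes, "genes x", nrow(x$p_values), "layers;",
      sum(x$is_lde), "LDE calls at alpha =", x$config$alpha, "/",
      x$n_genes, "and |log2FC| >", x$config$log2fc_threshold, "\n")
  invisible(x)
}

#' Write layer-wise differential expression results
#'
#' One CSV per layer (gene, fold change, log2 fold change, p-value, call)
#' plus a run-manifest text file echoing the configuration and seed.
#'
#' @param res An `lde_result`.
#' @param dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_lde_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (l in rownames(res$p_values)) {
    df <- data.frame(gene = colnames(res$p_values),
                     fold_change = res$fold_change[l, ],
                     log2_fold_change = res$log2_fold_change[l, ],
                     p_value = res$p_values[l, ],
                     is_lde = res$is_lde[l, ],
                     stringsAsFactors = FALSE)
    f <- file.path(dir, paste0("lde_", gsub("[^A-Za-z0-9_.-]", "_", l),
                               ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  mf <- file.path(dir, "lde_manifest.txt")
  writeLines(c(
    paste0("n_permutations=", res$config$n_permutations),
    paste0("alpha=", res$config$alpha),
    paste0("log2fc_threshold=", res$config$log2fc_threshold),
    paste0("seed=", if (is.null(res$config$seed)) "NA" else res$config$seed),
    paste0("warm_start=", res$config$warm_start),
    paste0("n_genes=", res$n_genes),
    paste0("files=", paste(basename(files), collapse = ","))), mf)
  invisible(c(files, mf))
}
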