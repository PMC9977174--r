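#' Bundle a spot-level spatial transcriptomics dataset
#'
#' Pairs a gene-by-spot count matrix with the required per-spot layer
#' annotation (from pathology or an upstream clustering such as
#' BayesSpace) and optional spot coordinates.
#'
#' @param counts Gene x spot count matrix.
#' @param layers Per-spot layer labels, named by spot id or in column
#'   order; may be `NULL` only for containers that are later annotated
#'   (model fitting requires layers).
#' @param coords Optional 2-column matrix/data.frame of spot coordinates,
#'   rows matching spots.
#' @return A list of class `spatial_data`.
#' @export
spatial_data <- function(counts, layers, coords = NULL) {
  assert_count_matrix(counts)
  spots <- colnames(counts)
  if (!is.null(layers)) {
    if (!is.null(names(layers))) {
      if (!all(spots %in% names(layers))) {
        stop("every spot needs a layer label")
      }
      layers <- layers[spots]
    } else if (length(layers) != ncol(counts)) {
      stop("`layers` must have one label per spot")
    }
    if (anyNA(layers)) stop("missing layer labels")
    layers <- factor(as.character(layers))
    names(layers) <- spots
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != ncol(counts) || ncol(coords) != 2) {
      stop("`coords` must be a spots x 2 matrix")
    }
    rownames(coords) <- spots
  }
  structure(list(counts = counts, layers = layers, coords = coords),
            class = "spatial_data")
}

#' @export
print.spatial_data <- function(x, ...) {
  cat("spatial_data:", nrow(x$counts), "genes x", ncol(x$counts),
      "spots", if (!is.null(x$layers))
        paste0("(", nlevels(x$layers), " layers)") else "(no layers)", "\n")
  invisible(x)
}

#' Prior on the layer-shift parameters
#'
#' The only prior in the spot-level MAP objective: independent
#' `N(0, t_prior_sd^2)` on every layer shift `T[L, g]`. Cell counts and
#' the gene-wise platform bias carry flat priors.
#'
#' @param t_prior_sd Standard deviation of the normal prior (default 1).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(t_prior_sd = 1) {
  stopifnot(is.numeric(t_prior_sd), length(t_prior_sd) == 1,
            t_prior_sd > 0)
  structure(list(t_prior_sd = t_prior_sd), class = "prior_spec")
}

#' Negative binomial size parameter of one spot and gene
#'
#' The spot-level model sums cell-level NB sizes over the spot's cells:
#' the size for spot s and gene g is
#' `sum_z beta_g * softplus(theta[g, z] + T[L_s, g]) * n[s, z]`.
#' This helper evaluates that sum for one spot/gene pair.
#'
#' @param n_s Non-negative cell counts per cell type (not all zero).
#' @param theta_g Pre-link locations per cell type for the gene.
#' @param t_lg Layer shift for the spot's layer and the gene.
#' @param beta_g Positive platform-bias factor for the gene.
#' @return The positive NB size parameter.
#' @export
spot_rate <- function(n_s, theta_g, t_lg, beta_g) {
  if (any(n_s < 0)) stop("cell counts must be non-negative")
  if (all(n_s == 0)) stop("cell counts must not all be zero")
  if (beta_g <= 0) stop("`beta_g` must be positive")
  if (length(theta_g) != length(n_s)) {
    stop("`theta_g` and `n_s` must have one entry per cell type")
  }
  sum(beta_g * softplus(theta_g + t_lg) * n_s)
}

#' Deconvolve spatial spots with layer-aware MAP estimation
#'
#' With cell-type profiles `theta` and dispersions `P` fixed from the
#' reference fit, estimates per-spot cell counts `n` (spots x types),
#' layer-wise expression shifts `T` (layers x genes) and gene-wise
#' platform bias `beta` by maximising
#' \deqn{\sum_{s,g} \log NB(X_{sg};\ \sum_z \beta_g\,
#'   \mathrm{softplus}(\theta_{gz} + T_{L_s g})\, n_{sz},\ P_g)
#'   + \sum_{L,g} \log N(T_{Lg}; 0, \sigma_T^2).}
#' Positivity is enforced by construction: `n = softplus(eta)` and
#' `beta = exp(b)` with unconstrained `eta`, `b`. Gene sets are
#' harmonised by exact-id intersection in reference order; spots with
#' zero total counts over the shared genes are dropped with a warning.
#' The optimisation is deterministic (no random initialisation).
#'
#' @param st A [spatial_data()] object with layer labels.
#' @param ref_model A fitted [fit_reference()] model.
#' @param prior Layer-shift prior, see [prior_spec()].
#' @param control Optimiser settings, see [fit_control()].
#' @param init Optional warm start: list with any of `n` (spots x types),
#'   `T` (layers x genes), `beta` (genes). Used by the permutation test to
#'   reuse the observed fit's composition estimates.
#' @return A list of class `spatial_fit`: `n`, `T`, `beta`, plus the
#'   harmonised `theta`, `P`, `gene_ids`, `spot_ids`, `layers`,
#'   `objective_trace` (non-decreasing penalised log-likelihood),
#'   `logPosterior`, `dropped_spots`, `prior`, `converged`.
#' @export
fit_spatial <- function(st, ref_model, prior = prior_spec(),
                        control = fit_control(), init = NULL) {
  stopifnot(inherits(st, "spatial_data"), inherits(ref_model, "ref_model"),
            inherits(prior, "prior_spec"))
  if (is.null(st$layers)) stop("`st` must carry per-spot layer labels")
  common <- intersect(ref_model$gene_ids, rownames(st$counts))
  if (length(common) < 10) {
    stop("only ", length(common), " genes shared between reference and ",
         "spatial data after harmonization; check gene identifiers and ",
         "filtering settings")
  }
  counts <- st$counts[common, , drop = FALSE]
  tot <- Matrix::colSums(counts)
  dropped <- colnames(counts)[tot == 0]
  if (length(dropped) > 0) {
    warning(length(dropped), " spot(s) with zero total counts dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    counts <- counts[, tot > 0, drop = FALSE]
  }
  layers <- droplevels(st$layers[colnames(counts)])
  theta <- ref_model$theta[common, , drop = FALSE]
  P <- ref_model$P[common]
  o <- ref_model$o[common]
  log_p <- -softplus(-o)
  log_1mp <- -softplus(o)

  X <- dense_counts(counts)
  G <- nrow(X); S <- ncol(X); Z <- ncol(theta); L <- nlevels(layers)
  rsX <- rowSums(X)
  lfact <- sum(lfactorial(X))
  sd2 <- prior$t_prior_sd^2

  # init: balanced composition scaled to the spot's total counts, no layer
  # effect, unit platform bias (unless warm-started)
  mu_cell <- sum(rowMeans(softplus(theta)) * P / (1 - P))
  n0 <- matrix(pmax(colSums(X) / (Z * mu_cell), 1e-2), S, Z)
  T0 <- matrix(0, L, G)
  b0 <- rep(0, G)
  if (!is.null(init)) {
    if (!is.null(init$n)) n0 <- matrix(pmax(init$n, 1e-6), S, Z)
    if (!is.null(init$T)) T0 <- matrix(init$T, L, G)
    if (!is.null(init$beta)) b0 <- log(init$beta)
  }
  par0 <- c(softplus_inv(n0), T0, b0)

  unpack <- function(par) {
    list(eta = matrix(par[seq_len(S * Z)], S, Z),
         T = matrix(par[S * Z + seq_len(L * G)], L, G),
         b = par[S * Z + L * G + seq_len(G)])
  }
  prior_const <- -L * G * log(prior$t_prior_sd * sqrt(2 * pi))
  Xi <- X
  storage.mode(Xi) <- "integer"
  layer_int <- as.integer(layers)
  const_term <- sum(rsX * log_p) - lfact + prior_const
  fngr <- function(par) {
    pr <- unpack(par)
    n <- softplus(pr$eta)
    beta <- exp(pr$b)
    bM <- vector("list", L)
    bsig <- vector("list", L)
    for (l in seq_len(L)) {
      th_l <- theta + rep(pr$T[l, ], times = Z)
      bM[[l]] <- beta * softplus(th_l)
      bsig[[l]] <- beta * sigmoid(th_l)
    }
    k <- spatial_nb_kernel(n, bM, bsig, layer_int, Xi, log_1mp)
    obj <- k$objective + const_term - sum(pr$T^2) / (2 * sd2)
    g_eta <- k$g_n * sigmoid(pr$eta)
    g_T <- k$g_T - pr$T / sd2
    list(objective = obj, gradient = c(g_eta, g_T, k$g_b))
  }

  lower <- c(rep(-30, S * Z), rep(-20, L * G), rep(-10, G))
  upper <- c(rep(1e3, S * Z), rep(20, L * G), rep(10, G))
  res <- maximize_lbfgs(par0, fngr, lower, upper, control)
  pr <- unpack(res$par)
  n <- softplus(pr$eta)
  dimnames(n) <- list(colnames(counts), colnames(theta))
  Tm <- pr$T
  dimnames(Tm) <- list(levels(layers), common)
  beta <- exp(pr$b)
  names(beta) <- common
  structure(list(n = n, T = Tm, beta = beta, theta = theta, P = P,
                 gene_ids = common, spot_ids = colnames(counts),
                 layers = layers, objective_trace = res$trace,
                 logPosterior = res$objective, dropped_spots = dropped,
                 prior = prior, converged = res$converged),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat("spatial_fit:", length(x$spot_ids), "spots,", ncol(x$n),
      "cell types,", nrow(x$T), "layers,", length(x$gene_ids),
      "genes; log-posterior =", format(x$logPosterior, digits = 8), "\n")
  invisible(x)
}

#' Per-spot cell-type proportions
#'
#' Normalises the fitted (or true) cell counts of each spot to sum to one.
#'
#' @param fit A `spatial_fit` object, or a spots x types matrix of
#'   non-negative cell counts.
#' @return Matrix of proportions, rows summing to 1.
#' @export
proportions <- function(fit) {
  n <- if (inherits(fit, "spatial_fit")) fit$n else as.matrix(fit)
  if (any(n < 0)) stop("cell counts must be non-negative")
  tot <- rowSums(n)
  if (any(tot == 0)) {
    bad <- rownames(n)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("spot(s) with zero total cell count: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n / tot
}

#' Write proportions as CSV
#'
#' Spots x cell-types table with a header row of cell-type names and
#' values rounded to 6 decimals.
#'
#' @param v Proportion matrix (e.g. from [proportions()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(v, path) {
  df <- data.frame(spot_id = rownames(v), round(v, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
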