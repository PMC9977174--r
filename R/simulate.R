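#' Configuration of the pseudo-spot simulation
#'
#' Defaults reproduce the package's reference study conditions: 100 genes
#' in six cell types, cell counts per type drawn from N(500, 100^2)
#' (rounded, floored at 1), each cell assigned to one of two layers with
#' layer-2 probability 0.3, counts drawn from
#' `NB(softplus(theta + T), P)` with `theta ~ N(theta_mean, theta_sd^2)`
#' (mean 0 by default, -2 in the sparse regime), layer shifts
#' `T ~ N(0, t_sd^2)` and gene dispersions `P ~ U(p_low, p_high)`.
#' Pseudo-spots pool 10-16 cells drawn with replacement from one layer:
#' 50 spots in layer 1 and 150 in layer 2. A fraction `1 - lde_fraction`
#' of genes has its shifts fixed at zero (no layer effect); the zeroed
#' genes are the first `ceiling((1 - lde_fraction) * n_genes)` in index
#' order and are recorded in the truth.
#'
#' @param n_genes,n_types Numbers of genes and cell types.
#' @param cells_per_type_mean,cells_per_type_sd Normal draw for the
#'   per-type cell count.
#' @param layer_prob Per-cell probability of layer 2 (Bernoulli).
#' @param theta_mean,theta_sd Normal draw for pre-link locations.
#' @param t_sd Standard deviation of the layer shifts.
#' @param p_low,p_high Uniform range of the gene dispersions.
#' @param spots_layer1,spots_layer2 Spot counts per layer.
#' @param cells_per_spot_min,cells_per_spot_max Discrete-uniform range
#'   (inclusive) of cells pooled per spot.
#' @param lde_fraction Fraction m of genes carrying a layer shift.
#' @param seed Integer seed; the whole output is determined by it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L, n_types = 6L,
                       cells_per_type_mean = 500, cells_per_type_sd = 100,
                       layer_prob = 0.3, theta_mean = 0, theta_sd = 1,
                       t_sd = 1, p_low = 0.2, p_high = 0.8,
                       spots_layer1 = 50L, spots_layer2 = 150L,
                       cells_per_spot_min = 10L, cells_per_spot_max = 16L,
                       lde_fraction = 1, seed = NULL) {
  stopifnot(n_genes >= 1, n_types >= 1, cells_per_type_mean > 0,
            cells_per_type_sd >= 0, layer_prob > 0, layer_prob < 1,
            theta_sd >= 0, t_sd >= 0, p_low > 0, p_high < 1,
            p_low < p_high, spots_layer1 >= 1, spots_layer2 >= 1,
            cells_per_spot_min >= 1,
            cells_per_spot_max >= cells_per_spot_min,
            lde_fraction >= 0, lde_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 cells_per_type_mean = cells_per_type_mean,
                 cells_per_type_sd = cells_per_type_sd,
                 layer_prob = layer_prob, theta_mean = theta_mean,
                 theta_sd = theta_sd, t_sd = t_sd, p_low = p_low,
                 p_high = p_high, spots_layer1 = as.integer(spots_layer1),
                 spots_layer2 = as.integer(spots_layer2),
                 cells_per_spot_min = as.integer(cells_per_spot_min),
                 cells_per_spot_max = as.integer(cells_per_spot_max),
                 lde_fraction = lde_fraction, seed = seed),
            class = "sim_config")
}

#' Simulate single cells with cell-type and layer structure
#'
#' Draws the generative parameters (`theta`, `T`, `P`), assigns each cell
#' a type and a layer, and samples its gene counts from the cell-level
#' negative binomial model. Sets the RNG seed from `cfg$seed` when
#' provided; the result is fully determined by that seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cells`: `counts` (genes x cells),
#'   `cell_types`, `layers` (both named factors), and `truth` with the
#'   drawn `theta` (genes x types), `T` (2 x genes), `P`, and the logical
#'   `lde_genes` mask of genes whose shifts were not zeroed.
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  G <- cfg$n_genes; Z <- cfg$n_types
  genes <- paste0("gene", seq_len(G))
  types <- paste0("type", seq_len(Z))

  n_per_type <- pmax(1L, as.integer(round(
    stats::rnorm(Z, cfg$cells_per_type_mean, cfg$cells_per_type_sd))))
  C <- sum(n_per_type)
  zc <- rep(seq_len(Z), times = n_per_type)
  layer <- stats::rbinom(C, 1L, cfg$layer_prob) + 1L   # 0 -> layer 1

  theta <- matrix(stats::rnorm(G * Z, cfg$theta_mean, cfg$theta_sd), G, Z,
                  dimnames = list(genes, types))
  T_mat <- matrix(stats::rnorm(2 * G, 0, cfg$t_sd), 2, G,
                  dimnames = list(c("layer1", "layer2"), genes))
  n_zero <- ceiling((1 - cfg$lde_fraction) * G)
  lde_genes <- rep(TRUE, G)
  if (n_zero > 0) {
    T_mat[, seq_len(n_zero)] <- 0
    lde_genes[seq_len(n_zero)] <- FALSE
  }
  P <- stats::runif(G, cfg$p_low, cfg$p_high)
  names(P) <- genes

  tT <- t(T_mat)                                        # G x 2
  size <- softplus(theta[, zc, drop = FALSE] + tT[, layer, drop = FALSE])
  counts <- matrix(stats::rnbinom(G * C, size = as.vector(size),
                                  prob = rep(1 - P, times = C)),
                   G, C)
  cells <- paste0("cell", seq_len(C))
  dimnames(counts) <- list(genes, cells)
  structure(list(
    counts = count_matrix(counts),
    cell_types = stats::setNames(factor(types[zc], levels = types), cells),
    layers = stats::setNames(
      factor(paste0("layer", layer), levels = c("layer1", "layer2")), cells),
    truth = list(theta = theta, T = T_mat, P = P, lde_genes = lde_genes)),
    class = "sim_cells")
}

#' Pool simulated cells into pseudo-spots
#'
#' Builds `spots_layer1 + spots_layer2` pseudo-spots. Each spot draws its
#' cell count uniformly from the integers
#' `cells_per_spot_min:cells_per_spot_max`, samples that many cells with
#' replacement from the cells of its own layer, and sums their gene
#' counts. The sampled membership, true per-spot cell counts `n_star`
#' and proportions `v_star` are recorded as ground truth. Continues the
#' current RNG stream (set `seed` to reseed explicitly).
#'
#' @param cells A [simulate_cells()] result.
#' @param cfg The same [sim_config()].
#' @param seed Optional seed for standalone use.
#' @return List with `spatial` (a [spatial_data()]) and `truth`
#'   (`n_star`, `v_star`, `members`, `cells_per_spot`).
#' @export
assemble_spots <- function(cells, cfg, seed = NULL) {
  stopifnot(inherits(cells, "sim_cells"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  X <- dense_counts(cells$counts)
  by_layer <- split(seq_len(ncol(X)), cells$layers)
  if (any(lengths(by_layer) == 0)) stop("a layer has no cells to sample")
  S <- cfg$spots_layer1 + cfg$spots_layer2
  spot_layer <- rep(c("layer1", "layer2"),
                    c(cfg$spots_layer1, cfg$spots_layer2))
  size_vals <- seq.int(cfg$cells_per_spot_min, cfg$cells_per_spot_max)
  sizes <- size_vals[sample.int(length(size_vals), S, replace = TRUE)]
  types <- levels(cells$cell_types)
  spots <- paste0("spot", seq_len(S))
  counts <- matrix(0, nrow(X), S, dimnames = list(rownames(X), spots))
  n_star <- matrix(0, S, length(types), dimnames = list(spots, types))
  members <- vector("list", S)
  for (s in seq_len(S)) {
    pool <- by_layer[[spot_layer[s]]]
    idx <- pool[sample.int(length(pool), sizes[s], replace = TRUE)]
    members[[s]] <- idx
    counts[, s] <- rowSums(X[, idx, drop = FALSE])
    n_star[s, ] <- table(factor(cells$cell_types[idx], levels = types))
  }
  layers <- stats::setNames(
    factor(spot_layer, levels = c("layer1", "layer2")), spots)
  list(spatial = spatial_data(count_matrix(counts), layers),
       truth = list(n_star = n_star, v_star = n_star / rowSums(n_star),
                    members = members, cells_per_spot = sizes))
}

#' Simulate a matched single-cell reference and pseudo-spot dataset
#'
#' One call to [simulate_cells()] followed by [assemble_spots()] under a
#' single RNG stream seeded by `cfg$seed`: the simulated cells serve both
#' as the single-cell reference (their layer labels are withheld from the
#' reference, mirroring real scRNA-seq) and as the pool from which
#' pseudo-spots are assembled.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_output`: `reference` (a
#'   [reference_data()]), `spatial` (a [spatial_data()]), `cells` (the
#'   raw `sim_cells`), and `truth` combining the generative parameters
#'   with the realised spot compositions.
#' @export
simulate_dataset <- function(cfg) {
  cells <- simulate_cells(cfg)
  sp <- assemble_spots(cells, cfg)
  truth <- c(cells$truth, sp$truth, list(cell_layers = cells$layers))
  structure(list(
    reference = reference_data(cells$counts, cells$cell_types),
    spatial = sp$spatial, cells = cells, truth = truth),
    class = "sim_output")
}

#' True layer-1-over-layer-2 log2 fold change of a simulation
#'
#' Evaluates the same between-layer fold change used for inference
#' ([fold_change()], including the max-over-types reduction) on the true
#' generative `theta` and `T`, and returns its log2 for layer 1.
#'
#' @param sim A `sim_output` (or any list with `truth$theta`, `truth$T`).
#' @return Named numeric vector over genes.
#' @export
true_log2fc <- function(sim) {
  tr <- if (!is.null(sim$truth)) sim$truth else sim
  log2(fold_change(tr$theta, tr$T))["layer1", ]
}

#' Grid single-cell resolution spatial data into pseudo-spots
#'
#' Mimics low-resolution spot data from single-cell resolution platforms:
#' cells are assigned to half-open rectangular bins of size
#' `bin_x` x `bin_y` (0-based bin indices, origin at the minimum
#' coordinate unless given), counts are summed per bin, empty bins are
#' dropped, and the true composition of each bin is tallied from the cell
#' labels.
#'
#' @param counts Gene x cell count matrix.
#' @param coords Cells x 2 matrix of coordinates.
#' @param labels Per-cell type labels (named or in column order).
#' @param bin_x,bin_y Bin sizes, > 0.
#' @param origin Optional length-2 origin; defaults to the coordinate
#'   minima.
#' @return List with `spatial` (a [spatial_data()] without layers),
#'   `truth` (`n_star`, `v_star`) and `bins` (per-cell bin assignment).
#' @export
grid_cells <- function(counts, coords, labels, bin_x, bin_y,
                       origin = NULL) {
  assert_count_matrix(counts)
  coords <- as.matrix(coords)
  if (bin_x <= 0 || bin_y <= 0) stop("bin sizes must be positive")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (nrow(coords) != ncol(counts)) stop("one coordinate pair per cell")
  if (!is.null(names(labels))) labels <- labels[colnames(counts)]
  labels <- factor(as.character(labels))
  if (is.null(origin)) origin <- c(min(coords[, 1]), min(coords[, 2]))
  ix <- floor((coords[, 1] - origin[1]) / bin_x)
  iy <- floor((coords[, 2] - origin[2]) / bin_y)
  bin <- paste0("bin_", ix, "_", iy)
  keys <- unique(bin)
  X <- dense_counts(counts)
  S <- length(keys)
  out <- matrix(0, nrow(X), S, dimnames = list(rownames(X), keys))
  n_star <- matrix(0, S, nlevels(labels),
                   dimnames = list(keys, levels(labels)))
  for (s in seq_len(S)) {
    idx <- which(bin == keys[s])
    out[, s] <- rowSums(X[, idx, drop = FALSE])
    n_star[s, ] <- table(labels[idx])
  }
  list(spatial = spatial_data(count_matrix(out), layers = NULL),
       truth = list(n_star = n_star, v_star = n_star / rowSums(n_star)),
       bins = stats::setNames(bin, colnames(counts)))
}
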