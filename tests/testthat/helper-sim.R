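# Shared fixtures: all test data is generated in code under fixed seeds.

# A small, fast study: fewer genes/types/spots than the default
# conditions, for unit tests that exercise the fitting machinery without
# needing the full-size dataset.
small_sim_config <- function(seed = 42L, ...) {
  sim_config(n_genes = 50L, n_types = 3L, cells_per_type_mean = 120,
             cells_per_type_sd = 10, spots_layer1 = 20L,
             spots_layer2 = 40L, seed = seed, ...)
}

# Loose optimizer settings used where only qualitative convergence
# matters, to keep unit tests quick.
quick_control <- function() fit_control(factr = 1e9)

# Tiny deterministic count matrix with default dimnames.
toy_counts <- function(m, genes = paste0("g", seq_len(nrow(m))),
                       units = paste0("u", seq_len(ncol(m)))) {
  count_matrix(as.matrix(m), gene_ids = genes, unit_ids = units)
}

# Central finite-difference gradient of f at x.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
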