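test_that("default configuration reproduces the study dimensions", {
  sim <- simulate_dataset(sim_config(seed = 101L))
  expect_identical(ncol(sim$spatial$counts), 200L)
  tab <- table(sim$spatial$layers)
  expect_identical(as.integer(tab[c("layer1", "layer2")]), c(50L, 150L))
  cps <- sim$truth$cells_per_spot
  expect_true(all(cps >= 10 & cps <= 16))
  # roughly 6 x 500 cells; layer-2 fraction near 0.3
  C <- ncol(sim$reference$counts)
  expect_lt(abs(C - 3000), 4 * sqrt(6) * 100)
  frac2 <- mean(sim$truth$cell_layers == "layer2")
  expect_lt(abs(frac2 - 0.3), 3 * sqrt(0.3 * 0.7 / C))
  expect_identical(nrow(sim$reference$counts), 100L)
  expect_identical(nlevels(sim$reference$cell_types), 6L)
})

test_that("spot counts equal the sums of their member cells", {
  sim <- simulate_dataset(small_sim_config(seed = 102L))
  X_cells <- as.matrix(sim$cells$counts)
  X_spots <- as.matrix(sim$spatial$counts)
  for (s in seq_along(sim$truth$members)) {
    expect_identical(X_spots[, s],
                     rowSums(X_cells[, sim$truth$members[[s]],
                                     drop = FALSE]))
  }
  # composition truth tallies the member types and normalizes
  expect_equal(unname(rowSums(sim$truth$n_star)),
               as.numeric(sim$truth$cells_per_spot))
  expect_equal(unname(rowSums(sim$truth$v_star)),
               rep(1, nrow(sim$truth$v_star)))
})

test_that("identical seeds give identical output", {
  a <- simulate_dataset(small_sim_config(seed = 103L))
  b <- simulate_dataset(small_sim_config(seed = 103L))
  expect_identical(as.matrix(a$reference$counts),
                   as.matrix(b$reference$counts))
  expect_identical(as.matrix(a$spatial$counts),
                   as.matrix(b$spatial$counts))
  expect_identical(a$truth$theta, b$truth$theta)
  expect_identical(a$truth$members, b$truth$members)
  c_ <- simulate_dataset(small_sim_config(seed = 104L))
  expect_false(identical(as.matrix(a$spatial$counts),
                         as.matrix(c_$spatial$counts)))
})

test_that("the layer-shift mask follows the configured fraction", {
  G <- small_sim_config()$n_genes
  sim0 <- simulate_cells(small_sim_config(seed = 105L, lde_fraction = 0))
  expect_true(all(sim0$truth$T == 0))
  expect_true(all(!sim0$truth$lde_genes))
  expect_equal(unname(true_log2fc(sim0)), rep(0, G))

  sim_half <- simulate_cells(small_sim_config(seed = 105L,
                                              lde_fraction = 0.5))
  expect_identical(sum(sim_half$truth$lde_genes), G %/% 2L)
  expect_true(all(sim_half$truth$T[, seq_len(ceiling(G / 2))] == 0))

  # degenerate shift scale: every gene non-LDE even at fraction 1
  sim_flat <- simulate_cells(small_sim_config(seed = 106L, t_sd = 0))
  expect_equal(unname(true_log2fc(sim_flat)), rep(0, G))
})

test_that("simulated counts match the NB mean of the generative model", {
  cfg <- sim_config(n_genes = 10L, n_types = 1L,
                    cells_per_type_mean = 5000, cells_per_type_sd = 0,
                    seed = 107L)
  cells <- simulate_cells(cfg)
  X <- as.matrix(cells$counts)
  tr <- cells$truth
  for (l in c("layer1", "layer2")) {
    idx <- which(cells$layers == l)
    mu_hat <- rowMeans(X[, idx, drop = FALSE])
    mu <- softplus(tr$theta[, 1] + tr$T[l, ]) * tr$P / (1 - tr$P)
    sd_mu <- sqrt(mu / (1 - tr$P)) / sqrt(length(idx)) # NB sd / sqrt(n)
    expect_true(all(abs(mu_hat - mu) < 5 * sd_mu + 1e-3))
  }
})

test_that("coordinate gridding bins half-open, conserves counts", {
  X <- toy_counts(matrix(1:12, 3, 4), genes = paste0("g", 1:3),
                  units = paste0("cell", 1:4))
  coords <- rbind(c(10, 10), c(390, 390), c(400, 10), c(799, 799))
  labels <- c("a", "a", "b", "b")
  gr <- grid_cells(X, coords, labels, 400, 400, origin = c(0, 0))
  bins <- unname(gr$bins)
  expect_identical(bins[1], bins[2])        # same 400x400 bin
  expect_identical(bins[3], "bin_1_0")      # x = 400 falls in bin 1
  expect_identical(bins[4], "bin_1_1")
  expect_equal(sum(as.matrix(gr$spatial$counts)), sum(as.matrix(X)))
  expect_equal(unname(rowSums(gr$truth$v_star)),
               rep(1, nrow(gr$truth$v_star)))
  # composition tallied from labels
  b0 <- bins[1]
  expect_equal(unname(gr$truth$n_star[b0, ]), c(2, 0))
  expect_error(grid_cells(X, coords, labels, -1, 400), "positive")
})
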