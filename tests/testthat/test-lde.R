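test_that("fold_change matches hand evaluation and brute force", {
  # identical shifts across layers: fold change 1 everywhere
  theta <- matrix(stats::rnorm(12), 4, 3)
  T_same <- rbind(rep(0.7, 4), rep(0.7, 4))
  expect_equal(unname(fold_change(theta, T_same)),
               matrix(1, 2, 4), tolerance = 1e-12)

  # two layers, one type: ratio of softplus locations
  fc <- fold_change(matrix(0, 1, 1), rbind(1, -1))
  expect_equal(fc[1, 1], softplus(1) / softplus(-1), tolerance = 1e-9)
  expect_equal(fc[2, 1], softplus(-1) / softplus(1), tolerance = 1e-9)

  # brute force over layers and types on random instances
  set.seed(33)
  for (rep in 1:5) {
    G <- 6; Z <- 4; L <- 3
    theta <- matrix(stats::rnorm(G * Z), G, Z)
    Tm <- matrix(stats::rnorm(L * G), L, G)
    fc <- fold_change(theta, Tm)
    for (l in seq_len(L)) {
      for (g in seq_len(G)) {
        ratios <- vapply(seq_len(Z), function(z) {
          num <- softplus(theta[g, z] + Tm[l, g])
          den <- mean(vapply(setdiff(seq_len(L), l), function(lp) {
            softplus(theta[g, z] + Tm[lp, g])
          }, numeric(1)))
          num / den
        }, numeric(1))
        expect_equal(fc[l, g], max(ratios), tolerance = 1e-10)
      }
    }
  }
  # max over types picks the larger per-type ratio
  theta2 <- matrix(c(0, 5), 1, 2)
  Tm2 <- rbind(1, -1)
  fc2 <- fold_change(theta2, Tm2)
  r_by_type <- c(softplus(0 + 1) / softplus(0 - 1),
                 softplus(5 + 1) / softplus(5 - 1))
  expect_equal(fc2[1, 1], max(r_by_type), tolerance = 1e-10)

  expect_error(fold_change(theta2, matrix(0, 1, 1)), "single layer")
})

test_that("lde_pvalue counts strict exceedances with no pseudo-count", {
  expect_equal(lde_pvalue(2.0, c(0.5, 1.0, 2.5)), 1 / 3)
  expect_equal(lde_pvalue(5, c(0.5, 1.0, 2.5)), 0)
  expect_equal(lde_pvalue(0, stats::rnorm(100) + 1e-9), 1)
  expect_equal(lde_pvalue(-2.0, c(0.5, -1.0, 2.5, -2.5)), 0.5)
  expect_error(lde_pvalue(1, numeric(0)), "non-empty")
})

test_that("the decision rule gates on Bonferroni p and |log2FC|", {
  cfg <- lde_config(n_permutations = 10L)
  expect_true(call_lde(1e-4, 1.5, 100, cfg))
  expect_false(call_lde(1e-4, 0.5, 100, cfg))    # effect-size gate
  expect_false(call_lde(0.01, 3, 100, cfg))      # 0.01 >= 0.05/100
  expect_false(call_lde(1e-4, -0.5, 100, cfg))
  expect_true(call_lde(1e-4, -1.5, 100, cfg))    # down-regulation passes
  expect_error(call_lde(0.5, 1, 0, cfg), "at least 1")
})

test_that("permutation p-values are multiples of 1/N in [0, 1]", {
  sim <- simulate_dataset(small_sim_config(seed = 13L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  res <- run_lde(sim$spatial, rm_,
                 lde_config(n_permutations = 10L, seed = 4L),
                 fit = fit, control = quick_control())
  expect_true(all(res$p_values >= 0 & res$p_values <= 1))
  expect_true(all(abs(res$p_values * 10 -
                        round(res$p_values * 10)) < 1e-12))
  expect_identical(dim(res$is_lde), dim(res$p_values))
})

test_that("an identity permutation reproduces the observed shifts", {
  sim <- simulate_dataset(small_sim_config(seed = 14L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  # refit under the observed labels from the permutation warm start:
  # optimizer noise aside, the shifts must agree
  refit <- fit_spatial(sim$spatial, rm_, control = quick_control(),
                       init = list(n = fit$n, beta = fit$beta,
                                   T = matrix(0, nrow(fit$T), ncol(fit$T))))
  expect_equal(refit$T, fit$T, tolerance = 0.05)
  expect_gt(stats::cor(as.vector(refit$T), as.vector(fit$T)), 0.99)
})

test_that("warm and cold permutation starts give matching p-values", {
  sim <- simulate_dataset(small_sim_config(seed = 15L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  p_warm <- run_lde(sim$spatial, rm_,
                    lde_config(n_permutations = 50L, seed = 8L,
                               warm_start = TRUE),
                    fit = fit, control = quick_control())$p_values
  p_cold <- run_lde(sim$spatial, rm_,
                    lde_config(n_permutations = 50L, seed = 8L,
                               warm_start = FALSE),
                    fit = fit, control = quick_control())$p_values
  # same seed, same permutations; only the refit initialization differs,
  # so p-values may move by a few near-tied comparisons at most
  expect_gt(stats::cor(as.vector(p_warm), as.vector(p_cold)), 0.9)
  expect_lt(mean(abs(p_warm - p_cold)), 0.04)
  expect_lt(max(abs(p_warm - p_cold)), 0.15)
})

test_that("permutation layers are relabelings preserving layer sizes", {
  sim <- simulate_dataset(small_sim_config(seed = 16L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  sims <- permutation_null(sim$spatial, rm_,
                           lde_config(n_permutations = 3L, seed = 2L),
                           fit = fit, control = quick_control())
  expect_identical(dim(sims), c(3L, 2L, length(fit$gene_ids)))
  expect_true(all(is.finite(sims)))
})

test_that("lde output files round the results faithfully", {
  sim <- simulate_dataset(small_sim_config(seed = 17L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  res <- run_lde(sim$spatial, rm_,
                 lde_config(n_permutations = 5L, seed = 3L),
                 fit = fit, control = quick_control())
  dir <- withr::local_tempdir()
  files <- write_lde_result(res, dir)
  expect_true(all(file.exists(files)))
  tab <- utils::read.csv(file.path(dir, "lde_layer1.csv"))
  expect_identical(tab$gene, colnames(res$p_values))
  expect_equal(tab$p_value, unname(res$p_values["layer1", ]))
  manifest <- readLines(file.path(dir, "lde_manifest.txt"))
  expect_true(any(grepl("n_permutations=5", manifest)))
  expect_true(any(grepl("seed=3", manifest)))
})
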