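test_that("spot_rate evaluates the additive NB size", {
  # single-cell reduction and hand evaluation
  expect_equal(spot_rate(c(1, 0), c(0.3, 2), 0, 1), softplus(0.3),
               tolerance = 1e-12)
  expect_equal(spot_rate(c(2, 3), c(0, 1), 0, 1),
               2 * log(2) + 3 * log(1 + exp(1)), tolerance = 1e-6)
  # linearity in n
  n <- c(1.5, 0.7, 2)
  th <- c(-1, 0.2, 1.1)
  expect_equal(spot_rate(2 * n, th, 0.5, 1.3),
               2 * spot_rate(n, th, 0.5, 1.3), tolerance = 1e-12)
  expect_error(spot_rate(c(-1, 1), c(0, 0), 0, 1), "non-negative")
  expect_error(spot_rate(c(0, 0), c(0, 0), 0, 1), "not all")
  expect_error(spot_rate(c(1, 1), c(0, 0), 0, -2), "positive")
})

test_that("spatial MAP objective gradient matches finite differences", {
  set.seed(21)
  cfg <- sim_config(n_genes = 12L, n_types = 2L, cells_per_type_mean = 60,
                    cells_per_type_sd = 5, spots_layer1 = 6L,
                    spots_layer2 = 8L, seed = 77L)
  sim <- simulate_dataset(cfg)
  rm_ <- fit_reference(sim$reference, quick_control())
  # one optimizer segment from the package init, then probe the
  # objective surface around the returned point via refits with
  # perturbed warm starts: instead compare analytic vs numeric gradient
  # through the exported objective pieces
  fit <- fit_spatial(sim$spatial, rm_, control = fit_control(max_iter = 5,
                                                             segment_iter = 5))
  G <- length(fit$gene_ids); Z <- ncol(fit$n); L <- nrow(fit$T)
  S <- length(fit$spot_ids)
  obj_of <- function(par) {
    n <- matrix(softplus(par[seq_len(S * Z)]), S, Z)
    Tm <- matrix(par[S * Z + seq_len(L * G)], L, G)
    beta <- exp(par[S * Z + L * G + seq_len(G)])
    ll <- sum(stats::dnorm(Tm, 0, fit$prior$t_prior_sd, log = TRUE))
    X <- as.matrix(sim$spatial$counts)[fit$gene_ids, fit$spot_ids]
    for (s in seq_len(S)) {
      l <- as.integer(fit$layers[s])
      r <- vapply(seq_len(G), function(g) {
        spot_rate(n[s, ], fit$theta[g, ], Tm[l, g], beta[g])
      }, numeric(1))
      ll <- ll + sum(nb_log_pmf(X[, s], r, fit$P))
    }
    ll
  }
  par0 <- c(softplus_inv(fit$n), fit$T, log(fit$beta))
  probe <- sample(length(par0), 12)
  g_num <- fd_grad(obj_of, par0)[probe]
  # analytic gradient via a tiny refit step: recompute through the same
  # internal evaluator used by fit_spatial
  fngr <- environment(NULL)
  g_ana <- local({
    # reconstruct the analytic gradient from the model equations
    n <- fit$n; Tm <- fit$T; beta <- fit$beta
    X <- as.matrix(sim$spatial$counts)[fit$gene_ids, fit$spot_ids]
    g_eta <- matrix(0, S, Z); g_T <- matrix(0, L, G); g_b <- numeric(G)
    for (s in seq_len(S)) {
      l <- as.integer(fit$layers[s])
      th_l <- fit$theta + rep(Tm[l, ], times = Z)
      M <- softplus(th_l)
      r <- as.vector((beta * M) %*% n[s, ])
      A <- digamma(X[, s] + r) - digamma(r) + log1p(-fit$P)
      g_eta[s, ] <- t(A) %*% (beta * M)
      g_T[l, ] <- g_T[l, ] + beta * (sigmoid(th_l) %*% n[s, ]) * A
      g_b <- g_b + A * r
    }
    g_T <- g_T - Tm / fit$prior$t_prior_sd^2
    g_eta <- g_eta * sigmoid(softplus_inv(n))
    unname(c(g_eta, g_T, g_b)[probe])
  })
  expect_equal(g_ana, unname(g_num), tolerance = 1e-4)
})

test_that("fitted proportions recover simulated composition better than uniform", {
  sim <- simulate_dataset(small_sim_config(seed = 5L))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  expect_true(all(diff(fit$objective_trace) >= -1e-6))
  v <- proportions(fit)
  expect_equal(unname(rowSums(v)), rep(1, nrow(v)), tolerance = 1e-10)
  err <- rmse(v, sim$truth$v_star[rownames(v), colnames(v)])
  base <- sqrt(mean((1 / ncol(v) - sim$truth$v_star)^2))
  expect_lt(err, base)
})

test_that("a tight prior with one layer collapses the shifts to zero", {
  sim <- simulate_dataset(small_sim_config(seed = 6L))
  st <- sim$spatial
  st$layers <- stats::setNames(
    factor(rep("only", length(st$layers))), names(st$layers))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(st, rm_, prior = prior_spec(1e-4),
                     control = quick_control())
  expect_equal(nrow(fit$T), 1L)
  expect_lt(max(abs(fit$T)), 1e-3)
})

test_that("shift matrix has one row per layer and one column per gene", {
  sim <- simulate_dataset(sim_config(seed = 31L, n_genes = 25L,
                                     n_types = 3L,
                                     cells_per_type_mean = 100,
                                     cells_per_type_sd = 10))
  rm_ <- fit_reference(sim$reference, quick_control())
  fit <- fit_spatial(sim$spatial, rm_, control = quick_control())
  expect_identical(dim(fit$T), c(2L, length(fit$gene_ids)))
  expect_identical(rownames(fit$T), c("layer1", "layer2"))
  expect_true(all(fit$beta > 0))
  expect_true(all(fit$n >= 0))
})

test_that("zero-count spots are dropped with a warning", {
  sim <- simulate_dataset(small_sim_config(seed = 7L))
  st <- sim$spatial
  counts <- as.matrix(st$counts)
  counts[, 3] <- 0L
  st2 <- spatial_data(count_matrix(counts), st$layers)
  rm_ <- fit_reference(sim$reference, quick_control())
  expect_warning(fit <- fit_spatial(st2, rm_, control = quick_control()),
                 "zero total counts")
  expect_identical(fit$dropped_spots, colnames(counts)[3])
  expect_false(colnames(counts)[3] %in% fit$spot_ids)
})

test_that("harmonization requires a usable shared gene set", {
  sim <- simulate_dataset(small_sim_config(seed = 8L))
  st <- sim$spatial
  rownames(st$counts) <- paste0("other_", rownames(st$counts))
  rm_ <- fit_reference(sim$reference, quick_control())
  expect_error(fit_spatial(st, rm_, control = quick_control()),
               "harmonization")
})

test_that("proportions normalizes rows and flags all-zero spots", {
  n <- rbind(s1 = c(2, 2, 2, 2, 2, 2), s2 = c(10, 0, 0, 0, 0, 0),
             s3 = c(1, 3, 0, 0, 0, 0))
  colnames(n) <- paste0("t", 1:6)
  v <- proportions(n)
  expect_equal(unname(v["s1", ]), rep(1 / 6, 6))
  expect_equal(unname(v["s2", ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(v["s3", 1:2]), c(0.25, 0.75))
  n0 <- rbind(ok = c(1, 1), bad = c(0, 0))
  expect_error(proportions(n0), "bad")
})
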