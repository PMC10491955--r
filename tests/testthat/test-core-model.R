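make_laps <- function(views, k1) lapply(lapply(views, knn_sparsify, k1 = k1),
                                        build_laplacian)

test_that("objective vanishes in the degenerate cases", {
  freq0 <- frequency_matrix(matrix(0, 3, 3), integer_classes = FALSE)
  p <- sefreq_params(k = 2, mu = 0)
  U <- matrix(0, 3, 2); V <- matrix(0, 2, 3)
  expect_equal(sefreq_objective(U, V, freq0, list(), list(),
                                numeric(0), numeric(0), p), 0)

  # perfect factorization of a fully known matrix, no regularization
  U <- rbind(c(1, 0), c(0, 1)); V <- rbind(c(1, 2), c(3, 4))
  R <- frequency_matrix(U %*% V)
  p2 <- sefreq_params(beta = 0, gamma = 0, k = 2)
  expect_equal(sefreq_objective(U, V, R, list(), list(),
                                numeric(0), numeric(0), p2), 0)
})

test_that("objective equals the elementwise double-loop oracle", {
  for (seed in 1:5) {
    inst <- random_instance(n = 10, m = 8, density = 0.5, seed = seed)
    graphs_d <- lapply(inst$drug_views, knn_sparsify, k1 = 3)
    graphs_e <- lapply(inst$effect_views, knn_sparsify, k1 = 3)
    p <- sefreq_params(k = 3, alpha = 0.2, mu = 1.5, beta = 1.3, gamma = 0.7,
                       delta = 2)
    withr::with_seed(seed + 50, {
      U <- matrix(runif(10 * 3), 10, 3)
      V <- matrix(runif(3 * 8), 3, 8)
    })
    w <- c(0.6, 0.4); h <- c(0.3, 0.7)
    expect_equal(
      sefreq_objective(U, V, inst$freq, lapply(graphs_d, build_laplacian),
                       lapply(graphs_e, build_laplacian), w, h, p),
      oracle_objective(U, V, inst$freq, graphs_d, graphs_e, w, h, p),
      tolerance = 1e-10)
  }
})

test_that("objective rejects inconsistent inputs", {
  inst <- random_instance(seed = 1)
  p <- sefreq_params(k = 3)
  expect_error(sefreq_objective(matrix(1, 4, 3), matrix(1, 3, 8), inst$freq,
                                list(), list(), numeric(0), numeric(0), p),
               "dimensions", ignore.case = TRUE)
  expect_error(sefreq_objective(matrix(NaN, 10, 3), matrix(1, 3, 8),
                                inst$freq, list(), list(), numeric(0),
                                numeric(0), p), "finite")
})

test_that("multiplicative updates preserve zeros and non-negativity", {
  inst <- random_instance(n = 8, m = 6, seed = 3)
  p <- sefreq_params(k = 3, k1 = 3)
  graphs_d <- lapply(inst$drug_views, knn_sparsify, k1 = 3)
  w <- rep(0.5, 2)
  U0 <- matrix(0, 8, 3); V0 <- matrix(runif(18), 3, 6)
  expect_equal(nmf_update_u(U0, V0, inst$freq, graphs_d, w, p),
               matrix(0, 8, 3), ignore_attr = TRUE)
  V00 <- matrix(0, 3, 6)
  expect_equal(nmf_update_v(matrix(runif(24), 8, 3), V00, inst$freq,
                            list(), numeric(0), p), matrix(0, 3, 6),
               ignore_attr = TRUE)
  expect_error(nmf_update_u(-U0 - 1, V0, inst$freq, graphs_d, w, p),
               "non-negative")

  for (seed in 1:100) {
    inst2 <- random_instance(n = 7, m = 6, seed = seed)
    withr::with_seed(seed, {
      U <- matrix(runif(7 * 3), 7, 3); V <- matrix(runif(3 * 6), 3, 6)
    })
    gd <- lapply(inst2$drug_views, knn_sparsify, k1 = 2)
    ge <- lapply(inst2$effect_views, knn_sparsify, k1 = 2)
    U1 <- nmf_update_u(U, V, inst2$freq, gd, c(0.5, 0.5), p)
    V1 <- nmf_update_v(U1, V, inst2$freq, ge, c(0.5, 0.5), p)
    expect_gte(min(U1), 0)
    expect_gte(min(V1), 0)
  }
})

test_that("with no regularization and all cells known the sweep is the classic weighted-NMF step", {
  # textbook multiplicative NMF on a fully observed matrix, written out
  # independently of the package's masked/guarded form
  withr::with_seed(42, {
    R <- matrix(sample(1:5, 30, TRUE), 6, 5)
    U0 <- matrix(runif(18), 6, 3)
    V0 <- matrix(runif(15), 3, 5)
  })
  freq <- frequency_matrix(R)
  p <- sefreq_params(beta = 0, gamma = 0, k = 3, eps = 1e-300)
  U1 <- nmf_update_u(U0, V0, freq, list(), numeric(0), p)
  U_classic <- U0 * (R %*% t(V0)) / ((U0 %*% V0) %*% t(V0))
  expect_equal(U1, U_classic, tolerance = 1e-10, ignore_attr = TRUE)
  V1 <- nmf_update_v(U1, V0, freq, list(), numeric(0), p)
  V_classic <- V0 * (t(U1) %*% R) / (t(U1) %*% (U1 %*% V0))
  expect_equal(V1, V_classic, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a full update sweep never increases the objective", {
  p <- sefreq_params(k = 4, k1 = 5, alpha = 0.05, mu = 1, beta = 2,
                     gamma = 2)
  for (seed in 1:20) {
    inst <- random_instance(n = 20, m = 15, density = 0.4, seed = seed)
    gd <- lapply(inst$drug_views, knn_sparsify, k1 = 5)
    ge <- lapply(inst$effect_views, knn_sparsify, k1 = 5)
    ld <- lapply(gd, build_laplacian); le <- lapply(ge, build_laplacian)
    withr::with_seed(seed + 7, {
      U <- matrix(runif(20 * 4), 20, 4); V <- matrix(runif(4 * 15), 4, 15)
    })
    U <- U / sqrt(sum(U^2)); V <- V / sqrt(sum(V^2))
    w <- rep(0.5, 2); h <- rep(0.5, 2)
    obj <- sefreq_objective(U, V, inst$freq, ld, le, w, h, p)
    for (it in 1:10) {
      U <- nmf_update_u(U, V, inst$freq, gd, w, p)
      V <- nmf_update_v(U, V, inst$freq, ge, h, p)
      w <- update_view_weights(sapply(ld, function(l) sum(U * (l$L %*% U))),
                               p$delta)
      h <- update_view_weights(sapply(le, function(l) sum((V %*% l$L) * V)),
                               p$delta)
      obj2 <- sefreq_objective(U, V, inst$freq, ld, le, w, h, p)
      expect_lte(obj2, obj + 1e-9)
      obj <- obj2
    }
  }
})

test_that("view-weight update matches direct evaluation and simplex grid search", {
  expect_equal(update_view_weights(c(2, 2, 2), 2), rep(1 / 3, 3))
  expect_equal(update_view_weights(c(1, 3), 2), c(0.75, 0.25))
  expect_error(update_view_weights(numeric(0), 2), "at least one")
  expect_error(update_view_weights(c(1, 2), 1), "delta")

  for (seed in 1:6) {
    traces <- withr::with_seed(seed, runif(if (seed %% 2) 2 else 3, 0.1, 5))
    for (delta in c(2, 3)) {
      w <- update_view_weights(traces, delta)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_gte(min(w), 0)
      w_grid <- oracle_simplex_grid(traces, delta)
      expect_lte(sum(w^delta * traces), sum(w_grid^delta * traces) + 1e-9)
      expect_lte(max(abs(w - w_grid)), 2e-3)
    }
  }
})

test_that("fitting is deterministic under a fixed seed", {
  inst <- random_instance(n = 12, m = 10, density = 0.5, seed = 9)
  p <- sefreq_params(k = 3, k1 = 4, max_iter = 30)
  f1 <- sefreq_fit(inst$freq, inst$drug_views, inst$effect_views,
                   params = p, seed = 5)
  f2 <- sefreq_fit(inst$freq, inst$drug_views, inst$effect_views,
                   params = p, seed = 5)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$U, f2$U)
  f3 <- sefreq_fit(inst$freq, inst$drug_views, inst$effect_views,
                   params = p, seed = 6)
  expect_false(identical(f1$objective, f3$objective))
})

test_that("fitting synthetic low-rank data decreases the objective", {
  sim <- simulate_frequency_data(n = 40, m = 50, rank = 3, density = 0.4,
                                 seed = 2)
  p <- sefreq_params(k = 5, k1 = 6, max_iter = 100)
  fit <- sefreq_fit(sim$freq, sim$drug_views, sim$effect_views, params = p,
                    seed = 1)
  expect_lt(tail(fit$objective, 1), fit$initial_objective)
  expect_length(fit$objective, 100)
  expect_equal(sum(fit$w), 1, tolerance = 1e-12)
  expect_equal(sum(fit$h), 1, tolerance = 1e-12)
})

test_that("a strong prior pulls unknown-cell predictions toward mu, monotonically in alpha", {
  sim <- simulate_frequency_data(n = 30, m = 40, rank = 3, density = 0.4,
                                 seed = 4)
  gaps <- sapply(c(0.05, 1, 10, 100), function(a) {
    p <- sefreq_params(alpha = a, mu = 1, k = 5, k1 = 5, max_iter = 150)
    fit <- sefreq_fit(sim$freq, sim$drug_views, sim$effect_views,
                      params = p, seed = 2)
    abs(mean(predict(fit)[unknown_mask(sim$freq) == 1]) - 1)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 0.1)
})

test_that("prediction is the plain factor product, non-negative and unclipped", {
  inst <- random_instance(n = 8, m = 6, seed = 12)
  p <- sefreq_params(k = 3, k1 = 3, max_iter = 20)
  fit <- sefreq_fit(inst$freq, inst$drug_views, inst$effect_views,
                    params = p, seed = 1)
  P <- predict(fit)
  expect_equal(P, fit$U %*% fit$V, ignore_attr = TRUE)
  expect_gte(min(P), 0)

  # identity-like factor returns V's rows unchanged
  fit2 <- fit
  fit2$U <- diag(3)[, , drop = FALSE]
  fit2$V <- matrix(1:9 / 10, 3, 3)
  fit2$freq <- frequency_matrix(matrix(c(1, 0, 0, 2, 0, 3, 1, 1, 0), 3, 3))
  expect_equal(unname(predict(fit2)), fit2$V)

  fit$U <- NULL
  expect_error(predict(fit), "fitted")
})

test_that("noiseless fully-known low-rank data is reconstructed accurately", {
  sim <- simulate_frequency_data(n = 25, m = 20, rank = 2, density = 1,
                                 noise_sd = 0, view_noise = 0,
                                 discretize = FALSE, seed = 6)
  p <- sefreq_params(beta = 0, gamma = 0, alpha = 0.05, k = 2, k1 = 3,
                     max_iter = 500)
  fit <- sefreq_fit(sim$freq, sim$drug_views, sim$effect_views, params = p,
                    seed = 3)
  P <- predict(fit)
  rmse <- sqrt(mean((P - unclass(sim$freq))^2))
  expect_lt(rmse, 0.1)
})

test_that("early stopping truncates the trace when enabled", {
  inst <- random_instance(n = 10, m = 8, density = 0.6, seed = 20)
  p <- sefreq_params(k = 2, k1 = 3, max_iter = 400, early_stop = TRUE,
                     tol = 1e-4)
  fit <- sefreq_fit(inst$freq, inst$drug_views, inst$effect_views,
                    params = p, seed = 1)
  expect_lt(fit$iterations, 400)
  expect_length(fit$objective, fit$iterations)
})
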