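# Independent brute-force oracles used to pin expected values.  These stay
# deliberately naive (elementwise double loops, exhaustive pair counting,
# grid search) and never call the code paths they check.

# Full objective by elementwise loops: squared error on known cells,
# Gaussian prior on unknown cells, and the Laplacian quadratic forms
# expanded as sums over all node pairs of the sparsified graphs.
oracle_objective <- function(U, V, freq, drug_graphs, effect_graphs,
                             w, h, params) {
  R <- unclass(freq)
  P <- U %*% V
  fit <- 0; prior <- 0
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      if (R[i, j] > 0) {
        fit <- fit + (R[i, j] - P[i, j])^2
      } else {
        prior <- prior + (P[i, j] - params$mu)^2
      }
    }
  }
  reg_d <- 0
  for (p in seq_along(drug_graphs)) {
    a <- unclass(drug_graphs[[p]])
    acc <- 0
    for (i in seq_len(nrow(a))) {
      for (mu_ in seq_len(ncol(a))) {
        acc <- acc + a[i, mu_] * sum((U[i, ] - U[mu_, ])^2)
      }
    }
    reg_d <- reg_d + w[p]^params$delta * acc
  }
  reg_e <- 0
  for (q in seq_along(effect_graphs)) {
    a <- unclass(effect_graphs[[q]])
    acc <- 0
    for (i in seq_len(nrow(a))) {
      for (mu_ in seq_len(ncol(a))) {
        acc <- acc + a[i, mu_] * sum((V[, i] - V[, mu_])^2)
      }
    }
    reg_e <- reg_e + h[q]^params$delta * acc
  }
  0.5 * fit + params$alpha / 2 * prior +
    params$beta / 2 * reg_d + params$gamma / 2 * reg_e
}

# tr(U' L U) as the pairwise sum 1/2 sum_{i,mu} A(i,mu) ||u_i - u_mu||^2
# ... times 2, since L = (D + Dt) - (A + A') counts each directed edge once
# in both halves; the identity under test is
#   tr(U' L U) == sum_{i,mu} A(i,mu) ||u_i - u_mu||^2.
oracle_laplacian_quad <- function(A, U) {
  acc <- 0
  for (i in seq_len(nrow(A))) {
    for (mu_ in seq_len(ncol(A))) {
      acc <- acc + A[i, mu_] * sum((U[i, ] - U[mu_, ])^2)
    }
  }
  acc
}

# AUC by exhaustive positive-negative pair counting with half credit for
# ties.
oracle_auc_paircount <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Minimize sum_p w_p^delta * t_p over the probability simplex by grid
# search at the given resolution (2 or 3 views).
oracle_simplex_grid <- function(traces, delta, res = 0.001) {
  x <- length(traces)
  if (x == 2) {
    w1 <- seq(0, 1, by = res)
    G <- cbind(w1, 1 - w1)
  } else if (x == 3) {
    w1 <- seq(0, 1, by = res)
    G <- do.call(rbind, lapply(w1, function(a) {
      b <- seq(0, 1 - a, by = res)
      cbind(a, b, 1 - a - b)
    }))
  } else {
    stop("grid oracle supports 2 or 3 views")
  }
  vals <- G^delta %*% traces
  G[which.min(vals), ]
}

# Small random test instance: frequency matrix with the given known
# density plus random symmetric similarity views on both axes.
random_instance <- function(n = 10, m = 8, density = 0.5,
                            n_drug_views = 2, n_effect_views = 2,
                            seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(0, n, m)
    idx <- sample(n * m, max(2, round(density * n * m)))
    vals[idx] <- sample(1:5, length(idx), replace = TRUE)
    # guarantee validity: at least one known cell in the matrix
    freq <- frequency_matrix(vals)
    rand_view <- function(nn, axis) {
      B <- matrix(runif(nn * nn), nn, nn)
      S <- (B + t(B)) / 2
      diag(S) <- 1
      similarity_view(S, kind = "annotation", axis = axis)
    }
    list(freq = freq,
         drug_views = replicate(n_drug_views, rand_view(n, "drug"),
                                simplify = FALSE),
         effect_views = replicate(n_effect_views, rand_view(m, "effect"),
                                  simplify = FALSE))
  })
}
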