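#' Generate a synthetic drug--side-effect frequency dataset
#'
#' Emulates the statistical structure the model assumes: a non-negative
#' low-rank score matrix, discretized to ordinal frequency classes 1--5,
#' observed at a given density, together with similarity views correlated
#' with the generating latent factors.
#'
#' Ground-truth factors `U*` (n x rank) and `V*` (rank x m) are drawn from
#' a gamma(2, 1) distribution; scores `S0 = U* V*` are standardized and
#' mapped to the class scale as `3 + z` (one class per standard deviation,
#' centred on class 3), Gaussian noise of sd `noise_sd` is added, and known
#' cells are rounded and clipped to classes 1--5.  A uniformly random
#' subset of `round(density * n * m)` cells is marked known.  Static
#' similarity views are Gaussian kernels of latent-factor distances
#' (bandwidth = median pairwise distance), mixed with an independent random
#' symmetric similarity in proportion `view_noise`; the frequency-profile
#' views are left to the fitter, which computes them from the generated
#' matrix (2 kernel drug views + the profile view gives the 3-view drug
#' axis; 1 kernel effect view gives the 2-view effect axis).
#'
#' `cold_drugs` / `cold_effects` zero out whole rows / columns after
#' masking, creating entirely new entities whose true classes are retained
#' in `truth` for cold-start tests.
#'
#' @param n,m Numbers of drugs and side effects.
#' @param rank True latent dimension.
#' @param density Fraction of cells observed, in (0, 1].
#' @param noise_sd Sd of additive Gaussian noise on the class-scale scores.
#' @param view_noise Mixing weight in \[0, 1\] of the random similarity
#'   component of each static view.
#' @param n_drug_views,n_effect_views Numbers of static (kernel) views.
#' @param cold_drugs,cold_effects Numbers of rows / columns zeroed to make
#'   new entities.
#' @param discretize If `FALSE`, known cells keep continuous non-negative
#'   scores: `U* V*` rescaled multiplicatively so the maximum is 5, which
#'   preserves the exact latent rank (multiplicative log-normal noise when
#'   `noise_sd > 0`).  Useful for pure reconstruction studies.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List of class `sefreq_sim`: `freq` (a [frequency_matrix()];
#'   continuous-valued when `discretize = FALSE`), `drug_views`, `effect_views`
#'   (lists of [similarity_view()]s), and `truth` (list with `U`, `V`,
#'   `scores` on the class scale, `classes`, and the cold indices).
#' @export
simulate_frequency_data <- function(n = 100, m = 150, rank = 5,
                                    density = 0.3, noise_sd = 0.25,
                                    view_noise = 0.2,
                                    n_drug_views = 2, n_effect_views = 1,
                                    cold_drugs = 0, cold_effects = 0,
                                    discretize = TRUE, seed = 1) {
  stopifnot(n >= 2, m >= 2, rank >= 1, rank <= min(n, m),
            density > 0, density <= 1, noise_sd >= 0,
            view_noise >= 0, view_noise <= 1,
            cold_drugs >= 0, cold_drugs < n,
            cold_effects >= 0, cold_effects < m)
  withr::with_seed(seed, {
    Ustar <- matrix(stats::rgamma(n * rank, shape = 2, rate = 1), n, rank)
    Vstar <- matrix(stats::rgamma(rank * m, shape = 2, rate = 1), rank, m)
    S0 <- Ustar %*% Vstar
    scores <- 3 + (S0 - mean(S0)) / stats::sd(S0)  # one class per sd
    noisy <- scores + stats::rnorm(n * m, sd = noise_sd)
    classes <- pmin(pmax(round(noisy), 1), 5)
    # continuous mode rescales multiplicatively (max -> 5) so the score
    # matrix keeps the exact rank of U* V*; the class mapping's affine
    # shift would add a rank-one component and clipping would break
    # low-rankness altogether
    cont <- S0 * (5 / max(S0))
    if (noise_sd > 0) {
      cont <- pmin(cont * exp(stats::rnorm(n * m, sd = noise_sd / 5)), 5)
    }

    n_known <- max(1L, round(density * n * m))
    known_idx <- sample(n * m, n_known)
    vals <- matrix(0, n, m)
    vals[known_idx] <- if (discretize) classes[known_idx] else cont[known_idx]

    drug_ids <- sprintf("drug_%03d", seq_len(n))
    effect_ids <- sprintf("effect_%03d", seq_len(m))
    dimnames(vals) <- list(drug_ids, effect_ids)

    cold_d <- if (cold_drugs > 0) sample(n, cold_drugs) else integer(0)
    cold_e <- if (cold_effects > 0) sample(m, cold_effects) else integer(0)
    vals[cold_d, ] <- 0
    vals[, cold_e] <- 0

    kernel_view <- function(fac_rows, ids, axis, kind) {
      d <- as.matrix(stats::dist(fac_rows))
      bw <- stats::median(d[upper.tri(d)])
      K <- exp(-d^2 / (2 * bw^2))
      nn <- nrow(K)
      B <- matrix(stats::runif(nn * nn), nn, nn)
      Rnd <- (B + t(B)) / 2
      diag(Rnd) <- 1
      S <- (1 - view_noise) * K + view_noise * Rnd
      dimnames(S) <- list(ids, ids)
      similarity_view(pmin(pmax(S, 0), 1), kind = kind, axis = axis)
    }
    dkinds <- rep(c("fingerprint", "annotation"), length.out = n_drug_views)
    ekinds <- rep(c("annotation", "latent_kernel"),
                  length.out = n_effect_views)
    drug_views <- lapply(seq_len(n_drug_views), function(p) {
      kernel_view(Ustar, drug_ids, "drug", dkinds[p])
    })
    effect_views <- lapply(seq_len(n_effect_views), function(q) {
      kernel_view(t(Vstar), effect_ids, "effect", ekinds[q])
    })

    freq <- frequency_matrix(vals, integer_classes = discretize)
    dimnames(scores) <- dimnames(classes) <- dimnames(vals)
    structure(list(
      freq = freq,
      drug_views = drug_views,
      effect_views = effect_views,
      truth = list(U = Ustar, V = Vstar, scores = scores, classes = classes,
                   cold_drugs = sort(cold_d), cold_effects = sort(cold_e)),
      spec = list(n = n, m = m, rank = rank, density = density,
                  noise_sd = noise_sd, view_noise = view_noise,
                  discretize = discretize, seed = seed)
    ), class = "sefreq_sim")
  })
}

#' @export
print.sefreq_sim <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<sefreq_sim> %d x %d, rank %d, density %.0f%%, noise_sd %.2f, view_noise %.2f, seed %d\n",
    s$n, s$m, s$rank, 100 * s$density, s$noise_sd, s$view_noise, s$seed))
  invisible(x)
}
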