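#' Hyperparameters for the frequency-factorization model
#'
#' Bundles every tunable of the model.  The two scenarios carry the
#' defaults used throughout: warm start (held-out cells belong to drugs
#' that keep other known cells) and cold start (whole drugs are new).
#'
#' * `alpha` — reciprocal variance (1/sigma^2) of the Gaussian prior placed
#'   on predicted scores of unknown cells; larger values pull unknown-cell
#'   predictions harder toward `mu`.
#' * `mu` — mean of that prior, on the frequency-class scale (default 1,
#'   i.e. unknown pairs are presumed near "very rare").
#' * `beta`, `gamma` — strengths of the drug-side and effect-side
#'   neighbourhood regularizers.
#' * `k` — latent dimension of the factors.
#' * `k1` — neighbourhood size when sparsifying similarity views.
#' * `k2` — number of neighbours used to rebuild embeddings of new
#'   (all-unknown) drugs or effects.
#' * `delta` — exponent on the view weights (> 1; default 2, which keeps
#'   every view contributing).
#' * `max_iter` — number of full update sweeps (default 500).
#' * `eps` — additive guard for multiplicative-update denominators and
#'   weight-update traces.
#' * `early_stop`, `tol` — optional stop when the relative objective change
#'   drops below `tol`; off by default so traces have `max_iter` entries.
#'
#' @param scenario `"warm"` or `"cold"`; fills `beta`, `gamma`, `k1` when
#'   not given (warm: beta = gamma = 2, k1 = 20; cold: beta = gamma = 4,
#'   k1 = 10).
#' @param alpha,mu,beta,gamma,k,k1,k2,delta,max_iter,eps,early_stop,tol
#'   See above.
#' @return List of class `sefreq_params`.
#' @export
sefreq_params <- function(scenario = c("warm", "cold"),
                          alpha = 0.05, mu = 1,
                          beta = NULL, gamma = NULL,
                          k = 200, k1 = NULL, k2 = 10,
                          delta = 2, max_iter = 500, eps = 1e-12,
                          early_stop = FALSE, tol = 1e-6) {
  scenario <- match.arg(scenario)
  defaults <- if (scenario == "warm") {
    list(beta = 2, gamma = 2, k1 = 20)
  } else {
    list(beta = 4, gamma = 4, k1 = 10)
  }
  p <- list(
    scenario = scenario,
    alpha = alpha, mu = mu,
    beta = beta %||% defaults$beta,
    gamma = gamma %||% defaults$gamma,
    k = as.integer(k), k1 = as.integer(k1 %||% defaults$k1),
    k2 = as.integer(k2), delta = delta,
    max_iter = as.integer(max_iter), eps = eps,
    early_stop = isTRUE(early_stop), tol = tol
  )
  stopifnot(p$alpha > 0, p$mu >= 0, p$beta >= 0, p$gamma >= 0,
            p$k >= 1, p$k1 >= 1, p$k2 >= 1, p$max_iter >= 1, p$eps > 0)
  if (p$delta <= 1) {
    stop("`delta` must exceed 1 (the weight update divides by delta - 1).",
         call. = FALSE)
  }
  class(p) <- "sefreq_params"
  p
}

#' @export
print.sefreq_params <- function(x, ...) {
  cat(sprintf(
    "<sefreq_params> %s start: alpha=%g mu=%g beta=%g gamma=%g k=%d k1=%d k2=%d delta=%g max_iter=%d\n",
    x$scenario, x$alpha, x$mu, x$beta, x$gamma, x$k, x$k1, x$k2, x$delta,
    x$max_iter))
  invisible(x)
}

## ---- internal algebra -----------------------------------------------------

# Weighted sum of (graph + t(graph)) over views: the "attraction" part of
# the combined Laplacian.
.weighted_adjacency <- function(graphs, w, delta) {
  Reduce(`+`, Map(function(g, wp) wp^delta * (unclass(g) + t(unclass(g))),
                  graphs, w))
}

# Weighted combined degree vector diag(D + Dt) over views.
.weighted_degrees <- function(graphs, w, delta) {
  Reduce(`+`, Map(function(g, wp) {
    a <- unclass(g)
    wp^delta * (rowSums(a) + colSums(a))
  }, graphs, w))
}

.trace_quad_u <- function(U, lap) sum(U * (lap$L %*% U))    # tr(U' L U)
.trace_quad_v <- function(V, lap) sum((V %*% lap$L) * V)    # tr(V L V')

## ---- objective ------------------------------------------------------------

#' Model objective value
#'
#' Evaluates the full regularized objective
#' `1/2 ||Iw o (R - UV)||_F^2 + alpha/2 ||Io o (UV - mu E)||_F^2 +
#'  beta/2 tr(U' sum_p w_p^delta L_dp U) +
#'  gamma/2 tr(V sum_q h_q^delta L_eq V')`,
#' where `Iw`/`Io` mask known/unknown cells.
#'
#' @param U n x k non-negative drug-factor matrix.
#' @param V k x m non-negative effect-factor matrix.
#' @param freq A [frequency_matrix()].
#' @param drug_laps,effect_laps Lists of [build_laplacian()] results, one
#'   per view.
#' @param w,h View-weight vectors matching the Laplacian lists.
#' @param params A [sefreq_params()].
#' @return Non-negative scalar.
#' @export
sefreq_objective <- function(U, V, freq, drug_laps, effect_laps, w, h, params) {
  R <- unclass(freq)
  if (nrow(U) != nrow(R) || ncol(V) != ncol(R) || ncol(U) != nrow(V)) {
    stop("Factor dimensions do not match the frequency matrix.", call. = FALSE)
  }
  if (length(drug_laps) != length(w) || length(effect_laps) != length(h)) {
    stop("Laplacian list lengths must match the weight vectors.", call. = FALSE)
  }
  if (!all(is.finite(U)) || !all(is.finite(V))) {
    stop("Factor matrices contain non-finite entries.", call. = FALSE)
  }
  P <- U %*% V
  Ik <- known_mask(freq)
  Io <- 1 - Ik
  fit_term <- 0.5 * sum((Ik * (R - P))^2)
  prior_term <- params$alpha / 2 * sum((Io * (P - params$mu))^2)
  reg_d <- if (length(drug_laps)) {
    params$beta / 2 *
      sum(mapply(function(lap, wp) wp^params$delta * .trace_quad_u(U, lap),
                 drug_laps, w))
  } else 0
  reg_e <- if (length(effect_laps)) {
    params$gamma / 2 *
      sum(mapply(function(lap, hq) hq^params$delta * .trace_quad_v(V, lap),
                 effect_laps, h))
  } else 0
  val <- fit_term + prior_term + reg_d + reg_e
  if (!is.finite(val)) stop("Objective is non-finite.", call. = FALSE)
  val
}

## ---- multiplicative updates -----------------------------------------------

#' One multiplicative update of the drug factors
#'
#' Rescales each entry of `U0` by a ratio of non-negative terms, so
#' non-negativity and exact zeros are preserved and the objective does not
#' increase (given `V0` and the current weights fixed).
#'
#' @param U0,V0 Current factors (before this sweep).
#' @param freq A [frequency_matrix()].
#' @param drug_graphs List of [knn_sparsify()] graphs, one per drug view.
#' @param w Drug view weights.
#' @param params A [sefreq_params()].
#' @return Updated `U`.
#' @export
nmf_update_u <- function(U0, V0, freq, drug_graphs, w, params) {
  if (min(U0) < 0 || min(V0) < 0) {
    stop("Factors must be non-negative.", call. = FALSE)
  }
  R <- unclass(freq)
  Ik <- known_mask(freq)
  Io <- 1 - Ik
  W <- Ik + params$alpha * Io
  num <- (R + params$alpha * params$mu * Io) %*% t(V0)
  den <- (W * (U0 %*% V0)) %*% t(V0)
  if (length(drug_graphs) && params$beta > 0) {
    num <- num + params$beta *
      (.weighted_adjacency(drug_graphs, w, params$delta) %*% U0)
    den <- den + params$beta *
      (.weighted_degrees(drug_graphs, w, params$delta) * U0)
  }
  U0 * num / (den + params$eps)
}

#' One multiplicative update of the effect factors
#'
#' Mirror of [nmf_update_u()] for `V`; uses the already-updated `U` of the
#' current sweep.
#'
#' @param U Drug factors after this sweep's U-update.
#' @param V0 Effect factors before this sweep.
#' @param freq A [frequency_matrix()].
#' @param effect_graphs List of [knn_sparsify()] graphs, one per effect view.
#' @param h Effect view weights.
#' @param params A [sefreq_params()].
#' @return Updated `V`.
#' @export
nmf_update_v <- function(U, V0, freq, effect_graphs, h, params) {
  if (min(U) < 0 || min(V0) < 0) {
    stop("Factors must be non-negative.", call. = FALSE)
  }
  R <- unclass(freq)
  Ik <- known_mask(freq)
  Io <- 1 - Ik
  W <- Ik + params$alpha * Io
  num <- t(U) %*% (R + params$alpha * params$mu * Io)
  den <- t(U) %*% (W * (U %*% V0))
  if (length(effect_graphs) && params$gamma > 0) {
    num <- num + params$gamma *
      (V0 %*% .weighted_adjacency(effect_graphs, h, params$delta))
    den <- den + params$gamma *
      sweep(V0, 2, .weighted_degrees(effect_graphs, h, params$delta), `*`)
  }
  V0 * num / (den + params$eps)
}

#' Closed-form adaptive view weights
#'
#' Given per-view regularizer traces `t_p` (e.g. `tr(U' L_dp U)`), returns
#' the simplex vector minimizing `sum_p w_p^delta t_p`:
#' `w_p = t_p^(-1/(delta-1)) / sum_p' t_p'^(-1/(delta-1))`.
#' Views whose neighbours are already embedded closely (small trace) get
#' larger weight.  Traces are floored at `eps` to keep the exponent finite.
#'
#' @param traces Non-negative numeric vector, one trace per view.
#' @param delta Weight exponent, > 1.
#' @param eps Floor applied to traces.
#' @return Simplex vector (sums to 1, all entries >= 0).
#' @export
update_view_weights <- function(traces, delta = 2, eps = 1e-12) {
  if (length(traces) < 1) stop("Need at least one view.", call. = FALSE)
  if (delta <= 1) stop("`delta` must exceed 1.", call. = FALSE)
  t_p <- pmax(traces, eps)
  u <- t_p^(-1 / (delta - 1))
  u / sum(u)
}

## ---- fitting --------------------------------------------------------------

.as_freq <- function(data) {
  if (inherits(data, "frequency_matrix")) data else as_frequency_matrix(data)
}

# Assemble the per-axis view lists: the frequency-profile view (computed
# from the training matrix, never from held-out cells) first, then the
# supplied static views aligned to the matrix ids.
.assemble_views <- function(freq, views, axis, include_frequency_view) {
  ids <- if (axis == "drug") rownames(freq) else colnames(freq)
  views <- lapply(views, function(v) {
    if (!inherits(v, "similarity_view")) {
      v <- similarity_view(v, kind = "annotation", axis = axis)
    }
    if (!identical(attr(v, "axis"), axis)) {
      stop("A ", attr(v, "axis"), "-axis view was supplied for the ", axis,
           " axis.", call. = FALSE)
    }
    if (!setequal(rownames(v), ids)) {
      stop("View ids do not match the frequency matrix ", axis, " ids.",
           call. = FALSE)
    }
    # align by id, never by position
    v2 <- unclass(v)[ids, ids, drop = FALSE]
    structure(v2, kind = attr(v, "kind"), axis = axis,
              class = class(v))
  })
  if (include_frequency_view) {
    views <- c(list(cosine_profile_similarity(freq, axis)), views)
  }
  if (!length(views)) {
    stop("At least one ", axis, " similarity view is required.", call. = FALSE)
  }
  views
}

#' Fit the multiview neighbourhood-regularized factorization
#'
#' Decomposes the frequency matrix `R ~ U V` with non-negative factors by
#' iterating the four update steps (U, V, drug-view weights, effect-view
#' weights) for `max_iter` sweeps.  Known cells are fitted by squared
#' error; unknown cells are tied to a Gaussian prior with mean `mu` and
#' precision `alpha`; per-view kNN-graph Laplacians pull similar drugs and
#' similar side effects toward similar latent signatures, with view weights
#' learned in closed form.
#'
#' The frequency-profile similarity views (cosine over rows / columns of
#' the training matrix) are computed internally by default, so that
#' held-out cells zeroed in `data` can never leak into the graphs; the
#' remaining views (fingerprints, annotations, ...) are passed in.  After
#' the sweeps, drugs or effects with no known cells at all get their
#' embeddings rebuilt from similar entities (see [refine_cold_start()]).
#'
#' @param data A [frequency_matrix()] or triplet data frame
#'   (`drug_id`, `effect_id`, `frequency`).
#' @param drug_views,effect_views Lists of [similarity_view()]s (static
#'   attribute views; the frequency-profile view is added internally when
#'   `include_frequency_views` is `TRUE`).
#' @param params A [sefreq_params()].
#' @param include_frequency_views Prepend the cosine frequency-profile view
#'   on each axis (default `TRUE`).
#' @param refine_cold Rebuild embeddings of all-unknown drugs/effects after
#'   fitting (default `TRUE`).
#' @param seed Integer seed controlling factor initialization.
#' @param verbose Print the objective every 50 sweeps.
#' @return Object of class `sefreq_fit` with elements `U`, `V`, `w`, `h`,
#'   `objective` (one value per sweep, preceded by the initial value),
#'   `params`, `freq`, the view graphs and Laplacians, `seed`, and indices
#'   of cold-refined entities.
#' @export
sefreq_fit <- function(data, drug_views = list(), effect_views = list(),
                       params = sefreq_params(),
                       include_frequency_views = TRUE,
                       refine_cold = TRUE, seed = 1, verbose = FALSE) {
  freq <- .as_freq(data)
  stopifnot(inherits(params, "sefreq_params"))
  n <- nrow(freq); m <- ncol(freq)
  k <- min(params$k, n, m)

  dviews <- .assemble_views(freq, drug_views, "drug", include_frequency_views)
  eviews <- .assemble_views(freq, effect_views, "effect", include_frequency_views)
  k1_d <- min(params$k1, n - 1)
  k1_e <- min(params$k1, m - 1)
  dgraphs <- lapply(dviews, knn_sparsify, k1 = k1_d)
  egraphs <- lapply(eviews, knn_sparsify, k1 = k1_e)
  dlaps <- lapply(dgraphs, build_laplacian)
  elaps <- lapply(egraphs, build_laplacian)

  x <- length(dviews); y <- length(eviews)
  w <- rep(1 / x, x); h <- rep(1 / y, y)

  init <- withr::with_seed(seed, {
    U <- matrix(stats::runif(n * k), n, k)
    V <- matrix(stats::runif(k * m), k, m)
    list(U = U / sqrt(sum(U^2)), V = V / sqrt(sum(V^2)))
  })
  U <- init$U; V <- init$V

  obj0 <- sefreq_objective(U, V, freq, dlaps, elaps, w, h, params)
  trace <- numeric(params$max_iter)
  iters <- params$max_iter
  prev <- obj0
  for (it in seq_len(params$max_iter)) {
    U <- nmf_update_u(U, V, freq, dgraphs, w, params)
    V <- nmf_update_v(U, V, freq, egraphs, h, params)
    if (x > 1) {
      w <- update_view_weights(vapply(dlaps, .trace_quad_u, numeric(1), U = U),
                               params$delta, params$eps)
    }
    if (y > 1) {
      h <- update_view_weights(vapply(elaps, .trace_quad_v, numeric(1), V = V),
                               params$delta, params$eps)
    }
    trace[it] <- sefreq_objective(U, V, freq, dlaps, elaps, w, h, params)
    if (verbose && it %% 50 == 0) {
      message(sprintf("sweep %4d  objective %.6g", it, trace[it]))
    }
    if (params$early_stop &&
        abs(prev - trace[it]) <= params$tol * max(abs(prev), 1)) {
      iters <- it
      trace <- trace[seq_len(it)]
      break
    }
    prev <- trace[it]
  }

  fit <- structure(list(
    U = U, V = V, w = w, h = h,
    objective = trace, initial_objective = obj0, iterations = iters,
    params = params, freq = freq,
    drug_views = dviews, effect_views = eviews,
    drug_graphs = dgraphs, effect_graphs = egraphs,
    drug_laplacians = dlaps, effect_laplacians = elaps,
    view_kinds = list(drug = vapply(dviews, attr, "", which = "kind"),
                      effect = vapply(eviews, attr, "", which = "kind")),
    seed = seed,
    cold_drugs = integer(0), cold_effects = integer(0)
  ), class = "sefreq_fit")

  if (refine_cold) {
    nd <- which(rowSums(known_mask(freq)) == 0)
    ne <- which(colSums(known_mask(freq)) == 0)
    if (length(nd) || length(ne)) {
      fit <- refine_cold_start(fit, new_drugs = nd, new_effects = ne)
    }
  }
  fit
}

#' Rebuild embeddings of new drugs and new side effects
#'
#' A drug (or side effect) with no known frequency cells contributes
#' nothing to the reconstruction loss, so its fitted embedding is driven
#' only by the prior and regularizer and is unreliable.  Its row of `U`
#' (column of `V`) is replaced by the similarity-weighted average of the
#' embeddings of its `k2` most similar entities that do have known cells.
#' The combination weight between entities i and j sums the sparsified
#' static views only — the frequency-profile view is excluded, since a new
#' entity's frequency profile is identically zero:
#' `s_ij = sum_{p >= 2} w_p^delta A~_dp(i, j)` (and likewise with `h_q`
#' for effects).  If every similarity to a known entity is zero (or no
#' static view exists), the unweighted mean embedding of all known
#' entities is used.
#'
#' @param fit A [sefreq_fit()] result.
#' @param new_drugs,new_effects Indices (or ids) of all-unknown rows /
#'   columns; default: detected from the training matrix.
#' @return The fit with replaced embeddings; `cold_drugs` / `cold_effects`
#'   record which entities were refined.
#' @export
refine_cold_start <- function(fit, new_drugs = NULL, new_effects = NULL) {
  stopifnot(inherits(fit, "sefreq_fit"))
  freq <- fit$freq
  Ik <- known_mask(freq)
  delta <- fit$params$delta
  k2 <- fit$params$k2

  resolve <- function(idx, ids, nmax, what) {
    if (is.null(idx)) return(integer(0))
    if (is.character(idx)) idx <- match(idx, ids)
    idx <- as.integer(idx)
    if (anyNA(idx) || any(idx < 1) || any(idx > nmax)) {
      stop("Unknown ", what, " index in cold-start specification.",
           call. = FALSE)
    }
    idx
  }
  nd <- resolve(new_drugs %||% which(rowSums(Ik) == 0),
                rownames(freq), nrow(freq), "drug")
  ne <- resolve(new_effects %||% which(colSums(Ik) == 0),
                colnames(freq), ncol(freq), "effect")
  if (any(rowSums(Ik)[nd] > 0)) {
    stop("Listed new drugs must have all-zero rows in the training matrix.",
         call. = FALSE)
  }
  if (any(colSums(Ik)[ne] > 0)) {
    stop("Listed new effects must have all-zero columns in the training matrix.",
         call. = FALSE)
  }

  # combined static-view similarity (frequency-profile view excluded)
  combined <- function(graphs, kinds, weights) {
    keep <- which(kinds != "frequency_profile")
    if (!length(keep)) return(NULL)
    Reduce(`+`, Map(function(g, wt) wt^delta * unclass(g),
                    graphs[keep], weights[keep]))
  }

  if (length(nd)) {
    s_d <- combined(fit$drug_graphs, fit$view_kinds$drug, fit$w)
    known_d <- setdiff(which(rowSums(Ik) > 0), nd)
    mean_emb <- colMeans(fit$U[known_d, , drop = FALSE])
    for (i in nd) {
      s <- if (is.null(s_d)) rep(0, nrow(freq)) else s_d[i, ]
      s[setdiff(seq_along(s), known_d)] <- 0
      if (all(s == 0)) {
        fit$U[i, ] <- mean_emb
      } else {
        nb <- order(-s)[seq_len(min(k2, sum(s > 0)))]
        nb <- nb[s[nb] > 0]
        fit$U[i, ] <- colSums(fit$U[nb, , drop = FALSE] * s[nb]) / sum(s[nb])
      }
    }
    fit$cold_drugs <- sort(union(fit$cold_drugs, nd))
  }
  if (length(ne)) {
    s_e <- combined(fit$effect_graphs, fit$view_kinds$effect, fit$h)
    known_e <- setdiff(which(colSums(Ik) > 0), ne)
    mean_emb <- rowMeans(fit$V[, known_e, drop = FALSE])
    for (j in ne) {
      s <- if (is.null(s_e)) rep(0, ncol(freq)) else s_e[j, ]
      s[setdiff(seq_along(s), known_e)] <- 0
      if (all(s == 0)) {
        fit$V[, j] <- mean_emb
      } else {
        nb <- order(-s)[seq_len(min(k2, sum(s > 0)))]
        nb <- nb[s[nb] > 0]
        fit$V[, j] <- (fit$V[, nb, drop = FALSE] %*% s[nb]) / sum(s[nb])
      }
    }
    fit$cold_effects <- sort(union(fit$cold_effects, ne))
  }
  fit
}

#' Predicted frequency scores
#'
#' Returns the continuous score matrix `U V` (drug x side effect) with no
#' clipping or rounding; scores are continuous surrogates of the frequency
#' classes 1--5 and feed the ranking and regression metrics directly.
#'
#' @param object A [sefreq_fit()] result.
#' @param ... Unused.
#' @return Numeric matrix with the frequency matrix's dimnames.
#' @export
predict.sefreq_fit <- function(object, ...) {
  if (is.null(object$U) || is.null(object$V)) {
    stop("Model has no fitted factors.", call. = FALSE)
  }
  P <- object$U %*% object$V
  dimnames(P) <- dimnames(object$freq)
  P
}

#' @export
print.sefreq_fit <- function(x, ...) {
  cat(sprintf(
    "<sefreq_fit> %d drugs x %d effects, k=%d, %d sweeps, objective %.6g -> %.6g\n",
    nrow(x$U), ncol(x$V), ncol(x$U), x$iterations,
    x$initial_objective, utils::tail(x$objective, 1)))
  cat("  drug view weights:  ",
      paste(sprintf("%s=%.3f", x$view_kinds$drug, x$w), collapse = " "), "\n")
  cat("  effect view weights:",
      paste(sprintf("%s=%.3f", x$view_kinds$effect, x$h), collapse = " "), "\n")
  if (length(x$cold_drugs) || length(x$cold_effects)) {
    cat(sprintf("  cold-start refined: %d drugs, %d effects\n",
                length(x$cold_drugs), length(x$cold_effects)))
  }
  invisible(x)
}

#' Tidy the learned view weights
#'
#' @param x A [sefreq_fit()].
#' @param ... Unused.
#' @return Tibble with columns `axis`, `view`, `kind`, `weight`.
#' @export
tidy.sefreq_fit <- function(x, ...) {
  tibble::tibble(
    axis = c(rep("drug", length(x$w)), rep("effect", length(x$h))),
    view = c(seq_along(x$w), seq_along(x$h)),
    kind = c(x$view_kinds$drug, x$view_kinds$effect),
    weight = c(x$w, x$h)
  )
}

#' One-row fit summary
#'
#' @param x A [sefreq_fit()].
#' @param ... Unused.
#' @return One-row tibble: dimensions, latent rank, sweeps, initial and
#'   final objective, counts of cold-refined entities.
#' @importFrom generics glance
#' @export
glance.sefreq_fit <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$U), n_effects = ncol(x$V), k = ncol(x$U),
    iterations = x$iterations,
    initial_objective = x$initial_objective,
    final_objective = utils::tail(x$objective, 1),
    n_cold_drugs = length(x$cold_drugs),
    n_cold_effects = length(x$cold_effects)
  )
}

#' Objective-trace plot
#'
#' @param object A [sefreq_fit()].
#' @param ... Unused.
#' @return A ggplot of the objective value per update sweep.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.sefreq_fit <- function(object, ...) {
  df <- tibble::tibble(sweep = seq_along(object$objective),
                       objective = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "update sweep", y = "objective value") +
    ggplot2::theme_minimal()
}
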