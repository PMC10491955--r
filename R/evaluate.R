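#' Build a cross-validation split
#'
#' Two protocols are supported.  CV1 (warm start) partitions the known
#' cells of the frequency matrix into `n_folds` random folds; each fold in
#' turn is the test set and its cells are zeroed in the training matrix.
#' CV2 (cold start) partitions the drugs; all cells of test-fold drugs are
#' zeroed, so those drugs are entirely new to the model.
#'
#' @param freq A [frequency_matrix()].
#' @param scheme `"CV1"` or `"CV2"`.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the random partition.
#' @return Object of class `cv_split`: a tibble of assignments
#'   (`drug`, `effect`, `fold` for CV1; `drug`, `fold` for CV2) plus the
#'   scheme, fold count and seed.
#' @export
make_cv_split <- function(freq, scheme = c("CV1", "CV2"), n_folds = 10,
                          seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(freq, "frequency_matrix"), n_folds >= 2)
  if (scheme == "CV1") {
    cells <- which(unclass(freq) > 0, arr.ind = TRUE)
    if (nrow(cells) < n_folds) {
      stop("Fewer known cells than folds.", call. = FALSE)
    }
    fold <- withr::with_seed(seed, {
      sample(rep(seq_len(n_folds), length.out = nrow(cells)))
    })
    assign <- tibble::tibble(drug = cells[, 1], effect = cells[, 2],
                             fold = fold)
  } else {
    if (nrow(freq) < n_folds) stop("Fewer drugs than folds.", call. = FALSE)
    fold <- withr::with_seed(seed, {
      sample(rep(seq_len(n_folds), length.out = nrow(freq)))
    })
    assign <- tibble::tibble(drug = seq_len(nrow(freq)), fold = fold)
  }
  structure(list(scheme = scheme, assignments = assign,
                 n_folds = as.integer(n_folds), seed = seed),
            class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat(sprintf("<cv_split> %s, %d folds, %d assigned items, seed %d\n",
              x$scheme, x$n_folds, nrow(x$assignments), x$seed))
  invisible(x)
}

#' Training matrix for one fold
#'
#' Zeroes the fold's test cells (CV1) or every cell of the fold's test
#' drugs (CV2), leaving the rest of the matrix untouched.
#'
#' @param freq The full [frequency_matrix()].
#' @param split A [make_cv_split()] result.
#' @param fold Fold number in `1:n_folds`.
#' @return A [frequency_matrix()] with test information removed.
#' @export
training_matrix <- function(freq, split, fold) {
  stopifnot(inherits(split, "cv_split"), fold %in% seq_len(split$n_folds))
  tr <- unclass(freq)
  a <- split$assignments[split$assignments$fold == fold, ]
  if (split$scheme == "CV1") {
    tr[cbind(a$drug, a$effect)] <- 0
  } else {
    tr[a$drug, ] <- 0
  }
  frequency_matrix(tr, rownames(freq), colnames(freq))
}

## ---- ranking metrics ------------------------------------------------------

#' Rank-based AUC and step-wise AUPR for one score vector
#'
#' `ranking_auc()` is the Wilcoxon statistic: the probability that a random
#' positive outscores a random negative, with half credit for ties.
#' `ranking_aupr()` is average precision with step-wise (no linear)
#' interpolation of the precision--recall curve; tied scores are resolved
#' pessimistically (negatives ranked above positives at equal score).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels, 1 = positive.
#' @return Scalar in \[0, 1\]; `NA` when either class is empty.
#' @export
ranking_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname ranking_auc
#' @export
ranking_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(-scores, labels)   # ties: negatives first (conservative)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab]) / np
}

#' Per-drug ranking metrics for one fold
#'
#' For every drug with at least one test-fold cell, the positives are that
#' drug's held-out known cells and the negatives are all of its cells that
#' are unknown in the full matrix (never observed); cells known in the
#' fold's training matrix are excluded.  The fold AUC/AUPR is the mean
#' over eligible drugs; drugs without test positives or without negatives
#' are skipped and counted.
#'
#' @param scores Predicted score matrix (drugs x effects).
#' @param freq_full The full [frequency_matrix()] (defines the negatives).
#' @param test_cells Two-column matrix/data frame of (drug, effect) indices
#'   held out in this fold.
#' @return List: `auc`, `aupr` (fold means), `n_drugs` evaluated,
#'   `skipped_drugs`, and a `per_drug` tibble.
#' @export
ranking_metrics_per_drug <- function(scores, freq_full, test_cells) {
  test_cells <- as.matrix(test_cells)[, 1:2, drop = FALSE]
  neg_mask <- unknown_mask(freq_full)
  drugs <- sort(unique(test_cells[, 1]))
  rows <- lapply(drugs, function(d) {
    pos_j <- test_cells[test_cells[, 1] == d, 2]
    neg_j <- which(neg_mask[d, ] == 1)
    if (length(pos_j) == 0 || length(neg_j) == 0) {
      return(tibble::tibble(drug = d, auc = NA_real_, aupr = NA_real_,
                            n_pos = length(pos_j), n_neg = length(neg_j)))
    }
    sc <- c(scores[d, pos_j], scores[d, neg_j])
    lb <- c(rep(1, length(pos_j)), rep(0, length(neg_j)))
    tibble::tibble(drug = d, auc = ranking_auc(sc, lb),
                   aupr = ranking_aupr(sc, lb),
                   n_pos = length(pos_j), n_neg = length(neg_j))
  })
  per_drug <- dplyr::bind_rows(rows)
  ok <- !is.na(per_drug$auc)
  list(auc = mean(per_drug$auc[ok]), aupr = mean(per_drug$aupr[ok]),
       n_drugs = sum(ok), skipped_drugs = sum(!ok), per_drug = per_drug)
}

#' Regression metrics on held-out known cells
#'
#' Root mean squared error, mean absolute error and Pearson correlation
#' between predicted scores and true frequency classes over the `t` known
#' test cells of a fold.  If either vector has zero variance the PCC is
#' undefined; it is reported as 0 with `pcc_degenerate = TRUE` and a
#' warning, preferring a defined value over a NaN.
#'
#' @param predictions,truths Numeric vectors of equal length (`t >= 2` for
#'   a meaningful PCC).
#' @return One-row tibble: `rmse`, `mae`, `pcc`, `t`, `pcc_degenerate`.
#' @export
regression_metrics <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 1)
  err <- predictions - truths
  degenerate <- stats::sd(predictions) == 0 || stats::sd(truths) == 0
  pcc <- if (length(truths) < 2 || degenerate) {
    if (degenerate) {
      warning("Zero variance in predictions or truths; PCC reported as 0.",
              call. = FALSE)
    }
    0
  } else {
    stats::cor(predictions, truths)
  }
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    pcc = pcc,
    t = length(truths),
    pcc_degenerate = degenerate || length(truths) < 2
  )
}

## ---- cross-validation driver ----------------------------------------------

#' Cross-validated evaluation of the model
#'
#' Runs the full protocol: builds the fold split, and for each fold zeroes
#' the test information, recomputes the frequency-profile similarity views
#' from the training matrix (so held-out cells cannot leak through the
#' graphs), fits the model, and scores the fold with per-drug AUC/AUPR and
#' cell-level RMSE/MAE/PCC.  Under CV2 the test drugs are all-zero rows,
#' so the fit's cold-start refinement rebuilds their embeddings from the
#' static views.
#'
#' @inheritParams sefreq_fit
#' @param scheme `"CV1"` (warm) or `"CV2"` (cold).
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling both the fold partition and every fold's
#'   factor initialization.
#' @param verbose Print a line per fold.
#' @return Object of class `sefreq_cv`: `per_fold` tibble (one row per
#'   fold), `summary` (the across-fold means), scheme, params, seed.
#' @export
sefreq_cv <- function(data, drug_views = list(), effect_views = list(),
                      params = sefreq_params(), scheme = c("CV1", "CV2"),
                      n_folds = 10, seed = 1, verbose = FALSE) {
  scheme <- match.arg(scheme)
  freq <- .as_freq(data)
  split <- make_cv_split(freq, scheme, n_folds = n_folds, seed = seed)
  known <- which(unclass(freq) > 0, arr.ind = TRUE)

  fold_rows <- lapply(seq_len(n_folds), function(f) {
    tr <- training_matrix(freq, split, f)
    fit <- sefreq_fit(tr, drug_views = drug_views,
                      effect_views = effect_views, params = params,
                      include_frequency_views = TRUE,
                      refine_cold = TRUE, seed = seed + f)
    P <- predict(fit)
    test_cells <- if (scheme == "CV1") {
      a <- split$assignments[split$assignments$fold == f, ]
      cbind(a$drug, a$effect)
    } else {
      td <- split$assignments$drug[split$assignments$fold == f]
      known[known[, 1] %in% td, , drop = FALSE]
    }
    rank_m <- ranking_metrics_per_drug(P, freq, test_cells)
    reg_m <- regression_metrics(P[test_cells], unclass(freq)[test_cells])
    if (verbose) {
      message(sprintf("fold %2d: AUC %.3f AUPR %.3f RMSE %.3f", f,
                      rank_m$auc, rank_m$aupr, reg_m$rmse))
    }
    tibble::tibble(fold = f, auc = rank_m$auc, aupr = rank_m$aupr,
                   rmse = reg_m$rmse, mae = reg_m$mae, pcc = reg_m$pcc,
                   t = reg_m$t, n_drugs = rank_m$n_drugs,
                   skipped_drugs = rank_m$skipped_drugs)
  })
  per_fold <- dplyr::bind_rows(fold_rows)
  summary <- per_fold |>
    dplyr::summarise(dplyr::across(c("auc", "aupr", "rmse", "mae", "pcc"),
                                   mean),
                     t = sum(.data$t),
                     skipped_drugs = sum(.data$skipped_drugs))
  structure(list(per_fold = per_fold, summary = summary, scheme = scheme,
                 n_folds = n_folds, params = params, seed = seed),
            class = "sefreq_cv")
}

#' @export
print.sefreq_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sefreq_cv> %s, %d folds (seed %d)\n  AUC %.3f  AUPR %.3f  RMSE %.3f  MAE %.3f  PCC %.3f\n",
    x$scheme, x$n_folds, x$seed, s$auc, s$aupr, s$rmse, s$mae, s$pcc))
  invisible(x)
}

#' Per-fold metric table
#'
#' @param x A [sefreq_cv()].
#' @param ... Unused.
#' @return The per-fold tibble.
#' @export
tidy.sefreq_cv <- function(x, ...) x$per_fold

#' Across-fold metric means
#'
#' @param x A [sefreq_cv()].
#' @param ... Unused.
#' @return One-row tibble of the averaged metrics.
#' @export
glance.sefreq_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(scheme = x$scheme, n_folds = x$n_folds),
                   x$summary)
}

#' Per-fold metric plot
#'
#' @param object A [sefreq_cv()].
#' @param ... Unused.
#' @return A ggplot of each metric across folds with the fold mean.
#' @export
autoplot.sefreq_cv <- function(object, ...) {
  df <- object$per_fold |>
    tidyr::pivot_longer(c("auc", "aupr", "rmse", "mae", "pcc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sensitivity sweep over prior hyperparameters
#'
#' Re-runs the full cross-validation for each row of a hyperparameter grid
#' (typically over the prior mean `mu` and precision `alpha`) and collects
#' the averaged metrics, for trend analyses of the trade-off between
#' association ranking (AUC) and frequency fitting (PCC).
#'
#' @inheritParams sefreq_cv
#' @param grid Data frame whose columns name `sefreq_params()` fields to
#'   override (e.g. `mu`, `alpha`), one CV run per row.
#' @return Tibble: the grid columns plus `auc`, `aupr`, `rmse`, `mae`,
#'   `pcc`.
#' @export
sensitivity_sweep <- function(data, drug_views = list(),
                              effect_views = list(),
                              grid, params = sefreq_params(),
                              scheme = c("CV1", "CV2"), n_folds = 10,
                              seed = 1, verbose = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("`grid` must be a non-empty data frame of parameter overrides.",
         call. = FALSE)
  }
  bad <- setdiff(names(grid), setdiff(names(params), "scenario"))
  if (length(bad)) {
    stop("Unknown parameter(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][i]
    cv <- sefreq_cv(data, drug_views, effect_views, params = p,
                    scheme = scheme, n_folds = n_folds, seed = seed,
                    verbose = verbose)
    dplyr::bind_cols(tibble::as_tibble(grid[i, , drop = FALSE]),
                     cv$summary[c("auc", "aupr", "rmse", "mae", "pcc")])
  })
  dplyr::bind_rows(rows)
}
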