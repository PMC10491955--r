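#' Construct a drug x side-effect frequency matrix
#'
#' The frequency matrix `R` holds one row per drug and one column per side
#' effect.  Entries are integer frequency classes 1 (very rare) to 5 (very
#' frequent); 0 marks a drug--side-effect pair whose frequency has never been
#' observed.  The known/unknown partition drives both the factorization loss
#' (squared error on known cells, Gaussian prior on unknown cells) and the
#' evaluation protocol, so it is validated here once and derived everywhere
#' else via [known_mask()] / [unknown_mask()].
#'
#' @param x Integer matrix with entries in `0:5`, or a triplet data frame
#'   (see [as_frequency_matrix()]).
#' @param drug_ids,effect_ids Optional character identifiers; default to the
#'   dimnames of `x` or `drug_1 ... / effect_...` placeholders.
#' @param integer_classes Require integer classes 0..5 (default).  Set to
#'   `FALSE` for continuous scores in \[0, 5\] (e.g. undiscretized
#'   synthetic data used in reconstruction studies).
#' @return A matrix of class `frequency_matrix` with unique dimnames.
#' @examples
#' R <- frequency_matrix(rbind(c(0, 3, 5), c(1, 0, 0)))
#' known_mask(R)
#' @export
frequency_matrix <- function(x, drug_ids = NULL, effect_ids = NULL,
                             integer_classes = TRUE) {
  if (is.data.frame(x)) {
    return(as_frequency_matrix(x))
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a triplet data frame.", call. = FALSE)
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("A frequency matrix needs at least 2 drugs and 2 side effects.", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 5) ||
      (integer_classes && any(x != round(x)))) {
    stop("Frequency entries must be integers in 0..5 (0 = unknown).", call. = FALSE)
  }
  storage.mode(x) <- "double"
  drug_ids <- drug_ids %||% rownames(x) %||% paste0("drug_", seq_len(nrow(x)))
  effect_ids <- effect_ids %||% colnames(x) %||% paste0("effect_", seq_len(ncol(x)))
  if (anyDuplicated(drug_ids) || anyDuplicated(effect_ids)) {
    stop("Drug and side-effect identifiers must be unique.", call. = FALSE)
  }
  dimnames(x) <- list(drug_ids, effect_ids)
  class(x) <- c("frequency_matrix", class(matrix()))
  x
}

#' Convert a triplet table to a frequency matrix
#'
#' Accepts a data frame with columns `drug_id`, `effect_id`, `frequency`
#' (or any three columns in that order).  Pairs absent from the table are
#' unknown (0).
#'
#' @param data Data frame of known drug--side-effect frequency classes.
#' @param drug_ids,effect_ids Optional identifier vectors fixing the row and
#'   column universe (and order); defaults to the sorted ids present.
#' @return A [frequency_matrix()].
#' @export
as_frequency_matrix <- function(data, drug_ids = NULL, effect_ids = NULL) {
  stopifnot(is.data.frame(data))
  nm <- names(data)
  cols <- if (all(c("drug_id", "effect_id", "frequency") %in% nm)) {
    data[c("drug_id", "effect_id", "frequency")]
  } else if (ncol(data) >= 3) {
    stats::setNames(data[1:3], c("drug_id", "effect_id", "frequency"))
  } else {
    stop("Triplet input needs columns drug_id, effect_id, frequency.", call. = FALSE)
  }
  cols$drug_id <- as.character(cols$drug_id)
  cols$effect_id <- as.character(cols$effect_id)
  drug_ids <- drug_ids %||% sort(unique(cols$drug_id))
  effect_ids <- effect_ids %||% sort(unique(cols$effect_id))
  bad_d <- setdiff(cols$drug_id, drug_ids)
  bad_e <- setdiff(cols$effect_id, effect_ids)
  if (length(bad_d) || length(bad_e)) {
    stop("Triplets reference ids outside the given universe: ",
         paste(utils::head(c(bad_d, bad_e), 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cols[c("drug_id", "effect_id")])) {
    stop("Duplicate (drug_id, effect_id) pairs in triplet input.", call. = FALSE)
  }
  m <- matrix(0, length(drug_ids), length(effect_ids),
              dimnames = list(drug_ids, effect_ids))
  m[cbind(match(cols$drug_id, drug_ids), match(cols$effect_id, effect_ids))] <-
    cols$frequency
  frequency_matrix(m)
}

#' Known / unknown cell masks
#'
#' `known_mask()` is 1 where a frequency class is recorded (`R > 0`),
#' `unknown_mask()` is its complement; the two sum to the all-ones matrix.
#'
#' @param freq A [frequency_matrix()].
#' @return A 0/1 matrix of the same shape.
#' @export
known_mask <- function(freq) {
  (unclass(freq) > 0) * 1
}

#' @rdname known_mask
#' @export
unknown_mask <- function(freq) {
  (unclass(freq) == 0) * 1
}

#' @export
print.frequency_matrix <- function(x, ...) {
  kn <- sum(x > 0)
  cat(sprintf("<frequency_matrix> %d drugs x %d side effects, %d known cells (%.2f%%)\n",
              nrow(x), ncol(x), kn, 100 * kn / length(x)))
  tab <- table(factor(x[x > 0], levels = 1:5))
  cat("  class counts 1..5:", paste(as.integer(tab), collapse = " "), "\n")
  invisible(x)
}

#' Tidy the known cells of a frequency matrix
#'
#' @param x A [frequency_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per known cell: `drug_id`, `effect_id`,
#'   `frequency`.
#' @importFrom generics tidy
#' @export
tidy.frequency_matrix <- function(x, ...) {
  idx <- which(unclass(x) > 0, arr.ind = TRUE)
  tibble::tibble(
    drug_id = rownames(x)[idx[, 1]],
    effect_id = colnames(x)[idx[, 2]],
    frequency = as.integer(x[idx])
  ) |> dplyr::arrange(.data$drug_id, .data$effect_id)
}

#' Summary descriptors of a frequency dataset
#'
#' Reports the counts a dataset is usually described by: matrix dimensions,
#' number and density of known frequency items, and the proportion of each
#' frequency class among known items (in percent).
#'
#' @param freq A [frequency_matrix()].
#' @return A one-row tibble.
#' @export
dataset_descriptors <- function(freq) {
  stopifnot(inherits(freq, "frequency_matrix"))
  kn <- sum(freq > 0)
  tab <- table(factor(freq[freq > 0], levels = 1:5))
  prop <- 100 * as.numeric(tab) / max(kn, 1)
  tibble::tibble(
    n_drugs = nrow(freq),
    n_effects = ncol(freq),
    n_known = as.integer(kn),
    density_pct = 100 * kn / length(freq),
    pct_very_rare = prop[1],
    pct_rare = prop[2],
    pct_infrequent = prop[3],
    pct_frequent = prop[4],
    pct_very_frequent = prop[5]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
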