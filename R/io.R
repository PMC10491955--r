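#' Read a frequency matrix from disk
#'
#' Two formats are accepted.  Dense TSV: a header row of side-effect ids,
#' a first column of drug ids, integer cells 0--5.  Triplet CSV: columns
#' `drug_id`, `effect_id`, `frequency`, with absent pairs meaning 0.
#' The format is chosen by file extension (`.tsv` dense, `.csv` triplet)
#' unless `format` is given.
#'
#' @param path File path.
#' @param format `"auto"`, `"dense"` or `"triplet"`.
#' @return A [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path, format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "triplet" else "dense"
  }
  if (format == "dense") {
    frequency_matrix(.read_labelled_matrix(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    as_frequency_matrix(df)
  }
}

#' Write a frequency matrix
#'
#' @param freq A [frequency_matrix()].
#' @param path Output path; `.tsv` writes the dense labelled matrix,
#'   `.csv` the known-cell triplets.
#' @param format `"auto"`, `"dense"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(freq, path,
                                   format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "triplet" else "dense"
  }
  if (format == "dense") {
    .write_labelled_matrix(unclass(freq), path, id_col = "drug_id")
  } else {
    readr::write_csv(tidy.frequency_matrix(freq), path)
  }
  invisible(path)
}

#' Read / write a labelled similarity matrix
#'
#' TSV with entity ids as header and first column.
#'
#' @param path File path.
#' @param kind,axis Passed to [similarity_view()].
#' @return A [similarity_view()].
#' @export
read_similarity_matrix <- function(path, kind = "annotation",
                                   axis = c("drug", "effect")) {
  axis <- match.arg(axis)
  similarity_view(.read_labelled_matrix(path), kind = kind, axis = axis)
}

#' @rdname read_similarity_matrix
#' @param view A [similarity_view()] to write.
#' @export
write_similarity_matrix <- function(view, path) {
  .write_labelled_matrix(unclass(view), path, id_col = "id")
  invisible(path)
}

#' Read multi-hot annotations
#'
#' Two-column TSV (`entity_id`, `term_id`), one pair per line (e.g. GO
#' molecular-function terms per drug, or MedDRA codes per side effect),
#' expanded to a binary entity x term matrix.
#'
#' @param path File path.
#' @param entity_ids Optional id universe fixing row order (entities with
#'   no annotations get all-zero rows).
#' @return Binary matrix with entity ids as rownames.
#' @export
read_multihot <- function(path, entity_ids = NULL) {
  df <- readr::read_tsv(path, col_names = c("entity_id", "term_id"),
                        col_types = "cc")
  entity_ids <- entity_ids %||% sort(unique(df$entity_id))
  terms <- sort(unique(df$term_id))
  m <- matrix(0, length(entity_ids), length(terms),
              dimnames = list(entity_ids, terms))
  keep <- df$entity_id %in% entity_ids
  m[cbind(match(df$entity_id[keep], entity_ids),
          match(df$term_id[keep], terms))] <- 1
  m
}

#' Read binary fingerprints
#'
#' TSV with a drug id followed by a 0/1 bit string per line.
#'
#' @param path File path.
#' @return Binary matrix drugs x bits with drug ids as rownames.
#' @export
read_fingerprints <- function(path) {
  df <- readr::read_tsv(path, col_names = c("drug_id", "bits"),
                        col_types = "cc")
  bits <- strsplit(df$bits, "")
  len <- unique(lengths(bits))
  if (length(len) != 1 || !all(unlist(bits) %in% c("0", "1"))) {
    stop("Fingerprint bit strings must be 0/1 and of equal length.",
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(bits, function(b) as.numeric(b)))
  rownames(m) <- df$drug_id
  m
}

#' Persist / restore a fitted model
#'
#' A model directory holds `U.tsv` and `V.tsv` (labelled factor matrices
#' at full precision) and `model.json` (view weights and kinds,
#' hyperparameters, seed, objective trace, cold-start indices).  A
#' reloaded model reproduces `predict()` output exactly.
#'
#' @param fit A [sefreq_fit()] result.
#' @param dir Directory to create / read.
#' @return `write_model()`: `dir` invisibly; `read_model()`: an object of
#'   class `sefreq_model_state` usable with `predict()`.
#' @export
write_model <- function(fit, dir) {
  stopifnot(inherits(fit, "sefreq_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  U <- fit$U; rownames(U) <- rownames(fit$freq)
  V <- fit$V; colnames(V) <- colnames(fit$freq)
  .write_labelled_matrix(U, file.path(dir, "U.tsv"), id_col = "drug_id")
  .write_labelled_matrix(t(V), file.path(dir, "V.tsv"), id_col = "effect_id")
  meta <- list(
    w = fit$w, h = fit$h, view_kinds = fit$view_kinds,
    params = unclass(fit$params), seed = fit$seed,
    iterations = fit$iterations,
    initial_objective = fit$initial_objective,
    objective = fit$objective,
    cold_drugs = fit$cold_drugs, cold_effects = fit$cold_effects
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  u_path <- file.path(dir, "U.tsv")
  if (!file.exists(u_path)) stop("Not a model directory: ", dir, call. = FALSE)
  U <- .read_labelled_matrix(u_path)
  V <- t(.read_labelled_matrix(file.path(dir, "V.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  structure(list(U = U, V = V, w = meta$w, h = meta$h,
                 view_kinds = meta$view_kinds, params = meta$params,
                 seed = meta$seed, iterations = meta$iterations,
                 initial_objective = meta$initial_objective,
                 objective = meta$objective,
                 cold_drugs = meta$cold_drugs,
                 cold_effects = meta$cold_effects,
                 drug_ids = rownames(U), effect_ids = colnames(V)),
            class = "sefreq_model_state")
}

#' @export
predict.sefreq_model_state <- function(object, ...) {
  P <- object$U %*% object$V
  dimnames(P) <- list(object$drug_ids, object$effect_ids)
  P
}

#' Write a simulated dataset as the package's on-disk formats
#'
#' Writes `frequency.tsv` (dense) and `frequency.csv` (triplets), one TSV
#' per static similarity view (`drug_view_<p>_<kind>.tsv`,
#' `effect_view_<q>_<kind>.tsv`), and the ground-truth factors
#' (`truth_U.tsv`, `truth_V.tsv`), so fixtures double as format
#' round-trip tests.
#'
#' @param sim A [simulate_frequency_data()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sefreq_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frequency_matrix(sim$freq, file.path(dir, "frequency.tsv"))
  if (sim$spec$discretize) {
    write_frequency_matrix(sim$freq, file.path(dir, "frequency.csv"))
  }
  for (p in seq_along(sim$drug_views)) {
    v <- sim$drug_views[[p]]
    write_similarity_matrix(
      v, file.path(dir, sprintf("drug_view_%d_%s.tsv", p, attr(v, "kind"))))
  }
  for (q in seq_along(sim$effect_views)) {
    v <- sim$effect_views[[q]]
    write_similarity_matrix(
      v, file.path(dir, sprintf("effect_view_%d_%s.tsv", q, attr(v, "kind"))))
  }
  U <- sim$truth$U
  dimnames(U) <- list(rownames(sim$freq), paste0("f", seq_len(ncol(U))))
  V <- t(sim$truth$V)
  dimnames(V) <- list(colnames(sim$freq), paste0("f", seq_len(ncol(V))))
  .write_labelled_matrix(U, file.path(dir, "truth_U.tsv"), id_col = "drug_id")
  .write_labelled_matrix(V, file.path(dir, "truth_V.tsv"), id_col = "effect_id")
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `freq`, `drug_views`, `effect_views`.
#' @export
read_dataset <- function(dir) {
  freq <- read_frequency_matrix(file.path(dir, "frequency.tsv"))
  parse_views <- function(pattern, axis) {
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    lapply(files, function(f) {
      kind <- sub(sprintf("^%s_view_\\d+_(.*)\\.tsv$", axis), "\\1", basename(f))
      if (!kind %in% c("frequency_profile", "fingerprint", "annotation",
                       "latent_kernel")) {
        kind <- "annotation"
      }
      read_similarity_matrix(f, kind = kind, axis = axis)
    })
  }
  list(freq = freq,
       drug_views = parse_views("^drug_view_\\d+_.*\\.tsv$", "drug"),
       effect_views = parse_views("^effect_view_\\d+_.*\\.tsv$", "effect"))
}

## ---- labelled-matrix primitives -------------------------------------------

# Base-R primitives: 17 significant digits on write and R's correctly
# rounded parser on read make the round trip bitwise exact.
.read_labelled_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) {
    stop("Malformed labelled matrix (need id column + data): ", path,
         call. = FALSE)
  }
  m <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, names(df)[-1]))
  rownames(m) <- as.character(df[[1]])
  m
}

.write_labelled_matrix <- function(m, path, id_col = "id") {
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  lines <- c(paste(c(id_col, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], chr[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
}
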