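#' Construct a similarity view
#'
#' A similarity view is one attribute's square, symmetric similarity matrix
#' over drugs or over side effects, with entries in \[0, 1\].  Views are the
#' raw material of the multiview neighbourhood regularizer: each is
#' sparsified to a k-nearest-neighbour graph and combined through learned
#' weights.
#'
#' @param matrix Square numeric matrix, symmetric to 1e-12, entries in
#'   \[0, 1\]; dimnames give entity ids.
#' @param kind One of `"frequency_profile"`, `"fingerprint"`,
#'   `"annotation"`, `"latent_kernel"`.
#' @param axis `"drug"` or `"effect"`.
#' @return Matrix of class `similarity_view` with `kind`/`axis` attributes.
#' @export
similarity_view <- function(matrix,
                            kind = c("frequency_profile", "fingerprint",
                                     "annotation", "latent_kernel"),
                            axis = c("drug", "effect")) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("A similarity view must be a square matrix.", call. = FALSE)
  }
  if (anyNA(matrix) || min(matrix) < -1e-12 || max(matrix) > 1 + 1e-12) {
    stop("Similarity entries must lie in [0, 1].", call. = FALSE)
  }
  if (max(abs(matrix - t(matrix))) > 1e-12) {
    stop("Similarity matrix must be symmetric (tolerance 1e-12).", call. = FALSE)
  }
  matrix <- pmin(pmax(matrix, 0), 1)
  if (is.null(rownames(matrix))) {
    ids <- paste0(axis, "_", seq_len(nrow(matrix)))
    dimnames(matrix) <- list(ids, ids)
  } else {
    colnames(matrix) <- rownames(matrix)
  }
  structure(matrix, kind = kind, axis = axis,
            class = c("similarity_view", "matrix", "array"))
}

#' @export
print.similarity_view <- function(x, ...) {
  cat(sprintf("<similarity_view> %s/%s, %d entities\n",
              attr(x, "axis"), attr(x, "kind"), nrow(x)))
  invisible(x)
}

#' Cosine similarity of frequency profiles
#'
#' For the drug axis, each drug's profile is its row of the frequency
#' matrix; for the effect axis, each side effect's profile is its column.
#' Similarity is the cosine of the angle between two profiles.  An entity
#' whose profile is all zero (possible for held-out drugs in cold-start
#' folds) gets similarity 0 to everything, rather than NaN.
#'
#' @param freq A [frequency_matrix()] (or plain numeric matrix of profiles
#'   as rows when `axis = "drug"` / columns when `axis = "effect"`).
#' @param axis `"drug"` or `"effect"`.
#' @return A [similarity_view()] of kind `"frequency_profile"`.
#' @export
cosine_profile_similarity <- function(freq, axis = c("drug", "effect")) {
  axis <- match.arg(axis)
  x <- unclass(freq)
  profiles <- if (axis == "drug") x else t(x)
  g <- tcrossprod(profiles)
  nrm <- sqrt(diag(g))
  denom <- outer(nrm, nrm)
  s <- ifelse(denom > 0, g / ifelse(denom > 0, denom, 1), 0)
  # cosine can exceed 1 by rounding; clamp before validation
  s <- pmin(pmax(s, 0), 1)
  s <- (s + t(s)) / 2
  ids <- rownames(profiles) %||% paste0(axis, "_", seq_len(nrow(profiles)))
  dimnames(s) <- list(ids, ids)
  similarity_view(s, kind = "frequency_profile", axis = axis)
}

#' Jaccard similarity of multi-hot annotation vectors
#'
#' Encodes each entity as the set of terms annotating it (GO molecular
#' function terms of a drug's targets; MedDRA SOC/HLGT/HLT/PT codes of a
#' side effect) and scores two entities by |intersection| / |union|.
#' Two empty sets score 0 by convention.
#'
#' @param multihot Binary matrix, entities x terms, with entity ids as
#'   rownames.
#' @param axis `"drug"` or `"effect"`.
#' @param kind View kind label, `"annotation"` by default.
#' @return A [similarity_view()].
#' @export
jaccard_similarity <- function(multihot, axis = c("drug", "effect"),
                               kind = "annotation") {
  axis <- match.arg(axis)
  if (!is.matrix(multihot) || anyNA(multihot) || !all(multihot %in% c(0, 1))) {
    stop("`multihot` must be a binary (0/1) matrix.", call. = FALSE)
  }
  inter <- tcrossprod(multihot)
  sz <- rowSums(multihot)
  uni <- outer(sz, sz, `+`) - inter
  s <- ifelse(uni > 0, inter / ifelse(uni > 0, uni, 1), 0)
  s <- (s + t(s)) / 2
  ids <- rownames(multihot) %||% paste0(axis, "_", seq_len(nrow(multihot)))
  dimnames(s) <- list(ids, ids)
  similarity_view(s, kind = kind, axis = axis)
}

#' Tanimoto similarity of binary fingerprints
#'
#' Chemical-structure similarity between drugs from topological
#' fingerprints: T(i, j) = c / (a + b - c) with a, b the on-bit counts of
#' the two fingerprints and c the shared on-bits.  On bit-vectors this
#' coincides with the Jaccard coefficient.
#'
#' @param fingerprints Binary matrix, drugs x bits, drug ids as rownames.
#' @return A [similarity_view()] of kind `"fingerprint"` on the drug axis.
#' @export
tanimoto_fingerprint_similarity <- function(fingerprints) {
  jaccard_similarity(fingerprints, axis = "drug", kind = "fingerprint")
}

#' Compute topological fingerprints from SMILES
#'
#' Optional convenience path: converts a SMILES table to 1024-bit
#' atom-pair-derived topological fingerprints via the ChemmineR /
#' ChemmineOB packages.  When the backend is unavailable, supply a
#' precomputed binary fingerprint matrix to
#' [tanimoto_fingerprint_similarity()] instead.
#'
#' @param smiles Data frame with columns `drug_id` and `smiles` (or any two
#'   columns in that order).
#' @return Binary matrix drugs x 1024 bits with drug ids as rownames.
#' @export
smiles_to_fingerprints <- function(smiles) {
  stopifnot(is.data.frame(smiles), ncol(smiles) >= 2)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES conversion needs the ChemmineR and ChemmineOB packages; ",
         "precompute binary fingerprints and pass them to ",
         "tanimoto_fingerprint_similarity() instead.", call. = FALSE)
  }
  ids <- as.character(smiles[[1]])
  sdf <- ChemmineR::smiles2sdf(stats::setNames(as.character(smiles[[2]]), ids))
  # pass the reference atom-pair descriptor set explicitly: desc2fp's own
  # data() lookup assumes ChemmineR is attached
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  descnames <- as.character(e$apfp$AP)[seq_len(1024)]
  fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf), descnames = descnames,
                           type = "matrix")
  storage.mode(fp) <- "double"
  rownames(fp) <- ids
  fp
}
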