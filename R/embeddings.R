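#' Construct an embedding matrix
#'
#' Container for dense sentence vectors: an n x d numeric matrix whose row i
#' represents `ids[i]`, plus the post-processing state (whether the corpus
#' mean has been subtracted and leading principal components removed).
#'
#' @param ids Character vector of sentence ids, one per row, no duplicates.
#' @param vectors Numeric n x d matrix with all entries finite.
#' @param backend Name of the encoder that produced the vectors.
#' @param postprocessed Logical; `TRUE` only for objects returned by
#'   [postprocess_embeddings()].
#' @param center Stored column means removed during post-processing (audit).
#' @param removed_components d x c matrix of removed principal axes (audit).
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(ids, vectors, backend = "unknown",
                             postprocessed = FALSE, center = NULL,
                             removed_components = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  ids <- as.character(ids)
  if (length(ids) != nrow(vectors)) {
    cl_stop("credlift_embedding_error", "length(ids) (%d) != nrow(vectors) (%d)",
            length(ids), nrow(vectors))
  }
  if (anyDuplicated(ids)) {
    cl_stop("credlift_duplicate_id_error", "duplicate ids in embedding matrix")
  }
  if (!all(is.finite(vectors))) {
    cl_stop("credlift_embedding_error", "embedding matrix has non-finite entries")
  }
  if (postprocessed && !is.null(removed_components)) {
    tol <- 1e-8 * max(1, max(abs(vectors)))
    if (max(abs(colMeans(vectors))) > tol ||
        max(abs(vectors %*% removed_components)) > tol) {
      cl_stop("credlift_embedding_error",
              "postprocessed matrix is not centered/orthogonal to its removed components")
    }
  }
  structure(
    list(ids = ids, vectors = vectors, dim = ncol(vectors),
         backend = backend, postprocessed = postprocessed,
         center = center, removed_components = removed_components),
    class = "embedding_matrix"
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d sentences x %d dims (backend: %s, postprocessed: %s)\n",
              nrow(x$vectors), x$dim, x$backend, x$postprocessed))
  invisible(x)
}

#' Deterministic hash-projection encoder backend
#'
#' A lightweight, fully offline sentence encoder: each sentence is tokenized
#' (lower-cased, split on non-alphanumerics), tokens are hashed into
#' `buckets` counts, and the count profile is mapped through a seeded random
#' Gaussian projection to `dim` dimensions. Sentences sharing many tokens
#' share hash buckets and therefore have higher cosine similarity than
#' token-disjoint sentences. Intended for tests, simulation and the synthetic
#' text corpus; a transformer encoder can be supplied through the same
#' backend contract (`list(name, dim, encode)`).
#'
#' @param dim Output dimensionality (>= 2).
#' @param seed Integer seed fixing the projection matrix.
#' @param buckets Number of hash buckets for the token count profile.
#' @return A backend: list with `name`, `dim` and `encode(texts)` returning an
#'   n x dim matrix, deterministic in its inputs.
#' @export
#' @examples
#' b <- hash_projection_backend(dim = 16, seed = 1)
#' v <- b$encode(c("statins lower cholesterol", "the opera opened yesterday"))
#' dim(v)
hash_projection_backend <- function(dim, seed, buckets = 512L) {
  if (dim < 2) cl_stop("credlift_embedding_error", "dim must be >= 2")
  projection <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    matrix(stats::rnorm(buckets * dim, sd = 1 / sqrt(dim)), nrow = buckets)
  })
  encode <- function(texts) {
    profiles <- t(vapply(as.character(texts), token_hash_profile,
                         numeric(buckets), buckets = buckets))
    unname(profiles %*% projection)
  }
  list(name = sprintf("hash_projection(dim=%d,seed=%d)", dim, as.integer(seed)),
       dim = as.integer(dim), encode = encode)
}

# Polynomial rolling hash of each token into [1, buckets]; pure arithmetic so
# the profile is identical across platforms and sessions.
token_hash_profile <- function(text, buckets) {
  tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  profile <- numeric(buckets)
  for (tok in tokens) {
    h <- 0
    for (cp in utf8ToInt(tok)) h <- (h * 31 + cp) %% buckets
    profile[h + 1] <- profile[h + 1] + 1
  }
  profile
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Encode a corpus into an embedding matrix
#'
#' @param records A sentence corpus (see [as_sentence_corpus()]).
#' @param backend An encoder backend (see [hash_projection_backend()] for the
#'   contract).
#' @return An `embedding_matrix` with rows in corpus order,
#'   `postprocessed = FALSE`.
#' @export
embed_corpus <- function(records, backend) {
  records <- as_sentence_corpus(records)
  if (nrow(records) == 0) {
    cl_stop("credlift_empty_corpus_error", "cannot embed an empty corpus")
  }
  vectors <- tryCatch(backend$encode(records$text),
                      error = function(e) {
                        cl_stop("credlift_backend_error",
                                "encoder backend '%s' failed: %s",
                                backend$name, conditionMessage(e))
                      })
  embedding_matrix(records$sentence_id, vectors, backend = backend$name)
}

#' Mean subtraction and principal-component removal
#'
#' Corpus-level embedding post-processing: subtract the column mean, then
#' project every row onto the orthogonal complement of the first
#' `n_components` principal axes of the centered matrix. The removed
#' direction(s) tend to carry dominant non-semantic (stylistic/syntactic)
#' variation; stripping them sharpens cosine geometry for clustering. The
#' principal axes are computed once on the full matrix, and each axis sign is
#' fixed by making its largest-magnitude entry positive so results are
#' reproducible across linear-algebra backends.
#'
#' @param X An `embedding_matrix` with `postprocessed = FALSE` and >= 2 rows.
#' @param n_components Number of leading components to remove (default 1).
#' @return A new `embedding_matrix` with `postprocessed = TRUE`; the removed
#'   axes and the subtracted mean are stored for audit.
#' @export
postprocess_embeddings <- function(X, n_components = 1L) {
  stopifnot(inherits(X, "embedding_matrix"))
  if (X$postprocessed) {
    cl_stop("credlift_embedding_error", "embedding matrix is already postprocessed")
  }
  if (nrow(X$vectors) < 2) {
    cl_stop("credlift_embedding_error", "post-processing needs at least 2 rows")
  }
  center <- colMeans(X$vectors)
  Xc <- sweep(X$vectors, 2, center)
  if (max(abs(Xc)) == 0) {
    cl_stop("credlift_zero_variance_error",
            "all rows identical: zero variance, no principal component to remove")
  }
  sv <- svd(Xc, nu = 0, nv = n_components)
  axes <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(axes))) {
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  Xp <- Xc - (Xc %*% axes) %*% t(axes)
  embedding_matrix(X$ids, Xp, backend = X$backend, postprocessed = TRUE,
                   center = center, removed_components = axes)
}

#' Persist / load an embedding matrix
#'
#' The matrix is written as a plain TSV (one row per sentence, no header) next
#' to a JSON sidecar (`<prefix>.json`) recording ids, dimensionality, backend
#' name and post-processing state.
#'
#' @param X An `embedding_matrix`.
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_embeddings <- function(X, prefix) {
  stopifnot(inherits(X, "embedding_matrix"))
  utils::write.table(X$vectors, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(ids = X$ids, dim = X$dim, backend = X$backend,
                  postprocessed = X$postprocessed)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vectors <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  embedding_matrix(sidecar$ids, vectors, backend = sidecar$backend,
                   postprocessed = isTRUE(sidecar$postprocessed))
}
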