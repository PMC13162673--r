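#' L2-normalize a vector
#'
#' Rescales a vector to unit Euclidean norm, preserving direction. Embedding
#' vectors are always re-normalized at ingestion rather than trusted, so that
#' cosine similarity computed as a plain inner product is exact regardless of
#' float drift introduced upstream of this package.
#'
#' @param v Numeric vector with at least one nonzero component.
#' @return Numeric vector of the same length with unit L2 norm.
#' @examples
#' l2_normalize(c(3, 4)) # c(0.6, 0.8)
#' @export
l2_normalize <- function(v) {
  if (!is.numeric(v) || length(v) == 0L) {
    stop("'v' must be a non-empty numeric vector", call. = FALSE)
  }
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("cannot normalize a zero (or non-finite) vector: direction undefined",
         call. = FALSE)
  }
  v / nrm
}

# Row-wise normalization for embedding matrices; errors on any zero row.
.l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  bad <- which(!is.finite(nrm) | nrm == 0)
  if (length(bad) > 0L) {
    stop("zero or non-finite embedding vector at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  m / nrm
}

#' Cosine distance between two unit vectors
#'
#' Distance is defined as `1 - u . v`, i.e. one minus the cosine similarity,
#' giving values in `[0, 2]`: 0 for identical directions, 1 for orthogonal
#' vectors, 2 for opposite directions.
#'
#' @param u,v Unit-norm numeric vectors of equal dimension.
#' @return Cosine distance in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  max(0, 1 - sum(u * v))
}

#' Construct a set of embedding records
#'
#' Bundles per-object metadata with an embedding matrix into an
#' `embedding_set`. One row per detected object: an opaque unique `object_id`,
#' the `sample_id` it came from, an optional category `label`, a `verified`
#' flag (TRUE only for labels confirmed by a human expert) and an ordinal
#' stream position `t`. Vectors are re-normalized to unit L2 norm.
#'
#' @param object_id Character vector of unique object identifiers.
#' @param vectors Numeric matrix, one row per object.
#' @param sample_id Character vector (recycled) of sample identifiers.
#' @param label Character vector (recycled) of category labels; `NA` = absent.
#' @param verified Logical vector (recycled); `TRUE` requires a label.
#' @param t Integer vector (recycled) of ordinal stream positions (>= 0).
#' @return An `embedding_set`: list with `meta` (data.frame) and `vectors`
#'   (unit-row matrix, rownames = object ids).
#' @export
embedding_records <- function(object_id, vectors, sample_id = "s1",
                              label = NA_character_, verified = FALSE, t = 0L) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  n <- nrow(vectors)
  object_id <- as.character(object_id)
  if (length(object_id) != n) {
    stop("length(object_id) must equal nrow(vectors)", call. = FALSE)
  }
  if (anyDuplicated(object_id)) {
    stop("duplicate object_id in records: ",
         object_id[duplicated(object_id)][1L], call. = FALSE)
  }
  meta <- data.frame(
    object_id = object_id,
    sample_id = rep_len(as.character(sample_id), n),
    label     = rep_len(as.character(label), n),
    verified  = rep_len(as.logical(verified), n),
    t         = rep_len(as.integer(t), n),
    stringsAsFactors = FALSE
  )
  if (any(meta$t < 0L, na.rm = TRUE)) stop("'t' must be >= 0", call. = FALSE)
  if (any(meta$verified & is.na(meta$label))) {
    stop("verified records must carry a label", call. = FALSE)
  }
  vectors <- .l2_normalize_rows(vectors)
  rownames(vectors) <- object_id
  structure(list(meta = meta, vectors = vectors), class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d records, dim %d, %d verified, %d labeled\n",
              nrow(x$meta), ncol(x$vectors), sum(x$meta$verified),
              sum(!is.na(x$meta$label))))
  invisible(x)
}

n_records <- function(x) nrow(x$meta)

#' Subset an embedding set
#'
#' Row subsetting of an `embedding_set` (metadata and vectors together),
#' for splitting records into reference and query sets.
#'
#' @param x An `embedding_set`.
#' @param i Logical, integer or negative-integer row index.
#' @return The subsetted `embedding_set`.
#' @export
subset_records <- function(x, i) {
  structure(list(meta = x$meta[i, , drop = FALSE],
                 vectors = x$vectors[i, , drop = FALSE]),
            class = "embedding_set")
}

#' Create an empty reference index
#'
#' The reference index is the searchable store of expert-verified labeled
#' embeddings. Only verified records may enter it (the training rule of the
#' continuous-adaptation loop), and it caches, for every label with at least
#' two members, the mean pairwise intra-label cosine distance used by the
#' KNN label-proposal heuristic.
#'
#' @param records Optional `embedding_set` of verified records to ingest.
#' @param dim Embedding dimension (default 128).
#' @return A `reference_index`.
#' @seealso [add_verified()], [knn_search()], [mean_intra_label_distance()]
#' @export
reference_index <- function(records = NULL, dim = 128L) {
  idx <- structure(list(
    dim = as.integer(dim),
    vectors = matrix(numeric(0), nrow = 0L, ncol = as.integer(dim)),
    object_ids = character(0),
    labels = character(0),
    label_means = numeric(0),      # named cache: mean intra-label distance
    model_cache = new.env(parent = emptyenv())
  ), class = "reference_index")
  if (!is.null(records)) idx <- add_verified(idx, records)
  idx
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d verified records, dim %d, %d labels\n",
              length(x$object_ids), x$dim, length(unique(x$labels))))
  invisible(x)
}

index_size <- function(index) length(index$object_ids)

# Mean pairwise cosine distance over all unordered pairs of rows.
.mean_pairwise_cosdist <- function(m) {
  n <- nrow(m)
  s <- tcrossprod(m)
  # sum over unordered pairs of (1 - s_ij)
  tot <- (sum(s) - sum(diag(s))) / 2
  npair <- n * (n - 1) / 2
  max(0, (npair - tot) / npair)
}

#' Add verified records to a reference index
#'
#' Only records with `verified = TRUE` (and hence a label) are ingested;
#' unverified records are rejected with a warning, mirroring the rule that
#' training data contains only expert-verified objects. Duplicate object ids
#' are an error. Per-label distance caches for every touched label are
#' recomputed, and fitted cluster / one-class models for those labels are
#' invalidated.
#'
#' @param index A `reference_index`.
#' @param records An `embedding_set`.
#' @return The updated `reference_index`.
#' @export
add_verified <- function(index, records) {
  stopifnot(inherits(index, "reference_index"),
            inherits(records, "embedding_set"))
  if (n_records(records) == 0L) return(index)
  if (ncol(records$vectors) != index$dim) {
    stop("dimension mismatch: index dim ", index$dim,
         ", records dim ", ncol(records$vectors), call. = FALSE)
  }
  keep <- records$meta$verified
  if (any(!keep)) {
    warning(sum(!keep), " unverified record(s) rejected from reference index",
            call. = FALSE)
    records <- subset_records(records, keep)
  }
  if (n_records(records) == 0L) return(index)
  dup <- records$meta$object_id %in% index$object_ids
  if (any(dup)) {
    stop("duplicate object_id already in index: ",
         records$meta$object_id[dup][1L], call. = FALSE)
  }
  touched <- unique(records$meta$label)
  out <- index
  out$vectors <- rbind(index$vectors, records$vectors)
  out$object_ids <- c(index$object_ids, records$meta$object_id)
  out$labels <- c(index$labels, records$meta$label)
  # refresh distance cache for touched labels
  means <- index$label_means
  for (lab in touched) {
    rows <- out$labels == lab
    if (sum(rows) >= 2L) {
      means[[lab]] <- .mean_pairwise_cosdist(out$vectors[rows, , drop = FALSE])
    }
  }
  out$label_means <- means
  # fresh model cache: keep only entries for untouched labels
  nc <- new.env(parent = emptyenv())
  for (key in ls(index$model_cache)) {
    if (!(get(key, envir = index$model_cache)$label %in% touched)) {
      assign(key, get(key, envir = index$model_cache), envir = nc)
    }
  }
  out$model_cache <- nc
  out
}

#' Exact k-nearest-neighbour search in cosine distance
#'
#' Exhaustive (flat-index) scan: the query is compared against every stored
#' vector, so results are exact, never approximate. Ties on distance are
#' broken by ascending `object_id` (byte order) for reproducibility.
#'
#' @param index A non-empty `reference_index`.
#' @param query Unit-norm numeric vector of dimension `index$dim`.
#' @param k Number of neighbours (>= 1); `min(k, n)` rows are returned.
#' @return data.frame with columns `object_id`, `label`, `distance`,
#'   sorted by ascending distance.
#' @export
knn_search <- function(index, query, k) {
  stopifnot(inherits(index, "reference_index"))
  n <- index_size(index)
  if (n == 0L) stop("knn_search on an empty index", call. = FALSE)
  if (length(query) != index$dim) {
    stop("query dimension ", length(query), " != index dim ", index$dim,
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  d <- pmax(0, 1 - drop(index$vectors %*% query))
  ord <- order(d, index$object_ids, method = "radix")
  take <- ord[seq_len(min(k, n))]
  data.frame(object_id = index$object_ids[take],
             label = index$labels[take],
             distance = d[take],
             stringsAsFactors = FALSE)
}

#' Mean intra-label cosine distance
#'
#' Arithmetic mean of the cosine distance over all unordered pairs of
#' verified members of `label`. This is the reference scale the KNN proposal
#' heuristic compares query-to-neighbour distances against. Served from a
#' cache that is refreshed on every index mutation touching the label.
#'
#' @param index A `reference_index`.
#' @param label Category name with at least 2 verified members.
#' @return Mean pairwise cosine distance (scalar).
#' @export
mean_intra_label_distance <- function(index, label) {
  stopifnot(inherits(index, "reference_index"))
  if (sum(index$labels == label) < 2L) {
    stop("label '", label, "' has fewer than 2 verified members; ",
         "intra-label mean distance undefined", call. = FALSE)
  }
  unname(index$label_means[[label]])
}

# All labels with at least `min_n` members.
labels_with_at_least <- function(index, min_n) {
  tab <- table(index$labels)
  names(tab)[tab >= min_n]
}
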