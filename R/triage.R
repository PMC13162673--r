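#' Parameters of the triage cascade
#'
#' Bundles and validates every tunable of the object-routing cascade.
#'
#' @param detection_threshold Detector-confidence gate in `[0,1]`; objects
#'   with confidence strictly below it go to manual review (default 0.8, so
#'   a confidence of exactly 0.8 passes).
#' @param k_neighbors Neighbourhood size of the KNN label proposal
#'   (default 10).
#' @param min_same_label Minimum number of same-label vectors among the
#'   `k_neighbors` nearest for a label to be proposed (default 5); must not
#'   exceed `k_neighbors`.
#' @param certainty_threshold One-class certainty below which an object is
#'   treated as novel and reviewed (default 0.95, strict: exactly 0.95
#'   passes).
#' @param min_cluster_size Minimum density-cluster size, also the minimum
#'   number of label members needed to fit cluster / one-class models
#'   (default 5).
#' @param nu Training-outlier budget of the one-class support-vector
#'   estimator (default 0.05).
#' @param core_dist_floor Absolute core-distance ceiling for density
#'   clustering on the cosine sphere (default 0.5).
#' @param cluster_eps Dendrogram scale below which density splits are
#'   ignored (default 0.2).
#' @param knn_aggregate How query-to-neighbour distances are aggregated
#'   before comparison with the intra-label mean: `"mean"` (default,
#'   matching the mean-vs-mean reading of the heuristic), `"median"` or
#'   `"max"`.
#' @param certainty_mode `"calibrated"` (default: rank-calibrated scores,
#'   see [certainty()]) or `"raw"` (min-max scaled decision values).
#' @param seed Integer seed recorded for downstream consumers.
#' @return A validated `triage_params` list.
#' @export
triage_params <- function(detection_threshold = 0.8, k_neighbors = 10L,
                          min_same_label = 5L, certainty_threshold = 0.95,
                          min_cluster_size = 5L, nu = 0.05,
                          core_dist_floor = 0.5, cluster_eps = 0.2,
                          knn_aggregate = c("mean", "median", "max"),
                          certainty_mode = c("calibrated", "raw"),
                          seed = 1L) {
  knn_aggregate <- match.arg(knn_aggregate)
  certainty_mode <- match.arg(certainty_mode)
  p <- list(detection_threshold = detection_threshold,
            k_neighbors = as.integer(k_neighbors),
            min_same_label = as.integer(min_same_label),
            certainty_threshold = certainty_threshold,
            min_cluster_size = as.integer(min_cluster_size),
            nu = nu, core_dist_floor = core_dist_floor,
            cluster_eps = cluster_eps, knn_aggregate = knn_aggregate,
            certainty_mode = certainty_mode, seed = as.integer(seed))
  if (p$detection_threshold < 0 || p$detection_threshold > 1) {
    stop("detection_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (p$certainty_threshold < 0 || p$certainty_threshold > 1) {
    stop("certainty_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (p$nu <= 0 || p$nu >= 1) stop("nu must lie in (0, 1)", call. = FALSE)
  if (p$k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  if (p$min_same_label < 1L || p$min_same_label > p$k_neighbors) {
    stop("min_same_label must lie in [1, k_neighbors]", call. = FALSE)
  }
  if (p$min_cluster_size < 2L) {
    stop("min_cluster_size must be >= 2", call. = FALSE)
  }
  structure(p, class = "triage_params")
}

#' Detection-confidence gate
#'
#' An object detection with estimated probability strictly below the
#' threshold is passed for manual evaluation; the boundary value passes.
#'
#' @param confidence Detector confidence in `[0, 1]`.
#' @param params A [triage_params()] object.
#' @return `TRUE` (pass) or `FALSE` (fail, route to review).
#' @export
detection_gate <- function(confidence, params = triage_params()) {
  stopifnot(is.numeric(confidence), confidence >= 0, confidence <= 1)
  confidence >= params$detection_threshold
}

#' KNN label proposal
#'
#' Among the `k_neighbors` nearest verified embeddings of the query, a label
#' qualifies if (a) it has at least `min_same_label` representatives in the
#' neighbourhood, and (b) the aggregated (default: mean) query-to-those-
#' representatives cosine distance is strictly lower than the mean pairwise
#' intra-label distance of that label across the whole index. Labels with
#' fewer than two index members cannot qualify (their intra-label mean is
#' undefined). When several labels qualify, the one with more neighbourhood
#' representatives wins, then the smaller aggregated distance, then byte
#' order of the label.
#'
#' @param index A non-empty `reference_index`.
#' @param query Unit-norm numeric vector.
#' @param params A [triage_params()] object.
#' @return List with `label` (character or `NULL` if no label qualifies)
#'   and `diagnostics` (per-candidate table plus the winning distances).
#' @export
propose_label_knn <- function(index, query, params = triage_params()) {
  nn <- knn_search(index, query, params$k_neighbors)
  labs <- unique(nn$label)
  cand <- data.frame(label = character(0), n_neighbors = integer(0),
                     query_distance = numeric(0), intra_mean = numeric(0),
                     qualifies = logical(0), stringsAsFactors = FALSE)
  agg <- switch(params$knn_aggregate, mean = mean, median = stats::median,
                max = max)
  for (lab in labs) {
    sel <- nn$label == lab
    if (sum(sel) < params$min_same_label) next
    qd <- agg(nn$distance[sel])
    im <- if (sum(index$labels == lab) >= 2L) {
      mean_intra_label_distance(index, lab)
    } else {
      NA_real_ # undefined intra-label mean: cannot qualify
    }
    cand <- rbind(cand, data.frame(
      label = lab, n_neighbors = sum(sel), query_distance = qd,
      intra_mean = im, qualifies = !is.na(im) && qd < im,
      stringsAsFactors = FALSE))
  }
  qual <- cand[cand$qualifies, , drop = FALSE]
  if (nrow(qual) == 0L) {
    return(list(label = NULL, diagnostics = list(candidates = cand)))
  }
  ord <- order(-qual$n_neighbors, qual$query_distance, qual$label,
               method = "radix")
  win <- qual[ord[1L], ]
  list(label = win$label,
       diagnostics = list(candidates = cand,
                          query_distance = win$query_distance,
                          intra_mean = win$intra_mean,
                          n_neighbors = win$n_neighbors))
}

#' Fit density clusters for one label of the reference index
#'
#' @param index A `reference_index`.
#' @param label Label with at least `min_cluster_size` verified members.
#' @param params A [triage_params()] object.
#' @return A `density_cluster_model` (see [density_clusters()]) with the
#'   member object ids attached as attribute `object_ids`.
#' @export
fit_label_clusters <- function(index, label, params = triage_params()) {
  rows <- which(index$labels == label)
  if (length(rows) < params$min_cluster_size) {
    stop("label '", label, "' has ", length(rows),
         " members, fewer than min_cluster_size = ", params$min_cluster_size,
         "; route object to review", call. = FALSE)
  }
  m <- density_clusters(index$vectors[rows, , drop = FALSE],
                        min_cluster_size = params$min_cluster_size,
                        core_floor = params$core_dist_floor,
                        selection_epsilon = params$cluster_eps)
  attr(m, "object_ids") <- index$object_ids[rows]
  attr(m, "label") <- label
  m
}

#' Fit a one-class support-vector boundary on a cluster
#'
#' Radial-basis one-class SVM with training-outlier budget `nu`; the kernel
#' scale is set by the median heuristic on pairwise squared Euclidean
#' distances. Decision scores are calibrated into certainties via the
#' empirical distribution of cross-fitted (5-fold out-of-fold) scores:
#' scoring a point against a boundary it helped shape is optimistically
#' biased, and the cross-fitted distribution is the honest reference for
#' "how do points of this cluster score".
#'
#' @param x Matrix of unit-norm cluster vectors (>= `min_cluster_size`
#'   rows).
#' @param params A [triage_params()] object.
#' @return A `one_class_model`; `$degenerate` flags an all-identical input
#'   (the model still fits, with a unit fallback kernel scale).
#' @export
fit_one_class <- function(x, params = triage_params()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < params$min_cluster_size) {
    stop("need at least min_cluster_size = ", params$min_cluster_size,
         " vectors to fit a one-class boundary, got ", n, call. = FALSE)
  }
  d2 <- stats::dist(x)^2
  med <- stats::median(d2)
  degenerate <- !is.finite(med) || med < 1e-12
  gamma <- if (degenerate) 1 else 1 / (2 * med)
  fit_args <- list(type = "one-classification", kernel = "radial",
                   nu = params$nu, gamma = gamma, scale = FALSE)
  score <- function(fit, q) {
    drop(attr(stats::predict(fit, q, decision.values = TRUE),
              "decision.values"))
  }
  # cross-fitted calibration scores (deterministic interleaved folds)
  k_folds <- min(5L, n)
  folds <- rep_len(seq_len(k_folds), n)
  oof <- numeric(n)
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    f <- do.call(e1071::svm, c(list(x = x[tr, , drop = FALSE]), fit_args))
    oof[!tr] <- score(f, x[!tr, , drop = FALSE])
  }
  fit <- do.call(e1071::svm, c(list(x = x), fit_args))
  structure(list(fit = fit, calibration = sort(oof), nu = params$nu,
                 gamma = gamma, degenerate = degenerate,
                 mode = params$certainty_mode, n = n),
            class = "one_class_model")
}

#' @export
print.one_class_model <- function(x, ...) {
  cat(sprintf("<one_class_model> n = %d, nu = %.3g, gamma = %.3g%s\n",
              x$n, x$nu, x$gamma,
              if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}

#' One-class certainty of a query
#'
#' Maps the signed decision score of the one-class boundary into `[0, 1]`,
#' higher meaning more typical of the cluster. In `"calibrated"` mode the
#' score is ranked (with interpolation) against the model's cross-fitted
#' calibration scores and the rank is re-anchored so that the `nu`-quantile
#' of calibration scores -- the estimated boundary -- maps to `1 - nu`.
#' With the defaults (`nu = 0.05`), certainty `>= 0.95` therefore means
#' "inside the cross-validated 5%-outlier boundary", which is exactly what
#' the 0.95 routing threshold consumes. In `"raw"` mode the score is
#' min-max scaled against the calibration range.
#'
#' @param model A `one_class_model` from [fit_one_class()].
#' @param query Unit-norm numeric vector (or matrix of rows).
#' @return Certainty value(s) in `[0, 1]`.
#' @export
certainty <- function(model, query) {
  stopifnot(inherits(model, "one_class_model"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  s <- drop(attr(stats::predict(model$fit, query, decision.values = TRUE),
                 "decision.values"))
  cal <- model$calibration
  n <- length(cal)
  if (model$mode == "raw") {
    rng <- range(cal)
    if (diff(rng) < 1e-15) return(as.numeric(s >= rng[1L] - 1e-12))
    return(pmin(1, pmax(0, (s - rng[1L]) / diff(rng))))
  }
  # interpolated rank of s within the calibration scores
  if (diff(range(cal)) < 1e-15) {
    fr <- ifelse(s >= cal[1L] - 1e-12, n / (n + 1), 1 / (n + 1))
  } else {
    pos <- seq_len(n) / (n + 1)
    u <- unique(cal) # cal is sorted
    pu <- vapply(u, function(v) mean(pos[cal == v]), numeric(1))
    fr <- stats::approx(u, pu, xout = s, rule = 2)$y
  }
  nu <- model$nu
  out <- ifelse(fr <= nu,
                fr / nu * (1 - nu),
                (1 - nu) + nu * (fr - nu) / (1 - nu))
  pmin(1, pmax(0, out))
}

# Cluster + one-class models for a label, cached on the index. Cache key is
# label plus member count (an index only ever grows, so the pair pins the
# member set) plus the parameters that shape the models.
.label_models <- function(index, label, params) {
  key <- paste(label, sum(index$labels == label),
               params$min_cluster_size, params$nu, params$core_dist_floor,
               params$cluster_eps, params$certainty_mode, sep = "|")
  if (exists(key, envir = index$model_cache, inherits = FALSE)) {
    return(get(key, envir = index$model_cache)$models)
  }
  clusters <- fit_label_clusters(index, label, params)
  oneclass <- lapply(seq_along(clusters$clusters), function(k) {
    fit_one_class(clusters$x[clusters$point_cluster == k, , drop = FALSE],
                  params)
  })
  models <- list(clusters = clusters, oneclass = oneclass)
  assign(key, list(label = label, models = models),
         envir = index$model_cache)
  models
}

.empty_trace <- function(object_id) {
  n <- length(object_id)
  data.frame(object_id = object_id, route = rep(NA_character_, n),
             proposed_label = rep(NA_character_, n),
             fail_stage = rep(NA_character_, n),
             detection_gate = rep("skipped", n),
             confidence = rep(NA_real_, n),
             knn_label = rep(NA_character_, n),
             knn_query_distance = rep(NA_real_, n),
             knn_intra_mean = rep(NA_real_, n),
             cluster_id = rep(NA_integer_, n),
             cluster_stage = rep("skipped", n),
             certainty = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

#' Route one detected object through the triage cascade
#'
#' Stages run strictly in order and stop at the first failure:
#' detection-confidence gate, KNN label proposal, density-cluster
#' membership within the proposed label, one-class certainty against the
#' matched cluster. The object is auto-accepted only if every stage passes
#' and the certainty is at least `certainty_threshold`; otherwise it is
#' routed to expert review. Any stage error (e.g. a label too small for
#' cluster models) also routes to review -- no object is ever left
#' unrouted.
#'
#' @param index A `reference_index` (may be empty: everything reviews).
#' @param det A list or one-row data.frame with `object_id` and
#'   `confidence`.
#' @param embedding Unit-norm numeric vector.
#' @param params A [triage_params()] object.
#' @return One-row data.frame: `object_id`, `route`
#'   (`"auto_accept"`/`"review"`), `proposed_label`, `fail_stage` and
#'   per-stage diagnostics (`detection_gate`, `knn_*`, `cluster_*`,
#'   `certainty`).
#' @export
triage_object <- function(index, det, embedding, params = triage_params()) {
  tr <- .empty_trace(as.character(det$object_id))
  tr$confidence <- det$confidence
  review <- function(tr, stage) {
    tr$route <- "review"; tr$fail_stage <- stage
    tr
  }
  # stage 1: detection gate
  if (!detection_gate(det$confidence, params)) {
    tr$detection_gate <- "fail"
    return(review(tr, "detection_gate"))
  }
  tr$detection_gate <- "pass"
  # stage 2: KNN proposal
  if (index_size(index) == 0L) return(review(tr, "knn_proposal"))
  prop <- propose_label_knn(index, embedding, params)
  if (is.null(prop$label)) return(review(tr, "knn_proposal"))
  tr$knn_label <- prop$label
  tr$knn_query_distance <- prop$diagnostics$query_distance
  tr$knn_intra_mean <- prop$diagnostics$intra_mean
  # stage 3: density-cluster membership
  models <- tryCatch(.label_models(index, prop$label, params),
                     error = function(e) NULL)
  if (is.null(models)) {
    tr$cluster_stage <- "error"
    return(review(tr, "cluster_membership"))
  }
  cid <- assign_cluster(models$clusters, embedding)
  tr$cluster_id <- cid
  if (cid == 0L) {
    tr$cluster_stage <- "noise"
    return(review(tr, "cluster_membership"))
  }
  tr$cluster_stage <- "member"
  # stage 4: one-class certainty (strictly-below threshold reviews)
  tr$certainty <- certainty(models$oneclass[[cid]], embedding)
  if (tr$certainty < params$certainty_threshold) {
    return(review(tr, "certainty"))
  }
  tr$route <- "auto_accept"
  tr$proposed_label <- prop$label
  tr
}

#' Triage a batch of detected objects
#'
#' Applies [triage_object()] to every object and splits the decisions into
#' the auto-accepted set and the expert review queue. Every input object
#' lands in exactly one of the two.
#'
#' @param index A `reference_index`.
#' @param detections data.frame with columns `object_id` and `confidence`
#'   (any further columns are ignored).
#' @param embeddings Numeric matrix with one unit-norm row per detection
#'   (same order), or an `embedding_set` matched by `object_id`.
#' @param params A [triage_params()] object.
#' @return List with `decisions` (full per-object table), `auto_accepted`,
#'   `review_queue` (row subsets) and `batch_stats`: `n`, `auto_fraction`
#'   (0 with `empty = TRUE` for an empty batch), `auto_by_label`,
#'   `stage_failures`.
#' @export
process_batch <- function(index, detections, embeddings,
                          params = triage_params()) {
  if (inherits(embeddings, "embedding_set")) {
    pos <- match(as.character(detections$object_id),
                 embeddings$meta$object_id)
    if (anyNA(pos)) {
      stop("detections reference object_ids absent from the embeddings",
           call. = FALSE)
    }
    embeddings <- embeddings$vectors[pos, , drop = FALSE]
  }
  embeddings <- as.matrix(embeddings)
  n <- nrow(detections)
  if (n != nrow(embeddings)) {
    stop("detections and embeddings disagree in length", call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- triage_object(index, detections[i, , drop = FALSE],
                               embeddings[i, ], params)
  }
  decisions <- do.call(rbind, rows)
  if (is.null(decisions)) decisions <- .empty_trace(character(0))
  auto <- decisions[!is.na(decisions$route) &
                      decisions$route == "auto_accept", , drop = FALSE]
  review <- decisions[!is.na(decisions$route) &
                        decisions$route == "review", , drop = FALSE]
  stage_levels <- c("detection_gate", "knn_proposal", "cluster_membership",
                    "certainty")
  stats <- list(
    n = n,
    empty = n == 0L,
    auto_fraction = if (n == 0L) 0 else nrow(auto) / n,
    auto_by_label = if (nrow(auto)) table(auto$proposed_label) else
      table(character(0)),
    stage_failures = table(factor(review$fail_stage, levels = stage_levels))
  )
  list(decisions = decisions, auto_accepted = auto, review_queue = review,
       batch_stats = stats)
}
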