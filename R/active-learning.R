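# Simulated human-in-the-loop rounds: triage a batch, send the review
# queue to a (simulated) expert, grow the verified reference index with
# the expert's labels only, refresh the metric-space models and track
# retrieval quality across rounds. "Retraining" here means refreshing the
# index and refitting the per-label cluster / one-class models -- the
# metric-space consumers of the cascade -- not neural retraining.

#' Simulated expert verification of a review queue
#'
#' Each queued object receives its ground-truth label with probability
#' `1 - error_rate`, otherwise a uniformly random wrong label from
#' `label_pool`. All returned records are `verified = TRUE`, ready for
#' [add_verified()]. Deterministic given `seed`.
#'
#' @param queue An `embedding_set` of review-routed objects.
#' @param truth Ground-truth labels: named character vector (names =
#'   object ids) or data.frame with `object_id` and `label`. Every queued
#'   object must be covered.
#' @param error_rate Expert error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param label_pool Labels an erring expert may pick from (default: the
#'   distinct truth labels).
#' @return An `embedding_set` with labels assigned and `verified = TRUE`.
#' @export
simulate_oracle <- function(queue, truth, error_rate = 0, seed = 1L,
                            label_pool = NULL) {
  stopifnot(inherits(queue, "embedding_set"))
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$label),
                             as.character(truth$object_id))
  }
  ids <- queue$meta$object_id
  labs <- unname(truth[ids])
  if (anyNA(labs)) {
    stop("missing ground-truth label for queued object(s): ",
         paste(utils::head(ids[is.na(labs)], 3L), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(label_pool)) label_pool <- sort(unique(unname(truth)))
  set.seed(seed)
  err <- stats::runif(length(labs)) < error_rate
  for (i in which(err)) {
    wrong <- setdiff(label_pool, labs[i])
    if (length(wrong) > 0L) labs[i] <- wrong[sample.int(length(wrong), 1L)]
  }
  out <- queue
  out$meta$label <- labs
  out$meta$verified <- TRUE
  out
}

#' Mean average precision at 5 retrieved neighbours
#'
#' For each evaluation query, the 5 nearest index records are retrieved;
#' a rank is relevant when its label matches the query's. Average precision
#' of one query is the mean of precision-at-rank over the relevant ranks
#' (0 when no retrieved record is relevant); mAP@5 is the mean over
#' queries.
#'
#' @param index A non-empty `reference_index`.
#' @param eval_set A labeled `embedding_set`, disjoint from the index by
#'   object id.
#' @return mAP@5 in `[0, 1]`.
#' @export
map_at_5 <- function(index, eval_set) {
  stopifnot(inherits(index, "reference_index"),
            inherits(eval_set, "embedding_set"))
  if (index_size(index) == 0L) stop("empty index", call. = FALSE)
  if (n_records(eval_set) == 0L) stop("empty evaluation set", call. = FALSE)
  if (any(eval_set$meta$object_id %in% index$object_ids)) {
    stop("evaluation set overlaps the index by object_id", call. = FALSE)
  }
  if (anyNA(eval_set$meta$label)) {
    stop("evaluation set must be fully labeled", call. = FALSE)
  }
  ap <- vapply(seq_len(n_records(eval_set)), function(i) {
    nn <- knn_search(index, eval_set$vectors[i, ], 5L)
    rel <- nn$label == eval_set$meta$label[i]
    if (!any(rel)) return(0)
    prec <- cumsum(rel) / seq_along(rel)
    mean(prec[rel])
  }, numeric(1))
  mean(ap)
}

#' Apply one round of expert verification to the index
#'
#' Appends the oracle-verified records to the reference index (which
#' invalidates the per-label model caches for every touched label) and
#' computes round metrics, including retrieval quality on a held-out
#' evaluation slice that never enters the index.
#'
#' @param index A `reference_index`.
#' @param oracle_out Verified `embedding_set` from [simulate_oracle()].
#' @param batch_result Output of [process_batch()] for this round (or
#'   `NULL` when the round had no usable index yet).
#' @param truth Named character vector of ground-truth labels.
#' @param eval_set Optional labeled `embedding_set` held out for mAP@5.
#' @param round_id Integer round number.
#' @return List with `index` (updated) and `metrics` (one-row data.frame:
#'   `round`, `auto_fraction`, `auto_label_accuracy`, `map_at_5`,
#'   `queue_size`, `index_size`).
#' @export
update_round <- function(index, oracle_out, batch_result = NULL,
                         truth = NULL, eval_set = NULL, round_id = 1L) {
  index <- add_verified(index, oracle_out)
  auto_fraction <- 0
  auto_acc <- NA_real_
  queue_size <- n_records(oracle_out)
  if (!is.null(batch_result)) {
    auto_fraction <- batch_result$batch_stats$auto_fraction
    auto <- batch_result$auto_accepted
    if (nrow(auto) > 0L && !is.null(truth)) {
      auto_acc <- mean(auto$proposed_label == unname(truth[auto$object_id]))
    }
  }
  map5 <- if (!is.null(eval_set) && n_records(eval_set) > 0L &&
              index_size(index) > 0L) {
    map_at_5(index, eval_set)
  } else {
    NA_real_
  }
  metrics <- data.frame(round = as.integer(round_id),
                        auto_fraction = auto_fraction,
                        auto_label_accuracy = auto_acc,
                        map_at_5 = map5,
                        queue_size = queue_size,
                        index_size = index_size(index))
  list(index = index, metrics = metrics)
}

#' Run the simulated human-in-the-loop active-learning loop
#'
#' Per round: a seeded 20% evaluation slice of the batch is held out
#' (never indexed, used only for mAP@5); the remaining objects are triaged
#' against the current index; the review queue is verified by the
#' simulated expert; the verified records -- and only those -- grow the
#' index. The loop starts from an empty index by default, so round 1 sends
#' everything to review, and automation builds up as verified data
#' accumulates.
#'
#' @param stream List of batches from [generate_drift_stream()] (each with
#'   `records`, `truth`, `confidence`).
#' @param params A [triage_params()] object.
#' @param n_rounds Number of rounds to run (default: all batches).
#' @param error_rate Simulated expert error probability.
#' @param seed Integer seed driving the evaluation split and the oracle.
#' @param eval_fraction Held-out fraction per batch (default 0.2).
#' @param index Optional starting `reference_index`.
#' @return List with `metrics` (one row per round), `index` (final) and
#'   `rounds` (per-round decision tables joined with truth).
#' @export
run_active_loop <- function(stream, params = triage_params(),
                            n_rounds = length(stream), error_rate = 0,
                            seed = 1L, eval_fraction = 0.2, index = NULL) {
  if (n_rounds < 1L) stop("n_rounds must be >= 1", call. = FALSE)
  if (n_rounds > length(stream)) {
    stop("n_rounds exceeds the number of stream batches", call. = FALSE)
  }
  if (is.null(index)) {
    index <- reference_index(dim = ncol(stream[[1L]]$records$vectors))
  }
  metrics <- vector("list", n_rounds)
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    b <- stream[[r]]
    nb <- n_records(b$records)
    if (nb == 0L) stop("empty stream batch at round ", r, call. = FALSE)
    truth <- stats::setNames(b$truth$label, b$truth$object_id)
    set.seed(seed + 7919L * r)
    n_eval <- round(eval_fraction * nb)
    eval_idx <- if (n_eval > 0L) sample.int(nb, n_eval) else integer(0)
    proc_idx <- setdiff(seq_len(nb), eval_idx)
    proc <- subset_records(b$records, proc_idx)
    detections <- data.frame(object_id = proc$meta$object_id,
                             confidence = b$confidence[proc_idx],
                             stringsAsFactors = FALSE)
    batch_result <- process_batch(index, detections, proc$vectors, params)
    queue_ids <- batch_result$review_queue$object_id
    queue <- subset_records(proc, match(queue_ids, proc$meta$object_id))
    oracle_out <- simulate_oracle(queue, truth, error_rate = error_rate,
                                  seed = seed + 13L * r)
    eval_set <- subset_records(b$records, eval_idx)
    eval_set$meta$label <- unname(truth[eval_set$meta$object_id])
    up <- update_round(index, oracle_out, batch_result = batch_result,
                       truth = truth, eval_set = eval_set, round_id = r)
    index <- up$index
    metrics[[r]] <- up$metrics
    dec <- batch_result$decisions
    dec$truth_label <- unname(truth[dec$object_id])
    rounds[[r]] <- dec
  }
  list(metrics = do.call(rbind, metrics), index = index, rounds = rounds)
}
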