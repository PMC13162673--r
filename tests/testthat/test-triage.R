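test_that("detection gate: strictly below threshold fails, boundary passes", {
  p <- triage_params(detection_threshold = 0.8)
  expect_false(detection_gate(0.79, p))
  expect_true(detection_gate(0.80, p))
  expect_true(detection_gate(1.0, p))
})

test_that("triage_params validates its ranges", {
  expect_error(triage_params(min_same_label = 11, k_neighbors = 10),
               "min_same_label")
  expect_error(triage_params(detection_threshold = 1.2), "\\[0, 1\\]")
  expect_error(triage_params(nu = 0), "nu")
})

test_that("KNN proposal requires enough close same-label neighbours", {
  d <- 16
  set.seed(31)
  # 6 tight label-A vectors + 3 distant label-B
  a <- tight_cluster(6, axis_vec(1, d), sd = 0.01)
  b <- tight_cluster(3, axis_vec(2, d), sd = 0.01)
  idx <- make_index(list(A = a, B = b))
  p <- triage_params()
  # query at A's centroid: both heuristic conditions hold by construction
  q <- l2_normalize(colMeans(a))
  mean_qd <- mean(apply(a, 1, function(v) 1 - sum(v * q)))
  expect_lt(mean_qd, oracle_mean_intra(a)) # the condition being tested
  prop <- propose_label_knn(idx, q, p)
  expect_equal(prop$label, "A")

  # only 4 label-A members: count condition unmet
  idx4 <- make_index(list(A = a[1:4, ], B = b))
  expect_null(propose_label_knn(idx4, q, p)$label)

  # orthogonal query: distance condition unmet
  q_orth <- axis_vec(3, d)
  expect_null(propose_label_knn(idx, q_orth, p)$label)
})

test_that("labels with a single member cannot qualify", {
  d <- 16
  set.seed(32)
  one <- matrix(axis_vec(1, d), 1)
  idx <- make_index(list(S = one))
  p <- triage_params(k_neighbors = 1, min_same_label = 1)
  prop <- propose_label_knn(idx, axis_vec(1, d), p)
  expect_null(prop$label)
  expect_false(any(prop$diagnostics$candidates$qualifies))
})

test_that("one-class boundary: in-sample acceptance, minimum size", {
  set.seed(33)
  x <- tight_cluster(50, axis_vec(1, 32), sd = 0.05)
  p <- triage_params()
  m <- fit_one_class(x, p)
  # training vectors re-scored against the fitted boundary: at least 90%
  # must clear the routing certainty, consistent with the nu = 0.05 budget
  cert <- vapply(seq_len(nrow(x)), function(i) certainty(m, x[i, ]),
                 numeric(1))
  expect_gte(mean(cert >= p$certainty_threshold), 0.9)
  expect_s3_class(fit_one_class(x[1:5, ], p), "one_class_model")
  expect_error(fit_one_class(x[1:4, ], p), "min_cluster_size")
  # degenerate all-identical input still fits, flagged
  same <- matrix(rep(axis_vec(1, 8), 6), nrow = 6, byrow = TRUE)
  md <- fit_one_class(same, p)
  expect_true(md$degenerate)
})

test_that("certainty: medoid high, far outlier low, codomain respected", {
  set.seed(34)
  x <- tight_cluster(60, axis_vec(1, 32), sd = 0.05)
  m <- fit_one_class(x, triage_params())
  dmat <- 1 - tcrossprod(x)
  medoid <- x[which.min(rowSums(dmat)), ]
  expect_gte(certainty(m, medoid), 0.95)
  expect_lt(certainty(m, axis_vec(2, 32)), 0.5)
  qs <- runif_sphere(30, 32)
  cs <- vapply(seq_len(30), function(i) certainty(m, qs[i, ]), numeric(1))
  expect_true(all(cs >= 0 & cs <= 1))
})

test_that("raw certainty mode scales scores into [0, 1]", {
  set.seed(35)
  x <- tight_cluster(40, axis_vec(1, 32), sd = 0.05)
  m <- fit_one_class(x, triage_params(certainty_mode = "raw"))
  expect_lt(certainty(m, axis_vec(2, 32)), 1e-9)
  expect_true(certainty(m, x[1, ]) >= 0 && certainty(m, x[1, ]) <= 1)
})

test_that("cascade runs stages in order and stops at first failure", {
  fix <- two_class_fixture(n_per = 30)
  p <- triage_params()
  # gate failure: later stages skipped
  dec <- triage_object(fix$index,
                       list(object_id = "q1", confidence = 0.5),
                       fix$center_a, p)
  expect_equal(dec$route, "review")
  expect_equal(dec$fail_stage, "detection_gate")
  expect_true(is.na(dec$knn_label))
  expect_equal(dec$cluster_stage, "skipped")

  # centroid of a well-populated tight class: all stages pass
  dec <- triage_object(fix$index,
                       list(object_id = "q2", confidence = 0.95),
                       fix$center_a, p)
  expect_equal(dec$route, "auto_accept")
  expect_equal(dec$proposed_label, "A")
  expect_gte(dec$certainty, p$certainty_threshold)

  # far query: review with no KNN proposal
  far <- axis_vec(5, fix$d)
  dec <- triage_object(fix$index,
                       list(object_id = "q3", confidence = 0.95), far, p)
  expect_equal(dec$route, "review")
  expect_equal(dec$fail_stage, "knn_proposal")
  expect_equal(dec$cluster_stage, "skipped")
})

test_that("every batch object is routed exactly once", {
  fix <- two_class_fixture(n_per = 25)
  set.seed(36)
  qs <- rbind(tight_cluster(10, fix$center_a, sd = 0.02),
              runif_sphere(5, fix$d))
  det <- data.frame(object_id = sprintf("q%02d", 1:15),
                    confidence = runif(15, 0.5, 1))
  res <- process_batch(fix$index, det, qs, triage_params())
  expect_equal(nrow(res$auto_accepted) + nrow(res$review_queue), 15L)
  expect_setequal(c(res$auto_accepted$object_id,
                    res$review_queue$object_id), det$object_id)
})

test_that("empty and all-fail batches report auto fraction 0", {
  fix <- two_class_fixture(n_per = 25)
  p <- triage_params()
  empty <- process_batch(fix$index,
                         data.frame(object_id = character(0),
                                    confidence = numeric(0)),
                         matrix(numeric(0), 0, fix$d), p)
  expect_true(empty$batch_stats$empty)
  expect_equal(empty$batch_stats$auto_fraction, 0)

  set.seed(37)
  qs <- tight_cluster(10, fix$center_a, sd = 0.02)
  det <- data.frame(object_id = sprintf("q%02d", 1:10), confidence = 0.1)
  res <- process_batch(fix$index, det, qs, p)
  expect_equal(res$batch_stats$auto_fraction, 0)
  expect_equal(unname(res$batch_stats$stage_failures["detection_gate"]), 10L)
})

test_that("raising the certainty threshold never converts review to auto", {
  set.seed(38)
  for (rep in 1:4) {
    fix <- two_class_fixture(n_per = 20 + 5 * rep, sd = 0.03,
                             seed = 100 + rep)
    qs <- rbind(tight_cluster(12, fix$center_a, sd = 0.08),
                runif_sphere(4, fix$d))
    det <- data.frame(object_id = sprintf("q%02d", 1:16),
                      confidence = runif(16, 0.7, 1))
    thr <- sort(runif(3, 0.5, 1))
    routes <- lapply(thr, function(ct) {
      p <- triage_params(certainty_threshold = ct)
      res <- process_batch(fix$index, det, qs, p)
      res$decisions$route
    })
    for (i in 1:2) {
      moved_up <- routes[[i]] == "review" & routes[[i + 1]] == "auto_accept"
      expect_false(any(moved_up))
    }
  }
})

test_that("model caches are reused within an index and refreshed on update", {
  fix <- two_class_fixture(n_per = 25)
  p <- triage_params()
  q <- fix$center_a
  dec1 <- triage_object(fix$index, list(object_id = "q", confidence = 1), q, p)
  expect_gt(length(ls(fix$index$model_cache)), 0L)
  # adding members to label A must invalidate A's cached models
  new <- embedding_records("extraA", matrix(tight_cluster(1, fix$center_a,
                                                          sd = 0.02), 1),
                           label = "A", verified = TRUE)
  idx2 <- add_verified(fix$index, new)
  keys <- ls(idx2$model_cache)
  expect_false(any(grepl("^A\\|", keys)))
})
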