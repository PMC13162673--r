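test_that("simulated expert: perfect oracle copies truth, errors are binomial", {
  set.seed(61)
  q <- embedding_records(sprintf("o%04d", 1:50), runif_sphere(50, 16),
                         label = NA_character_, verified = FALSE)
  truth <- setNames(sample(c("a", "b", "c"), 50, replace = TRUE),
                    q$meta$object_id)
  out <- simulate_oracle(q, truth, error_rate = 0, seed = 1)
  expect_true(all(out$meta$verified))
  expect_equal(out$meta$label, unname(truth[out$meta$object_id]))

  big <- embedding_records(sprintf("b%05d", 1:1000), runif_sphere(1000, 8),
                           verified = FALSE)
  truth_big <- setNames(rep(c("a", "b"), 500), big$meta$object_id)
  out <- simulate_oracle(big, truth_big, error_rate = 0.1, seed = 2)
  wrong <- sum(out$meta$label != unname(truth_big[out$meta$object_id]))
  expect_lt(abs(wrong - 100), 3 * sqrt(1000 * 0.1 * 0.9))

  expect_error(simulate_oracle(q, truth[-1], error_rate = 0),
               "missing ground-truth")
  expect_error(simulate_oracle(q, truth, error_rate = 1), "error_rate")
})

test_that("mAP@5 matches hand cases and the brute-force oracle", {
  d <- 8
  # all five nearest share the query label -> 1; none -> 0
  idx <- make_index(list(A = tight_cluster(6, axis_vec(1, d), 0.01, seed = 62),
                         B = tight_cluster(6, axis_vec(2, d), 0.01, seed = 63)))
  qa <- embedding_records("qa", matrix(axis_vec(1, d), 1), label = "A")
  qb <- embedding_records("qb", matrix(axis_vec(1, d), 1), label = "B")
  expect_equal(map_at_5(idx, qa), 1)
  expect_equal(map_at_5(idx, qb), 0)

  # relevant at ranks 1 and 3 only: AP = (1/1 + 2/3)/2 = 5/6
  vs <- rbind(axis_vec(1, d),                       # rank 1, label A
              l2_normalize(c(0.9, 0.44, rep(0, 6))), # rank 2, label B
              l2_normalize(c(0.8, 0.6, rep(0, 6))),  # rank 3, label A
              l2_normalize(c(0.7, 0.71, rep(0, 6))), # rank 4, label B
              l2_normalize(c(0.6, 0.8, rep(0, 6))))  # rank 5, label B
  idx5 <- reference_index(
    embedding_records(sprintf("r%d", 1:5), vs,
                      label = c("A", "B", "A", "B", "B"), verified = TRUE),
    dim = d)
  q <- embedding_records("q", matrix(axis_vec(1, d), 1), label = "A")
  expect_equal(map_at_5(idx5, q), 5 / 6, tolerance = 1e-12)

  # random instances against the oracle
  set.seed(64)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    vecs <- runif_sphere(n, d)
    labs <- sample(c("x", "y"), n, replace = TRUE)
    idx_r <- reference_index(
      embedding_records(sprintf("i%03d", 1:n), vecs, label = labs,
                        verified = TRUE), dim = d)
    m <- 8
    ev <- runif_sphere(m, d)
    evl <- sample(c("x", "y"), m, replace = TRUE)
    eval_set <- embedding_records(sprintf("e%02d", 1:m), ev, label = evl)
    want <- mean(vapply(seq_len(m), function(i) {
      oracle_ap5(vecs, labs, ev[i, ], evl[i])
    }, numeric(1)))
    expect_equal(map_at_5(idx_r, eval_set), want, tolerance = 1e-9)
  }

  expect_error(map_at_5(idx, embedding_records(idx$object_ids[1],
                                               matrix(axis_vec(1, d), 1),
                                               label = "A")),
               "overlaps")
})

test_that("update_round grows the index by the verified records only", {
  idx <- two_class_fixture(n_per = 10)$index
  n0 <- length(idx$object_ids)
  # empty queue: index unchanged, metrics still emitted
  empty <- embedding_records(character(0), matrix(numeric(0), 0, 16))
  up <- update_round(idx, empty, round_id = 3L)
  expect_equal(up$metrics$index_size, n0)
  expect_equal(up$metrics$round, 3L)

  ver <- embedding_records(sprintf("n%02d", 1:7), runif_sphere(7, 16, seed = 65),
                           label = "C", verified = TRUE)
  up <- update_round(idx, ver)
  expect_equal(up$metrics$index_size, n0 + 7L)
  expect_true("C" %in% up$index$labels)
})

test_that("verification of a novel class turns its review route into auto", {
  d <- 32
  set.seed(66)
  known <- make_index(list(A = tight_cluster(30, axis_vec(1, d), 0.02),
                           B = tight_cluster(30, axis_vec(2, d), 0.02)))
  novel_center <- axis_vec(3, d)
  novel <- tight_cluster(40, novel_center, 0.02)
  p <- triage_params()
  det <- data.frame(object_id = sprintf("nv%02d", 1:40), confidence = 0.95)
  before <- process_batch(known, det, novel, p)
  expect_equal(nrow(before$auto_accepted), 0L)
  # expert verifies the reviewed novel objects; index refreshes
  queue <- embedding_records(before$review_queue$object_id,
                             novel, verified = FALSE)
  truth <- setNames(rep("C", 40), det$object_id)
  oracle_out <- simulate_oracle(queue, truth, seed = 3)
  idx2 <- add_verified(known, oracle_out)
  fresh <- tight_cluster(20, novel_center, 0.02)
  det2 <- data.frame(object_id = sprintf("fr%02d", 1:20), confidence = 0.95)
  after <- process_batch(idx2, det2, fresh, p)
  expect_gte(nrow(after$auto_accepted) / 20, 0.6)
  expect_true(all(after$auto_accepted$proposed_label == "C"))
})

test_that("active loop: stationary stream automates more over rounds", {
  cfg <- synth_config(n_classes = 3, kappa = 800, seed = 67)
  sched <- matrix(rep(c(0.6, 0.25, 0.15), 4), nrow = 4, byrow = TRUE,
                  dimnames = list(NULL, c("sp01", "sp02", "sp03")))
  stream <- generate_drift_stream(cfg, sched, batch_size = 120)
  res <- run_active_loop(stream, triage_params(), seed = 5)
  m <- res$metrics
  expect_equal(nrow(m), 4L)
  expect_equal(m$auto_fraction[1], 0) # empty starting index
  expect_gte(m$auto_fraction[4], m$auto_fraction[1])
  expect_true(all(diff(m$index_size) >= 0))
  # verified-only rule: every index id entered through the oracle queue
  expect_true(all(grepl("^r[0-9]", res$index$object_ids)))

  one <- run_active_loop(stream, triage_params(), n_rounds = 1, seed = 5)
  expect_equal(nrow(one$metrics), 1L)
})
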