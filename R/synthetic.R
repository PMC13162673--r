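# Seeded generators for everything the pipeline consumes: clustered
# unit-sphere embeddings (emulating metric-learned image embeddings), novel
# class injections, drifting sample streams, detector confidences and paired
# human/machine abundance tables with category-specific machine bias.

#' Configuration of the synthetic embedding generator
#'
#' Defaults emulate the embedding geometry of a trained metric-learning
#' classifier on a monitoring sample stream: 128-dimensional unit vectors;
#' one dominant class holding ~79% of objects (the typical share of the
#' dominant copepod in the monitoring narrative) with the remainder split
#' evenly; within-class concentration `kappa = 800`, giving a mean
#' within-class pairwise cosine distance of ~0.14 (same-class cosine
#' similarity ~0.86); class centers at pairwise cosine distance >= 0.5.
#' Detector confidences follow Beta(18, 2): mean 0.90 with ~8% of objects
#' under the 0.8 gate.
#'
#' @param dim Embedding dimension.
#' @param n_classes Number of known classes.
#' @param n_objects Total objects drawn by [generate_embeddings()].
#' @param mixture Class mixture weights (recycled/normalized); default: one
#'   dominant class at 0.79, the rest equal.
#' @param kappa Within-class concentration (> 0); larger is tighter. The
#'   tangent-space spread is `1/sqrt(kappa)` per coordinate, matching the
#'   von Mises-Fisher concentration in the large-`kappa` regime.
#' @param min_separation Minimum pairwise cosine distance between class
#'   centers, in (0, 2).
#' @param novel_fraction Fraction of stream objects drawn from injected
#'   novel classes, in `[0, 1)`.
#' @param conf_shape1,conf_shape2 Beta parameters of detector confidences.
#' @param seed Integer seed; every generator below is deterministic in it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(dim = 128L, n_classes = 5L, n_objects = 500L,
                         mixture = NULL, kappa = 800, min_separation = 0.5,
                         novel_fraction = 0, conf_shape1 = 18,
                         conf_shape2 = 2, seed = 1L) {
  if (is.null(mixture)) {
    mixture <- if (n_classes == 1L) 1 else
      c(0.79, rep(0.21 / (n_classes - 1L), n_classes - 1L))
  }
  mixture <- rep_len(mixture, n_classes)
  mixture <- mixture / sum(mixture)
  cfg <- list(dim = as.integer(dim), n_classes = as.integer(n_classes),
              n_objects = as.integer(n_objects), mixture = mixture,
              kappa = kappa, min_separation = min_separation,
              novel_fraction = novel_fraction, conf_shape1 = conf_shape1,
              conf_shape2 = conf_shape2, seed = as.integer(seed))
  if (cfg$kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (cfg$min_separation <= 0 || cfg$min_separation >= 2) {
    stop("min_separation must lie in (0, 2)", call. = FALSE)
  }
  if (cfg$novel_fraction < 0 || cfg$novel_fraction >= 1) {
    stop("novel_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# n uniform unit vectors in d dimensions.
.sample_sphere <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), nrow = n)
  m / sqrt(rowSums(m^2))
}

# Class centers by rejection sampling under the pairwise separation
# constraint. Errors if the constraint cannot be met.
.sample_centers <- function(n_classes, dim, min_sep, existing = NULL,
                            max_tries = 1000L) {
  centers <- existing
  for (i in seq_len(n_classes)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- .sample_sphere(1L, dim)[1L, ]
      if (is.null(centers) ||
          all(1 - drop(centers %*% cand) >= min_sep)) {
        centers <- rbind(centers, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n_classes, " class centers at pairwise ",
           "cosine separation >= ", min_sep,
           "; use fewer classes or a lower separation", call. = FALSE)
    }
  }
  rownames(centers) <- NULL
  centers
}

# Directional sampling around a center: Gaussian perturbation in the
# tangent space (per-coordinate sd 1/sqrt(kappa)) followed by
# renormalization -- the standard large-kappa surrogate for von
# Mises-Fisher sampling.
.sample_around <- function(n, center, kappa) {
  d <- length(center)
  z <- matrix(stats::rnorm(n * d, sd = 1 / sqrt(kappa)), nrow = n)
  z <- z - outer(drop(z %*% center), center) # project onto tangent space
  x <- sweep(z, 2L, center, "+")
  x / sqrt(rowSums(x^2))
}

#' Generate clustered unit-sphere embeddings with ground truth
#'
#' Class centers are sampled uniformly on the sphere subject to the
#' pairwise separation constraint (rejection sampling), members by
#' tangent-space Gaussian perturbation with concentration `kappa`. Class
#' sizes follow a multinomial draw from the configured mixture. Detector
#' confidences are attached per object. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param id_prefix Prefix of generated object ids.
#' @return List with `records` (`embedding_set`, labels = ground truth,
#'   unverified), `truth` (data.frame `object_id`, `label`, `novel`),
#'   `confidence` (numeric), `centers` (matrix with class rownames) and
#'   `classes` (character).
#' @export
generate_embeddings <- function(config = synth_config(),
                                id_prefix = "obj") {
  set.seed(config$seed)
  classes <- sprintf("sp%02d", seq_len(config$n_classes))
  centers <- .sample_centers(config$n_classes, config$dim,
                             config$min_separation)
  rownames(centers) <- classes
  counts <- drop(stats::rmultinom(1L, config$n_objects, config$mixture))
  labels <- rep(classes, counts)
  vectors <- matrix(0, nrow = config$n_objects, ncol = config$dim)
  row <- 1L
  for (k in seq_len(config$n_classes)) {
    if (counts[k] == 0L) next
    vectors[row:(row + counts[k] - 1L), ] <-
      .sample_around(counts[k], centers[k, ], config$kappa)
    row <- row + counts[k]
  }
  ids <- sprintf("%s%05d", id_prefix, seq_len(config$n_objects))
  confidence <- stats::rbeta(config$n_objects, config$conf_shape1,
                             config$conf_shape2)
  records <- embedding_records(ids, vectors, sample_id = "synth",
                               label = labels, verified = FALSE,
                               t = seq_along(ids) - 1L)
  list(records = records,
       truth = data.frame(object_id = ids, label = labels, novel = FALSE,
                          stringsAsFactors = FALSE),
       confidence = confidence, centers = centers, classes = classes)
}

#' Inject a novel class into generated embeddings
#'
#' Adds a cluster whose center respects the separation constraint against
#' every existing center; its members are flagged `novel = TRUE` in the
#' ground truth. With `n_novel = 0` the input is returned unchanged.
#'
#' @param gen Output of [generate_embeddings()].
#' @param config The [synth_config()] used to generate `gen`.
#' @param n_novel Number of novel objects (default: from
#'   `config$novel_fraction` relative to the existing object count).
#' @param label Ground-truth name of the novel class.
#' @return Same shape as [generate_embeddings()], records appended.
#' @export
inject_novel_class <- function(gen, config, n_novel = NULL,
                               label = "novel01") {
  if (is.null(n_novel)) {
    n_novel <- round(config$novel_fraction /
                       max(1 - config$novel_fraction, 1e-12) *
                       n_records(gen$records))
  }
  if (n_novel == 0L) return(gen)
  set.seed(config$seed + 104729L)
  center <- .sample_centers(1L, config$dim, config$min_separation,
                            existing = gen$centers)
  center <- center[nrow(center), , drop = FALSE]
  rownames(center) <- label
  vecs <- .sample_around(n_novel, center[1L, ], config$kappa)
  ids <- sprintf("nov%05d", seq_len(n_novel))
  conf <- stats::rbeta(n_novel, config$conf_shape1, config$conf_shape2)
  recs <- embedding_records(ids, vecs, sample_id = "synth", label = label,
                            verified = FALSE,
                            t = n_records(gen$records) + seq_len(n_novel) - 1L)
  gen$records <- structure(
    list(meta = rbind(gen$records$meta, recs$meta),
         vectors = rbind(gen$records$vectors, recs$vectors)),
    class = "embedding_set")
  gen$truth <- rbind(gen$truth,
                     data.frame(object_id = ids, label = label, novel = TRUE,
                                stringsAsFactors = FALSE))
  gen$confidence <- c(gen$confidence, conf)
  gen$centers <- rbind(gen$centers, center)
  gen
}

#' Generate a drifting stream of sample batches
#'
#' Draws one batch per round from round-specific class-mixture weights, so
#' that later rounds can introduce classes absent from earlier rounds
#' (seasonal drift). All classes named by the schedule share one center
#' layout sampled under the separation constraint.
#'
#' @param config A [synth_config()] (its `mixture` is ignored here).
#' @param schedule Numeric matrix, rounds x classes, with column names;
#'   each row must sum to 1 (weights of that round's mixture). A zero
#'   column entry means the class is absent from that round.
#' @param batch_size Objects per round (recycled to the number of rounds).
#' @return List of batches; each batch has `records` (unverified
#'   `embedding_set`, labels = truth), `truth`, `confidence`, `round`.
#'   The center matrix is attached as attribute `centers`.
#' @export
generate_drift_stream <- function(config, schedule, batch_size = 200L) {
  schedule <- as.matrix(schedule)
  if (is.null(colnames(schedule))) {
    stop("schedule needs class names as column names", call. = FALSE)
  }
  if (any(abs(rowSums(schedule) - 1) > 1e-9)) {
    stop("each schedule row must sum to 1", call. = FALSE)
  }
  if (any(schedule < 0)) stop("negative mixture weight", call. = FALSE)
  classes <- colnames(schedule)
  n_rounds <- nrow(schedule)
  batch_size <- rep_len(as.integer(batch_size), n_rounds)
  set.seed(config$seed)
  centers <- .sample_centers(length(classes), config$dim,
                             config$min_separation)
  rownames(centers) <- classes
  batches <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(config$seed + 7001L * r)
    counts <- drop(stats::rmultinom(1L, batch_size[r], schedule[r, ]))
    labels <- rep(classes, counts)
    vectors <- matrix(0, nrow = batch_size[r], ncol = config$dim)
    row <- 1L
    for (k in seq_along(classes)) {
      if (counts[k] == 0L) next
      vectors[row:(row + counts[k] - 1L), ] <-
        .sample_around(counts[k], centers[k, ], config$kappa)
      row <- row + counts[k]
    }
    ids <- sprintf("r%02d-%05d", r, seq_len(batch_size[r]))
    conf <- stats::rbeta(batch_size[r], config$conf_shape1,
                         config$conf_shape2)
    batches[[r]] <- list(
      records = embedding_records(ids, vectors,
                                  sample_id = sprintf("round%02d", r),
                                  label = labels, verified = FALSE,
                                  t = seq_along(ids) - 1L),
      truth = data.frame(object_id = ids, label = labels,
                         stringsAsFactors = FALSE),
      confidence = conf, round = r)
  }
  attr(batches, "centers") <- centers
  batches
}

#' Generate a paired human/machine abundance table
#'
#' Emulates the two observers of a monitoring sample: the human count is
#' the true count with (optional) Poisson counting noise; the machine count
#' is the true count scaled by a per-category multiplicative bias (< 1 for
#' overlap-prone categories the detector undercounts, > 1 for the dominant
#' category it overcounts) with the same noise law. Both are converted to
#' thousand specimens per square metre via [counts_to_areal()]. With all
#' biases 1 the two observers are exchangeable, which is the null
#' configuration used to calibrate the permutation test.
#'
#' @param truth_counts Named non-negative numeric vector of true counts per
#'   category.
#' @param bias Multiplicative machine bias: scalar or vector recycled to the
#'   categories; must be > 0.
#' @param noise `"poisson"` for independent Poisson counting noise on both
#'   observers, `"none"` for exact counts.
#' @param seed Integer seed.
#' @param counted_fraction Fraction of the sample actually counted, (0, 1].
#' @param net_mouth_diameter_m Net inlet diameter in metres (default 0.375).
#' @return A [paired_abundance()] table in thousand specimens per m^2.
#' @export
generate_paired_counts <- function(truth_counts, bias = 1,
                                   noise = c("poisson", "none"), seed = 1L,
                                   counted_fraction = 1,
                                   net_mouth_diameter_m = 0.375) {
  noise <- match.arg(noise)
  if (any(truth_counts < 0)) stop("negative truth count", call. = FALSE)
  nc <- length(truth_counts)
  if (is.null(names(truth_counts))) {
    names(truth_counts) <- sprintf("cat%02d", seq_len(nc))
  }
  bias <- rep_len(bias, nc)
  if (any(bias <= 0)) stop("bias must be > 0", call. = FALSE)
  set.seed(seed)
  if (noise == "poisson") {
    h_raw <- stats::rpois(nc, truth_counts)
    m_raw <- stats::rpois(nc, truth_counts * bias)
  } else {
    h_raw <- truth_counts
    m_raw <- truth_counts * bias
  }
  paired_abundance(
    category = names(truth_counts),
    human = counts_to_areal(h_raw, counted_fraction, net_mouth_diameter_m),
    machine = counts_to_areal(m_raw, counted_fraction, net_mouth_diameter_m))
}

#' Default monitoring-like truth counts and machine biases
#'
#' A composition echoing a summer monitoring sample: one dominant copepod
#' category plus its developmental stages, a couple of cladoceran stages
#' and several rotifer categories. The default bias vector undercounts the
#' rotifer categories (they overlap in images) and overcounts the dominant
#' adult copepod.
#'
#' @return List with `truth` (named counts) and `bias` (named multipliers).
#' @export
default_count_scenario <- function() {
  truth <- c(cop_adult = 450, cop_copepodite1 = 160, cop_copepodite2 = 120,
             cop_nauplius1 = 200, cop_nauplius2 = 170, cop_nauplius3 = 90,
             clad_juvenile = 40, clad_adult = 25,
             rot_keratella_weg = 60, rot_keratella_neg = 80,
             rot_kellicottia = 45, rot_filinia = 20, rot_synchaeta = 30)
  bias <- rep(1, length(truth))
  names(bias) <- names(truth)
  bias["cop_adult"] <- 1.15
  bias[grep("^rot_", names(bias))] <- 0.7
  list(truth = truth, bias = bias)
}
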