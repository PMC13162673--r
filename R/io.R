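# Readers and writers for the pipeline's delimited-text dialects.
# Embedding tables: header object_id, sample_id, label (empty allowed),
# verified (0/1), t, v1..vd; tab or comma, auto-detected, and the writer
# emits the dialect it read. Counts: wide (category, human, machine) or
# long (sample, category, observer, value) CSV.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

#' Read an embedding table
#'
#' @param path Delimited text file (tab or comma, auto-detected) with
#'   header `object_id, sample_id, label, verified, t, v1..vd`.
#' @return An `embedding_set`; the detected delimiter is attached as
#'   attribute `sep` so [write_embeddings()] can round-trip the dialect.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, fill = TRUE,
                          colClasses = list(character = c("object_id",
                                                          "sample_id",
                                                          "label")),
                          data.table = FALSE, showProgress = FALSE)
  need <- c("object_id", "sample_id", "label", "verified", "t")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("embedding table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vcols <- grep("^v[0-9]+$", names(dt), value = TRUE)
  if (length(vcols) == 0L) stop("no embedding columns v1..vd", call. = FALSE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  if (nrow(dt) == 0L) {
    warning("empty embedding table: ", path, call. = FALSE)
    out <- embedding_records(character(0),
                             matrix(numeric(0), 0L, length(vcols)))
    attr(out, "sep") <- sep
    return(out)
  }
  vmat <- as.matrix(dt[, vcols, drop = FALSE])
  storage.mode(vmat) <- "double"
  bad <- which(rowSums(is.na(vmat)) > 0L)
  if (length(bad) > 0L) {
    stop("malformed embedding row at line ", bad[1L] + 1L,
         " of ", path, " (expected ", length(vcols),
         " vector components)", call. = FALSE)
  }
  lab <- as.character(dt$label)
  lab[!is.na(lab) & lab == ""] <- NA_character_
  out <- embedding_records(dt$object_id, vmat, sample_id = dt$sample_id,
                           label = lab, verified = dt$verified != 0,
                           t = dt$t)
  attr(out, "sep") <- sep
  out
}

#' Write an embedding table
#'
#' @param records An `embedding_set`.
#' @param path Output file.
#' @param sep Field delimiter; defaults to the dialect `records` was read
#'   with (attribute `sep`), else tab.
#' @export
write_embeddings <- function(records, path, sep = NULL) {
  stopifnot(inherits(records, "embedding_set"))
  if (is.null(sep)) sep <- attr(records, "sep") %||% "\t"
  v <- records$vectors
  colnames(v) <- sprintf("v%d", seq_len(ncol(v)))
  meta <- records$meta
  meta$label[is.na(meta$label)] <- ""
  meta$verified <- as.integer(meta$verified)
  data.table::fwrite(cbind(meta, as.data.frame(v)), path, sep = sep,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a detection table
#'
#' @param path Delimited text with header
#'   `object_id, image_id, x, y, w, h, confidence`.
#' @return data.frame of validated detection records.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("object_id",
                                                          "image_id")),
                          showProgress = FALSE)
  need <- c("object_id", "image_id", "x", "y", "w", "h", "confidence")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("detection table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(dt$confidence < 0 | dt$confidence > 1)) {
    stop("confidence outside [0, 1]", call. = FALSE)
  }
  if (any(dt$w <= 0 | dt$h <= 0)) stop("non-positive bbox size",
                                       call. = FALSE)
  if (any(dt$x < 0 | dt$y < 0)) stop("negative bbox origin", call. = FALSE)
  dt[, need]
}

#' Write a detection table
#' @param detections data.frame as returned by [read_detections()].
#' @param path Output file.
#' @export
write_detections <- function(detections, path) {
  data.table::fwrite(detections, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a paired abundance table
#'
#' Accepts either the wide dialect (header `category, human, machine`) or
#' the long dialect (`sample, category, observer, value` with observers
#' `human` and `machine`); both yield the same table.
#'
#' @param path CSV file.
#' @return A [paired_abundance()] table.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (all(c("category", "human", "machine") %in% names(dt))) {
    return(paired_abundance(dt$category, dt$human, dt$machine))
  }
  if (all(c("category", "observer", "value") %in% names(dt))) {
    h <- dt[dt$observer == "human", ]
    m <- dt[dt$observer == "machine", ]
    if (anyDuplicated(h$category) || anyDuplicated(m$category)) {
      stop("duplicate category within one observer", call. = FALSE)
    }
    if (!setequal(h$category, m$category)) {
      stop("human and machine cover different categories", call. = FALSE)
    }
    m <- m[match(h$category, m$category), ]
    return(paired_abundance(h$category, h$value, m$value))
  }
  stop("counts file must be wide (category, human, machine) or long ",
       "(sample, category, observer, value)", call. = FALSE)
}

#' Write a paired abundance table (wide dialect)
#' @param table A [paired_abundance()] table.
#' @param path Output CSV.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "paired_abundance"))
  data.table::fwrite(as.data.frame(table), path, sep = ",", quote = FALSE)
  invisible(path)
}

# Flatten an agreement report into a named numeric/character vector.
.report_fields <- function(report) {
  ba <- report$bland_altman
  c(list(
    n_categories = report$n_categories,
    human_mean = unname(report$human_mean_sd["mean"]),
    human_sd = unname(report$human_mean_sd["sd"]),
    machine_mean = unname(report$machine_mean_sd["mean"]),
    machine_sd = unname(report$machine_mean_sd["sd"]),
    perm_p = report$perm_p,
    wilcoxon_p = report$wilcoxon_p,
    mannwhitney_p = report$mannwhitney_p,
    pearson_r = report$pearson_r,
    bland_altman_bias = if (is.null(ba)) NA_real_ else ba$bias,
    bland_altman_sd = if (is.null(ba)) NA_real_ else ba$sd,
    bland_altman_lower = if (is.null(ba)) NA_real_ else ba$lower,
    bland_altman_upper = if (is.null(ba)) NA_real_ else ba$upper,
    bland_altman_excluded = if (is.null(ba)) "" else
      paste(ba$excluded, collapse = ";"),
    breakdown_equal = unname(report$breakdown["equal"]),
    breakdown_machine_lower = unname(report$breakdown["machine_lower"]),
    breakdown_machine_higher = unname(report$breakdown["machine_higher"])
  ))
}

#' Write an agreement report as key-value text
#' @param report An [agreement_report()].
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  fields <- .report_fields(report)
  fmt <- vapply(fields, function(v) {
    if (is.character(v)) v else format(v, digits = 15)
  }, character(1))
  writeLines(paste0(names(fields), ": ", fmt), path)
  invisible(path)
}

#' Parse back a key-value agreement report
#' @param path File written by [write_report()].
#' @return Named list; numeric fields as numerics.
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([^:]+): ?(.*)$", lines))
  out <- list()
  for (p in kv) {
    if (length(p) != 3L) next
    val <- p[3L]
    num <- suppressWarnings(as.numeric(val))
    out[[p[2L]]] <- if (is.na(num) && val != "NA") val else num
  }
  out
}

#' Write per-object triage decisions
#' @param decisions Decision table from [process_batch()].
#' @param path Output file (tab-delimited).
#' @export
write_decisions <- function(decisions, path) {
  data.table::fwrite(decisions, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a triage decision table
#' @param path File written by [write_decisions()].
#' @return data.frame of decisions.
#' @export
read_decisions <- function(path) {
  data.table::fread(path, header = TRUE, data.table = FALSE, na.strings = "NA",
                    colClasses = list(character = "object_id"),
                    showProgress = FALSE)
}

#' Write per-round active-learning metrics as CSV
#' @param metrics Metrics table from [run_active_loop()].
#' @param path Output CSV.
#' @export
write_metrics <- function(metrics, path) {
  data.table::fwrite(metrics, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

#' Default run configuration
#'
#' All triage and generator parameters with their defaults, as one flat
#' list; this is what a config file overrides and what gets echoed into
#' every output directory for provenance.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  tp <- unclass(triage_params())
  sc <- unclass(synth_config())
  c(tp, sc[setdiff(names(sc), names(tp))],
    list(n_perm = 9999L, rounds = 5L, batch_size = 200L,
         n_reference = 300L, n_query = 200L, novel_size = 50L,
         error_rate = 0, eval_fraction = 0.2))
}

#' Read a YAML run configuration, merged over the defaults
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list (defaults overridden by the file's fields).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(cfg), "mixture"))
    if (length(unknown) > 0L) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  cfg
}

#' Write a run configuration as YAML
#' @param cfg Config list.
#' @param path Output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.config_triage_params <- function(cfg) {
  triage_params(detection_threshold = cfg$detection_threshold,
                k_neighbors = cfg$k_neighbors,
                min_same_label = cfg$min_same_label,
                certainty_threshold = cfg$certainty_threshold,
                min_cluster_size = cfg$min_cluster_size,
                nu = cfg$nu, core_dist_floor = cfg$core_dist_floor,
                cluster_eps = cfg$cluster_eps,
                knn_aggregate = cfg$knn_aggregate,
                certainty_mode = cfg$certainty_mode, seed = cfg$seed)
}

.config_synth <- function(cfg, seed = cfg$seed) {
  synth_config(dim = cfg$dim, n_classes = cfg$n_classes,
               n_objects = cfg$n_objects,
               mixture = cfg$mixture, kappa = cfg$kappa,
               min_separation = cfg$min_separation,
               novel_fraction = cfg$novel_fraction,
               conf_shape1 = cfg$conf_shape1, conf_shape2 = cfg$conf_shape2,
               seed = seed)
}
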