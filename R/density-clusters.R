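# Hierarchical density-based clustering on the unit hypersphere.
#
# The pipeline needs, per label, the density-cluster structure of that
# label's verified embeddings, plus a membership query for new points.
# This is an HDBSCAN-style procedure specialised to cosine distance:
#   1. core distance of each point = distance to its min_pts-th nearest
#      neighbour (the point itself counts, as in the DBSCAN* convention);
#   2. points with core distance above an absolute floor are noise outright
#      -- cosine distance has an intrinsic scale (1 = orthogonal, i.e. no
#      directional association), so "dense" is meaningful in absolute terms;
#   3. mutual-reachability distances + single-linkage give the density
#      hierarchy; the dendrogram is condensed with a minimum cluster size,
#      ignoring structure below `selection_epsilon` (micro-splits well under
#      the within-class neighbour scale carry no signal for triage);
#   4. flat clusters are selected by excess-of-mass stability, the root
#      being an admissible cluster (a label frequently forms one coherent
#      cluster and must not be dissolved into noise).

.LAMBDA_FLOOR <- 1e-12

#' Fit density clusters on unit-norm vectors under cosine distance
#'
#' @param x Numeric matrix of unit-norm rows (one embedding per row).
#' @param min_cluster_size Minimum number of points a cluster may contain.
#' @param min_pts Neighbourhood size for core distances (default
#'   `min_cluster_size`).
#' @param core_floor Absolute core-distance ceiling for a point to count as
#'   dense; points above it are noise before the hierarchy is built.
#' @param selection_epsilon Distance scale below which dendrogram splits are
#'   ignored (treated as one cluster).
#' @return A `density_cluster_model` with per-point assignments
#'   (`point_cluster`, 0 = noise), per-cluster member lists and membership
#'   radii, supporting [assign_cluster()].
#' @export
density_clusters <- function(x, min_cluster_size = 5L,
                             min_pts = min_cluster_size,
                             core_floor = 0.5, selection_epsilon = 0.2) {
  x <- as.matrix(x)
  n <- nrow(x)
  mcs <- as.integer(min_cluster_size)
  if (n < mcs) {
    stop("need at least min_cluster_size = ", mcs, " points, got ", n,
         "; route object to review instead", call. = FALSE)
  }
  d_mat <- 1 - tcrossprod(x)
  d_mat[d_mat < 0] <- 0
  diag(d_mat) <- 0
  core <- apply(d_mat, 1L, function(r) sort(r, partial = min_pts)[min_pts])
  dense <- which(core <= core_floor)
  model <- structure(list(
    x = x, core = core, dense = dense,
    point_cluster = integer(n), clusters = list(),
    min_cluster_size = mcs, min_pts = as.integer(min_pts),
    core_floor = core_floor, selection_epsilon = selection_epsilon
  ), class = "density_cluster_model")
  if (length(dense) < mcs) return(model) # everything noise

  sub <- d_mat[dense, dense, drop = FALSE]
  mrd <- pmax(sub, outer(core[dense], core[dense], pmax))
  diag(mrd) <- 0
  hc <- stats::hclust(stats::as.dist(mrd), method = "single")
  cond <- .condense_tree(hc, mcs, selection_epsilon)
  sel <- .select_clusters_eom(cond)
  # map back to original indices
  k <- 0L
  for (cl in sel) {
    k <- k + 1L
    members <- dense[cl$points]
    model$point_cluster[members] <- k
    model$clusters[[k]] <- list(
      members = members,
      tau = max(selection_epsilon, cl$hmax)
    )
  }
  model
}

#' @export
print.density_cluster_model <- function(x, ...) {
  cat(sprintf("<density_cluster_model> %d points, %d cluster(s), %d noise\n",
              nrow(x$x), length(x$clusters), sum(x$point_cluster == 0L)))
  invisible(x)
}

# Condense the single-linkage dendrogram (hclust on mutual reachability)
# into clusters of size >= mcs. Splits at heights <= eps are ignored: all
# leaves below such a node stay members of the current cluster, recorded at
# the capped density level lambda = 1/max(eps, floor).
# Returns a list of cluster records:
#   birth (lambda), death (lambda or NA), death_size, parent, children,
#   points (leaf indices), point_lambda, hmax (max internal merge height).
.condense_tree <- function(hc, mcs, eps) {
  m <- nrow(hc$merge)
  n_leaves <- m + 1L
  leaves <- vector("list", m)
  sizes <- integer(m)
  for (i in seq_len(m)) {
    a <- hc$merge[i, 1L]; b <- hc$merge[i, 2L]
    la <- if (a < 0L) -a else leaves[[a]]
    lb <- if (b < 0L) -b else leaves[[b]]
    leaves[[i]] <- c(la, lb)
    sizes[i] <- length(leaves[[i]])
  }
  lam <- function(h) 1 / max(h, .LAMBDA_FLOOR)
  lam_cap <- 1 / max(eps, .LAMBDA_FLOOR)

  cl <- list()
  new_cluster <- function(birth, parent) {
    cl[[length(cl) + 1L]] <<- list(birth = birth, death = NA_real_,
                                   death_size = 0L, parent = parent,
                                   children = integer(0),
                                   points = integer(0),
                                   point_lambda = numeric(0), hmax = 0)
    length(cl)
  }
  add_points <- function(id, pts, lambda, h) {
    cl[[id]]$points <<- c(cl[[id]]$points, pts)
    cl[[id]]$point_lambda <<- c(cl[[id]]$point_lambda,
                                rep(lambda, length(pts)))
    cl[[id]]$hmax <<- max(cl[[id]]$hmax, h)
  }
  child_info <- function(node) {
    if (node < 0L) list(size = 1L, leaves = -node, node = node)
    else list(size = sizes[node], leaves = leaves[[node]], node = node)
  }

  root <- new_cluster(birth = 0, parent = 0L)
  stack <- list(list(node = m, cluster = root))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node; cid <- top$cluster
    h <- hc$height[node]
    if (h <= eps) {
      # structure below eps is one block: all leaves stay members
      add_points(cid, leaves[[node]], lam_cap, h)
      next
    }
    lv <- lam(h)
    a <- child_info(hc$merge[node, 1L])
    b <- child_info(hc$merge[node, 2L])
    if (a$size >= mcs && b$size >= mcs) {
      cl[[cid]]$death <- lv
      cl[[cid]]$death_size <- a$size + b$size
      cl[[cid]]$hmax <- max(cl[[cid]]$hmax, h)
      for (ch in list(a, b)) {
        sub_id <- new_cluster(birth = lv, parent = cid)
        cl[[cid]]$children <- c(cl[[cid]]$children, sub_id)
        if (ch$node < 0L) add_points(sub_id, ch$leaves, lam_cap, 0)
        else stack[[length(stack) + 1L]] <- list(node = ch$node,
                                                 cluster = sub_id)
      }
    } else {
      for (ch in list(a, b)) {
        if (ch$size < mcs) {
          add_points(cid, ch$leaves, lv, h) # chaff falls out at this level
        } else {
          cl[[cid]]$hmax <- max(cl[[cid]]$hmax, h)
          stack[[length(stack) + 1L]] <- list(node = ch$node, cluster = cid)
        }
      }
    }
  }
  # root is born at its first recorded event (sklearn-style convention),
  # not at lambda = 0, so its stability reflects only structure it owns
  ev <- c(cl[[root]]$point_lambda,
          vapply(cl[[root]]$children, function(i) cl[[i]]$birth, 0))
  if (!is.na(cl[[root]]$death)) ev <- c(ev, cl[[root]]$death)
  cl[[root]]$birth <- if (length(ev) > 0L) min(ev) else 0
  cl
}

# Excess-of-mass cluster selection over the condensed tree; the root
# competes like any other cluster. Returns selected clusters, each with all
# points of its unselected descendants absorbed.
.select_clusters_eom <- function(cl) {
  k <- length(cl)
  stab <- numeric(k); sel_stab <- numeric(k); selected <- logical(k)
  for (i in k:1) { # children are always created after their parent
    s <- sum(cl[[i]]$point_lambda - cl[[i]]$birth)
    if (!is.na(cl[[i]]$death)) {
      s <- s + (cl[[i]]$death - cl[[i]]$birth) * cl[[i]]$death_size
    }
    stab[i] <- s
    kids <- cl[[i]]$children
    if (length(kids) == 0L) {
      selected[i] <- TRUE
      sel_stab[i] <- s
    } else {
      sk <- sum(sel_stab[kids])
      if (s > sk) {
        selected[i] <- TRUE
        sel_stab[i] <- s
      } else {
        sel_stab[i] <- sk
      }
    }
  }
  # top-down: a selected ancestor absorbs every descendant
  absorb_into <- integer(k) # 0 = own fate
  for (i in seq_len(k)) {
    anc <- if (i == 1L) 0L else {
      p <- cl[[i]]$parent
      if (absorb_into[p] > 0L) absorb_into[p] else if (selected[p]) p else 0L
    }
    if (anc > 0L) {
      absorb_into[i] <- anc
      selected[i] <- FALSE
    }
  }
  out <- list()
  for (i in seq_len(k)) {
    if (!selected[i]) next
    pts <- cl[[i]]$points; hmax <- cl[[i]]$hmax
    for (j in seq_len(k)) {
      if (absorb_into[j] == i) {
        pts <- c(pts, cl[[j]]$points)
        hmax <- max(hmax, cl[[j]]$hmax)
      }
    }
    out[[length(out) + 1L]] <- list(points = sort(pts), hmax = hmax)
  }
  out
}

#' Cluster membership query for a new point
#'
#' A query joins the cluster whose members it can reach within that
#' cluster's formation scale: the reachability of the query to a member
#' `i` is `max(d(q, i), core(i))`, and the query is a member of cluster `k`
#' if its best reachability to `k`'s members does not exceed `k`'s
#' membership radius (the largest merge height at which `k`'s members
#' connected, floored at `selection_epsilon`). Among qualifying clusters the
#' closest wins; otherwise the query is noise.
#'
#' @param model A fitted `density_cluster_model`.
#' @param query Unit-norm numeric vector.
#' @return Integer cluster id (1-based), or `0` for noise.
#' @export
assign_cluster <- function(model, query) {
  stopifnot(inherits(model, "density_cluster_model"))
  if (length(model$clusters) == 0L) return(0L)
  d <- pmax(0, 1 - drop(model$x %*% query))
  best <- 0L; best_r <- Inf
  for (k in seq_along(model$clusters)) {
    mem <- model$clusters[[k]]$members
    r <- min(pmax(d[mem], model$core[mem]))
    if (r <= model$clusters[[k]]$tau && r < best_r) {
      best <- k; best_r <- r
    }
  }
  best
}
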