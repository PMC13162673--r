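# Shared fixture builders: small embedding geometries constructed in code.

# n uniform unit vectors.
runif_sphere <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * d), nrow = n)
  m / sqrt(rowSums(m^2))
}

# A tight cluster: tangent Gaussian around `center` with spread `sd`.
tight_cluster <- function(n, center, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(center)
  z <- matrix(rnorm(n * d, sd = sd), nrow = n)
  z <- z - outer(drop(z %*% center), center)
  x <- sweep(z, 2L, center, "+")
  x / sqrt(rowSums(x^2))
}

# Orthonormal axis vector e_i in d dimensions.
axis_vec <- function(i, d) {
  v <- numeric(d)
  v[i] <- 1
  v
}

# Verified index over labelled vector blocks:
# make_index(list(A = matA, B = matB)).
make_index <- function(blocks, prefix = "ref") {
  vecs <- do.call(rbind, unname(blocks))
  labs <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  ids <- sprintf("%s%04d", prefix, seq_len(nrow(vecs)))
  reference_index(
    embedding_records(ids, vecs, label = labs, verified = TRUE),
    dim = ncol(vecs))
}

# Two-class geometry used across triage tests: tight, well-separated
# clusters in moderate dimension (separation far exceeds within spread).
two_class_fixture <- function(n_per = 30, d = 16, sd = 0.02, seed = 42) {
  set.seed(seed)
  ca <- axis_vec(1, d)
  cb <- axis_vec(2, d)
  list(index = make_index(list(A = tight_cluster(n_per, ca, sd),
                               B = tight_cluster(n_per, cb, sd))),
       center_a = ca, center_b = cb, d = d, sd = sd)
}
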