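#' Paired human/machine abundance table
#'
#' One monitoring sample counted by two observers: the human expert and the
#' machine pipeline, per category (species or developmental stage), in
#' thousand specimens per square metre.
#'
#' @param category Character vector of unique category names.
#' @param human,machine Non-negative numeric vectors of equal length.
#' @return A `paired_abundance` data.frame.
#' @export
paired_abundance <- function(category, human, machine) {
  category <- as.character(category)
  if (length(category) < 1L) stop("empty table", call. = FALSE)
  if (anyDuplicated(category)) {
    stop("duplicate category: ", category[duplicated(category)][1L],
         call. = FALSE)
  }
  if (length(human) != length(category) ||
      length(machine) != length(category)) {
    stop("category, human and machine must have equal length", call. = FALSE)
  }
  if (any(human < 0) || any(machine < 0)) {
    stop("negative abundance", call. = FALSE)
  }
  structure(data.frame(category = category, human = as.numeric(human),
                       machine = as.numeric(machine),
                       stringsAsFactors = FALSE),
            class = c("paired_abundance", "data.frame"))
}

#' Mean and standard deviation of an abundance series
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector `c(mean, sd)`; sd uses the n-1 denominator.
#' @export
summarize_mean_sd <- function(values) {
  if (length(values) < 2L) {
    stop("need at least 2 values for a mean/sd summary", call. = FALSE)
  }
  c(mean = mean(values), sd = stats::sd(values))
}

#' Sign-flip permutation test on the summed paired difference
#'
#' Tests whether the human and machine counts are exchangeable within
#' categories. The statistic is `T = |sum_i(h_i - m_i)|` -- the L1 norm of
#' the summed paired differences -- and the null is generated by
#' independent sign flips of each per-category difference. Note the naive
#' "sum of per-category |h_i - m_i|" statistic is invariant under
#' within-pair swaps and therefore degenerate for this design; requesting
#' it is refused with an explanation.
#'
#' With `n <= 12` categories (or `exact = TRUE`) all `2^n` sign patterns
#' are enumerated and `p = #\{T* >= T\} / 2^n` (the identity pattern counts,
#' so p is never 0). Otherwise `n_perm` sampled flips are used with the
#' add-one convention `p = (1 + #\{T* >= T\}) / (1 + n_perm)`. All-zero
#' differences give `p = 1` exactly.
#'
#' @param table A [paired_abundance()] table (or numeric `human` with
#'   `machine` supplied).
#' @param machine Optional machine counts when `table` is a plain vector.
#' @param n_perm Number of sampled permutations (sampled mode only).
#' @param seed Integer seed for sampled mode.
#' @param exact `NULL` (auto: exhaustive iff `n <= 12`), `TRUE` or `FALSE`.
#' @param statistic `"sum_diff"`; the degenerate `"per_category_l1"` is
#'   refused.
#' @return List with `p`, `statistic`, `method` (`"exact"`/`"sampled"`)
#'   and `n_perm_used`.
#' @export
permutation_test_l1 <- function(table, machine = NULL, n_perm = 9999L,
                                seed = 1L, exact = NULL,
                                statistic = c("sum_diff",
                                              "per_category_l1")) {
  statistic <- match.arg(statistic)
  if (statistic == "per_category_l1") {
    stop("the per-category L1 statistic sum(|h_i - m_i|) is invariant ",
         "under within-pair label swaps (swapping h_i and m_i leaves every ",
         "|h_i - m_i| unchanged), so its permutation distribution is a ",
         "point mass and the test is degenerate; use the default ",
         "'sum_diff' statistic |sum(h_i - m_i)| instead", call. = FALSE)
  }
  if (inherits(table, "paired_abundance")) {
    d <- table$human - table$machine
  } else {
    d <- as.numeric(table) - as.numeric(machine)
  }
  n <- length(d)
  t_obs <- abs(sum(d))
  if (all(d == 0)) {
    return(list(p = 1, statistic = 0, method = "degenerate",
                n_perm_used = 0L))
  }
  tol <- 1e-9 * max(1, t_obs)
  if (is.null(exact)) exact <- n <= 12L
  if (exact) {
    m <- 2L^n
    t_null <- numeric(m)
    idx <- 0:(m - 1L)
    for (i in seq_len(n)) {
      sgn <- ifelse(bitwAnd(idx, 2L^(i - 1L)) > 0L, -1, 1)
      t_null <- t_null + sgn * d[i]
    }
    p <- mean(abs(t_null) >= t_obs - tol)
    list(p = p, statistic = t_obs, method = "exact", n_perm_used = m)
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    t_null <- abs(drop(signs %*% d))
    p <- (1 + sum(t_null >= t_obs - tol)) / (1 + n_perm)
    list(p = p, statistic = t_obs, method = "sampled",
         n_perm_used = as.integer(n_perm))
  }
}

#' Wilcoxon signed-rank test on paired abundance differences
#'
#' Two-sided signed-rank test on the per-category differences
#' `h_i - m_i`. Zero differences are dropped before ranking (the original
#' convention; `zeros = "pratt"` ranks them first and then discards their
#' contribution). For `n <= 15` retained differences the exact null is
#' enumerated over all sign assignments of the (possibly tied) ranks and
#' the two-sided p is twice the smaller tail, capped at 1; above that a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param table A [paired_abundance()] table or numeric vector of human
#'   counts.
#' @param machine Optional machine counts when `table` is a plain vector.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @param exact `NULL` (auto: `n <= 15`), `TRUE` or `FALSE`.
#' @return List with `p`, `W` (sum of positive ranks), `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(table, machine = NULL,
                                 zeros = c("drop", "pratt"), exact = NULL) {
  zeros <- match.arg(zeros)
  if (inherits(table, "paired_abundance")) {
    d <- table$human - table$machine
  } else {
    d <- as.numeric(table) - as.numeric(machine)
  }
  if (all(d == 0)) {
    stop("all paired differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  if (zeros == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else { # pratt: rank with zeros present, then discard zero ranks
    r_all <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  w_obs <- sum(r[d > 0])
  if (is.null(exact)) exact <- n <= 15L
  if (exact) {
    m <- 2L^n
    w_null <- numeric(m)
    idx <- 0:(m - 1L)
    for (i in seq_len(n)) {
      w_null <- w_null + r[i] * (bitwAnd(idx, 2L^(i - 1L)) > 0L)
    }
    tol <- 1e-9
    p_lo <- mean(w_null <= w_obs + tol)
    p_hi <- mean(w_null >= w_obs - tol)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4 # Var(sum r_i B_i), exact under ties
    sigma <- sqrt(sigma2)
    cc <- sign(w_obs - mu) * 0.5
    z <- (w_obs - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p = p, W = w_obs, n_used = n, method = method)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided two-sample rank-sum test. `U` counts pairs `(x_i, y_j)` with
#' `x_i > y_j` (ties count one half). With `n * m <= 64` the exact
#' (conditional-on-ties) null distribution is computed by enumerating all
#' group assignments of the pooled values; otherwise a normal approximation
#' with tie correction and continuity correction is used. The two-sided p
#' is twice the smaller tail, capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact `NULL` (auto: `n * m <= 64`), `TRUE` or `FALSE`.
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty",
                               call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (is.null(exact)) exact <- n * m <= 64
  if (exact) {
    ch <- utils::combn(n + m, n)
    u_null <- colSums(matrix(r[ch], nrow = n)) - n * (n + 1) / 2
    tol <- 1e-9
    p_lo <- mean(u_null <= u + tol)
    p_hi <- mean(u_null >= u - tol)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    nn <- n + m
    tie_tab <- table(r)
    sigma2 <- n * m / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) /
                              (nn * (nn - 1)))
    mu <- n * m / 2
    cc <- sign(u - mu) * 0.5
    p <- if (sigma2 <= 0) 1 else
      min(1, 2 * stats::pnorm(-abs((u - mu - cc) / sqrt(sigma2))))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}

#' Pearson correlation between the two observers
#'
#' @param table A [paired_abundance()] table or numeric vector.
#' @param machine Optional machine counts when `table` is a plain vector.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(table, machine = NULL) {
  if (inherits(table, "paired_abundance")) {
    h <- table$human; m <- table$machine
  } else {
    h <- as.numeric(table); m <- as.numeric(machine)
  }
  if (length(h) < 3L) stop("need n >= 3 for a correlation", call. = FALSE)
  if (stats::sd(h) == 0 || stats::sd(m) == 0) {
    stop("zero variance in one of the series", call. = FALSE)
  }
  stats::cor(h, m)
}

#' Bland-Altman analysis in log2 space
#'
#' For each category with both counts strictly positive, plots-coordinates
#' `x = (log2 h + log2 m) / 2` and `y = log2 h - log2 m` are computed; the
#' bias is `mean(y)` and the limits of agreement are `bias +/- 2 sd(y)`
#' (exactly 2, the display convention of the monitoring comparison, not
#' 1.96). Categories with a zero count in either observer are excluded and
#' listed rather than pseudocounted: a pseudocount choice would silently
#' dominate the limits for rare taxa.
#'
#' @param table A [paired_abundance()] table.
#' @return List with `points` (data.frame `category`, `x`, `y`), `bias`,
#'   `sd`, `lower`, `upper`, `excluded` (character).
#' @export
bland_altman_log2 <- function(table) {
  stopifnot(inherits(table, "paired_abundance"))
  usable <- table$human > 0 & table$machine > 0
  if (sum(usable) < 2L) {
    stop("need at least 2 categories with positive counts in both ",
         "observers", call. = FALSE)
  }
  h <- log2(table$human[usable]); m <- log2(table$machine[usable])
  y <- h - m
  bias <- mean(y)
  s <- stats::sd(y)
  list(points = data.frame(category = table$category[usable],
                           x = (h + m) / 2, y = y,
                           stringsAsFactors = FALSE),
       bias = bias, sd = s, lower = bias - 2 * s, upper = bias + 2 * s,
       excluded = table$category[!usable])
}

#' Category-level agreement breakdown
#'
#' Fraction of categories where the machine count equals the human count
#' (within `tol`), undercounts it, or overcounts it. The three fractions
#' sum to 1.
#'
#' @param table A [paired_abundance()] table.
#' @param tol Absolute tolerance for "equal" (default 0).
#' @return Named numeric vector `c(equal, machine_lower, machine_higher)`.
#' @export
category_breakdown <- function(table, tol = 0) {
  stopifnot(inherits(table, "paired_abundance"))
  d <- table$machine - table$human
  n <- nrow(table)
  c(equal = sum(abs(d) <= tol) / n,
    machine_lower = sum(d < -tol) / n,
    machine_higher = sum(d > tol) / n)
}

#' Convert raw counts to areal abundance
#'
#' Standard vertical-haul conversion: the counted fraction is scaled up to
#' the whole sample and divided by the net mouth area, yielding thousand
#' specimens per square metre of water column.
#'
#' @param raw_count Non-negative counts.
#' @param counted_fraction Fraction of the sample counted, in (0, 1].
#' @param net_mouth_diameter_m Net inlet diameter in metres (default
#'   0.375, the 37.5 cm mouth of the monitoring net).
#' @return Abundance in thousand specimens per m^2.
#' @export
counts_to_areal <- function(raw_count, counted_fraction = 1,
                            net_mouth_diameter_m = 0.375) {
  if (any(raw_count < 0)) stop("negative count", call. = FALSE)
  if (counted_fraction <= 0 || counted_fraction > 1) {
    stop("counted_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (net_mouth_diameter_m <= 0) stop("diameter must be > 0", call. = FALSE)
  area <- pi * (net_mouth_diameter_m / 2)^2
  (raw_count / counted_fraction) / area / 1000
}

#' Full human-vs-machine agreement report for one paired table
#'
#' Bundles the complete comparison suite: per-observer mean +/- sd,
#' sign-flip permutation test on the summed difference, Wilcoxon
#' signed-rank, Mann-Whitney rank-sum, Pearson correlation, Bland-Altman
#' analysis in log2 space and the category-level breakdown.
#'
#' @param table A [paired_abundance()] table.
#' @param n_perm Permutations for the sampled-mode permutation test.
#' @param seed Integer seed.
#' @param tol Tolerance of the category breakdown.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(table, n_perm = 9999L, seed = 1L, tol = 0) {
  stopifnot(inherits(table, "paired_abundance"))
  perm <- permutation_test_l1(table, n_perm = n_perm, seed = seed)
  wil <- tryCatch(wilcoxon_signed_rank(table), error = function(e) NULL)
  ba <- tryCatch(bland_altman_log2(table), error = function(e) NULL)
  structure(list(
    n_categories = nrow(table),
    human_mean_sd = summarize_mean_sd(table$human),
    machine_mean_sd = summarize_mean_sd(table$machine),
    perm_p = perm$p,
    wilcoxon_p = if (is.null(wil)) NA_real_ else wil$p,
    mannwhitney_p = mann_whitney_u(table$human, table$machine)$p,
    pearson_r = pearson_r(table),
    bland_altman = ba,
    breakdown = category_breakdown(table, tol = tol)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Human vs machine abundance agreement\n")
  cat(sprintf("  categories: %d\n", x$n_categories))
  cat(sprintf("  human:   %.3f +/- %.3f thousand/m^2\n",
              x$human_mean_sd["mean"], x$human_mean_sd["sd"]))
  cat(sprintf("  machine: %.3f +/- %.3f thousand/m^2\n",
              x$machine_mean_sd["mean"], x$machine_mean_sd["sd"]))
  cat(sprintf("  permutation p = %.4f, Wilcoxon p = %s, Mann-Whitney p = %.4f\n",
              x$perm_p,
              if (is.na(x$wilcoxon_p)) "NA" else sprintf("%.4f", x$wilcoxon_p),
              x$mannwhitney_p))
  cat(sprintf("  Pearson r = %.4f\n", x$pearson_r))
  if (!is.null(x$bland_altman)) {
    cat(sprintf("  Bland-Altman (log2): bias %.4f, limits [%.4f, %.4f]%s\n",
                x$bland_altman$bias, x$bland_altman$lower,
                x$bland_altman$upper,
                if (length(x$bland_altman$excluded))
                  paste0(", excluded: ",
                         paste(x$bland_altman$excluded, collapse = ", "))
                else ""))
  }
  cat(sprintf("  breakdown: equal %.0f%%, machine lower %.0f%%, machine higher %.0f%%\n",
              100 * x$breakdown["equal"], 100 * x$breakdown["machine_lower"],
              100 * x$breakdown["machine_higher"]))
  invisible(x)
}
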