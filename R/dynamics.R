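#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the median, over features with
#' nonzero counts in every sample, of the ratio of the count to that
#' feature's geometric mean across samples; normalized counts are the raw
#' counts divided by the size factor.
#'
#' @param counts integer matrix (features x samples) or an [mw_counts()]
#' @return list with `normalized` (numeric matrix) and `size_factors`
#'   (named per-sample vector)
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'             dimnames = list(paste0("f", 1:3), c("a", "b")))
#' normalize_median_of_ratios(m)$size_factors  # b = 2x a
#' @export
normalize_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "mw_counts")) counts$counts else as.matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no feature has nonzero counts in all samples; ",
         "median-of-ratios reference undefined")
  logm <- log(m[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - log_geo)))
  list(normalized = sweep(m, 2, sf, "/"), size_factors = sf)
}

#' Expressed-feature filter
#'
#' Keeps features whose per-time-point mean normalized count reaches the
#' threshold in at least one time-point (inclusive; the conventional
#' cutoff is 10 normalized counts).
#'
#' @param normalized normalized count matrix (features x samples)
#' @param samples sample sheet (see [mw_counts()])
#' @param threshold minimum per-time-point mean (default 10)
#' @return character vector of retained feature ids
#' @export
expressed_filter <- function(normalized, samples, threshold = 10) {
  tm <- timepoint_means(normalized, samples)
  rownames(tm)[apply(tm, 1, max) >= threshold]
}

#' All-versus-all Spearman correlation between time-points
#'
#' Correlates per-time-point expression vectors (replicates averaged)
#' over the supplied features, with average ranks for ties. Time-points
#' with constant expression yield `NA` against all others.
#'
#' @param normalized normalized count matrix (features x samples)
#' @param samples sample sheet
#' @return symmetric time-point x time-point matrix of Spearman r
#' @export
timepoint_correlation <- function(normalized, samples) {
  tm <- timepoint_means(normalized, samples)
  r <- suppressWarnings(cor(tm, method = "spearman"))
  diag(r) <- 1
  r
}

#' Z-score expression profiles across time-points
#'
#' Row-standardises per-time-point mean expression; constant rows become
#' all-zero (and are conventionally excluded from clustering).
#'
#' @param normalized normalized count matrix
#' @param samples sample sheet
#' @return features x time-points z-score matrix
#' @export
zscore_profiles <- function(normalized, samples) {
  tm <- timepoint_means(normalized, samples)
  mu <- rowMeans(tm)
  s <- apply(tm, 1, sd)
  z <- (tm - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Fuzzy c-means clustering (Bezdek alternating optimization)
#'
#' Random row-stochastic initial memberships (seeded), then alternating
#' updates: centers are membership^m weighted means, memberships follow
#' the inverse-squared-distance rule
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))`. A feature coinciding with
#' a center receives membership 1 there (limit convention). Converged
#' when the largest membership change falls below `tol`.
#'
#' @param profiles numeric matrix (features x dimensions), typically
#'   z-score profiles
#' @param k number of clusters (>= 2)
#' @param fuzzifier membership softness m > 1 (default 2)
#' @param tol convergence tolerance on memberships (default 1e-6)
#' @param max_iter iteration cap (default 1000)
#' @param rng_seed integer seed for the initial memberships
#' @param n_starts number of random restarts; the run with the lowest
#'   final objective is returned (default 5). Restart r uses seed
#'   `rng_seed + r - 1`, so results stay deterministic.
#' @return list with `membership` (features x k, rows sum to 1),
#'   `centers` (k x dimensions), `hard_label` (argmax cluster),
#'   `high_confidence` (max membership >= 0.6), `objective` (value per
#'   iteration of the best run, non-increasing), `iterations`
#' @export
fuzzy_cmeans <- function(profiles, k, fuzzifier = 2.0, tol = 1e-6,
                         max_iter = 1000L, rng_seed = 1L, n_starts = 5L) {
  best <- NULL
  for (r in seq_len(n_starts)) {
    fit <- fuzzy_cmeans_once(profiles, k, fuzzifier, tol, max_iter,
                             rng_seed + r - 1L)
    if (is.null(best) ||
        fit$objective[length(fit$objective)] <
          best$objective[length(best$objective)])
      best <- fit
  }
  best
}

fuzzy_cmeans_once <- function(profiles, k, fuzzifier, tol, max_iter,
                              rng_seed) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (k < 2) stop("k must be >= 2")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (n < k) stop("need at least k features")
  set.seed(rng_seed)
  u <- matrix(runif(n * k), n, k)
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (iter in seq_len(max_iter)) {
    um <- u^fuzzifier
    centers <- t(um) %*% x / colSums(um)
    # squared Euclidean distances features x k
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    u_new <- matrix(0, n, k)
    zero <- d2 < 1e-300
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      u_new[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    reg <- which(!has_zero)
    if (length(reg) > 0) {
      # u_ij = 1 / sum_l (d2_ij / d2_il)^(1/(m-1)); dividing by the row
      # minimum first keeps the powers in [0, 1] for any fuzzifier
      dr <- d2[reg, , drop = FALSE]
      rel <- dr / apply(dr, 1, min)
      inv <- rel^(-1 / (fuzzifier - 1))
      u_new[reg, ] <- inv / rowSums(inv)
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  hard <- max.col(u, ties.method = "first")
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(k)))
  dimnames(centers) <- list(paste0("C", seq_len(k)), colnames(x))
  list(membership = u, centers = centers, hard_label = hard,
       high_confidence = apply(u, 1, max) >= 0.6,
       objective = obj, iterations = iter)
}

#' Elbow-based selection of the number of clusters
#'
#' Runs [fuzzy_cmeans()] across `k_range`, records the final objective
#' `sum u^m d^2`, and selects the k maximizing the second difference of
#' the log-objective curve — the point where the relative improvement
#' collapses, which is scale-invariant and robust to one dominant early
#' merge. When no positive second difference exists the smallest k is
#' returned with `flagged = TRUE`.
#'
#' @param profiles numeric matrix (features x dimensions)
#' @param k_range candidate cluster counts (default 2:10)
#' @param rng_seed seed passed to every [fuzzy_cmeans()] run
#' @param ... further arguments to [fuzzy_cmeans()]
#' @return list with `k`, `objective` (named curve), `flagged`
#' @export
elbow_select_k <- function(profiles, k_range = 2:10, rng_seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(profiles)) stop("k_range exceeds feature count")
  objs <- vapply(k_range, function(k) {
    fit <- fuzzy_cmeans(profiles, k, rng_seed = rng_seed, ...)
    fit$objective[length(fit$objective)]
  }, numeric(1))
  names(objs) <- k_range
  if (length(k_range) < 3) {
    return(list(k = k_range[1], objective = objs, flagged = TRUE))
  }
  d2 <- diff(diff(log(pmax(objs, 1e-12))))  # second difference, log scale
  if (all(d2 <= 0)) {
    return(list(k = k_range[1], objective = objs, flagged = TRUE))
  }
  k_sel <- k_range[which.max(d2) + 1]
  list(k = k_sel, objective = objs, flagged = FALSE)
}

#' Chi-squared test of cluster composition
#'
#' For each cluster of size N with observed novel/conserved member
#' counts, expected counts are `N * p` and `N * (1 - p)` where `p` is the
#' novel fraction of the whole expressed population; the statistic is the
#' usual sum of (obs - exp)^2 / exp with df = 1 and no continuity
#' correction.
#'
#' @param hard_label integer cluster label per feature
#' @param is_novel logical per feature (TRUE = newly annotated)
#' @param population_ratio novel fraction p in (0, 1); defaults to the
#'   observed fraction over all features
#' @return data.frame with cluster, n, observed counts, statistic,
#'   p_value, and a low-expected-count warning flag
#' @export
composition_test <- function(hard_label, is_novel, population_ratio = NULL) {
  p <- population_ratio %||% mean(is_novel)
  if (p <= 0 || p >= 1) stop("population_ratio must lie in (0, 1)")
  out <- lapply(sort(unique(hard_label)), function(cl) {
    sel <- hard_label == cl
    n <- sum(sel)
    obs <- c(novel = sum(is_novel[sel]), conserved = sum(!is_novel[sel]))
    expd <- c(novel = n * p, conserved = n * (1 - p))
    x2 <- sum((obs - expd)^2 / expd)
    data.frame(cluster = cl, n = n, novel = obs[["novel"]],
               conserved = obs[["conserved"]],
               statistic = x2, p_value = pchisq(x2, df = 1, lower.tail = FALSE),
               low_expected = any(expd < 1))
  })
  do.call(rbind, out)
}
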