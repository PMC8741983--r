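#' Per-feature negative-binomial dispersion by method of moments
#'
#' Estimates the NB dispersion alpha in `var = mu + alpha mu^2` from
#' normalized counts: sample mean and variance are computed within each
#' group, pooled across groups (within-group variance, overall mean), and
#' `alpha = max(0, (s2 - mu) / mu^2)`, floored at `floor`. Features with
#' zero mean are returned as `NA` (skipped by the tests).
#'
#' @param normalized normalized count matrix (features x samples)
#' @param groups factor/vector of group labels per sample (>= 2
#'   replicates per group)
#' @param floor lower bound on alpha (default 1e-8)
#' @return named numeric vector of dispersions (NA where undefined)
#' @export
estimate_dispersion <- function(normalized, groups, floor = 1e-8) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  n <- ncol(normalized)
  grand_mu <- rowMeans(normalized)
  # pooled within-group variance
  ss <- 0; df <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    mu_g <- rowMeans(normalized[, cols, drop = FALSE])
    ss <- ss + rowSums((normalized[, cols, drop = FALSE] - mu_g)^2)
    df <- df + length(cols) - 1
  }
  s2 <- ss / df
  alpha <- pmax(floor, (s2 - grand_mu) / grand_mu^2)
  alpha[grand_mu == 0] <- NA_real_
  alpha
}

#' Mean-dispersion trend
#'
#' Smooths noisy per-feature dispersion estimates into a trend over the
#' mean: features are binned by log mean, the mean dispersion estimate is
#' taken per bin (the moment estimator is unbiased but right-skewed, so
#' the bin mean, not the median, is the calibrated summary), and bin
#' values are interpolated. With few replicates the per-feature moment
#' estimator is dominated by sampling noise; tests use the trended value
#' instead so their standard errors are calibrated (the limma-trend
#' compromise).
#'
#' @param mu per-feature mean normalized counts
#' @param alpha per-feature dispersion estimates (NA allowed)
#' @param n_bins number of log-mean bins (default 10)
#' @param min_per_bin minimum features per bin before falling back to the
#'   global median (default 20)
#' @return numeric vector of trended dispersions aligned with `mu`
#' @export
dispersion_trend <- function(mu, alpha, n_bins = 10L, min_per_bin = 20L) {
  ok <- !is.na(alpha) & mu > 0
  if (sum(ok) < min_per_bin)
    return(rep(max(1e-8, mean(alpha[ok])), length(mu)))
  lm_ok <- log(mu[ok])
  br <- unique(quantile(lm_ok, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3)
    return(rep(max(1e-8, mean(alpha[ok])), length(mu)))
  bins <- cut(lm_ok, br, include.lowest = TRUE)
  med <- tapply(alpha[ok], bins, mean)
  ctr <- tapply(lm_ok, bins, mean)
  keep <- !is.na(med) & table(bins) >= pmin(min_per_bin, sum(ok) / n_bins)
  if (sum(keep) < 2)
    return(rep(max(1e-8, mean(alpha[ok])), length(mu)))
  fit <- stats::approx(ctr[keep], med[keep], xout = log(pmax(mu, min(mu[ok]))),
                       rule = 2)$y
  pmax(1e-8, fit)
}

#' Negative-binomial Wald test between two time-points
#'
#' Simplified NB Wald pipeline: median-of-ratios normalization over all
#' samples, per-feature moment dispersion pooled over the two groups,
#' `log2FC = log2((mean_b + c) / (mean_a + c))` with pseudocount c, a
#' delta-method standard error under the NB variance function, two-sided
#' normal p-values, and Benjamini-Hochberg adjustment across the tested
#' features of the contrast. Features with zero counts in both groups are
#' excluded from testing and from the BH denominator.
#'
#' @param counts an [mw_counts()] object
#' @param tp_a,tp_b time-points to contrast (log2FC is b over a)
#' @param lfc_prior_pseudocount pseudocount c in the fold-change means
#'   (default 0.5)
#' @param dispersion `"trend"` (default) tests with the
#'   [dispersion_trend()] of the per-feature estimates, which keeps null
#'   p-values calibrated at few replicates; `"per_feature"` uses the raw
#'   moment estimates.
#' @return data.frame: feature_id, baseMean_a, baseMean_b, log2FC, SE,
#'   stat, pvalue, padj
#' @export
wald_test_pair <- function(counts, tp_a, tp_b, lfc_prior_pseudocount = 0.5,
                           dispersion = c("trend", "per_feature")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(counts, "mw_counts"))
  sa <- counts$samples$sample_id[counts$samples$time_point == tp_a]
  sb <- counts$samples$sample_id[counts$samples$time_point == tp_b]
  if (length(sa) == 0 || length(sb) == 0)
    stop("both time-points must be present with replicates")
  norm <- normalize_median_of_ratios(counts$counts)$normalized
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(norm[, sa, drop = FALSE])
  mb <- rowMeans(norm[, sb, drop = FALSE])
  tested <- ma > 0 | mb > 0
  sub <- norm[tested, c(sa, sb), drop = FALSE]
  grp <- rep(c("a", "b"), c(na, nb))
  if (dispersion == "trend") {
    # un-floored moment estimates: flooring would bias the bin means up
    alpha_raw <- estimate_dispersion(sub, grp, floor = -Inf)
    alpha <- dispersion_trend(rowMeans(sub), alpha_raw)
  } else {
    alpha <- estimate_dispersion(sub, grp)
  }
  ps <- lfc_prior_pseudocount
  mu_a <- ma[tested]; mu_b <- mb[tested]
  lfc <- log2((mu_b + ps) / (mu_a + ps))
  var_mean <- function(mu, n) (mu + alpha * mu^2) / n
  se <- sqrt((var_mean(mu_a, na) / (mu_a + ps)^2 +
                var_mean(mu_b, nb) / (mu_b + ps)^2)) / log(2)
  se[se == 0] <- NA
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  p[is.na(p)] <- 1
  data.frame(feature_id = rownames(norm)[tested],
             baseMean_a = mu_a, baseMean_b = mu_b,
             log2FC = lfc, SE = se, stat = stat, pvalue = p,
             padj = p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Two-wave summary of zygotic genome activation
#'
#' Counts significantly up- and down-regulated features (log2FC and
#' adjusted-p thresholds) per feature class and contrast, and assigns
#' each class a wave verdict: `"wave1"` if only the first adjacent-stage
#' contrast shows up-regulation, `"wave2"` if only the second, `"both"`,
#' or `"neither"`.
#'
#' @param results named list: for each feature class, a list of two
#'   [wald_test_pair()] result data.frames named `contrast1` and
#'   `contrast2` (the earlier and the later adjacent-stage contrast)
#' @param lfc_threshold log2 fold-change threshold (default 1.5)
#' @param padj_threshold adjusted p-value threshold (default 0.001)
#' @return data.frame per class and contrast with counts `n_up`,
#'   `n_down`, `n_tested`, fractions, and the per-class `verdict`
#' @export
classify_waves <- function(results, lfc_threshold = 1.5,
                           padj_threshold = 0.001) {
  rows <- list()
  for (cls in names(results)) {
    res <- results[[cls]]
    stopifnot(all(c("contrast1", "contrast2") %in% names(res)))
    ups <- integer(2)
    for (ci in 1:2) {
      de <- res[[paste0("contrast", ci)]]
      up <- sum(de$log2FC >= lfc_threshold & de$padj <= padj_threshold,
                na.rm = TRUE)
      dn <- sum(de$log2FC <= -lfc_threshold & de$padj <= padj_threshold,
                na.rm = TRUE)
      ups[ci] <- up
      rows[[length(rows) + 1]] <-
        data.frame(class = cls, contrast = paste0("contrast", ci),
                   n_up = up, n_down = dn, n_tested = nrow(de),
                   frac_up = up / max(1, nrow(de)),
                   frac_down = dn / max(1, nrow(de)))
    }
    verdict <- if (ups[1] > 0 && ups[2] > 0) "both"
      else if (ups[1] > 0) "wave1"
      else if (ups[2] > 0) "wave2"
      else "neither"
    for (j in (length(rows) - 1):length(rows)) rows[[j]]$verdict <- verdict
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
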