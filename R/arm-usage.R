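#' Relative arm usage
#'
#' log2 ratio of 5p to 3p arm read counts for one precursor in one sample:
#' `log2((N5 + pseudocount) / (N3 + pseudocount))`. The pseudocount keeps
#' the statistic finite and exactly antisymmetric for zero-count arms.
#'
#' @param N5,N3 non-negative read counts on the 5p and 3p arms
#'   (vectorised)
#' @param pseudocount positive real added to both arms (default 1)
#' @return numeric vector of log2 relative arm usage values
#' @examples
#' compute_rau(100, 100)   # 0
#' compute_rau(1000, 100)  # log2(1001/101)
#' @export
compute_rau <- function(N5, N3, pseudocount = 1) {
  if (any(N5 < 0) || any(N3 < 0)) stop("arm counts must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((N5 + pseudocount) / (N3 + pseudocount))
}

#' Relative arm usage profiles across time-points
#'
#' Sums replicate arm counts within each time-point, then computes the
#' relative arm usage per precursor and time-point. Time-points with no
#' record for a precursor are reported as `NA`, not zero.
#'
#' @param arm_counts data.frame with columns `precursor_id`,
#'   `time_point`, `N5`, `N3` (replicate rows are summed per time-point)
#' @param pseudocount see [compute_rau()]
#' @return precursor x time-point numeric matrix of rau values
#' @export
rau_profile <- function(arm_counts, pseudocount = 1) {
  stopifnot(all(c("precursor_id", "time_point", "N5", "N3") %in%
                  names(arm_counts)))
  tps <- sort(unique(arm_counts$time_point))
  pres <- unique(arm_counts$precursor_id)
  out <- matrix(NA_real_, length(pres), length(tps),
                dimnames = list(pres, paste0("T", tps)))
  agg5 <- stats::aggregate(N5 ~ precursor_id + time_point, data = arm_counts, FUN = sum)
  agg3 <- stats::aggregate(N3 ~ precursor_id + time_point, data = arm_counts, FUN = sum)
  agg <- merge(agg5, agg3, by = c("precursor_id", "time_point"))
  for (i in seq_len(nrow(agg))) {
    out[agg$precursor_id[i], paste0("T", agg$time_point[i])] <-
      compute_rau(agg$N5[i], agg$N3[i], pseudocount)
  }
  out
}

#' Classify the developmental arm-usage pattern of one precursor
#'
#' Time-points with `|rau|` below the dominance threshold count as
#' codominant ("white tiles"); a developmental switch requires one
#' time-point at or above the threshold on each side of zero. Otherwise
#' the profile is stably 5p- or 3p-dominant by the sign of the mean of
#' its dominant entries, or codominant when no entry is dominant.
#'
#' @param profile numeric vector of rau values over time-points (NAs are
#'   treated as missing)
#' @param dominance_threshold twofold dominance band (default 1.0 on the
#'   log2 scale)
#' @return list with `category` (`stable_5p`, `stable_3p`, `codominant`,
#'   `developmental_switch`) and `switch_timepoints` (adjacent index pairs
#'   where the sign of the dominant arm flips; empty unless switching)
#' @export
classify_development <- function(profile, dominance_threshold = 1.0) {
  x <- profile[!is.na(profile)]
  if (length(x) == 0) stop("all-missing rau profile")
  if (length(x) < 2) stop("need at least 2 non-missing time-points")
  dom5 <- profile >= dominance_threshold
  dom3 <- profile <= -dominance_threshold
  if (any(dom5, na.rm = TRUE) && any(dom3, na.rm = TRUE)) {
    # adjacent (in observed order) pairs where dominance flips sign
    idx <- which(!is.na(profile))
    sign_dom <- ifelse(dom5[idx], 1L, ifelse(dom3[idx], -1L, 0L))
    keep <- sign_dom != 0
    idx <- idx[keep]; sign_dom <- sign_dom[keep]
    flips <- which(diff(sign_dom) != 0)
    pairs <- lapply(flips, function(f) c(idx[f], idx[f + 1]))
    return(list(category = "developmental_switch", switch_timepoints = pairs))
  }
  dom <- x[abs(x) >= dominance_threshold]
  if (length(dom) == 0)
    return(list(category = "codominant", switch_timepoints = list()))
  cat <- if (mean(dom) > 0) "stable_5p" else "stable_3p"
  list(category = cat, switch_timepoints = list())
}

#' Cross-species arm-switch comparison
#'
#' Compares pooled relative arm usage of one microRNA between two species.
#' `switched` means opposite dominant arms (opposite rau signs);
#' `exceeds_tenfold` means the difference in arm usage is at least the
#' fold boundary (default tenfold, i.e. `log2(10)` on the rau scale) —
#' the boundary drawn as dotted lines in cross-species arm-usage plots.
#'
#' @param rau_a,rau_b finite rau values for the same microRNA in two
#'   species (whole-dataset pooled counts)
#' @param fold_boundary fold-difference boundary (default 10)
#' @return list with logicals `switched` and `exceeds_tenfold`
#' @export
cross_species_switch <- function(rau_a, rau_b, fold_boundary = 10) {
  stopifnot(is.finite(rau_a), is.finite(rau_b), fold_boundary > 0)
  list(switched = sign(rau_a) != 0 && sign(rau_b) != 0 &&
         sign(rau_a) != sign(rau_b),
       exceeds_tenfold = abs(rau_a - rau_b) >= log2(fold_boundary))
}
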