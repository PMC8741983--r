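#' Find canonical seed-match sites of a microRNA in a 3'UTR
#'
#' Scans the UTR (sense strand) for exact reverse complements of miRNA
#' nt 2-7 (the 6mer core) and classifies each occurrence by the standard
#' site taxonomy: 7mer-m8 when the match extends to nt 8, 7mer-A1 when an
#' A faces miRNA nt 1, 8mer when both. G:U pairs do not count as matches
#' in site typing. Overlapping occurrences at different offsets are
#' reported separately.
#'
#' @param mirna mature sequence, length >= 8 (RNA or DNA alphabet)
#' @param utr UTR sequence (sense strand)
#' @return data.frame with `start`, `end` (0-based half-open interval of
#'   the typed site on the UTR), `site_type`, `core_start` (0-based start
#'   of the 6mer core)
#' @export
find_seed_sites <- function(mirna, utr) {
  check_nt(mirna, "mirna"); check_nt(utr, "utr")
  m <- to_dna(mirna)
  if (nchar(m) < 8) stop("mature sequence must be >= 8 nt")
  u <- to_dna(utr)
  core <- revcomp(substr(m, 2, 7))
  pos <- gregexpr(core, u, fixed = TRUE)[[1]]
  if (pos[1] == -1)
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), core_start = integer(0)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m8_part <- comp[[substr(m, 8, 8)]]
  out <- lapply(as.integer(pos), function(p) {
    left <- if (p > 1) substr(u, p - 1, p - 1) else ""
    right <- if (p + 6 <= nchar(u)) substr(u, p + 6, p + 6) else ""
    has_m8 <- left == m8_part
    has_a1 <- right == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1" else "6mer"
    s0 <- (p - 1) - if (has_m8) 1L else 0L
    e0 <- (p - 1) + 6L + if (has_a1) 1L else 0L
    data.frame(start = s0, end = e0, site_type = type, core_start = p - 1L)
  })
  do.call(rbind, out)
}

# Nearest-neighbour stack free energies at 37 C (kcal/mol) for RNA
# Watson-Crick dinucleotide stacks (Xia et al. 1998), keyed by the two
# 5'->3' bases on the miRNA strand. Stacks involving G:U wobbles use
# approximate magnitudes (see vignette).
WC_STACK <- c(AA = -0.93, AU = -1.10, AC = -2.24, AG = -2.08,
              UA = -1.33, UU = -0.93, UC = -2.35, UG = -2.11,
              CA = -2.11, CU = -2.08, CC = -3.26, CG = -2.36,
              GA = -2.35, GU = -2.24, GC = -3.42, GG = -3.26)
GU_STACK_MIXED <- -1.2   # one wobble, one Watson-Crick pair
GU_STACK_TANDEM <- -0.5  # two adjacent wobbles

pair_type <- function(a, b) {
  # a on the miRNA, b on the target; returns "wc", "gu" or NA
  key <- paste0(a, b)
  if (key %in% c("AU", "UA", "CG", "GC")) "wc"
  else if (key %in% c("GU", "UG")) "gu"
  else NA_character_
}

stack_energy <- function(a1, b1, a2, b2) {
  t1 <- pair_type(a1, b1); t2 <- pair_type(a2, b2)
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  if (t1 == "wc" && t2 == "wc") return(WC_STACK[[paste0(a1, a2)]])
  if (t1 == "gu" && t2 == "gu") return(GU_STACK_TANDEM)
  GU_STACK_MIXED
}

#' Minimum free energy of a microRNA:target duplex
#'
#' Dynamic programme over antiparallel intermolecular pairings only (no
#' intramolecular structure): Watson-Crick and G:U pairs, nearest-
#' neighbour stacking energies at 37 C, and an affine destabilisation for
#' interior loops/bulges between helices (`loop_open + loop_per_nt` per
#' unpaired base, loop arms capped at `max_loop`). A duplex with no
#' stacked pair has energy 0; any stacked pair makes it negative.
#'
#' @param mirna mature sequence (5'->3')
#' @param utr_window target window (5'->3'), typically the site plus a
#'   flank of one mature length
#' @param loop_open,loop_per_nt interior-loop penalty parameters
#'   (defaults +4.0 and +0.5 kcal/mol)
#' @param max_loop maximum unpaired stretch on either strand between
#'   consecutive helices (default 8)
#' @return free energy in kcal/mol (<= 0)
#' @export
duplex_energy <- function(mirna, utr_window, loop_open = 4.0,
                          loop_per_nt = 0.5, max_loop = 8L) {
  check_nt(mirna, "mirna"); check_nt(utr_window, "utr_window")
  mv <- strsplit(to_rna(mirna), "")[[1]]
  uv <- strsplit(to_rna(utr_window), "")[[1]]
  M <- length(mv); L <- length(uv)
  if (L < 1 || M < 1) stop("window shorter than site")
  # pairable[i, j]: miRNA base i with target base j (antiparallel)
  best <- matrix(NA_real_, M, L)
  overall <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(L)) {
      if (is.na(pair_type(mv[i], uv[j]))) next
      e <- 0   # open a new duplex at this pair
      pmin_i <- max(1L, i - 1L - max_loop)
      pmax_j <- min(L, j + 1L + max_loop)
      for (p in pmin_i:(i - 1L)) {
        if (p < 1) break
        for (q in (j + 1L):pmax_j) {
          if (q > L) break
          prev <- best[p, q]
          if (is.na(prev)) next
          a <- i - p - 1L; b <- q - j - 1L
          step <- if (a == 0L && b == 0L)
            stack_energy(mv[p], uv[q], mv[i], uv[j])
          else loop_open + loop_per_nt * (a + b)
          if (!is.na(step) && prev + step < e) e <- prev + step
        }
      }
      best[i, j] <- e
      if (e < overall) overall <- e
    }
  }
  min(0, overall)
}

#' Filter microRNA-mRNA interactions
#'
#' A site survives when its duplex energy is strictly below the cutoff;
#' an interaction passes when at least `min_sites` sites survive ("the
#' same UTR targeted more than once") and both partners are expressed at
#' the threshold in at least one time-point. Co-expression at the same
#' time-point is not required.
#'
#' @param sites data.frame with `utr_id`, `mirna_id` (one row per site)
#' @param energies numeric vector of duplex energies, one per site row
#' @param expr_mirna,expr_mrna named vectors of the maximum
#'   per-time-point mean normalized expression for each partner
#' @param energy_cutoff strict upper bound on site energy (default -10
#'   kcal/mol; a site at exactly the cutoff fails)
#' @param expr_threshold expressed threshold (default 10)
#' @param min_sites minimum surviving sites per interaction (default 2)
#' @return data.frame per (mirna, mRNA) pair: site counts, `min_dG`,
#'   expression flags, `passes_filters`
#' @export
filter_interactions <- function(sites, energies, expr_mirna, expr_mrna,
                                energy_cutoff = -10, expr_threshold = 10,
                                min_sites = 2L) {
  stopifnot(nrow(sites) == length(energies))
  bad_m <- setdiff(sites$mirna_id, names(expr_mirna))
  bad_u <- setdiff(sites$utr_id, names(expr_mrna))
  if (length(bad_m) > 0 || length(bad_u) > 0)
    stop("site references unknown partner: ",
         paste(head(c(bad_m, bad_u), 5), collapse = ", "))
  sites$dG <- energies
  keys <- unique(sites[, c("mirna_id", "utr_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- sites$mirna_id == keys$mirna_id[i] & sites$utr_id == keys$utr_id[i]
    dg <- sites$dG[sel]
    surviving <- sum(dg < energy_cutoff)
    em <- expr_mirna[[keys$mirna_id[i]]] >= expr_threshold
    eu <- expr_mrna[[keys$utr_id[i]]] >= expr_threshold
    data.frame(mirna_id = keys$mirna_id[i], mrna_id = keys$utr_id[i],
               n_sites_total = sum(sel), n_sites = surviving,
               min_dG = min(dg),
               expressed_mirna = em, expressed_mrna = eu,
               passes_filters = surviving >= min_sites && em && eu)
  })
  do.call(rbind, out)
}

#' Hypergeometric enrichment of targeted mRNAs per expression cluster
#'
#' With m targeted and n non-targeted mRNAs in the UTR-bearing
#' population, a cluster of size k containing q targeted mRNAs is tested
#' for over-enrichment (upper tail, `P(X >= q)`) and under-enrichment
#' (lower tail, `P(X <= q)`); the smaller tail is reported as the
#' direction, with Bonferroni adjustment across clusters.
#'
#' @param targeted named logical vector over the UTR-bearing mRNAs
#' @param clusters named cluster assignment over the same mRNAs
#' @return data.frame per cluster: k, q, direction, p_over, p_under,
#'   p_value (reported tail), padj (Bonferroni), note for skipped
#'   clusters
#' @export
targeting_enrichment <- function(targeted, clusters) {
  ids <- names(targeted)
  stopifnot(!is.null(ids), setequal(ids, names(clusters)))
  clusters <- clusters[ids]
  m <- sum(targeted); n <- sum(!targeted)
  cls <- sort(unique(clusters))
  rows <- lapply(cls, function(cl) {
    k <- sum(clusters == cl)
    if (k == 0)
      return(data.frame(cluster = cl, k = 0L, q = 0L,
                        direction = NA, p_over = NA, p_under = NA,
                        p_value = NA, note = "empty cluster"))
    q <- sum(targeted[clusters == cl])
    p_over <- phyper(q - 1, m, n, k, lower.tail = FALSE)
    p_under <- phyper(q, m, n, k, lower.tail = TRUE)
    dir <- if (p_over <= p_under) "over" else "under"
    data.frame(cluster = cl, k = k, q = q, direction = dir,
               p_over = p_over, p_under = p_under,
               p_value = min(p_over, p_under), note = "")
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  out$padj <- NA_real_
  out$padj[ok] <- pmin(1, out$p_value[ok] * sum(ok))   # Bonferroni
  out
}

#' Two-sided Mann-Whitney U test, exact under ties for small samples
#'
#' The U statistic counts pairs where x exceeds y (ties contribute 1/2).
#' When the number of group assignments `choose(n1 + n2, n1)` is at most
#' `max_enum`, the exact permutation distribution of U over the pooled
#' values is enumerated and the two-sided p-value is
#' `P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|)`. Larger samples use the
#' normal approximation with tie correction.
#'
#' @param x,y numeric samples
#' @param max_enum enumeration budget (default 20000 assignments)
#' @return list with `U`, `p_value`, `exact`
#' @export
mann_whitney <- function(x, y, max_enum = 20000) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  ustat <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  u <- ustat(x, y)
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    pool <- c(x, y)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(sel) ustat(pool[sel], pool[-sel]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, p_value = p, exact = TRUE))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p_value = 2 * pnorm(-abs(z)), exact = FALSE)
}

#' Pairwise targeting-burden tests between expression clusters
#'
#' For every targeted mRNA computes (a) the number of distinct targeting
#' microRNAs and (b) the total number of surviving target sites in its
#' UTR, then compares every cluster pair with a two-sided Mann-Whitney
#' test per metric, Bonferroni-adjusted over the number of pairs.
#' Cluster pairs where either cluster has fewer than 2 targeted mRNAs
#' are skipped with a note.
#'
#' @param interactions output of [filter_interactions()]
#' @param clusters named cluster assignment over mRNAs
#' @return data.frame: metric, cluster_a, cluster_b, n_a, n_b, U,
#'   p_value, padj, note
#' @export
targeting_burden_tests <- function(interactions, clusters) {
  passing <- interactions[interactions$passes_filters, , drop = FALSE]
  per_mrna <- lapply(split(passing, passing$mrna_id), function(d)
    data.frame(mrna_id = d$mrna_id[1],
               n_mirnas = length(unique(d$mirna_id)),
               n_sites = sum(d$n_sites)))
  per_mrna <- do.call(rbind, per_mrna)
  cls <- sort(unique(clusters))
  pairs <- combn(cls, 2)
  rows <- list()
  for (metric in c("n_mirnas", "n_sites")) {
    n_pairs_tested <- 0
    pvals <- rep(NA_real_, ncol(pairs))
    tmp <- list()
    for (pi in seq_len(ncol(pairs))) {
      a <- pairs[1, pi]; b <- pairs[2, pi]
      ids_a <- names(clusters)[clusters == a]
      ids_b <- names(clusters)[clusters == b]
      va <- per_mrna[[metric]][per_mrna$mrna_id %in% ids_a]
      vb <- per_mrna[[metric]][per_mrna$mrna_id %in% ids_b]
      if (length(va) < 2 || length(vb) < 2) {
        tmp[[pi]] <- data.frame(metric = metric, cluster_a = a, cluster_b = b,
                                n_a = length(va), n_b = length(vb),
                                U = NA_real_, p_value = NA_real_,
                                note = "fewer than 2 targeted mRNAs")
        next
      }
      mw <- mann_whitney(va, vb)
      pvals[pi] <- mw$p_value
      n_pairs_tested <- n_pairs_tested + 1
      tmp[[pi]] <- data.frame(metric = metric, cluster_a = a, cluster_b = b,
                              n_a = length(va), n_b = length(vb),
                              U = mw$U, p_value = mw$p_value, note = "")
    }
    for (pi in seq_len(ncol(pairs))) {
      tmp[[pi]]$padj <- if (is.na(pvals[pi])) NA_real_
        else min(1, pvals[pi] * n_pairs_tested)
    }
    rows <- c(rows, tmp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
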