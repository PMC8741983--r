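# Independent oracles used to cross-check the package implementations.
# Each is written against a different code path (Biostrings C code,
# direct combinatorial enumeration, rank formulas) than the function it
# checks.

# Exhaustive local-alignment oracle: iteratively extracts the best local
# alignment with Biostrings::pairwiseAlignment (same scoring scheme),
# records it when it passes the thresholds, and recurses on the subject
# fragments left and right of the extracted locus.
oracle_local_hits <- function(query, subject, contig = "contig1",
                              match = 2, mismatch = -3,
                              gap_open = 5, gap_extend = 2,
                              min_identity = 0.30, min_coverage = 0.5,
                              min_score = 20) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  qlen <- nchar(query)
  hits <- list()
  extract <- function(frag, offset) {
    if (nchar(frag) < 4) return()
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(frag),
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    sc <- Biostrings::score(al)
    if (sc < min_score) return()
    pat <- Biostrings::alignedPattern(al)
    sub <- Biostrings::alignedSubject(al)
    cols <- nchar(as.character(pat))
    matches <- sum(strsplit(as.character(pat), "")[[1]] ==
                     strsplit(as.character(sub), "")[[1]])
    s_rng <- al@subject@range
    q_rng <- al@pattern@range
    identity <- matches / cols
    coverage <- BiocGenerics::width(q_rng) / qlen
    s0 <- offset + BiocGenerics::start(s_rng) - 1   # 0-based
    s1 <- offset + BiocGenerics::end(s_rng)
    if (identity >= min_identity && coverage >= min_coverage) {
      hits[[length(hits) + 1]] <<- data.frame(
        contig = contig, start = s0, end = s1, score = sc,
        identity = identity, coverage = coverage)
    }
    extract(substr(frag, 1, BiocGenerics::start(s_rng) - 1), offset)
    extract(substr(frag, BiocGenerics::end(s_rng) + 1, nchar(frag)),
            offset + BiocGenerics::end(s_rng))
  }
  extract(subject, 0)
  if (length(hits) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

# Both-strand wrapper matching search_genome's output conventions
oracle_search <- function(query, genome_seq, ...) {
  fwd <- oracle_local_hits(mirwave:::to_dna(query), genome_seq, ...)
  if (nrow(fwd) > 0) fwd$strand <- "+"
  rev <- oracle_local_hits(revcomp(mirwave:::to_dna(query)), genome_seq, ...)
  if (nrow(rev) > 0) rev$strand <- "-"
  out <- rbind(fwd, rev)
  if (nrow(out) < 2) return(out)
  # collapse overlapping loci keeping the best score (earlier start wins ties)
  out <- out[order(-out$score, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(out)) {
      if (keep[j] && out$start[j] < out$end[i] && out$start[i] < out$end[j])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Exact hypergeometric upper/lower tails by direct combinatorial sums
oracle_hyper_upper <- function(q, m, n, k) {
  xs <- q:min(m, k)
  xs <- xs[xs >= max(0, k - n)]
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}
oracle_hyper_lower <- function(q, m, n, k) {
  xs <- max(0, k - n):q
  xs <- xs[xs <= min(m, k)]
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# Exact two-sided Mann-Whitney p by enumeration, computing U through the
# rank-sum identity (average ranks), independent of the package's
# pair-counting implementation.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Spearman via Pearson on average ranks (rank-formula route)
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# count in-range read lengths by a plain loop (size-selection oracle)
oracle_count_in_range <- function(seqs, lo, hi) {
  n <- 0
  for (s in seqs) {
    l <- nchar(s)
    if (l >= lo && l <= hi) n <- n + 1
  }
  n
}
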