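#' Size-select small reads
#'
#' Retains reads whose length lies inside an inclusive window; the
#' conventional window for microRNA discovery is 18-26 nt.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, and
#'   optionally `precursor_id`, `start`, `end` (0-based half-open).
#' @param min_len,max_len inclusive length bounds (defaults 18 and 26).
#' @return the input rows whose sequence length is within bounds, in
#'   input order.
#' @examples
#' r <- data.frame(read_id = c("a", "b"), sequence = c("ACGU", strrep("A", 22)))
#' size_select(r)  # keeps only the 22-mer
#' @export
size_select <- function(reads, min_len = 18L, max_len = 26L) {
  if (min_len < 0 || max_len < 0) stop("lengths must be non-negative")
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Remove reads matching a contaminant blacklist
#'
#' A read is removed when it matches any blacklist sequence (e.g. tRNAs,
#' rRNAs) as a substring with at most `max_mismatches` mismatches —
#' the semantics of filtering reads through a short-read mapper run with
#' a small mismatch budget.
#'
#' @param reads data.frame with a `sequence` column
#' @param blacklist character vector of contaminant sequences
#' @param max_mismatches mismatch budget (default 3)
#' @return surviving reads, in input order
#' @export
exclude_contaminants <- function(reads, blacklist, max_mismatches = 3L) {
  if (length(blacklist) == 0) return(reads)
  blk <- to_dna(blacklist)
  seqs <- to_dna(reads$sequence)
  hit <- vapply(seqs, function(s) {
    n <- nchar(s)
    sv <- strsplit(s, "")[[1]]
    for (b in blk) {
      m <- nchar(b)
      if (m < n) next
      bv <- strsplit(b, "")[[1]]
      for (off in 0:(m - n)) {
        if (sum(sv != bv[(off + 1):(off + n)]) <= max_mismatches) return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  reads[!hit, , drop = FALSE]
}

#' Per-arm read statistics for a precursor candidate
#'
#' Assigns each mapped read to the 5p or 3p arm when it overlaps that
#' arm's annotated mature interval by at least `assignment_overlap` of the
#' read length (reads overlapping neither arm sufficiently are ignored),
#' then tallies read counts, the modal 5'-end fraction, and the read
#' length histogram per arm.
#'
#' @param reads data.frame with `start`, `end` (0-based half-open
#'   coordinates on the precursor) for reads mapped to this precursor
#' @param precursor one row of a precursor table with `mature5p_start`,
#'   `mature5p_end`, `mature3p_start`, `mature3p_end`
#' @param assignment_overlap minimum fraction of the read length that must
#'   overlap a mature interval (default 0.5)
#' @return list with elements `p5` and `p3`, each a list with
#'   `read_count`, `modal_5prime_fraction` (0 when no reads assigned) and
#'   `length_histogram` (named integer vector)
#' @export
arm_stats <- function(reads, precursor, assignment_overlap = 0.5) {
  ivs <- list(p5 = c(precursor$mature5p_start, precursor$mature5p_end),
              p3 = c(precursor$mature3p_start, precursor$mature3p_end))
  one_arm <- function(iv) {
    if (nrow(reads) == 0) {
      return(list(read_count = 0L, modal_5prime_fraction = 0,
                  length_histogram = integer(0)))
    }
    len <- reads$end - reads$start
    ov <- pmax(0, pmin(reads$end, iv[2]) - pmax(reads$start, iv[1]))
    sel <- ov >= assignment_overlap * len & len > 0
    n <- sum(sel)
    if (n == 0) {
      return(list(read_count = 0L, modal_5prime_fraction = 0,
                  length_histogram = integer(0)))
    }
    starts <- reads$start[sel]
    hist <- table(len[sel])
    list(read_count = as.integer(n),
         modal_5prime_fraction = max(table(starts)) / n,
         length_histogram = setNames(as.integer(hist), names(hist)))
  }
  list(p5 = one_arm(ivs$p5), p3 = one_arm(ivs$p3))
}

#' Apply microRNA candidate filtering rules
#'
#' A candidate is accepted when all three rules hold (inclusively): at
#' least `min_reads` reads on both the 5p and 3p arms, loop length at
#' least `min_loop` nt, and at least `min_homogeneity` of each arm's
#' reads sharing the same 5' end. Candidates flagged as conserved
#' (confidently annotated homologs in other species) are rescued even
#' when rules are violated.
#'
#' @param candidates precursor data.frame (see [gen_hairpin_readstacks()])
#'   with columns `precursor_id`, `mature5p_end`, `mature3p_start`,
#'   `conserved_flag`
#' @param stats named list: for each precursor_id the output of
#'   [arm_stats()]
#' @param min_reads minimum reads per arm (default 10)
#' @param min_loop minimum loop length in nt (default 8)
#' @param min_homogeneity minimum modal 5'-end fraction (default 0.5)
#' @return data.frame with `precursor_id`, `accepted`, `reasons`
#'   (comma-separated among `arm_support`, `loop_length`,
#'   `five_prime_heterogeneity`), `rescued_by_conservation`
#' @export
filter_candidates <- function(candidates, stats, min_reads = 10L,
                              min_loop = 8L, min_homogeneity = 0.5) {
  missing <- setdiff(candidates$precursor_id, names(stats))
  if (length(missing) > 0)
    stop("missing arm statistics for candidate(s): ",
         paste(head(missing, 5), collapse = ", "))
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    id <- candidates$precursor_id[i]
    st <- stats[[id]]
    reasons <- character(0)
    if (st$p5$read_count < min_reads || st$p3$read_count < min_reads)
      reasons <- c(reasons, "arm_support")
    loop <- candidates$mature3p_start[i] - candidates$mature5p_end[i]
    if (loop < min_loop) reasons <- c(reasons, "loop_length")
    if (st$p5$modal_5prime_fraction < min_homogeneity ||
        st$p3$modal_5prime_fraction < min_homogeneity)
      reasons <- c(reasons, "five_prime_heterogeneity")
    rescued <- length(reasons) > 0 && isTRUE(candidates$conserved_flag[i])
    data.frame(precursor_id = id,
               accepted = length(reasons) == 0 || rescued,
               reasons = paste(reasons, collapse = ","),
               rescued_by_conservation = rescued)
  })
  do.call(rbind, out)
}

#' Length distribution and positional nucleotide frequencies of reads
#'
#' Summarises a read set the way small-RNA QC figures do: the read length
#' histogram over all reads, and per-position nucleotide frequencies over
#' the first 22 nt computed on the set of distinct (non-redundant) read
#' sequences. Reads shorter than 22 nt contribute only to the positions
#' they cover; each position's frequencies are renormalised to sum to 1.
#'
#' @param reads data.frame with a `sequence` column
#' @param n_positions number of 5' positions to profile (default 22)
#' @return list with `length_histogram` (named integer vector) and
#'   `nt_frequency` (4 x `n_positions` matrix, rows A/C/G/U)
#' @export
read_profile_summary <- function(reads, n_positions = 22L) {
  lens <- nchar(reads$sequence)
  hist <- table(lens)
  uniq <- unique(to_rna(reads$sequence))
  freq <- matrix(0, 4, n_positions,
                 dimnames = list(RNA_BASES, seq_len(n_positions)))
  for (pos in seq_len(n_positions)) {
    nts <- substr(uniq, pos, pos)
    nts <- nts[nts != ""]
    if (length(nts) == 0) next
    tab <- table(factor(nts, levels = RNA_BASES))
    freq[, pos] <- as.numeric(tab) / length(nts)
  }
  list(length_histogram = setNames(as.integer(hist), names(hist)),
       nt_frequency = freq)
}
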