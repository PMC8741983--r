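#' Seed-and-extend homology search of a precursor against a genome
#'
#' Exact `word_size`-mer seeds on both strands nominate candidate regions,
#' which are scanned by Smith-Waterman local alignment under the stated
#' scoring (match +2, mismatch -3, affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`). Alignments are extracted best-first and
#' non-overlapping; a hit is reported when its score reaches `min_score`,
#' its identity (identical columns / alignment columns) reaches
#' `min_identity`, and it covers at least `min_coverage` of the query.
#' The score/identity/coverage thresholds are the deterministic analog of
#' a BLAST e-value cutoff.
#'
#' @param query precursor sequence (RNA or DNA alphabet)
#' @param genome named character vector of contig sequences (one species)
#' @param word_size exact seed length (default 4)
#' @param match,mismatch alignment scores (defaults +2 / -3)
#' @param gap_open,gap_extend positive gap costs (defaults 5 and 2)
#' @param min_identity minimum aligned identity (default 0.30)
#' @param min_coverage minimum fraction of the query aligned (default 0.5)
#' @param min_score minimum alignment score (default 20)
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open on the + strand), `strand`, `score`, `identity`,
#'   `coverage`; zero rows when the genome is empty or has no hit
#' @export
search_genome <- function(query, genome, word_size = 4L,
                          match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2,
                          min_identity = 0.30, min_coverage = 0.5,
                          min_score = 20) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0))
  if (length(genome) == 0 || all(nchar(genome) == 0)) return(empty)
  q <- to_dna(query)
  qlen <- nchar(q)
  if (qlen < word_size) stop("query shorter than word_size")
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))

  strand_queries <- c(`+` = q, `-` = revcomp(q))
  hits <- list()
  for (contig in names(genome)) {
    subj <- to_dna(genome[[contig]])
    slen <- nchar(subj)
    if (slen == 0) next
    for (strand in c("+", "-")) {
      qs <- strand_queries[[strand]]
      # exact word seeds -> merged candidate regions
      words <- unique(substring(qs, seq_len(qlen - word_size + 1),
                                seq_len(qlen - word_size + 1) + word_size - 1))
      seed_pos <- sort(unique(unlist(lapply(words, function(w) {
        p <- gregexpr(w, subj, fixed = TRUE)[[1]]
        if (p[1] == -1) integer(0) else as.integer(p)
      }))))
      if (length(seed_pos) == 0) next
      lo <- pmax(1L, seed_pos - qlen)
      hi <- pmin(slen, seed_pos + qlen + word_size)
      regions <- merge_intervals(lo, hi)
      for (r in seq_len(nrow(regions))) {
        frag_stack <- list(c(regions$lo[r], regions$hi[r]))
        while (length(frag_stack) > 0) {
          fr <- frag_stack[[1]]; frag_stack <- frag_stack[-1]
          if (fr[2] - fr[1] + 1 < word_size) next
          al <- .sw_best(qs, substr(subj, fr[1], fr[2]),
                         match, mismatch, gap_open, gap_extend)
          if (al$score < min_score) next
          s0 <- fr[1] + al$sstart - 2L      # 0-based start on contig
          s1 <- fr[1] + al$send - 1L        # half-open end
          identity <- al$matches / al$cols
          coverage <- (al$qend - al$qstart + 1) / qlen
          if (identity >= min_identity && coverage >= min_coverage) {
            hits[[length(hits) + 1]] <-
              data.frame(contig = contig, start = s0, end = s1,
                         strand = strand, score = al$score,
                         identity = identity, coverage = coverage)
          }
          # recurse left and right of the extracted locus
          frag_stack <- c(frag_stack,
                          list(c(fr[1], fr[1] + al$sstart - 2L)),
                          list(c(fr[1] + al$send, fr[2])))
        }
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  collapse_overlapping_hits(out)
}

# merge closed 1-based intervals given by parallel lo/hi vectors
merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  out_lo <- integer(0); out_hi <- integer(0)
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi + 1) mhi <- max(mhi, hi[i])
    else { out_lo <- c(out_lo, mlo); out_hi <- c(out_hi, mhi); mlo <- lo[i]; mhi <- hi[i] }
  }
  data.frame(lo = c(out_lo, mlo), hi = c(out_hi, mhi))
}

# keep the best-scoring hit among mutually overlapping loci (same contig,
# either strand); ties broken by earlier start for determinism
collapse_overlapping_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(-hits$score, hits$contig, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in (i + 1):nrow(hits)) {
      if (!keep[j]) next
      if (hits$contig[j] == hits$contig[i] &&
          hits$start[j] < hits$end[i] && hits$start[i] < hits$end[j])
        keep[j] <- FALSE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group precursors into microRNA families
#'
#' Two-stage grouping: precursors whose dominant mature sequence aligns to
#' a reference catalog sequence at >= `min_identity` identity over the
#' mature length join that catalog family and are flagged conserved;
#' remaining precursors are clustered into novel families by identical
#' extended seed (mature nt 2-8).
#'
#' @param precursors data.frame with columns `precursor_id`, `mature_seq`
#' @param catalog named character vector of reference mature sequences;
#'   names are family ids
#' @param min_identity conserved-assignment identity threshold
#'   (default 0.7)
#' @return data.frame with `precursor_id`, `family_id`, `conserved`
#' @export
assign_families <- function(precursors, catalog, min_identity = 0.7) {
  if (any(is.na(precursors$mature_seq) | precursors$mature_seq == ""))
    stop("precursor lacking mature annotation: ",
         paste(precursors$precursor_id[is.na(precursors$mature_seq) |
                                         precursors$mature_seq == ""],
               collapse = ", "))
  mats <- to_dna(precursors$mature_seq)
  cat_seqs <- to_dna(catalog)
  fam <- character(nrow(precursors))
  conserved <- logical(nrow(precursors))
  for (i in seq_along(mats)) {
    best_id <- 0; best_fam <- NA_character_
    for (f in names(cat_seqs)) {
      al <- .sw_best(mats[i], cat_seqs[[f]], 2, -3, 5, 2)
      idq <- if (al$score <= 0) 0 else al$matches / nchar(mats[i])
      if (idq > best_id) { best_id <- idq; best_fam <- f }
    }
    if (best_id >= min_identity) { fam[i] <- best_fam; conserved[i] <- TRUE }
  }
  # novel families: identical extended seed (nt 2-8)
  novel_idx <- which(!conserved)
  if (length(novel_idx) > 0) {
    seeds <- substr(mats[novel_idx], 2, 8)
    uniq <- unique(seeds)
    ids <- setNames(sprintf("novel-%03d", seq_along(uniq)), uniq)
    fam[novel_idx] <- ids[seeds]
  }
  data.frame(precursor_id = precursors$precursor_id, family_id = fam,
             conserved = conserved)
}

#' Build the family x species copy-number matrix
#'
#' Cell (family, species) counts the non-overlapping accepted hit loci in
#' that species across all members of the family; overlapping hits are
#' collapsed to the best-scoring locus first.
#'
#' @param hits data.frame of accepted hits with columns `precursor_id`,
#'   `species_id`, `contig`, `start`, `end`, `score`
#' @param families output of [assign_families()]
#' @param species character vector of all species (matrix columns)
#' @return integer matrix, families x species
#' @export
build_family_matrix <- function(hits, families, species) {
  unknown <- setdiff(hits$species_id, species)
  if (length(unknown) > 0)
    stop("unknown species in hits: ", paste(unknown, collapse = ", "))
  nofam <- setdiff(hits$precursor_id, families$precursor_id)
  if (length(nofam) > 0)
    stop("hit query without family: ", paste(head(nofam, 5), collapse = ", "))
  fams <- sort(unique(families$family_id))
  mat <- matrix(0L, length(fams), length(species),
                dimnames = list(fams, species))
  if (nrow(hits) == 0) return(mat)
  hits$family_id <- families$family_id[match(hits$precursor_id,
                                             families$precursor_id)]
  for (f in fams) for (sp in species) {
    h <- hits[hits$family_id == f & hits$species_id == sp, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- collapse_overlapping_hits(h[, c("contig", "start", "end", "score"),
                                     drop = FALSE])
    mat[f, sp] <- nrow(h)
  }
  mat
}

#' Cluster species from the family matrix
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) of species column vectors, binarised to presence/absence by
#' default. Species are ordered lexicographically before clustering so
#' tie-breaking is deterministic.
#'
#' @param matrix family x species matrix (see [build_family_matrix()])
#' @param mode `"presence_absence"` (binarise) or `"copy_number"`
#' @return list with `newick` (string, branch lengths = merge heights),
#'   `hclust` (the [stats::hclust] object) and `phylo` (an [ape] tree)
#' @export
cluster_species <- function(matrix, mode = c("presence_absence", "copy_number")) {
  mode <- match.arg(mode)
  if (ncol(matrix) < 2) stop("need at least 2 species to cluster")
  m <- matrix[, order(colnames(matrix)), drop = FALSE]
  if (mode == "presence_absence") m <- (m > 0) + 0
  d <- dist(t(m), method = "euclidean")
  hc <- hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  list(newick = ape::write.tree(phy), hclust = hc, phylo = phy)
}

#' Summarise conservation breadth of microRNA families
#'
#' Classifies families by where their homologs occur: present in at least
#' one species other than the focal one; restricted to the focal species'
#' clade; the core set (conserved in another species and not
#' clade-restricted); and families unique to the focal species.
#'
#' @param matrix family x species copy-number matrix; must contain a
#'   column for the focal species (its own annotation)
#' @param self_species focal species column name
#' @param clade_map named character vector mapping every species to a
#'   clade
#' @return list with `per_family` data.frame (family_id, n_other_species,
#'   present_other, clade_restricted, unique) and the `present_other`,
#'   `clade_restricted`, `core`, `unique` family-id sets
#' @export
summarize_conservation <- function(matrix, self_species, clade_map) {
  if (!self_species %in% colnames(matrix))
    stop("self_species absent from matrix: ", self_species)
  if (!all(colnames(matrix) %in% names(clade_map)))
    stop("clade_map must cover all species")
  other <- setdiff(colnames(matrix), self_species)
  self_clade <- clade_map[[self_species]]
  pf <- data.frame(family_id = rownames(matrix))
  pf$n_other_species <- vapply(rownames(matrix), function(f)
    sum(matrix[f, other] > 0), integer(1), USE.NAMES = FALSE)
  pf$present_other <- pf$n_other_species > 0
  pf$clade_restricted <- vapply(rownames(matrix), function(f) {
    sp <- other[matrix[f, other] > 0]
    length(sp) > 0 && all(clade_map[sp] == self_clade)
  }, logical(1), USE.NAMES = FALSE)
  pf$unique <- vapply(rownames(matrix), function(f) {
    matrix[f, self_species] > 0 && pf$n_other_species[match(f, pf$family_id)] == 0
  }, logical(1), USE.NAMES = FALSE)
  list(per_family = pf,
       present_other = pf$family_id[pf$present_other],
       clade_restricted = pf$family_id[pf$clade_restricted],
       core = pf$family_id[pf$present_other & !pf$clade_restricted],
       unique = pf$family_id[pf$unique])
}
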