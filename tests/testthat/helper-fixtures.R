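# Shared fixture builders (everything is generated in code at test time).

# arm_stats for every precursor of a generated stack set
stack_stats <- function(gs) {
  st <- lapply(seq_len(nrow(gs$precursors)), function(i) {
    p <- gs$precursors[i, ]
    arm_stats(gs$reads[gs$reads$precursor_id == p$precursor_id, , drop = FALSE], p)
  })
  names(st) <- gs$precursors$precursor_id
  st
}

# minimal mw_counts object from a plain matrix and time-point labels
quick_counts <- function(m, time_points, class = "mirna",
                         conservation = "novel") {
  reps <- stats::ave(time_points, time_points, FUN = seq_along)
  samples <- data.frame(sample_id = colnames(m), time_point = time_points,
                        replicate = reps)
  features <- data.frame(feature_id = rownames(m), class = class,
                         conservation = rep_len(conservation, nrow(m)))
  mw_counts(m, samples, features)
}

# random mature miRNA sequences with distinct seeds
random_matures <- function(n, len = 22, seed = 1) {
  set.seed(seed)
  repeat {
    out <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(substr(out, 2, 7))) break
  }
  names(out) <- sprintf("mir_%03d", seq_len(n))
  out
}

# best matching of fitted hard labels to planted labels (maximum
# agreement over label permutations, greedy on the confusion matrix)
match_labels <- function(fitted, planted) {
  tab <- table(fitted, planted)
  map <- character(nrow(tab))
  used <- character(0)
  for (i in order(-apply(tab, 1, max))) {
    cand <- colnames(tab)[order(-tab[i, ])]
    cand <- setdiff(cand, used)
    map[i] <- cand[1]
    used <- c(used, cand[1])
  }
  names(map) <- rownames(tab)
  map[as.character(fitted)]
}
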