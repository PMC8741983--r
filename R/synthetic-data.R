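#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generators. Defaults
#' mirror the study design emulated by the package: seven developmental
#' time-points, four small-RNA replicates and two mRNA replicates per
#' time-point, negative-binomial counts, and archetype proportions matching
#' the four microRNA expression clusters (maternal 26%, early-zygotic 15%,
#' mid 20%, late 39%).
#'
#' @param rng_seed integer; fully determines every generator's output.
#' @param n_timepoints number of developmental time-points (default 7).
#' @param n_replicates_small small-RNA replicates per time-point (default 4).
#' @param n_replicates_large mRNA/lncRNA replicates per time-point (default 2).
#' @param nb_dispersion NB dispersion alpha in var = mu + alpha mu^2.
#' @param archetype_fractions named proportions over archetypes
#'   `maternal`, `early_zygotic`, `mid`, `late`, `flat`; must sum to 1.
#' @param fold_change_planted multiplicative fold change applied to planted
#'   up-regulated features (default 8, i.e. log2FC = 3).
#' @param library_size_range pair of positive integers; per-sample target
#'   library sizes are drawn uniformly from this range.
#' @return a `sim_config` list
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' @export
sim_config <- function(rng_seed,
                       n_timepoints = 7L,
                       n_replicates_small = 4L,
                       n_replicates_large = 2L,
                       nb_dispersion = 0.1,
                       archetype_fractions = c(maternal = 0.26,
                                               early_zygotic = 0.15,
                                               mid = 0.20, late = 0.39),
                       fold_change_planted = 8,
                       library_size_range = c(2e5, 5e5)) {
  stopifnot(length(rng_seed) == 1, is.finite(rng_seed))
  known <- c("maternal", "early_zygotic", "mid", "late", "flat")
  if (is.null(names(archetype_fractions)) ||
      !all(names(archetype_fractions) %in% known))
    stop("archetype_fractions must be named with archetypes among: ",
         paste(known, collapse = ", "))
  if (abs(sum(archetype_fractions) - 1) > 1e-9)
    stop("archetype_fractions must sum to 1")
  if (n_timepoints < 1 || n_replicates_small < 1 || n_replicates_large < 1)
    stop("all counts must be >= 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (fold_change_planted <= 0) stop("fold_change_planted must be > 0")
  stopifnot(length(library_size_range) == 2,
            all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2])
  structure(list(rng_seed = as.integer(rng_seed),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates_small = as.integer(n_replicates_small),
                 n_replicates_large = as.integer(n_replicates_large),
                 nb_dispersion = nb_dispersion,
                 archetype_fractions = archetype_fractions,
                 fold_change_planted = fold_change_planted,
                 library_size_range = library_size_range),
            class = "sim_config")
}

# Relative mean trajectory of each archetype over T time-points.
# maternal: geometric decay with half-life of one time-point;
# early_zygotic: burst peaking at time-point 2; mid: bump at mid-course;
# late: rise towards the final time-point; flat: constant null.
archetype_trajectory <- function(archetype, n_timepoints,
                                 decay_halflife = 1) {
  t <- seq_len(n_timepoints)
  traj <- switch(archetype,
    maternal = 2^(-(t - 1) / decay_halflife),
    early_zygotic = {
      x <- exp(-((t - 2)^2) / (2 * 0.8^2))
      x + 0.02
    },
    mid = {
      mid_t <- ceiling(n_timepoints / 2) + 0.5
      exp(-((t - mid_t)^2) / (2 * 1.0^2)) + 0.02
    },
    late = {
      x <- exp(-((t - n_timepoints)^2) / (2 * 1.5^2))
      x + 0.02
    },
    flat = rep(1, n_timepoints),
    stop("unknown archetype: ", archetype)
  )
  traj / max(traj)
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws feature x sample negative-binomial counts whose mean trajectories
#' follow developmental archetypes, with optional up-regulated features
#' planted between an adjacent time-point pair at the configured fold
#' change, and per-sample library-size multipliers.
#'
#' @param config a [sim_config()]
#' @param feature_class `"mirna"`, `"mrna"` or `"lncrna"`; decides the
#'   number of replicates per time-point.
#' @param n_features number of background features.
#' @param base_means optional vector of per-feature baseline means
#'   (recycled); default log-normal around 150.
#' @param n_planted_up number of extra features planted as up-regulated.
#' @param planted_contrast adjacent time-point pair `c(a, b)`; planted
#'   features jump by `fold_change_planted` from time-point `b` onward.
#' @param conserved_fraction fraction of features labelled "conserved" in
#'   the feature sheet (the rest "novel").
#' @return list with `counts` (an [mw_counts()]) and `truth` (list with
#'   per-feature archetypes/planted flags and per-sample multipliers).
#' @export
gen_count_matrix <- function(config, feature_class = c("mirna", "mrna", "lncrna"),
                             n_features = 500, base_means = NULL,
                             n_planted_up = 0, planted_contrast = c(2L, 3L),
                             conserved_fraction = 0.5) {
  feature_class <- match.arg(feature_class)
  set.seed(config$rng_seed + 101L)
  T <- config$n_timepoints
  nrep <- if (feature_class == "mirna") config$n_replicates_small else config$n_replicates_large

  fr <- config$archetype_fractions
  n_by_arch <- quota_alloc(n_features, fr / sum(fr))
  archetypes <- rep(names(fr), n_by_arch)
  n_tot <- n_features + n_planted_up
  if (is.null(base_means)) base_means <- rlnorm(n_tot, meanlog = log(150), sdlog = 1)
  base_means <- rep_len(base_means, n_tot)

  traj <- matrix(0, n_tot, T)
  for (i in seq_len(n_features))
    traj[i, ] <- archetype_trajectory(archetypes[i], T)
  if (n_planted_up > 0) {
    stopifnot(length(planted_contrast) == 2,
              planted_contrast[2] == planted_contrast[1] + 1,
              planted_contrast[2] <= T)
    for (i in n_features + seq_len(n_planted_up)) {
      x <- rep(1, T)
      x[seq(planted_contrast[2], T)] <- config$fold_change_planted
      traj[i, ] <- x
    }
    archetypes <- c(archetypes, rep("planted_up", n_planted_up))
  }

  samples <- expand.grid(replicate = seq_len(nrep), time_point = seq_len(T))
  samples <- data.frame(sample_id = sprintf("S%d_r%d", samples$time_point,
                                            samples$replicate),
                        time_point = samples$time_point,
                        replicate = samples$replicate)
  nsamp <- nrow(samples)
  lib <- runif(nsamp, config$library_size_range[1], config$library_size_range[2])
  lambda <- lib / exp(mean(log(lib)))

  mu <- traj * base_means                      # features x time-points
  counts <- matrix(0L, n_tot, nsamp)
  for (s in seq_len(nsamp)) {
    m <- mu[, samples$time_point[s]] * lambda[s]
    counts[, s] <- nb_draw(n_tot, m, config$nb_dispersion)
  }
  feature_ids <- sprintf("%s_%04d", feature_class, seq_len(n_tot))
  dimnames(counts) <- list(feature_ids, samples$sample_id)
  conserved <- rep("novel", n_tot)
  conserved[sample.int(n_tot, round(conserved_fraction * n_tot))] <- "conserved"
  features <- data.frame(feature_id = feature_ids, class = feature_class,
                         conservation = conserved)
  truth <- list(
    features = data.frame(feature_id = feature_ids, archetype = archetypes,
                          base_mean = base_means,
                          planted_up = archetypes == "planted_up"),
    samples = data.frame(sample_id = samples$sample_id, lambda = lambda,
                         target_library_size = lib),
    mean_trajectories = `dimnames<-`(mu, list(feature_ids, paste0("T", 1:T))),
    planted_contrast = if (n_planted_up > 0) planted_contrast else NULL
  )
  list(counts = mw_counts(counts, samples, features), truth = truth)
}

#' Default read-stack plan
#'
#' Random mixture of passing and failing precursor stacks: most stacks are
#' set well inside the acceptance region; a fraction violate exactly one of
#' the three rules (arm support, loop length, 5' homogeneity).
#'
#' @param n number of precursors
#' @param fail_fraction fraction of stacks violating one rule
#' @return data.frame consumed by [gen_hairpin_readstacks()]
#' @export
default_stack_plan <- function(n, fail_fraction = 0.3) {
  plan <- data.frame(
    precursor_id = sprintf("pre_%04d", seq_len(n)),
    depth_5p = sample(30:80, n, replace = TRUE),
    depth_3p = sample(30:80, n, replace = TRUE),
    modal_frac_5p = runif(n, 0.75, 0.95),
    modal_frac_3p = runif(n, 0.75, 0.95),
    loop_len = sample(9:15, n, replace = TRUE),
    conserved = FALSE
  )
  n_fail <- round(fail_fraction * n)
  if (n_fail > 0) {
    idx <- sample.int(n, n_fail)
    rule <- sample(c("arm", "loop", "het"), n_fail, replace = TRUE)
    plan$depth_3p[idx[rule == "arm"]] <- sample(1:9, sum(rule == "arm"), replace = TRUE)
    plan$loop_len[idx[rule == "loop"]] <- sample(0:7, sum(rule == "loop"), replace = TRUE)
    plan$modal_frac_5p[idx[rule == "het"]] <- runif(sum(rule == "het"), 0.25, 0.45)
  }
  plan
}

#' Generate hairpin precursors with planted read stacks
#'
#' Each planned precursor gets a random hairpin sequence (8-nt flanks,
#' 22-nt mature arms, configurable loop) and a stack of reads per arm.
#' Read 5' ends jitter over offsets -2..+2 around the annotated mature
#' start; the number of reads at each offset follows a deterministic
#' largest-remainder quota for the requested modal fraction, so the
#' realized modal fraction is exact at planned boundary values.
#'
#' @param config a [sim_config()]
#' @param plan data.frame with columns `precursor_id`, `depth_5p`,
#'   `depth_3p`, `modal_frac_5p`, `modal_frac_3p`, `loop_len`, `conserved`;
#'   see [default_stack_plan()].
#' @return list with `precursors` (data.frame: precursor_id, sequence,
#'   mature5p_start/end, mature3p_start/end, conserved_flag; 0-based
#'   half-open intervals), `reads` (data.frame: read_id, precursor_id,
#'   start, end, sequence), and `truth` (planned values, realized modal
#'   fractions, intended verdict and violated rules per precursor).
#' @export
gen_hairpin_readstacks <- function(config, plan = NULL) {
  set.seed(config$rng_seed + 202L)
  if (is.null(plan)) plan <- default_stack_plan(100)
  if (any(plan$loop_len < 0)) stop("loop length must be >= 0")
  if (any(plan$depth_5p < 0 | plan$depth_3p < 0)) stop("depths must be >= 0")
  if (any(plan$modal_frac_5p > 1 | plan$modal_frac_3p > 1 |
          plan$modal_frac_5p < 0.21 | plan$modal_frac_3p < 0.21))
    stop("modal fractions must lie in [0.21, 1]")

  flank <- 8L; mat_len <- 22L
  offsets <- -2:2
  stack_one_arm <- function(depth, modal_frac, mature_start, seqlen) {
    if (depth == 0) return(integer(0))
    p <- rep((1 - modal_frac) / 4, 5)
    p[offsets == 0] <- modal_frac
    cnt <- quota_alloc(depth, p)
    starts <- rep(mature_start + offsets, cnt)
    starts[sample.int(length(starts))]   # random order, fixed composition
  }

  precursors <- data.frame(precursor_id = plan$precursor_id,
                           sequence = NA_character_,
                           mature5p_start = NA_integer_, mature5p_end = NA_integer_,
                           mature3p_start = NA_integer_, mature3p_end = NA_integer_,
                           conserved_flag = plan$conserved)
  reads_list <- vector("list", nrow(plan))
  truth <- plan
  truth$realized_modal_5p <- NA_real_
  truth$realized_modal_3p <- NA_real_

  for (i in seq_len(nrow(plan))) {
    loop <- plan$loop_len[i]
    seqlen <- 2L * flank + 2L * mat_len + loop
    s <- rand_seq(1, seqlen, RNA_BASES)
    m5 <- c(flank, flank + mat_len)                     # 0-based half-open
    m3 <- c(flank + mat_len + loop, flank + 2L * mat_len + loop)
    precursors$sequence[i] <- s
    precursors$mature5p_start[i] <- m5[1]; precursors$mature5p_end[i] <- m5[2]
    precursors$mature3p_start[i] <- m3[1]; precursors$mature3p_end[i] <- m3[2]

    st5 <- stack_one_arm(plan$depth_5p[i], plan$modal_frac_5p[i], m5[1], seqlen)
    st3 <- stack_one_arm(plan$depth_3p[i], plan$modal_frac_3p[i], m3[1], seqlen)
    starts <- c(st5, st3)
    if (length(starts) > 0) {
      lens <- sample(21:23, length(starts), replace = TRUE)
      ends <- pmin(starts + lens, seqlen)
      reads_list[[i]] <- data.frame(
        read_id = sprintf("%s_rd%04d", plan$precursor_id[i], seq_along(starts)),
        precursor_id = plan$precursor_id[i],
        start = starts, end = ends,
        sequence = substring(s, starts + 1, ends))
    }
    modal_of <- function(st, depth) if (depth == 0) 0 else max(table(st)) / depth
    truth$realized_modal_5p[i] <- modal_of(st5, plan$depth_5p[i])
    truth$realized_modal_3p[i] <- modal_of(st3, plan$depth_3p[i])
  }
  reads <- do.call(rbind, reads_list)
  rownames(reads) <- NULL

  # intended verdict from the realized stack, under the default thresholds
  reasons <- lapply(seq_len(nrow(plan)), function(i) {
    r <- character(0)
    if (plan$depth_5p[i] < 10 || plan$depth_3p[i] < 10) r <- c(r, "arm_support")
    if (plan$loop_len[i] < 8) r <- c(r, "loop_length")
    if (truth$realized_modal_5p[i] < 0.5 || truth$realized_modal_3p[i] < 0.5)
      r <- c(r, "five_prime_heterogeneity")
    r
  })
  truth$verdict <- ifelse(lengths(reasons) == 0 | plan$conserved, "pass", "fail")
  truth$violated <- vapply(reasons, paste, character(1), collapse = ",")
  list(precursors = precursors, reads = reads, truth = truth)
}

#' Generate planted per-time-point arm-count profiles
#'
#' Emits replicate-level 5p/3p arm counts for precursors with planted
#' arm-usage categories: stably 5p- or 3p-dominant, codominant, or a
#' developmental switch flipping dominance midway through the course.
#'
#' @param config a [sim_config()]
#' @param categories character vector drawn from `stable_5p`, `stable_3p`,
#'   `codominant`, `developmental_switch` (one entry per precursor).
#' @param depth mean per-arm read depth
#' @return list with `arm_counts` (precursor_id, sample_id, time_point,
#'   replicate, N5, N3) and `truth` (precursor_id, category, switch point).
#' @export
gen_arm_count_table <- function(config, categories, depth = 200) {
  set.seed(config$rng_seed + 303L)
  T <- config$n_timepoints
  nrep <- config$n_replicates_small
  switch_at <- floor(T / 2)                # dominance flips after this tp
  rows <- list(); k <- 0
  for (i in seq_along(categories)) {
    cat_i <- categories[i]
    ratio <- switch(cat_i,                 # N5:N3 odds per time-point
      stable_5p = rep(8, T),
      stable_3p = rep(1 / 8, T),
      codominant = rep(1, T),
      developmental_switch = c(rep(8, switch_at), rep(1 / 8, T - switch_at)),
      stop("unknown category: ", cat_i))
    for (tp in seq_len(T)) for (r in seq_len(nrep)) {
      n5 <- stats::rpois(1, depth * ratio[tp] / (1 + ratio[tp]))
      n3 <- stats::rpois(1, depth / (1 + ratio[tp]))
      k <- k + 1
      rows[[k]] <- data.frame(precursor_id = sprintf("pre_%04d", i),
                              sample_id = sprintf("S%d_r%d", tp, r),
                              time_point = tp, replicate = r,
                              N5 = n5, N3 = n3)
    }
  }
  truth <- data.frame(precursor_id = sprintf("pre_%04d", seq_along(categories)),
                      category = categories,
                      switch_after = ifelse(categories == "developmental_switch",
                                            switch_at, NA))
  list(arm_counts = do.call(rbind, rows), truth = truth)
}

#' Generate genomes with planted precursor homologs
#'
#' Builds i.i.d.-uniform background genomes and plants precursor copies at
#' controlled identity (substitutions only; exactly
#' `floor((1 - identity) * length)` positions mutated), on either strand,
#' at non-overlapping loci.
#'
#' @param config a [sim_config()]
#' @param precursors named character vector of precursor sequences
#' @param species_plan data.frame with columns `species_id`,
#'   `precursor_id`, `copies`, `identity`
#' @param genome_length background genome length per species
#' @return list with `genomes` (named character vector, one per species)
#'   and `truth` (`hits` data.frame with species_id, precursor_id, copy,
#'   start, end (0-based half-open), strand, identity; `copy_number`
#'   precursor x species matrix).
#' @export
gen_genomes_with_homologs <- function(config, precursors, species_plan,
                                      genome_length = 10000) {
  set.seed(config$rng_seed + 404L)
  if (length(precursors) < 1) stop("need at least one precursor")
  if (any(species_plan$identity <= 0 | species_plan$identity > 1))
    stop("identity must lie in (0, 1]")
  species <- unique(species_plan$species_id)
  genomes <- setNames(rand_seq(length(species), genome_length, DNA_BASES), species)
  hit_rows <- list(); k <- 0
  occupied <- setNames(vector("list", length(species)), species)

  for (j in seq_len(nrow(species_plan))) {
    sp <- species_plan$species_id[j]
    pid <- species_plan$precursor_id[j]
    qseq <- to_dna(precursors[[pid]])
    qlen <- nchar(qseq)
    n_sub <- floor((1 - species_plan$identity[j]) * qlen)
    for (cp in seq_len(species_plan$copies[j])) {
      mut <- strsplit(qseq, "")[[1]]
      if (n_sub > 0) {
        pos <- sample.int(qlen, n_sub)
        mut[pos] <- vapply(mut[pos], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
      }
      planted <- paste(mut, collapse = "")
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") planted else revcomp(planted)
      # non-overlapping placement
      for (try in 1:200) {
        start0 <- sample.int(genome_length - qlen, 1) # 0-based
        iv <- c(start0, start0 + qlen)
        clash <- any(vapply(occupied[[sp]], function(o)
          iv[1] < o[2] && o[1] < iv[2], logical(1)))
        if (!clash) break
        if (try == 200) stop("could not place homolog without overlap")
      }
      occupied[[sp]] <- c(occupied[[sp]], list(iv))
      g <- genomes[[sp]]
      substr(g, start0 + 1, start0 + qlen) <- ins
      genomes[[sp]] <- g
      k <- k + 1
      hit_rows[[k]] <- data.frame(species_id = sp, precursor_id = pid,
                                  copy = cp, start = start0,
                                  end = start0 + qlen, strand = strand,
                                  identity = (qlen - n_sub) / qlen)
    }
  }
  hits <- do.call(rbind, hit_rows)
  cn <- matrix(0L, length(precursors), length(species),
               dimnames = list(names(precursors), species))
  for (r in seq_len(nrow(hits)))
    cn[hits$precursor_id[r], hits$species_id[r]] <-
      cn[hits$precursor_id[r], hits$species_id[r]] + 1L
  list(genomes = genomes, truth = list(hits = hits, copy_number = cn))
}

#' Generate 3'UTRs with planted microRNA seed sites
#'
#' Background UTR sequence is patched until it contains no canonical 6mer
#' core match for any input microRNA; planted sites are then written in at
#' non-overlapping positions. Extended sites are the full reverse
#' complement of the mature sequence (strongly pairing, energy far below
#' the usual -10 kcal/mol cutoff); non-extended sites cover only mature
#' nt 1-8.
#'
#' @param config a [sim_config()]
#' @param mirnas named character vector of mature sequences (18-26 nt)
#' @param plan data.frame with columns `utr_id`, `mirna_id`, `n_sites`,
#'   `extended` (logical). Each row plants `n_sites` sites for one
#'   miRNA/UTR pair. UTRs appearing in no row are pure background.
#' @param utr_length length of every generated UTR
#' @return list with `utrs` (named character vector) and `truth` (`sites`
#'   data.frame: utr_id, mirna_id, site index, start, end (0-based
#'   half-open), extended; `pairs`: planted site count per pair).
#' @export
gen_utr_targets <- function(config, mirnas, plan, utr_length = 2000) {
  set.seed(config$rng_seed + 505L)
  lens <- nchar(mirnas)
  if (any(lens < 18 | lens > 26)) stop("mature sequences must be 18-26 nt")
  if (is.null(names(mirnas))) stop("mirnas must be named")
  mirnas <- to_rna(mirnas)
  cores <- vapply(mirnas, function(m) to_dna(revcomp(substr(m, 2, 7))),
                  character(1))

  patch_background <- function(seq) {
    for (iter in 1:200) {
      hit <- FALSE
      for (core in cores) {
        p <- gregexpr(core, seq, fixed = TRUE)[[1]]
        if (p[1] != -1) {
          hit <- TRUE
          for (pos in p) {
            at <- pos + sample.int(6, 1) - 1
            old <- substr(seq, at, at)
            substr(seq, at, at) <- sample(setdiff(DNA_BASES, old), 1)
          }
        }
      }
      if (!hit) return(seq)
    }
    stop("failed to scrub background of seed matches")
  }

  utr_ids <- unique(plan$utr_id)
  utrs <- setNames(character(length(utr_ids)), utr_ids)
  site_rows <- list(); k <- 0

  for (uid in utr_ids) {
    rows <- plan[plan$utr_id == uid, , drop = FALSE]
    need <- sum(rows$n_sites * (nchar(mirnas[rows$mirna_id]) + 2))
    if (need > utr_length)
      stop("UTR length too short to host requested sites: ", uid)
    done <- FALSE
    for (attempt in 1:50) {
      seqs <- patch_background(rand_seq(1, utr_length, DNA_BASES))
      placed <- list(); local_rows <- list(); ok <- TRUE
      for (r in seq_len(nrow(rows))) {
        if (rows$n_sites[r] == 0) next
        m <- mirnas[[rows$mirna_id[r]]]
        site <- if (rows$extended[r]) to_dna(revcomp(m)) else
          to_dna(revcomp(substr(m, 1, 8)))
        slen <- nchar(site)
        for (s in seq_len(rows$n_sites[r])) {
          pos0 <- NA
          for (try in 1:200) {
            cand <- sample.int(utr_length - slen, 1)      # 0-based
            iv <- c(cand, cand + slen)
            clash <- any(vapply(placed, function(o)
              iv[1] < o[2] + 2 && o[1] < iv[2] + 2, logical(1)))
            if (!clash) { pos0 <- cand; break }
          }
          if (is.na(pos0)) { ok <- FALSE; break }
          substr(seqs, pos0 + 1, pos0 + slen) <- site
          placed <- c(placed, list(c(pos0, pos0 + slen)))
          local_rows[[length(local_rows) + 1]] <-
            data.frame(utr_id = uid, mirna_id = rows$mirna_id[r],
                       site = s, start = pos0, end = pos0 + slen,
                       extended = rows$extended[r])
        }
        if (!ok) break
      }
      if (!ok) next
      # verify: realized canonical core counts equal the plan
      counts_ok <- all(vapply(seq_len(nrow(rows)), function(r) {
        core <- cores[[rows$mirna_id[r]]]
        p <- gregexpr(core, seqs, fixed = TRUE)[[1]]
        n_found <- if (p[1] == -1) 0L else length(p)
        n_found == rows$n_sites[r]
      }, logical(1)))
      others <- setdiff(names(mirnas), rows$mirna_id)
      clean_ok <- all(vapply(others, function(mid) {
        p <- gregexpr(cores[[mid]], seqs, fixed = TRUE)[[1]]
        p[1] == -1
      }, logical(1)))
      if (counts_ok && clean_ok) {
        for (lr in local_rows) { k <- k + 1; site_rows[[k]] <- lr }
        done <- TRUE
        break
      }
    }
    if (!done) stop("failed to realize planted site plan for ", uid)
    utrs[[uid]] <- seqs
  }
  sites <- do.call(rbind, Filter(Negate(is.null), site_rows))
  if (is.null(sites)) {
    sites <- data.frame(utr_id = character(0), mirna_id = character(0),
                        site = integer(0), start = integer(0),
                        end = integer(0), extended = logical(0))
    pairs <- data.frame(utr_id = character(0), mirna_id = character(0),
                        n_sites = integer(0))
  } else {
    pairs <- stats::aggregate(site ~ utr_id + mirna_id, data = sites,
                              FUN = length)
    names(pairs)[3] <- "n_sites"
  }
  zero <- plan[plan$n_sites == 0, c("utr_id", "mirna_id")]
  if (nrow(zero) > 0) {
    zero$n_sites <- 0L
    pairs <- rbind(pairs, zero)
  }
  list(utrs = utrs, truth = list(sites = sites, pairs = pairs))
}
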