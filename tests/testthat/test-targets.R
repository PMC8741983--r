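test_that("seed sites are found and typed by the canonical taxonomy", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  # 8mer: revcomp of nt 1-8 places the m8 match left and an A right
  utr8 <- paste0("GGGGG", revcomp(substr(m, 1, 8)), "GGGGG")
  s8 <- find_seed_sites(m, utr8)
  expect_equal(s8$site_type, "8mer")
  # 6mer only: core complement with non-matching flanks
  utr6 <- paste0("GGGGG", revcomp(substr(m, 2, 7)), "GGGGG")
  s6 <- find_seed_sites(m, utr6)
  expect_equal(s6$site_type, "6mer")
  expect_equal(s6$end - s6$start, 6)
  # 7mer-A1: A to the right of the core only
  utr7 <- paste0("GGGGG", revcomp(substr(m, 2, 7)), "AGGGG")
  expect_equal(find_seed_sites(m, utr7)$site_type, "7mer-A1")
  expect_error(find_seed_sites("UGAGNUAGUA", "ACGU"), "outside")

  # site-free background: zero sites, matching an exhaustive string scan
  cfg <- sim_config(rng_seed = 3)
  mir <- random_matures(10, seed = 3)
  plan <- data.frame(utr_id = "bg", mirna_id = names(mir)[1],
                     n_sites = 0L, extended = TRUE)
  gu <- gen_utr_targets(cfg, mir, plan, utr_length = 2000)
  for (mm in mir)
    expect_equal(nrow(find_seed_sites(mm, gu$utrs[["bg"]])), 0)
})

test_that("duplex energy equals the hand-summed stack table on a full duplex", {
  # independent copy of the Watson-Crick nearest-neighbour table
  xia <- c(AA = -0.93, AU = -1.10, AC = -2.24, AG = -2.08,
           UA = -1.33, UU = -0.93, UC = -2.35, UG = -2.11,
           CA = -2.11, CU = -2.08, CC = -3.26, CG = -2.36,
           GA = -2.35, GU = -2.24, GC = -3.42, GG = -3.26)
  set.seed(4)
  for (rep_i in 1:5) {
    m <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    hand <- sum(xia[substring(m, 1:21, 2:22)])
    expect_equal(duplex_energy(m, revcomp(m)), hand)
  }
  # no complementary dinucleotide anywhere: energy 0
  expect_equal(duplex_energy("AAAAAA", "AAAAAA"), 0)
  expect_equal(duplex_energy("ACACAC", "CACACA"), 0)
  # invariant under reverse-complement relabeling of both strands
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  w <- paste0("CCAAC", revcomp(substr(m, 1, 12)), "AAGGG")
  expect_equal(duplex_energy(m, w), duplex_energy(revcomp(w), revcomp(m)))
  expect_error(duplex_energy("ACGU", ""), "window")
})

test_that("interaction filter applies strict energy, site-count and expression rules", {
  sites <- data.frame(utr_id = c("u1", "u1", "u2", "u2", "u3"),
                      mirna_id = "mirA")
  energies <- c(-15, -15, -15, -9.5, -25)
  em <- c(mirA = 50)
  eu <- c(u1 = 40, u2 = 40, u3 = 40)
  res <- filter_interactions(sites, energies, em, eu)
  expect_true(res$passes_filters[res$mrna_id == "u1"])
  expect_false(res$passes_filters[res$mrna_id == "u2"])   # 1 surviving site
  expect_false(res$passes_filters[res$mrna_id == "u3"])   # single site

  # boundary: exactly -10 fails the strict cutoff
  res10 <- filter_interactions(data.frame(utr_id = c("u1", "u1"),
                                          mirna_id = "mirA"),
                               c(-10, -10), em, eu["u1"])
  expect_false(res10$passes_filters)
  expect_equal(res10$n_sites, 0)

  # unexpressed partner blocks the interaction
  res_lo <- filter_interactions(sites[1:2, ], energies[1:2],
                                c(mirA = 9.9), eu)
  expect_false(res_lo$passes_filters)

  # monotone in the cutoff: relaxing never removes a passing interaction
  r_strict <- filter_interactions(sites, energies, em, eu, energy_cutoff = -12)
  r_loose <- filter_interactions(sites, energies, em, eu, energy_cutoff = -8)
  expect_true(all(r_loose$passes_filters >= r_strict$passes_filters))

  expect_error(filter_interactions(sites, energies, em, eu["u1"]),
               "unknown partner")
})

test_that("planted interactions are recovered through the whole target pipeline", {
  cfg <- sim_config(rng_seed = 17)
  mir <- random_matures(4, seed = 17)
  plan <- expand.grid(utr_id = paste0("u", 1:6), mirna_id = names(mir)[1:2],
                      stringsAsFactors = FALSE)
  set.seed(17)
  plan$n_sites <- sample(0:2, nrow(plan), replace = TRUE)
  plan$extended <- TRUE
  gu <- gen_utr_targets(cfg, mir, plan, utr_length = 1500)
  em <- setNames(rep(100, length(mir)), names(mir))
  eu <- setNames(rep(100, length(gu$utrs)), names(gu$utrs))
  rows <- list()
  for (mid in names(mir)) for (uid in names(gu$utrs)) {
    ss <- find_seed_sites(mir[[mid]], gu$utrs[[uid]])
    if (nrow(ss) == 0) next
    for (i in seq_len(nrow(ss))) {
      win <- substr(gu$utrs[[uid]], max(1, ss$start[i] - 22), ss$end[i] + 22)
      rows[[length(rows) + 1]] <-
        data.frame(utr_id = uid, mirna_id = mid,
                   dG = duplex_energy(mir[[mid]], win))
    }
  }
  found <- do.call(rbind, rows)
  res <- filter_interactions(found[, c("utr_id", "mirna_id")], found$dG, em, eu)
  for (i in seq_len(nrow(plan))) {
    r <- res[res$mirna_id == plan$mirna_id[i] & res$mrna_id == plan$utr_id[i], ]
    if (plan$n_sites[i] >= 2) {
      expect_true(nrow(r) == 1 && r$passes_filters)
    } else {
      expect_true(nrow(r) == 0 || !r$passes_filters)
    }
  }
})

test_that("hypergeometric enrichment matches exact combinatorial enumeration", {
  # m=5 targeted, n=5 not, cluster k=4 with q=3: upper tail = 55/210
  targeted <- setNames(rep(c(TRUE, FALSE), each = 5), paste0("g", 1:10))
  clusters <- setNames(c(rep("c1", 3), "c2", "c2", rep("c2", 4), "c1"),
                       paste0("g", 1:10))
  res <- targeting_enrichment(targeted, clusters)
  r1 <- res[res$cluster == "c1", ]
  expect_equal(r1$q, 3)
  expect_equal(r1$k, 4)
  expect_equal(r1$p_over, 55 / 210, tolerance = 1e-12)
  expect_equal(r1$p_over, oracle_hyper_upper(3, 5, 5, 4), tolerance = 1e-15)
  expect_equal(r1$p_under, oracle_hyper_lower(3, 5, 5, 4), tolerance = 1e-15)
  # the two tails share P(X = q), so they sum to >= 1
  expect_gte(r1$p_over + r1$p_under, 1)

  set.seed(7)
  for (i in 1:30) {
    m <- sample(2:30, 1); n <- sample(2:30, 1)
    k <- sample(1:(m + n - 1), 1)
    q <- sample(max(0, k - n):min(m, k), 1)
    expect_equal(phyper(q - 1, m, n, k, lower.tail = FALSE),
                 oracle_hyper_upper(q, m, n, k), tolerance = 1e-12)
  }

  # cluster at exactly the population rate: both tails >= 0.5
  t2 <- setNames(rep(c(TRUE, FALSE), 10), paste0("h", 1:20))
  c2 <- setNames(rep(c("a", "b"), each = 10), paste0("h", 1:20))
  res2 <- targeting_enrichment(t2, c2)
  expect_true(all(res2$p_over >= 0.5 | res2$p_under >= 0.5))
})

test_that("Mann-Whitney is exact under ties for small groups", {
  r <- mann_whitney(c(1, 1, 2), c(5, 6, 7))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)      # 2 of the 20 arrangements as extreme
  expect_true(r$exact)

  # identical multisets: p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # 100 random tied instances vs the rank-sum enumeration oracle
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }

  # tie-free case agrees with wilcox.test's exact distribution
  set.seed(12)
  x <- sample(1:100, 6); y <- sample(101:200, 5)
  w <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mann_whitney(x, y)$p_value, w$p.value, tolerance = 1e-12)
})

test_that("burden tests compare clusters pairwise with Bonferroni", {
  inter <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m1", "m1", "m2", "m1", "m2", "m3"),
    mrna_id = c("a1", "a1", "a1", "a2", "b1", "b1", "b2", "b2", "b2"),
    n_sites = 2L, passes_filters = TRUE)
  clusters <- c(a1 = "cA", a2 = "cA", b1 = "cB", b2 = "cB", c1 = "cC")
  res <- targeting_burden_tests(inter, clusters)
  expect_setequal(unique(res$metric), c("n_mirnas", "n_sites"))
  # cluster C has no targeted mRNAs: its pairs are skipped with a note
  skipped <- res[res$cluster_b == "cC" | res$cluster_a == "cC", ]
  expect_true(all(skipped$note != ""))
  tested <- res[res$note == "", ]
  expect_true(all(tested$padj >= tested$p_value - 1e-12))
  expect_true(all(tested$padj <= 1))

  # identical value multisets: adjusted p = 1
  inter2 <- data.frame(
    mirna_id = rep(c("m1", "m2"), 4),
    mrna_id = rep(c("x1", "x2", "y1", "y2"), each = 2),
    n_sites = 2L, passes_filters = TRUE)
  cl2 <- c(x1 = "cX", x2 = "cX", y1 = "cY", y2 = "cY")
  res2 <- targeting_burden_tests(inter2, cl2)
  expect_true(all(res2$p_value == 1))
})
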