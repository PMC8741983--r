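test_that("median-of-ratios matches closed forms and the DESeq2 oracle", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  nr <- normalize_median_of_ratios(m)
  expect_equal(unname(nr$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(nr$normalized[, "a"], nr$normalized[, "b"])

  m2 <- cbind(a = c(5, 50, 500), b = c(5, 50, 500))
  rownames(m2) <- paste0("f", 1:3)
  expect_equal(unname(normalize_median_of_ratios(m2)$size_factors), c(1, 1))

  # scaling one of m samples by c shifts the geometric-mean reference by
  # c^(1/m): its size factor scales by exactly c^(1-1/m) and the
  # normalized matrix changes only by one global constant
  set.seed(1)
  m3 <- matrix(rpois(200, 100), 20, 10,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  n0 <- normalize_median_of_ratios(m3)
  m4 <- m3; m4[, 3] <- m4[, 3] * 4
  n1 <- normalize_median_of_ratios(m4)
  expect_equal(n1$size_factors[3] / n0$size_factors[3], 4^(1 - 1 / 10),
               tolerance = 1e-9, ignore_attr = TRUE)
  rel_change <- n1$normalized / n0$normalized
  expect_lt(diff(range(rel_change)), 1e-9)

  # independent implementation oracle
  skip_if_not_installed("DESeq2")
  expect_equal(unname(nr$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
  expect_equal(unname(n0$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)))

  expect_error(normalize_median_of_ratios(diag(0:1)), "nonzero")
})

test_that("planted library-size multipliers are recovered within 5%", {
  # resequencing the same flat library at different depths: counting
  # noise only, so the planted multiplier is the estimand
  cfg <- sim_config(rng_seed = 21, archetype_fractions = c(flat = 1),
                    nb_dispersion = 0)
  g <- gen_count_matrix(cfg, "mirna", n_features = 50)
  sf <- normalize_median_of_ratios(g$counts)$size_factors
  lam <- g$truth$samples$lambda
  rel <- (sf / lam) / exp(mean(log(sf / lam)))
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("expressed filter is inclusive at the threshold and matches a scan", {
  m <- rbind(low = rep(9.9, 8), edge = c(10, 10, rep(0, 6)),
             high = rep(50, 8))
  colnames(m) <- paste0("S", rep(1:4, each = 2), "_r", rep(1:2, 4))
  samp <- data.frame(sample_id = colnames(m),
                     time_point = rep(1:4, each = 2), replicate = rep(1:2, 4))
  kept <- expressed_filter(m, samp)
  expect_setequal(kept, c("edge", "high"))

  set.seed(3)
  m2 <- matrix(rexp(400, 1 / 12), 50, 8, dimnames = list(paste0("f", 1:50),
                                                         colnames(m)))
  kept2 <- expressed_filter(m2, samp)
  tmeans <- sapply(1:4, function(tp)
    rowMeans(m2[, samp$sample_id[samp$time_point == tp]]))
  expect_setequal(kept2, rownames(m2)[apply(tmeans, 1, max) >= 10])
})

test_that("time-point Spearman matrix is rank-invariant, symmetric, tie-aware", {
  set.seed(2)
  base <- rexp(50, 1 / 50)
  m <- cbind(A1 = base, B1 = base^2 + 3,        # strictly increasing transform
             C1 = max(base) - base)             # reversed ranks
  rownames(m) <- paste0("f", 1:50)
  samp <- data.frame(sample_id = colnames(m), time_point = 1:3, replicate = 1)
  r <- timepoint_correlation(m, samp)
  expect_equal(unname(r["T1", "T2"]), 1)
  expect_equal(unname(r["T1", "T3"]), -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  # ties handled by average ranks: agree with rank-formula oracle
  m2 <- cbind(A1 = sample(rep(1:10, 5)), B1 = sample(rep(1:5, 10)))
  rownames(m2) <- paste0("g", 1:50)
  samp2 <- data.frame(sample_id = colnames(m2), time_point = 1:2, replicate = 1)
  r2 <- timepoint_correlation(m2, samp2)
  expect_equal(unname(r2["T1", "T2"]), oracle_spearman(m2[, 1], m2[, 2]))
})

test_that("z-score profiles are standardised and constant rows zeroed", {
  m <- rbind(v = c(1, 5, 9, 13), const = rep(7, 4))
  colnames(m) <- paste0("S", 1:4, "_r1")
  samp <- data.frame(sample_id = colnames(m), time_point = 1:4, replicate = 1)
  z <- zscore_profiles(m, samp)
  expect_equal(mean(z["v", ]), 0)
  expect_equal(sd(z["v", ]), 1)
  expect_equal(unname(z["const", ]), rep(0, 4))
})

test_that("fuzzy c-means recovers planted groups and obeys its identities", {
  set.seed(5)
  g1 <- matrix(rnorm(50 * 4, -1, 0.1), 50, 4)
  g2 <- matrix(rnorm(50 * 4, +1, 0.1), 50, 4)
  x <- rbind(g1, g2)
  rownames(x) <- paste0("f", 1:100)
  fit <- fuzzy_cmeans(x, 2, rng_seed = 11)
  planted <- rep(1:2, each = 50)
  agree <- max(mean(fit$hard_label == planted),
               mean(fit$hard_label == 3 - planted))
  expect_equal(agree, 1)
  expect_true(all(apply(fit$membership, 1, max) > 0.9))
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(diff(fit$objective) <= 1e-8))

  # equidistant point between two symmetric centers: memberships 1/2
  x2 <- rbind(matrix(rep(c(-1, 1), each = 20), 40, 2, byrow = FALSE))
  x2 <- rbind(matrix(-1, 20, 2), matrix(1, 20, 2), c(0, 0))
  rownames(x2) <- paste0("p", 1:41)
  fit2 <- fuzzy_cmeans(x2, 2, rng_seed = 3)
  expect_equal(unname(fit2$membership[41, ]), c(0.5, 0.5), tolerance = 1e-3)

  # a feature at (or numerically at) a center gets membership near 1
  at_center <- which(apply(x2[1:40, ], 1, function(r) all(r == -1)))[1]
  expect_gt(max(fit2$membership[at_center, ]), 0.99)

  # fuzzifier near 1 approaches k-means hard labels
  fit3 <- fuzzy_cmeans(x, 2, fuzzifier = 1.05, rng_seed = 11)
  km <- kmeans(x, centers = fit3$centers)
  expect_gte(max(mean(fit3$hard_label == km$cluster),
                 mean(fit3$hard_label == 3 - km$cluster)), 0.99)
})

test_that("re-implemented c-means agrees with the reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(17)
  x <- rbind(matrix(rnorm(120, -2, 0.3), 30, 4),
             matrix(rnorm(120, 0, 0.3), 30, 4),
             matrix(rnorm(120, 2, 0.3), 30, 4))
  rownames(x) <- paste0("f", 1:90)
  fit <- fuzzy_cmeans(x, 3, rng_seed = 2)
  ref <- e1071::cmeans(x, centers = 3, m = 2)
  # same partition up to label permutation
  tab <- table(fit$hard_label, ref$cluster)
  expect_equal(sum(apply(tab, 1, max)), 90)
  # centers coincide after matching
  map <- apply(tab, 1, which.max)
  expect_equal(unname(fit$centers), unname(ref$centers[map, ]),
               tolerance = 0.05)
})

test_that("elbow selection finds four planted archetypes and flags flat curves", {
  cfg <- sim_config(rng_seed = 41)
  g <- gen_count_matrix(cfg, "mirna", n_features = 400)
  nr <- normalize_median_of_ratios(g$counts)
  keep <- expressed_filter(nr$normalized, g$counts$samples)
  z <- zscore_profiles(nr$normalized[keep, ], g$counts$samples)
  el <- elbow_select_k(z, 2:8, rng_seed = 4)
  expect_equal(el$k, 4)
  expect_false(el$flagged)
  expect_true(all(diff(el$objective) <= 1e-8))  # objective non-increasing in k

  set.seed(6)
  noise <- matrix(rnorm(600), 100, 6, dimnames = list(paste0("f", 1:100), NULL))
  el2 <- elbow_select_k(noise, 2:6, rng_seed = 4)
  expect_true(is.numeric(el2$objective))
  expect_true(el2$k %in% 2:6)
})

test_that("composition test matches the closed-form statistic", {
  # observed (42, 19) at p = 0.5: X2 = 2 * 11.5^2 / 30.5
  lab <- rep(1, 61)
  novel <- c(rep(TRUE, 42), rep(FALSE, 19))
  res <- composition_test(lab, novel, population_ratio = 0.5)
  expect_equal(res$statistic, 2 * 11.5^2 / 30.5)
  expect_equal(res$p_value, pchisq(2 * 11.5^2 / 30.5, 1, lower.tail = FALSE))

  # observed proportions equal to p give a zero statistic
  res2 <- composition_test(rep(1, 10), rep(c(TRUE, FALSE), 5),
                           population_ratio = 0.5)
  expect_equal(res2$statistic, 0)

  # exhaustive enumeration of the null at N <= 10: the chi-squared tail
  # ordering agrees with the exact binomial tail ordering
  N <- 8; p <- 0.4
  qs <- 0:N
  stats <- vapply(qs, function(q) {
    obs <- c(q, N - q); expd <- c(N * p, N * (1 - p))
    sum((obs - expd)^2 / expd)
  }, numeric(1))
  probs <- dbinom(qs, N, p)
  exact_tail <- vapply(qs, function(q)
    sum(probs[stats >= stats[q + 1] - 1e-12]), numeric(1))
  asym <- pchisq(stats, 1, lower.tail = FALSE)
  expect_equal(order(exact_tail), order(asym))

  expect_true(composition_test(rep(1, 2), c(TRUE, FALSE), 0.1)$low_expected)
  expect_error(composition_test(lab, novel, population_ratio = 1.2), "0, 1")
})
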