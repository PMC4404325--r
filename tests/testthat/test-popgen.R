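test_that("diversity statistics match closed forms", {
  set.seed(601)
  # n = 10, all haplotypes distinct -> HD exactly 1
  aln <- t(sapply(1:10, function(i) mutate_sites(random_seq(100), i)))
  div <- basic_diversity(aln)
  expect_identical(div$HD, 1)

  # two sequences differing at 1 of 100 sites
  a <- random_seq(100)
  b <- a; b[7] <- setdiff(c("A", "C", "G", "T"), a[7])[1]
  d2 <- basic_diversity(rbind(a, b))
  expect_equal(d2$k, 1)
  expect_equal(d2$pi, 0.01)
  expect_equal(d2$S, 1L)
  expect_equal(d2$eta_s, 1L)

  same <- rbind(a, a)
  d0 <- basic_diversity(same)
  expect_equal(d0$S, 0L)
  expect_equal(d0$HD, 0)
  expect_equal(d0$pi, 0)

  expect_error(basic_diversity(matrix("A", 1, 5)), "at least 2")
})

test_that("Tajima's D matches a hand-computed case and its zero point", {
  # n=4, S=3, k=1.5: worked through Tajima's coefficients by hand
  expect_equal(tajimas_d(4, 3, 1.5), -0.7544, tolerance = 1e-3)
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(10, 5, 5 / a1), 0, tolerance = 1e-12)
  expect_true(is.na(tajimas_d(10, 0, 0)))
})

test_that("Fu & Li's D* is negative under a singleton excess", {
  r <- fu_li_tests(10, eta = 20, eta_s = 20, k = 3)
  expect_lt(r$Dstar, 0)
  expect_lt(r$Fstar, 0)
  r0 <- fu_li_tests(10, eta = 0, eta_s = 0, k = 0)
  expect_true(is.na(r0$Dstar))
})

test_that("Fu's Fs reproduces the two-sequence Ewens case", {
  expect_equal(fus_fs(2, 1, 2), 0, tolerance = 1e-12)
  expect_true(is.na(fus_fs(5, 2, 1)))      # single haplotype: S' = 1
  expect_true(is.na(fus_fs(5, 0, 3)))      # k = 0 undefined
  # many haplotypes for the observed diversity -> strongly negative
  expect_lt(fus_fs(20, 1, 15), -5)
})

test_that("R2 reproduces the two-sequence case", {
  a <- random_seq(50)
  b <- a; b[3] <- setdiff(c("A", "C", "G", "T"), a[3])[1]
  expect_equal(r2_statistic(rbind(a, b)), 0.5)
  expect_true(is.na(r2_statistic(rbind(a, a))))
})

test_that("statistics are invariant to collapsing and re-expanding", {
  set.seed(602)
  base <- random_seq(120)
  aln <- rbind(base, base, mutate_sites(base, 2), mutate_sites(base, 4),
               mutate_sites(base, 4))
  rownames(aln) <- paste0("s", 1:5)
  tab <- collapse_haplotypes(barcodegap::as_alignment(aln), min_len = 120)
  back <- expand_haplotypes(tab)[rownames(aln), ]
  expect_equal(neutrality_stats(back), neutrality_stats(aln))
  expect_equal(basic_diversity(back)$k, basic_diversity(aln)$k)
})

test_that("fixed-S nulls are reproducible and self-consistent", {
  n1 <- neutral_null(12, S = 8, reps = 300, seed = 7,
                     observed = list(D = 0, Fs = -1))
  n2 <- neutral_null(12, S = 8, reps = 300, seed = 7,
                     observed = list(D = 0, Fs = -1))
  expect_identical(n1$p, n2$p)
  expect_identical(n1$stats, n2$stats)

  # p-value of the null median is about one half
  med <- stats::median(n1$stats[, "Fs"], na.rm = TRUE)
  n3 <- neutral_null(12, S = 8, reps = 1000, seed = 8,
                     observed = list(Fs = med))
  expect_gt(n3$p["Fs"], 0.4)
  expect_lt(n3$p["Fs"], 0.6)
})

test_that("exact differentiation matches complete enumeration", {
  tab <- matrix(c(7, 0, 0, 7), 2, 2)
  res <- exact_differentiation(tab)
  expect_equal(res$method, "exact")
  expect_equal(res$p, 2 / 3432, tolerance = 1e-12)

  same <- matrix(c(3, 4, 3, 4), 2, 2)
  expect_gte(exact_differentiation(same)$p, 0.99)

  expect_error(exact_differentiation(matrix(c(1, 1, 0, 0), 2, 2)),
               "zero samples")
  expect_error(exact_differentiation(matrix(1:3, 3, 1)), "2 populations")

  # Monte-Carlo route (3 populations) is seeded and valid
  t3 <- matrix(c(4, 1, 0, 3, 2, 1, 0, 2, 4), 3, 3)
  r1 <- exact_differentiation(t3, reps = 2000, seed = 5)
  r2 <- exact_differentiation(t3, reps = 2000, seed = 5)
  expect_equal(r1$method, "monte-carlo")
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 0)
  expect_lte(r1$p, 1)
})

test_that("exact test p-values are calibrated under panmixia", {
  set.seed(603)
  reps <- 200
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    haps <- sample(8, 20, replace = TRUE, prob = c(8, 4, 2, 1, 1, 1, 1, 1))
    pop <- sample(rep(1:2, each = 10))
    counts <- table(factor(haps, levels = 1:8), pop)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    ps[r] <- exact_differentiation(counts)$p
  }
  expect_lte(mean(ps <= 0.05), 0.08)     # conservative-to-nominal
  expect_gt(mean(ps), 0.4)
})

test_that("population pooling joins undifferentiated populations", {
  set.seed(604)
  counts <- cbind(P1 = c(6, 3, 1), P2 = c(5, 4, 1), P3 = c(0, 0, 10))
  rownames(counts) <- paste0("h", 1:3)
  res <- pool_populations(counts)
  expect_equal(res$pool[["P1"]], res$pool[["P2"]])
  expect_false(res$pool[["P3"]] == res$pool[["P1"]])
})

test_that("AMOVA separates fixed populations and not panmictic ones", {
  set.seed(605)
  a <- random_seq(200)
  b <- mutate_sites(a, 20)               # ~10% divergent
  seqs <- rbind(a, a, a, a, b, b, b, b)
  rownames(seqs) <- paste0("s", 1:8)
  pops <- rep(c("X", "Y"), each = 4)
  res <- amova(seqs, pops, permutations = 200, seed = 1)
  expect_equal(unname(res$phi["phi_ST"]), 1)
  expect_lt(res$p["phi_ST"], 0.05)

  # all-identical sequences: zero components, p = 1
  same <- rbind(a, a, a, a, a, a)
  rownames(same) <- paste0("t", 1:6)
  res0 <- amova(same, rep(c("X", "Y"), each = 3), permutations = 100)
  expect_equal(unname(res0$components), c(0, 0))
  expect_equal(unname(res0$p["phi_ST"]), 1)

  # a population of one is excluded with a warning
  expect_warning(amova(seqs, c(rep("X", 4), rep("Y", 3), "Z"),
                       permutations = 50), "size 1")
})

test_that("AMOVA keeps the nominal level on panmictic data", {
  set.seed(606)
  ok <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    sim <- simulate_coalescent_sample(12, theta = 4, L = 200,
                                      avoid_stops = FALSE)
    res <- amova(sim$alignment, sample(rep(c("P1", "P2"), each = 6)),
                 model = "p", permutations = 200,
                 seed = r)
    ok <- ok + as.integer(res$p["phi_ST"] > 0.05)
  }
  expect_gte(ok, 24L)
})

test_that("two-level AMOVA decomposes variance into three components", {
  cx <- simulate_species_complex(list(seed = 33, K = 2, between = 0.08,
                                      n = c(8, 8)))
  seqs <- cx$alignment
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  groups <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  res <- amova(seqs, pops, groups = groups, permutations = 100, seed = 2)
  expect_equal(length(res$components), 3L)
  expect_gt(res$phi["phi_CT"], 0.5)      # species split dominates
})

test_that("the per-population table reports statistics and p-values", {
  cx <- simulate_species_complex(list(seed = 34, K = 1, n = 12, theta = 5))
  tab <- population_stats_table(cx$alignment,
                                rep("P1", nrow(cx$alignment)),
                                reps = 300, seed = 9)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("HD", "pi", "D", "Fs", "p_D", "p_Fs") %in% names(tab)))
  expect_true(tab$HD >= 0 && tab$HD <= 1)
  expect_true(all(tab[, startsWith(names(tab), "p_")] <= 1, na.rm = TRUE))
})
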