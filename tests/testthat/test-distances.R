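test_that("closed-form distances behave on canonical cases", {
  expect_equal(pairwise_distance("ACGT", "ACGA", "p"), 0.25)
  for (m in c("p", "jc69", "k2p", "tn93")) {
    expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT", m), 0)
  }
  # p = 0.25 -> JC69 = -(3/4) ln(2/3)
  a <- rep(c("A", "C", "G", "T"), 3)
  b <- a; b[c(1, 5, 9)] <- c("C", "C", "C")
  expect_equal(mean(a != b), 0.25)
  expect_equal(pairwise_distance(a, b, "jc69"), -0.75 * log(1 - 1 / 3),
               tolerance = 1e-12)
  expect_error(pairwise_distance("ACG", "ACGT"), "length mismatch")
})

test_that("saturation is reported as non-estimable, not silent infinity", {
  a <- rep("A", 20)
  b <- rep("G", 20)
  expect_warning(d <- pairwise_distance(a, b, "jc69"), "non-estimable")
  expect_true(is.na(d))
})

test_that("JC69/K2P/TN93 match the ape oracle on random pairs", {
  set.seed(301)
  models <- c(jc69 = "JC69", k2p = "K80", tn93 = "TN93")
  for (r in 1:100) {
    a <- random_seq(300, freqs = c(0.3, 0.2, 0.2, 0.3))
    b <- mutate_sites(a, sample(5:60, 1))
    m <- rbind(a, b)
    rownames(m) <- c("x", "y")
    bin <- ape::as.DNAbin(tolower(m))
    for (mine in names(models)) {
      d_ape <- as.numeric(ape::dist.dna(bin, model = models[[mine]]))
      expect_equal(pairwise_distance(a, b, mine), d_ape, tolerance = 1e-6)
    }
  }
})

test_that("constrained GTR+I with JC constraints collapses to JC69", {
  set.seed(302)
  rates <- setNames(rep(1, 6), c("AC", "AG", "AT", "CG", "CT", "GT"))
  freqs <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  for (r in 1:100) {
    a <- random_seq(400)
    b <- mutate_sites(a, sample(5:80, 1))
    d_jc <- pairwise_distance(a, b, "jc69")
    d_gtr <- pairwise_distance(a, b, "gtr_i", rates = rates, freqs = freqs,
                               pinv = 0)
    expect_equal(d_gtr, d_jc, tolerance = 1e-4)
  }
})

test_that("JC69 approaches p in the low-divergence limit", {
  a <- rep("A", 10000)
  b <- a; b[1] <- "C"
  p <- 1e-4
  expect_lt(abs(pairwise_distance(a, b, "jc69") - p), 1e-6)
})

test_that("model corrections never fall below the p-distance", {
  set.seed(303)
  for (r in 1:25) {
    a <- random_seq(200)
    b <- mutate_sites(a, sample(1:40, 1))
    p <- pairwise_distance(a, b, "p")
    for (m in c("jc69", "k2p", "tn93")) {
      expect_gte(pairwise_distance(a, b, m), p - 1e-12)
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
  set.seed(304)
  base <- random_seq(150)
  aln <- t(sapply(1:5, function(i) mutate_sites(base, i * 3)))
  rownames(aln) <- paste0("h", 1:5)
  dm <- distance_matrix(aln, model = "jc69")
  expect_equal(dm$values, t(dm$values))
  expect_equal(unname(diag(dm$values)), rep(0, 5))
  perm <- c(3, 1, 5, 2, 4)
  dm2 <- distance_matrix(aln[perm, ], model = "jc69")
  expect_equal(dm2$values[rownames(aln), rownames(aln)], dm$values)

  same <- aln[c(1, 1, 1), ]
  rownames(same) <- paste0("x", 1:3)
  expect_equal(unname(distance_matrix(same, model = "p")$values),
               matrix(0, 3, 3))
})

test_that("between-species distances dominate within-species distances", {
  cx <- simulate_species_complex(list(seed = 21, K = 2, between = 0.08,
                                      n = c(6, 6)))
  dm <- distance_matrix(cx$alignment, model = "jc69")
  sp <- cx$truth$species[dm$ids]
  same <- outer(sp, sp, "==")
  within <- dm$values[same & upper.tri(same)]
  between <- dm$values[!same & upper.tri(same)]
  expect_lt(max(within), min(between))
})

test_that("gtr_i matrix machinery estimates pinv and runs end to end", {
  cx <- simulate_species_complex(list(seed = 22, K = 2, between = 0.06,
                                      n = c(5, 5), theta = c(1, 1)))
  dm <- distance_matrix(cx$alignment, model = "gtr_i")
  expect_true(dm$pinv > 0.5)           # mostly constant columns
  expect_equal(dm$values, t(dm$values))
  expect_false(anyNA(dm$values))       # the pinv guard keeps pairs estimable
  # +I stretches distances but broadly preserves the ranking behind the gap
  dmp <- distance_matrix(cx$alignment, model = "p")
  off <- upper.tri(dm$values)
  expect_gt(suppressWarnings(cor(dm$values[off], dmp$values[off],
                                 method = "spearman")), 0.8)
  # within-species pairs stay clearly below between-species pairs
  sp <- cx$truth$species[dm$ids]
  same <- outer(sp, sp, "==")
  expect_lt(max(dm$values[same & off]), min(dm$values[!same & off]))
})
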