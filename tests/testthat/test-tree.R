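test_that("newick parsing reads and normalizes supports", {
  st <- parse_tree("((a,b)95,(c,d)88);")
  expect_equal(length(st$tree$tip.label), 4L)
  expect_setequal(st$tree$node.label[!is.na(st$tree$node.label)], c(95, 88))

  st2 <- parse_tree("((a,b)0.95,(c,d)0.88);")
  expect_setequal(st2$tree$node.label[!is.na(st2$tree$node.label)], c(95, 88))

  expect_error(parse_tree("((a,a),(b,c));"), "duplicate tip")
  expect_error(parse_tree("((a,b"), "malformed")
})

test_that("monophyly follows unrooted bipartition semantics", {
  st <- parse_tree("((a1,a2)90,(b1,b2)80);")
  r <- monophyly_test(st, c("a1", "a2"))
  expect_true(r$monophyletic)
  expect_equal(r$support, 90)

  expect_false(monophyly_test(st, c("a1", "b1"))$monophyletic)

  s <- monophyly_test(st, "a1")
  expect_true(s$monophyletic)
  expect_true(is.na(s$support))

  # complement side of an edge counts
  r2 <- monophyly_test(st, c("a1", "a2", "b1"))
  expect_true(r2$monophyletic)

  expect_error(monophyly_test(st, c("a1", "zz")), "unknown tips")
  expect_error(monophyly_test(st, c("a1", "a2", "b1", "b2")),
               "proper non-empty subset")
})

test_that("monophyly is invariant under re-rooting", {
  set.seed(501)
  for (r in 1:20) {
    tr <- ape::rtree(10)
    tr$node.label <- NULL
    tips <- sample(tr$tip.label, sample(2:8, 1))
    res <- vapply(tr$tip.label[1:3], function(out_tip) {
      rr <- ape::root(tr, outgroup = out_tip, resolve.root = TRUE)
      st <- structure(list(tree = rr, support_scale = "percent"),
                      class = "support_tree")
      monophyly_test(st, tips)$monophyletic
    }, logical(1))
    expect_true(all(res) || !any(res))
  }
})

test_that("monophyly agrees with the ape oracle on random trees", {
  set.seed(502)
  agree <- 0L
  total <- 200L
  n_true <- 0L
  for (r in seq_len(total)) {
    tr <- ape::rtree(12)
    tr$node.label <- NULL
    st <- structure(list(tree = tr, support_scale = "percent"),
                    class = "support_tree")
    # half the cases are genuine clades, so both verdicts are exercised
    tips <- if (r %% 2 == 0) {
      clades <- ape::prop.part(tr)
      cl <- clades[[sample(seq_along(clades)[-1], 1)]]
      tr$tip.label[cl]
    } else sample(tr$tip.label, sample(2:10, 1))
    mine <- monophyly_test(st, tips)$monophyletic
    oracle <- ape::is.monophyletic(ape::unroot(tr), tips)
    n_true <- n_true + as.integer(oracle)
    agree <- agree + as.integer(mine == oracle)
  }
  expect_equal(agree, total)
  expect_gt(n_true, 50L)   # both branches genuinely covered
})

test_that("the Bayes factor formula and its verdict boundary are exact", {
  b0 <- bayes_factor(-100, -100, 3, 3)
  expect_equal(b0$bf, 0)
  expect_false(b0$favored)

  b <- bayes_factor(0, -50, 2, 1)
  expect_equal(b$bf, 100 + log(0.01))
  expect_true(b$favored)

  # BF exactly 10 is favored ("at least 10")
  b10 <- bayes_factor(5, 0, 2, 2)
  expect_equal(b10$bf, 10)
  expect_true(b10$favored)

  # antisymmetry up to the parameter-penalty sign
  fwd <- bayes_factor(-10, -20, 4, 2)$bf
  rev <- bayes_factor(-20, -10, 2, 4)$bf
  expect_equal(fwd + rev, 0)

  expect_error(bayes_factor(Inf, 0, 1, 1), "non-finite")
  expect_error(bayes_factor(0, 0, 0, 1), "positive integers")
})

test_that("posterior consolidation merges weak splits only", {
  part <- structure(data.frame(haplotype = paste0("h", 1:6),
                               species = rep(c("A", "B", "C"), each = 2)),
                    class = c("species_partition", "data.frame"),
                    threshold = 0.027, provenance = "gap")
  posts <- data.frame(species1 = c("A", "B"), species2 = c("B", "C"),
                      posterior = c(1.00, 0.25))
  out <- consolidate_partition(part, posts)
  expect_equal(n_species(out), 2L)                 # B+C merged, A retained
  expect_setequal(unique(out$species), c("A", "B"))

  unchanged <- consolidate_partition(part, posts[0, ])
  expect_equal(unchanged$species, part$species)

  expect_error(consolidate_partition(part,
                                     data.frame(species1 = "A",
                                                species2 = "B",
                                                posterior = 1.2)),
               "\\[0, 1\\]")
  expect_error(consolidate_partition(part,
                                     data.frame(species1 = "A",
                                                species2 = "Z",
                                                posterior = 0.5)),
               "unknown species")

  # merging is commutative across independent splits and never adds species
  posts2 <- posts[2:1, ]
  out2 <- consolidate_partition(part, posts2)
  expect_equal(sort(unique(out2$species)), sort(unique(out$species)))
  expect_lte(n_species(out), n_species(part))
})

test_that("monophyly reports cover the species of a partition", {
  cx <- simulate_species_complex(list(seed = 31, K = 2, between = 0.08,
                                      n = c(4, 4)))
  tab <- collapse_haplotypes(cx$alignment, min_len = 640)
  dm <- distance_matrix(tab, model = "jc69")
  part <- cluster_at_threshold(dm, 0.027)
  # a star-ish tree over the haplotypes grouped by species
  sp <- split(part$haplotype, part$species)
  clade <- function(tips, sup) {
    if (length(tips) == 1) tips
    else paste0("(", paste(tips, collapse = ","), ")", sup)
  }
  nwk <- paste0("(", clade(sp[[1]], 90), ",", clade(sp[[2]], 85), ");")
  rep <- monophyly_report(parse_tree(nwk), part)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$monophyletic))
})
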