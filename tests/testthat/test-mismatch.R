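test_that("mismatch distributions count pairwise differences", {
  a <- random_seq(60)
  m3 <- rbind(a, a, a)
  mm <- mismatch_distribution(m3)
  expect_equal(unname(mm), 3L)                   # all mass at class 0
  expect_equal(names(mm), "0")

  b <- a; b[1:3] <- vapply(a[1:3], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  mm2 <- mismatch_distribution(rbind(a, b))
  expect_equal(unname(mm2[4]), 1L)               # single pair at class 3

  set.seed(701)
  aln <- t(sapply(1:6, function(i) mutate_sites(random_seq(80), i)))
  expect_equal(sum(mismatch_distribution(aln)), choose(6, 2))
})

test_that("expected mismatch distributions match closed forms", {
  st <- expected_mismatch("stationary", list(theta = 1), 10)
  expect_equal(st[1:3], c(0.5, 0.25, 0.125))

  # Poisson limit: theta0 -> 0, theta1 -> Inf
  tau <- 3.2
  dem <- expected_mismatch("demographic",
                           list(tau = tau, theta0 = 0, theta1 = Inf), 30)
  expect_equal(dem[1:25], dpois(0:24, tau), tolerance = 1e-9)

  expect_error(expected_mismatch("stationary", list(theta = -1), 5),
               "negative")
})

test_that("expected mismatch mass is conserved across models and grids", {
  for (theta in c(0.1, 1, 10)) {
    expect_equal(sum(expected_mismatch("stationary", list(theta = theta), 40)),
                 1, tolerance = 1e-9)
  }
  for (tau in c(0, 1, 5, 12)) for (th0 in c(0, 0.5, 2)) {
    expect_equal(sum(expected_mismatch("demographic",
                                       list(tau = tau, theta0 = th0,
                                            theta1 = 50), 60)),
                 1, tolerance = 1e-9)
  }
  for (tau in c(0.5, 4)) for (M in c(0.1, 1, 10)) {
    expect_equal(sum(expected_mismatch("spatial",
                                       list(tau = tau, theta = 1, M = M),
                                       60)),
                 1, tolerance = 1e-9)
  }
})

test_that("raggedness matches its definition", {
  expect_equal(raggedness(rep(0.2, 5)), 0)
  expect_equal(raggedness(c(1, 0)), 1)
  expect_equal(raggedness(c(0.5, 0.25, 0.25)), 0.0625)
})

test_that("fitting an exact model expectation gives SSD ~ 0 and p ~ 1", {
  e <- expected_mismatch("demographic",
                         list(tau = 4, theta0 = 0.5, theta1 = 50), 20)
  counts <- round(e * 10000)
  fit <- fit_expansion(counts, n = 25, bootstrap_reps = 40, seed = 3)
  expect_lt(fit$SSD, 1e-5)
  expect_gt(fit$p_SSD, 0.9)
  expect_equal(fit$tau, 4, tolerance = 0.25)

  fit2 <- fit_expansion(counts, n = 25, bootstrap_reps = 40, seed = 3)
  expect_identical(fit$tau, fit2$tau)
  expect_identical(fit$p_SSD, fit2$p_SSD)

  expect_error(fit_expansion(c(10, 0, 0)), "nonzero mismatch classes")
  expect_error(fit_expansion(counts, bootstrap_reps = 10), "sample size")
})

test_that("the SSD bootstrap holds near its nominal level under expansion", {
  # the goodness-of-fit null is the fitted expansion model itself, so the
  # calibration check simulates under a true sudden expansion
  set.seed(702)
  reps <- 100L
  rej <- 0L
  n_done <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_coalescent_sample(
      30, theta = 50, demography = list(type = "expansion", t = 0.1,
                                        growth = 100),
      mutation = "infinite_sites")
    d <- barcodegap:::mutation_mismatch(sim$genealogy, sim$mut_nodes)
    counts <- tabulate(d + 1, nbins = max(d, 1) + 1)
    if (sum(counts > 0) < 2) next
    fit <- fit_expansion(setNames(counts, seq_along(counts) - 1),
                         n = 30, bootstrap_reps = 60,
                         seed = r, starts = 4)
    n_done <- n_done + 1L
    rej <- rej + as.integer(fit$p_SSD <= 0.05)
  }
  expect_lte(rej / n_done, 0.20)
})

test_that("expansion dating reproduces the published example", {
  d <- date_expansion(6.74, L = 640, generations_per_year = 13.5,
                      pairwise_rate_per_my = 0.065)
  expect_equal(round(d$t_years, -4), 160000)

  expect_equal(date_expansion(0)$t_years, 0)

  d1 <- date_expansion(5, L = 640)
  d2 <- date_expansion(5, L = 1280)
  expect_equal(d1$t_years / d2$t_years, 2, tolerance = 1e-12)

  # linear in tau, inverse-linear in u
  d3 <- date_expansion(10, L = 640)
  expect_equal(d3$t_years / d1$t_years, 2, tolerance = 1e-12)

  expect_error(date_expansion(-1), "non-negative")
  expect_error(date_expansion(1, generations_per_year = 0), "positive")
})
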