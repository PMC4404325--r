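# Per-population diversity and neutrality statistics with
# coalescent-simulation null distributions, exact tests of population
# differentiation, and AMOVA.

# ---- summary statistics from an alignment ----------------------------------

# Per-column resolved-state counts; a segregating site has >= 2 resolved
# states (DnaSP-like; missing data by pairwise deletion elsewhere).
site_state_counts <- function(seqs) {
  apply(seqs, 2, function(col) {
    col <- col[is_resolved(col)]
    if (length(col) == 0) return(integer(0))
    table(col)
  }, simplify = FALSE)
}

# Mean pairwise difference count, pairwise deletion.
mean_pairwise_diff <- function(seqs) {
  n <- nrow(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- pair_mask(seqs[i, ], seqs[j, ])
    tot <- tot + sum(seqs[i, use] != seqs[j, use])
  }
  tot / choose(n, 2)
}

#' Basic diversity statistics for one population sample
#'
#' @param seqs Character matrix of aligned sequences (rows = individuals).
#' @return List with `n`, `L`, `S` (segregating sites), `eta` (total
#'   mutations, counting multi-state sites once per extra state), `eta_s`
#'   (singleton mutations), `k` (mean pairwise differences), `pi`
#'   (`k / L`), `HD` (haplotype diversity `n(1 - sum p_i^2)/(n - 1)`),
#'   `thetaW` (Watterson's estimator per locus, `S / a1`).
#' @export
basic_diversity <- function(seqs) {
  n <- nrow(seqs)
  if (n < 2) stop_input("need at least 2 sequences")
  L <- ncol(seqs)
  tabs <- site_state_counts(seqs)
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (tab in tabs) {
    if (length(tab) >= 2) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + min(sum(tab == 1), length(tab) - 1L)
    }
  }
  k <- mean_pairwise_diff(seqs)
  haps <- apply(seqs, 1, paste, collapse = "")
  p <- table(haps) / n
  HD <- n * (1 - sum(p^2)) / (n - 1)
  a1 <- sum(1 / seq_len(n - 1))
  list(n = n, L = L, S = S, eta = eta, eta_s = eta_s, k = k, pi = k / L,
       HD = HD, thetaW = S / a1)
}

# ---- neutrality statistics --------------------------------------------------

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard Tajima
#' (1989) coefficients.
#'
#' @param n Sample size.
#' @param S Number of segregating sites.
#' @param k Mean pairwise differences.
#' @return D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(n, S, k) {
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu & Li's D* and F* (outgroup-free)
#'
#' Uses the total mutation count `eta` and singleton count `eta_s` with the
#' Simonsen et al. (1995)-corrected variance coefficients (as in
#' DnaSP/libsequence).
#'
#' @param n Sample size.
#' @param eta Total number of mutations.
#' @param eta_s Number of singleton mutations.
#' @param k Mean pairwise differences (needed for F*).
#' @return List with `Dstar` and `Fstar` (`NA` when `eta = 0`).
#' @export
fu_li_tests <- function(n, eta, eta_s, k) {
  if (eta < 1) return(list(Dstar = NA_real_, Fstar = NA_real_))
  i <- seq_len(n - 1)
  a <- sum(1 / i); b <- sum(1 / i^2)
  a1 <- a + 1 / n                       # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (a1 - 2 * n / (n + 1))) / a - vF
  Fstar <- (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  list(Dstar = Dstar, Fstar = Fstar)
}

# Log unsigned Stirling numbers of the first kind, rows up to n (memoized).
.stirling_env <- new.env(parent = emptyenv())

log_stirling_first <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_env[[key]])) return(.stirling_env[[key]])
  ls <- matrix(-Inf, n, n)
  ls[1, 1] <- 0
  if (n > 1) {
    for (r in 2:n) {
      for (cc in seq_len(r)) {
        terms <- c(if (cc > 1) ls[r - 1, cc - 1] else -Inf,
                   if (cc <= r - 1) log(r - 1) + ls[r - 1, cc] else -Inf)
        ls[r, cc] <- logsumexp(terms)
      }
    }
  }
  .stirling_env[[key]] <- ls
  ls
}

#' Fu's Fs
#'
#' `S' = P(K >= K_obs | theta = k)` under the Ewens sampling distribution
#' (Stirling-number recursion in log space), `Fs = ln(S' / (1 - S'))`,
#' with `theta` estimated by the mean pairwise differences `k`.
#'
#' @param n Sample size.
#' @param k Mean pairwise differences (> 0).
#' @param K_obs Observed number of distinct haplotypes.
#' @return Fs; `NA` (with attribute `note`) when the statistic is
#'   undefined (`k = 0`, or `K_obs = 1` giving `S' = 1`).
#' @export
fus_fs <- function(n, k, K_obs) {
  if (is.na(k) || k <= 0) return(NA_real_)
  if (K_obs <= 1) {
    out <- NA_real_
    attr(out, "note") <- "S' = 1 (single haplotype); Fs undefined"
    return(out)
  }
  ls <- log_stirling_first(n)
  ltheta <- log(k)
  lrising <- sum(log(k + 0:(n - 1)))
  lp <- ls[n, seq_len(n)] + seq_len(n) * ltheta - lrising
  lS <- logsumexp(lp[K_obs:n])
  l1mS <- logsumexp(lp[seq_len(K_obs - 1)])
  lS - l1mS
}

#' Ramos-Onsins & Rozas R2 statistic
#'
#' `R2 = sqrt(mean((U_i - k/2)^2)) / S`, where `U_i` is the number of
#' singleton mutations carried by sequence `i`.
#'
#' @param seqs Character matrix of aligned sequences.
#' @return R2, or `NA` when `S = 0`.
#' @export
r2_statistic <- function(seqs) {
  div <- basic_diversity(seqs)
  if (div$S < 1) return(NA_real_)
  n <- div$n
  U <- integer(n)
  for (j in seq_len(ncol(seqs))) {
    col <- seqs[, j]
    res <- is_resolved(col)
    tab <- table(col[res])
    if (length(tab) < 2) next
    for (state in names(tab)[tab == 1]) {
      U[which(res & col == state)] <- U[which(res & col == state)] + 1L
    }
  }
  r2_from_summary(U, div$k, div$S, n)
}

# R2 from summaries (shared with the simulation nulls).
r2_from_summary <- function(U, k, S, n) {
  if (S < 1) return(NA_real_)
  sqrt(sum((U - k / 2)^2) / n) / S
}

# All five test statistics from infinite-sites summaries.
stats_from_summary <- function(sm) {
  fl <- fu_li_tests(sm$n, sm$eta, sm$eta_s, sm$k)
  c(D = tajimas_d(sm$n, sm$S, sm$k),
    Dstar = fl$Dstar, Fstar = fl$Fstar,
    Fs = as.numeric(fus_fs(sm$n, sm$k, sm$K)),
    R2 = r2_from_summary(sm$U, sm$k, sm$S, sm$n))
}

#' Neutrality statistics for one population sample
#'
#' @param seqs Character matrix of aligned sequences.
#' @return Named vector `D`, `Dstar`, `Fstar`, `Fs`, `R2`.
#' @export
neutrality_stats <- function(seqs) {
  div <- basic_diversity(seqs)
  haps <- apply(seqs, 1, paste, collapse = "")
  fl <- fu_li_tests(div$n, div$eta, div$eta_s, div$k)
  c(D = tajimas_d(div$n, div$S, div$k),
    Dstar = fl$Dstar, Fstar = fl$Fstar,
    Fs = as.numeric(fus_fs(div$n, div$k, length(unique(haps)))),
    R2 = r2_statistic(seqs))
}

# ---- coalescent null distributions -----------------------------------------

#' Neutral coalescent null distributions and p-values
#'
#' Simulates standard neutral coalescent genealogies with mutations placed
#' either as exactly `S` draws (multinomial by branch length) or as
#' Poisson(`theta/2` per unit branch length), computes D, D*, F*, Fs and
#' R2 for each replicate, and (optionally) p-values for observed values:
#' two-tailed for D, D* and F* (`2 * min` of the tail probabilities),
#' left-tailed for Fs and R2, each with the observed replicate included in
#' the count. Ties with the observed value contribute half their weight
#' (mid-p): under fixed-S conditioning some statistics (notably D*, a
#' function of the singleton count alone) take few distinct values, and
#' the usual inclusive empirical p-value would be badly conservative.
#'
#' @param n Sample size.
#' @param S Fixed number of segregating mutations (fixed-S conditioning),
#'   or `NULL` to condition on `theta`.
#' @param theta Scaled mutation rate (used when `S` is `NULL`).
#' @param reps Number of replicates (default 16000).
#' @param seed Integer seed.
#' @param observed Optional named list/vector with any of `D`, `Dstar`,
#'   `Fstar`, `Fs`, `R2`.
#' @return List with `stats` (reps x 5 matrix) and `p` (named vector, or
#'   `NULL` when no observed values given).
#' @export
neutral_null <- function(n, S = NULL, theta = NULL, reps = 16000, seed = 1,
                         observed = NULL) {
  if (reps < 100) stop_input("use at least 100 replicates")
  if (is.null(S) && is.null(theta)) stop_input("give S or theta")
  local_seed(seed)
  out <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("D", "Dstar", "Fstar", "Fs", "R2")))
  for (r in seq_len(reps)) {
    gen <- sim_genealogy(n)
    mut <- place_mutations(gen, S = S, theta = theta)
    sm <- mutation_summaries(gen, mut)
    out[r, ] <- stats_from_summary(sm)
  }
  p <- NULL
  if (!is.null(observed)) {
    p <- numeric(0)
    for (nm in intersect(names(observed), colnames(out))) {
      obs <- observed[[nm]]
      if (is.na(obs)) { p[nm] <- NA_real_; next }
      null <- out[, nm]
      null <- null[!is.na(null)]
      if (nm %in% c("Fs", "R2")) {
        p[nm] <- tail_p(null, obs, left = TRUE)
      } else {
        p[nm] <- min(1, 2 * min(tail_p(null, obs, left = TRUE),
                                tail_p(null, obs, left = FALSE)))
      }
    }
  }
  list(stats = out, p = p)
}

# Empirical tail probability with mid-p tie handling; the observed value
# counts as half a tie.
tail_p <- function(null, obs, left = TRUE, tol = 1e-12) {
  m <- length(null)
  eq <- sum(abs(null - obs) < tol)
  strict <- if (left) sum(null < obs - tol) else sum(null > obs + tol)
  (strict + 0.5 * (eq + 1)) / (m + 1)
}

# ---- differentiation --------------------------------------------------------

# log probability of a contingency table under fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Complete enumeration of two-column margin-fixed tables; returns the exact
# p-value, or NULL when the enumeration exceeds `cap` tables.
enumerate_two_pop <- function(tab, lp_obs, cap = 1e6) {
  r <- rowSums(tab); c1 <- colSums(tab)[1]
  n_r <- length(r)
  count <- 0
  p <- 0
  lgr <- sum(lgamma(r + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1)
  rec <- function(i, rem, lacc) {
    if (count > cap) return(FALSE)
    if (i == n_r) {
      if (rem >= 0 && rem <= r[i]) {
        count <<- count + 1
        lp <- lgr + lacc - lgamma(rem + 1) - lgamma(r[i] - rem + 1)
        if (lp <= lp_obs + 1e-9) p <<- p + exp(lp)
      }
      return(TRUE)
    }
    lo <- max(0, rem - sum(r[(i + 1):n_r]))
    hi <- min(r[i], rem)
    if (lo > hi) return(TRUE)
    for (x in lo:hi) {
      ok <- rec(i + 1, rem - x, lacc - lgamma(x + 1) - lgamma(r[i] - x + 1))
      if (!ok) return(FALSE)
    }
    TRUE
  }
  ok <- rec(1, c1, 0)
  if (!ok) return(NULL)
  min(1, p)
}

#' Exact test of population differentiation
#'
#' Tests whether haplotypes are distributed randomly among populations:
#' the p-value is the probability, under fixed row and column margins, of
#' tables as or less likely than the observed one. Two-population tables
#' are enumerated completely when feasible; otherwise (and always for
#' three or more populations) a Monte-Carlo margin-preserving sample
#' (Patefield algorithm, [stats::r2dtable()]) is used.
#'
#' @param counts Integer matrix, haplotypes x populations.
#' @param reps Monte-Carlo table count (default 100000).
#' @param seed Integer seed.
#' @param enumeration_cap Maximum number of tables to enumerate (default
#'   1e6).
#' @return List of class `"differentiation_result"` with `p`, `method`
#'   (`"exact"` or `"monte-carlo"`) and `replicates`.
#' @export
exact_differentiation <- function(counts, reps = 1e5, seed = 1,
                                  enumeration_cap = 1e6) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_input("need at least 2 populations")
  if (nrow(counts) < 2) stop_input("need at least 2 haplotypes")
  if (any(colSums(counts) == 0)) stop_input("population with zero samples")
  lp_obs <- log_table_prob(counts)
  if (ncol(counts) == 2) {
    p <- enumerate_two_pop(counts, lp_obs, cap = enumeration_cap)
    if (!is.null(p)) {
      out <- list(p = p, method = "exact", replicates = NA_integer_)
      class(out) <- "differentiation_result"
      return(out)
    }
  }
  local_seed(seed)
  sims <- stats::r2dtable(reps, rowSums(counts), colSums(counts))
  lps <- vapply(sims, log_table_prob, numeric(1))
  p <- (1 + sum(lps <= lp_obs + 1e-9)) / (reps + 1)
  out <- list(p = p, method = "monte-carlo", replicates = reps)
  class(out) <- "differentiation_result"
  out
}

#' Pool populations that are not significantly differentiated
#'
#' Pairwise exact tests among populations (optionally restricted to those
#' sharing a species and meeting a minimum sample size); populations
#' connected through pairs with `p >= alpha` are pooled (single linkage).
#'
#' @param counts Haplotype x population count matrix.
#' @param species Optional named vector population -> species label; only
#'   same-species pairs are eligible for pooling.
#' @param alpha Significance level below which populations stay separate
#'   (default 0.05).
#' @param min_n Minimum population sample size for testing (default 7).
#' @param reps,seed Passed to [exact_differentiation()].
#' @return List with `pool` (named vector population -> pool label) and
#'   `tests` (data frame of the pairwise tests).
#' @export
pool_populations <- function(counts, species = NULL, alpha = 0.05,
                             min_n = 7, reps = 1e5, seed = 1) {
  pops <- colnames(counts)
  parent <- uf_new(length(pops))
  tests <- data.frame(pop1 = character(0), pop2 = character(0),
                      p = numeric(0))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    if (!is.null(species) && species[pops[i]] != species[pops[j]]) next
    if (sum(counts[, i]) < min_n || sum(counts[, j]) < min_n) next
    sub <- counts[, c(i, j)]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    res <- exact_differentiation(sub, reps = reps,
                                 seed = substream_seed(seed, i * 1000 + j))
    tests <- rbind(tests, data.frame(pop1 = pops[i], pop2 = pops[j],
                                     p = res$p))
    if (res$p >= alpha) parent <- uf_union(parent, i, j)
  }
  comp <- uf_components(parent)
  pool <- vapply(comp, function(cc) pops[min(which(comp == cc))],
                 character(1))
  list(pool = stats::setNames(pool, pops), tests = tests)
}

# ---- AMOVA ------------------------------------------------------------------

#' Analysis of molecular variance (AMOVA)
#'
#' Excoffier-style variance decomposition on squared model-corrected
#' distances among individuals, one level (among/within populations) or
#' two levels (among groups / among populations within groups / within
#' populations), with permutation p-values obtained by permuting
#' individuals among populations.
#'
#' @param seqs Character matrix of aligned sequences (rows = individuals).
#' @param populations Character vector of population labels per row.
#' @param groups Optional named vector population -> group for a two-level
#'   analysis.
#' @param model Distance model (default `"tn93"`).
#' @param permutations Permutation count (default 16000).
#' @param seed Integer seed.
#' @return List of class `"amova_result"` with `components` (named
#'   variance components), `phi` (named Phi statistics), `p` (permutation
#'   p-values), `permutations`.
#' @export
amova <- function(seqs, populations, groups = NULL, model = "tn93",
                  permutations = 16000, seed = 1) {
  populations <- as.character(populations)
  sizes <- table(populations)
  drop <- names(sizes)[sizes < 2]
  if (length(drop) > 0) {
    warning("excluding populations of size 1: ", paste(drop, collapse = ", "))
    keep <- !(populations %in% drop)
    seqs <- seqs[keep, , drop = FALSE]
    populations <- populations[keep]
  }
  if (length(unique(populations)) < 2) stop_input("need >= 2 populations")
  dm <- distance_matrix(seqs, model = model)
  d2 <- dm$values^2
  d2[is.na(d2)] <- max(d2, na.rm = TRUE)

  decomp <- function(pop) {
    N <- length(pop)
    P <- length(unique(pop))
    ss_total <- sum(d2[upper.tri(d2)]) / N
    ss_within <- 0
    for (p in unique(pop)) {
      idx <- which(pop == p)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss_among <- ss_total - ss_within
    df_a <- P - 1
    df_w <- N - P
    msd_a <- ss_among / df_a
    msd_w <- if (df_w > 0) ss_within / df_w else 0
    n0 <- (N - sum(table(pop)^2) / N) / df_a
    sigma_w <- msd_w
    sigma_a <- (msd_a - msd_w) / n0
    tot <- sigma_a + sigma_w
    phi <- if (tot > 0) sigma_a / tot else 0
    list(sigma_a = sigma_a, sigma_w = sigma_w, phi = phi)
  }

  obs <- decomp(populations)
  local_seed(seed)
  phi_perm <- replicate(permutations, decomp(sample(populations))$phi)
  p_st <- (1 + sum(phi_perm >= obs$phi - 1e-12)) / (permutations + 1)
  if (obs$sigma_a == 0 && obs$sigma_w == 0) p_st <- 1

  components <- c(among_populations = obs$sigma_a,
                  within_populations = obs$sigma_w)
  phi <- c(phi_ST = obs$phi)
  p <- c(phi_ST = p_st)

  if (!is.null(groups)) {
    grp <- unname(groups[populations])
    N <- length(populations)
    G <- length(unique(grp))
    ss_total <- sum(d2[upper.tri(d2)]) / N
    ss_wp <- 0
    for (pp in unique(populations)) {
      idx <- which(populations == pp)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_wp <- ss_wp + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss_wg <- 0
    for (g in unique(grp)) {
      idx <- which(grp == g)
      sub <- d2[idx, idx]
      ss_wg <- ss_wg + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ss_ag <- ss_total - ss_wg
    ss_ap <- ss_wg - ss_wp
    df_ag <- G - 1
    df_ap <- length(unique(populations)) - G
    df_wp <- N - length(unique(populations))
    pop_sizes <- table(populations)
    grp_of_pop <- groups[names(pop_sizes)]
    n_g <- tapply(as.numeric(pop_sizes), grp_of_pop, sum)
    n1 <- (N - sum(tapply(as.numeric(pop_sizes)^2, grp_of_pop, sum) /
                     n_g)) / df_ap
    n2 <- (sum(tapply(as.numeric(pop_sizes)^2, grp_of_pop, sum) / n_g) -
             sum(as.numeric(pop_sizes)^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    msd_wp <- if (df_wp > 0) ss_wp / df_wp else 0
    msd_ap <- if (df_ap > 0) ss_ap / df_ap else 0
    msd_ag <- ss_ag / df_ag
    sigma_c <- msd_wp
    sigma_b <- if (df_ap > 0) (msd_ap - sigma_c) / n1 else 0
    sigma_a <- (msd_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    components <- c(among_groups = sigma_a,
                    among_populations_within_groups = sigma_b,
                    within_populations = sigma_c)
    phi <- c(phi_CT = if (tot > 0) sigma_a / tot else 0,
             phi_SC = if (sigma_b + sigma_c > 0)
               sigma_b / (sigma_b + sigma_c) else 0,
             phi_ST = if (tot > 0) (sigma_a + sigma_b) / tot else 0)
  }

  out <- list(components = components, phi = phi, p = p,
              permutations = permutations)
  class(out) <- "amova_result"
  out
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$permutations, "permutations )\n")
  print(round(x$components, 6))
  print(round(x$phi, 4))
  cat("p:", paste(names(x$p), signif(x$p, 3), collapse = ", "), "\n")
  invisible(x)
}

# ---- per-population table ---------------------------------------------------

#' Per-population diversity and neutrality table
#'
#' Computes, for each population with at least `min_n` samples, the full
#' set of diversity and neutrality statistics plus coalescent-simulation
#' p-values (fixed-S conditioning). Statistics are reported as missing
#' when `S = 0`.
#'
#' @param seqs Character matrix of aligned sequences.
#' @param populations Population label per row.
#' @param min_n Minimum sample size (default 4).
#' @param reps Null-simulation replicates (default 16000).
#' @param seed Integer seed.
#' @return Data frame with one row per population: `population`, `n`, `S`,
#'   `pi`, `HD`, `k`, `D`, `Dstar`, `Fstar`, `Fs`, `R2` and `p_` columns.
#' @export
population_stats_table <- function(seqs, populations, min_n = 4,
                                   reps = 16000, seed = 1) {
  pops <- unique(populations)
  rows <- list()
  for (pp in pops) {
    idx <- which(populations == pp)
    if (length(idx) < min_n) next
    sub <- seqs[idx, , drop = FALSE]
    div <- basic_diversity(sub)
    st <- neutrality_stats(sub)
    pvals <- rep(NA_real_, 5)
    names(pvals) <- c("D", "Dstar", "Fstar", "Fs", "R2")
    if (div$S > 0) {
      nn <- neutral_null(div$n, S = div$S, reps = reps,
                         seed = substream_seed(seed, match(pp, pops)),
                         observed = as.list(st))
      pvals[names(nn$p)] <- nn$p
    }
    rows[[pp]] <- data.frame(population = pp, n = div$n, S = div$S,
                             pi = div$pi, HD = div$HD, k = div$k,
                             D = st["D"], Dstar = st["Dstar"],
                             Fstar = st["Fstar"], Fs = st["Fs"],
                             R2 = st["R2"],
                             p_D = pvals["D"], p_Dstar = pvals["Dstar"],
                             p_Fstar = pvals["Fstar"], p_Fs = pvals["Fs"],
                             p_R2 = pvals["R2"], row.names = NULL)
  }
  do.call(rbind, rows)
}
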