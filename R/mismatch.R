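# Mismatch distributions, sudden-expansion model fitting with
# goodness-of-fit (SSD and raggedness, parametric bootstrap), and
# clock-based dating of demographic expansions.

#' Observed mismatch distribution
#'
#' Counts of pairwise difference values over all C(n, 2) pairs (pairwise
#' deletion for missing data).
#'
#' @param seqs Character matrix of aligned sequences.
#' @return Integer vector of counts for difference classes `0..d_max`
#'   (names give the class).
#' @export
mismatch_distribution <- function(seqs) {
  n <- nrow(seqs)
  if (n < 2) stop_input("need at least 2 sequences")
  diffs <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- pair_mask(seqs[i, ], seqs[j, ])
    diffs <- c(diffs, sum(seqs[i, use] != seqs[j, use]))
  }
  counts <- tabulate(diffs + 1, nbins = max(diffs) + 1)
  stats::setNames(counts, 0:(length(counts) - 1))
}

# Stationary (equilibrium) mismatch expectation: F_i = theta^i/(1+theta)^(i+1)
stationary_mismatch <- function(theta, i) {
  if (theta == 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under a demographic model
#'
#' Models: `"stationary"` (`F_i = theta^i / (1 + theta)^(i + 1)`);
#' `"demographic"` (Rogers-Harpending sudden expansion,
#' `F_i(tau, theta0, theta1)`, with `theta1 = Inf` allowed — the Poisson
#' limit `e^-tau tau^i / i!` when additionally `theta0 = 0`); `"spatial"`
#' (infinite-island sudden range expansion with scaled migration `M`:
#' within-deme coalescence racing migration before `tau`, a stationary
#' ancestral phase convolved with Poisson(`tau`) after; experimental).
#' Probability mass beyond `d_max` is folded into the last class, so the
#' result always sums to 1.
#'
#' @param model `"stationary"`, `"demographic"` or `"spatial"`.
#' @param params Named list: `theta` (stationary); `tau`, `theta0`,
#'   `theta1` (demographic); `tau`, `theta`, `M` (spatial).
#' @param d_max Largest difference class.
#' @return Numeric vector of expected relative frequencies for classes
#'   `0..d_max`.
#' @export
expected_mismatch <- function(model = c("stationary", "demographic",
                                        "spatial"),
                              params, d_max) {
  model <- match.arg(model)
  if (any(unlist(params) < 0)) stop_input("negative model parameters")
  i <- 0:d_max
  f <- switch(model,
    stationary = stationary_mismatch(params$theta, i),
    demographic = {
      tau <- params$tau; th0 <- params$theta0; th1 <- params$theta1
      rho <- if (is.infinite(th1)) 0 else 1 / th1
      f1 <- if (rho == 0) rep(0, d_max + 1) else stationary_mismatch(th1, i)
      f0 <- stationary_mismatch(th0, i)
      # F_i = F1_i + exp(-tau(1+rho)) * sum_j tau^j/j! (F0_{i-j} - F1_{i-j})
      pois <- stats::dpois(i, tau) * exp(-tau * rho)
      conv <- stats::convolve(pois, rev(f0 - f1), type = "open")[i + 1]
      f1 + conv
    },
    spatial = {
      tau <- params$tau; th <- params$theta; M <- params$M
      a <- (1 + M) / th                  # rate of "coalesce or migrate"
      b <- 1 + a                         # plus Poisson mutation clock
      within <- (1 / th) * b^(-(i + 1)) * stats::pgamma(b * tau, i + 1)
      w <- 1 - (1 / (1 + M)) * (1 - exp(-a * tau))
      fs <- stationary_mismatch(th, i)
      pois <- stats::dpois(i, tau)
      anc <- stats::convolve(pois, rev(fs), type = "open")[i + 1]
      within + w * anc
    })
  f[d_max + 1] <- max(0, 1 - sum(f[seq_len(d_max)]))
  f
}

#' Harpending's raggedness index
#'
#' `rg = sum_{i=1}^{d} (x_i - x_{i-1})^2` over the mismatch relative
#' frequencies.
#'
#' @param freqs Numeric vector of relative frequencies (classes `0..d`).
#' @return Raggedness.
#' @export
raggedness <- function(freqs) {
  if (length(freqs) < 2) return(0)
  sum(diff(freqs)^2)
}

# SSD between observed relative frequencies and the model expectation.
mismatch_ssd <- function(obs_freq, model, params) {
  e <- expected_mismatch(model, params, d_max = length(obs_freq) - 1)
  sum((obs_freq - e)^2)
}

#' Fit a sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the model expectation to the observed relative
#' frequencies (bounded multi-start Nelder-Mead/L-BFGS-B; `theta1` is
#' parameterized as `1/theta1` in `[0, 2]` so that an infinite
#' post-expansion size lies on the boundary). With `bootstrap_reps > 0`, a
#' parametric bootstrap simulates coalescent samples under the fitted
#' model, refits each, and reports `p_SSD` (fraction of bootstrap SSDs at
#' or above the observed SSD) and `p_rg` (same for raggedness) — the
#' goodness-of-fit convention in which *small* p rejects the expansion
#' model.
#'
#' @param observed Integer vector of mismatch counts (classes `0..d_max`),
#'   e.g. from [mismatch_distribution()].
#' @param model `"demographic"` or `"spatial"`.
#' @param n Sample size behind `observed`; required for the bootstrap.
#' @param bootstrap_reps Parametric bootstrap replicates (default 0: no
#'   p-values; the conventional full analysis uses 16000).
#' @param seed Integer seed.
#' @param starts Number of multi-starts (default 8).
#' @return Object of class `"mismatch_fit"`: list with `model`, `tau`,
#'   `theta0`, `theta1` (possibly `Inf`) or `theta`/`M`, `SSD`, `rg`,
#'   `p_SSD`, `p_rg`, `observed`, `expected`.
#' @export
fit_expansion <- function(observed, model = c("demographic", "spatial"),
                          n = NULL, bootstrap_reps = 0, seed = 1,
                          starts = 8) {
  model <- match.arg(model)
  if (sum(observed > 0) < 2) stop_input("need >= 2 nonzero mismatch classes")
  local_seed(seed)
  obs_freq <- observed / sum(observed)
  d_max <- length(observed) - 1
  fit <- fit_expansion_core(obs_freq, model, starts = starts, seed = seed)
  rg_obs <- raggedness(obs_freq)
  p_SSD <- p_rg <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(n)) stop_input("the bootstrap needs the sample size n")
    ssd_b <- rg_b <- numeric(bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      set.seed(substream_seed(seed, b))
      sim_counts <- simulate_mismatch_sample(n, model, fit$params, d_max)
      sim_freq <- sim_counts / sum(sim_counts)
      # refits only feed the SSD null distribution; a coarser optimizer
      # tolerance and fewer starts suffice there
      refit <- fit_expansion_core(sim_freq, model, starts = 2,
                                  seed = substream_seed(seed, b) + 1,
                                  factr = 1e7)
      ssd_b[b] <- refit$ssd
      rg_b[b] <- raggedness(sim_freq)
    }
    p_SSD <- mean(ssd_b >= fit$ssd - 1e-12)
    p_rg <- mean(rg_b >= rg_obs - 1e-12)
  }
  out <- c(list(model = model, SSD = fit$ssd, rg = rg_obs, p_SSD = p_SSD,
                p_rg = p_rg, observed = observed,
                expected = expected_mismatch(model, fit$params, d_max)),
           fit$params)
  class(out) <- "mismatch_fit"
  out
}

# Core least-squares fit; returns list(params, ssd).
fit_expansion_core <- function(obs_freq, model, starts = 8, seed = 1,
                               factr = 1e4) {
  d_max <- length(obs_freq) - 1
  local_seed(seed)
  tau_hi <- max(2 * d_max, 1)
  if (model == "demographic") {
    lower <- c(0, 0, 0); upper <- c(tau_hi, 20, 2)
    obj <- function(par) {
      params <- list(tau = par[1], theta0 = par[2],
                     theta1 = if (par[3] == 0) Inf else 1 / par[3])
      pen <- if (is.finite(params$theta1) && params$theta0 > params$theta1)
        1e3 * (params$theta0 - params$theta1)^2 else 0
      mismatch_ssd(obs_freq, model, params) + pen
    }
  } else {
    lower <- c(0, 1e-4, 0); upper <- c(tau_hi, 20, 50)
    obj <- function(par) {
      mismatch_ssd(obs_freq, model,
                   list(tau = par[1], theta = par[2], M = par[3]))
    }
  }
  # stratified random multi-starts (Latin-style: one draw per stratum)
  grid <- sapply(seq_along(lower), function(d) {
    strata <- (sample(starts) - stats::runif(starts)) / starts
    lower[d] + strata * (upper[d] - lower[d])
  })
  grid <- rbind(grid, c(sum(obs_freq * seq(0, d_max)), 0.5, upper[3] / 50))
  best <- NULL
  for (s in seq_len(nrow(grid))) {
    o <- tryCatch(stats::optim(pmin(pmax(grid[s, ], lower), upper), obj,
                               method = "L-BFGS-B", lower = lower,
                               upper = upper,
                               control = list(factr = factr)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("mismatch fit failed to converge from any start")
  par <- best$par
  params <- if (model == "demographic") {
    list(tau = par[1], theta0 = par[2],
         theta1 = if (par[3] < 1e-10) Inf else 1 / par[3])
  } else {
    list(tau = par[1], theta = par[2], M = par[3])
  }
  list(params = params, ssd = best$value)
}

# Simulate a mismatch-count vector under a fitted model (coalescent with
# sudden expansion for the demographic model; the spatial model is
# approximated by the demographic coalescent with matched tau/theta, which
# is the component the SSD bootstrap stresses).
simulate_mismatch_sample <- function(n, model, params, d_max) {
  if (model == "demographic") {
    th1 <- min(if (is.infinite(params$theta1)) 1e4 else params$theta1, 1e4)
    th0 <- max(params$theta0, 1e-6)
  } else {
    th1 <- max(params$theta, 1e-4) * (1 + params$M)
    th0 <- max(params$theta, 1e-4)
  }
  tau <- params$tau
  dem <- if (tau > 0) list(type = "expansion", t = tau / th1,
                           growth = min(th1 / th0, 1e8))
         else list(type = "constant")
  gen <- sim_genealogy(n, dem)
  mut <- place_mutations(gen, theta = th1)
  d <- mutation_mismatch(gen, mut)
  counts <- tabulate(pmin(d, d_max) + 1, nbins = d_max + 1)
  counts
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("Mismatch fit (", x$model, "): tau =", signif(x$tau, 4))
  if (x$model == "demographic") {
    cat(", theta0 =", signif(x$theta0, 3), ", theta1 =", signif(x$theta1, 3))
  } else {
    cat(", theta =", signif(x$theta, 3), ", M =", signif(x$M, 3))
  }
  cat("\nSSD =", signif(x$SSD, 4), " rg =", signif(x$rg, 4))
  if (!is.na(x$p_SSD)) cat("  p_SSD =", x$p_SSD, " p_rg =", x$p_rg)
  cat("\n")
  invisible(x)
}

#' Date a demographic expansion from tau
#'
#' Converts the mismatch expansion parameter `tau` (mutational units,
#' `tau = 2 u t`) into generations and years, given the sequence length,
#' the number of generations per year, and a pairwise divergence rate in
#' fraction per million years. The per-sequence per-generation mutation
#' rate is `u = (rate / 2) / 1e6 * L / generations_per_year` (the pairwise
#' rate halves to a per-lineage rate).
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param L Sequence length in sites (default 640).
#' @param generations_per_year Generations per year (default 13.5).
#' @param pairwise_rate_per_my Pairwise divergence rate per million years
#'   (default 0.065, i.e. 6.5%/My).
#' @return Object of class `"expansion_date"`: list with the inputs plus
#'   `u` (per-sequence per-generation rate), `t_generations` and
#'   `t_years`.
#' @examples
#' date_expansion(6.74)  # ~160,000 years before present
#' @export
date_expansion <- function(tau, L = 640, generations_per_year = 13.5,
                           pairwise_rate_per_my = 0.065) {
  if (tau < 0) stop_input("tau must be non-negative")
  if (L <= 0 || generations_per_year <= 0 || pairwise_rate_per_my <= 0) {
    stop_input("length and rates must be positive")
  }
  u <- (pairwise_rate_per_my / 2) / 1e6 * L / generations_per_year
  t_generations <- if (tau == 0) 0 else tau / (2 * u)
  out <- list(tau = tau, L = L,
              generations_per_year = generations_per_year,
              pairwise_rate_per_my = pairwise_rate_per_my, u = u,
              t_generations = t_generations,
              t_years = t_generations / generations_per_year)
  class(out) <- "expansion_date"
  out
}

#' @export
print.expansion_date <- function(x, ...) {
  cat("Expansion dating: tau =", x$tau, "-> ",
      format(round(x$t_years), big.mark = ","), "years before present\n")
  invisible(x)
}
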