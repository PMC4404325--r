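# Model-corrected pairwise distances among haplotypes. P, JC69, K2P and
# TN93 use their closed forms; the constrained GTR+I distance is the
# maximum-likelihood branch length for the pair under a time-reversible
# rate matrix with empirical base frequencies, configurable exchangeability
# equality constraints (default: the TIM3 constraints AC=CG and AT=GT with
# free transitions) and a fixed invariant-site proportion.

DIST_MODELS <- c("p", "jc69", "k2p", "tn93", "gtr_i")

# Sites where both sequences carry an unambiguous base; other IUPAC codes,
# N and gaps are treated as missing for distance purposes.
pair_mask <- function(a, b) is_resolved(a) & is_resolved(b)

#' Pairwise genetic distance between two aligned sequences
#'
#' @param a,b Aligned sequences of equal length (strings or character
#'   vectors).
#' @param model One of `"p"`, `"jc69"`, `"k2p"`, `"tn93"`, `"gtr_i"`.
#' @param rates Named exchangeability vector (`AC`,`AG`,`AT`,`CG`,`CT`,`GT`)
#'   for `gtr_i`; default all equal.
#' @param freqs Base frequencies (named `A`,`C`,`G`,`T`) for `gtr_i`;
#'   default: empirical frequencies of the pair (uniform if missing).
#' @param pinv Proportion of invariant sites for `gtr_i` (default 0).
#' @return Distance in substitutions per site; `NA` with a warning when the
#'   model correction is non-estimable (saturation).
#' @examples
#' pairwise_distance("ACGT", "ACGA", model = "p")      # 0.25
#' @export
pairwise_distance <- function(a, b, model = c("p", "jc69", "k2p", "tn93",
                                              "gtr_i"),
                              rates = NULL, freqs = NULL, pinv = 0) {
  model <- match.arg(model)
  a <- if (length(a) == 1) strsplit(toupper(a), "")[[1]] else toupper(a)
  b <- if (length(b) == 1) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(a) != length(b)) stop_input("sequence length mismatch")
  use <- pair_mask(a, b)
  n <- sum(use)
  if (n == 0) stop_input("no shared resolved sites")
  a <- a[use]; b <- b[use]
  diff <- a != b
  p <- mean(diff)
  if (model == "p") return(p)
  if (model == "jc69") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) { warning("JC69 non-estimable (saturation)"); return(NA_real_) }
    return(-0.75 * log(arg))
  }
  ts_frac <- sum(diff & is_transition(a, b)) / n
  tv_frac <- p - ts_frac
  if (model == "k2p") {
    a1 <- 1 - 2 * ts_frac - tv_frac
    a2 <- 1 - 2 * tv_frac
    if (a1 <= 0 || a2 <= 0) {
      warning("K2P non-estimable (saturation)"); return(NA_real_)
    }
    return(-0.5 * log(a1) - 0.25 * log(a2))
  }
  if (model == "tn93") {
    g <- prop.table(table(factor(c(a, b), levels = BASES)))
    gA <- g["A"]; gC <- g["C"]; gG <- g["G"]; gT <- g["T"]
    gR <- gA + gG; gY <- gC + gT
    P1 <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A"))) / n
    P2 <- sum(diff & ((a == "C" & b == "T") | (a == "T" & b == "C"))) / n
    Q <- tv_frac
    if (gA * gG == 0 || gC * gT == 0 || gR * gY == 0) {
      warning("TN93 non-estimable (degenerate base frequencies)")
      return(NA_real_)
    }
    w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
    w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
      warning("TN93 non-estimable (saturation)"); return(NA_real_)
    }
    d <- -2 * gA * gG / gR * log(w1) - 2 * gC * gT / gY * log(w2) -
      2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
    return(as.numeric(d))
  }
  # gtr_i: ML branch length from the 4x4 site-pattern counts
  if (is.null(freqs)) {
    freqs <- prop.table(table(factor(c(a, b), levels = BASES)))
    freqs <- as.numeric(freqs) + 1e-9
    freqs <- stats::setNames(freqs / sum(freqs), BASES)
  }
  if (is.null(rates)) {
    rates <- stats::setNames(rep(1, 6), c("AC", "AG", "AT", "CG", "CT", "GT"))
  }
  counts <- table(factor(a, levels = BASES), factor(b, levels = BASES))
  gtr_ml_distance(counts, rates, freqs, pinv)
}

# Build a normalized time-reversible rate matrix (mean rate 1).
gtr_rate_matrix <- function(rates, freqs) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("A", "T"),
                 c("C", "G"), c("C", "T"), c("G", "T"))
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  nm <- paste0(pairs[, 1], pairs[, 2])
  for (i in seq_len(6)) {
    x <- pairs[i, 1]; y <- pairs[i, 2]
    Q[x, y] <- rates[nm[i]] * freqs[y]
    Q[y, x] <- rates[nm[i]] * freqs[x]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# P(t) via eigendecomposition of the symmetrized rate matrix.
gtr_transition_prob <- function(eig, freqs, t) {
  sp <- sqrt(freqs)
  P <- (1 / sp) * (eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))) *
    rep(sp, each = 4)
  # guard tiny negative values from round-off
  P[P < 0] <- 0
  P
}

gtr_ml_distance <- function(counts, rates, freqs, pinv) {
  Q <- gtr_rate_matrix(rates, freqs)
  sp <- sqrt(freqs)
  S <- (sp %o% (1 / sp)) * Q        # symmetric similar matrix
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  negll <- function(t) {
    P <- gtr_transition_prob(eig, freqs, t)
    site_p <- (1 - pinv) * freqs * P
    diag(site_p) <- diag(site_p) + pinv * freqs
    site_p[site_p <= 0] <- 1e-300
    -sum(counts * log(site_p))
  }
  opt <- stats::optimize(negll, interval = c(1e-9, 10), tol = 1e-8)
  if (opt$minimum > 10 - 1e-4) {
    warning("GTR+I distance hit the search bound (saturation)")
    return(NA_real_)
  }
  opt$minimum
}

#' Estimate constrained exchangeability rates from an alignment
#'
#' Empirical method-of-moments estimate: substitution-type counts pooled
#' over all sequence pairs, scaled by the product of the base frequencies
#' involved, then averaged within each constraint class. The default
#' classes encode the TIM3 constraints in the jModelTest convention
#' (AC=CG, AT=GT, transitions AG and CT free).
#'
#' @param aln A `"barcode_alignment"` or character matrix of haplotypes.
#' @param classes List of character vectors naming exchangeability classes
#'   over `AC`,`AG`,`AT`,`CG`,`CT`,`GT`.
#' @return Named exchangeability vector normalized so `GT = 1`.
#' @export
estimate_gtr_rates <- function(aln,
                               classes = list(c("AC", "CG"), c("AT", "GT"),
                                              "AG", "CT")) {
  all_pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  if (!setequal(unlist(classes), all_pairs)) {
    stop_input("constraint classes must cover AC, AG, AT, CG, CT, GT exactly")
  }
  n <- nrow(aln)
  freqs <- prop.table(table(factor(as.vector(aln)[is_resolved(as.vector(aln))],
                                   levels = BASES)))
  cnt <- stats::setNames(numeric(6), all_pairs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- aln[i, ]; b <- aln[j, ]
    use <- pair_mask(a, b) & a != b
    if (!any(use)) next
    key <- paste0(pmin(a[use], b[use]), pmax(a[use], b[use]))
    tab <- table(factor(key, levels = all_pairs))
    cnt <- cnt + as.numeric(tab)
  }
  pf <- c(AC = freqs["A"] * freqs["C"], AG = freqs["A"] * freqs["G"],
          AT = freqs["A"] * freqs["T"], CG = freqs["C"] * freqs["G"],
          CT = freqs["C"] * freqs["T"], GT = freqs["G"] * freqs["T"])
  raw <- (cnt + 0.5) / as.numeric(pf)   # half-count smoothing
  rates <- stats::setNames(numeric(6), all_pairs)
  for (cl in classes) rates[cl] <- mean(raw[cl])
  rates / rates["GT"]
}

#' Pairwise distance matrix over haplotypes
#'
#' For `model = "gtr_i"` the base frequencies and exchangeabilities are
#' estimated alignment-wide (see [estimate_gtr_rates()]) and the
#' invariant-site proportion defaults to the observed fraction of constant
#' columns, a simple deterministic estimate (pairwise joint optimization of
#' `pinv` is unidentifiable).
#'
#' @param x A `"haplotype_table"`, `"barcode_alignment"` or character
#'   matrix.
#' @param model Distance model (see [pairwise_distance()]).
#' @param rates,freqs,pinv Optional GTR+I parameters; estimated from the
#'   data when `NULL`.
#' @param classes Constraint classes for [estimate_gtr_rates()].
#' @return Object of class `"dist_matrix"`: list with `values` (symmetric
#'   numeric matrix, `NA` for non-estimable pairs), `model`, `pinv`, `ids`.
#' @export
distance_matrix <- function(x, model = c("p", "jc69", "k2p", "tn93", "gtr_i"),
                            rates = NULL, freqs = NULL, pinv = NULL,
                            classes = list(c("AC", "CG"), c("AT", "GT"),
                                           "AG", "CT")) {
  model <- match.arg(model)
  aln <- if (inherits(x, "haplotype_table")) haplotype_alignment(x) else x
  n <- nrow(aln)
  if (n < 2) stop_input("need at least 2 haplotypes")
  if (model == "gtr_i") {
    if (is.null(pinv)) {
      res <- apply(aln, 2, function(col) {
        col <- col[is_resolved(col)]
        length(col) > 0 && length(unique(col)) == 1
      })
      pinv <- mean(res)
      # estimability guard: the +I mixture can explain at most ~3/4 of the
      # variable fraction as pairwise mismatches; a pinv above this bound
      # (the constant-column proportion overshoots in small structured
      # samples) would push divergent pairs to the saturation boundary
      p_max <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        use <- pair_mask(aln[i, ], aln[j, ])
        if (any(use)) p_max <- max(p_max, mean(aln[i, use] != aln[j, use]))
      }
      pinv <- min(pinv, max(0, 1 - p_max / 0.70))
    }
    if (is.null(freqs)) {
      v <- as.vector(aln)
      freqs <- prop.table(table(factor(v[is_resolved(v)], levels = BASES)))
      freqs <- stats::setNames(as.numeric(freqs), BASES)
    }
    if (is.null(rates)) rates <- estimate_gtr_rates(aln, classes = classes)
  } else {
    if (is.null(pinv)) pinv <- 0
  }
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- suppressWarnings(
      pairwise_distance(aln[i, ], aln[j, ], model = model,
                        rates = rates, freqs = freqs,
                        pinv = if (model == "gtr_i") pinv else 0))
    d[i, j] <- d[j, i] <- dij
  }
  if (anyNA(d)) {
    warning(sum(is.na(d)) / 2, " pair(s) non-estimable under ", model)
  }
  out <- list(values = d, model = model, pinv = pinv, ids = rownames(aln))
  class(out) <- "dist_matrix"
  out
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix (", x$model, "): ", length(x$ids), " haplotypes",
      if (x$model == "gtr_i") paste0(", pinv = ", signif(x$pinv, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Export a distance matrix as TSV
#'
#' @param m A `"dist_matrix"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(m, path) {
  utils::write.table(data.frame(haplotype = m$ids, m$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
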