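# Coalescent synthetic-data generator. Emulates the statistical structure
# the analysis assumes: species clusters separated by target corrected
# divergences, within-species coalescent variation under constant-size or
# sudden-expansion demographies, and numt contaminants. Every dataset
# carries a truth record so downstream stages can be tested against known
# answers.

#' Simulate a neutral coalescent genealogy
#'
#' Hudson coalescent with exponential waiting times, time in units of
#' `2N_present` generations. Under a sudden expansion the coalescence rate
#' is multiplied by `growth` (= N_present / N_ancient) beyond the
#' expansion time.
#'
#' @param n Sample size (>= 2).
#' @param demography Either `list(type = "constant")` or
#'   `list(type = "expansion", t = <scaled time>, growth = <fold change>)`.
#' @param seed Optional integer seed.
#' @return List of class `"genealogy"` with `n`, `parent` (parent index per
#'   node; 0 for the root), `node_time`, `branch_length` (to the parent)
#'   and `total_length`.
#' @export
sim_genealogy <- function(n, demography = list(type = "constant"),
                          seed = NULL) {
  if (n < 2) stop_input("need n >= 2")
  local_seed(seed)
  t_exp <- if (identical(demography$type, "expansion")) demography$t else Inf
  growth <- if (identical(demography$type, "expansion")) demography$growth else 1
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  time <- 0
  while (length(active) > 1) {
    k <- length(active)
    rate <- k * (k - 1) / 2 * (if (time >= t_exp) growth else 1)
    w <- stats::rexp(1, rate)
    if (time < t_exp && time + w > t_exp) { time <- t_exp; next }
    time <- time + w
    pick <- sample(k, 2)
    children <- active[pick]
    parent[children] <- nxt
    node_time[nxt] <- time
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  bl <- numeric(n_nodes)
  has_parent <- parent > 0
  bl[has_parent] <- node_time[parent[has_parent]] - node_time[has_parent]
  out <- list(n = n, parent = parent, node_time = node_time,
              branch_length = bl, total_length = sum(bl))
  class(out) <- "genealogy"
  out
}

# Logical tip-membership matrix (node x tip) for a genealogy.
genealogy_tip_sets <- function(gen) {
  n <- gen$n
  n_nodes <- 2L * n - 1L
  sets <- matrix(FALSE, n_nodes, n)
  sets[cbind(seq_len(n), seq_len(n))] <- TRUE
  ord <- order(gen$node_time[(n + 1):n_nodes]) + n
  for (v in setdiff(seq_len(n_nodes), ord)) {
    if (gen$parent[v] > 0) sets[gen$parent[v], ] <-
        sets[gen$parent[v], ] | sets[v, ]
  }
  # accumulate internal nodes in time order (children coalesce earlier)
  for (v in ord) {
    if (gen$parent[v] > 0) sets[gen$parent[v], ] <-
        sets[gen$parent[v], ] | sets[v, ]
  }
  sets
}

# Place mutations on branches: exactly S (multinomial by branch length) or
# Poisson(theta/2 * total length). Returns the branch (node index) of each
# mutation.
place_mutations <- function(gen, S = NULL, theta = NULL) {
  bl <- gen$branch_length
  nodes <- which(bl > 0)
  probs <- bl[nodes] / sum(bl[nodes])
  m <- if (!is.null(S)) S else stats::rpois(1, theta / 2 * gen$total_length)
  if (m == 0) return(integer(0))
  nodes[sample.int(length(nodes), m, replace = TRUE, prob = probs)]
}

# Infinite-sites summaries from mutation placements: S, eta_s, k, K,
# per-tip singleton counts U. Used by the simulation oracles and the null
# distributions (no sequences needed).
mutation_summaries <- function(gen, mut_nodes, sets = NULL) {
  n <- gen$n
  if (is.null(sets)) sets <- genealogy_tip_sets(gen)
  S <- length(mut_nodes)
  if (S == 0) {
    return(list(n = n, S = 0L, eta = 0L, eta_s = 0L, k = 0, K = 1L,
                U = rep(0L, n)))
  }
  counts <- rowSums(sets[mut_nodes, , drop = FALSE])
  folded <- pmin(counts, n - counts)
  k <- sum(counts * (n - counts)) / choose(n, 2)
  singles <- which(folded == 1)
  U <- integer(n)
  for (m in singles) {
    carrier <- if (counts[m] == 1) which(sets[mut_nodes[m], ])
               else which(!sets[mut_nodes[m], ])
    U[carrier] <- U[carrier] + 1L
  }
  inc <- sets[mut_nodes, , drop = FALSE]
  keys <- apply(inc, 2, function(col) paste(which(col), collapse = ","))
  list(n = n, S = S, eta = S, eta_s = length(singles), k = k,
       K = length(unique(keys)), U = U)
}

# Pairwise-difference counts between all tips from mutation placements.
mutation_mismatch <- function(gen, mut_nodes, sets = NULL) {
  n <- gen$n
  if (is.null(sets)) sets <- genealogy_tip_sets(gen)
  d <- matrix(0L, n, n)
  for (m in mut_nodes) {
    inset <- sets[m, ]
    d[inset, !inset] <- d[inset, !inset] + 1L
  }
  d[upper.tri(d)] + t(d)[upper.tri(d)]
}

# One K2P mutation at a uniformly chosen site; transition with probability
# tstv/(tstv+1). With avoid_stops, mutations creating a frame-0 TAA/TAG
# are rejected (purifying selection on the coding barcode).
mutate_once <- function(s, tstv = 10, avoid_stops = FALSE) {
  L <- length(s)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (try in 1:50) {
    site <- sample.int(L, 1)
    base <- s[site]
    new <- if (stats::runif(1) < tstv / (tstv + 1)) transitions[[base]]
           else sample(setdiff(BASES, c(base, transitions[[base]])), 1)
    if (avoid_stops) {
      cod_start <- site - (site - 1) %% 3
      if (cod_start + 2 <= L) {
        codon <- s[cod_start:(cod_start + 2)]
        codon[site - cod_start + 1] <- new
        if (paste(codon, collapse = "") %in% c("TAA", "TAG")) next
      }
    }
    s[site] <- new
    return(s)
  }
  s
}

# Random codon-structured sequence with no frame-0 stop codons.
random_coding_sequence <- function(L, base_freqs = c(A = 0.3, C = 0.15,
                                                     G = 0.15, T = 0.4)) {
  s <- sample(BASES, L, replace = TRUE, prob = base_freqs[BASES])
  for (p in seq(1, L - 2, by = 3)) {
    while (paste(s[p:(p + 2)], collapse = "") %in% c("TAA", "TAG")) {
      s[p + 2] <- sample(BASES, 1, prob = base_freqs[BASES])
    }
  }
  s
}

# Mutate a copy of `s` until its JC-corrected distance from `s` reaches
# target (within rtol). Finite-site K2P process, optionally stop-avoiding.
evolve_to_distance <- function(s, target, tstv = 10, avoid_stops = TRUE,
                               rtol = 0.05) {
  if (target <= 0) return(s)
  x <- s
  repeat {
    x <- mutate_once(x, tstv = tstv, avoid_stops = avoid_stops)
    p <- mean(x != s)
    d <- if (p < 0.745) -0.75 * log(1 - 4 * p / 3) else Inf
    if (d >= target * (1 - rtol)) return(x)
  }
}

#' Simulate a coalescent sample of barcode sequences
#'
#' Simulates a genealogy with [sim_genealogy()], drops mutations on its
#' branches at rate `theta/2` per unit branch length (or exactly `S` when
#' conditioning on the number of segregating sites) and realizes them
#' either under a finite-site K2P process on an ancestral sequence or as
#' abstract infinite-site mutations.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (per locus); ignored when `S` given.
#' @param demography Passed to [sim_genealogy()].
#' @param L Sequence length in sites.
#' @param seed Optional integer seed.
#' @param S Optional fixed number of mutations (fixed-S conditioning).
#' @param mutation `"k2p"` (finite sites, returns sequences) or
#'   `"infinite_sites"` (returns placements only).
#' @param tstv Transition/transversion ratio of the K2P process.
#' @param ancestral Ancestral sequence (character vector of length `L`);
#'   random codon-clean sequence when `NULL`.
#' @param avoid_stops Reject mutations creating frame-0 stop codons
#'   (default `TRUE`; emulates purifying selection on a real barcode).
#' @return List with `alignment` (character matrix, `NULL` for
#'   infinite-sites mode), `genealogy`, `mut_nodes`, `tip_sets`.
#' @export
simulate_coalescent_sample <- function(n, theta = NULL,
                                       demography = list(type = "constant"),
                                       L = 640, seed = NULL, S = NULL,
                                       mutation = c("k2p", "infinite_sites"),
                                       tstv = 10, ancestral = NULL,
                                       avoid_stops = TRUE) {
  mutation <- match.arg(mutation)
  local_seed(seed)
  if (is.null(theta) && is.null(S)) stop_input("give theta or S")
  gen <- sim_genealogy(n, demography)
  mut_nodes <- place_mutations(gen, S = S, theta = theta)
  sets <- genealogy_tip_sets(gen)
  aln <- NULL
  if (mutation == "k2p") {
    if (is.null(ancestral)) ancestral <- random_coding_sequence(L)
    n_nodes <- 2L * n - 1L
    seqs <- vector("list", n_nodes)
    root <- which(gen$parent == 0)
    seqs[[root]] <- ancestral
    ord <- order(gen$node_time, decreasing = TRUE)   # root first
    for (v in setdiff(ord, root)) {
      s <- seqs[[gen$parent[v]]]
      for (mm in which(mut_nodes == v)) {
        s <- mutate_once(s, tstv = tstv, avoid_stops = avoid_stops)
      }
      seqs[[v]] <- s
    }
    aln <- t(vapply(seqs[seq_len(n)], identity, character(L)))
    rownames(aln) <- paste0("s", seq_len(n))
    aln <- as_alignment(aln)
  }
  list(alignment = aln, genealogy = gen, mut_nodes = mut_nodes,
       tip_sets = sets)
}

#' Simulate a numt contaminant from a source haplotype
#'
#' `"stop"` mode plants in-frame (frame 0) stop codons on top of a few
#' background mutations and guarantees that the stop-minimizing frame
#' still contains at least one stop. `"tv_bias"` mode applies strongly
#' transversion-biased mutations (at least 10 transversions, ts/tv at
#' most 1/6 against the source, so the ratio stays numt-like even after
#' the source's own transition-rich private substitutions are counted
#' against a cluster consensus).
#'
#' @param source Source sequence (character vector or string).
#' @param mode `"stop"` or `"tv_bias"`.
#' @param seed Optional integer seed.
#' @param n_mut Background mutation count (default 12 for `"stop"`; at
#'   least 14, about 2% of a 640-nt barcode, for `"tv_bias"`).
#' @return Contaminant sequence as a character vector.
#' @export
simulate_numt <- function(source, mode = c("stop", "tv_bias"), seed = NULL,
                          n_mut = 12) {
  mode <- match.arg(mode)
  local_seed(seed)
  s <- if (length(source) == 1) strsplit(toupper(source), "")[[1]]
       else toupper(source)
  if (length(s) < 30) stop_input("source too short for a numt simulation")
  L <- length(s)
  if (mode == "stop") {
    for (i in seq_len(n_mut)) s <- mutate_once(s, avoid_stops = FALSE)
    repeat {
      pos <- sample(seq(1, L - 2, by = 3), 1)
      s[pos:(pos + 2)] <- c("T", "A", sample(c("A", "G"), 1))
      if (find_stop_codons(s)$stops >= 1) break
    }
  } else {
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    n_mut <- max(n_mut, 14)
    repeat {
      for (i in seq_len(n_mut)) {
        site <- sample.int(L, 1)
        if (stats::runif(1) < 0.95) {
          s[site] <- sample(transversions[[s[site]]], 1)
        } else {
          s <- mutate_once(s, avoid_stops = FALSE)
        }
      }
      src <- if (length(source) == 1) strsplit(toupper(source), "")[[1]]
             else toupper(source)
      prof <- transversion_excess(s, src, max_tstv = 1, min_diff = 3)
      if (prof$tv >= 10 && (prof$ts / prof$tv) <= 1 / 6) break
      n_mut <- 4
    }
  }
  s
}

#' Simulate a multi-species barcode complex with truth record
#'
#' Species ancestral sequences are placed on an ultrametric caterpillar
#' species tree whose divergence levels are the `between` targets: species
#' `k` (k >= 2) diverges from all of species `1..k-1` at corrected
#' distance `between[k-1]`, realized by iterative K2P mutation until the
#' JC-corrected distance reaches the branch target within 5%. Within each
#' species a coalescent sample is grafted onto the ancestral sequence.
#' Optionally appends numt contaminants.
#'
#' @param cfg List with elements `seed`, `L`, `K`, `between` (length
#'   `K - 1`, increasing), `n` (per-species sample sizes), `theta`
#'   (per-species), `demography` (list per species), `tstv`, `numt`
#'   (`list(count =, mode =)` or `NULL`).
#' @return List with `alignment`, `popmap` (sample/population/host/
#'   country), `truth` (`species` named vector, `numt_ids`, `theta`,
#'   `demography`, per-species genealogies).
#' @export
simulate_species_complex <- function(cfg = list()) {
  defaults <- list(seed = 1, L = 640, K = 3, between = c(0.05, 0.12),
                   n = NULL, theta = NULL, demography = NULL, tstv = 10,
                   numt = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  K <- cfg$K
  if (is.null(cfg$n)) cfg$n <- rep(10, K)
  # theta = 1 keeps even the deepest within-species pair below ~1%
  # divergence on a 640-nt barcode, well clear of a 2.7%-style gap
  if (is.null(cfg$theta)) cfg$theta <- rep(1, K)
  if (is.null(cfg$demography)) {
    cfg$demography <- rep(list(list(type = "constant")), K)
  }
  if (K > 1) {
    if (length(cfg$between) != K - 1) {
      stop_input("need K - 1 between-species divergence targets")
    }
    if (is.unsorted(cfg$between, strictly = FALSE)) {
      stop_input("divergence targets must be non-decreasing (ultrametric ",
                 "levels; otherwise the targets violate the triangle ",
                 "inequality on the species tree)")
    }
  }
  local_seed(cfg$seed)
  root <- random_coding_sequence(cfg$L)
  # backbone node M_k sits at height between[k-1]/2; M_K is the root
  anc <- vector("list", K)
  if (K == 1) {
    anc[[1]] <- root
  } else {
    h <- cfg$between / 2
    backbone <- vector("list", K)      # backbone[[k]] = M_k for k >= 2
    backbone[[K]] <- root
    if (K > 2) {
      # branch from M_{k+1} (height h[k]) down to M_k (height h[k-1])
      for (k in (K - 1):2) {
        backbone[[k]] <- evolve_to_distance(backbone[[k + 1]], h[k] - h[k - 1],
                                            tstv = cfg$tstv)
      }
    }
    anc[[1]] <- evolve_to_distance(backbone[[2]], h[1], tstv = cfg$tstv)
    for (k in 2:K) {
      anc[[k]] <- evolve_to_distance(backbone[[max(k, 2)]], h[k - 1],
                                     tstv = cfg$tstv)
    }
  }
  alns <- list()
  genealogies <- list()
  species <- character(0)
  for (k in seq_len(K)) {
    sim <- simulate_coalescent_sample(cfg$n[k], theta = cfg$theta[k],
                                      demography = cfg$demography[[k]],
                                      L = cfg$L, ancestral = anc[[k]],
                                      tstv = cfg$tstv)
    rownames(sim$alignment) <- sprintf("SP%d_%02d", k, seq_len(cfg$n[k]))
    alns[[k]] <- unclass(sim$alignment)
    genealogies[[k]] <- sim$genealogy
    species <- c(species,
                 stats::setNames(rep(paste0("SP", k), cfg$n[k]),
                                 rownames(sim$alignment)))
  }
  aln <- do.call(rbind, alns)
  numt_ids <- character(0)
  if (!is.null(cfg$numt) && cfg$numt$count > 0) {
    modes <- rep(cfg$numt$mode, length.out = cfg$numt$count)
    # numts descend from historically common mitochondrial lineages, so the
    # contaminant's source is the modal haplotype, not a random deep lineage
    keys <- apply(aln, 1, paste, collapse = "")
    modal <- names(sort(table(keys), decreasing = TRUE))[1]
    for (i in seq_len(cfg$numt$count)) {
      src <- aln[match(modal, keys), ]
      contaminant <- simulate_numt(src, mode = modes[i])
      id <- sprintf("NUMT_%02d", i)
      aln <- rbind(aln, stats::setNames(matrix(contaminant, 1), NULL))
      rownames(aln)[nrow(aln)] <- id
      numt_ids <- c(numt_ids, id)
      species[id] <- "numt"
    }
  }
  popmap <- data.frame(sample = rownames(aln),
                       population = sub("_.*", "", rownames(aln)),
                       host = "synthetic", country = "synthetic",
                       stringsAsFactors = FALSE)
  list(alignment = as_alignment(aln), popmap = popmap,
       truth = list(species = species, numt_ids = numt_ids,
                    theta = cfg$theta, demography = cfg$demography,
                    genealogies = genealogies))
}
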