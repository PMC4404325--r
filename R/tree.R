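# Evaluation of putative species on support-annotated gene trees:
# monophyly under unrooted bipartition semantics, Bayes-factor model
# comparison, and consolidation of putative species using externally
# computed multispecies-coalescent speciation posteriors.

#' Parse a support-annotated newick tree
#'
#' Internal node labels are read as posterior clade supports; values on the
#' `[0, 1]` scale are auto-detected and rescaled to `[0, 100]`.
#'
#' @param path Path to a newick file, or a newick string.
#' @return List of class `"support_tree"` with `tree` (an [ape::phylo]
#'   with normalized numeric `node.label`) and `support_scale`
#'   (`"percent"` after normalization).
#' @export
parse_tree <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "") else path
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop_input("malformed newick: ",
                                                  conditionMessage(e)))
  if (is.null(tree)) stop_input("malformed newick")
  if (anyDuplicated(tree$tip.label)) {
    stop_input("duplicate tip labels: ",
               paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                     collapse = ", "))
  }
  supports <- suppressWarnings(as.numeric(tree$node.label))
  if (any(!is.na(supports))) {
    mx <- max(supports, na.rm = TRUE)
    if (mx <= 1) supports <- supports * 100
    if (any(supports < 0 | supports > 100, na.rm = TRUE)) {
      stop_input("support values outside [0, 100]")
    }
  }
  tree$node.label <- supports
  out <- list(tree = tree, support_scale = "percent")
  class(out) <- "support_tree"
  out
}

# Tip-descendant sets for every node of a phylo, as logical vectors.
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- matrix(FALSE, n_node, n_tip)
  sets[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  # postorder: each child's subtree is complete before its edge is processed
  for (i in ape::postorder(tree)) {
    parent <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    sets[parent, ] <- sets[parent, ] | sets[child, ]
  }
  sets
}

#' Test a tip set for monophyly on an unrooted support tree
#'
#' A set is monophyletic iff some edge's bipartition has one side exactly
#' equal to the set (unrooted convention; the complement side counts too).
#' Singleton sets are monophyletic with undefined support; support is also
#' undefined when the defining edge is external.
#'
#' @param stree A `"support_tree"` from [parse_tree()].
#' @param tips Character vector of tip labels (proper non-empty subset).
#' @return List of class `"monophyly_result"` with `species` (the tip set),
#'   `monophyletic` (logical) and `support` (numeric, `NA` when
#'   non-monophyletic or undefined).
#' @export
monophyly_test <- function(stree, tips) {
  tree <- stree$tree
  labels <- tree$tip.label
  unknown <- setdiff(tips, labels)
  if (length(unknown) > 0) {
    stop_input("unknown tips: ", paste(unknown, collapse = ", "))
  }
  n_tip <- length(labels)
  if (length(tips) < 1 || length(tips) >= n_tip) {
    stop_input("tip set must be a proper non-empty subset of the tree tips")
  }
  target <- labels %in% tips
  if (length(tips) == 1) {
    out <- list(species = tips, monophyletic = TRUE, support = NA_real_)
    class(out) <- "monophyly_result"
    return(out)
  }
  sets <- node_tip_sets(tree)
  root <- n_tip + 1
  mono <- FALSE
  support <- NA_real_
  for (v in seq_len(nrow(sets))) {
    if (v == root) next  # the root's "clade" is the full tip set
    side <- sets[v, ]
    if (all(side == target) || all(side == !target)) {
      mono <- TRUE
      if (v > n_tip && !is.null(tree$node.label)) {
        support <- tree$node.label[v - n_tip]
      }
      if (isTRUE(!is.na(support))) break
    }
  }
  out <- list(species = tips, monophyletic = mono,
              support = if (mono) support else NA_real_)
  class(out) <- "monophyly_result"
  out
}

#' Monophyly report for every species in a partition
#'
#' Species whose haplotypes are all present in the tree are tested; a
#' species covering all tree tips (or none) is skipped with `NA`.
#'
#' @param stree A `"support_tree"`.
#' @param partition A `"species_partition"`.
#' @return Data frame with columns `species`, `n_tips`, `monophyletic`,
#'   `support`.
#' @export
monophyly_report <- function(stree, partition) {
  labels <- stree$tree$tip.label
  species <- sort(unique(partition$species))
  rows <- lapply(species, function(sp) {
    tips <- intersect(partition$haplotype[partition$species == sp], labels)
    if (length(tips) == 0 || length(tips) >= length(labels)) {
      return(data.frame(species = sp, n_tips = length(tips),
                        monophyletic = NA, support = NA_real_))
    }
    r <- monophyly_test(stree, tips)
    data.frame(species = sp, n_tips = length(tips),
               monophyletic = r$monophyletic, support = r$support)
  })
  do.call(rbind, rows)
}

#' Bayes factor for a partitioned vs unpartitioned model
#'
#' `BF = 2 * (lnL1 - lnL0) + (P1 - P0) * ln(0.01)`, where `lnL` are
#' marginal log-likelihoods and `P` parameter counts of the alternative
#' (partitioned) and null (unpartitioned) models. A Bayes factor of at
#' least 10 is interpreted as significant support for the partitioned
#' model (threshold inclusive).
#'
#' @param lnL1,lnL0 Marginal log-likelihoods (alternative, null).
#' @param P1,P0 Parameter counts (positive integers).
#' @return List with `bf` and logical `favored`.
#' @examples
#' bayes_factor(-100, -150, 2, 1)
#' @export
bayes_factor <- function(lnL1, lnL0, P1, P0) {
  if (!all(is.finite(c(lnL1, lnL0)))) stop_input("non-finite log-likelihoods")
  if (P1 < 1 || P0 < 1 || P1 != round(P1) || P0 != round(P0)) {
    stop_input("parameter counts must be positive integers")
  }
  bf <- 2 * (lnL1 - lnL0) + (P1 - P0) * log(0.01)
  list(bf = bf, favored = bf >= 10)
}

#' Consolidate a species partition using speciation posteriors
#'
#' Candidate splits (pairs of current species labels) with a
#' multispecies-coalescent speciation posterior below `keep_threshold` are
#' merged; the lexicographically smaller label wins. The posteriors are
#' inputs computed elsewhere (e.g. BPP); only the decision logic lives
#' here.
#'
#' @param p A `"species_partition"`.
#' @param posteriors Data frame with columns `species1`, `species2`,
#'   `posterior` (each in `[0, 1]`). An empty data frame (or `NULL`)
#'   leaves the partition unchanged.
#' @param keep_threshold Minimum posterior required to keep a split
#'   (default 0.95).
#' @return The consolidated `"species_partition"` with provenance updated.
#' @export
consolidate_partition <- function(p, posteriors, keep_threshold = 0.95) {
  if (is.null(posteriors) || nrow(posteriors) == 0) return(p)
  if (any(posteriors$posterior < 0 | posteriors$posterior > 1)) {
    stop_input("posteriors must lie in [0, 1]")
  }
  labels <- sort(unique(p$species))
  for (col in c("species1", "species2")) {
    unknown <- setdiff(posteriors[[col]], labels)
    if (length(unknown) > 0) {
      stop_input("unknown species label(s): ", paste(unknown, collapse = ", "))
    }
  }
  parent <- uf_new(length(labels))
  merged <- posteriors[posteriors$posterior < keep_threshold, , drop = FALSE]
  for (i in seq_len(nrow(merged))) {
    parent <- uf_union(parent, match(merged$species1[i], labels),
                       match(merged$species2[i], labels))
  }
  comp <- uf_components(parent)
  new_label <- vapply(comp, function(cc) min(labels[comp == cc]), character(1))
  map <- stats::setNames(new_label, labels)
  p$species <- unname(map[p$species])
  attr(p, "provenance") <- paste(attr(p, "provenance"),
                                 "posterior-consolidation", sep = "+")
  attr(p, "keep_threshold") <- keep_threshold
  p
}
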