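# Screening for nuclear mitochondrial pseudogenes (numts). A true COI
# barcode is protein coding: its reading frame is free of stop codons, and
# its substitutions are transition-rich. Numts betray themselves by
# in-frame stops and/or an excess of transversions relative to the
# consensus of the most similar haplotype cluster.

#' Count in-frame stop codons in the best reading frame
#'
#' Removes gaps, translates the sequence in all three forward frames under
#' the invertebrate mitochondrial genetic code (translation table 5; stop
#' codons TAA and TAG) and returns the frame offset with the fewest stops,
#' ties broken by the smallest offset.
#'
#' @param seq Nucleotide sequence (character string or vector).
#' @param code Genetic code id passed to [seqinr::translate()]'s `numcode`
#'   (default 5, invertebrate mitochondrial).
#' @return List with `frame` (offset 0, 1 or 2) and `stops` (count in that
#'   frame).
#' @examples
#' find_stop_codons("ATGTAAATG")  # frame 1 is stop-free
#' @export
find_stop_codons <- function(seq, code = 5) {
  s <- if (length(seq) == 1) strsplit(toupper(seq), "")[[1]] else toupper(seq)
  s <- s[s != "-"]
  if (length(s) < 3) stop_input("sequence shorter than one codon")
  stops <- vapply(0:2, function(f) {
    if (length(s) - f < 3) return(Inf)
    aa <- seqinr::translate(s, frame = f, numcode = code)
    sum(aa == "*")
  }, numeric(1))
  best <- which.min(stops)  # which.min returns the first (smallest offset) tie
  list(frame = best - 1L, stops = as.integer(stops[best]))
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the most frequent resolved base (A/C/G/T), optionally
#' weighting each sequence (e.g. by its sample count, so that a rare
#' contaminant cannot dominate the consensus); ties broken alphabetically;
#' columns with no resolved base become `N`.
#'
#' @param seqs Character matrix of aligned sequences (or a
#'   `"barcode_alignment"`).
#' @param weights Optional non-negative weight per row (default 1 each).
#' @return Single consensus sequence as a character vector of bases.
#' @export
consensus_sequence <- function(seqs, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(seqs))
  apply_idx <- seq_len(ncol(seqs))
  vapply(apply_idx, function(j) {
    col <- seqs[, j]
    keep <- is_resolved(col)
    if (!any(keep)) return("N")
    w <- tapply(weights[keep], factor(col[keep], levels = BASES), sum)
    w[is.na(w)] <- 0
    BASES[which.max(w)]
  }, character(1))
}

#' Transition/transversion profile of a haplotype against a consensus
#'
#' Counts transitions (A<->G, C<->T) and transversions among resolved sites
#' that differ between the haplotype and the consensus, and flags a
#' transversion excess when ts/tv falls below `max_tstv` with at least
#' `min_diff` differences. With zero transversions the ratio is `Inf`; with
#' zero differences it is undefined (`NaN`) and never flagged.
#'
#' @param h Haplotype sequence (string or character vector).
#' @param consensus Consensus sequence of equal length.
#' @param max_tstv Flagging threshold on the ts/tv ratio (default 0.5:
#'   genuine COI substitutions are strongly transition-biased, so a clean
#'   haplotype a few steps from its consensus almost never drops below
#'   one transition per two transversions, while numts accumulate
#'   unconstrained nuclear substitutions and routinely do).
#' @param min_diff Minimum number of differing sites required to flag
#'   (default 3).
#' @return List with `ts`, `tv`, `ratio` and logical `flag`.
#' @export
transversion_excess <- function(h, consensus, max_tstv = 0.5, min_diff = 3) {
  a <- if (length(h) == 1) strsplit(toupper(h), "")[[1]] else toupper(h)
  b <- if (length(consensus) == 1) strsplit(toupper(consensus), "")[[1]]
       else toupper(consensus)
  if (length(a) != length(b)) stop_input("sequence/consensus length mismatch")
  use <- is_resolved(a) & is_resolved(b) & a != b
  ts <- sum(is_transition(a[use], b[use]))
  tv <- sum(use) - ts
  ratio <- if (tv == 0 && ts == 0) NaN else if (tv == 0) Inf else ts / tv
  flag <- isTRUE(sum(use) >= min_diff && tv > 0 && ratio < max_tstv)
  list(ts = ts, tv = tv, ratio = ratio, flag = flag)
}

#' Screen haplotypes for numt signatures
#'
#' Each haplotype is (i) scanned for in-frame stop codons in its best
#' reading frame and (ii) compared with the majority-rule consensus of its
#' own haplotype cluster at the delimitation threshold (its nearest other
#' cluster when it is a singleton), flagging transversion excess. The
#' consensus is weighted by sample counts over the whole cluster: numts
#' are typically rare single reads, so a count-weighted majority reflects
#' the genuine mitochondrial lineage even when a contaminant sits inside
#' a small cluster.
#'
#' @param table A `"haplotype_table"`.
#' @param dist_threshold Single-linkage clustering threshold (uncorrected
#'   p-distance) used to pick each haplotype's consensus cluster; default
#'   0.027, the barcode-gap species cut-off.
#' @param max_tstv,min_diff Passed to [transversion_excess()].
#' @param code Genetic code id (default 5).
#' @return Data frame with one row per haplotype: `haplotype`, `frame`,
#'   `stops`, `ts`, `tv`, `ratio`, `flag_stop`, `flag_tv`, `flagged`.
#' @export
screen_numts <- function(table, dist_threshold = 0.027, max_tstv = 0.5,
                         min_diff = 3, code = 5) {
  if (length(table$haplotypes) == 0) stop_input("empty haplotype table")
  aln <- haplotype_alignment(table)
  n <- nrow(aln)
  ids <- rownames(aln)
  dm <- distance_matrix(aln, model = "p")
  comp <- if (n > 1) {
    part <- cluster_at_threshold(dm, dist_threshold)
    stats::setNames(part$species, part$haplotype)[ids]
  } else stats::setNames("c1", ids)

  counts <- table$counts[ids]
  res <- lapply(seq_len(n), function(i) {
    stop_res <- find_stop_codons(aln[i, ], code = code)
    mates <- which(comp == comp[i])
    if (length(mates) == 1 && n > 1) {
      # singleton cluster: consensus of the nearest other cluster, taken
      # among clusters with more than one sample when any exists (a rare
      # single read is itself a numt candidate, not a reference)
      cl_count <- tapply(counts, comp, sum)
      multi <- names(cl_count)[cl_count > 1 & names(cl_count) != comp[i]]
      pool <- if (length(multi) > 0) which(comp %in% multi) else
        setdiff(seq_len(n), i)
      nearest <- pool[which.min(dm$values[i, pool])]
      mates <- which(comp == comp[nearest])
    }
    if (length(mates) == 1 && mates[1] == i) {
      tv_res <- list(ts = 0L, tv = 0L, ratio = NaN, flag = FALSE)
    } else {
      cons <- consensus_sequence(aln[mates, , drop = FALSE],
                                 weights = counts[mates])
      tv_res <- transversion_excess(aln[i, ], cons, max_tstv = max_tstv,
                                    min_diff = min_diff)
    }
    data.frame(haplotype = ids[i], frame = stop_res$frame,
               stops = stop_res$stops, ts = tv_res$ts, tv = tv_res$tv,
               ratio = tv_res$ratio, flag_stop = stop_res$stops > 0,
               flag_tv = tv_res$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$flag_stop | out$flag_tv
  out
}

#' Remove flagged haplotypes from a table
#'
#' @param table A `"haplotype_table"`.
#' @param report Output of [screen_numts()].
#' @return The table with flagged haplotypes (and their samples) removed.
#' @export
drop_flagged_haplotypes <- function(table, report) {
  bad <- report$haplotype[report$flagged]
  if (length(bad) == 0) return(table)
  keep <- setdiff(names(table$haplotypes), bad)
  dropped_samples <- names(table$membership)[table$membership %in% bad]
  table$haplotypes <- table$haplotypes[keep]
  table$counts <- table$counts[keep]
  table$membership <- table$membership[!(table$membership %in% bad)]
  table$excluded <- c(table$excluded, dropped_samples)
  table
}
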