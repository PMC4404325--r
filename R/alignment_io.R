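#' Read an aligned barcode FASTA file
#'
#' Reads a FASTA file of aligned nucleotide sequences into a character
#' matrix (one row per sequence, one column per alignment site), upper-cased
#' and validated against the IUPAC nucleotide alphabet (including gaps).
#'
#' @param path Path to a FASTA file.
#' @return A character matrix of class `"barcode_alignment"` with sequence
#'   ids as row names.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGTAC", ">s2", "acgtacgtac"), fa)
#' aln <- read_alignment(fa)
#' dim(aln)
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  dna <- tryCatch(ape::read.FASTA(path),
                  error = function(e) stop_input("unparseable FASTA: ",
                                                 conditionMessage(e)))
  if (length(dna) == 0) stop_input("empty FASTA file: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) {
    stop_input("sequences are not aligned: lengths ",
               paste(sort(unique(lens)), collapse = ", "))
  }
  chars <- toupper(t(vapply(as.character(dna), identity,
                            character(lens[1]))))
  rownames(chars) <- names(dna)
  as_alignment(chars)
}

#' Validate a character matrix as a barcode alignment
#'
#' @param x Character matrix, rows = sequences, columns = aligned sites,
#'   row names = sample ids.
#' @return `x` with class `"barcode_alignment"`.
#' @export
as_alignment <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    stop_input("alignment must be a character matrix")
  }
  if (nrow(x) < 1 || ncol(x) < 1) stop_input("alignment has no data")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c(IUPAC_ALPHABET, "?"))
  if (length(bad) > 0) {
    stop_input("non-IUPAC characters in alignment: ",
               paste(bad, collapse = " "))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  class(x) <- c("barcode_alignment", class(x))
  x
}

#' Collapse aligned sequences to unique haplotypes
#'
#' Applies the barcode filtering rule used for species delimitation: a
#' sample is retained only if the first `min_len` aligned sites (from
#' `window_start`) contain no fully ambiguous base call (`N` or `?`).
#' Retained sequences are truncated to that window and identical windows
#' share one haplotype id, assigned in first-seen sample order.
#'
#' Gap characters count as resolved alignment columns, so two haplotypes
#' differing only by gaps remain distinct.
#'
#' @param aln A `"barcode_alignment"` matrix.
#' @param min_len Window width in sites (default 640, the minimum barcode
#'   length required of a retained sample).
#' @param window_start 1-based first column of the window.
#' @return An object of class `"haplotype_table"`: a list with elements
#'   `haplotypes` (named character vector id -> sequence string), `counts`
#'   (named integer, samples per haplotype), `membership` (named character,
#'   sample id -> haplotype id), `excluded` (character vector of dropped
#'   sample ids) and `window` (`c(start, length)`).
#' @export
collapse_haplotypes <- function(aln, min_len = 640, window_start = 1) {
  if (!inherits(aln, "barcode_alignment")) aln <- as_alignment(aln)
  if (min_len < 1) stop_input("min_len must be positive")
  if (window_start < 1 || window_start + min_len - 1 > ncol(aln)) {
    stop_input("window [", window_start, ", ", window_start + min_len - 1,
               "] outside alignment of length ", ncol(aln))
  }
  win <- aln[, window_start:(window_start + min_len - 1), drop = FALSE]
  ambiguous <- apply(win, 1, function(s) any(s %in% c("N", "?")))
  resolved_n <- apply(win, 1, function(s) sum(!(s %in% c("N", "?"))))
  keep <- !ambiguous & resolved_n >= min_len
  excluded <- rownames(aln)[!keep]
  if (!any(keep)) {
    warning("all samples excluded by the haplotype filter")
    out <- list(haplotypes = character(0), counts = integer(0),
                membership = character(0), excluded = excluded,
                window = c(start = window_start, length = min_len))
    class(out) <- "haplotype_table"
    return(out)
  }
  seqs <- apply(win[keep, , drop = FALSE], 1, paste, collapse = "")
  uniq <- unique(seqs)            # preserves first-seen order
  hap_ids <- paste0("H", seq_along(uniq))
  names(uniq) <- hap_ids
  membership <- hap_ids[match(seqs, uniq)]
  names(membership) <- names(seqs)
  counts <- table(factor(membership, levels = hap_ids))
  counts <- stats::setNames(as.integer(counts), hap_ids)
  out <- list(haplotypes = uniq, counts = counts, membership = membership,
              excluded = excluded,
              window = c(start = window_start, length = min_len))
  class(out) <- "haplotype_table"
  out
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", length(x$haplotypes), "haplotypes from",
      sum(x$counts), "samples (", length(x$excluded), "excluded )\n")
  invisible(x)
}

#' Convert a haplotype table back to an alignment
#'
#' One row per haplotype (ids as row names); used to feed the distance and
#' screening modules.
#'
#' @param table A `"haplotype_table"`.
#' @return A `"barcode_alignment"` character matrix.
#' @export
haplotype_alignment <- function(table) {
  if (length(table$haplotypes) == 0) stop_input("empty haplotype table")
  m <- t(vapply(strsplit(table$haplotypes, ""), identity,
                character(nchar(table$haplotypes[1]))))
  rownames(m) <- names(table$haplotypes)
  as_alignment(m)
}

#' Expand a haplotype table to one sequence per retained sample
#'
#' @param table A `"haplotype_table"`.
#' @return A `"barcode_alignment"` with one row per sample.
#' @export
expand_haplotypes <- function(table) {
  aln <- haplotype_alignment(table)
  m <- aln[table$membership, , drop = FALSE]
  rownames(m) <- names(table$membership)
  as_alignment(m)
}

#' Load a sample-to-population map
#'
#' Reads a tab-separated file with header columns `sample`, `population`,
#' `host`, `country`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per sample.
#' @export
load_population_map <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "host", "country")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_input("population map lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) {
    stop_input("duplicate sample ids in population map: ",
               paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  df[need]
}

#' Report samples missing from a population map
#'
#' @param aln A `"barcode_alignment"` or `"haplotype_table"`.
#' @param popmap Data frame from [load_population_map()].
#' @return Character vector of sample ids absent from the map (warned).
#' @export
unmapped_samples <- function(aln, popmap) {
  ids <- if (inherits(aln, "haplotype_table")) names(aln$membership)
         else rownames(aln)
  missing_ids <- setdiff(ids, popmap$sample)
  if (length(missing_ids) > 0) {
    warning("samples absent from population map: ",
            paste(missing_ids, collapse = ", "))
  }
  missing_ids
}

#' Write a haplotype table to TSV (+ optional FASTA of unique haplotypes)
#'
#' @param table A `"haplotype_table"`.
#' @param tsv Path for the TSV export (haplotype, count, members).
#' @param fasta Optional path for a FASTA of the unique haplotypes.
#' @return Invisibly, the TSV path.
#' @export
write_haplotype_table <- function(table, tsv, fasta = NULL) {
  members <- split(names(table$membership), table$membership)
  df <- data.frame(
    haplotype = names(table$haplotypes),
    count = table$counts[names(table$haplotypes)],
    members = vapply(names(table$haplotypes),
                     function(h) paste(members[[h]], collapse = ","),
                     character(1)),
    sequence = unname(table$haplotypes),
    stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    seqinr::write.fasta(as.list(unname(table$haplotypes)),
                        names = names(table$haplotypes), file.out = fasta)
  }
  invisible(tsv)
}

#' Read a haplotype table written by [write_haplotype_table()]
#'
#' @param tsv Path to the TSV export.
#' @return A `"haplotype_table"` (with an empty exclusion list; exclusions
#'   are a property of the original filtering run).
#' @export
read_haplotype_table <- function(tsv) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  haps <- stats::setNames(df$sequence, df$haplotype)
  counts <- stats::setNames(as.integer(df$count), df$haplotype)
  membership <- character(0)
  for (i in seq_len(nrow(df))) {
    mem <- strsplit(df$members[i], ",", fixed = TRUE)[[1]]
    membership[mem] <- df$haplotype[i]
  }
  out <- list(haplotypes = haps, counts = counts, membership = membership,
              excluded = character(0),
              window = c(start = NA, length = nchar(df$sequence[1])))
  class(out) <- "haplotype_table"
  out
}
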