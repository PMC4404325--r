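# Shared fixture builders: everything is generated in code at test time.

# Write a FASTA file from named sequences; returns the path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm),
                                                     seqs[[nm]])))
  writeLines(lines, path)
  path
}

# Random resolved sequence of length L as a character vector.
random_seq <- function(L, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = freqs)
}

# Mutate `m` random sites of a sequence (uniform substitution).
mutate_sites <- function(s, m) {
  idx <- sample(length(s), m)
  for (i in idx) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  s
}

# A hand-built dist_matrix object for gap/cluster tests.
fake_dist <- function(values, ids = NULL) {
  n <- nrow(values)
  if (is.null(ids)) ids <- LETTERS[seq_len(n)]
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, model = "p", pinv = 0, ids = ids),
            class = "dist_matrix")
}

# A small population map TSV; returns the path.
write_popmap <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
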