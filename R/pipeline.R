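# Orchestration of the full barcode workflow: filter -> numt screen ->
# distances -> gap detection -> threshold clustering -> optional tree
# check and posterior consolidation -> per-population statistics ->
# mismatch fitting and dating. Every intermediate artifact is persisted;
# the summary is machine-readable JSON.

#' Run the full barcode delimitation and phylogeography pipeline
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   \describe{
#'     \item{input}{`fasta` (required), `popmap` (TSV path, optional),
#'       `tree` (newick path, optional), `posteriors` (TSV with columns
#'       species1, species2, posterior; optional).}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{out_dir}{Output directory (required).}
#'     \item{filter}{`min_len` (640), `window_start` (1).}
#'     \item{numt}{`dist_threshold` (0.027), `max_tstv` (0.5), `min_diff`
#'       (3), `exclude` (TRUE).}
#'     \item{distance}{`model` ("tn93"; "gtr_i" gives the TIM3-constrained
#'       GTR+I distance, whose fixed-pinv stretch can distort the fixed
#'       histogram bin scale on sparse data).}
#'     \item{gap}{`bin_width` (0.0025), `min_gap_bins` (2), `threshold`
#'       ("auto" = first gap midpoint, or a number).}
#'     \item{popgen}{`min_n` (4), `reps` (16000).}
#'     \item{mismatch}{`model` ("demographic"), `bootstrap_reps` (16000),
#'       `min_n` (7), `date` (TRUE), `generations_per_year` (13.5),
#'       `pairwise_rate_per_my` (0.065).}
#'   }
#' @return Invisibly, the summary list (also written as
#'   `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1,
    filter = list(min_len = 640, window_start = 1),
    numt = list(dist_threshold = 0.027, max_tstv = 0.5, min_diff = 3,
                exclude = TRUE),
    distance = list(model = "tn93"),
    gap = list(bin_width = 0.0025, min_gap_bins = 2, threshold = "auto"),
    popgen = list(min_n = 4, reps = 16000),
    mismatch = list(model = "demographic", bootstrap_reps = 16000,
                    min_n = 7, date = TRUE, generations_per_year = 13.5,
                    pairwise_rate_per_my = 0.065))
  config <- utils::modifyList(defaults, config)
  if (is.null(config$input$fasta)) stop_input("config$input$fasta required")
  if (is.null(config$out_dir)) stop_input("config$out_dir required")
  for (p in c(config$input$fasta, config$input$popmap, config$input$tree,
              config$input$posteriors)) {
    if (!is.null(p) && !file.exists(p)) stop_input("input not found: ", p)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste("barcodegap", as.character(utils::packageVersion("barcodegap"))),
                 paste("seed", config$seed),
                 paste("R", getRversion()))
  summary <- list(seed = config$seed)

  # 1. filter / collapse
  aln <- read_alignment(config$input$fasta)
  table <- collapse_haplotypes(aln, min_len = config$filter$min_len,
                               window_start = config$filter$window_start)
  write_haplotype_table(table, file.path(out_dir, "haplotypes.tsv"),
                        fasta = file.path(out_dir, "haplotypes.fasta"))
  log_lines <- c(log_lines,
                 paste("filter: min_len", config$filter$min_len,
                       "(paper-stated), excluded", length(table$excluded)))
  summary$n_samples <- nrow(aln)
  summary$n_retained <- sum(table$counts)
  summary$n_haplotypes <- length(table$haplotypes)

  # 2. numt screen
  report <- screen_numts(table, dist_threshold = config$numt$dist_threshold,
                         max_tstv = config$numt$max_tstv,
                         min_diff = config$numt$min_diff)
  utils::write.table(report, file.path(out_dir, "numt_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$numt_flagged <- report$haplotype[report$flagged]
  if (isTRUE(config$numt$exclude)) table <- drop_flagged_haplotypes(table, report)
  summary$n_haplotypes_clean <- length(table$haplotypes)

  # 3. distances
  dm <- distance_matrix(table, model = config$distance$model)
  write_distance_matrix(dm, file.path(out_dir, "distances.tsv"))

  # 4. gap analysis + clustering
  g <- detect_gaps(distance_histogram(dm, bin_width = config$gap$bin_width),
                   min_gap_bins = config$gap$min_gap_bins)
  utils::write.table(
    data.frame(lower_edge = (seq_along(g$counts) - 1) * g$bin_width,
               count = g$counts),
    file.path(out_dir, "distance_histogram.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  threshold <- config$gap$threshold
  if (identical(threshold, "auto")) {
    if (nrow(g$breaks) == 0) {
      threshold <- Inf
      warning("no gap detected; all haplotypes form one species")
    } else threshold <- g$breaks$midpoint[1]
  }
  part <- if (is.finite(threshold)) cluster_at_threshold(dm, threshold)
          else {
            p <- data.frame(haplotype = dm$ids, species = dm$ids[1])
            attr(p, "threshold") <- Inf; attr(p, "provenance") <- "gap"
            class(p) <- c("species_partition", "data.frame"); p
          }
  summary$gap_midpoints <- g$breaks$midpoint
  summary$threshold <- threshold

  # 5. optional tree evaluation and posterior consolidation
  if (!is.null(config$input$tree)) {
    stree <- parse_tree(config$input$tree)
    mono <- monophyly_report(stree, part)
    utils::write.table(mono, file.path(out_dir, "monophyly.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$monophyly <- mono
  }
  if (!is.null(config$input$posteriors)) {
    posts <- utils::read.delim(config$input$posteriors,
                               stringsAsFactors = FALSE)
    part <- consolidate_partition(part, posts)
  }
  utils::write.table(part, file.path(out_dir, "species_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_species <- n_species(part)
  summary$species <- stats::setNames(part$species, part$haplotype)

  # 6. per-population statistics and mismatch fits
  if (!is.null(config$input$popmap)) {
    popmap <- load_population_map(config$input$popmap)
    unmapped_samples(table, popmap)
    seqs <- expand_haplotypes(table)
    pops <- popmap$population[match(rownames(seqs), popmap$sample)]
    keep <- !is.na(pops)
    seqs <- seqs[keep, , drop = FALSE]
    pops <- pops[keep]
    stats_tab <- population_stats_table(seqs, pops,
                                        min_n = config$popgen$min_n,
                                        reps = config$popgen$reps,
                                        seed = config$seed)
    if (!is.null(stats_tab)) {
      utils::write.table(stats_tab, file.path(out_dir, "population_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$population_stats <- stats_tab
    }
    fits <- list()
    for (pp in unique(pops)) {
      idx <- which(pops == pp)
      if (length(idx) < config$mismatch$min_n) next
      mm <- mismatch_distribution(seqs[idx, , drop = FALSE])
      if (sum(mm > 0) < 2) next
      fit <- fit_expansion(mm, model = config$mismatch$model,
                           n = length(idx),
                           bootstrap_reps = config$mismatch$bootstrap_reps,
                           seed = substream_seed(config$seed,
                                                 match(pp, unique(pops))))
      entry <- list(population = pp, tau = fit$tau, SSD = fit$SSD,
                    rg = fit$rg, p_SSD = fit$p_SSD, p_rg = fit$p_rg)
      if (isTRUE(config$mismatch$date)) {
        dd <- date_expansion(fit$tau, L = ncol(seqs),
                             generations_per_year =
                               config$mismatch$generations_per_year,
                             pairwise_rate_per_my =
                               config$mismatch$pairwise_rate_per_my)
        entry$t_years <- dd$t_years
      }
      fits[[pp]] <- entry
    }
    summary$mismatch_fits <- fits
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
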