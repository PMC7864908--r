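#' Read / write FASTA
#'
#' FASTA I/O via Biostrings, returned as a named character vector so the
#' simulation and alignment layers can work on plain strings.  Writing
#' wraps sequence lines at 60 columns.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write FASTQ
#'
#' A minimal strict FASTQ reader: malformed records (bad header, length
#' mismatch between sequence and quality) are rejected with the file and
#' line number.  Written records carry a constant dummy quality (`I`),
#' as simulated reads have no quality model.
#'
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop(path, ": truncated FASTQ (", length(lines), " lines)")
  n <- length(lines) / 4
  ids <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    l <- (i - 1L) * 4L
    if (!startsWith(lines[l + 1L], "@"))
      stop(path, ": line ", l + 1L, ": expected '@' header")
    if (!startsWith(lines[l + 3L], "+"))
      stop(path, ": line ", l + 3L, ": expected '+' separator")
    if (nchar(lines[l + 2L]) != nchar(lines[l + 4L]))
      stop(path, ": line ", l + 4L,
           ": quality length differs from sequence length")
    ids[i] <- sub("^@", "", strsplit(lines[l + 1L], " ")[[1]][1])
    seqs[i] <- lines[l + 2L]
  }
  setNames(seqs, ids)
}

#' @rdname read_fastq
#' @param reads named character vector of read sequences.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' Read / write TSV tables
#'
#' UTF-8, LF, header row.  `required` columns are checked on read and a
#' schema error names the missing column.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname read_tsv
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default pipeline thresholds
#'
#' All printed defaults of the authentication and bait-design stages in
#' one place: minimum percent identity 95, top score fraction 0.10,
#' terminal lesion window 5, minimum 50 reads per profiled taxon, 80-nt
#' baits at 3x tiling with 84-nt padding, collapse at >0.83 overlap /
#' >0.95 identity, add-on hit filters 60 bp / 80% / 50 hits, Tm bins at
#' 60/62.5/65/67.5/70 C.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_pident = 95, top_fraction = 0.10, lesion_window = 5L,
       min_reads = 50L, bait_length = 80L, density = 3L,
       pad_length = 84L, min_overlap = 0.83, min_identity = 0.95,
       hit_min_len = 60L, hit_min_pident = 80, hit_max = 50L,
       tm_bins = c(60, 62.5, 65, 67.5, 70))
}

#' Authenticate one read set against a panel
#'
#' Chains alignment, identity/top-fraction filtering, naive-LCA
#' assignment and ancient/default classification for one read set.
#'
#' @param reads named character vector of reads.
#' @param panel reference panel.
#' @param min_pident,top_fraction,lesion_window filter and classifier
#'   settings (printed defaults).
#' @param seed_k candidate-screen k-mer size ([align_reads()]).
#' @return list `alignments` (all candidate alignments), `best` (per-read
#'   best surviving alignment), `assignments`, `classes`, `summaries`
#'   (per-taxon ancient/default counts).
#' @export
authenticate_reads <- function(reads, panel, min_pident = 95,
                               top_fraction = 0.10, lesion_window = 5L,
                               seed_k = 11L) {
  aln <- align_reads(reads, panel, seed_k = seed_k)
  asn <- assign_reads(aln, panel, min_pident, top_fraction)
  classes <- classify_reads(asn$best, window = lesion_window)
  summaries <- summarize_taxa(asn$assignments, classes, panel)
  list(alignments = aln, best = asn$best,
       assignments = asn$assignments, classes = classes,
       summaries = summaries)
}

#' Run the full synthetic-core replay pipeline
#'
#' Simulates the depth-indexed samples and EBCs of one or more datasets,
#' authenticates every read set, subtracts EBC taxa, computes the
#' percent eukaryote sedaDNA damage per sample and the depth / cross-
#' dataset Pearson correlations.  Deterministic for a fixed
#' configuration; samples with an undefined damage stat are excluded
#' from the correlations (with their exclusion recorded).
#'
#' @param panel reference panel.
#' @param specs_by_dataset named list (by dataset label) of lists of
#'   [sample_spec()]s, e.g. from [depth_series_specs()].
#' @param ebc list with `contaminant_taxa`, `n_reads`, `seed` describing
#'   the extraction blank, or `NULL` for no blank.
#' @param thresholds list from [default_thresholds()] (overridable).
#' @param out_dir optional directory; when given, damage-stat and
#'   summary tables are written there as TSV.
#' @return list `damage_stats` (per sample: `sample_id`, `dataset_label`,
#'   `depth_cmbsf`, `pct_damage`, totals, `ok`), `correlations`
#'   (matrix from [correlation_matrix()], r lower / p upper triangle),
#'   `depth_tests` (per dataset [pearson_two_tailed()] vs depth),
#'   `summaries` (per-sample taxon summaries, post-EBC), `ebc_summaries`,
#'   `excluded` (sample ids dropped from the correlations).
#' @export
run_pipeline <- function(panel, specs_by_dataset, ebc = NULL,
                         thresholds = default_thresholds(),
                         out_dir = NULL) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  ebc_summaries <- NULL
  if (!is.null(ebc)) {
    eb <- simulate_ebc(panel, ebc$contaminant_taxa, ebc$n_reads,
                       seed = ebc$seed %||% 1L)
    ebc_auth <- authenticate_reads(eb$reads, panel, th$min_pident,
                                   th$top_fraction, th$lesion_window)
    ebc_summaries <- ebc_auth$summaries
  }
  stats <- list(); sums <- list()
  for (ds in names(specs_by_dataset)) {
    for (spec in specs_by_dataset[[ds]]) {
      sim <- simulate_sample(panel, spec)
      auth <- authenticate_reads(sim$reads, panel, th$min_pident,
                                 th$top_fraction, th$lesion_window)
      summ <- auth$summaries
      if (!is.null(ebc_summaries) && nrow(ebc_summaries))
        summ <- subtract_ebc(summ, ebc_summaries)
      pd <- percent_damage(summ)
      stats[[length(stats) + 1L]] <-
        cbind(data.frame(sample_id = spec$sample_id, dataset_label = ds,
                         depth_cmbsf = spec$depth_cmbsf,
                         stringsAsFactors = FALSE), pd)
      if (nrow(summ)) {
        summ$sample_id <- spec$sample_id
        summ$dataset_label <- ds
        sums[[length(sums) + 1L]] <- summ
      }
    }
  }
  damage_stats <- do.call(rbind, stats)
  summaries <- if (length(sums)) do.call(rbind, sums) else NULL
  excluded <- damage_stats$sample_id[!damage_stats$ok]
  if (length(excluded))
    message("excluded from correlations (undefined damage stat): ",
            paste(excluded, collapse = ", "))

  depth_tests <- list()
  for (ds in names(specs_by_dataset)) {
    d <- damage_stats[damage_stats$dataset_label == ds & damage_stats$ok, ]
    depth_tests[[ds]] <- pearson_two_tailed(d$depth_cmbsf, d$pct_damage)
  }
  # wide table by depth rank for the cross-dataset correlation matrix
  ds_names <- names(specs_by_dataset)
  depths <- sort(unique(damage_stats$depth_cmbsf))
  wide <- data.frame(depth_cmbsf = depths)
  for (ds in ds_names) {
    d <- damage_stats[damage_stats$dataset_label == ds, ]
    wide[[paste0(ds, "_pct_damage")]] <-
      d$pct_damage[match(depths, d$depth_cmbsf)]
  }
  correlations <- if (ncol(wide) >= 2) correlation_matrix(wide) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(damage_stats, file.path(out_dir, "damage_stats.tsv"))
    if (!is.null(summaries))
      write_tsv(summaries, file.path(out_dir, "taxon_summaries.tsv"))
    if (!is.null(ebc_summaries))
      write_tsv(ebc_summaries, file.path(out_dir, "ebc_summaries.tsv"))
  }
  list(damage_stats = damage_stats, correlations = correlations,
       depth_tests = depth_tests, summaries = summaries,
       ebc_summaries = ebc_summaries, excluded = excluded)
}
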