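#!/usr/bin/env Rscript
# Stage 1: lay out the synthetic study.
#
# Builds the desk-scale reference panel (two taxa per domain) and the
# study design: three datasets (shotgun, planktonbaits, habbaits) of 27
# depth-indexed samples each, with the terminal deamination rate rising
# from 0.02 at the surface to 0.25 at 130 cmbsf, plus one extraction
# blank control sharing two contaminant taxa with the samples.  Writes
# the panel FASTA, the sample sheet and one example FASTQ.

suppressPackageStartupMessages(library(sedadna))
dir.create("results", showWarnings = FALSE)

panel <- build_reference_panel(c(Bacteria = 2, Archaea = 2,
                                 Eukaryota = 2),
                               seq_length = 600, seed = 100)
write_fasta(setNames(panel$sequence,
                     paste(panel$taxon_id, panel$domain, panel$name,
                           sep = "|")),
            "results/reference_panel.fasta")

datasets <- c("shotgun", "planktonbaits", "habbaits")
specs <- lapply(seq_along(datasets), function(k)
  depth_series_specs(datasets[k], seed = 100 + 40 * k))
names(specs) <- datasets

sheet <- do.call(rbind, lapply(unlist(specs, recursive = FALSE),
  function(s) data.frame(sample_id = s$sample_id,
                         dataset_label = s$dataset_label,
                         depth_cmbsf = s$depth_cmbsf,
                         n_reads = s$n_reads,
                         delta5 = s$damage$delta5,
                         eukaryote_mix = s$domain_mix[["Eukaryota"]],
                         seed = s$seed)))
rownames(sheet) <- NULL
write_tsv(sheet, "results/sample_sheet.tsv")

example <- simulate_sample(panel, specs$shotgun[[27]])
write_fastq(example$reads, "results/example_deepest_shotgun.fastq")
truth <- example$truth[, c("read_id", "taxon_id", "domain", "ref_start",
                           "ref_end", "strand", "length",
                           "is_damaged_terminal")]
write_tsv(truth, "results/example_deepest_shotgun_truth.tsv")

cat(sprintf("panel: %d taxa x %d nt; design: %d samples across %d datasets\n",
            nrow(panel), nchar(panel$sequence[1]), nrow(sheet),
            length(datasets)))
cat(sprintf("deepest shotgun sample: %d reads, %.1f%% carry a terminal lesion\n",
            length(example$reads),
            100 * mean(example$truth$is_damaged_terminal)))
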