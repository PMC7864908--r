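#!/usr/bin/env Rscript
# Stage 4: the authenticity proxy against depth, and enrichment.
#
# Consumes the damage stats of stage 2 and reports (i) the two-tailed
# Pearson correlations between percent eukaryote sedaDNA damage and
# subseafloor depth, per dataset and between datasets (compact matrix:
# r in the lower triangle, p in the upper), (ii) mean +- SD domain
# proportions per dataset, and (iii) the capture-over-shotgun eukaryote
# enrichment ratios.

suppressPackageStartupMessages(library(sedadna))
stats <- read_tsv("results/damage_stats.tsv",
                  required = c("sample_id", "dataset_label",
                               "depth_cmbsf", "pct_damage"))
summ <- read_tsv("results/taxon_summaries.tsv",
                 required = c("taxon_id", "domain", "n_default",
                              "n_ancient", "sample_id", "dataset_label"))

datasets <- unique(stats$dataset_label)
depths <- sort(unique(stats$depth_cmbsf))
wide <- data.frame(depth_cmbsf = depths)
for (ds in datasets) {
  d <- stats[stats$dataset_label == ds, ]
  wide[[paste0(ds, "_pct_damage")]] <-
    d$pct_damage[match(depths, d$depth_cmbsf)]
}
cm <- correlation_matrix(wide)
cat("correlation matrix (r lower triangle, two-tailed p upper):\n")
print(round(cm, 5))
write_tsv(cbind(variable = rownames(cm), as.data.frame(cm)),
          "results/correlation_matrix.tsv")

# domain proportions per sample from the default read counts
props <- list()
for (ds in datasets) {
  per_sample <- lapply(split(summ[summ$dataset_label == ds, ],
                             summ$sample_id[summ$dataset_label == ds]),
                       function(s) {
    tot <- sum(s$n_default)
    v <- tapply(s$n_default, factor(s$domain,
                                    c("Bacteria", "Archaea",
                                      "Eukaryota")), sum)
    v[is.na(v)] <- 0
    c(v / tot, other = 0)
  })
  props[[ds]] <- domain_proportion_stats(per_sample)
  cat(sprintf("\n%s domain proportions (mean +- SD over samples):\n", ds))
  print(props[[ds]], digits = 3)
}

shot <- setNames(props$shotgun$mean, props$shotgun$domain)
for (ds in setdiff(datasets, "shotgun")) {
  cap <- setNames(props[[ds]]$mean, props[[ds]]$domain)
  er <- enrichment_ratio(cap, shot)
  cat(sprintf("\n%s : shotgun eukaryote enrichment = %.1fx\n",
              ds, er[["Eukaryota"]]))
}

enr <- do.call(rbind, lapply(setdiff(datasets, "shotgun"), function(ds) {
  cap <- setNames(props[[ds]]$mean, props[[ds]]$domain)
  data.frame(dataset = ds, domain = names(cap),
             ratio_over_shotgun = unname(enrichment_ratio(cap, shot)))
}))
write_tsv(enr, "results/enrichment_ratios.tsv")
if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/damage_vs_depth.pdf",
                  plot_damage_depth(stats), width = 6, height = 4)
}
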