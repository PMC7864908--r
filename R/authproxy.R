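#' Subtract extraction-blank-control taxa from sample summaries
#'
#' Any taxon with a default or ancient read count in any EBC is removed
#' from every sample, by taxon identity (a contaminant seen in a blank is
#' distrusted everywhere, not count-differenced).
#'
#' @param sample_summaries per-taxon summary table
#'   ([summarize_taxa()]), optionally with a `sample_id` column covering
#'   several samples.
#' @param ebc_summaries per-taxon summary of the EBC read sets (same
#'   layout); an empty table triggers a warning and no subtraction.
#' @return `sample_summaries` without EBC taxa.
#' @export
subtract_ebc <- function(sample_summaries, ebc_summaries) {
  if (is.null(ebc_summaries) || !nrow(ebc_summaries)) {
    warning("no EBC taxa supplied; samples returned unchanged")
    return(sample_summaries)
  }
  bad <- unique(ebc_summaries$taxon_id[ebc_summaries$n_default > 0 |
                                         ebc_summaries$n_ancient > 0])
  out <- sample_summaries[!(sample_summaries$taxon_id %in% bad), ,
                          drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent eukaryote sedaDNA damage of one sample
#'
#' Sums default and ancient read counts over eukaryote taxa and reports
#' `100 * sum(ancient) / sum(default)` — the per-sample authenticity
#' proxy.  Ancient reads are a subset of default reads, so the value lies
#' in \[0,100\].
#'
#' @param summaries per-taxon summary of one sample (post EBC
#'   subtraction).
#' @param domain domain whose reads enter the proxy (default
#'   `"Eukaryota"`).
#' @return one-row data.frame `pct_damage`, `n_default_total`,
#'   `n_ancient_total`, `ok`; when no eukaryote default reads exist the
#'   stat is undefined (`ok = FALSE`, `pct_damage = NA`) and the sample
#'   should be excluded from correlations.
#' @export
percent_damage <- function(summaries, domain = "Eukaryota") {
  s <- summaries[summaries$domain == domain, , drop = FALSE]
  nd <- sum(s$n_default); na <- sum(s$n_ancient)
  if (nd == 0)
    return(data.frame(pct_damage = NA_real_, n_default_total = 0L,
                      n_ancient_total = as.integer(na), ok = FALSE))
  data.frame(pct_damage = 100 * na / nd,
             n_default_total = as.integer(nd),
             n_ancient_total = as.integer(na), ok = TRUE)
}

#' Domain proportions of assigned reads
#'
#' Relative abundance of each domain among filter-passing reads.
#' Taxon- and domain-level assignments contribute to their domain;
#' root-level ties are counted as `"other"`.  Proportions sum to 1 over
#' assigned reads.
#'
#' @param assignments assignment table from [assign_reads()].
#' @return named numeric over `Bacteria`, `Archaea`, `Eukaryota`,
#'   `other`, or `NULL` with a warning when no read was assigned.
#' @export
domain_proportions <- function(assignments) {
  a <- assignments[assignments$passed_filters, , drop = FALSE]
  if (!nrow(a)) {
    warning("no assigned reads; domain proportions undefined")
    return(NULL)
  }
  dom <- ifelse(is.na(a$domain), "other", a$domain)
  tab <- table(factor(dom, levels = c(DOMAINS, "other")))
  setNames(as.numeric(tab) / nrow(a), names(tab))
}

#' Mean and standard deviation of domain proportions across samples
#'
#' @param prop_list list of named proportion vectors
#'   ([domain_proportions()] per sample).
#' @return data.frame `domain`, `mean`, `sd`.
#' @export
domain_proportion_stats <- function(prop_list) {
  prop_list <- Filter(Negate(is.null), prop_list)
  stopifnot(length(prop_list) > 0)
  doms <- names(prop_list[[1]])
  m <- sapply(doms, function(d) mean(vapply(prop_list, `[[`, numeric(1), d)))
  s <- sapply(doms, function(d) sd(vapply(prop_list, `[[`, numeric(1), d)))
  data.frame(domain = doms, mean = as.numeric(m), sd = as.numeric(s),
             stringsAsFactors = FALSE)
}

#' Capture-over-shotgun enrichment ratio per domain
#'
#' Ratio of mean relative abundance per domain between a capture dataset
#' and its shotgun counterpart; the headline quantity of a target
#' enrichment experiment (e.g. a 4-fold eukaryote increase).
#'
#' @param capture,shotgun named mean proportion vectors over the same
#'   domain set.
#' @return named numeric of ratios; `NA` where the shotgun proportion is
#'   zero.
#' @export
enrichment_ratio <- function(capture, shotgun) {
  stopifnot(setequal(names(capture), names(shotgun)))
  shotgun <- shotgun[names(capture)]
  out <- ifelse(shotgun > 0, capture / shotgun, NA_real_)
  setNames(as.numeric(out), names(capture))
}

#' Two-tailed Pearson correlation
#'
#' Sample Pearson coefficient with the exact two-tailed p-value from the
#' t transform `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with
#'   nonzero variance.
#' @return list `r`, `p_two_tailed`, `n`, `ok`; degenerate input returns
#'   `ok = FALSE` with `NA` statistics.
#' @export
pearson_two_tailed <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_two_tailed = NA_real_, n = n, ok = FALSE))
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p_two_tailed = p, n = n, ok = TRUE)
}

#' Pairwise correlation matrix, r below and p above the diagonal
#'
#' The conventional compact layout for reporting the depth and
#' cross-dataset correlations of the damage proxy: Pearson r in the lower
#' triangle, two-tailed p in the upper triangle, `NA` diagonal.
#'
#' @param data data.frame of numeric columns (e.g. depth plus the
#'   per-dataset damage proxies); rows with any `NA` are dropped
#'   pairwise.
#' @return square numeric matrix with dimnames from `data`.
#' @export
correlation_matrix <- function(data) {
  k <- ncol(data)
  out <- matrix(NA_real_, k, k, dimnames = list(names(data), names(data)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i <= j) next
    ct <- pearson_two_tailed(data[[i]], data[[j]])
    out[i, j] <- ct$r
    out[j, i] <- ct$p_two_tailed
  }
  out
}
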