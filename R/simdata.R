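#' Damage model parameters
#'
#' Parametric model of terminal cytosine deamination in ancient DNA:
#' at 5' position `i` each C is read as T with probability
#' `delta5 * decay^(i-1)`, at 3' position `j` each G is read as A with
#' probability `delta3 * decay^(j-1)` (the complementary strand's
#' deamination signal), and every base is additionally substituted
#' uniformly at random with probability `background_error`.  Substitution
#' only; fragment lengths are preserved.
#'
#' @param delta5 probability of C->T at the first 5' position, in \[0,1\].
#' @param delta3 probability of G->A at the first 3' position, in \[0,1\].
#' @param decay per-position geometric decay factor, in (0,1\].
#' @param background_error per-base probability of a uniform random
#'   substitution, in \[0,0.05\].
#' @param min_frag,max_frag fragment length bounds (nt),
#'   `30 <= min_frag <= max_frag <= 200`.
#' @return a `damage_params` list.
#' @examples
#' damage_params(delta5 = 0.3, delta3 = 0.3, decay = 0.5)
#' @export
damage_params <- function(delta5 = 0.1, delta3 = 0.1, decay = 0.5,
                          background_error = 0.001,
                          min_frag = 30L, max_frag = 120L) {
  stopifnot(delta5 >= 0, delta5 <= 1, delta3 >= 0, delta3 <= 1,
            decay > 0, decay <= 1,
            background_error >= 0, background_error <= 0.05,
            min_frag >= 30, max_frag <= 200, min_frag <= max_frag)
  structure(list(delta5 = delta5, delta3 = delta3, decay = decay,
                 background_error = background_error,
                 min_frag = as.integer(min_frag),
                 max_frag = as.integer(max_frag)),
            class = "damage_params")
}

#' Build a random reference panel
#'
#' Generates i.i.d. random reference sequences at a target GC content,
#' labelled by domain.  Stands in for a curated nucleotide reference
#' database at desk scale.
#'
#' @param n_taxa_per_domain named integer vector over
#'   `c("Bacteria","Archaea","Eukaryota")` (or a single integer applied to
#'   all three domains).
#' @param seq_length reference length in nt, `>= 200`.
#' @param gc_content target GC fraction in (0,1).
#' @param seed integer seed; the panel is deterministic given it.
#' @return a `data.frame` with columns `taxon_id`, `name`, `domain`,
#'   `sequence`.
#' @examples
#' panel <- build_reference_panel(1, seq_length = 500, seed = 1)
#' @export
build_reference_panel <- function(n_taxa_per_domain, seq_length = 1000L,
                                  gc_content = 0.5, seed = 1L) {
  if (length(n_taxa_per_domain) == 1L && is.null(names(n_taxa_per_domain)))
    n_taxa_per_domain <- setNames(rep(n_taxa_per_domain, 3L), DOMAINS)
  if (!all(names(n_taxa_per_domain) %in% DOMAINS))
    stop("n_taxa_per_domain must be named by domain: ",
         paste(DOMAINS, collapse = ", "))
  if (any(n_taxa_per_domain < 1)) stop("taxon counts must be positive")
  if (seq_length < 200) stop("seq_length must be >= 200")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  withr_seed(seed, {
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    rows <- lapply(names(n_taxa_per_domain), function(dom) {
      k <- n_taxa_per_domain[[dom]]
      ids <- sprintf("%s_%03d", tolower(substr(dom, 1, 3)), seq_len(k))
      seqs <- vapply(seq_len(k), function(i) {
        paste(sample(DNA_BASES, seq_length, replace = TRUE, prob = probs),
              collapse = "")
      }, character(1))
      data.frame(taxon_id = ids,
                 name = sprintf("%s taxon %d", dom, seq_len(k)),
                 domain = dom, sequence = seqs, stringsAsFactors = FALSE)
    })
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    panel
  })
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply terminal deamination damage to a fragment
#'
#' The fragment is taken in sequenced 5'->3' orientation.  Deamination is
#' applied first (C->T from the 5' end, G->A from the 3' end, geometric
#' position decay), then uniform background substitutions.  Every change
#' is recorded as a lesion with both end-relative positions.
#'
#' Uses the current RNG state; seed the stream with [set.seed()] (or let
#' [simulate_sample()] manage seeding) for reproducibility.
#'
#' @param fragment nucleotide string over A/C/G/T.
#' @param params a [damage_params()] object.
#' @return list with `sequence` (damaged fragment), `lesions` (data.frame
#'   `pos5`, `pos3`, `ref`, `obs`, `source`), and `is_damaged_terminal`
#'   (TRUE when any C->T lies at 5' positions 1-5 or any G->A at 3'
#'   positions 1-5).
#' @examples
#' set.seed(1)
#' apply_damage("CCCC", damage_params(1, 0, 1, 0))
#' @export
apply_damage <- function(fragment, params) {
  stopifnot(inherits(params, "damage_params"), nchar(fragment) >= 1)
  s <- strsplit(fragment, "", fixed = TRUE)[[1]]
  L <- length(s)
  orig <- s
  pos5 <- seq_len(L)
  pos3 <- L - pos5 + 1L

  src <- character(0); where <- integer(0)
  iC <- which(s == "C")
  if (length(iC) && params$delta5 > 0) {
    p <- params$delta5 * params$decay^(pos5[iC] - 1)
    hit <- iC[runif(length(iC)) < p]
    s[hit] <- "T"
    where <- c(where, hit); src <- c(src, rep("deamination", length(hit)))
  }
  iG <- which(s == "G")
  if (length(iG) && params$delta3 > 0) {
    p <- params$delta3 * params$decay^(pos3[iG] - 1)
    hit <- iG[runif(length(iG)) < p]
    s[hit] <- "A"
    where <- c(where, hit); src <- c(src, rep("deamination", length(hit)))
  }
  if (params$background_error > 0) {
    hit <- which(runif(L) < params$background_error)
    for (i in hit) s[i] <- sample(setdiff(DNA_BASES, s[i]), 1L)
    where <- c(where, hit); src <- c(src, rep("background", length(hit)))
  }
  keep <- s[where] != orig[where]            # background may restore a base
  where <- where[keep]; src <- src[keep]
  o <- order(where)
  lesions <- data.frame(pos5 = pos5[where][o], pos3 = pos3[where][o],
                        ref = orig[where][o], obs = s[where][o],
                        source = src[o], stringsAsFactors = FALSE)
  flag <- any(lesions$ref == "C" & lesions$obs == "T" & lesions$pos5 <= 5) ||
          any(lesions$ref == "G" & lesions$obs == "A" & lesions$pos3 <= 5)
  list(sequence = paste(s, collapse = ""), lesions = lesions,
       is_damaged_terminal = flag)
}

#' Exact probability that a fixed fragment is classified as damaged
#'
#' Enumerates the C positions within the first 5 bases and G positions
#' within the last 5 bases of the fragment and combines the independent
#' per-position conversion probabilities (deamination plus background) in
#' closed form.  Serves as the analytic counterpart of Monte-Carlo runs of
#' [apply_damage()].
#'
#' @inheritParams apply_damage
#' @return probability in \[0,1\].
#' @export
terminal_damage_prob <- function(fragment, params) {
  s <- strsplit(fragment, "", fixed = TRUE)[[1]]
  L <- length(s)
  bg <- params$background_error
  p_no <- 1
  for (i in seq_len(min(5L, L))) {
    if (s[i] == "C") {
      q <- params$delta5 * params$decay^(i - 1)
      p_no <- p_no * (1 - (q * (1 - bg) + (1 - q) * bg / 3))
    }
  }
  for (j in seq_len(min(5L, L))) {
    i <- L - j + 1L
    if (s[i] == "G") {
      q <- params$delta3 * params$decay^(j - 1)
      p_no <- p_no * (1 - (q * (1 - bg) + (1 - q) * bg / 3))
    }
  }
  1 - p_no
}

#' Specify a simulated sample
#'
#' Bundles the metadata and generative settings of one sediment sample:
#' depth below seafloor, dataset type (shotgun or one of the two capture
#' styles), read count, domain mixture and damage model.
#'
#' @param sample_id sample identifier.
#' @param depth_cmbsf depth in centimetres below seafloor (>= 0).
#' @param age_years age relative to 1950 (negative = post-1950); metadata
#'   only.
#' @param dataset_label one of `"shotgun"`, `"planktonbaits"`,
#'   `"habbaits"`.
#' @param n_reads number of reads to simulate.
#' @param domain_mix named proportions over the three domains, summing
#'   to 1.
#' @param damage a [damage_params()] object.
#' @param seed master seed for this sample; all of its randomness flows
#'   from it.
#' @return a `sample_spec` list.
#' @export
sample_spec <- function(sample_id, depth_cmbsf = 0, age_years = NA_real_,
                        dataset_label = c("shotgun", "planktonbaits",
                                          "habbaits"),
                        n_reads = 1000L,
                        domain_mix = c(Bacteria = 0.86, Archaea = 0.09,
                                       Eukaryota = 0.05),
                        damage = damage_params(), seed = 1L) {
  dataset_label <- match.arg(dataset_label)
  stopifnot(depth_cmbsf >= 0, n_reads >= 0,
            inherits(damage, "damage_params"))
  if (!setequal(names(domain_mix), DOMAINS) ||
      any(domain_mix < 0) || abs(sum(domain_mix) - 1) > 1e-9)
    stop("domain_mix must be named proportions over ",
         paste(DOMAINS, collapse = ", "), " summing to 1")
  structure(list(sample_id = sample_id, depth_cmbsf = depth_cmbsf,
                 age_years = age_years, dataset_label = dataset_label,
                 n_reads = as.integer(n_reads),
                 domain_mix = domain_mix[DOMAINS], damage = damage,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

#' Default domain mixtures by dataset type
#'
#' Shotgun sequencing of coastal marine sediment is dominated by Bacteria
#' (0.86/0.09/0.05 Bacteria/Archaea/Eukaryota); the two capture styles
#' raise the eukaryote share to 0.21 (broad plankton baits) and 0.47
#' (harmful-algal-bloom baits) at the expense of Bacteria.
#'
#' @param dataset_label one of `"shotgun"`, `"planktonbaits"`,
#'   `"habbaits"`.
#' @return named proportions over the three domains.
#' @export
default_domain_mix <- function(dataset_label) {
  switch(dataset_label,
    shotgun       = c(Bacteria = 0.86, Archaea = 0.09, Eukaryota = 0.05),
    planktonbaits = c(Bacteria = 0.70, Archaea = 0.09, Eukaryota = 0.21),
    habbaits      = c(Bacteria = 0.45, Archaea = 0.08, Eukaryota = 0.47),
    stop("unknown dataset_label: ", dataset_label))
}

#' Specify a depth-indexed series of samples
#'
#' Builds the study-design defaults of the synthetic core: `n_samples`
#' samples at evenly spaced depths whose terminal-deamination rate rises
#' linearly with depth from `delta_range[1]` to `delta_range[2]`
#' (both ends, `delta3 = delta5`).
#'
#' @param dataset_label dataset type; sets the domain mixture and default
#'   read count via [default_domain_mix()].
#' @param n_samples number of samples (default 27).
#' @param depths depths in cmbsf (default evenly spaced 0-130).
#' @param delta_range range of the terminal deamination rate across the
#'   series (default 0.02 to 0.25).
#' @param n_reads reads per sample (default 1200 shotgun, 800 capture).
#' @param decay,background_error damage model settings.
#' @param seed base seed; sample `i` uses `seed + i`.
#' @return list of [sample_spec()] objects.
#' @export
depth_series_specs <- function(dataset_label = "shotgun", n_samples = 27L,
                               depths = seq(0, 130, length.out = n_samples),
                               delta_range = c(0.02, 0.25),
                               n_reads = if (dataset_label == "shotgun")
                                 1200L else 800L,
                               decay = 0.5, background_error = 0.001,
                               seed = 1L) {
  stopifnot(length(depths) == n_samples)
  deltas <- delta_range[1] +
    (delta_range[2] - delta_range[1]) * (depths - min(depths)) /
      max(depths - min(depths))
  lapply(seq_len(n_samples), function(i) {
    sample_spec(sample_id = sprintf("%s_%02d", dataset_label, i),
                depth_cmbsf = depths[i],
                dataset_label = dataset_label, n_reads = n_reads,
                domain_mix = default_domain_mix(dataset_label),
                damage = damage_params(deltas[i], deltas[i], decay,
                                       background_error),
                seed = seed + i)
  })
}

#' Simulate a read set from a reference panel
#'
#' Draws `spec$n_reads` fragments: taxon by `spec$domain_mix` then
#' uniformly within the domain, start uniform on the reference, length
#' uniform on `[min_frag, max_frag]` (clamped to the reference), strand
#' uniform.  Minus-strand fragments are reverse-complemented before
#' damage, so all lesions are recorded in sequenced orientation.
#'
#' @param panel a reference panel from [build_reference_panel()].
#' @param spec a [sample_spec()].
#' @return list with `reads` (named character vector of damaged read
#'   sequences) and `truth` (data.frame `read_id`, `taxon_id`, `domain`,
#'   `ref_start` (0-based), `ref_end` (half-open), `strand`, `length`,
#'   `is_damaged_terminal`, plus a list column `lesions`).
#' @export
simulate_sample <- function(panel, spec) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0,
            inherits(spec, "sample_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_reads
    if (n == 0L)
      return(list(reads = setNames(character(0), character(0)),
                  truth = empty_truth()))
    doms <- sample(DOMAINS, n, replace = TRUE, prob = spec$domain_mix)
    taxon <- vapply(doms, function(d) {
      cand <- panel$taxon_id[panel$domain == d]
      if (!length(cand)) stop("panel has no taxa in domain ", d)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, character(1), USE.NAMES = FALSE)
    refs <- setNames(panel$sequence, panel$taxon_id)
    reflen <- nchar(refs)[taxon]
    len <- pmin(sample(spec$damage$min_frag:spec$damage$max_frag, n,
                       replace = TRUE), reflen)
    start <- vapply(seq_len(n), function(i) {
      sample.int(reflen[i] - len[i] + 1L, 1L) - 1L   # 0-based
    }, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frags <- substr(refs[taxon], start + 1L, start + len)
    frags[strand == "-"] <- revcomp(frags[strand == "-"])
    read_id <- sprintf("%s_r%05d", spec$sample_id, seq_len(n))
    dmg <- lapply(frags, apply_damage, params = spec$damage)
    truth <- data.frame(read_id = read_id, taxon_id = taxon,
                        domain = doms, ref_start = start,
                        ref_end = start + len, strand = strand,
                        length = len,
                        is_damaged_terminal =
                          vapply(dmg, `[[`, logical(1),
                                 "is_damaged_terminal"),
                        stringsAsFactors = FALSE)
    truth$lesions <- lapply(dmg, `[[`, "lesions")
    reads <- setNames(vapply(dmg, `[[`, character(1), "sequence"), read_id)
    list(reads = reads, truth = truth)
  })
}

empty_truth <- function() {
  t <- data.frame(read_id = character(0), taxon_id = character(0),
                  domain = character(0), ref_start = integer(0),
                  ref_end = integer(0), strand = character(0),
                  length = integer(0), is_damaged_terminal = logical(0),
                  stringsAsFactors = FALSE)
  t$lesions <- list()
  t
}

#' Simulate an extraction blank control (EBC)
#'
#' EBC reads come only from laboratory/reagent contaminant taxa and carry
#' no deamination damage (background sequencing error only) — they are
#' modern DNA.
#'
#' @param panel reference panel.
#' @param contaminant_taxa character vector of `taxon_id`s, a non-empty
#'   subset of the panel.
#' @param n_reads number of reads.
#' @param seed master seed.
#' @param background_error per-base error rate (default 0.001).
#' @param min_frag,max_frag fragment length bounds.
#' @return as [simulate_sample()].
#' @export
simulate_ebc <- function(panel, contaminant_taxa, n_reads, seed = 1L,
                         background_error = 0.001,
                         min_frag = 30L, max_frag = 120L) {
  if (!length(contaminant_taxa))
    stop("contaminant_taxa must be non-empty")
  missing <- setdiff(contaminant_taxa, panel$taxon_id)
  if (length(missing))
    stop("contaminant taxa not in panel: ", paste(missing, collapse = ", "))
  sub <- panel[panel$taxon_id %in% contaminant_taxa, , drop = FALSE]
  # equal weight across contaminants irrespective of domain: give every
  # contaminant its own pseudo-domain weight by sampling taxa directly
  withr_seed(seed, {
    if (n_reads == 0L)
      return(list(reads = setNames(character(0), character(0)),
                  truth = empty_truth()))
    params <- damage_params(0, 0, 1, background_error, min_frag, max_frag)
    taxon <- sample(sub$taxon_id, n_reads, replace = TRUE)
    refs <- setNames(sub$sequence, sub$taxon_id)
    domv <- setNames(sub$domain, sub$taxon_id)
    reflen <- nchar(refs)[taxon]
    len <- pmin(sample(min_frag:max_frag, n_reads, replace = TRUE), reflen)
    start <- vapply(seq_len(n_reads), function(i) {
      sample.int(reflen[i] - len[i] + 1L, 1L) - 1L
    }, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    frags <- substr(refs[taxon], start + 1L, start + len)
    frags[strand == "-"] <- revcomp(frags[strand == "-"])
    read_id <- sprintf("ebc_r%05d", seq_len(n_reads))
    dmg <- lapply(frags, apply_damage, params = params)
    truth <- data.frame(read_id = read_id, taxon_id = taxon,
                        domain = domv[taxon], ref_start = start,
                        ref_end = start + len, strand = strand,
                        length = len,
                        is_damaged_terminal =
                          vapply(dmg, `[[`, logical(1),
                                 "is_damaged_terminal"),
                        stringsAsFactors = FALSE)
    truth$lesions <- lapply(dmg, `[[`, "lesions")
    rownames(truth) <- NULL
    reads <- setNames(vapply(dmg, `[[`, character(1), "sequence"), read_id)
    list(reads = reads, truth = truth)
  })
}
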