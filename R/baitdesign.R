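#' Mask short N runs
#'
#' Every maximal run of Ns shorter than 10 is converted to Ts; runs of 10
#' or more are left as Ns (baits overlapping them are discarded at tiling
#' time).  Idempotent.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return masked sequence.
#' @examples
#' mask_n_runs("ACGTNNNNACGT")
#' @export
mask_n_runs <- function(sequence) {
  m <- gregexpr("N+", sequence)[[1]]
  if (m[1] == -1L) return(sequence)
  len <- attr(m, "match.length")
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_along(m)) {
    if (len[i] < 10L)
      s[m[i]:(m[i] + len[i] - 1L)] <- "T"
  }
  paste(s, collapse = "")
}

#' Pad short targets with trailing Ts
#'
#' Targets shorter than `min_length` (default 84 nt, one bait length plus
#' one tiling step) are extended with Ts to exactly `min_length`; longer
#' targets are unchanged.
#'
#' @param sequence target sequence.
#' @param min_length padded length (default 84).
#' @return padded sequence.
#' @export
pad_target <- function(sequence, min_length = 84L) {
  stopifnot(nzchar(sequence))
  L <- nchar(sequence)
  if (L >= min_length) return(sequence)
  paste0(sequence, strrep("T", min_length - L))
}

#' Tile bait candidates over a padded target
#'
#' Baits of `bait_length` nt start every `round(bait_length / density)`
#' nt (27 at the defaults — 3x tiling); when the last regular start
#' leaves the 3' end uncovered one additional bait is clamped to
#' `length - bait_length`.  Baits containing an N (an unmasked long run)
#' are discarded.
#'
#' @param target padded target sequence.
#' @param bait_length bait size in nt (default 80).
#' @param density tiling density (default 3).
#' @param target_id provenance label.
#' @return data.frame `bait_id`, `target_id`, `offset` (0-based start on
#'   the padded target), `sequence`, `status` (`"raw"`); empty (with a
#'   message) when the target is shorter than `bait_length`.
#' @export
tile_baits <- function(target, bait_length = 80L, density = 3L,
                       target_id = "target") {
  L <- nchar(target)
  empty <- data.frame(bait_id = character(0), target_id = character(0),
                      offset = integer(0), sequence = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (L < bait_length) {
    message("target ", target_id, " shorter than bait length; no baits")
    return(empty)
  }
  step <- as.integer(round(bait_length / density))
  starts <- seq.int(0L, L - bait_length, by = step)
  if (max(starts) + bait_length < L) starts <- c(starts, L - bait_length)
  seqs <- substr(rep(target, length(starts)), starts + 1L,
                 starts + bait_length)
  keep <- !grepl("N", seqs, fixed = TRUE)
  data.frame(bait_id = sprintf("%s_%05d", target_id, starts[keep]),
             target_id = target_id, offset = starts[keep],
             sequence = seqs[keep], status = "raw",
             stringsAsFactors = FALSE)
}

# best ungapped offset alignment between two equal-length baits:
# TRUE when some shift keeps > min_overlap of the bait length aligned
# at > min_identity over the overlap
bait_redundant <- function(a, b, min_overlap = 0.83, min_identity = 0.95) {
  bl <- nchar(a)
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  max_shift <- bl - floor(bl * min_overlap) - 1L   # overlap must exceed
  for (s in -max_shift:max_shift) {
    ov <- bl - abs(s)
    if (ov / bl <= min_overlap) next
    ia <- if (s >= 0) (1L + s):bl else 1L:(bl + s)
    ib <- if (s >= 0) 1L:ov else (1L - s):bl
    if (sum(sa[ia] == sb[ib]) / ov > min_identity) return(TRUE)
  }
  FALSE
}

#' Collapse redundant baits
#'
#' Greedy single-linkage clustering under the redundancy predicate: two
#' baits are redundant when their best ungapped offset alignment covers
#' more than `min_overlap` of the bait length at more than `min_identity`
#' over the overlap.  One representative per cluster is retained (lowest
#' `target_id`, then lowest `offset`), so no two retained baits are
#' redundant with each other's cluster seed; idempotent on its output.
#'
#' @param baits bait data.frame from [tile_baits()] (all one length).
#' @param min_overlap minimum overlap fraction (default 0.83, exclusive).
#' @param min_identity minimum identity over the overlap (default 0.95,
#'   exclusive).
#' @return the retained rows, with dropped rows' status set to
#'   `"collapsed-away"` in the `removed` attribute.
#' @export
collapse_baits <- function(baits, min_overlap = 0.83, min_identity = 0.95) {
  n <- nrow(baits)
  if (n <= 1L) return(baits)
  o <- order(baits$target_id, baits$offset)
  baits <- baits[o, , drop = FALSE]
  # union-find over redundant pairs (single linkage, transitive)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    if (bait_redundant(baits$sequence[i], baits$sequence[j],
                       min_overlap, min_identity))
      parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- !duplicated(roots)          # rows sorted: first of cluster wins
  removed <- baits[!keep, , drop = FALSE]
  if (nrow(removed)) removed$status <- "collapsed-away"
  out <- baits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Estimate a hybridisation melting temperature
#'
#' Classical salt/GC/length/mismatch linear Tm model:
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 (%GC) - 675/N - (%mismatch)`,
#' with 0.9 M Na+ as the standard hybridisation buffer.  Hits shorter
#' than 20 nt have no defined Tm (`NA`) and are ignored downstream.
#'
#' @param n_len aligned length in nt.
#' @param gc_fraction GC fraction of the aligned region, in \[0,1\].
#' @param mismatch_fraction mismatch fraction over the aligned region.
#' @param sodium_molar monovalent cation concentration (default 0.9 M).
#' @return Tm in degrees Celsius (`NA_real_` when `n_len < 20`).
#' @examples
#' estimate_tm(80, 0.5, 0)  # ~92.8 C
#' @export
estimate_tm <- function(n_len, gc_fraction, mismatch_fraction = 0,
                        sodium_molar = 0.9) {
  ifelse(n_len < 20, NA_real_,
         81.5 + 16.6 * log10(sodium_molar) + 0.41 * (100 * gc_fraction) -
           675 / n_len - 100 * mismatch_fraction)
}

#' Screen a bait against a genome panel
#'
#' Exact-seed (11-mer) anchored ungapped extension on both strands: every
#' diagonal sharing a seed is scanned for its best ungapped segment
#' (match +1 / mismatch -1) and segments reaching `min_score` are
#' reported with aligned length, percent identity, score
#' (matches - mismatches) and estimated Tm.  A desk-scale stand-in for a
#' BLAST screen; deterministic.
#'
#' @param bait bait sequence.
#' @param genomes named character vector of genome sequences.
#' @param k seed size (default 11).
#' @param min_score minimum segment score (default 11).
#' @param sodium_molar passed to [estimate_tm()].
#' @return data.frame `genome_id`, `strand`, `q_start`, `s_start`
#'   (1-based; minus-strand coordinates on the reverse complement),
#'   `length`, `matches`, `pident`, `score`, `tm`.
#' @export
screen_hits <- function(bait, genomes, k = 11L, min_score = 11L,
                        sodium_molar = 0.9) {
  rows <- list()
  for (g in names(genomes)) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") genomes[[g]] else revcomp(genomes[[g]])
      h <- cpp_screen_ungapped(bait, subj, k, min_score)
      if (!nrow(h)) next
      h$genome_id <- g; h$strand <- strand
      seg <- substr(rep(bait, nrow(h)), h$q_start,
                    h$q_start + h$length - 1L)
      gc <- vapply(strsplit(seg, "", fixed = TRUE), function(s)
        mean(s %in% c("G", "C")), numeric(1))
      h$pident <- 100 * h$matches / h$length
      h$tm <- estimate_tm(h$length, gc,
                          (h$length - h$matches) / h$length, sodium_molar)
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows))
    return(data.frame(genome_id = character(0), strand = character(0),
                      q_start = integer(0), s_start = integer(0),
                      length = integer(0), matches = integer(0),
                      pident = numeric(0), score = integer(0),
                      tm = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$genome_id, out$s_start),
             c("genome_id", "strand", "q_start", "s_start", "length",
               "matches", "pident", "score", "tm")]
  rownames(out) <- NULL
  out
}

#' Hit-count filter for add-on baits
#'
#' Hits below both 60 bp aligned length and 80% identity are discarded
#' from the count; the bait is kept only when fewer than `max_hits`
#' qualifying hits remain.
#'
#' @param hits hit data.frame with `length` and `pident`.
#' @param min_len,min_pident a hit is only excluded from the count when
#'   it falls below both (defaults 60 bp / 80%).
#' @param max_hits keep the bait iff qualifying hits `< max_hits`
#'   (default 50).
#' @return list `keep` (logical), `n_hits` (qualifying hit count).
#' @export
hit_count_filter <- function(hits, min_len = 60L, min_pident = 80,
                             max_hits = 50L) {
  qual <- !(hits$length < min_len & hits$pident < min_pident)
  n <- sum(qual)
  list(keep = n < max_hits, n_hits = n)
}

# Tm-bin bookkeeping for one bait's post-discard, post-truncation target
# hits. thresholds = c(60, 62.5, 65, 67.5, 70).
tm_bins <- function(tm, thresholds = c(60, 62.5, 65, 67.5, 70)) {
  tm <- tm[!is.na(tm)]
  list(above60 = sum(tm > thresholds[1]),
       mid = sum(tm > thresholds[2] & tm <= thresholds[3]),
       high = sum(tm > thresholds[3] & tm <= thresholds[4]),
       band = sum(tm > thresholds[4] & tm < thresholds[5]),
       vhigh = sum(tm >= thresholds[5]))
}

# evaluate the specificity conditions for one bait; flank counts may be
# NA in round 1 (conditions c-e then unavailable)
specificity_conditions <- function(bins, n_passing_flanks = NA_integer_,
                                   n_failing_flanks = NA_integer_) {
  if (bins$above60 == 0) return("a")
  clean_high <- bins$high == 0 && bins$band == 0 && bins$vhigh == 0
  if (bins$mid <= 2 && clean_high) return("b")
  if (!is.na(n_failing_flanks) && bins$mid <= 10 && clean_high &&
      n_failing_flanks >= 1) return("c")
  if (!is.na(n_passing_flanks) && bins$mid <= 10 && bins$high <= 2 &&
      bins$band == 0 && bins$vhigh == 0 && n_passing_flanks < 2)
    return("d")
  if (!is.na(n_passing_flanks) && bins$mid <= 2 && bins$high <= 1 &&
      bins$band == 0 && bins$vhigh <= 1 && n_passing_flanks < 2)
    return("e")
  NA_character_
}

#' Tm-based specificity filter over a bait set
#'
#' Per bait: any hit against a non-target genome fails it outright;
#' otherwise the single highest-Tm target-genome hit is discarded
#' (allowing one legitimate locus), hits are truncated to the top
#' `max_hits` by score, binned by Tm, and the bait passes when one of the
#' stringency conditions holds: (a) no hits above 60 C; (b) at most 2
#' hits in 62.5-65 C and none hotter; (c) at most 10 hits in 62.5-65 C,
#' none hotter, and at least one failing flanking bait; (d) at most 10
#' hits in 62.5-65 C, at most 2 in 65-67.5 C, and fewer than 2 passing
#' flanking baits; (e) at most 2 hits in 62.5-65 C, at most 1 in
#' 65-67.5 C, at most 1 at 70 C or above, and fewer than 2 passing
#' flanking baits.
#'
#' Flank-dependent conditions are evaluated in two rounds: round 1 sets
#' provisional statuses from the flank-independent conditions (a)-(b);
#' round 2 evaluates (c)-(e) against the round-1 statuses of the
#' adjacent baits on the same target (a lone bait has no flanks; a flank
#' with unknown status counts as failing).
#'
#' @param baits bait data.frame (`bait_id`, `target_id`, `offset`).
#' @param hits data.frame of Tm hits over all baits (`bait_id`,
#'   `genome_id`, `score`, `tm`).
#' @param nontarget_genomes character vector of genome ids counted as
#'   non-target.
#' @param max_hits score-ranked truncation (default 500).
#' @param thresholds Tm bin edges in C (default
#'   `c(60, 62.5, 65, 67.5, 70)`).
#' @return `baits` with added columns `round1` (logical), `passed`
#'   (logical), `condition` (letter or NA), `fail_reason`.
#' @export
specificity_filter <- function(baits, hits, nontarget_genomes = character(0),
                               max_hits = 500L,
                               thresholds = c(60, 62.5, 65, 67.5, 70)) {
  n <- nrow(baits)
  binsl <- vector("list", n)
  nontarget_hit <- logical(n)
  for (i in seq_len(n)) {
    h <- hits[hits$bait_id == baits$bait_id[i], , drop = FALSE]
    if (any(h$genome_id %in% nontarget_genomes)) {
      nontarget_hit[i] <- TRUE
      next
    }
    h <- h[!is.na(h$tm), , drop = FALSE]
    if (nrow(h)) h <- h[-which.max(h$tm), , drop = FALSE]  # allow 1 locus
    h <- h[order(-h$score), , drop = FALSE]
    if (nrow(h) > max_hits) h <- h[seq_len(max_hits), , drop = FALSE]
    binsl[[i]] <- tm_bins(h$tm, thresholds)
  }
  round1 <- vapply(seq_len(n), function(i) {
    if (nontarget_hit[i]) return(FALSE)
    isTRUE(specificity_conditions(binsl[[i]]) %in% c("a", "b"))
  }, logical(1))
  passed <- logical(n); condition <- rep(NA_character_, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    if (nontarget_hit[i]) {
      reason[i] <- "non-target genome hit"
      next
    }
    sibs <- which(baits$target_id == baits$target_id[i])
    sibs <- sibs[order(baits$offset[sibs])]
    pos <- match(i, sibs)
    idx <- c(pos - 1L, pos + 1L)
    fl <- sibs[idx[idx >= 1L & idx <= length(sibs)]]
    npass <- sum(round1[fl])
    nfail <- length(fl) - npass
    cond <- specificity_conditions(binsl[[i]], npass, nfail)
    if (!is.na(cond)) {
      passed[i] <- TRUE; condition[i] <- cond
    } else reason[i] <- "no specificity condition satisfied"
  }
  baits$round1 <- round1
  baits$passed <- passed
  baits$condition <- condition
  baits$fail_reason <- reason
  baits$status <- ifelse(passed, "passed", "failed")
  baits
}

#' Broad-panel bait design (mask, pad, tile, exclusion screen, collapse)
#'
#' The generalist design flow: N-run masking, padding to 84 nt, 3x
#' tiling of 80-nt baits, removal of baits hitting any exclusion genome
#' (e.g. a bacterial reference panel), and redundancy collapse.
#'
#' @param targets named character vector of target sequences.
#' @param exclusion_genomes named character vector of genomes whose hits
#'   disqualify a bait (optional).
#' @param bait_length,density,pad_length,min_overlap,min_identity
#'   pipeline thresholds (defaults 80 / 3 / 84 / 0.83 / 0.95).
#' @param seed_k,min_score screen settings ([screen_hits()]).
#' @return list `baits` (retained bait data.frame), `counts` (named
#'   integer bookkeeping: raw, post_screen, collapsed).
#' @export
design_baits <- function(targets, exclusion_genomes = NULL,
                         bait_length = 80L, density = 3L,
                         pad_length = 84L, min_overlap = 0.83,
                         min_identity = 0.95, seed_k = 11L,
                         min_score = 11L) {
  tiled <- do.call(rbind, lapply(names(targets), function(id) {
    tile_baits(pad_target(mask_n_runs(targets[[id]]), pad_length),
               bait_length, density, target_id = id)
  }))
  raw <- nrow(tiled)
  if (!is.null(exclusion_genomes) && raw > 0) {
    hit <- vapply(tiled$sequence, function(b) {
      nrow(screen_hits(b, exclusion_genomes, seed_k, min_score)) > 0
    }, logical(1), USE.NAMES = FALSE)
    tiled <- tiled[!hit, , drop = FALSE]
  }
  post <- nrow(tiled)
  collapsed <- collapse_baits(tiled, min_overlap, min_identity)
  list(baits = collapsed,
       counts = c(raw = raw, post_screen = post,
                  collapsed = nrow(collapsed)))
}

#' Reference bookkeeping of the two published bait sets
#'
#' The raw/filtered/final bait counts of the two published capture sets
#' this pipeline emulates: the broad plankton set (41,798 raw 80-nt
#' baits, 36,836 after the bacterial exclusion screen, 15,942 after
#' collapse, plus 10 cyanobacterial add-on baits = 15,952 total) and the
#' harmful-algal-bloom set (23,064 raw, 15,310 after Tm specificity
#' filtering).  Used as consistency anchors in tests; the counts
#' themselves are database-snapshot dependent and not recomputable at
#' desk scale.
#'
#' @return data.frame `bait_set`, `raw`, `post_screen`, `collapsed`,
#'   `addon`, `total`.
#' @export
published_bait_counts <- function() {
  data.frame(
    bait_set = c("planktonbaits1", "habbaits1"),
    raw = c(41798L, 23064L),
    post_screen = c(36836L, NA_integer_),
    collapsed = c(15942L, NA_integer_),
    addon = c(10L, 0L),
    total = c(15952L, 15310L),
    stringsAsFactors = FALSE)
}
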