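#' Semi-global alignment of a read against one reference
#'
#' Glocal alignment: the read is aligned end to end, the reference
#' contributes a local substring.  Both strands are tried and the better
#' kept; events are always reported in the read's sequenced 5'->3'
#' orientation (for minus-strand hits the reference is
#' reverse-complemented internally, so reference bases are given on the
#' strand the read matches).  A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`; with the defaults every gap column
#' costs 2.
#'
#' @param read read sequence (sequenced orientation), length >= 20.
#' @param reference reference sequence.
#' @param taxon_id optional taxon label carried into the result.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (defaults +1/-1/2/2; gap costs are positive numbers subtracted from
#'   the score).
#' @return a one-row data.frame with `read_id` (NA here; fillers add it),
#'   `taxon_id`, `strand`, `score`, `pident`, `ref_start` (0-based on the
#'   given reference strand), `ref_end`, `n_col` (aligned columns),
#'   `status` (`"ok"` or `"too short"`), and an `events` string encoding
#'   one record per aligned column as `pos5:pos3:ref>read` joined by
#'   commas (gap-in-read columns have pos5 = pos3 = 0).
#' @export
align_semi_global <- function(read, reference, taxon_id = NA_character_,
                              match = 1L, mismatch = -1L,
                              gap_open = 2L, gap_extend = 2L) {
  if (nchar(read) < 20)
    return(data.frame(taxon_id = taxon_id, strand = NA_character_,
                      score = NA_integer_, pident = NA_real_,
                      ref_start = NA_integer_, ref_end = NA_integer_,
                      n_col = NA_integer_, status = "too short",
                      events = NA_character_, stringsAsFactors = FALSE))
  fwd <- cpp_align_semiglobal(read, reference, match, mismatch,
                              gap_open, gap_extend)
  rcref <- revcomp(reference)
  rev <- cpp_align_semiglobal(read, rcref, match, mismatch,
                              gap_open, gap_extend)
  n <- nchar(reference)
  if (rev$score > fwd$score) {
    aln <- rev; strand <- "-"
    ref_start <- n - aln$ref_end; ref_end <- n - aln$ref_start
  } else {
    aln <- fwd; strand <- "+"
    ref_start <- aln$ref_start; ref_end <- aln$ref_end
  }
  ra <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  qa <- strsplit(aln$read_aln, "", fixed = TRUE)[[1]]
  m <- nchar(read)
  pos5 <- aln$pos5
  pos3 <- ifelse(pos5 > 0L, m - pos5 + 1L, 0L)
  n_col <- length(ra)
  pident <- 100 * sum(ra == qa) / n_col
  data.frame(taxon_id = taxon_id, strand = strand, score = aln$score,
             pident = pident, ref_start = ref_start, ref_end = ref_end,
             n_col = n_col, status = "ok",
             events = paste(sprintf("%d:%d:%s>%s", pos5, pos3, ra, qa),
                            collapse = ","),
             stringsAsFactors = FALSE)
}

#' Decode a compact event string
#'
#' @param events a `pos5:pos3:ref>read` comma-joined string as produced by
#'   [align_semi_global()].
#' @return data.frame with columns `pos5`, `pos3`, `ref`, `read`
#'   (gap columns carry `pos5 = pos3 = 0` and `"-"`).
#' @export
decode_events <- function(events) {
  if (is.na(events) || !nzchar(events))
    return(data.frame(pos5 = integer(0), pos3 = integer(0),
                      ref = character(0), read = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(events, ",", fixed = TRUE)[[1]], "[:>]")
  data.frame(pos5 = as.integer(vapply(parts, `[`, character(1), 1L)),
             pos3 = as.integer(vapply(parts, `[`, character(1), 2L)),
             ref = vapply(parts, `[`, character(1), 3L),
             read = vapply(parts, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Align a set of reads against a reference panel
#'
#' For every read, candidate references are pre-screened for a shared
#' 11-mer on either strand (a seed heuristic in the spirit of
#' production-scale aligners); candidates are aligned semi-globally and
#' the per-reference best alignments returned.  When no reference shares
#' a seed the read is aligned against the whole panel, so the heuristic
#' never silently drops a read.
#'
#' @param reads named character vector (names are read ids).
#' @param panel reference panel data.frame (`taxon_id`, `sequence`).
#' @param seed_k k-mer size of the candidate screen (default 11); set to
#'   `0` to disable the screen and align every read against every
#'   reference.
#' @inheritParams align_semi_global
#' @return data.frame of alignments, one row per (read, candidate
#'   reference), columns as [align_semi_global()] plus `read_id`.
#' @export
align_reads <- function(reads, panel, seed_k = 11L,
                        match = 1L, mismatch = -1L,
                        gap_open = 2L, gap_extend = 2L) {
  stopifnot(!is.null(names(reads)))
  refs <- setNames(panel$sequence, panel$taxon_id)
  rcrefs <- revcomp(refs)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    cand <- names(refs)
    if (seed_k > 0L && nchar(rd) >= seed_k) {
      hit <- vapply(seq_along(refs), function(j) {
        cpp_shared_kmer(rd, refs[[j]], seed_k) ||
          cpp_shared_kmer(rd, rcrefs[[j]], seed_k)
      }, logical(1))
      if (any(hit)) cand <- names(refs)[hit]
    }
    rows <- lapply(cand, function(tx) {
      align_semi_global(rd, refs[[tx]], taxon_id = tx, match = match,
                        mismatch = mismatch, gap_open = gap_open,
                        gap_extend = gap_extend)
    })
    df <- do.call(rbind, rows)
    df <- cbind(read_id = names(reads)[i], df, stringsAsFactors = FALSE)
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter a read's alignments by identity and top score fraction
#'
#' Drops alignments below the percent-identity floor (inclusive boundary:
#' `pident >= min_pident` passes), then keeps alignments whose score is
#' within `top_fraction` of the surviving maximum
#' (`score >= (1 - top_fraction) * max`).
#'
#' @param alignments data.frame of alignments for one read.
#' @param min_pident minimum percent identity (default 95).
#' @param top_fraction retained score window below the maximum
#'   (default 0.10).
#' @return the surviving rows (possibly none).
#' @export
filter_alignments <- function(alignments, min_pident = 95,
                              top_fraction = 0.10) {
  ok <- alignments[!is.na(alignments$pident) &
                     alignments$pident >= min_pident, , drop = FALSE]
  if (!nrow(ok)) return(ok)
  ok[ok$score >= (1 - top_fraction) * max(ok$score), , drop = FALSE]
}

#' Assign a read to a taxon (naive LCA on ties)
#'
#' A unique top-scoring taxon wins outright; ties across taxa fall back
#' to the lowest common ancestor in the supplied two-level taxonomy
#' (shared domain, else the root).
#'
#' @param surviving pre-filtered alignments of one read (possibly empty).
#' @param taxonomy data.frame mapping `taxon_id` to `domain` (the panel
#'   works as is).
#' @return one-row data.frame: `assigned_id`, `level` (`"taxon"`,
#'   `"domain"`, `"root"`, `"unassigned"`), `domain` (NA above domain
#'   level), `n_candidate_alignments`, `passed_filters`.
#' @export
assign_read <- function(surviving, taxonomy) {
  if (!nrow(surviving))
    return(data.frame(assigned_id = NA_character_, level = "unassigned",
                      domain = NA_character_, n_candidate_alignments = 0L,
                      passed_filters = FALSE, stringsAsFactors = FALSE))
  missing <- setdiff(surviving$taxon_id, taxonomy$taxon_id)
  if (length(missing))
    stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
  top <- surviving[surviving$score == max(surviving$score), , drop = FALSE]
  taxa <- unique(top$taxon_id)
  doms <- unique(taxonomy$domain[match(taxa, taxonomy$taxon_id)])
  if (length(taxa) == 1L)
    return(data.frame(assigned_id = taxa, level = "taxon", domain = doms,
                      n_candidate_alignments = nrow(surviving),
                      passed_filters = TRUE, stringsAsFactors = FALSE))
  if (length(doms) == 1L)
    return(data.frame(assigned_id = doms, level = "domain", domain = doms,
                      n_candidate_alignments = nrow(surviving),
                      passed_filters = TRUE, stringsAsFactors = FALSE))
  data.frame(assigned_id = "root", level = "root", domain = NA_character_,
             n_candidate_alignments = nrow(surviving),
             passed_filters = TRUE, stringsAsFactors = FALSE)
}

#' Filter and assign every read in an alignment table
#'
#' Applies [filter_alignments()] and [assign_read()] per read and keeps
#' each read's best surviving alignment (highest score, then highest
#' pident) for downstream damage typing — a read is counted once, via its
#' assigned taxon's best alignment.
#'
#' @param alignments output of [align_reads()].
#' @param taxonomy `taxon_id`/`domain` mapping (the panel works as is).
#' @inheritParams filter_alignments
#' @return list with `assignments` (one row per read: `read_id`,
#'   `assigned_id`, `level`, `domain`, `n_candidate_alignments`,
#'   `passed_filters`) and `best` (the per-read best surviving alignment
#'   rows, reads that failed filtering absent).
#' @export
assign_reads <- function(alignments, taxonomy, min_pident = 95,
                         top_fraction = 0.10) {
  split_aln <- split(alignments, alignments$read_id)
  asn <- vector("list", length(split_aln))
  best <- vector("list", length(split_aln))
  for (i in seq_along(split_aln)) {
    surv <- filter_alignments(split_aln[[i]], min_pident, top_fraction)
    a <- assign_read(surv, taxonomy)
    a$read_id <- names(split_aln)[i]
    asn[[i]] <- a
    if (nrow(surv)) {
      o <- order(-surv$score, -surv$pident, surv$taxon_id)
      best[[i]] <- surv[o[1L], , drop = FALSE]
    }
  }
  assignments <- do.call(rbind, asn)
  assignments <- assignments[, c("read_id", "assigned_id", "level",
                                 "domain", "n_candidate_alignments",
                                 "passed_filters")]
  rownames(assignments) <- NULL
  best <- do.call(rbind, best)
  if (!is.null(best)) rownames(best) <- NULL
  list(assignments = assignments,
       best = best %||% alignments[0, , drop = FALSE])
}
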