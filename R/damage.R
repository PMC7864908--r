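#' Classify a read as ancient or default from its alignment events
#'
#' A filter-passing read is "default"; it is additionally "ancient" when
#' its alignment shows at least one terminal damage lesion: a reference C
#' read as T within the first 5 bases from the 5' end, or a reference G
#' read as A within the first 5 bases from the 3' end (the two channels
#' of double-stranded-library deamination).  C->T near the 3' end (or
#' G->A near the 5' end) does not qualify.
#'
#' @param events decoded event data.frame ([decode_events()]) or the
#'   compact event string of one alignment.
#' @param passed_filters whether the alignment survived filtering; when
#'   `FALSE` both flags are `FALSE`.
#' @param window terminal window size in bases (default 5).
#' @return list `default_flag`, `ancient_flag` (ancient implies default).
#' @export
classify_read <- function(events, passed_filters = TRUE, window = 5L) {
  if (!passed_filters)
    return(list(default_flag = FALSE, ancient_flag = FALSE))
  if (is.character(events)) events <- decode_events(events)
  anc <- any(events$ref == "C" & events$read == "T" &
               events$pos5 >= 1L & events$pos5 <= window) ||
         any(events$ref == "G" & events$read == "A" &
               events$pos3 >= 1L & events$pos3 <= window)
  list(default_flag = TRUE, ancient_flag = anc)
}

#' Classify every read's best alignment
#'
#' @param best per-read best alignments (`best` element of
#'   [assign_reads()]).
#' @param window terminal window size (default 5).
#' @return data.frame `read_id`, `default_flag`, `ancient_flag`.
#' @export
classify_reads <- function(best, window = 5L) {
  # vectorised scan of the compact event encoding; equivalent to
  # classify_read() per row (property-tested)
  w <- paste0("(", paste(seq_len(window), collapse = "|"), ")")
  re5 <- paste0("(^|,)", w, ":[0-9]+:C>T(,|$)")
  re3 <- paste0("(^|,)[0-9]+:", w, ":G>A(,|$)")
  anc <- grepl(re5, best$events) | grepl(re3, best$events)
  data.frame(read_id = best$read_id, default_flag = TRUE,
             ancient_flag = anc, stringsAsFactors = FALSE)
}

#' Per-taxon ancient/default read counts
#'
#' Counts each assigned read once (via its best alignment).  Only
#' taxon-level assignments contribute; taxa with neither default nor
#' ancient reads are omitted.
#'
#' @param assignments assignment table from [assign_reads()].
#' @param classes classification table from [classify_reads()].
#' @param taxonomy `taxon_id`/`domain` mapping.
#' @return data.frame `taxon_id`, `domain`, `n_default`, `n_ancient`
#'   (`n_ancient <= n_default`, never both zero).
#' @export
summarize_taxa <- function(assignments, classes, taxonomy) {
  a <- assignments[assignments$passed_filters &
                     assignments$level == "taxon", , drop = FALSE]
  if (!nrow(a))
    return(data.frame(taxon_id = character(0), domain = character(0),
                      n_default = integer(0), n_ancient = integer(0),
                      stringsAsFactors = FALSE))
  cl <- classes[match(a$read_id, classes$read_id), , drop = FALSE]
  n_default <- tapply(cl$default_flag, a$assigned_id, sum)
  n_ancient <- tapply(cl$ancient_flag, a$assigned_id, sum)
  out <- data.frame(taxon_id = names(n_default),
                    domain = taxonomy$domain[match(names(n_default),
                                                   taxonomy$taxon_id)],
                    n_default = as.integer(n_default),
                    n_ancient = as.integer(n_ancient),
                    stringsAsFactors = FALSE)
  out <- out[out$n_default > 0 | out$n_ancient > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional misincorporation profile for one taxon
#'
#' For each read end (5', 3') and each of the 12 substitution types, the
#' frequency at positions 1..P is the number of aligned columns at that
#' position showing the substitution divided by the number of columns
#' whose reference base is the substitution's source base.  Positions
#' with zero denominator are reported as `NA`, not zero.  C->T from the
#' 5' end and G->A from the 3' end are the damage signal channels; the
#' remaining types form the noise estimate ([profile_noise()]).
#'
#' A profile is only emitted when at least `min_reads` alignments are
#' supplied; real sedaDNA work profiles a species from as few as 50
#' reads, and below that the positional frequencies are too unstable.
#'
#' @param alignments alignment rows (with `events`) of the reads to
#'   profile — the figure-style profile uses ancient reads only; pass all
#'   filter-passing reads to estimate the generative damage rates.
#' @param P maximum position from each end (default 10).
#' @param min_reads minimum alignments required (default 50).
#' @param taxon_id label stored in the result.
#' @return object of class `damage_profile`: list with `taxon_id`,
#'   `n_reads` and `table` (data.frame `end`, `position`, `sub`,
#'   `numerator`, `denominator`, `frequency`), or a list with
#'   `status = "insufficient reads"` when below `min_reads`.
#' @export
build_profile <- function(alignments, P = 10L, min_reads = 50L,
                          taxon_id = NA_character_) {
  n <- nrow(alignments)
  if (is.null(n) || n < min_reads)
    return(structure(list(status = "insufficient reads",
                          taxon_id = taxon_id, n_reads = n %||% 0L),
                     class = "damage_profile"))
  # positions are read-relative, so alignments can be pooled before decoding
  ev <- decode_events(paste(alignments$events, collapse = ","))
  ev <- ev[ev$pos5 > 0L, , drop = FALSE]         # drop gap-in-read columns
  subs <- expand.grid(ref = DNA_BASES, read = DNA_BASES,
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$read, , drop = FALSE]
  grid <- expand.grid(end = c("5p", "3p"), position = seq_len(P),
                      i = seq_len(nrow(subs)), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    end <- grid$end[g]; pos <- grid$position[g]
    rf <- subs$ref[grid$i[g]]; rd <- subs$read[grid$i[g]]
    at <- if (end == "5p") ev$pos5 == pos else ev$pos3 == pos
    den <- sum(at & ev$ref == rf & ev$read != "-")
    num <- sum(at & ev$ref == rf & ev$read == rd)
    data.frame(end = end, position = pos, sub = paste0(rf, ">", rd),
               numerator = num, denominator = den,
               frequency = if (den > 0) num / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$end, tab$position, tab$sub), ]
  rownames(tab) <- NULL
  structure(list(status = "ok", taxon_id = taxon_id, n_reads = n,
                 table = tab),
            class = "damage_profile")
}

#' Signal channel of a damage profile
#'
#' @param profile a `damage_profile` from [build_profile()].
#' @param end `"5p"` (C->T) or `"3p"` (G->A).
#' @return data.frame `position`, `frequency` of the damage channel for
#'   that end.
#' @export
profile_signal <- function(profile, end = c("5p", "3p")) {
  end <- match.arg(end)
  stopifnot(profile$status == "ok")
  sub <- if (end == "5p") "C>T" else "G>A"
  t <- profile$table
  t <- t[t$end == end & t$sub == sub, c("position", "frequency")]
  rownames(t) <- NULL
  t
}

#' Noise channel of a damage profile
#'
#' Mean frequency per end and position across the 10 substitution types
#' that are neither C->T nor G>A (missing frequencies excluded from the
#' mean).
#'
#' @param profile a `damage_profile`.
#' @return data.frame `end`, `position`, `noise`.
#' @export
profile_noise <- function(profile) {
  stopifnot(profile$status == "ok")
  t <- profile$table
  t <- t[!(t$sub %in% c("C>T", "G>A")), , drop = FALSE]
  agg <- aggregate(frequency ~ end + position, data = t, FUN = mean,
                   na.rm = TRUE, na.action = NULL)
  names(agg)[3] <- "noise"
  agg$noise[is.nan(agg$noise)] <- NA_real_
  agg[order(agg$end, agg$position), ]
}

#' @export
print.damage_profile <- function(x, ...) {
  if (x$status != "ok") {
    cat("<damage_profile>", x$taxon_id, "-", x$status,
        sprintf("(%d reads)\n", x$n_reads))
    return(invisible(x))
  }
  cat("<damage_profile>", x$taxon_id, "from", x$n_reads, "reads\n")
  s5 <- profile_signal(x, "5p"); s3 <- profile_signal(x, "3p")
  cat("  5' C>T:", paste(sprintf("%.3f", s5$frequency[1:5]),
                         collapse = " "), "\n")
  cat("  3' G>A:", paste(sprintf("%.3f", s3$frequency[1:5]),
                         collapse = " "), "\n")
  invisible(x)
}
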