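# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Full-matrix Gotoh semi-global score: read aligned end to end, reference
# local, gap of length k costs open + (k - 1) * extend.  One strand.
oracle_semiglobal_score <- function(read, ref, match = 1, mismatch = -1,
                                    open = 2, extend = 2) {
  m <- nchar(read); n <- nchar(ref)
  r <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in 2:(m + 1)) Y[i, 1] <- -open - (i - 2) * extend
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sc <- if (r[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - extend,
                     Y[i, j - 1] - open)
      Y[i, j] <- max(M[i - 1, j] - open, Y[i - 1, j] - extend,
                     X[i - 1, j] - open)
    }
  }
  max(M[m + 1, ], Y[m + 1, ])
}

oracle_semiglobal_best <- function(read, ref, ...) {
  max(oracle_semiglobal_score(read, ref, ...),
      oracle_semiglobal_score(oracle_revcomp(read), ref, ...))
}

# event-list scan for the ancient/default rule
oracle_classify <- function(events, window = 5) {
  for (k in seq_len(nrow(events))) {
    if (events$ref[k] == "C" && events$read[k] == "T" &&
        events$pos5[k] >= 1 && events$pos5[k] <= window)
      return(TRUE)
    if (events$ref[k] == "G" && events$read[k] == "A" &&
        events$pos3[k] >= 1 && events$pos3[k] <= window)
      return(TRUE)
  }
  FALSE
}

# pairwise redundancy predicate recomputed from scratch for the collapse
# oracle: best ungapped offset alignment, > min_overlap of bait length
# and > min_identity over the overlap
oracle_redundant <- function(a, b, min_overlap = 0.83,
                             min_identity = 0.95) {
  bl <- nchar(a)
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  for (s in (-bl + 1):(bl - 1)) {
    ov <- bl - abs(s)
    if (ov / bl <= min_overlap) next
    if (s >= 0) { ia <- (1 + s):bl; ib <- 1:ov }
    else { ia <- 1:ov; ib <- (1 - s):bl }
    if (sum(sa[ia] == sb[ib]) / ov > min_identity) return(TRUE)
  }
  FALSE
}

# transitive-closure clusters under the redundancy predicate
oracle_collapse_clusters <- function(seqs, ...) {
  n <- length(seqs)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cl[i] != cl[j] && oracle_redundant(seqs[i], seqs[j], ...)) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cl
}

# brute-force ungapped local optima on every diagonal (one strand)
oracle_ungapped_hits <- function(query, subject, min_score = 11) {
  m <- nchar(query); n <- nchar(subject)
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  hits <- list()
  for (d in (-(m - 1)):(n - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(m, n - d)
    if (i0 > i1) next
    cur <- 0; best <- 0; curs <- i0; bs <- i0; be <- i0 - 1
    for (i in i0:i1) {
      v <- if (q[i] == s[i + d]) 1 else -1
      if (cur <= 0) { cur <- v; curs <- i } else cur <- cur + v
      if (cur > best) { best <- cur; bs <- curs; be <- i }
    }
    if (best >= min_score) {
      len <- be - bs + 1
      nm <- sum(q[bs:be] == s[(bs:be) + d])
      hits[[length(hits) + 1]] <-
        data.frame(q_start = bs, s_start = bs + d, length = len,
                   matches = nm, score = best)
    }
  }
  if (!length(hits))
    return(data.frame(q_start = integer(0), s_start = integer(0),
                      length = integer(0), matches = integer(0),
                      score = integer(0)))
  do.call(rbind, hits)
}

# small mixed-domain panel shared by several tests
toy_panel <- function(seq_length = 600, n = c(Bacteria = 2, Archaea = 2,
                                              Eukaryota = 2), seed = 42) {
  build_reference_panel(n, seq_length = seq_length, seed = seed)
}

# random compact event string plus its decoded form
rand_events <- function(read_len = 60, n_mismatch = 4) {
  pos <- sort(sample(read_len, n_mismatch))
  ref <- sample(c("A", "C", "G", "T"), n_mismatch, replace = TRUE)
  read <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  all_pos <- seq_len(read_len)
  refs <- sample(c("A", "C", "G", "T"), read_len, replace = TRUE)
  reads <- refs
  refs[pos] <- ref; reads[pos] <- read
  paste(sprintf("%d:%d:%s>%s", all_pos, read_len - all_pos + 1, refs,
                reads), collapse = ",")
}
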