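test_that("N-run masking converts only runs shorter than 10", {
  expect_equal(mask_n_runs("ACGTNNNNACGT"), "ACGTTTTTACGT")
  expect_equal(mask_n_runs(strrep("N", 10)), strrep("N", 10))
  expect_equal(mask_n_runs(paste0("AC", strrep("N", 9), "GT")),
               paste0("AC", strrep("T", 9), "GT"))
  set.seed(71)
  for (i in 1:100) {
    s <- rand_seq(sample(30:120, 1), alphabet = c("A", "C", "G", "T",
                                                  "N", "N"))
    expect_identical(mask_n_runs(mask_n_runs(s)), mask_n_runs(s))
  }
})

test_that("short targets are padded to exactly 84 nt with trailing Ts", {
  p <- pad_target(rand_seq(60))
  expect_equal(nchar(p), 84L)
  expect_equal(substr(p, 61, 84), strrep("T", 24))
  s84 <- rand_seq(84)
  expect_identical(pad_target(s84), s84)
  s200 <- rand_seq(200)
  expect_identical(pad_target(s200), s200)
})

test_that("3x tiling steps by 27 nt and clamps the terminal bait", {
  b80 <- tile_baits(rand_seq(80), target_id = "t")
  expect_equal(nrow(b80), 1L)
  expect_equal(b80$offset, 0L)

  b84 <- tile_baits(rand_seq(84), target_id = "t")
  expect_equal(b84$offset, c(0L, 4L))

  b134 <- tile_baits(rand_seq(134), target_id = "t")
  expect_equal(b134$offset, c(0L, 27L, 54L))
  expect_equal(max(b134$offset) + 80L, 134L)

  expect_true(all(nchar(b134$sequence) == 80))

  # baits over unmasked N runs are discarded
  withN <- paste0(rand_seq(40), strrep("N", 12), rand_seq(100))
  bN <- tile_baits(withN, target_id = "t")
  expect_false(any(grepl("N", bN$sequence)))

  expect_message(empty <- tile_baits(rand_seq(60), target_id = "t"),
                 "shorter")
  expect_equal(nrow(empty), 0L)

  # coverage: the union of bait intervals spans any N-free target
  set.seed(81)
  for (L in sample(80:400, 10)) {
    b <- tile_baits(rand_seq(L), target_id = "t")
    covered <- logical(L)
    for (k in seq_len(nrow(b)))
      covered[(b$offset[k] + 1):(b$offset[k] + 80)] <- TRUE
    expect_true(all(covered))
  }
})

test_that("collapse drops redundant baits and matches the closure oracle", {
  set.seed(91)
  s <- rand_seq(80)
  two_same <- data.frame(bait_id = c("a", "b"), target_id = c("t1", "t2"),
                         offset = c(0L, 0L), sequence = c(s, s),
                         status = "raw")
  kept <- collapse_baits(two_same)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$target_id, "t1")     # lowest target wins

  # 66/80 = 82.5% overlap at full identity: below the >83% bar
  core <- rand_seq(94)
  a <- substr(core, 1, 80); b <- substr(core, 15, 94)
  near <- data.frame(bait_id = c("a", "b"), target_id = "t",
                     offset = c(0L, 14L), sequence = c(a, b),
                     status = "raw")
  expect_equal(nrow(collapse_baits(near)), 2L)

  # random sets against the brute-force transitive closure
  for (rep in 1:5) {
    base <- replicate(6, rand_seq(80))
    seqs <- character(0)
    for (s0 in base) {
      seqs <- c(seqs, s0)
      if (runif(1) < 0.7) {           # near-duplicate by light mutation
        v <- strsplit(s0, "")[[1]]
        for (k in sample(80, sample(0:3, 1)))
          v[k] <- sample(c("A", "C", "G", "T"), 1)
        seqs <- c(seqs, paste(v, collapse = ""))
      }
    }
    df <- data.frame(bait_id = sprintf("b%02d", seq_along(seqs)),
                     target_id = "t", offset = seq_along(seqs) - 1L,
                     sequence = seqs, status = "raw")
    kept <- collapse_baits(df)
    cl <- oracle_collapse_clusters(seqs)
    expect_equal(nrow(kept), length(unique(cl)))
    # soundness: retained baits pairwise non-redundant clusters
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept))
        expect_false(cl[match(kept$bait_id[i], df$bait_id)] ==
                       cl[match(kept$bait_id[j], df$bait_id)])
    }
    # idempotence
    again <- collapse_baits(kept)
    expect_equal(again$bait_id, kept$bait_id)
  }
})

test_that("Tm model evaluates the salt/GC/length/mismatch formula", {
  expect_equal(estimate_tm(80, 0.5, 0),
               81.5 + 16.6 * log10(0.9) + 20.5 - 675 / 80,
               tolerance = 1e-12)
  expect_equal(estimate_tm(80, 0.5, 0), 92.80, tolerance = 0.01)
  expect_equal(estimate_tm(80, 0.5, 0) - estimate_tm(80, 0.5, 0.10), 10)
  expect_true(is.na(estimate_tm(19, 0.5, 0)))
  # monotone in GC and length, decreasing in mismatch
  expect_gt(estimate_tm(80, 0.6, 0), estimate_tm(80, 0.5, 0))
  expect_gt(estimate_tm(80, 0.5, 0), estimate_tm(60, 0.5, 0))
  expect_gt(estimate_tm(80, 0.5, 0), estimate_tm(80, 0.5, 0.05))
})

test_that("hit-count filter uses the conjunctive discard and <50 rule", {
  mk <- function(n, len = 70, pid = 90)
    data.frame(length = rep(len, n), pident = rep(pid, n))
  expect_true(hit_count_filter(mk(49))$keep)
  expect_false(hit_count_filter(mk(50))$keep)
  # 55 bp at 75% identity fails both thresholds: excluded from the count
  mixed <- rbind(mk(49), data.frame(length = 55, pident = 75))
  expect_true(hit_count_filter(mixed)$keep)
  expect_equal(hit_count_filter(mixed)$n_hits, 49L)
  # short but high-identity hits still count
  still <- rbind(mk(49), data.frame(length = 55, pident = 90))
  expect_false(hit_count_filter(still)$keep)
})

test_that("specificity conditions pass and fail as printed", {
  baits <- data.frame(bait_id = c("b1", "b2", "b3"), target_id = "t",
                      offset = c(0L, 27L, 54L), sequence = "x",
                      status = "raw")
  hit <- function(bait, genome, tm, score = 50)
    data.frame(bait_id = bait, genome_id = genome, score = score, tm = tm)
  # zero hits after the top-Tm discard: (a)
  h0 <- hit("b1", "target_g", 75)
  r0 <- specificity_filter(baits[1, ], h0)
  expect_true(r0$passed)
  expect_equal(r0$condition, "a")
  # two hits in 62.5-65 and none hotter: (b) (third hit absorbs discard)
  hb <- rbind(hit("b1", "g", 64), hit("b1", "g", 63), hit("b1", "g", 64.5))
  rb <- specificity_filter(baits[1, ], hb)
  expect_true(rb$passed)
  expect_equal(rb$condition, "b")
  # a non-target hit fails outright, whatever the Tm
  hn <- rbind(hit("b1", "good_g", 40), hit("b1", "bad_g", 30))
  rn <- specificity_filter(baits[1, ], hn, nontarget_genomes = "bad_g")
  expect_false(rn$passed)
  expect_match(rn$fail_reason, "non-target")
  # adding hits cannot rescue a bait failing under (a)-(b)
  many <- do.call(rbind, lapply(1:8, function(i) hit("b1", "g", 64)))
  r_many <- specificity_filter(baits[1, ], many)
  expect_false(r_many$round1)
  more <- rbind(many, hit("b1", "g", 63.5))
  expect_false(specificity_filter(baits[1, ], more)$round1)
  # ... but a failing flank opens condition (c) in round 2
  h3 <- rbind(many,
              do.call(rbind, lapply(1:8, function(i) hit("b2", "g", 64))),
              hit("b3", "g", 40))
  r3 <- specificity_filter(baits, h3)
  expect_false(r3$round1[1])
  expect_true(r3$passed[1])
  expect_equal(r3$condition[1], "c")
})

test_that("screening finds planted hits and matches the diagonal oracle", {
  set.seed(101)
  genome <- rand_seq(2000)
  bait <- substr(genome, 501, 580)
  h <- screen_hits(bait, c(g1 = genome))
  plus <- h[h$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$pident, 100)
  expect_equal(plus$length, 80L)
  expect_equal(plus$s_start, 501L)

  # no shared 11-mer on either strand, no hits
  expect_equal(nrow(screen_hits(strrep("A", 80),
                                c(g = strrep("C", 500)))), 0L)

  # seeded search equals the exhaustive diagonal oracle; compared at a
  # score floor high enough that a qualifying segment always contains an
  # exact seed (at the default floor a chance 15/18-match segment can
  # score in without any 11-mer run, which no seeded search can see)
  for (rep in 1:20) {
    g <- rand_seq(500)
    b <- if (rep %% 2 == 0) rand_seq(80) else {
      x <- substr(g, 101, 180)
      v <- strsplit(x, "")[[1]]
      for (k in sample(80, 4)) v[k] <- sample(c("A", "C", "G", "T"), 1)
      paste(v, collapse = "")
    }
    got <- screen_hits(b, c(g = g), min_score = 20L)
    got_plus <- got[got$strand == "+",
                    c("q_start", "s_start", "length", "matches", "score")]
    want <- oracle_ungapped_hits(b, g, min_score = 20)
    o1 <- got_plus[order(got_plus$s_start), ]
    o2 <- want[order(want$s_start), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
    if (rep %% 2 == 1) {     # the planted locus is found at the default
      def <- screen_hits(b, c(g = g))
      expect_true(any(def$strand == "+" & def$s_start >= 95 &
                        def$s_start <= 185 & def$score >= 60))
    }
  }
})

test_that("broad design flow is deterministic and bookkeeping consistent", {
  set.seed(111)
  targets <- setNames(replicate(3, rand_seq(sample(60:200, 1))),
                      c("t1", "t2", "t3"))
  excl <- c(bac = rand_seq(1000))
  d1 <- design_baits(targets, excl)
  d2 <- design_baits(targets, excl)
  expect_identical(d1, d2)
  expect_true(d1$counts["raw"] >= d1$counts["post_screen"])
  expect_true(d1$counts["post_screen"] >= d1$counts["collapsed"])

  pub <- published_bait_counts()
  pb <- pub[pub$bait_set == "planktonbaits1", ]
  expect_equal(pb$collapsed + pb$addon, pb$total)
})
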