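test_that("ancient classification applies the strand-polarised rule", {
  ev1 <- data.frame(pos5 = 2L, pos3 = 59L, ref = "C", read = "T")
  expect_true(classify_read(ev1)$ancient_flag)

  # T>C at 5' position 1 and G>A at 3' position 6 both miss the rule
  ev2 <- data.frame(pos5 = c(1L, 55L), pos3 = c(60L, 6L),
                    ref = c("T", "G"), read = c("C", "A"))
  cl2 <- classify_read(ev2)
  expect_true(cl2$default_flag)
  expect_false(cl2$ancient_flag)

  # C>T near the 3' end does not qualify
  ev3 <- data.frame(pos5 = 58L, pos3 = 3L, ref = "C", read = "T")
  expect_false(classify_read(ev3)$ancient_flag)

  expect_false(classify_read(ev1, passed_filters = FALSE)$default_flag)
})

test_that("classify_read and the vectorised classifier match a scan oracle", {
  set.seed(31)
  for (i in 1:300) {
    enc <- rand_events(sample(30:90, 1), sample(0:6, 1))
    ev <- decode_events(enc)
    want <- oracle_classify(ev)
    expect_identical(classify_read(ev)$ancient_flag, want)
    got_vec <- classify_reads(data.frame(read_id = "r", events = enc))
    expect_identical(got_vec$ancient_flag, want)
  }
})

test_that("per-taxon summaries count, omit and add up", {
  asn <- data.frame(read_id = sprintf("r%02d", 1:12),
                    assigned_id = c(rep("euk_001", 10), "bac_001",
                                    "bac_001"),
                    level = "taxon", domain = c(rep("Eukaryota", 10),
                                                "Bacteria", "Bacteria"),
                    n_candidate_alignments = 1, passed_filters = TRUE)
  cls <- data.frame(read_id = sprintf("r%02d", 1:12),
                    default_flag = TRUE,
                    ancient_flag = c(rep(TRUE, 3), rep(FALSE, 9)))
  panel <- toy_panel()
  s <- summarize_taxa(asn, cls, panel)
  euk <- s[s$taxon_id == "euk_001", ]
  expect_equal(euk$n_default, 10L)
  expect_equal(euk$n_ancient, 3L)
  expect_true(all(s$n_ancient <= s$n_default))

  # reads failing filters leave no taxa behind
  asn_f <- asn; asn_f$passed_filters <- FALSE
  expect_equal(nrow(summarize_taxa(asn_f, cls, panel)), 0L)

  # additivity across merged read sets
  s2 <- summarize_taxa(rbind(asn, asn), rbind(cls, cls), panel)
  expect_equal(s2$n_default[s2$taxon_id == "euk_001"], 20L)
})

test_that("profiles gate on read count and report exact frequencies", {
  few <- data.frame(read_id = sprintf("r%d", 1:49),
                    events = rep("1:60:C>T", 49))
  p <- build_profile(few, taxon_id = "t")
  expect_equal(p$status, "insufficient reads")

  # every read C>T at 5' position 1 over a C reference base
  certain <- data.frame(read_id = sprintf("r%d", 1:60),
                        events = rep("1:60:C>T,2:59:A>A", 60))
  pc <- build_profile(certain, taxon_id = "t")
  expect_equal(pc$status, "ok")
  s5 <- profile_signal(pc, "5p")
  expect_equal(s5$frequency[1], 1.0)
  # no A reference at position 1: missing, not zero
  tab <- pc$table
  expect_true(is.na(tab$frequency[tab$end == "5p" & tab$position == 1 &
                                    tab$sub == "A>C"]))
})

test_that("profile recovers generative damage rates from all reads", {
  panel <- build_reference_panel(c(Bacteria = 1, Archaea = 1,
                                   Eukaryota = 1),
                                 seq_length = 1500, seed = 51)
  spec <- sample_spec("pr", n_reads = 2500, seed = 52,
                      domain_mix = c(Bacteria = 0, Archaea = 0,
                                     Eukaryota = 1),
                      damage = damage_params(0.3, 0.3, 0.5, 0))
  sim <- simulate_sample(panel, spec)
  auth <- authenticate_reads(sim$reads, panel)
  prof <- build_profile(auth$best, taxon_id = "euk_001")
  s5 <- profile_signal(prof, "5p")
  s3 <- profile_signal(prof, "3p")
  tab <- prof$table
  for (pos in 1:2) {
    want <- 0.3 * 0.5^(pos - 1)
    den5 <- tab$denominator[tab$end == "5p" & tab$position == pos &
                              tab$sub == "C>T"]
    expect_lt(abs(s5$frequency[pos] - want),
              3 * sqrt(want * (1 - want) / den5))
    den3 <- tab$denominator[tab$end == "3p" & tab$position == pos &
                              tab$sub == "G>A"]
    expect_lt(abs(s3$frequency[pos] - want),
              3 * sqrt(want * (1 - want) / den3))
  }
  # noise stays near zero without background error
  nz <- profile_noise(prof)
  expect_lt(max(nz$noise, na.rm = TRUE), 0.02)
})

test_that("swapping read ends and complementing swaps signal channels", {
  set.seed(61)
  enc <- replicate(80, rand_events(60, 5))
  aln <- data.frame(read_id = sprintf("r%d", 1:80), events = enc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  enc_swapped <- vapply(enc, function(e) {
    ev <- decode_events(e)
    paste(sprintf("%d:%d:%s>%s", ev$pos3, ev$pos5, comp[ev$ref],
                  comp[ev$read]), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  aln2 <- data.frame(read_id = aln$read_id, events = enc_swapped)
  p1 <- build_profile(aln, taxon_id = "t")
  p2 <- build_profile(aln2, taxon_id = "t")
  expect_equal(profile_signal(p2, "3p")$frequency,
               profile_signal(p1, "5p")$frequency)
  expect_equal(profile_signal(p2, "5p")$frequency,
               profile_signal(p1, "3p")$frequency)
})

test_that("classification agrees with simulator truth at zero background", {
  panel <- build_reference_panel(c(Bacteria = 1, Archaea = 1,
                                   Eukaryota = 2),
                                 seq_length = 800, seed = 71)
  spec <- sample_spec("tc", n_reads = 600, seed = 72,
                      damage = damage_params(0.25, 0.25, 0.5, 0))
  sim <- simulate_sample(panel, spec)
  auth <- authenticate_reads(sim$reads, panel)
  m <- merge(auth$classes,
             sim$truth[, c("read_id", "taxon_id", "is_damaged_terminal")],
             by = "read_id")
  asn <- auth$assignments[match(m$read_id, auth$assignments$read_id), ]
  ok <- asn$assigned_id == m$taxon_id       # alignment found true locus
  expect_gt(mean(ok), 0.95)
  expect_true(all(m$ancient_flag[ok] == m$is_damaged_terminal[ok]))
})
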