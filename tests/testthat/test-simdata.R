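test_that("reference panels have requested shape, GC and determinism", {
  p <- build_reference_panel(1, seq_length = 500, gc_content = 0.5,
                             seed = 1)
  expect_equal(nrow(p), 3L)
  expect_setequal(p$domain, c("Bacteria", "Archaea", "Eukaryota"))
  expect_true(all(nchar(p$sequence) == 500))
  expect_true(all(strsplit(paste(p$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_false(any(duplicated(p$taxon_id)))

  expect_identical(p, build_reference_panel(1, 500, 0.5, seed = 1))

  big <- build_reference_panel(c(Eukaryota = 1, Bacteria = 1, Archaea = 1),
                               seq_length = 10000, gc_content = 0.5,
                               seed = 3)
  gc <- mean(strsplit(big$sequence[1], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(build_reference_panel(0, 500), "positive")
  expect_error(build_reference_panel(1, 100), ">= 200")
})

test_that("apply_damage honours zero-rate, certainty and conservation", {
  set.seed(1)
  none <- apply_damage("ACGTACGT", damage_params(0, 0, 1, 0))
  expect_identical(none$sequence, "ACGTACGT")
  expect_equal(nrow(none$lesions), 0L)
  expect_false(none$is_damaged_terminal)

  full <- apply_damage("CCCC", damage_params(1, 0, 1, 0))
  expect_identical(full$sequence, "TTTT")
  expect_equal(nrow(full$lesions), 4L)
  expect_true(all(full$lesions$ref == "C" & full$lesions$obs == "T"))
  expect_true(full$is_damaged_terminal)

  set.seed(9)
  for (i in 1:50) {
    f <- rand_seq(sample(30:120, 1))
    d <- apply_damage(f, damage_params(0.4, 0.4, 0.6, 0.01))
    expect_equal(nchar(d$sequence), nchar(f))
  }
})

test_that("deamination rates recover the generative parameters", {
  set.seed(7)
  n <- 20000
  params <- damage_params(0.3, 0, 0.5, 0)
  frag <- paste0("CC", strrep("A", 38))
  hits1 <- hits2 <- 0L
  for (i in seq_len(n)) {
    d <- apply_damage(frag, params)
    s <- substr(d$sequence, 1, 2)
    if (substr(s, 1, 1) == "T") hits1 <- hits1 + 1L
    if (substr(s, 2, 2) == "T") hits2 <- hits2 + 1L
  }
  expect_lt(abs(hits1 / n - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(hits2 / n - 0.15), 3 * sqrt(0.15 * 0.85 / n))
})

test_that("terminal-lesion flag is recomputable and monotone in delta5", {
  set.seed(21)
  frags <- replicate(400, rand_seq(sample(30:120, 1)))
  rates <- c(0, 0.1, 0.3, 0.6)
  frac <- numeric(length(rates))
  for (k in seq_along(rates)) {
    params <- damage_params(rates[k], rates[k], 0.5, 0.002)
    flags <- logical(0)
    for (f in frags[1:200]) {
      d <- apply_damage(f, params)
      # recompute from the lesion list
      re <- any(d$lesions$ref == "C" & d$lesions$obs == "T" &
                  d$lesions$pos5 <= 5) ||
            any(d$lesions$ref == "G" & d$lesions$obs == "A" &
                  d$lesions$pos3 <= 5)
      expect_identical(re, d$is_damaged_terminal)
      flags <- c(flags, d$is_damaged_terminal)
    }
    frac[k] <- mean(flags)
  }
  # non-decreasing within 3 SE at n = 200 per rate
  se <- sqrt(0.25 / 200)
  expect_true(all(diff(frac) > -3 * se))
})

test_that("closed-form damage probability matches Monte Carlo", {
  set.seed(5)
  for (rep in 1:3) {
    f <- rand_seq(60)
    params <- damage_params(0.35, 0.25, 0.5, 0.003)
    p <- terminal_damage_prob(f, params)
    n <- 5000
    obs <- mean(replicate(n, apply_damage(f, params)$is_damaged_terminal))
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("simulate_sample respects mixture, orientation and determinism", {
  panel <- toy_panel()
  spec0 <- sample_spec("s0", n_reads = 0, seed = 1)
  sim0 <- simulate_sample(panel, spec0)
  expect_length(sim0$reads, 0)
  expect_equal(nrow(sim0$truth), 0L)

  spec_e <- sample_spec("se", n_reads = 50,
                        domain_mix = c(Bacteria = 0, Archaea = 0,
                                       Eukaryota = 1), seed = 2)
  sim_e <- simulate_sample(panel, spec_e)
  expect_true(all(sim_e$truth$domain == "Eukaryota"))

  # fragments re-extracted from the reference reproduce the read
  # modulo lesions, on both strands
  refs <- setNames(panel$sequence, panel$taxon_id)
  spec_d <- sample_spec("sd", n_reads = 30, seed = 3,
                        damage = damage_params(0, 0, 1, 0))
  sim_d <- simulate_sample(panel, spec_d)
  for (i in seq_len(nrow(sim_d$truth))) {
    t <- sim_d$truth[i, ]
    frag <- substr(refs[[t$taxon_id]], t$ref_start + 1, t$ref_end)
    if (t$strand == "-") frag <- oracle_revcomp(frag)
    expect_identical(unname(sim_d$reads[[t$read_id]]), frag)
  }

  spec_m <- sample_spec("sm", n_reads = 50000, seed = 4,
                        domain_mix = c(Bacteria = 0.86, Eukaryota = 0.05,
                                       Archaea = 0.09),
                        damage = damage_params(0, 0, 1, 0))
  sim_m <- simulate_sample(toy_panel(seq_length = 400), spec_m)
  frac <- mean(sim_m$truth$domain == "Eukaryota")
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))

  again <- simulate_sample(panel, sample_spec("sd", n_reads = 30, seed = 3,
                                              damage = damage_params(0, 0, 1, 0)))
  expect_identical(sim_d$reads, again$reads)
})

test_that("EBC reads come only from contaminants, undamaged", {
  panel <- toy_panel()
  one <- simulate_ebc(panel, "euk_001", 40, seed = 5)
  expect_true(all(one$truth$taxon_id == "euk_001"))
  expect_false(any(one$truth$is_damaged_terminal &
                     vapply(one$truth$lesions, function(l)
                       any(l$source == "deamination"), logical(1))))

  two <- simulate_ebc(panel, c("euk_001", "bac_001"), 100, seed = 6)
  counts <- table(two$truth$taxon_id)
  expect_true(all(counts >= 20 & counts <= 80))

  expect_identical(simulate_ebc(panel, "euk_001", 40, seed = 5)$reads,
                   one$reads)
  expect_error(simulate_ebc(panel, "missing_taxon", 10), "not in panel")
  expect_error(simulate_ebc(panel, character(0), 10), "non-empty")
})
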