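# sedadna

Authentication of marine sedimentary ancient DNA (sedaDNA) and
hybridisation-capture bait design, as a tested, fully synthetic-data-
driven R workflow.

## The problem

Marine sediments archive DNA from past plankton communities, but
eukaryote sedaDNA is scarce (a few percent of a shotgun metagenome) and
any "ancient" claim needs authentication.  Old DNA carries terminal
cytosine deamination, read as C→T substitutions near the 5′ end of a
fragment and G→A near the 3′ end.  This package implements:

* a read simulator with a parametric terminal-damage model
  (C→T at 5′ position *i* with probability δ₅·d^(i−1), G→A mirrored at
  the 3′ end) and full ground truth;
* semi-global alignment with percent-identity (≥ 95) and top-score-
  fraction (0.10) filtering and naive-LCA taxon assignment;
* ancient/default read classification — a read is *ancient* when its
  alignment shows a damage lesion within the first 5 bases of either
  end — and per-position misincorporation profiles (≥ 50 reads per
  taxon);
* extraction-blank-control (EBC) taxon subtraction and the per-sample
  authenticity proxy
  **% eukaryote sedaDNA damage = 100 · Σ ancient / Σ default** over
  eukaryote taxa, with two-tailed Pearson depth correlations
  (t = r·sqrt((n−2)/(1−r²)));
* domain-proportion and capture-enrichment accounting;
* a bait-design pipeline: N-run masking, 84-nt padding, 80-nt baits at
  3× tiling (27-nt steps), redundancy collapse (> 83% overlap, > 95%
  identity), melting-temperature estimation
  (Tm = 81.5 + 16.6·log₁₀[Na⁺] + 0.41·%GC − 675/N − %mm) and the
  stringency conditions (a)–(e) with two-round flanking-bait logic.

## Worked example

```r
library(sedadna)

panel <- build_reference_panel(c(Bacteria = 2, Archaea = 2, Eukaryota = 2),
                               seq_length = 600, seed = 100)
spec <- sample_spec("deep", depth_cmbsf = 130, n_reads = 800,
                    domain_mix = default_domain_mix("habbaits"),
                    damage = damage_params(0.25, 0.25, 0.5, 0.001),
                    seed = 7)
sim  <- simulate_sample(panel, spec)
auth <- authenticate_reads(sim$reads, panel)
percent_damage(auth$summaries)
```

```
  pct_damage n_default_total n_ancient_total   ok
1   23.28767             365              85 TRUE
```

365 eukaryote reads passed the identity and top-fraction filters
("default"); 85 of them carry a terminal C→T/G→A lesion ("ancient"),
giving a damage proxy of 23.3% — the value expected for the deepest,
most-damaged layer of the synthetic core (δ = 0.25 maps to ≈ 24%
because each end's first five positions contribute ≈ 0.48·δ each).

The full study replay lives in `analysis/` (run from the repository
root, outputs under `results/`):

```sh
Rscript analysis/01_simulate.R          # panel + 3x27-sample design + EBC
Rscript analysis/02_authenticate.R      # align, classify, subtract, proxy
Rscript analysis/03_damage_profiles.R   # misincorporation profiles
Rscript analysis/04_depth_correlation.R # Table-style r/p matrix, enrichment
Rscript analysis/05_bait_design.R       # both bait-design flows
```

Stage 2 prints, per dataset, the depth correlation of the proxy —

```
shotgun        depth vs %damage: r = 0.687, p = 7.57e-05 (n = 27)
planktonbaits  depth vs %damage: r = 0.904, p = 1.09e-10 (n = 27)
habbaits       depth vs %damage: r = 0.940, p = 3.80e-13 (n = 27)
%-damage range across samples: 0.0-27.3%
```

— the shotgun proxy being the noisiest because only a few dozen
eukaryote reads per sample survive filtering and blank subtraction.
Stage 4 prints the compact correlation matrix (r below, two-tailed p
above the diagonal) and the eukaryote enrichment ratios of the two
capture datasets over shotgun (4.1× and 9.3× in this replay).

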