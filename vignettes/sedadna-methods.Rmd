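---
title: "Authenticating marine sedimentary ancient DNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating marine sedimentary ancient DNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedadna)
```

## The problem

DNA shed by past plankton communities is preserved in trace amounts in
seafloor sediment (sedimentary ancient DNA, sedaDNA).  Two obstacles
dominate its analysis.  First, eukaryote sequences are a small minority
of a shotgun metagenome from marine sediment (a few percent), so
hybridisation capture with RNA baits is used to enrich the taxa of
interest.  Second, any claim that a sequence is *ancient* needs
authentication: genuinely old DNA accumulates cytosine deamination at
fragment ends, visible after sequencing as C→T substitutions near the
5′ end and, on double-stranded libraries, G→A near the 3′ end.  This
package implements both halves — the damage-based authentication
workflow and the bait design pipeline — against synthetic data with full
ground truth, so every stage is testable.

## The damage model

`apply_damage()` implements a parametric terminal-deamination model: at
5′ position $i$ each C is read as T with probability
$\delta_5\,d^{\,i-1}$, at 3′ position $j$ each G is read as A with
probability $\delta_3\,d^{\,j-1}$, with decay $d \in (0,1]$, followed by
a uniform per-base background error.  This geometric shape was chosen
because it reproduces the canonical U-shaped terminal misincorporation
profile of ancient DNA; no generative model is prescribed by the damage
patterns themselves, which are only ever observed as positional
frequencies.  Substitutions only — no indels, nick/overhang physics,
quality scores or adapters — so fragment length is conserved and the
probability that a fixed fragment acquires a terminal lesion is an
elementary product over its first and last five bases
(`terminal_damage_prob()`), giving the simulator an exact oracle.

Fragment lengths are uniform on 30–120 nt.  Real subseafloor fragment
size distributions are library- and site-specific; uniform keeps the
closed-form enumeration trivial and spans the range where terminal-
lesion classification is meaningful.  Damage is applied after
reverse-complementing minus-strand fragments, i.e. in sequenced
orientation, matching how damage is observed in read alignments.

## Classification: default and ancient reads

Reads are aligned semi-globally (read end-to-end, reference locally;
match +1, mismatch −1, a gap of length $k$ costs $2k$; both strands
tried).  Two filters mirror standard ancient-metagenomics screening
settings: percent identity ≥ 95 (inclusive — the threshold is
documented as a minimum) and retention of alignments scoring within 10%
of the read's best.  Reads surviving the filters are "default"; the
subset whose best alignment shows at least one damage lesion within the
first five bases of either end is "ancient".  A damage lesion is
polarised: C→T counts only from the 5′ end and G→A only from the 3′
end.  The looser reading — either substitution at either end — is
defensible from the phrase "a lesion in the first 5 bases of either
end", but the polarised reading is what double-stranded-library
chemistry produces and what the signal channels of the standard profile
plots show, so it is used throughout.

Ties among equal-scoring taxa are resolved by a naive lowest-common-
ancestor over a two-level taxonomy (taxon → domain): deterministic,
never random.  Reads assigned above taxon level contribute to domain
proportions but not to per-taxon counts.  A destacking step (removing
stacked duplicate alignments) is deliberately absent: the emulated
configuration runs with destacking disabled.

## The % eukaryote sedaDNA damage proxy

Per sample, after removing every taxon observed in any extraction blank
control (EBC; removal is by taxon identity, not count differencing —
a reagent contaminant is distrusted everywhere), the proxy is

$$\%\,\text{damage} = 100 \cdot
  \frac{\sum_{\text{euk.\ taxa}} n_{\text{ancient}}}
       {\sum_{\text{euk.\ taxa}} n_{\text{default}}}.$$

Ancient reads are a subset of default reads, so the proxy is bounded by
0 and 100.  The phrase "proportion between ancient and default totals"
admits an alternative denominator (ancient + default), but since the
default set already contains every ancient read that denominator would
double-count and cap the proxy below 100%; the subset reading is used.
Both variants are monotone transforms of each other, so correlation
results are insensitive to the choice, while absolute percentages are
not.  Samples with no eukaryote default reads have an undefined proxy
and are excluded from correlations explicitly (`ok = FALSE`), never
silently zeroed.

Depth relationships use the two-tailed Pearson correlation with the
exact t transform ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df), implemented
directly and cross-checked against `stats::cor.test` in the tests.  No
multiple-testing correction is applied, matching how such correlation
tables are conventionally reported.  `correlation_matrix()` emits the
compact layout with $r$ below and $p$ above the diagonal.

## Profiles: conditioned and unconditioned

`build_profile()` computes, per read end, position and substitution
type, the frequency (columns showing the substitution) / (columns whose
reference base is the source base); zero-denominator cells are missing,
not zero.  The noise channel is the per-position mean of the ten
substitution types other than C→T and G→A.

One subtlety deserves emphasis.  The figure-style profile of real
studies is computed *from ancient reads only*.  Conditioning on
"carries at least one terminal lesion" inflates terminal frequencies
(at $\delta_5 = 0.3$ roughly twofold at position 1), exactly as in the
plotting tools this emulates.  The unconditional profile over all
filter-passing reads is the one that recovers the generative
$\delta\,d^{\,i-1}$, and that is what the parameter-recovery tests use.
`build_profile()` profiles whatever alignments it is given; the caller
chooses the conditioning.  Profiles are only emitted from ≥ 50 reads,
the practical floor for per-species damage plots in sparse data.

## The synthetic study

The default study design (`depth_series_specs()`) emulates the
structure of a two-core coastal sediment survey: 27 samples per dataset
at depths 0–130 cmbsf; shotgun domain mixture 0.86/0.09/0.05
(Bacteria/Archaea/Eukaryota), capture mixtures raising the eukaryote
share to 0.21 (broad plankton baits) and 0.47 (HAB baits) — the
published per-site mean proportions of the emulated study — giving
eukaryote enrichment ratios near 4× and 9×.  The deamination rate rises
linearly with depth from 0.02 to 0.25 ($\delta_5 = \delta_3$, decay
0.5, background error 0.001).  With the five-base window this maps to a
per-sample proxy of roughly 2–24%, the span reported from real cores;
the linear-in-depth rise is a deliberate simplification of the
concave-with-plateau pattern seen in real data, sufficient for the
qualitative claim the synthetic study supports (a significantly
positive depth correlation, preserved under capture).  Reads per
sample (1200 shotgun, 800 capture) and panel size (two taxa per domain,
600 nt references) are desk-scale choices that keep a full three-
dataset replay in minutes while leaving dozens of eukaryote reads per
shotgun sample — enough for a stable but honestly noisy proxy.

What passing these tests does **not** show: the simulator draws i.i.d.
random references (no conserved regions, paralogy or database bias), a
uniform fragment-length distribution, no sequencing-quality model, and
an EBC whose contaminants are panel taxa.  Real-data complications —
misassignment across related genomes, reference databases missing taxa,
damage/length confounding — are outside what this synthetic design can
exercise.

## Bait design

The design pipeline reproduces a vendor-style workflow with every
printed threshold as a default: mask N runs shorter than 10 to Ts
(longer runs stay and disqualify overlapping baits), pad targets to
84 nt, tile 80-nt baits every `round(80/3) = 27` nt with a clamped
terminal bait so the 3′ end is always covered, collapse redundancy at
> 83% overlap and > 95% identity (greedy single-linkage with a
deterministic representative: lowest target, then lowest offset —
the vendor's exact collapse algorithm is unpublished), and screen
candidates against genome panels.

Hybridisation melting temperatures use the classical linear model
$T_m = 81.5 + 16.6\log_{10}[\mathrm{Na^+}] + 0.41\,(\%GC) - 675/N -
\%\text{mismatch}$ with Na⁺ = 0.9 M as the standard buffer.  Vendor Tm
estimates come from a proprietary model, so absolute temperatures
differ; the 60/62.5/65/67.5/70 °C decision thresholds are therefore
configurable rather than sacred.  The specificity conditions (a)–(e)
are taken with their printed counts read as upper bounds; hits below
62.5 °C are tolerated by (b)–(e), and the unmentioned 67.5–70 °C band
is treated as disqualifying except where "70 °C or above" is named.
The flanking-bait circularity in (c)–(e) is broken by a two-round
scheme: round 1 assigns provisional pass/fail from the flank-free
conditions (a)–(b); round 2 evaluates (c)–(e) against those statuses,
counting an unknown flank as failing and giving a lone bait zero flanks
of either kind.  The add-on hit-count filter discards hits only when
they fail *both* the 60 bp length and 80% identity thresholds (the
conjunctive reading of the printed rule) and keeps baits with fewer
than 50 qualifying hits.

`screen_hits()` stands in for BLAST at desk scale: exact 11-mer seeds,
ungapped best-segment extension per diagonal on both strands, score =
matches − mismatches.  Like any seeded search it could in principle
miss a qualifying segment containing no exact 11-mer; on random or
planted sequences this is vanishingly rare, and the tests compare its
output against a seed-free exhaustive diagonal scan.

## Numerical and interface choices

* All randomness flows from one master seed per sample/panel; any run
  is byte-reproducible from its configuration.
* Undefined statistics (empty denominators, zero variance, sub-minimum
  read counts) propagate as explicit statuses, never silent zeros.
* Alignment events are serialised compactly (`pos5:pos3:ref>read`) so
  alignment tables survive TSV round-trips; gap-in-read columns carry
  position 0 and count as mismatches in percent identity.
* The analysis is organised as numbered driver scripts under
  `analysis/` over package functions, rather than a monolithic CLI; the
  scripts are the subcommands.

## Known limitations

Single-threaded dynamic programming limits panels to desk scale
(hundreds of kilobases); the damage model has no overhang/nick
structure, so it cannot distinguish single- from double-stranded
library preparation; the LCA is two-level only; and the bait pipeline's
absolute Tm values (hence pass rates) are calibration-dependent.  None
of these affect the internal consistency the tests establish: exact
classification, parameter recovery within binomial error, bounded and
EBC-clean proxies, and deterministic bait sets.
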