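---
title: "Prioritizing rare cancer drivers by integrating expression, mutation effect and systems-level gene properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare cancer drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(driverlens)
library(dplyr)
```

## The problem

A sequenced tumour genome typically carries tens of non-synonymous somatic
mutations, the vast majority of which are passengers: variants fixed in the
clone because a true driver elsewhere conferred a growth advantage.
Frequency-based driver discovery works well for genes that recur across
many tumours, but it is blind to rare drivers — and it is confounded by
gene length, because long genes accumulate passengers at a higher rate
simply by offering more target sequence.

driverlens takes the complementary route: instead of asking *how often* a
gene is mutated, it asks whether a mutated gene *looks like* a known cancer
gene. The cascade operates per sample and per gene, and every decision is
retained in an auditable trace.

## The cascade

**Sample filter.** Tumours in which a known cancer gene (Cancer Gene
Census-style list) is both mutated and called expressed are set aside: a
plausible driver is already at hand, and the goal is to explain the
remaining tumours. Samples whose mutated genes all lack expression data are
also discarded — nothing can be concluded about them. The requirement that
the known gene be *expressed* (not merely mutated) is configurable
(`require_known_expressed`), and a chosen set of known genes can be
exempted (`exempt_known`) to benchmark the cascade on samples whose true
driver is known.

**Expression.** A mutation in a silent gene cannot act through the encoded
protein, so a putative driver must be expressed in the tumour that carries
it. Expression is called from microarray probe detection p-values: a gene
is expressed in a context when at least half of its probes have detection
p < `alpha_detection` (default 0.05). "At least half" is exact integer
arithmetic — with three probes, two are required. Genes without probes give
`no_data`, which is treated as absence of evidence and excluded from
denominators, never conflated with silence.

**Mutation effect.** Frameshift, nonsense and splice-site mutations are
accepted as damaging outright. Missense mutations require a two-of-three
consensus among effect predictors: damage-oriented SIFT > 0.95,
PolyPhen > 0.9, or a MutationTaster "disease causing" label. Thresholds are
strict inequalities, and a missing score is a negative vote, so the
denominator of the consensus never shrinks. SIFT is consumed on the
damage-oriented scale; canonical SIFT scores (damaging near 0) are
converted as 1 − score at read time (`sift_raw = TRUE`).

**Length and recurrence.** Because passenger counts grow with coding
length, very long genes recur across cancer types without being drivers
(`length_recurrence_trend()` quantifies this as an OLS slope of coding
length on recurrence level). Genes with coding length < 4,450 bp — the
bottom 95% of human gene lengths — pass unconditionally; longer genes pass
only if mutated in fewer than five cancer types. The published description
of this cutoff appears in two forms that differ by one ("fewer than five"
vs "more than five removed"); the package defaults to the stricter
retain-iff-<5 reading and exposes the other as
`long_gene_rule = "results"`.

**Systems-level properties.** Known cancer genes are (i) encoded by
proteins that are highly connected *and* central in the protein interaction
network, (ii) direct interactors of known cancer proteins, (iii) of
either ancient or metazoan/vertebrate evolutionary origin, and (iv)
predominantly singletons (no human paralog — a hint of dosage sensitivity).
Central hubs are nodes strictly above the 75th-percentile thresholds of
both degree and unnormalized betweenness, computed once over the whole
network with the linear-interpolation quantile convention (R type 7) so
that thresholds are bit-reproducible. A candidate passes when it shows at
least `min_systems_true` of the four flags.

The combination rule is the one genuinely open design point: published
descriptions state the four properties but not how they combine. Requiring
all four would contradict the behaviour of known cancer genes themselves
(most are not hubs), and any-single-property is nearly vacuous. The
default is two-of-four, surfaced in `pipeline_config()` rather than
hard-coded, and the cascade's monotonicity (a stricter configuration can
only shrink the driver set) is enforced by property tests. Likewise, which
epochs count as "cancer-like" origin is configurable; the default set
{ancient, metazoa, vertebrata} excludes eukaryote-specific origin because
the rationale — impairment of very basic or of regulatory processes — pins
the two bursts of cancer-gene emergence to cellular origins and to
multicellularity, not to the eukaryote stem.

Genes absent from the interaction network are non-hubs and non-interactors
rather than errors: interaction maps cover roughly 13,500 of ~19,000 human
genes, so absence is routine and must not crash a cohort run.

## Group-level statistics

The evidence that expression separates drivers from passengers rests on
group comparisons, all available as standalone functions:

* `expressed_fraction_comparison()` contrasts the expressed fraction of a
  gene group against the rest in one context with an uncorrected 1-df
  chi-squared on the 2×2 table (the closed form
  \(N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))\)); Yates correction is a
  flag, off by default since the uncorrected statistic is the printed,
  formula-level description. In `highly_expressed` mode a gene counts when
  its level exceeds the context median over all genes with data, mutated
  genes included. The log2 ratio of the two fractions is the volcano-plot
  x-axis and is flagged undefined (not ±Inf) when either fraction is zero.
* `classify_breadth()` bins genes by breadth of expression: housekeeping
  when expressed in ≥ 98% of tissues (107 of 109), tissue-selective when
  in < 25% (27 of 109). `class_enrichment_fisher()` tests class
  enrichment/depletion with a two-sided Fisher exact test, the right tool
  at the small counts involved.
* `compare_breadth_distributions()` is a two-sided Wilcoxon rank-sum test
  with Shapiro-Wilk p-values reported alongside. The normality test never
  switches the method automatically — it documents why a rank test is used.

## shRNA silencing scores

Pooled shRNA screens report hairpin abundance in the final cell population
of each cell line against the initial DNA pool. For probe \(i\) in cell
line \(h\) with \(m\) line replicates and \(n\) pool replicates:

$$\mathrm{log2ratio}_{shRNA,h,i} = \log_2 \frac{\tfrac1m \sum_j
\mathrm{score}_{h,i,j}}{\tfrac1n \sum_k \mathrm{score}_{DNA,i,k}}$$

A positive value means hairpin enrichment — silencing the target favoured
proliferation, the signature of tumour-suppressor loss. Genes collapse to
their top-scoring probe (`direction = "max"`), the false-positive-averse
convention when probes per gene are few; `"min"` serves depletion
readouts. Two contracts are worth stating: the ratio is invariant under a
common positive rescaling of all conditions and shifts by exactly
\(\log_2 c\) when only the cell-line replicates are scaled by \(c\); and a
non-positive replicate mean (possible after upstream normalisation of raw
GCT values) makes the ratio missing rather than clamped, because a clamp
would leak into the max-collapse. Upstream normalisation itself is
pass-through by default, with optional per-condition median scaling —
the screens consumed here arrive already normalised, and re-normalising
silently would be worse than not at all.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the cascade relies
on, with known ground truth:

* coding lengths are log-normal (meanlog log 1500, sdlog 0.67 — median
  1.5 kb and a 95th percentile close to the 4,450 bp cut, matching the
  shape of human coding lengths);
* passenger mutations are Poisson per (sample, gene) with rate
  `passenger_rate_per_bp` × length (default 2 × 10⁻⁵/bp ≈ 70 mutated genes
  per sample at 2,000 genes, in the range of exome screens); setting the
  rate to 0 gives a noise-free cohort;
* probe detection p-values are Uniform(0, α) for expressed gene-contexts
  and Uniform(α, 1) otherwise, with 1–5 probes per gene (median 5) and 90%
  of genes covered by probes at all;
* the network grows by preferential attachment (`igraph::sample_pa`),
  giving the heavy-tailed degree distribution real interactomes show;
* 90% of samples (the published cohort share) receive one mutated and
  expressed known cancer gene; each remaining clean sample receives two
  planted drivers that are expressed, damagingly mutated (frameshift by
  default, so recovery does not hinge on the predictor-score model; a
  missense mode exercises the two-of-three rule), shorter than 4,450 bp,
  and annotated with a cancer-like origin and singleton status so they
  carry ≥ 2 systems properties;
* the screen draws positive log-normal abundances with planted-suppressor
  hairpins multiplied by \(2^{\text{effect}+\varepsilon}\),
  \(\varepsilon \sim N(0, 0.3^2)\), effect 1 for suppressors and 0
  otherwise.

What the generator does **not** emulate: real mutation spectra, expression
correlation among tissues, hub-driver coupling (planted drivers earn their
systems pass through annotation, not through network position), or probe
cross-hybridisation. Consequently, perfect recovery on a noise-free
synthetic cohort demonstrates the internal consistency of the cascade —
each planted signal survives exactly the stage built to detect it — not
performance on real tumours, where annotation error and passenger load make
recovery imperfect.

## Numerical choices and degenerate inputs

* Quantile thresholds use R's default type-7 interpolation; hub cuts are
  strict (`>`), so a degree-degenerate network yields no hubs rather than
  all hubs.
* Breadth cutoffs use exact integer boundaries with a 10⁻⁹ guard against
  binary-fraction artefacts (0.98 × 100 must cut at 98, not 99).
* The chi-squared is reported without continuity correction by default;
  empty groups yield a flagged undefined comparison, not an exception.
* Length-trend fitting defaults to per-level median lengths (robust to the
  long tail); `fit_all_points = TRUE` fits gene-level points — provided
  because which of the two the original trend line used is not stated.
* Ties in the top-probe collapse are harmless (the tied value is
  returned); ties in rank tests fall back to the normal approximation, as
  `wilcox.test` does.
* All generation and analysis is deterministic given the seed; identical
  bundle and configuration give byte-identical reports.

## Problem sizes used in the test suite

The bundled tests run cohorts of 10–100 samples and 100–2,000 genes; the
betweenness oracle checks 200 random graphs of at most 8 nodes against
exhaustive path enumeration; Fisher p-values are checked against
hypergeometric enumeration on all 531 tables with margins ≤ 6; the
monotonicity property is checked on 20 seeded cohorts. These sizes give
stable verdicts for every property tested while keeping a full run around
a minute.

## Known limitations

* Gene identifiers are matched as opaque case-sensitive strings; symbol
  aliasing must be resolved upstream.
* The interaction network is a plain union of curated edge lists with
  deduplication; no evidence weighting.
* No multiple-testing correction is applied across contexts in the volcano
  statistics (raw p-values are reported, as in the analyses this package
  operationalises); apply `p.adjust` downstream if cohorts are screened
  exhaustively.
* Hairpin off-target deconvolution (ATARiS-style) is out of scope; the
  top-probe collapse is a deliberate, simple summary.
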