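---
title: "Methods: quantile-based marker set enrichment and key driver convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile-based marker set enrichment and key driver convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convergene)
```

# Overview

`convergene` scores tissue gene modules for enrichment of GWAS association
signal, finds network hubs whose neighborhoods concentrate those module
genes, and quantifies whether rare-variant gene catalogs converge on the
same subnetworks. This vignette is the package's own account of the models,
their assumptions, the tunable parameters, and the numerical and design
choices behind them.

# Marker dependency filtering

GWAS markers carry heavy local redundancy through linkage disequilibrium, and
a marker is only informative about a gene through some mapping evidence. MDF
therefore does two things before any enrichment statistic is computed.

**Mapping.** Three evidence sources are supported and merged by union:
per-tissue eQTL and sQTL tables (taken as given; any QTL-strength filtering
belongs upstream), and distance mapping, where marker *m* maps to gene *g*
iff they share a chromosome and `pos(m)` lies in `[start(g) − W, end(g) + W]`
with `W = window_kb × 1000` (1-based inclusive coordinates, boundary
inclusive; default `window_kb = 20`). A (marker, gene, tissue) pair supported
by several sources keeps one record per source, so evidence provenance is
never lost.

**Clumping.** Markers are sorted by ascending p (ties broken
lexicographically by marker id, which makes every run reproducible), and the
best unclaimed marker repeatedly retained while its partners with
`r² > r2_threshold` (strictly greater; default 0.5) are discarded. Markers
absent from the LD table are treated as unlinked. This greedy best-p seeding
is standard clumping practice; we deliberately do not use connected
components as "blocks" because components chain weakly linked markers into
arbitrarily long spans.

Two properties of this rule are worth recording. The retained set is a
*maximal independent set* of the supra-threshold LD graph — no two retained
markers are linked, and adding back any discarded marker breaks independence
— and clumping is idempotent. The retained set is, however, **not monotone in
the threshold**: raising `r2_threshold` removes edges, which can promote a
previously discarded marker that then discards several of its own partners.
With priority `A < B < C < D` and edges A–B at r² 0.6, B–C and B–D at 0.9,
threshold 0.5 retains {A, C, D} while 0.7 retains {A, B}. The test suite
asserts the true invariants (independence, maximality, idempotence,
best-marker retention) rather than monotonicity.

No GWAS p-value cutoff is applied at any point: the enrichment statistic and
its permutation null both want the full spectrum of association strengths.

# Marker set enrichment analysis

## The statistic

All retained markers are ranked by −log₁₀ p (ties again lexicographic). For
a module whose genes carry `m` distinct retained markers out of `M` total,
and a quantile cutpoint `q`, the "positive" markers are the global top
`k_q = ⌊(1 − q)·M⌋`; the module observes `O` of them and expects
`E = m·k_q/M` — its share of the global positive fraction — so that
`E[χ] ≈ 0` under the null by construction. The statistic sums over the grid:

$$\chi = \sum_{i=1}^{n} \frac{O_i - E_i}{\sqrt{E_i + \kappa}}$$

with `n = 10` cutpoints spaced evenly from 0.5 to `q_upper = 1 − 1/μ`, μ the
run-wide median module marker-set size (computed once per run, after the MDF
intersection), and stability constant `κ = 1` guarding the near-empty tails.
The signed sum means deficits subtract; enrichment is directional and
deficits simply land at p > 0.5. The upper limit adapts the grid to module
size: μ ≤ 2 would give `q_upper ≤ 0.5` and is rejected as a degenerate range.

Counting uses *distinct markers*, not marker–gene records, matching the null
hypothesis that the distinct markers of N random genes contain an equal
proportion of positive associations.

## The null and its calibration

Each module is standardized against `n_permutations` (default 1000) random
gene sets of the same gene count drawn uniformly without replacement from the
tissue's eligible universe (genes with ≥ 1 retained marker), using the
(n−1)-denominator SD and a one-sided Gaussian upper tail for p, followed by
Benjamini–Hochberg FDR. The FDR family defaults to all modules across tissues
in one run; a per-tissue family is available (`fdr_family = "tissue"`), and
neither choice is asserted as canonical. Because the null depends only on
(tissue, gene count), null distributions are cached per size; sizes are
processed in sorted order under one seeded stream, so results do not depend
on module order.

Defaults worth knowing: `min_module_size = 10` genes (after marker
intersection) — very small modules make both `q_upper` and the Gaussian
approximation unstable, and filtered modules are reported in a `skipped`
table rather than dropped silently; `null_sd = 0` (e.g. constant p-values)
is flagged and the module's p set to 1 with a warning rather than a divide
by zero.

## Numerical choices

`k_q` is mathematically `⌊(1 − q)·M⌋` over rationals, but binary floating
point makes `(1 − 0.9)·100 = 9.999…`, which would floor to 9. The
implementation (and, independently, the test oracle) adds a 1e−9 guard
before flooring to express the exact-arithmetic intent. Gaussian tail
probabilities are clamped into `(1e−300, 1]` so downstream −log₁₀ transforms
stay finite.

# Key driver analysis

Hub candidates are the top `hub_top_fraction` (default 0.25) of nodes by
total degree, where degree counts each distinct directed edge once (in +
out). The cutoff is the degree of the `⌈fraction·n⌉`-th largest node and
boundary ties are kept, so the candidate set is never smaller than the
nominal fraction and a stricter fraction's set is nested in a looser one.
Edge direction encodes regulatory semantics only; neighborhoods are
traversed undirected (`neighborhood_depth = 1` by default, i.e. first-degree
neighbors), which is also the convention used for visual subnetwork exports.

The enrichment statistic is the overlap between a hub's subnetwork and the
disease set (union of genes in FDR-significant MSEA modules, intersected
with the network's nodes). "Reshuffled subnetworks of the same size" are
operationalized as uniform node sets of equal size — a node-label
permutation — rather than degree-preserving rewiring, because that matches
the size-matching description exactly and admits an exact hypergeometric
cross-check, which is reported in every result row (`P_HYPERGEOM`). The
permutation Z and Gaussian p mirror the MSEA construction (the overlap is
the single-cutpoint analog of χ). Nulls are cached per subnetwork size
within each network.

**Known limitation.** For very small subnetworks the overlap is a tiny
discrete count and a Gaussian tail on it is anti-conservative: with 6-node
subnetworks and a 10% disease fraction the expected overlap is 0.6, and the
z > 1.645 rule effectively flags overlap ≥ 2, an attained level near 0.11
rather than 0.05. This is the same small-count instability that motivates
the MSEA module-size floor. The package's calibration checks therefore run
on networks dense enough that hub subnetworks have expected overlap ≥ 1
(median subnetwork ~17 nodes at `edges_per_node = 10`), and for sparse
networks the exact `P_HYPERGEOM` column is the recommended inferential
quantity.

# Convergence of rare and common variant signal

The rare catalog stratifies genes into levels {S, 1, 2, 3} (Syndromic, high
confidence, strong candidate, suggestive), analyzed both as a collective
(`rare_all`) and per level. The common-variant gene set needs a rule the
upstream literature leaves implicit; the package defines it as genes whose
best retained mapped marker has `p < common_p_threshold` (default 1e−4) and
always exports the continuous per-gene best −log₁₀ p so no information is
lost to the binarization.

Each KD subnetwork × variant class is tested with the one-sided exact
hypergeometric test — identical to one-sided Fisher, implemented once and
shared with the pathway ORA stage — over the network's gene universe by
default (an explicit per-group background, e.g. a transcriptome gene list,
can be supplied). Fold enrichment is `(overlap/unit)/(catalog/background)`,
defined as 0 at zero overlap. BH adjustment runs within each variant class,
and classification at the FDR threshold yields a partition
both/rare-only/common-only/neither per network group. Group contrasts
(first group vs the rest, per class, on −log₁₀ p) report a pooled
Shapiro–Wilk normality p (skipped with a flag for constant or oversized
samples) and a two-sided rank-sum test; one-sided alternatives are available
through `compare_groups()` directly.

# The synthetic study generator

The generator's defaults define the study conditions under which the
package's statistical claims are tested; they were chosen once, for realism
at desk scale, and are echoed into every bundle's `truth.json`.

* **Markers**: 20,000 on one synthetic chromosome, 1 kb apart (so the
  ±20 kb window is meaningful), positions 1-based and strictly increasing.
  The marker universe is deliberately large relative to gene footprints: a
  gene's distance window captures ~41 of 20,000 markers (~0.2%), so a
  module's marker set is sparse in the genome the way real gene sets are
  sparse in a SNP panel. (At 2,000 markers the same windows tile the
  chromosome many times over and planted signal stops being sparse —
  enrichment contrast collapses.)
* **LD**: 1000 blocks of 5 consecutive markers, all within-block pairs at
  r² 0.8, cross-block pairs implicitly 0 — the simplest structure that
  exercises the clumping rule.
* **Signal**: planted markers draw p ~ Beta(a, 1) via the inverse CDF
  `u^{1/a}`, a single-knob monotone stretch toward 0 (`a = 0.2` by default;
  `a = 1` is exactly the null). `signal_fraction` (default 0.5) of a planted
  module's *distinct mapped markers, across all mapping sources*, is
  designated as signal; applying the fraction to QTL markers alone would be
  structurally diluted by the ~41 distance markers per gene.
* **Modules**: per tissue, sizes uniform in 20–30 genes; planted modules
  (first tissue, disjoint gene sets, one dedicated QTL marker per gene) are
  the default 2 so that their ≥ 40 genes can supply the planted hubs' 32
  disease neighbors.
* **Networks**: directed preferential attachment (`edges_per_node = 3`)
  gives heavy-tailed degrees; planted hubs are appended afterwards and wired
  hub→neighbor to exactly `hub_neighbors = 40` growth nodes, of which
  `round(40 × 0.8) = 32` are disease genes — exact by construction and
  verified by parsing the emitted files back. Two groups ("brain",
  "peripheral") are generated; hubs are planted in the first.
* **Rare catalog**: level sizes {S: 5, 1: 15, 2: 20, 3: 25}; half the
  catalog is drawn from planted-hub neighborhoods by default
  (`rare_hub_overlap = 0.5`), the knob behind the convergence analyses.

What the generator does **not** emulate: realistic human LD maps (no decay
with distance, no cross-block leakage), allele frequencies or effect-size
architectures, expression matrices (modules are emitted directly), gene
length variation, or population structure. Passing tests therefore show that
the statistics are correct and calibrated *under these generative
assumptions*, not that any biological conclusion transfers to real data.

# Problem sizes and reproducibility

The test suite's simulation-based checks use: pure-null and planted-signal
studies of 200 single-tissue modules with 1000-draw permutation nulls over
10 and 20 seeds respectively; hub recovery on 2000-node networks over 20
seeds and null hub calibration on denser 2000-node networks over 10 seeds;
1000 randomized small LD graphs (≤ 12 markers) against an exhaustive greedy
oracle; 200 random micro-studies (≤ 50 markers) against a direct-count
profile oracle; full tail enumeration of every feasible 2×2 table with
background ≤ 25; and two complete pipeline runs compared byte for byte.
These sizes are the package's chosen verification scale; all randomness is
seeded, and identical (configuration, seed) pairs reproduce byte-identical
bundles and result tables end to end.
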