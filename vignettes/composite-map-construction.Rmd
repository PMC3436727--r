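---
title: "Composite linkage map construction: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite linkage map construction: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compositemap)
```

## The problem

A genetic linkage map orders molecular markers along chromosomes in
recombination units (centiMorgans). When several mapping pedigrees of
the same species have each produced their own map, no single map carries
all markers, and joint re-estimation from the pooled segregation data is
computationally infeasible for thousands of partially informative
(dominant) markers. A *composite* map sidesteps re-estimation entirely:
markers are transferred between finished maps through their shared
(anchor) loci, using only the relative positions each component map has
already estimated.

This trades statistical rigour for scale. The composite map inherits the
local marker-order uncertainty of its components — marker order within
intervals of a few cM should be treated as approximate — but it
establishes the relative position of every marker mapped in any
pedigree, which no component map can do alone.

## The merge model

**Seed map.** One component map is the fixed backbone. By default the
package picks the map with the most markers (ties: larger progeny
count, then lexical map id), the same reasoning used when the map with
the largest family and marker count is chosen by hand. Seed marker
positions are never altered by merging; the only transformation they
undergo is a rigid per-group shift so that every finished group starts
at 0 cM.

**Homology.** Linkage groups are matched across maps by shared-marker
majority: each component group is assigned to the reference group with
which it shares the most markers, requiring at least `min_anchors`
(default 3) shared markers and no tie. Homology deliberately uses
counts, not correlations — group membership (synteny) is a different
question from order agreement (colinearity), and is decided first.

**Candidate ranking.** For each building composite group, every
unconsumed homologous component group is scored by

\[ \text{fit} = |\rho| \times \log_{10}(n) \]

with \(n\) the shared-marker count and \(\rho\) the Spearman rank
correlation of shared-marker positions. The logarithm rewards anchor
count with diminishing returns, so a moderately correlated group with
many anchors can outrank a near-perfect group anchored by a handful of
markers — the projection fitted through many anchors is the more
trustworthy one. Two details are deliberate design choices rather than
inherited rules:

- *Absolute correlation.* Linkage-group orientation is arbitrary across
  independently built maps, so a perfectly colinear but reversed group
  has \(\rho = -1\) and must not be discarded. Eligibility and fit use
  \(|\rho|\); reversed groups are flipped
  (\(p_i \leftarrow \max(p_i) - p_i\)) before regression.
- *Log base.* Scaling all scores by a positive constant cannot change
  which candidate ranks first, so the ranking is invariant to the
  base; base 10 is used for reporting and the invariance is asserted in
  the test suite.

Ties in fit value break by larger \(n\), then by the input order of the
component maps, making builds deterministic.

**Eligibility.** A candidate needs \(n \ge 3\) and \(|\rho| \ge 0.50\).
Three anchors is the minimum that gives the regression a residual
degree of freedom; 0.50 excludes groups whose order disagrees more than
it agrees.

**Projection.** Anchor positions are fitted by ordinary least squares,
\(p_c = m\,p_i + c\), with \(p_c\) on the building group and \(p_i\) on
the (orientation-resolved) component group. Anchors are unweighted.
Every component marker absent from the building group is placed at its
regressed position; markers already present are not moved, but their
support set records the additional map. Later rounds recompute anchors
against the *current* building group, so markers projected earlier act
as anchors for maps that share little with the seed — this chaining is
what lets a small map merge even when it overlaps mainly with another
non-seed map.

**Degenerate inputs.** Projected positions may fall below 0 or beyond
the current group ends; they are kept as-is and resolved by the final
rigid shift. All-identical anchor positions abort the fit with an
error. Markers projected to exactly the same position are kept as
distinct co-located loci (real composite maps show on the order of 10%
co-located markers); no jitter is applied, and reported "unique locus"
counts collapse them.

**Trimming.** After a group is finished, terminal markers sitting
\(\ge 5\) cM from their neighbour and supported by fewer than 2
component maps are removed, iterating from both ends until stable.
These are the classic artefacts of extrapolated regression at group
ends. The operation is idempotent and logged.

## Colinearity pre-screening

Before building, each component group can be screened against the
reference map: the report lists every pairwise Spearman correlation and
flags groups whose best \(|\rho|\) (with \(\ge 3\) anchors) falls below
`screen_rho = 0.90`. The threshold reflects the empirical gap in real
map sets between retained groups (order correlations ≳ 0.92 against the
composite) and discordant ones (0.19–0.79). Screening is *advisory* by
default — mirroring the visual-inspection workflow it replaces — and
`build_composite()` only drops groups explicitly passed as exclusions
(the CLI's `--auto-exclude` wires the two together).

## Quality-control statistics

- `correlation_table()` — signed Spearman ρ between the composite and
  each component map per linkage group, with flags for maps that
  contributed merge rounds. Against the seed map these are identically
  1 (backbone immutability).
- `summary_table()` — per-group length, marker counts by type, unique
  loci, mean interval (length / (unique loci − 1); the totals row uses
  total length / (total unique loci − number of groups)). Per-group
  multicopy percentages are reported against both the DArT count and
  the total position count, since both denominators appear in
  practice.
- `multicopy_chisquare()` — tests whether multicopy DArT positions are
  distributed across groups in proportion to DArT content:
  \(E_i = (\sum \text{mc} / \sum \text{DArT}) \times \text{DArT}_i\),
  \(X^2 = \sum (O_i - E_i)^2 / E_i\), df = groups − 1, upper-tail
  p-value. Only DArT positions enter either side, as the marker system
  in which duplications are assayed. The implementation is
  cross-checked against `stats::chisq.test()` in the tests.
- `multicopy_accounting()` — the bookkeeping identity
  *positions = distinct markers + Σ(copies − 1)*, plus the copy-number
  histogram.
- `flag_redundant()` — groups of markers that co-locate (within a
  tolerance, default exact) on identical linkage-group sets; these are
  candidates for being identical clones under different names and
  deserve sequence-level follow-up, which is out of scope here.

## The synthetic generator

`simulate_map_set()` builds a known true map (default 11 groups, 400
markers each, group lengths uniform on 80–140 cM) and samples component
maps from it. The defaults are shaped like the seven-pedigree
*Eucalyptus* map set the method was developed on:

| parameter | default | emulates |
|---|---|---|
| retention | 0.53, 0.42, 0.24, 0.13, 0.11, 0.14, 0.16 | 2290 down to 498 markers per map out of ~4350 |
| length scale | 1.00–1.14 per map | component lengths 1033–1258 cM around a 1107 cM reference |
| noise sd | 1 cM | local order uncertainty among tightly linked markers |
| swap rate | 0.02 | residual adjacent-marker order errors |
| multicopy fraction | 0.02 | ~2% of markers on two or more groups |
| redundant pairs | 2 | identical clones under two names |

Noise is applied in map-distance space rather than simulating genotypes
and re-estimating maps: the method consumes finished maps, and
distance-space perturbation reproduces the error structure that matters
to it (local rank swaps, map-length differences) at a scale where
ground truth is exact. Two real-data features are *not* emulated:
marker sharing across pedigrees is driven by marker polymorphism, not
independent retention, so real anchor sets are more clustered than
simulated ones; and real component maps can contain internally
rearranged regions rather than whole-group scrambles
(`inject_discordant_lg()` models only the latter). Passing recovery
tests therefore demonstrates correctness of the merge machinery, not a
guarantee about arbitrarily pathological inputs.

## Validation results computed by the test suite

The published composite map itself cannot be rebuilt from printed
tables (the component maps' full marker lists are not part of the
package), so the engine is validated property-wise, at sizes chosen to
keep the default suite fast while exercising the full seven-map shape:

- backbone immutability and exact identity merges on constructed maps;
- fit-value selection against hand-computed scores, under multiple log
  bases;
- OLS projection against the closed-form normal equations (1e-9);
- exact recovery (ρ = 1, position error below 1e-6 cM after rigid
  shift) for noise-free subsampled components (11 groups × 120
  markers, 5 maps);
- noisy recovery on the full default shape (7 maps, 11 × 400 markers,
  1 cM noise): per-group composite-vs-truth ρ ≥ 0.95 required in ≥95%
  of 20 seeded replicates — the observed values sit above 0.99,
  consistent with the 0.96–0.99 range typical of included maps in real
  builds;
- the χ² statistic on the published per-group counts (12.9998 at full
  precision, df = 10, p = 0.224) and all marker/position accounting
  identities.

`scripts/acceptance.R` recomputes these quantities from scratch with a
user-supplied seed.

## Known limitations

- Marker order within a few cM is inherited noise, not signal; users
  comparing fine-scale order should consult the component maps.
- The composite covers only linkage groups present in the seed map;
  groups absent from the seed are not assembled from the remaining maps.
- Per-group choices between alternative versions of a component map
  (e.g. framework vs comprehensive builds of the same pedigree) are
  user configuration — the package does not pick for you, because the
  underlying criterion (order agreement with the other maps) involves
  judgement about which regions matter.
- Multicopy classification depends on homology assignment; an
  unassigned (low-evidence) component group makes its markers look
  multicopy against the rest of the set, which is flagged rather than
  silently merged.
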