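---
title: "Annotating intrinsic disorder in heat-resistant proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating intrinsic disorder in heat-resistant proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idptools)
```

## The problem

Intrinsically disordered proteins (IDPs) lack a stable tertiary structure
in their native state. Because they have no hydrophobic core to expose,
they tend to stay soluble when a cell extract is boiled, so the
"heat-resistant proteome" — the fraction that survives 98 °C — is an
experimentally convenient enrichment of IDPs and IDR-containing proteins.
Once such a protein set has been identified by mass spectrometry, the
informatic half of the study is: predict per-residue disorder, summarise
it per protein, decide which proteins count as IDPs, and characterise the
set (amino-acid composition bias, physicochemical properties, subcellular
distribution, molecular functions). `idptools` implements that informatic
half as a reusable, tested pipeline, together with a synthetic proteome
generator that stands in for proprietary raw data.

## Disorder predictors

Two predictor families with fully published algorithms are implemented;
neural-network predictors whose weights are not redistributable are
supported through the score-track import interface
(`read_score_table()` + `binarize()`) instead of being re-trained.

**Charge–hydropathy (unfoldability).** Folded proteins combine high mean
hydropathy with low mean net charge. Over a sliding window centred at
residue *i* (width 51 by default, truncated at the ends — truncation
avoids inventing residues and is the common convention), with `<H>` the
mean Kyte–Doolittle hydropathy rescaled to [0, 1] as `(H + 4.5)/9` and
`<q>` the mean charge (K, R = +1; D, E = −1; H = 0 by default, it is
near-neutral at typical working pH):

```
score_i = 2.785 <H> − |<q>| − 1.151
```

Negative scores predict disorder; the boundary itself (score 0) is
ordered. The constants are the published fold/unfold boundary of the
charge–hydropathy method family; they are exposed as parameters
(`charge_hydropathy_params()`) so alternative boundaries can be tested.

**Pairwise energy estimation.** Disordered sequences cannot form enough
favourable inter-residue contacts. For residue *i* with amino acid *a*,
the composition `f` of the surrounding window (21 residues by default,
excluding position *i* itself) estimates the energy
`e_i = Σ_b M[a, b] f(b)`, which a logistic transform maps to a disorder
probability:

```
score_i = 1 / (1 + exp((e_i − midpoint) / (−slope)))
```

Residues with `score_i ≥ 0.5` are called disordered (probability-like
scores treat the boundary as disordered; unfoldability scores treat it as
ordered — the two tie rules are deliberate and tested). The shipped
default matrix is a transparent surrogate,
`M[a,b] = −h_a h_b + 0.4 |q_a| |q_b|`: hydrophobic pairs stabilise,
charged pairs destabilise. Its `midpoint = −0.15` and `slope = 0.05` were
fixed by a separation analysis of the default synthetic compositions
(ordered contexts give mean energies around −0.3 to −0.75, disordered
contexts around −0.1). Any symmetric 20×20 matrix can be substituted via
`energy_model_params()` or `read_energy_matrix()`, e.g. a published
statistical-potential matrix; the published parameters are intentionally
not hard-coded as ground truth.

The ambiguity code X carries no propensity information: it is excluded
from windows and compositions, and the means are renormalised over the
non-X residues. A window containing only X yields NA, which binarizes to
"ordered".

## Per-protein summaries and IDP calling

`summarize_disorder()` reduces each call track to the number of
disordered residues, the percent disorder, and the longest disordered
region (LDR, strict maximal runs — runs separated by even a single
ordered residue are not merged), binned as 0–9, 10–29, 30–49, 50–99 and
≥ 100 residues. The "100<" label follows the conventional table layout;
its glyph notwithstanding, the bins must partition the non-negative
integers, so it means LDR ≥ 100.

`call_idp()` implements two criteria:

* **strict** — LDR ≥ 30 consecutive disordered residues. The bound is
  inclusive, anchored by the 30–49 LDR bin of the validated class.
* **extended** — additionally, proteins with 10 ≤ LDR < 30 *and* percent
  disorder > 10. The band is half-open so the clauses partition; the
  long-region clause carries no percent condition of its own. Each
  predictor's own percent disorder is used.

`consensus_table()` / `consensus_sets()` combine predictors by k-of-n
voting; the default k = n (a protein must be selected by every predictor)
is the conservative "all software agree" rule. Consensus sets are
monotone decreasing in k, and every strict-mode IDP is an extended-mode
IDP; both properties are tested.

## Composition enrichment

`bootstrap_enrichment()` compares the pooled amino-acid composition of a
query set against a background set: per amino acid,
`(C_query − C_background) / C_background`. Significance comes from a
bootstrap that resamples **proteins**, not residues, independently within
each set — residues within a protein are not independent draws, so the
protein-level bootstrap is the conservative choice. The CI is the
empirical (α/2, 1 − α/2) quantile band over B ≥ 100 replicates and the
two-sided p-value is `2·min(frac ≤ 0, frac ≥ 0)` clipped to [2/B, 1];
amino acids absent from a replicate background are NA in that replicate
rather than divided by zero. B below 100 is refused (quantiles too
unstable). No multiple-testing correction is applied by default, matching
the per-residue-bar convention of composition-profiling tools; a
Bonferroni flag is available. A calibration suite (200 null pairs of 50
proteins × 300 residues, B = 500) checks that per-residue rejection at
α = 0.05 stays inside the 99 % binomial band. The binomial-test variant
of composition profiling is a possible extension; the bootstrap is the
implemented scheme.

## Proteome-level statistics

* `theoretical_pI()` bisects the Henderson–Hasselbalch net charge on
  [0, 14] until the bracket is narrower than 1e-6 (≤ 60 iterations; the
  returned charge magnitude is far below 1e-4). The default pKa table is
  the widely used Bjellqvist-style set, shipped as editable data
  (`inst/extdata/pka_default.tsv`) because the table is a convention, not
  an algorithm. Convergence on the bracket rather than on the charge
  matters: titration curves are extremely flat around the pI, and a
  charge-tolerance stop would return a pH visibly short of the true root.
* `molecular_weight()` sums average residue masses plus one water; X gets
  the mean canonical residue mass by default.
* `dr_length_regression()` regresses disordered-residue counts
  (`DR = round(percent · length / 100)`, rounded to whole residues) on
  protein length. The default model includes an intercept — with only a
  slope and an R² reported by convention, which model was fitted is
  ambiguous, so a `through_origin` flag covers the proportional reading.
* `yield_percent()` and `frequency_by_category()` cover treatment-yield
  arithmetic and compartment/GO frequency tables (GO terms are
  multi-label: one protein may count in several categories, so GO
  percentages may sum past 100; compartment percentages sum to 100 for a
  fully annotated set).

## The synthetic proteome generator

Real heat-resistant proteomes come with MS identifications that cannot be
redistributed, so the test bed is synthetic: `synthetic_spec()` +
`generate_proteome()` build proteomes of ordered-composition backbones
with planted disordered regions and exact ground-truth labels. The
default design:

* 150 proteins of 250–500 residues, 0–2 regions of 30–120 residues each.
  The ranges guarantee the worst-case draw (two maximal regions plus the
  mandatory one-residue separator) fits the shortest protein, so the
  uniform rejection placement (capped at 1000 tries) is well-posed.
* Regions are non-overlapping and non-adjacent, which keeps the ground
  truth analytic: the true LDR of a protein is exactly its longest
  planted region.
* The disordered composition is enriched in E, K, G, S, A and depleted in
  C, W, F, Y and the aliphatic hydrophobics; the ordered composition is
  dominated by I, L, V, F, A, M. This mirrors the qualitative composition
  bias of disordered regions, with the contrast strong enough that a
  window-based predictor crosses its decision boundary at roughly 60–70 %
  window disorder content. The exact probabilities
  (`fig5_like_compositions()`) are declared package defaults, not
  measured values.

What the generator deliberately does **not** emulate: mass-spectrometry
sampling and PSM counts, heat-denaturation physics, length-composition
correlations, homology structure between proteins, or soft disorder
gradients at region edges (the planted truth is binary and sharp). A
pipeline that passes the recovery tests is therefore shown to be a
correct implementation under idealised composition bias — not to match
any particular organism's precision/recall.

Generation is deterministic given the spec seed; the whole pipeline run,
including every report file, is byte-identical across reruns.

## Problem sizes and numerical choices

The shipped verification suite uses deliberately modest sizes chosen to
exercise every property at comfortable statistical margins: brute-force
oracle comparison on 1000 random sequences (length ≤ 200, windows ≤ 7,
agreement to 1e-9), the exhaustive IDP truth table on LDR 0–120 ×
percent 0–100, bootstrap calibration over 200 simulated pairs, and
recovery runs on the 150-protein default proteome. Expected behaviour at
those sizes, measured by the acceptance script: recovery of planted
LDR ≥ 30 proteins around 85–95 % with zero false calls on region-free
proteins (the charge–hydropathy window of 51 blurs region edges by about
8 residues per side, which is what keeps recovery below 100 % for regions
near the 30-residue boundary), regression slope recovery within 3
standard errors, and null composition rejection rates between 0.02 and
0.09.

Degenerate inputs are pinned down by tests: single-residue sequences
collapse the window to a point; even windows, windows of size 1 for the
energy model (empty context), negative LDRs, empty call tracks, all-X
record sets, B < 100, non-positive controls and degenerate regression
designs are all rejected with descriptive errors.

## Known limitations

* The two built-in predictors are window-composition methods; they cannot
  see long-range contacts, and their defaults (windows 51 and 21) blunt
  sensitivity to regions much shorter than ~20 residues. Published
  neural-network predictors must be run externally and imported.
* The default energy matrix is a two-term surrogate. It separates
  strongly composition-biased disorder well, but it is not a fitted
  statistical potential; for production use on real proteomes, substitute
  a published matrix.
* Percent-disorder and LDR are the only per-protein disorder statistics;
  no per-domain segmentation is attempted.
* Deduplication across source databases is out of scope: record ids are
  treated as opaque and must be unique.
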