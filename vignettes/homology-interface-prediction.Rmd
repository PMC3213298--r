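---
title: "Homology-based interface prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based interface prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homint)
library(dplyr)
```

# The model

`homint` predicts protein–protein interface residues by *transferring*
experimentally observed interface labels from sequence homologs whose
complex structures are known. The underlying assumption is empirical:
interface residues are conserved among sufficiently close homologs, and
"sufficiently close" can be expressed in terms of BLASTP alignment
statistics. Two transfer modes exist:

* **Non-partner-specific (NPS)**: the query's interface is the union over
  all partners; any homolog with known interfaces can vote.
* **Partner-specific (PS)**: for a query pair A–B, only *homo-interologs*
  vote — pairs (A′, B′) of homologs of A and B that interact within one
  solved complex — and only with their pairwise (A′-with-B′) labels.
  This matters because transient interfaces are typically specific to the
  partner: the union interface of a promiscuous protein can look poorly
  conserved while each pairwise interface is strongly conserved.

The per-query procedure is a cascade of three steps.

**1. Homology zones.** Each hit is classified into Safe, Twilight 1,
Twilight 2 or Dark zones by inclusive thresholds on
(log EVal, positive score, log LAL) for NPS — see `nps_zones()` — or
(average log EVal, average positive score, Frac~AA′~, Frac~BB′~) for PS —
see `ps_zones()`. All logarithms are natural, percentages on the 0–100
scale. Prediction uses the strictest populated zone; PS prediction never
uses the Dark zone. The Twilight band is split in two rows so that the
cascade stays monotone: Twilight 1 requires a stronger expectation value
(≤ −50) with a higher positive score than Twilight 2 (≤ 1). Hits with
1 < log EVal ≤ ln 10 satisfy no zone: they survive the BLASTP search
cutoff (EVal ≤ 10) but are never used. `log(EVal)` is floored at −450 when
the reported expectation value underflows to exactly zero, so that
vanishing EVals stay finite and comparable.

**2. Interface-conservation ranking.** Within the chosen zone, candidate
templates are ranked by a linear model of the interface-conservation (IC)
score — the Matthews correlation between labels transferred from the
template and the query's true labels (`ic_score()`). The shipped
coefficients (see `ic_model()`) were estimated on large collections of
query–homolog alignments; `fit_ic()` refits them by ordinary least squares
when recalibration is wanted (e.g. obligate-only data). Predicted IC is
used *only for ranking*, so it is deliberately not clipped to [−1, 1].
Inputs are raw (unstandardised); the coefficient magnitudes only make
sense with positive scores in percent and PS fractions in [0, 1]. The top
K = 10 templates are kept; ties break deterministically (lower raw EVal,
then template id).

**3. Majority vote.** Every selected template votes at each aligned query
position: +1 if its aligned residue is an interface residue, −1 if not,
abstaining on gap columns and on residues without coordinates (`?`).
The vote score is positives over votes cast, and a score ≥ 0.5 calls an
interface residue. Abstention (rather than a negative vote) on `?` was
chosen so missing coordinates cannot create negative evidence. The
denominator counts votes actually cast, not templates consulted. Positions
covered by no template get call 0 but keep `n_votes = 0`, so evaluation
can distinguish them from confident negatives; a query with no usable
template in any zone yields a *non-prediction*, distinct from an all-zero
prediction. When one template aligns to the query with several HSPs, only
the HSP with the best predicted IC votes — one vote per template per
position.

# Structure-derived labels

Truth labels come from multi-chain structures: a residue is an interface
residue when it is a *surface* residue — relative solvent-accessible area
(RASA) at least 5 % — with at least one atom within 4 Å of any atom of a
partner chain (`label_interfaces()`). Distances use all atoms present
(heavy atoms when hydrogens are absent; the 4 Å cutoff is mildly sensitive
to this, which is documented rather than corrected). Accessibility is
computed on the *isolated* chain, not the complex, so surface status does
not depend on the partner; SASA uses a built-in Shrake–Rupley
implementation (deterministic Fibonacci sphere lattice, probe 1.4 Å,
Bondi element radii) normalised by the Tien et al. (2013) theoretical
Gly-X-Gly maxima. RASA of highly exposed or terminal residues can exceed
1 under this normalisation; that is expected and harmless, since only the
5 % floor matters. The production contact search uses a 4 Å cell grid; an
O(n²) brute-force scan serves as its test oracle.

Sequence mapping uses residue numbering directly when it is consistent
with the supplied full sequence, and falls back to a local alignment of
the observed residue string against the full sequence otherwise. This is
a lighter-weight stand-in for curated coordinate-to-sequence mapping
databases; numbering errors that a curated mapping would repair can, in
rare cases, shift labels here.

Templates are retained only when their labels are trustworthy
(`filter_templates()`): X-ray structures, resolution ≤ 3.5 Å, at least 3
interface residues. For unbiased evaluation, `filter_homologs()` also
removes self hits and hits that share ≥ 95 % alignment identity *and* the
species with the query — identity alone is not disqualifying, since
near-identical proteins from different species are legitimate templates.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `dist_cutoff` | 4.0 | Å | inter-chain atomic contact definition |
| `rasa_cutoff` | 0.05 | fraction | surface-residue floor |
| `probe` | 1.4 | Å | solvent probe radius |
| `n_points` | 240 | — | Shrake–Rupley sphere samples per atom |
| `k` | 10 | templates | vote pool ceiling |
| vote threshold | 0.5 | fraction | interface call |
| `max_resolution` | 3.5 | Å | template retention |
| `min_interface` | 3 | residues | template retention |
| zone tables | `nps_zones()`, `ps_zones()` | — | cascade thresholds |

Zone thresholds were calibrated on transient dimers and are intentionally
conservative; for obligate queries they can be relaxed by editing the zone
tibble or loading a YAML alternative (`read_zone_config()`), which the CLI
exposes via `--zones`.

# Genuinely open choices, and what was decided

* **Frac~AA′~ functional form.** The PS model combines the query-side and
  template-side alignment fractions of a chain. The product
  `(LAL/len A)·(LAL/len A′)` is the combination adopted here (it is the
  quantity the PS conservation analysis exhibits); `min()` of the two is
  available via `frac_combine = "min"` in `find_interologs()`. Table
  thresholds compare the combined fraction ×100.
* **LAL semantics.** LAL counts alignment columns including gaps, the
  BLAST `length` field convention.
* **Boundary lengths in the BLAST parameter table.** The matrix/gap bands
  overlap at 50 and 85 residues as printed; ties resolve to the
  longer-query row, making the bands disjoint: [1, 34], [35, 49],
  [50, 84], [85, ∞).
* **Undefined metrics.** Ratios with zero denominators (e.g. precision
  with no predicted positives) are reported `NA`, excluded from
  protein-based averages and counted, rather than coerced to zero, which
  would bias the averages.
* **Twilight cascade order.** Safe → Twilight 1 → Twilight 2 → Dark,
  strictest first, with inclusive comparisons exactly as the thresholds
  are printed; overlapping zone definitions are therefore harmless.

# Numerical notes

* `log(EVal)` floor −450 only for `EVal == 0` exactly; representable but
  tiny EVals keep their true logarithm (which can be below −450).
* OLS fitting rejects designs with fewer than p + 2 observations and
  names collinear columns on rank deficiency.
* Counts recovered from percentage columns (`pident`/`ppos`) round to the
  nearest integer.
* The vote rule at exactly 0.5 calls an interface (inclusive ≥).
* Ranking and voting are fully deterministic given identical inputs.

# The synthetic generator: what it does and does not emulate

`make_complex()` builds coarse-grained chains — one backbone and one
side-chain pseudo-atom per residue — on extended paths, with
designed contact patches placed at ~3.5 Å (within 3.2–3.8 Å after jitter)
and all other inter-chain residue pairs well beyond the cutoff, so the
true labels are known analytically. `mutate_homolog()` derives homologs
with controlled substitution/indel rates and an `interface_bias` that
slows interface mutation; a substituted position flips its label with
probability 0.3, so label divergence tracks sequence divergence and the
bias has a measurable conservation effect. Fabricated expectation values
follow `eval = LAL · exp(−1.5 · n_identical)`; λ = 1.5 places ~60-residue
templates at moderate divergence in the Twilight zones and near-identical
~200-residue templates in the Safe zone (the Safe zone's log LAL ≥ 5.2
requires alignments of ≥ 182 columns). `make_ps_scenario()` wires a
two-partner query with disjoint interfaces, good interologs, a
low-resolution decoy and the query's own complex; its templates carry
exact partner-specific labels (no flips), because the scenario probes the
transfer machinery, not label noise.

What this does **not** emulate: real side-chain packing and burial, true
Karlin–Altschul EVal statistics, paralog confusion, conformational change
on binding, or coordinate-numbering pathologies of real structure files.
Passing tests therefore demonstrate the correctness of the statistics,
zoning, ranking, labelling geometry and vote transfer — not field accuracy
on real complexes, which depends on template availability and genuine
conservation.

Test and acceptance problem sizes are deliberately modest — chains of
10–70 residues, template sets of ≤ 5, 100–200 randomised cases, OLS at
n = 5000 — chosen as the smallest sizes at which every decision branch and
boundary of the method is exercised.

# Known limitations

* Coverage: no usable homolog (or interolog) means no prediction — the
  method abstains rather than guessing.
* mmCIF input, NMR-derived template labels and non-protein interfaces are
  out of scope.
* The linear IC models are rank heuristics; their absolute predictions are
  not calibrated probabilities.
* PS label transfer is only as partner-specific as the template index:
  complexes must be annotated with which chain pairs actually interact.
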