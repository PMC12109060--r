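---
title: "Methods: profiling tea-extract bioactivity from plate to network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling tea-extract bioactivity from plate to network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teashuttle)
```

`teashuttle` implements, as one offline and fully testable pipeline, the
chain of analyses used to characterise bioactive compounds in semi-fermented
(Oolong) tea: bench assays that quantify what the extract contains and how
strongly it scavenges radicals; electrochemical profiling that asks whether
the extract carries *electron shuttles* (ES) — aromatics with ortho- or
para-dihydroxy substituents that mediate reversible electron transfer; a
cheminformatic screen that selects drug-like, ES-bearing compounds; and a
network-pharmacology arm that connects those compounds to the deregulated
genes of four breast-cancer subtypes and ranks the hub genes they target.
Every stage consumes plain-text tables and every input class can be
generated synthetically with known ground truth, so the whole pipeline runs
and is verified without any network access.

## 1. Assay quantification

Content assays (total polyphenols, flavonoids, condensed tannins, and the
ferric-reducing power assay) are calibrated by ordinary least squares on
replicate-averaged standards, `A = slope * c + intercept`. Replicates are
averaged *before* the regression; this is routine plate practice and it
keeps the reported R-squared comparable with values quoted for level-mean
fits. Quantification inverts the line, `c = (A - intercept)/slope`, scaled
by the caller's dilution chain; the mass bookkeeping (per-gram basis) is
deliberately left to the caller because extraction protocols differ. For
the ferric-reducing assay each sample carries its own blank; since the
blank signal is what the calibration intercept measures, the
blank-corrected absorbance is divided by the slope alone.

Radical scavenging is the standard DPPH statistic
`%RSA = 100 * ((A_ctl - A_blk) - (A_spl - A_blk)) / (A_ctl - A_blk)`,
which is invariant to adding a constant to all three absorbances. The IC50
is the 50% crossing of a straight line fitted by OLS to `%RSA` against
*raw* concentration over all supplied points. Two open choices were
resolved as follows: concentrations enter untransformed (log-concentration
is an equally defensible convention, but the linear generator and the
worked examples are exact on the raw scale, and the bench protocol reports
raw mg/mL); and no bracketing or 4PL fit is attempted — the method is a
global linear interpolation, with an `extrapolated` flag raised when the
crossing falls more than one dilution step outside the observed range and a
`degenerate` flag when every point sits exactly at 50%.

## 2. Electrochemistry

**Microbial fuel cell.** With an external load `R` and anode area `A`, the
cell current is `I = V/R` and the areal power `P = V*I/A`. Records report
the mean and SD of `P` over a plateau window (by default the last 40% of
the time course). Power densities are labelled mW/m^2; published tables of
this kind sometimes print "mV/m^2", which is a unit typo we do not
reproduce. Fold amplification divides a condition's mean power density by
the pre-dosing blank's, so geometry and load cancel; the SD of the ratio is
propagated to first order, `sqrt((s_a/b)^2 + (a s_b/b^2)^2)` — the
source tables do not state their propagation rule, and first-order
propagation is the conventional choice. The ES-presence rule is a strict
threshold: amplification above 2.00-fold indicates electron shuttles.

**Cyclic voltammetry.** The closed-loop area of one cycle is
`integral from V_L to V_H of (i_h - i_l) dV`, with `i_h` the oxidation
(forward, increasing-voltage) sweep and `i_l` the reduction sweep — the
assignment is a convention exposed as the `ih_direction` argument. Sweeps
rarely sample identical voltages, so both are linearly interpolated onto a
common uniform 10 mV grid (matching the instrument's sampling granularity)
before subtraction and trapezoidal integration; this makes the integrand
well defined and the result invariant to sample ordering. Areas are
reported in uA.V; when a cycle takes one second per volt this is numerically
a power in uW, which is the equivalence assumed when such areas are quoted
as "power generated". Scan rate is carried as metadata only — protocols
quote both 10 and 100 mV/s for the same setup, and no computed quantity
here depends on it. The per-cycle profile reports an attenuation ratio
(last/first area) and a stabilisation cycle: the first cycle after which
every successive relative change is at most 2%.

## 3. Compound screening

The drug-likeness filters follow their printed wording exactly: Lipinski
(HBD < 5, HBA < 10, MW < 500 Da, logP < 5 — all strict), Veber
(rotatable bonds < 10, TPSA < 140 A^2 — strict), and the absorption
screen (high gastrointestinal absorption class, bioavailability >= 0.55 —
the one non-strict bound — and human intestinal absorption < 0.3). The
absorption scores are *inputs*: they emulate the output of proprietary
ADMET web models, which this package does not re-implement. A descriptor
fallback (`compute_descriptors()`) exists for libraries without
precomputed physicochemical values; it uses Open Babel's generic models
and is documented as non-equivalent to any specific service.

The ES structural rule is a substructure match: a compound is positive when
some aromatic carbocyclic six-ring carries hydroxyls at 1,2 (ortho) or 1,4
(para) positions. Every six-ring of a fused system is considered, matching
is done on the perceived aromatic graph (so kekulised SMILES behave
identically), and 1,2,3-triols match through their ortho pairs. Enediols
such as ascorbic acid do *not* satisfy the aromatic rule; because published
screens have retained such compounds without stating why, an explicit
opt-in (`allow_enediol = TRUE`) extends the rule rather than silently
guessing. `screen_library()` composes the four rules conjunctively and
emits a per-rule attrition table; relaxing any threshold or dropping any
rule can only enlarge the survivor set, which the test suite checks as a
property.

## 4. Differential expression

Expression matrices are log2-scale intensities; `normalize_expression()`
log-transforms matrices that look linear (maximum above 50, a heuristic the
caller can override) and optionally quantile-normalises columns. The
two-group statistic is an empirical-Bayes moderated t: per gene the pooled
variance `s^2` on `d = n1 + n2 - 2` degrees of freedom is shrunk towards a
prior `s0^2` with prior degrees of freedom `d0`,
`s_tilde^2 = (d0 s0^2 + d s^2)/(d0 + d)`, and `t = log2FC / (s_tilde *
sqrt(1/n1 + 1/n2))` is referred to `d + d0` degrees of freedom. The prior
is fitted by the method of moments on the log variances under a scaled-F
model (mean and variance of `log s^2` determine `d0` through a trigamma
inversion). This is the standard variance-moderation model; the
precision-weight (mean-variance trend) layer of array pipelines is
deliberately not re-implemented — the pipeline's substance is the
thresholding chain, and the moderated t is verified against both a pooled-t
closed form (at `prior_df = 0`) and an independent implementation in the
test suite. With `d0` estimated as infinite (no excess variance
dispersion), all genes share `s0^2` and the reference distribution is
normal.

Calls use strict thresholds: adjusted p (Benjamini–Hochberg, via
`p.adjust`) below 0.05 and signed linear fold change beyond ±1.5, where
`signed_fc = 2^log2FC` for positive effects and `-2^(-log2FC)` for
negative ones. Because fold-change conventions are genuinely ambiguous in
array reports, `fc_scale = "log2"` switches the threshold to the log2
scale. Duplicate gene symbols (multi-probe genes) are collapsed to the
record with the smallest raw p before set operations. Target predictions
are filtered per source: ligand-similarity rows at probability >= 0.10,
ATC-classifier rows at probability >= 0.60 with model accuracy >= 0.90;
the subtype overlap is a plain sorted intersection of DEG calls with the
pooled qualified targets.

## 5. Network hubs

`build_ppi_network()` keeps edges with STRING combined score >= 700 (70%
confidence), removes self-loops and duplicates, then drops nodes with no
more than 2 edges. The wording of that pruning rule does not say whether it
iterates, so a single pass is the default and `prune = "kcore"` iterates to
the 3-core; both are available and the difference is tested.

Four centralities are implemented from first principles on the adjacency
structure: degree; harmonic closeness (sum of reciprocal BFS distances,
with unreachable nodes contributing zero — chosen over Freeman closeness
because pruning can disconnect the graph, with `method = "classic"`
available for comparison); MCC, the sum over maximal cliques containing a
node of `(|C|-1)!`, enumerated by Bron–Kerbosch with pivoting (an isolated
node counts its singleton clique, scoring 1; enumeration refuses graphs
beyond a 5000-node cap); and MNC, the size of the largest connected
component of the open neighbourhood. All four are checked against
exhaustive-enumeration oracles on hundreds of random small graphs and
against an independent graph library.

Hub lists take the top 15 per algorithm, ranked score-descending with the
gene symbol as a deterministic tie-break; the cut at rank `k` is strict
(ties beyond `k` are excluded) so lists are reproducible. The consensus is
the intersection across all four algorithms — the source protocol lists
four algorithms and then says "three", an inconsistency we resolve by
defaulting to all four with an `algorithms` argument to override rather
than guessing the intent. Key hubs are the intersection of per-subtype
consensus lists per direction.

## 6. Enrichment

Over-representation uses the exact upper-tail hypergeometric probability:
for a universe of `N` genes, a term of `K` and a query of `n`,
`p = P(X >= k)` for an overlap of `k`, with fold enrichment
`(k/n)/(K/N)`. An optional EASE-style variant discounts one overlapping
gene, reproducing the more conservative score some annotation servers
report; both are exact computations and the default is the standard
hypergeometric. The universe defaults to all genes in the annotation
collection and is overridable (e.g. to the expression platform's gene
list, closer to how annotation servers define their background — which
background the published analysis used is not stated, so neither default is
asserted as equivalent). Matching the published criterion, no
multiple-testing correction is applied to enrichment p-values; ranking
filters at p < 0.05 (strict), sorts by descending `-log10 p` with the term
id as tie-break and truncates to 20.

## 7. The synthetic-data module

The generators define the study conditions rather than adapting to tests:

* **Expression** — per-gene baseline means drawn once from N(7, 1), i.i.d.
  Gaussian noise with `noise_sd = 0.3` log2 units; the default design is
  the emulated microarray study's: 29/30/30/41 tumour samples across four
  subtypes against 11 normals. Spiked genes shift by ±2 log2 units in every
  tumour group. There is no probe-level structure, no batch effect, no
  mean-variance trend — so passing recovery tests demonstrates the
  thresholding chain is correct, not that the pipeline is robust to real
  array artefacts.
* **Compounds** — scaffolds with unambiguous structural classes (catechol-,
  hydroquinone-, pyrogallol-like positives; meta-diols, mono-ols, ethers,
  non-aromatics as negatives), so classifier accuracy on this library is
  expected to be exactly 100% and any deviation is a defect. Descriptors
  and absorption scores are sampled from ranges straddling every threshold.
* **Network** — an Erdos–Renyi background (default edge probability 0.04 on
  60 nodes) with one planted clique (default size 6) whose edges always
  score above the 70% cutoff.
* **Plates** — standards on the published calibration lines (e.g.
  `y = 3.8354x - 0.0132` for the polyphenol assay) with Gaussian noise of
  0.01 AU, two-fold dilution ladders matching the bench protocol; the DPPH
  generator keeps `%RSA` linear in concentration with a slope (default
  50 %/(mg/mL)) chosen so the whole ladder stays inside (0, 100)%.
* **Electrochemistry** — voltage plateaus chosen to realise configured
  amplification factors (defaults are the water-extract dosing schedule's
  published ratios, blank at 9.882 mW/m^2); voltammograms are a rectangular
  capacitive gap plus Gaussian oxidation/reduction peaks on a fixed 10 mV
  grid, with a per-cycle decay factor that makes geometric attenuation
  exact.

One master seed fans out to fixed per-generator child seeds, so outputs are
bit-for-bit reproducible and adding a generator never perturbs the others.

## 8. Numerical choices and verification sizes

Calibration and IC50 fits are closed-form OLS (verified against the normal
equations at 1e-10); the hypergeometric tail uses `phyper` and is verified
against an exact binomial-coefficient sum at 1e-12 over hundreds of random
configurations with universes up to 60 genes; loop areas are verified
against fine-grid (up to 1e6-point) quadrature within 0.1%; the centrality
implementations are verified on 200 random graphs of up to 8 nodes against
exhaustive-subset oracles. The differential-expression checks use 2000
genes with 100 spikes for recovery and 50 independent null simulations of
1000 genes (30 vs 11 samples) for the false-positive rate; these sizes make
the checks sharp while keeping the default verification run fast, and the
conclusions do not depend on them.

## 9. Interfaces and limitations

The exported functions are the interface; `run_pipeline()` with
`pipeline_config()` (or a YAML file via `read_pipeline_config()`)
orchestrates the stages end to end, writes every table under an output
directory and records a manifest of content hashes, so identical
configurations yield identical manifests. Known limitations: no probe-level
preprocessing, no docking or molecular-dynamics stages (external engines,
out of scope), no re-implementation of proprietary ADMET or
target-prediction models (their outputs are inputs here), no GO-graph
propagation, and no electrochemical mechanism fitting beyond the loop-area
statistics.
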