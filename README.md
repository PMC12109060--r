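# teashuttle

Semi-fermented (Oolong) tea extracts carry two pharmacologically
interesting classes of phenolics: **antioxidants**, which scavenge radicals
irreversibly, and **electron shuttles (ES)** — aromatics bearing *ortho*-
or *para*-dihydroxy substituents that mediate *reversible* electron
transfer and can stimulate bioelectricity generation. `teashuttle` is an R
package for researchers who want to run the full desk-side analysis chain
that characterises such extracts and connects their compounds to disease
gene networks, entirely offline and with every stage testable against known
ground truth.

The pipeline covers:

* **Assay quantification** — linear calibration of content assays
  (polyphenols/flavonoids/tannins as gallic-acid, rutin and catechin
  equivalents; ferric-reducing power as Trolox equivalents), the DPPH
  radical-scavenging statistic
  `%RSA = 100 * (A_ctl − A_spl) / (A_ctl − A_blk)` and IC50 by linear
  interpolation of the 50% crossing.
* **Electrochemistry** — microbial-fuel-cell power density
  `P = V²/(R·A)`, blank-normalised fold amplification with the
  `> 2.00`-fold ES-presence rule, and cyclic-voltammetry closed-loop areas
  `∫ (i_h − i_l) dV` with per-cycle attenuation and stabilisation
  profiling.
* **Compound screening** — Lipinski (HBD < 5, HBA < 10, MW < 500,
  logP < 5), Veber (RotB < 10, TPSA < 140 Å²), absorption-score filters
  (GI high, bioavailability ≥ 0.55, HIA < 0.3) and the ES structural rule
  as a SMARTS substructure match on aromatic six-rings.
* **Differential expression** — an empirical-Bayes moderated t
  (`t = log2FC / (s̃·√(1/n₁+1/n₂))`, variance shrunk towards a
  moment-fitted prior), Benjamini–Hochberg adjustment, calls at
  adj-p < 0.05 and signed linear fold change beyond ±1.5, and overlap with
  probability-filtered compound-target predictions.
* **Network hubs** — STRING-dialect edge lists filtered at 70% confidence
  with ≤2-edge nodes pruned, then four centralities implemented from
  scratch: degree, harmonic closeness, MCC (Σ over maximal cliques of
  `(|C|−1)!`, via Bron–Kerbosch) and MNC (largest neighbourhood
  component); top-15 consensus and cross-subtype key-hub intersection.
* **GO enrichment** — exact hypergeometric over-representation with fold
  enrichment `(k/n)/(K/N)`, p < 0.05 filtering and top-20 ranking by
  `−log10 p`.
* **Synthetic data** — seeded generators for every input class (expression
  with spiked fold changes, compound libraries with known ES labels,
  planted-clique interaction networks, calibration plates, MFC plateaus,
  voltammograms), so the whole chain verifies without downloads.

## Worked example

The package bundles the power-density table of four tea extract
preparations measured in a two-chamber microbial fuel cell, and the
per-subtype hub-gene lists of a breast-cancer network-pharmacology
analysis:

```r
library(teashuttle)

pd   <- example_power_density()
otlw <- amplification(pd[pd$extract == "OTL-W", ], blank_id = "blank1")
otlw[, c("condition_id", "pd_mean", "amplification")]
#>   condition_id pd_mean amplification
#> 1       blank1    9.88          1.00
#> 2       250ppm   16.35          1.65
#> 3       500ppm   18.95          1.92
#> 4       750ppm   20.13          2.04
#> 5      1000ppm   21.37          2.16
#> 6      1500ppm   22.17          2.24
#> 7      2000ppm   24.37          2.47
#> 8       blank2   12.07          1.22
#> 9     dopamine   33.53          3.39
```

The water extract more than doubles the blank's power density from 750 ppm
upward — `es_presence(otlw$amplification)` flags those four conditions as
electron-shuttle positive (amplification strictly above 2.00-fold), with
the dopamine standard at 3.39-fold confirming the cell responds to a known
shuttle. The structural rule agrees with the electrochemistry on the
defining cases:

```r
es_classify(c("Oc1ccccc1O", "Oc1cccc(O)c1", "Oc1ccc(O)cc1"))
#>         smiles es_positive motif
#> 1   Oc1ccccc1O        TRUE ortho    (catechol)
#> 2 Oc1cccc(O)c1       FALSE  <NA>    (resorcinol - meta diol)
#> 3 Oc1ccc(O)cc1        TRUE  para    (hydroquinone)
```

Intersecting the per-subtype hub lists gives the key hubs shared by all
four breast-cancer subtypes:

```r
hubs <- example_hub_lists()
key_hub_intersection(hubs$down)
#> [1] "HSP90AB1" "MAPK1"
key_hub_intersection(hubs$up)
#> [1] "PIK3CA" "PIK3R1"
```

So across subtypes, the compound-targetable downregulated networks share
the MAPK-pathway kinase gene *MAPK1* and the chaperone gene *HSP90AB1*,
and the upregulated networks share the PI3K subunit genes *PIK3CA* and
*PIK3R1*.

A full synthetic run (simulate → assay → electrochemistry → screen → DEG →
hubs → enrichment) is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), outdir = "run1")
res$manifest   # every output file with its content hash
```

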