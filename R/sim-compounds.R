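# Scaffold pools for the simulated compound library. Positives all carry an
# aromatic carbocyclic six-ring with hydroxyls in ortho or para positions;
# negatives are meta-diols, mono-ols, ethers or non-aromatics, so the
# structural classes are unambiguous by construction.
.es_positive_scaffolds <- c(
  catechol            = "Oc1ccccc1O",
  hydroquinone        = "Oc1ccc(O)cc1",
  pyrogallol          = "Oc1cccc(O)c1O",
  methylcatechol      = "Cc1ccc(O)c(O)c1",
  gallic_acid         = "OC(=O)c1cc(O)c(O)c(O)c1",
  caffeic_acid        = "OC(=O)C=Cc1ccc(O)c(O)c1",
  protocatechuic_acid = "OC(=O)c1ccc(O)c(O)c1",
  luteolin            = "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)cc2=O",
  quercetin           = "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O",
  tert_butylhydroquinone = "CC(C)(C)c1cc(O)ccc1O"
)

.es_negative_scaffolds <- c(
  resorcinol    = "Oc1cccc(O)c1",
  phenol        = "Oc1ccccc1",
  m_cresol      = "Cc1cccc(O)c1",
  benzoic_acid  = "OC(=O)c1ccccc1",
  vanillin      = "COc1cc(C=O)ccc1O",
  anisole       = "COc1ccccc1",
  salicylic_acid = "OC(=O)c1ccccc1O",
  cyclohexanol  = "OC1CCCCC1",
  glycerol      = "OCC(O)CO",
  caffeine      = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"
)

#' Simulate a compound library with known electron-shuttle labels
#'
#' Builds a library mixing electron-shuttle-positive scaffolds (catechol-,
#' hydroquinone- and pyrogallol-like aromatics) with negative scaffolds
#' (meta-diols, mono-ols, aryl ethers, non-aromatics), in proportion
#' `frac_es_positive`. Pharmacokinetic descriptors and absorption scores
#' are sampled from ranges straddling the screening thresholds so every
#' rule of [screen_library()] is exercised; per-rule ground truth is
#' recorded at generation time, before any downstream computation.
#'
#' @param config A [sim_config()].
#' @return A list with elements `compounds` (data frame: `compound_id`,
#'   `smiles`, `mw`, `hbd`, `hba`, `logp`, `rotb`, `tpsa`,
#'   `gi_absorption`, `bioavailability_score`, `hia_score`) and `truth`
#'   (data frame of per-rule expected outcomes plus the scaffold used).
#' @export
#' @examples
#' lib <- simulate_compound_library(sim_config(seed = 3, n_compounds = 10))
#' table(lib$truth$es_positive)
simulate_compound_library <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "compounds"))
  n <- cfg$n_compounds
  n_pos <- round(cfg$frac_es_positive * n)
  es_positive <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))

  scaffold <- character(n)
  scaffold[es_positive] <- sample(names(.es_positive_scaffolds),
                                  sum(es_positive), replace = TRUE)
  scaffold[!es_positive] <- sample(names(.es_negative_scaffolds),
                                   sum(!es_positive), replace = TRUE)
  smiles <- ifelse(es_positive,
                   .es_positive_scaffolds[scaffold],
                   .es_negative_scaffolds[scaffold])

  compounds <- data.frame(
    compound_id = sprintf("CMP%03d", seq_len(n)),
    smiles = unname(smiles),
    mw = round(runif(n, 150, 620), 2),
    hbd = sample(0:6, n, replace = TRUE),
    hba = sample(0:12, n, replace = TRUE),
    logp = round(runif(n, -1, 6), 2),
    rotb = sample(0:12, n, replace = TRUE),
    tpsa = round(runif(n, 20, 180), 2),
    gi_absorption = sample(c("High", "Low"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
    bioavailability_score = round(runif(n, 0.30, 0.90), 2),
    hia_score = round(runif(n, 0, 0.6), 3),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    compound_id = compounds$compound_id,
    scaffold = unname(scaffold),
    es_positive = es_positive,
    lipinski_pass = compounds$hbd < 5 & compounds$hba < 10 &
      compounds$mw < 500 & compounds$logp < 5,
    veber_pass = compounds$rotb < 10 & compounds$tpsa < 140,
    absorption_pass = compounds$gi_absorption == "High" &
      compounds$bioavailability_score >= 0.55 & compounds$hia_score < 0.3,
    stringsAsFactors = FALSE)

  list(compounds = compounds, truth = truth)
}
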