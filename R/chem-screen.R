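# SMARTS patterns for the electron-shuttle structural rule: a hydroxyl pair
# on adjacent (ortho) or 1,4 (para) carbons of an aromatic carbocyclic
# six-ring. Matching is performed on the perceived aromatic molecular
# graph, so kekulised input and fused ring systems are handled.
.es_smarts <- c(ortho = "[OX2H]c1ccccc1[OX2H]",
                para = "[OX2H]c1ccc([OX2H])cc1")
.enediol_smarts <- c(enediol = "[OX2H][#6]=[#6][OX2H]")

.smiles_to_sdf <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  parse <- function(x, nm) {
    suppressWarnings(tryCatch(ChemmineR::smiles2sdf(setNames(x, nm)),
                              error = function(e) NULL))
  }
  out <- parse(smiles, ids)
  # Open Babel silently drops molecules it cannot parse; identify them.
  if (is.null(out) || length(out) != length(smiles) ||
      !all(ChemmineR::validSDF(out))) {
    ok <- vapply(seq_along(smiles), function(i) {
      one <- parse(smiles[i], ids[i])
      !is.null(one) && length(one) == 1L && all(ChemmineR::validSDF(one))
    }, logical(1))
    ts_stop("smiles_parse_error",
            paste("unparseable SMILES:",
                  paste(smiles[!ok], collapse = ", ")))
  }
  out
}

#' Classify compounds by the electron-shuttle structural rule
#'
#' A compound is called electron-shuttle positive when at least one
#' aromatic carbocyclic six-ring carries hydroxyl groups in the ortho (1,2)
#' or para (1,4) positions - the substitution pattern that makes phenolics
#' reversible redox mediators. Every six-ring, including rings of fused
#' systems, is considered; pyrogallol-type 1,2,3-triols match through their
#' ortho pairs. Classification is invariant to SMILES kekulisation and atom
#' ordering because matching happens on the perceived molecular graph.
#'
#' Enediol systems (e.g. ascorbic acid) do not satisfy the default aromatic
#' rule; `allow_enediol = TRUE` opt-in extends the positive set to
#' non-aromatic enediols.
#'
#' @param smiles Character vector of SMILES strings.
#' @param allow_enediol Also accept non-aromatic enediol motifs.
#' @return Data frame with `smiles`, `es_positive` (logical) and `motif`
#'   (`"ortho"`, `"para"`, `"ortho+para"`, `"enediol"` or `NA`).
#' @export
#' @examples
#' \donttest{
#' es_classify(c("Oc1ccccc1O", "Oc1cccc(O)c1"))  # ortho TRUE, meta FALSE
#' }
es_classify <- function(smiles, allow_enediol = FALSE) {
  sdf <- .smiles_to_sdf(smiles)
  hit <- function(pat) {
    as.numeric(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = FALSE)) > 0
  }
  ortho <- hit(.es_smarts[["ortho"]])
  para <- hit(.es_smarts[["para"]])
  motif <- rep(NA_character_, length(smiles))
  motif[para] <- "para"
  motif[ortho] <- "ortho"
  motif[ortho & para] <- "ortho+para"
  positive <- ortho | para
  if (allow_enediol) {
    ene <- hit(.enediol_smarts[["enediol"]])
    motif[ene & !positive] <- "enediol"
    positive <- positive | ene
  }
  data.frame(smiles = smiles, es_positive = positive, motif = motif,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute physicochemical descriptors from SMILES
#'
#' Descriptor fallback for libraries that arrive without precomputed
#' values: molecular weight, hydrogen-bond donors/acceptors, logP and
#' topological polar surface area from Open Babel's models, plus a
#' SMARTS-based rotatable-bond count. These are generic cheminformatics
#' estimates, not equivalents of any particular web service's predictions;
#' absorption scores are never predicted here and must be supplied as
#' inputs.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Data frame `smiles`, `mw`, `hbd`, `hba`, `logp`, `rotb`, `tpsa`.
#' @export
compute_descriptors <- function(smiles) {
  sdf <- .smiles_to_sdf(smiles)
  pr <- ChemmineR::propOB(sdf)
  rot <- as.numeric(ChemmineR::smartsSearchOB(
    sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))
  data.frame(smiles = smiles, mw = pr$MW, hbd = pr$HBD, hba = pr$HBA1,
             logp = pr$logP, rotb = rot, tpsa = pr$TPSA,
             row.names = NULL, stringsAsFactors = FALSE)
}

.need_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    ts_stop("incomplete_record",
            sprintf("%s requires column(s): %s", what,
                    paste(miss, collapse = ", ")))
  bad <- cols[vapply(cols, function(cl) any(is.na(x[[cl]])), logical(1))]
  if (length(bad))
    ts_stop("incomplete_record",
            sprintf("%s has missing values in: %s", what,
                    paste(bad, collapse = ", ")))
  invisible(x)
}

#' Lipinski rule-of-five filter
#'
#' Oral drug-likeness: fewer than 5 hydrogen-bond donors, fewer than 10
#' acceptors, molecular weight under 500 Da and logP under 5. All
#' inequalities are strict.
#'
#' @param descriptors Data frame (or named list) with `hbd`, `hba`, `mw`,
#'   `logp`.
#' @param mw_max,hbd_max,hba_max,logp_max Thresholds.
#' @return Logical vector.
#' @export
lipinski <- function(descriptors, mw_max = 500, hbd_max = 5, hba_max = 10,
                     logp_max = 5) {
  d <- as.data.frame(descriptors)
  .need_cols(d, c("hbd", "hba", "mw", "logp"), "lipinski")
  d$hbd < hbd_max & d$hba < hba_max & d$mw < mw_max & d$logp < logp_max
}

#' Veber oral-bioavailability filter
#'
#' Fewer than 10 rotatable bonds and total polar surface area under
#' 140 squared angstroms (both strict).
#'
#' @param descriptors Data frame (or named list) with `rotb`, `tpsa`.
#' @param rotb_max,tpsa_max Thresholds.
#' @return Logical vector.
#' @export
veber <- function(descriptors, rotb_max = 10, tpsa_max = 140) {
  d <- as.data.frame(descriptors)
  .need_cols(d, c("rotb", "tpsa"), "veber")
  d$rotb < rotb_max & d$tpsa < tpsa_max
}

#' Absorption-score filter
#'
#' Consumes predicted absorption scores supplied with the library (they
#' emulate web-service ADMET output and are never predicted here): a high
#' gastrointestinal absorption class, a bioavailability score of at least
#' 0.55 (non-strict) and a human intestinal absorption score under 0.3
#' (strict).
#'
#' @param records Data frame with `gi_absorption` (character class, or a
#'   numeric probability of high absorption with 0.5 cutoff),
#'   `bioavailability_score`, `hia_score`.
#' @param bioavailability_min,hia_max Thresholds.
#' @return Logical vector.
#' @export
absorption_filter <- function(records, bioavailability_min = 0.55,
                              hia_max = 0.3) {
  d <- as.data.frame(records)
  .need_cols(d, c("gi_absorption", "bioavailability_score", "hia_score"),
             "absorption_filter")
  gi_high <- if (is.numeric(d$gi_absorption)) d$gi_absorption >= 0.5
             else tolower(as.character(d$gi_absorption)) == "high"
  gi_high & d$bioavailability_score >= bioavailability_min &
    d$hia_score < hia_max
}

#' Screen a compound library through all pharmacological rules
#'
#' A compound survives when every enabled rule passes: Lipinski, Veber, the
#' absorption-score filter and the electron-shuttle structural rule.
#' Disabling a rule (dropping it from `rules`) can only enlarge the
#' survivor set. Alongside the flagged table, a per-rule attrition summary
#' is returned, auditing how many compounds each rule passes marginally and
#' how many survive the rules applied in sequence.
#'
#' @param compounds Data frame with `compound_id`, `smiles`, descriptor and
#'   score columns (see [lipinski()], [veber()], [absorption_filter()]).
#' @param rules Character subset of
#'   `c("lipinski", "veber", "absorption", "es")`.
#' @param allow_enediol Passed to [es_classify()].
#' @param ... Threshold overrides passed to the individual rules, e.g.
#'   `mw_max`, `bioavailability_min`.
#' @return List with `screened` (the input plus logical flag columns,
#'   `motif` and `survives`) and `attrition` (data frame `rule`, `n_input`,
#'   `n_pass_rule`, `n_surviving`).
#' @export
screen_library <- function(compounds,
                           rules = c("lipinski", "veber", "absorption", "es"),
                           allow_enediol = FALSE, ...) {
  rules <- match.arg(rules, several.ok = TRUE)
  out <- compounds
  if (nrow(out) == 0L) {
    empty <- data.frame(rule = rules, n_input = 0L, n_pass_rule = 0L,
                        n_surviving = 0L, stringsAsFactors = FALSE)
    out$survives <- logical(0)
    return(list(screened = out, attrition = empty))
  }
  dots <- list(...)
  call_rule <- function(fn, allowed) {
    do.call(fn, c(list(out), dots[intersect(names(dots), allowed)]))
  }
  flags <- list()
  if ("lipinski" %in% rules)
    flags$lipinski_pass <- call_rule(lipinski,
                                     c("mw_max", "hbd_max", "hba_max", "logp_max"))
  if ("veber" %in% rules)
    flags$veber_pass <- call_rule(veber, c("rotb_max", "tpsa_max"))
  if ("absorption" %in% rules)
    flags$absorption_pass <- call_rule(absorption_filter,
                                       c("bioavailability_min", "hia_max"))
  if ("es" %in% rules) {
    es <- es_classify(out$smiles, allow_enediol = allow_enediol)
    flags$es_positive <- es$es_positive
    out$motif <- es$motif
  }
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out$survives <- Reduce(`&`, flags, accumulate = FALSE)

  surviving <- rep(TRUE, nrow(out))
  attr_rows <- lapply(seq_along(flags), function(i) {
    surviving <<- surviving & flags[[i]]
    data.frame(rule = sub("_(pass|positive)$", "", names(flags)[i]),
               n_input = nrow(out),
               n_pass_rule = sum(flags[[i]]),
               n_surviving = sum(surviving),
               stringsAsFactors = FALSE)
  })
  list(screened = out, attrition = do.call(rbind, attr_rows))
}
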