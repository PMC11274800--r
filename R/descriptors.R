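# Physicochemical descriptor profiling: the per-molecule descriptor vector
# (MW, HBD, HBA, TPSA, logP, nRotB, ESOL, SAscore, QED, optional logD) used
# throughout the diversity and scoring analyses.

#' ESOL aqueous solubility estimate
#'
#' Delaney's published linear regression on clogP, molecular weight,
#' rotatable-bond count and aromatic proportion:
#' `log10(S) = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`
#' with S in mol/L and AP the fraction of heavy atoms that are aromatic.
#'
#' @param logp,mw,nrotb,aromatic_proportion Numeric vectors.
#' @return Estimated log10 solubility (mol/L).
#' @export
esol <- function(logp, mw, nrotb, aromatic_proportion) {
  0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * nrotb - 0.74 * aromatic_proportion
}

aromatic_proportion <- function(smiles) {
  vapply(smiles, function(s) {
    a <- smiles_atom_seq(s)
    heavy <- a$elem != "H" & a$elem != "*"
    if (!any(heavy)) return(0)
    mean(a$aromatic[heavy])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Profile a library with the standard descriptor vector
#'
#' Computes, for every curated molecule, molecular weight, hydrogen-bond
#' donor and acceptor counts, topological polar surface area, logP,
#' rotatable bonds, ESOL solubility, synthetic accessibility (SAscore),
#' drug-likeness (QED) and, when supplied, an externally computed logD.
#'
#' @param data Data frame of curated records, or a character vector of
#'   SMILES.
#' @param smiles Name of the SMILES column (see [scaffold_profile()]).
#' @param logd Optional numeric vector (or name of a column in `data`)
#'   with externally computed logD values.
#' @param sa_table Fragment-familiarity table for the SAscore; defaults to
#'   the built-in parameterization (see [sa_fragment_table()]).
#' @return A tibble with one row per molecule: `smiles`, `mw`, `hbd`,
#'   `hba`, `tpsa`, `logp`, `nrotb`, `esol`, `sascore`, `qed`, `logd`.
#' @export
profile_library <- function(data, smiles = NULL, logd = NULL,
                            sa_table = NULL) {
  smi <- extract_smiles(data, smiles)
  if (!length(smi)) stop("no molecules to profile")
  if (is.character(logd) && length(logd) == 1L && is.data.frame(data)) {
    logd <- data[[logd]]
  }
  can <- canonical_smiles(smi)
  if (anyNA(can)) {
    stop("unparseable structures at positions: ",
         paste(which(is.na(can)), collapse = ", "))
  }
  props <- ob_properties(smi)
  nrotb <- smarts_count(as_sdfset(smi), ROTB_SMARTS)
  ap <- aromatic_proportion(smi)
  q <- qed_score(smi)
  tibble::tibble(
    smiles = smi,
    mw = props$MW,
    hbd = as.integer(props$HBD),
    hba = as.integer(props$HBA2),
    tpsa = props$TPSA,
    logp = props$logP,
    nrotb = as.integer(nrotb),
    esol = esol(props$logP, props$MW, nrotb, ap),
    sascore = sa_score(smi, table = sa_table),
    qed = q$qed,
    logd = if (is.null(logd)) NA_real_ else as.numeric(logd)
  )
}

#' Ligand efficiency
#'
#' Docking score divided by the number of heavy atoms (kcal/mol per heavy
#' atom; more negative is better).
#'
#' @param score Docking score(s), kcal/mol.
#' @param heavy_atoms Heavy-atom count(s), `>= 1`.
#' @return Numeric vector of ligand efficiencies.
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1")
  score / heavy_atoms
}

#' Read a docking-score table
#'
#' CSV with columns `id`, `program`, `score` and either a `heavy_atoms`
#' column or a library to look the structures up in; adds the
#' ligand-efficiency column `le`.
#'
#' @param path CSV file path.
#' @param library Optional curated library tibble with `id` and
#'   `canonical_smiles`, used to compute heavy-atom counts when the CSV
#'   lacks them.
#' @return A tibble with `id`, `program`, `score`, `heavy_atoms`, `le`.
#' @export
read_docking_table <- function(path, library = NULL) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("id", "program", "score")
  if (!all(need %in% names(tbl))) {
    stop("docking table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"heavy_atoms" %in% names(tbl)) {
    if (is.null(library)) stop("no heavy_atoms column and no library given")
    idx <- match(tbl$id, library$id)
    if (anyNA(idx)) stop("docking ids missing from library: ",
                         paste(tbl$id[is.na(idx)], collapse = ", "))
    tbl$heavy_atoms <- heavy_atom_count(library$canonical_smiles[idx])
  }
  tbl$le <- ligand_efficiency(tbl$score, tbl$heavy_atoms)
  tbl
}
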