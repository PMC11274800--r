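# Fragment-library and training-set preparation: RO3 size filtering, MaxMin
# diversity selection on fingerprints, logD gating, and the two pipelines
# built from them (285-compound training sets; 400 -> logD <= 3 -> 177
# fragment libraries).

#' MaxMin diversity selection
#'
#' Greedy MaxMin picking on Tanimoto distance (1 - similarity): the first
#' pick is designated by the seed (`seed mod pool size`), and every later
#' pick maximizes its minimum distance to the already-picked set (ties
#' resolved to the earliest pool index). Deterministic given pool order and
#' seed.
#'
#' @param data Data frame with a SMILES column, or character vector.
#' @param k Number of molecules to select.
#' @param fingerprint Fingerprint kind (see [fp_matrix()]); MACCS keys by
#'   default as is customary for diversity picking.
#' @param seed Integer seed (designates the first pick).
#' @param smiles SMILES column name override.
#' @return The selected rows (tibble) in pick order, with a `.pick` column;
#'   attributes `seed`, `fingerprint`, `k`, and `short` (TRUE when the pool
#'   was smaller than `k`).
#' @export
maxmin_select <- function(data, k, fingerprint = "MACCS166", seed = 1L,
                          smiles = NULL) {
  smi <- extract_smiles(data, smiles)
  n <- length(smi)
  if (n < 1L) stop("empty pool")
  if (k < 1L) stop("k must be >= 1")
  tbl <- if (is.data.frame(data)) tibble::as_tibble(data) else
    tibble::tibble(smiles = smi)
  short <- k > n
  if (short) {
    rlang::warn(sprintf("pool (%d) smaller than k (%d): returning whole pool", n, k))
    picked <- seq_len(n)
  } else {
    fps <- fp_matrix(smi, fingerprint)
    first <- (as.integer(seed) %% n) + 1L
    picked <- integer(k)
    picked[1L] <- first
    mind <- 1 - as.vector(tanimoto_cross(fps, fps[first, , drop = FALSE]))
    mind[first] <- -Inf
    if (k > 1L) {
      for (j in 2L:k) {
        nxt <- which.max(mind)
        picked[j] <- nxt
        d <- 1 - as.vector(tanimoto_cross(fps, fps[nxt, , drop = FALSE]))
        mind <- pmin(mind, d)
        mind[nxt] <- -Inf
      }
    }
  }
  out <- tbl[picked, , drop = FALSE]
  out$.pick <- seq_along(picked)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "fingerprint") <- fingerprint
  attr(out, "k") <- as.integer(k)
  attr(out, "short") <- short
  out
}

#' Rule-of-three molecular-weight filter for fragments
#'
#' Keeps fragments with MW strictly below `max_mw` (RO3 bound, 300 Da by
#' default). Water, ammonia and hydrochloric acid are always discarded
#' regardless of weight.
#'
#' @param frags Fragment tibble from [recap_fragments()] (needs `smiles`,
#'   `mw`).
#' @param max_mw Strict upper bound in g/mol.
#' @return The retained rows.
#' @export
ro3_filter <- function(frags, max_mw = 300) {
  if (!all(c("smiles", "mw") %in% names(frags))) {
    stop("frags must have smiles and mw columns")
  }
  capped <- canonical_smiles(strip_dummies(frags$smiles))
  excluded <- capped %in% c("O", "N", "Cl")
  frags[!excluded & !is.na(frags$mw) & frags$mw < max_mw, , drop = FALSE]
}

#' logD filter for fragments
#'
#' Keeps fragments with externally computed logD less than or equal to
#' `max_logd` (closed bound). Every fragment must have a logD entry;
#' missing entries are an error that lists the offending identifiers.
#'
#' @param frags Fragment tibble with an `id` column.
#' @param logd_table Data frame with `id` and `logd` columns (or a named
#'   numeric vector keyed by id).
#' @param max_logd Inclusive upper bound (default 3.0).
#' @return The retained rows, with a `logd` column attached.
#' @export
logd_filter <- function(frags, logd_table, max_logd = 3.0) {
  if (!"id" %in% names(frags)) stop("frags must have an id column")
  if (is.numeric(logd_table)) {
    logd_table <- tibble::tibble(id = names(logd_table), logd = unname(logd_table))
  }
  idx <- match(frags$id, logd_table$id)
  if (anyNA(idx)) {
    stop("missing logD for fragment id(s): ",
         paste(frags$id[is.na(idx)], collapse = ", "))
  }
  frags$logd <- logd_table$logd[idx]
  frags[frags$logd <= max_logd, , drop = FALSE]
}

#' Prepare a de novo training set
#'
#' Keeps molecules with MW strictly greater than 300 (to avoid
#' fragment-like compounds), then selects a diverse subset of
#' `target_size` molecules by MaxMin on MACCS keys/Tanimoto. If fewer than
#' `target_size` molecules survive the filter, all survivors are returned
#' with a warning.
#'
#' @param library Curated library tibble.
#' @param target_size Number of molecules to select (default 285).
#' @param seed Integer seed for the MaxMin initialization.
#' @param smiles SMILES column override.
#' @return Selected rows in pick order (see [maxmin_select()]).
#' @export
prepare_training_set <- function(library, target_size = 285, seed = 1L,
                                 smiles = NULL) {
  smi <- extract_smiles(library, smiles)
  tbl <- if (is.data.frame(library)) tibble::as_tibble(library) else
    tibble::tibble(smiles = smi)
  if ("status" %in% names(tbl)) tbl <- tbl[tbl$status == "CURATED", , drop = FALSE]
  mw <- ob_properties(smi)$MW
  keep <- !is.na(mw) & mw > 300
  tbl <- tbl[keep, , drop = FALSE]
  if (nrow(tbl) == 0L) {
    rlang::warn("no molecules with MW > 300; empty selection")
    out <- tbl
    out$.pick <- integer(0)
    attr(out, "short") <- TRUE
    return(out)
  }
  maxmin_select(tbl, k = target_size, fingerprint = "MACCS166", seed = seed,
                smiles = smiles)
}

#' Prepare a fragment library
#'
#' The fragment-selection pipeline: RO3 MW filter (< 300 Da, excluded
#' species dropped), MaxMin to `intermediate_k` (MACCS keys/Tanimoto), logD
#' gate (<= `max_logd`, externally computed values), and a final MaxMin to
#' `final_k`. Stage counts are recorded in the `stages` attribute. Stages
#' with fewer molecules than requested return everything with a warning.
#'
#' @param frags Fragment tibble from [recap_fragments()] with an `id`
#'   column.
#' @param logd_table Data frame `id`/`logd` covering at least the fragments
#'   surviving the intermediate selection.
#' @param intermediate_k,final_k Selection sizes (defaults 400 and 177).
#' @param max_mw,max_logd Filter bounds.
#' @param seed Integer seed used for both MaxMin stages.
#' @return Selected fragment rows in final pick order, with attribute
#'   `stages` (named integer vector of per-stage counts).
#' @export
prepare_fragment_library <- function(frags, logd_table, intermediate_k = 400,
                                     final_k = 177, max_mw = 300,
                                     max_logd = 3.0, seed = 1L) {
  if (!"id" %in% names(frags)) {
    frags$id <- ordinal_ids(nrow(frags), "FRAG")
  }
  stages <- c(input = nrow(frags))
  s1 <- ro3_filter(frags, max_mw = max_mw)
  stages["ro3"] <- nrow(s1)
  s2 <- maxmin_select(s1, k = intermediate_k, fingerprint = "MACCS166",
                      seed = seed)
  stages["maxmin_intermediate"] <- nrow(s2)
  s3 <- logd_filter(s2, logd_table, max_logd = max_logd)
  stages["logd"] <- nrow(s3)
  out <- maxmin_select(s3, k = final_k, fingerprint = "MACCS166", seed = seed)
  stages["final"] <- nrow(out)
  attr(out, "stages") <- stages
  out
}
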