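# RECAP (retrosynthetic combinatorial analysis procedure) fragmentation.
# Cleavable bonds are identified by local graph predicates implementing the
# published rule set (amide, ester, amine, urea, ether, olefin, quaternary
# nitrogen, aromatic N - aliphatic C, lactam N - aliphatic C, aromatic C -
# aromatic C, sulfonamide); all cleavable bonds are cut and the connected
# components (leaf fragments) are emitted with dummy-atom attachment
# markers and growing-site indices.

recap_cleavable_bonds <- function(g) {
  at <- g$atoms
  bonds <- g$bonds
  n_b <- nrow(bonds)
  if (n_b == 0L) return(integer(0))
  elem <- at$elem; arom <- at$aromatic; chg <- at$charge
  deg <- integer(nrow(at))
  for (k in seq_len(n_b)) {
    deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
    deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
  }
  # neighbour bond indices per atom
  nbb <- g$nb
  other_end <- function(k, a) {
    if (bonds$a1[k] == a) bonds$a2[k] else bonds$a1[k]
  }
  has_double_O <- function(a) {
    any(vapply(nbb[[a]], function(k) {
      bonds$order[k] == 2L && elem[other_end(k, a)] == "O"
    }, logical(1)))
  }
  is_carbonyl_C <- function(a) elem[a] == "C" && !arom[a] && has_double_O(a)
  adjacent_carbonyl <- function(a) {
    any(vapply(nbb[[a]], function(k) is_carbonyl_C(other_end(k, a)), logical(1)))
  }
  n_bonded_N <- function(a) {
    sum(vapply(nbb[[a]], function(k) elem[other_end(k, a)] == "N", logical(1)))
  }
  is_sulfonyl_S <- function(a) {
    elem[a] == "S" &&
      sum(vapply(nbb[[a]], function(k) {
        bonds$order[k] == 2L && elem[other_end(k, a)] == "O"
      }, logical(1))) >= 2L
  }

  cleave <- logical(n_b)
  for (k in seq_len(n_b)) {
    if (g$ring_bond[k]) next            # only acyclic bonds are cut
    a <- bonds$a1[k]; b <- bonds$a2[k]
    ord <- bonds$order[k]
    ea <- elem[a]; eb <- elem[b]
    # never cut a bond to a terminal single atom twice over; terminal
    # halogens etc. are not RECAP cuts anyway
    pairs <- list(c(a, b), c(b, a))
    for (p in pairs) {
      x <- p[1]; y <- p[2]
      ex <- elem[x]; ey <- elem[y]
      if (ord == 1L) {
        # 1. amide / 7-ish lactam exocyclic: N - C(=O)
        if (ex == "N" && !arom[x] && is_carbonyl_C(y)) {
          # urea (rule 2) is the same cut with a second N on the carbonyl
          cleave[k] <- TRUE
        }
        # 3. ester: O - C(=O), O acyclic
        if (ex == "O" && !arom[x] && deg[x] == 2L && is_carbonyl_C(y)) {
          cleave[k] <- TRUE
        }
        # 4. amine: N(sp3, >= 2 heavy neighbours, not amide/sulfonamide) - C(sp3)
        if (ex == "N" && !arom[x] && chg[x] == 0L && deg[x] >= 2L &&
            !adjacent_carbonyl(x) &&
            !any(vapply(nbb[[x]], function(kk) is_sulfonyl_S(other_end(kk, x)),
                        logical(1))) &&
            ey == "C" && !arom[y] && !is_carbonyl_C(y) && deg[y] >= 2L) {
          cleave[k] <- TRUE
        }
        # 6. ether: C - O - C, O acyclic, not ester
        if (ex == "O" && !arom[x] && deg[x] == 2L && !adjacent_carbonyl(x) &&
            ey == "C" && !is_carbonyl_C(y)) {
          both_c <- all(vapply(nbb[[x]], function(kk) {
            elem[other_end(kk, x)] == "C"
          }, logical(1)))
          if (both_c) cleave[k] <- TRUE
        }
        # 8. quaternary nitrogen
        if (ex == "N" && chg[x] == 1L && deg[x] == 4L && ey == "C") {
          cleave[k] <- TRUE
        }
        # 9. aromatic N - aliphatic C
        if (ex == "N" && arom[x] && ey == "C" && !arom[y]) cleave[k] <- TRUE
        # 10. lactam N - aliphatic C: ring N next to an in-ring carbonyl,
        # exocyclic bond to sp3 C
        if (ex == "N" && !arom[x] && g$ring_atom[x] && ey == "C" && !arom[y] &&
            !is_carbonyl_C(y) &&
            any(vapply(nbb[[x]], function(kk) {
              g$ring_bond[kk] && is_carbonyl_C(other_end(kk, x))
            }, logical(1)))) {
          cleave[k] <- TRUE
        }
        # 11. aromatic C - aromatic C (biaryl)
        if (ex == "C" && arom[x] && ey == "C" && arom[y]) cleave[k] <- TRUE
        # 12. sulfonamide: N - S(=O)(=O)
        if (ex == "N" && !arom[x] && is_sulfonyl_S(y)) cleave[k] <- TRUE
      } else if (ord == 2L) {
        # 7. olefin: acyclic C=C between non-aromatic carbons
        if (ex == "C" && ey == "C" && !arom[x] && !arom[y]) cleave[k] <- TRUE
      }
    }
  }
  which(cleave)
}

#' RECAP fragmentation of a molecule
#'
#' Cuts every bond matching the RECAP cleavage rules and returns the leaf
#' fragments (full decomposition). Each fragment carries dummy-atom (`*`)
#' attachment markers; `growing_sites` gives the 0-based positions of those
#' markers in the fragment's canonical-SMILES atom order. A molecule with
#' no cleavable bond yields zero rows.
#'
#' @param smiles Character vector of curated SMILES.
#' @param parent_id Optional identifier vector (recycled to parents).
#' @return A tibble with columns `smiles` (fragment, with `*` markers),
#'   `parent_id`, `mw`, `heavy_atoms`, `growing_sites` (list column of
#'   0-based integer vectors), `n_sites`.
#' @export
recap_fragments <- function(smiles, parent_id = NULL) {
  parent_id <- parent_id %||% ordinal_ids(length(smiles), "PAR")
  stopifnot(length(parent_id) == length(smiles))
  rows <- list()
  for (i in seq_along(smiles)) {
    g <- mol_graph(smiles[i])
    cuts <- recap_cleavable_bonds(g)
    if (!length(cuts)) next
    mask <- rep(TRUE, nrow(g$bonds)); mask[cuts] <- FALSE
    comp <- graph_components(nrow(g$atoms), g$bonds, mask)
    for (cid in unique(comp[comp > 0L])) {
      members <- which(comp == cid)
      frag_cuts <- cuts[vapply(cuts, function(k) {
        (g$bonds$a1[k] %in% members) || (g$bonds$a2[k] %in% members)
      }, logical(1))]
      fsmi <- subgraph_smiles(g, members, cut = frag_cuts)
      sites <- which(smiles_atom_seq(fsmi)$elem == "*") - 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        smiles = fsmi, parent_id = parent_id[i],
        heavy_atoms = length(members),
        growing_sites = list(sites), n_sites = length(sites))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(id = character(0), smiles = character(0),
                          parent_id = character(0), mw = numeric(0),
                          heavy_atoms = integer(0),
                          growing_sites = list(), n_sites = integer(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$mw <- fragment_mw(out$smiles)
  ord <- stats::ave(seq_len(nrow(out)), out$parent_id, FUN = seq_along)
  out$id <- sprintf("%s_F%02d", out$parent_id, ord)
  out[, c("id", "smiles", "parent_id", "mw", "heavy_atoms", "growing_sites",
          "n_sites")]
}

# MW of fragments: the dummy marker is removed and the open valence is
# filled with implicit hydrogen, i.e. the fragment is weighed as the
# capped molecule it would be on its own.
fragment_mw <- function(smiles) {
  capped <- canonical_smiles(strip_dummies(smiles))
  mw <- rep(NA_real_, length(smiles))
  ok <- !is.na(capped)
  if (any(ok)) mw[ok] <- ob_properties(capped[ok])$MW
  mw
}

# Remove * attachment markers from fragment SMILES, leaving a valid
# hydrogen-capped molecule.
strip_dummies <- function(smiles) {
  s <- gsub("(=*)", "", smiles, fixed = TRUE)
  s <- gsub("(*)", "", s, fixed = TRUE)
  s <- gsub("*=", "", s, fixed = TRUE)
  s <- gsub("=*", "", s, fixed = TRUE)
  s <- gsub("*", "", s, fixed = TRUE)
  s
}
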