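# Low-level chemistry layer: everything that talks to OpenBabel (via
# ChemmineOB/ChemmineR) or walks a molecular graph lives here. One
# canonical-SMILES dialect (OpenBabel "can") is used throughout the package;
# SMILES equality across toolkits is not guaranteed.

# OpenBabel prints parse warnings on stderr; they are expected for rejected
# records and must not leak into user output.
ob_quiet <- function(expr) {
  withCallingHandlers(
    suppressWarnings(expr),
    message = function(m) invokeRestart("muffleMessage")
  )
}

ob_convert <- function(source, from, to, options = NULL) {
  if (is.null(options)) {
    ob_quiet(ChemmineOB::convertFormat(from, to, source))
  } else {
    ob_quiet(ChemmineOB::convertFormat(from, to, source, options = options))
  }
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the package-wide canonical dialect (OpenBabel canonical
#' SMILES). Unparseable inputs yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param neutralize If `TRUE`, neutralize formal charges before writing.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles, neutralize = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  titles <- paste0("t", seq_len(n))
  src <- paste0(trimws(smiles[ok]), "\t", titles[ok], "\n", collapse = "")
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  res <- ob_convert(src, "SMI", "CAN", options = opts)
  if (nzchar(res)) {
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[`, "", 1L)
    ttl <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else "", "")
    idx <- match(ttl, titles)
    keep <- !is.na(idx) & nzchar(can)
    out[idx[keep]] <- can[keep]
  }
  # An unparseable record aborts the remainder of an OpenBabel batch; retry
  # still-missing records one at a time so later valid rows are not lost.
  miss <- which(ok & is.na(out))
  if (length(miss)) {
    for (i in miss) {
      r1 <- ob_convert(paste0(trimws(smiles[i]), "\n"), "SMI", "CAN", options = opts)
      r1 <- trimws(strsplit(r1, "\n", fixed = TRUE)[[1]][1])
      r1 <- strsplit(r1, "\t", fixed = TRUE)[[1]][1]
      if (!is.na(r1) && nzchar(r1)) out[i] <- r1
    }
  }
  out
}

# Token-scan a SMILES string into its atom sequence. The atom order equals
# the atom order OpenBabel uses when the same string is converted to SDF,
# which is what aligns aromaticity/charge info with atom/bond blocks.
# Returns a data.frame with columns elem, aromatic, charge, per atom.
smiles_atom_seq <- function(smi) {
  elems <- character(0); arom <- logical(0); chg <- integer(0)
  i <- 1L; n <- nchar(smi)
  two <- c("Cl", "Br")
  while (i <= n) {
    ch <- substr(smi, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smi, i, n), fixed = TRUE)
      stopifnot(j > 0L)
      body <- substr(smi, i + 1L, i + j - 2L)
      i <- i + j
      # strip isotope
      body2 <- sub("^[0-9]+", "", body)
      m <- regmatches(body2, regexpr("^([A-Z][a-z]?|[a-z]{1,2}|\\*)", body2))
      sym <- m[1]
      rest <- substr(body2, nchar(sym) + 1L, nchar(body2))
      is_arom <- sym == tolower(sym) && sym != "*"
      # charge: trailing +/- possibly with digits or repeats
      q <- 0L
      plus <- gregexpr("+", rest, fixed = TRUE)[[1]]
      minus <- gregexpr("-", rest, fixed = TRUE)[[1]]
      np <- if (plus[1] == -1L) 0L else length(plus)
      nm <- if (minus[1] == -1L) 0L else length(minus)
      dig <- regmatches(rest, regexpr("[+-][0-9]+", rest))
      if (length(dig)) {
        q <- as.integer(substr(dig, 2L, nchar(dig))) *
          (if (substr(dig, 1L, 1L) == "+") 1L else -1L)
      } else {
        q <- np - nm
      }
      sym_std <- if (is_arom) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      elems <- c(elems, sym_std); arom <- c(arom, is_arom); chg <- c(chg, q)
    } else if (ch == "%") {
      i <- i + 3L
    } else if (ch %in% c("(", ")", "-", "=", "#", "$", ":", "/", "\\", ".", "~", "@")) {
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      i <- i + 1L
    } else {
      sym2 <- substr(smi, i, i + 1L)
      if (sym2 %in% two) {
        elems <- c(elems, sym2); arom <- c(arom, FALSE); chg <- c(chg, 0L)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        elems <- c(elems, ch); arom <- c(arom, FALSE); chg <- c(chg, 0L)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        elems <- c(elems, toupper(ch)); arom <- c(arom, TRUE); chg <- c(chg, 0L)
        i <- i + 1L
      } else if (ch == "*") {
        elems <- c(elems, "*"); arom <- c(arom, FALSE); chg <- c(chg, 0L)
        i <- i + 1L
      } else {
        stop("unexpected character in SMILES: '", ch, "' in ", smi)
      }
    }
  }
  data.frame(elem = elems, aromatic = arom, charge = chg,
             stringsAsFactors = FALSE)
}

#' Count heavy atoms in a SMILES string
#'
#' @param smiles Character vector of SMILES.
#' @return Integer vector of heavy-atom counts (dummy `*` atoms excluded).
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    a <- smiles_atom_seq(s)
    sum(a$elem != "H" & a$elem != "*")
  }, integer(1), USE.NAMES = FALSE)
}

# Elements present in each SMILES (from the atom token scan).
smiles_elements <- function(smi) {
  unique(smiles_atom_seq(smi)$elem)
}

# Remove stereochemistry annotations from SMILES text and re-canonicalize.
strip_stereo_smiles <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("/", "-", s, fixed = TRUE)
  s <- gsub("\\", "-", s, fixed = TRUE)
  canonical_smiles(s)
}

# Molecular graph: atoms (element, aromatic, charge), bonds (a1, a2, order),
# ring membership per bond (a bond is in a ring iff it is not a bridge).
# Built from the SDF OpenBabel generates for the given SMILES; the SMILES
# atom-token order matches the SDF atom order.
mol_graph <- function(smiles) {
  sdf <- ob_quiet(ChemmineR::smiles2sdf(smiles))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  atoms <- smiles_atom_seq(smiles)
  n_at <- nrow(ab)
  if (nrow(atoms) != n_at) {
    stop("atom count mismatch between SMILES scan and SDF for: ", smiles)
  }
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  nb <- vector("list", n_at)
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$a1[k]]] <- c(nb[[bonds$a1[k]]], k)
    nb[[bonds$a2[k]]] <- c(nb[[bonds$a2[k]]], k)
  }
  ring_bond <- bond_in_ring(n_at, bonds)
  ring_atom <- rep(FALSE, n_at)
  if (any(ring_bond)) {
    ring_atom[unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))] <- TRUE
  }
  list(smiles = smiles, atoms = atoms, bonds = bonds, nb = nb,
       ring_bond = ring_bond, ring_atom = ring_atom)
}

# Bridge detection (iterative DFS with low-links): a bond lies in a cycle
# iff it is not a bridge.
bond_in_ring <- function(n_at, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n_at)
  for (k in seq_len(m)) {
    adj[[bonds$a1[k]]] <- rbind(adj[[bonds$a1[k]]], c(bonds$a2[k], k))
    adj[[bonds$a2[k]]] <- rbind(adj[[bonds$a2[k]]], c(bonds$a1[k], k))
  }
  disc <- integer(n_at); low <- integer(n_at)
  is_bridge <- rep(FALSE, m)
  timer <- 0L
  for (root in seq_len(n_at)) {
    if (disc[root] != 0L) next
    # stack rows: node, parent-edge, next-neighbour-pointer
    stack <- list(c(root, 0L, 1L))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top[1]; pe <- top[2]; ptr <- top[3]
      if (ptr == 1L) {
        timer <- timer + 1L
        disc[v] <- timer; low[v] <- timer
      }
      nbrs <- adj[[v]]
      advanced <- FALSE
      while (ptr <= NROW(nbrs)) {
        u <- nbrs[ptr, 1]; e <- nbrs[ptr, 2]
        ptr <- ptr + 1L
        if (e == pe) next
        if (disc[u] == 0L) {
          stack[[length(stack)]] <- c(v, pe, ptr)
          stack[[length(stack) + 1L]] <- c(u, e, 1L)
          advanced <- TRUE
          break
        } else {
          low[v] <- min(low[v], disc[u])
        }
      }
      if (!advanced) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          par <- stack[[length(stack)]][1]
          low[par] <- min(low[par], low[v])
          if (low[v] > disc[par]) is_bridge[pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# Connected components over a subset of atoms given a bond mask.
graph_components <- function(n_at, bonds, bond_mask, atom_mask = rep(TRUE, n_at)) {
  comp <- integer(n_at)
  adj <- vector("list", n_at)
  for (k in which(bond_mask)) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    if (atom_mask[a] && atom_mask[b]) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  cid <- 0L
  for (v in which(atom_mask)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      for (u in adj[[x]]) if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  comp
}

# Serialize a subgraph (optionally with dummy atoms replacing severed
# neighbours) as an SDF V2000 block and return its canonical SMILES.
# `keep`: integer atom indices to retain. `cut`: integer bond indices whose
# severed ends (relative to `keep`) each get a `*` dummy neighbour.
subgraph_smiles <- function(g, keep, cut = integer(0)) {
  keep <- sort(unique(keep))
  remap <- integer(nrow(g$atoms))
  remap[keep] <- seq_along(keep)
  elems <- g$atoms$elem[keep]
  chgs <- g$atoms$charge[keep]
  b_keep <- which(g$bonds$a1 %in% keep & g$bonds$a2 %in% keep &
                    !(seq_len(nrow(g$bonds)) %in% cut))
  bl <- data.frame(a1 = remap[g$bonds$a1[b_keep]],
                   a2 = remap[g$bonds$a2[b_keep]],
                   order = g$bonds$order[b_keep])
  # dummy atoms at cut positions
  for (k in cut) {
    ends <- c(g$bonds$a1[k], g$bonds$a2[k])
    inside <- ends[ends %in% keep]
    for (a in inside) {
      elems <- c(elems, "*"); chgs <- c(chgs, 0L)
      bl <- rbind(bl, data.frame(a1 = remap[a], a2 = length(elems),
                                 order = g$bonds$order[k]))
    }
  }
  sdf_to_canonical(elems, chgs, bl)
}

sdf_to_canonical <- function(elems, charges, bonds) {
  n_at <- length(elems)
  n_bd <- nrow(bonds)
  hdr <- sprintf("frag\n libprof\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 n_at, n_bd)
  at <- vapply(seq_len(n_at), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, elems[i])
  }, "")
  bd <- if (n_bd) vapply(seq_len(n_bd), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1[k], bonds$a2[k], bonds$order[k])
  }, "") else character(0)
  chg_lines <- character(0)
  ich <- which(charges != 0L)
  if (length(ich)) {
    chg_lines <- vapply(ich, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, charges[i])
    }, "")
  }
  block <- paste(c(hdr, at, bd, chg_lines, "M  END", "$$$$", ""), collapse = "\n")
  res <- ob_convert(block, "SDF", "CAN")
  out <- strsplit(res, "\n", fixed = TRUE)[[1]][1]
  out <- trimws(strsplit(out %||% "", "\t", fixed = TRUE)[[1]][1])
  if (!length(out) || is.na(out) || !nzchar(out)) {
    stop("subgraph serialization failed")
  }
  out
}

# Batch molecular properties from OpenBabel (MW, logP, TPSA, HBD, HBA...).
# Single-heavy-atom molecules crash the SDF route; their few properties are
# filled from a small element table instead.
ob_properties <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  n_heavy <- heavy_atom_count(smiles)
  multi <- n_heavy > 1L
  out <- data.frame(title = paste0("m", seq_along(smiles)),
                    MW = NA_real_, logP = NA_real_, TPSA = NA_real_,
                    HBD = NA_real_, HBA1 = NA_real_, HBA2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(multi)) {
    nm <- out$title[multi]
    sdf <- ob_quiet(ChemmineR::smiles2sdf(stats::setNames(smiles[multi], nm)))
    props <- ob_quiet(ChemmineR::propOB(sdf))
    idx <- match(nm, props$title)
    for (col in c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2")) {
      out[[col]][multi] <- props[[col]][idx]
    }
  }
  if (any(!multi)) {
    for (i in which(!multi)) {
      a <- smiles_atom_seq(smiles[i])
      a <- a[a$elem != "*", , drop = FALSE]
      if (nrow(a) == 1L) {
        sa <- single_atom_props(a$elem)
        out$MW[i] <- sa["mw"]; out$logP[i] <- 0
        out$TPSA[i] <- sa["tpsa"]; out$HBD[i] <- sa["hbd"]
        out$HBA1[i] <- sa["hba"]; out$HBA2[i] <- sa["hba"]
      }
    }
  }
  out
}

# Hydrogen-capped single-atom species (H2O, NH3, HCl, CH4, ...).
single_atom_props <- function(elem) {
  tab <- list(
    C  = c(mw = 16.043, tpsa = 0,     hbd = 0, hba = 0),
    N  = c(mw = 17.031, tpsa = 26.02, hbd = 1, hba = 1),
    O  = c(mw = 18.015, tpsa = 20.23, hbd = 1, hba = 1),
    S  = c(mw = 34.081, tpsa = 38.80, hbd = 1, hba = 0),
    F  = c(mw = 20.006, tpsa = 0,     hbd = 0, hba = 0),
    Cl = c(mw = 36.461, tpsa = 0,     hbd = 0, hba = 0),
    Br = c(mw = 80.912, tpsa = 0,     hbd = 0, hba = 0),
    I  = c(mw = 127.912, tpsa = 0,    hbd = 0, hba = 0)
  )
  tab[[elem]] %||% c(mw = NA_real_, tpsa = NA_real_, hbd = NA_real_,
                     hba = NA_real_)
}

# Convert a SMILES vector to a named SDFset once; downstream SMARTS and
# ring queries reuse it instead of re-parsing per query.
as_sdfset <- function(smiles) {
  if (methods::is(smiles, "SDFset")) return(smiles)
  nm <- paste0("m", seq_along(smiles))
  ob_quiet(ChemmineR::smiles2sdf(stats::setNames(smiles, nm)))
}

# SMARTS match counts over a vector of SMILES (or a prepared SDFset).
smarts_count <- function(smiles, smarts) {
  sdf <- as_sdfset(smiles)
  nm <- ChemmineR::sdfid(sdf)
  res <- ob_quiet(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE))
  as.integer(res[match(nm, names(res))])
}

# Aromatic SSSR-like ring count (rings up to size 8), used by QED's AROM
# term and the synthetic-accessibility penalties. Accepts a single SMILES
# or one molecule of an SDFset.
ring_info <- function(smiles) {
  mol <- if (methods::is(smiles, "SDF")) smiles else as_sdfset(smiles)[[1]]
  r <- ob_quiet(ChemmineR::rings(mol, upper = 8, type = "all", arom = TRUE))
  rings <- r$RINGS
  arom <- r$AROMATIC
  sizes <- vapply(rings, length, integer(1))
  atom_ids <- lapply(rings, function(x) as.integer(sub("^.*_", "", x)))
  list(n_rings = length(rings),
       n_aromatic = sum(arom),
       sizes = sizes,
       atoms = atom_ids)
}
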