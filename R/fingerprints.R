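# Binary structural fingerprints and Tanimoto similarity. MACCS keys come
# out of OpenBabel with the standard 166-key numbering; circular (ECFP4,
# radius 2) fingerprints are OpenBabel's 4096-bit implementation folded to
# the requested width; FP2 is OpenBabel's linear-path fingerprint (1024
# bits), the path-based member of the fingerprint menu.

FP_KINDS <- c("MACCS166", "ECFP4_1024", "ECFP4_2048", "FP2_1024")

#' Compute a fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of curated SMILES.
#' @param kind One of `"MACCS166"`, `"ECFP4_1024"`, `"ECFP4_2048"`,
#'   `"FP2_1024"`.
#' @return A logical 0/1 matrix with one row per molecule.
#' @export
fp_matrix <- function(smiles, kind = FP_KINDS) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) >= 1L)
  # the circular-fingerprint hash is sensitive to atom input order, so all
  # fingerprints are computed from the canonical atom order
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("fingerprinting failed; unparseable SMILES at positions: ",
         paste(which(is.na(can)), collapse = ", "))
  }
  smiles <- can
  nm <- paste0("m", seq_along(smiles))
  sdf <- tryCatch(
    ob_quiet(ChemmineR::smiles2sdf(stats::setNames(smiles, nm))),
    error = function(e) stop("fingerprinting failed; are all SMILES curated? (",
                             conditionMessage(e), ")")
  )
  ob_name <- switch(kind, MACCS166 = "MACCS", FP2_1024 = "FP2", "ECFP4")
  m <- methods::slot(ob_quiet(ChemmineR::fingerprintOB(sdf, ob_name)), "fpma")
  m <- m[match(nm, rownames(m)), , drop = FALSE]
  out <- switch(kind,
                MACCS166 = m[, 1:166, drop = FALSE],
                FP2_1024 = m,
                ECFP4_1024 = fold_fp(m, 1024L),
                ECFP4_2048 = fold_fp(m, 2048L))
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

# OR-fold a wide fingerprint matrix down to nbits columns.
fold_fp <- function(m, nbits) {
  stopifnot(ncol(m) %% nbits == 0L)
  k <- ncol(m) / nbits
  out <- matrix(0L, nrow(m), nbits)
  for (j in seq_len(k)) {
    out <- pmax(out, m[, ((j - 1L) * nbits + 1L):(j * nbits), drop = FALSE])
  }
  out
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are all-zero.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# All-pairs Tanimoto similarity between the rows of A and the rows of B,
# by matrix algebra (never loops over pairs). Both-empty pairs -> 1.
tanimoto_cross <- function(A, B) {
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  s
}
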