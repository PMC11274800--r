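# Bemis-Murcko chemotypes and scaffold-diversity statistics: per-dataset
# chemotype counts, cyclic-system-retrieval (CSR) curves, trapezoidal AUC,
# F50 and scaled Shannon entropy (SSE) over the most frequent chemotypes.

#' Bemis-Murcko scaffold of a molecule
#'
#' Retains ring systems plus the linkers connecting them (and atoms attached
#' to the scaffold by double or triple bonds); side chains are removed.
#' Ring-free molecules map to the `"ACYCLIC"` chemotype.
#'
#' @param smiles Character vector of curated SMILES.
#' @return Character vector of canonical chemotype SMILES (or `"ACYCLIC"`).
#' @export
bm_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    g <- mol_graph(s)
    if (!any(g$ring_atom)) return("ACYCLIC")
    n_at <- nrow(g$atoms)
    keep <- rep(TRUE, n_at)
    repeat {
      deg <- integer(n_at)
      for (k in seq_len(nrow(g$bonds))) {
        a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
        if (keep[a] && keep[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
      }
      drop <- keep & !g$ring_atom & deg <= 1L
      if (!any(drop)) break
      keep[drop] <- FALSE
    }
    # exocyclic multiple bonds to the retained frame stay (e.g. carbonyl
    # linkers)
    repeat {
      add <- FALSE
      for (k in seq_len(nrow(g$bonds))) {
        if (g$bonds$order[k] >= 2L) {
          a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
          if (keep[a] && !keep[b]) { keep[b] <- TRUE; add <- TRUE }
          if (keep[b] && !keep[a]) { keep[a] <- TRUE; add <- TRUE }
        }
      }
      if (!add) break
    }
    subgraph_smiles(g, which(keep))
  }, "", USE.NAMES = FALSE)
}

#' Scaffold-diversity profile of a library
#'
#' Computes the chemotype count table and the derived diversity statistics:
#' number of molecules M, number of chemotypes N, N/M, the
#' cyclic-system-retrieval curve (fraction of molecules recovered vs
#' fraction of chemotypes, most frequent first), its trapezoidal AUC, F50
#' (smallest chemotype fraction recovering half of the molecules), the
#' scaled Shannon entropy over the `sse_top_n` most frequent chemotypes
#' (counts renormalized among themselves; scaled by `log(n)`, or `log(N)`
#' when fewer chemotypes exist), and the acyclic fraction.
#'
#' @param data A data frame of molecules, or a character vector of SMILES.
#' @param smiles Name of the SMILES column (default `canonical_smiles`,
#'   falling back to `smiles`).
#' @param sse_top_n Number of most frequent chemotypes entering the SSE.
#' @param include_acyclic Treat ring-free molecules as one `"ACYCLIC"`
#'   chemotype inside the counts (default) rather than excluding them.
#' @param chemotypes Optional precomputed chemotype vector (skips scaffold
#'   perception; used by the generators and for testing).
#' @return An object of class `libprof_scaffold_profile`.
#' @export
scaffold_profile <- function(data, smiles = NULL, sse_top_n = 10,
                             include_acyclic = TRUE, chemotypes = NULL) {
  if (is.null(chemotypes)) {
    smi <- extract_smiles(data, smiles)
    if (!length(smi)) stop("scaffold_profile() needs at least one molecule")
    chemotypes <- bm_scaffold(smi)
  }
  if (!length(chemotypes)) stop("scaffold_profile() needs at least one molecule")
  m_total <- length(chemotypes)
  acyclic_fraction <- mean(chemotypes == "ACYCLIC")
  if (!include_acyclic) {
    chemotypes <- chemotypes[chemotypes != "ACYCLIC"]
    if (!length(chemotypes)) stop("no cyclic molecules in dataset")
  }
  tb <- table(chemotypes)
  counts <- tibble::tibble(chemotype = names(tb), n = as.integer(tb))
  counts <- counts[order(-counts$n, counts$chemotype), , drop = FALSE]
  M <- sum(counts$n); N <- nrow(counts)
  cum <- cumsum(counts$n)
  csr <- tibble::tibble(chemotype_fraction = c(0, seq_len(N) / N),
                        molecule_fraction = c(0, cum / M))
  auc <- sum(diff(csr$chemotype_fraction) *
               (utils::head(csr$molecule_fraction, -1) +
                  utils::tail(csr$molecule_fraction, -1)) / 2)
  f50 <- min(which(cum / M >= 0.5)) / N
  structure(list(counts = counts, M = M, N = N, nm_ratio = N / M,
                 csr = csr, auc = auc, f50 = f50,
                 sse = scaled_shannon_entropy(counts$n, sse_top_n),
                 sse_top_n = sse_top_n,
                 acyclic_fraction = acyclic_fraction,
                 include_acyclic = include_acyclic),
            class = "libprof_scaffold_profile")
}

#' Scaled Shannon entropy of chemotype counts
#'
#' Entropy of the `top_n` largest counts, renormalized among themselves and
#' scaled by its maximum (`log(n)`, using `n = min(top_n, length(counts))`).
#' Equals 1 when the top counts are all equal (maximum diversity) and 0 when
#' a single chemotype holds everything.
#'
#' @param counts Integer vector of chemotype counts (any order).
#' @param top_n How many of the most frequent chemotypes to use.
#' @return Value in `[0, 1]`.
#' @export
scaled_shannon_entropy <- function(counts, top_n = 10) {
  counts <- sort(counts[counts > 0], decreasing = TRUE)
  n <- min(top_n, length(counts))
  if (n <= 1L) return(0)
  top <- counts[seq_len(n)]
  # the analytic limits are exact, not floating-point approximations
  if (length(unique(top)) == 1L) return(1)
  p <- top / sum(top)
  -sum(p * log(p)) / log(n)
}

#' Compare the chemotype sets of two libraries
#'
#' Exact set algebra on chemotype SMILES; the `"ACYCLIC"` pseudo-chemotype
#' is excluded.
#'
#' @param profile_a,profile_b Objects from [scaffold_profile()].
#' @return A list with `shared`, `unique_a`, `unique_b` character vectors.
#' @export
scaffold_overlap <- function(profile_a, profile_b) {
  a <- setdiff(profile_a$counts$chemotype, "ACYCLIC")
  b <- setdiff(profile_b$counts$chemotype, "ACYCLIC")
  list(shared = intersect(a, b),
       unique_a = setdiff(a, b),
       unique_b = setdiff(b, a))
}

#' @export
print.libprof_scaffold_profile <- function(x, ...) {
  cat("Scaffold profile:", x$M, "molecules,", x$N, "chemotypes\n")
  cat(sprintf("  N/M %.3f | AUC %.3f | F50 %.3f | SSE%d %.3f | acyclic %.1f%%\n",
              x$nm_ratio, x$auc, x$f50, x$sse_top_n, x$sse,
              100 * x$acyclic_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy libprof_scaffold_profile
#' @export
tidy.libprof_scaffold_profile <- function(x, ...) x$counts

#' @method glance libprof_scaffold_profile
#' @export
glance.libprof_scaffold_profile <- function(x, ...) {
  tibble::tibble(M = x$M, N = x$N, nm_ratio = x$nm_ratio, auc = x$auc,
                 f50 = x$f50, sse = x$sse, sse_top_n = x$sse_top_n,
                 acyclic_fraction = x$acyclic_fraction)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cyclic-system-retrieval curve
#'
#' @param object A `libprof_scaffold_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot libprof_scaffold_profile
#' @export
autoplot.libprof_scaffold_profile <- function(object, ...) {
  ggplot2::ggplot(object$csr,
                  ggplot2::aes(.data$chemotype_fraction,
                               .data$molecule_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "Fraction of chemotypes",
                  y = "Fraction of molecules",
                  title = sprintf("CSR curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

# Pull a SMILES vector out of a data frame (or pass a character vector
# through). Prefers canonical_smiles, falls back to smiles.
extract_smiles <- function(data, smiles = NULL) {
  if (is.character(data)) return(data)
  col <- smiles %||%
    (if ("canonical_smiles" %in% names(data)) "canonical_smiles" else "smiles")
  if (!col %in% names(data)) stop("no SMILES column '", col, "' in data")
  out <- data[[col]]
  if ("status" %in% names(data)) out <- out[data$status == "CURATED"]
  out[!is.na(out) & nzchar(out)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
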