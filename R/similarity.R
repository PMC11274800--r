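# Pairwise fingerprint similarity statistics. Computation streams over row
# blocks of the fingerprint matrix, so the full M x M similarity matrix is
# never materialized; only the off-diagonal values (upper triangle) are
# accumulated.

#' Pairwise similarity statistics of a library
#'
#' Tanimoto similarity over all M(M-1)/2 off-diagonal pairs for the chosen
#' fingerprint, summarized as median, mean and an empirical CDF.
#'
#' @param data Data frame with a SMILES column, or character vector.
#' @param fingerprint Fingerprint kind (see [fp_matrix()]).
#' @param smiles SMILES column override.
#' @param block Row-block size for the streaming computation.
#' @return A `libprof_simstats` object with fields `fingerprint`, `n`,
#'   `median`, `mean`, `cdf` (tibble of `similarity`,
#'   `cumulative_fraction`).
#' @export
pairwise_similarity_stats <- function(data, fingerprint = "MACCS166",
                                      smiles = NULL, block = 256L) {
  smi <- extract_smiles(data, smiles)
  n <- length(smi)
  if (n < 2L) stop("need at least two molecules")
  fps <- fp_matrix(smi, fingerprint)
  n_pairs <- n * (n - 1) / 2
  vals <- numeric(n_pairs)
  pos <- 0L
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    if (e >= n && s == n) break
    sim_block <- tanimoto_cross(fps[s:e, , drop = FALSE], fps)
    for (i in s:e) {
      if (i < n) {
        v <- sim_block[i - s + 1L, (i + 1L):n]
        vals[(pos + 1L):(pos + length(v))] <- v
        pos <- pos + length(v)
      }
    }
  }
  stopifnot(pos == n_pairs)
  cdf_x <- sort(unique(c(round(vals, 6), max(vals))))
  if (length(cdf_x) > 512L) {
    cdf_x <- stats::quantile(vals, probs = seq(0, 1, length.out = 512),
                             names = FALSE)
    cdf_x <- sort(unique(c(cdf_x, max(vals))))
  }
  cdf <- tibble::tibble(
    similarity = cdf_x,
    cumulative_fraction = vapply(cdf_x, function(x) mean(vals <= x), 0))
  structure(list(fingerprint = fingerprint, n = n,
                 median = stats::median(vals), mean = mean(vals), cdf = cdf),
            class = "libprof_simstats")
}

#' @export
print.libprof_simstats <- function(x, ...) {
  cat(sprintf("Pairwise %s/Tanimoto over %d molecules: median %.3f, mean %.3f\n",
              x$fingerprint, x$n, x$median, x$mean))
  invisible(x)
}

#' @method glance libprof_simstats
#' @export
glance.libprof_simstats <- function(x, ...) {
  tibble::tibble(fingerprint = x$fingerprint, n = x$n, median = x$median,
                 mean = x$mean)
}

#' @method autoplot libprof_simstats
#' @export
autoplot.libprof_simstats <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(.data$similarity, .data$cumulative_fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("%s/Tanimoto similarity", object$fingerprint),
                  y = "Cumulative fraction",
                  title = sprintf("median = %.3f", object$median)) +
    ggplot2::theme_minimal()
}

#' Median pairwise Euclidean distance in property space
#'
#' Computes the six standard properties (MW, HBD, HBA, TPSA, nRotB, logP),
#' scales them (z-score by default, optionally over a pooled reference set
#' so multiple datasets share one scale), and summarizes the pairwise
#' Euclidean distances by their median.
#'
#' @param data Data frame with a SMILES column, or character vector.
#' @param scaling `"zscore"` or `"minmax"`.
#' @param smiles SMILES column override.
#' @param scale_ref Optional data frame of pooled property values (columns
#'   `mw`, `hbd`, `hba`, `tpsa`, `nrotb`, `logp`) from which the scaling
#'   parameters are taken.
#' @return Median pairwise distance (a single number) with the scaled
#'   property table as attribute `properties`.
#' @export
property_distance <- function(data, scaling = c("zscore", "minmax"),
                              smiles = NULL, scale_ref = NULL) {
  scaling <- match.arg(scaling)
  smi <- extract_smiles(data, smiles)
  if (length(smi) < 2L) stop("need at least two molecules")
  pr <- property6_table(smi)
  ref <- scale_ref %||% pr
  x <- as.matrix(pr)
  r <- as.matrix(ref[, colnames(x)])
  if (scaling == "zscore") {
    ctr <- colMeans(r); scl <- apply(r, 2, stats::sd)
  } else {
    ctr <- apply(r, 2, min); scl <- apply(r, 2, max) - ctr
  }
  scl[scl == 0 | is.na(scl)] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  d <- stats::dist(z)
  out <- stats::median(d)
  attr(out, "properties") <- tibble::as_tibble(as.data.frame(z))
  out
}

# The six pharmaceutical properties used for property-space analyses.
property6_table <- function(smiles) {
  props <- ob_properties(smiles)
  nrotb <- smarts_count(as_sdfset(smiles), ROTB_SMARTS)
  tibble::tibble(mw = props$MW, hbd = as.numeric(props$HBD),
                 hba = as.numeric(props$HBA2), tpsa = props$TPSA,
                 nrotb = as.numeric(nrotb), logp = props$logP)
}

#' Consensus-diversity-plot data for a set of libraries
#'
#' One point per dataset: x = median MACCS keys/Tanimoto similarity
#' (higher = less diverse), y = scaffold-recovery AUC (higher = less
#' diverse), point color = median property-space distance (scaled over the
#' pooled datasets), point size = dataset size.
#'
#' @param datasets Named list of data frames (or character vectors of
#'   SMILES); names are the dataset codes.
#' @param sse_top_n Passed to [scaffold_profile()].
#' @return A tibble of CDPlot points (one row per dataset) with attribute
#'   `profiles` (the scaffold profiles).
#' @export
cdplot_data <- function(datasets, sse_top_n = 10) {
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  smi <- lapply(datasets, extract_smiles)
  pooled <- property6_table(unlist(smi, use.names = FALSE))
  profiles <- list()
  rows <- lapply(names(datasets), function(code) {
    s <- smi[[code]]
    stats_m <- pairwise_similarity_stats(s, "MACCS166")
    prof <- scaffold_profile(s, sse_top_n = sse_top_n)
    profiles[[code]] <<- prof
    pd <- property_distance(s, scale_ref = pooled)
    tibble::tibble(dataset_code = code, x = stats_m$median, y = prof$auc,
                   color_value = as.numeric(pd), size_value = length(s))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "profiles") <- profiles
  class(out) <- c("libprof_cdplot", class(out))
  out
}

#' Plot a consensus diversity plot
#'
#' @param object Output of [cdplot_data()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot libprof_cdplot
#' @export
autoplot.libprof_cdplot <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$x, .data$y, colour = .data$color_value,
                               size = .data$size_value,
                               label = .data$dataset_code)) +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::geom_text(vjust = -1.2, size = 3, colour = "black") +
    ggplot2::scale_colour_gradient(low = "#1a9850", high = "#d73027",
                                   name = "Property\ndistance") +
    ggplot2::scale_size_continuous(name = "Size") +
    ggplot2::labs(x = "Median MACCS/Tanimoto similarity",
                  y = "Scaffold CSR AUC") +
    ggplot2::theme_minimal()
}
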