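# 2D chemical-space embeddings: PCA (deterministic) and exact t-SNE
# (deterministic given a seed) over property vectors or fingerprints.

#' Embed libraries into a 2D chemical space
#'
#' @param datasets Named list of data frames or SMILES vectors (dataset
#'   code -> molecules), or a single data frame/vector.
#' @param representation `"PROPERTIES6"` (six z-scored properties),
#'   `"MACCS166"` or `"ECFP4_1024"`.
#' @param method `"PCA"` or `"TSNE"`.
#' @param seed Integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity; clamped to `(n - 1) / 3`.
#' @param max_iter t-SNE gradient-descent iterations.
#' @return A tibble `id`, `dataset_code`, `dim1`, `dim2`; for PCA the
#'   explained-variance fractions are attached as attribute
#'   `explained_variance`.
#' @export
embed_chemspace <- function(datasets,
                            representation = c("PROPERTIES6", "MACCS166",
                                               "ECFP4_1024"),
                            method = c("PCA", "TSNE"), seed = 1L,
                            perplexity = 30, max_iter = 500) {
  representation <- match.arg(representation)
  method <- match.arg(method)
  if (!is.list(datasets) || is.data.frame(datasets)) {
    datasets <- list(all = datasets)
  }
  smi <- lapply(datasets, extract_smiles)
  code <- rep(names(smi), lengths(smi))
  all_smi <- unlist(smi, use.names = FALSE)
  ids <- unlist(lapply(datasets, function(d) {
    if (is.data.frame(d) && "id" %in% names(d)) {
      s <- extract_smiles(d)
      d$id[match(s, if ("canonical_smiles" %in% names(d)) d$canonical_smiles else d$smiles)]
    } else NULL
  }), use.names = FALSE)
  if (length(ids) != length(all_smi)) ids <- ordinal_ids(length(all_smi), "EMB")
  if (length(all_smi) < 3L) stop("need at least three molecules to embed")

  x <- if (representation == "PROPERTIES6") {
    p <- as.matrix(property6_table(all_smi))
    scl <- apply(p, 2, stats::sd)
    if (all(scl == 0 | is.na(scl))) stop("zero-variance input; cannot embed")
    scl[scl == 0 | is.na(scl)] <- 1
    sweep(sweep(p, 2, colMeans(p)), 2, scl, "/")
  } else {
    fp_matrix(all_smi, representation) * 1.0
  }

  if (method == "PCA") {
    keep <- apply(x, 2, stats::sd) > 0
    if (!any(keep)) stop("zero-variance input; cannot embed")
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    y <- pc$x[, 1:k, drop = FALSE]
    if (k == 1L) y <- cbind(y, 0)
    ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:k]
  } else {
    y <- tsne_exact(x, seed = seed, perplexity = perplexity,
                    max_iter = max_iter)
    ev <- NULL
  }
  out <- tibble::tibble(id = ids, dataset_code = code,
                        dim1 = y[, 1], dim2 = y[, 2])
  attr(out, "method") <- method
  attr(out, "representation") <- representation
  if (!is.null(ev)) attr(out, "explained_variance") <- ev
  class(out) <- c("libprof_embedding", class(out))
  out
}

#' Plot a chemical-space embedding
#'
#' @param object Output of [embed_chemspace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot libprof_embedding
#' @export
autoplot.libprof_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2,
                                       colour = .data$dataset_code)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  colour = "Dataset",
                  title = sprintf("%s on %s", attr(object, "method"),
                                  attr(object, "representation"))) +
    ggplot2::theme_minimal()
}

# Exact t-SNE (no tree approximation): suitable for the desk-scale sets
# this package embeds. Symmetric SNE affinities from a per-point binary
# search on perplexity; gradient descent with momentum and early
# exaggeration; deterministic given the seed.
tsne_exact <- function(x, seed = 1L, perplexity = 30, max_iter = 500,
                       eta = 200, momentum = c(0.5, 0.8),
                       exaggeration = 12, exaggerate_until = 100L) {
  n <- nrow(x)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(h - log_u) < 1e-5) break
      if (h > log_u) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    p[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (n - 1)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  y <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  for (iter in seq_len(max_iter)) {
    pe <- if (iter <= exaggerate_until) p * exaggeration else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    stiff <- 4 * (pe - q) * num
    grad <- matrix(0, n, 2)
    rs <- rowSums(stiff)
    grad[, 1] <- rs * y[, 1] - stiff %*% y[, 1]
    grad[, 2] <- rs * y[, 2] - stiff %*% y[, 2]
    mom <- if (iter <= 250) momentum[1] else momentum[2]
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
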