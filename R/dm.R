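# Distance-to-model (DM) confidence: mean Jaccard distance of a query to
# the training compounds, quartile binning of evaluation records, and
# prediction with confidence bins (Q1..Q4, BEYOND).

#' Mean Jaccard distance to a training set
#'
#' For each query fingerprint, the mean over training compounds of
#' `1 - Tanimoto`.
#'
#' @param query_fps,train_fps 0/1 fingerprint matrices (same width).
#' @return Numeric vector, one distance per query row.
#' @export
dm_distance <- function(query_fps, train_fps) {
  if (is.null(dim(query_fps))) query_fps <- matrix(query_fps, nrow = 1)
  if (nrow(train_fps) == 0L) stop("empty training set")
  if (ncol(query_fps) != ncol(train_fps)) stop("fingerprint width mismatch")
  sims <- tanimoto_cross(query_fps, train_fps)
  rowMeans(1 - sims)
}

# LOO variant: DM of each training compound to the others.
dm_distance_loo <- function(train_fps) {
  n <- nrow(train_fps)
  sims <- tanimoto_cross(train_fps, train_fps)
  (rowSums(1 - sims)) / (n - 1)
}

#' Distance-to-model quartile report
#'
#' Splits evaluation records into four equal-occupancy quartiles by their
#' DM value (stable input order breaks ties) and reports, per quartile,
#' active/inactive counts and precision/recall for the ACTIVE class.
#' Boundaries are the 25/50/75th percentiles of the DM values (or supplied
#' explicitly).
#'
#' @param eval_records Tibble with columns `truth`, `pred`
#'   (ACTIVE/INACTIVE) and `dm`.
#' @param boundaries Optional numeric vector of three cut points; computed
#'   from the data when omitted.
#' @return A `libprof_dm_report`: `boundaries`, `max_dm`, `rows` (tibble
#'   with quartile, n_active, n_inactive, precision, recall). Quartiles
#'   with no predicted actives report precision `NA`, never 0/0.
#' @export
dm_quartile_report <- function(eval_records, boundaries = NULL) {
  need <- c("truth", "pred", "dm")
  stopifnot(all(need %in% names(eval_records)))
  n <- nrow(eval_records)
  if (is.null(boundaries)) {
    if (n < 4L) stop("need at least 4 records to form quartiles")
    boundaries <- stats::quantile(eval_records$dm, c(0.25, 0.5, 0.75),
                                  names = FALSE)
  }
  stopifnot(length(boundaries) == 3L)
  # equal-occupancy assignment: rank by dm, stable in input order
  o <- order(eval_records$dm)
  q <- integer(n)
  q[o] <- ceiling(seq_len(n) / (n / 4))
  q[q > 4L] <- 4L
  rows <- lapply(1:4, function(qq) {
    r <- eval_records[q == qq, , drop = FALSE]
    cm <- confusion_metrics(r$truth, r$pred)
    tibble::tibble(quartile = paste0("Q", qq),
                   n_active = sum(r$truth == "ACTIVE"),
                   n_inactive = sum(r$truth == "INACTIVE"),
                   precision = cm$precision_active,
                   recall = cm$recall_active)
  })
  structure(list(boundaries = boundaries,
                 max_dm = max(eval_records$dm),
                 rows = dplyr::bind_rows(rows),
                 n = n),
            class = "libprof_dm_report")
}

#' @export
print.libprof_dm_report <- function(x, ...) {
  cat("Distance-to-model quartiles (boundaries:",
      paste(sprintf("%.3f", x$boundaries), collapse = ", "), ")\n")
  print(as.data.frame(x$rows), row.names = FALSE)
  invisible(x)
}

#' @method tidy libprof_dm_report
#' @export
tidy.libprof_dm_report <- function(x, ...) x$rows

#' Predict activity with distance-to-model confidence
#'
#' Retrains the winning model on the entire labeled dataset, predicts the
#' query molecules, and bins each prediction into the confidence quartile
#' of its mean Jaccard distance (circular fingerprints) to the training
#' compounds. Queries whose DM exceeds the largest DM seen in the
#' evaluation records are binned `BEYOND` (unknown confidence).
#'
#' @param spec A [model_spec()] (e.g. `attr(grid, "best_spec")`).
#' @param newdata Data frame with a SMILES column, or character vector.
#' @param train Full labeled dataset (rows with `kept == FALSE` ignored).
#' @param dm_report A [dm_quartile_report()] built from the training
#'   LOO evaluation; supplies the quartile boundaries and the BEYOND
#'   threshold. Computed from `train` + `spec` when omitted.
#' @param seed Integer seed.
#' @param smiles SMILES column override for `newdata`.
#' @return A tibble: `id`, `smiles`, `pred`, `dm`, `confidence_bin`
#'   (Q1..Q4, BEYOND).
#' @export
predict_with_confidence <- function(spec, newdata, train, dm_report = NULL,
                                    seed = 1L, smiles = NULL) {
  if ("kept" %in% names(train)) train <- train[train$kept, , drop = FALSE]
  smi <- extract_smiles(newdata, smiles)
  y <- factor(train$label, CLASS_LEVELS)
  X <- fp_matrix(train$canonical_smiles, spec$fingerprint) * 1.0
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  fit <- fit_backend(spec, X, y, seed = seed)
  Xq <- fp_matrix(smi, spec$fingerprint) * 1.0
  colnames(Xq) <- colnames(X)
  pred <- predict_backend(fit, Xq)
  # DM on circular fingerprints, as for the evaluation records
  fps_tr <- fp_matrix(train$canonical_smiles, "ECFP4_2048")
  fps_q <- fp_matrix(smi, "ECFP4_2048")
  dm <- dm_distance(fps_q, fps_tr)
  if (is.null(dm_report)) {
    ev <- loocv_balanced_accuracy(spec, train, seed = seed, X = X)
    dm_tr <- dm_distance_loo(fps_tr)
    dm_report <- dm_quartile_report(
      tibble::tibble(truth = ev$predictions$truth,
                     pred = ev$predictions$pred, dm = dm_tr))
  }
  b <- dm_report$boundaries
  bin <- cut(dm, breaks = c(-Inf, b, Inf),
             labels = c("Q1", "Q2", "Q3", "Q4"))
  bin <- as.character(bin)
  bin[dm > dm_report$max_dm] <- "BEYOND"
  ids <- if (is.data.frame(newdata) && "id" %in% names(newdata)) {
    newdata$id[seq_along(smi)]
  } else ordinal_ids(length(smi), "QRY")
  tibble::tibble(id = ids, smiles = smi, pred = as.character(pred),
                 dm = dm, confidence_bin = bin)
}
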