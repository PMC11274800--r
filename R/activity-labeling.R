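# IC50 activity labeling (threshold 10 uM) and stratified splitting.

UNIT_TO_UM <- c(nM = 1e-3, uM = 1, mM = 1e3)

#' Label an IC50 activity table
#'
#' Applies the threshold labeling rule at `threshold_um` (10 uM by
#' default): `=`, `<`, `<=` with value at or below the threshold are
#' ACTIVE; `=` above the threshold, and `>`, `>=` with value at or above
#' the threshold, are INACTIVE. Qualifier/value combinations that do not
#' pin the class (e.g. `< 100 uM`, `> 1 uM`) are AMBIGUOUS and removed
#' from the labeled set. Structures are canonicalized; duplicates with
#' conflicting labels are CONTRADICTORY and removed, duplicates with
#' concordant labels collapse to one record keeping the median value.
#'
#' @param data Tibble with columns `id`, `smiles`, `standard_value`,
#'   `standard_units` (`nM`, `uM`/`µM`, `mM`), `standard_relation`
#'   (`=`, `<`, `<=`, `>`, `>=`).
#' @param threshold_um Activity threshold in micromolar.
#' @return A tibble of all input records with `canonical_smiles`,
#'   `value_um`, `label` (`ACTIVE`, `INACTIVE`, `AMBIGUOUS`,
#'   `CONTRADICTORY`) and `kept` columns; summary counts in attribute
#'   `summary`. Only `kept` rows (one per structure) enter modeling.
#' @export
label_activity <- function(data, threshold_um = 10) {
  need <- c("id", "smiles", "standard_value", "standard_units",
            "standard_relation")
  if (!all(need %in% names(data))) {
    stop("activity table needs columns: ", paste(need, collapse = ", "))
  }
  units <- gsub("µ", "u", trimws(data$standard_units))
  bad_units <- !(units %in% names(UNIT_TO_UM))
  if (any(bad_units)) {
    stop("unknown unit(s) in rows: ",
         paste(which(bad_units), collapse = ", "),
         " (", paste(unique(units[bad_units]), collapse = ", "), ")")
  }
  value_um <- data$standard_value * UNIT_TO_UM[units]
  rel <- trimws(data$standard_relation)
  label <- dplyr::case_when(
    rel %in% c("=", "<", "<=") & value_um <= threshold_um ~ "ACTIVE",
    rel == "=" & value_um > threshold_um ~ "INACTIVE",
    rel %in% c(">", ">=") & value_um >= threshold_um ~ "INACTIVE",
    TRUE ~ "AMBIGUOUS"
  )
  out <- tibble::as_tibble(data)
  out$value_um <- value_um
  out$canonical_smiles <- canonical_smiles(out$smiles)
  out$label <- label
  out$label[is.na(out$canonical_smiles)] <- "AMBIGUOUS"
  # duplicate handling among the labeled records
  out$kept <- out$label %in% c("ACTIVE", "INACTIVE")
  lab <- out[out$kept, , drop = FALSE]
  if (nrow(lab)) {
    by_str <- split(seq_len(nrow(lab)), lab$canonical_smiles)
    drop_rows <- integer(0)
    contra_rows <- integer(0)
    for (rows in by_str) {
      if (length(rows) == 1L) next
      labs <- unique(lab$label[rows])
      if (length(labs) > 1L) {
        contra_rows <- c(contra_rows, rows)
      } else {
        # concordant: keep the record carrying the median value
        med <- stats::median(lab$value_um[rows])
        keep_one <- rows[which.min(abs(lab$value_um[rows] - med))]
        drop_rows <- c(drop_rows, setdiff(rows, keep_one))
      }
    }
    idx <- which(out$kept)
    if (length(contra_rows)) {
      out$label[idx[contra_rows]] <- "CONTRADICTORY"
      out$kept[idx[contra_rows]] <- FALSE
    }
    if (length(drop_rows)) out$kept[idx[drop_rows]] <- FALSE
  }
  attr(out, "summary") <- list(
    n_input = nrow(out),
    n_ambiguous = sum(out$label == "AMBIGUOUS"),
    n_contradictory = sum(out$label == "CONTRADICTORY"),
    n_duplicate_collapsed = sum(out$label %in% c("ACTIVE", "INACTIVE") & !out$kept),
    n_active = sum(out$label == "ACTIVE" & out$kept),
    n_inactive = sum(out$label == "INACTIVE" & out$kept)
  )
  out
}

#' Stratified train/test split
#'
#' Splits the kept records of a labeled activity table into train and test
#' sets preserving the class proportions to within rounding; deterministic
#' given the seed.
#'
#' @param data Labeled tibble (from [label_activity()]; rows with
#'   `kept == FALSE` are ignored) with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles.
#' @export
stratified_split <- function(data, train_fraction = 0.8, seed = 1L) {
  if ("kept" %in% names(data)) data <- data[data$kept, , drop = FALSE]
  stopifnot("label" %in% names(data))
  classes <- unique(data$label)
  if (length(classes) < 2L) stop("both classes must be present")
  if (any(table(data$label) < 2L)) stop("every class needs at least 2 members")
  withr::with_seed(as.integer(seed), {
    tr_idx <- integer(0)
    for (cl in classes) {
      rows <- which(data$label == cl)
      n_tr <- round(train_fraction * length(rows))
      tr_idx <- c(tr_idx, sample(rows, n_tr))
    }
    tr_idx <- sort(tr_idx)
    list(train = data[tr_idx, , drop = FALSE],
         test = data[-tr_idx, , drop = FALSE])
  })
}
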