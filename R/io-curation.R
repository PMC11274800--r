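# Library I/O and the standardization protocol. All user-facing functions
# take and return tibbles with at least columns id, source_smiles,
# canonical_smiles, status, rejection_reason.

ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

new_record_tbl <- function(id, source_smiles,
                           canonical_smiles = rep("", length(id)),
                           status = rep("RAW", length(id)),
                           rejection_reason = rep(NA_character_, length(id))) {
  tibble::tibble(id = as.character(id),
                 source_smiles = as.character(source_smiles),
                 canonical_smiles = canonical_smiles,
                 status = status,
                 rejection_reason = rejection_reason)
}

#' Read a chemical library
#'
#' Reads a library of molecules from a SMILES file (one molecule per line,
#' optional tab-separated identifier), an SDF (V2000) file, or a CSV table
#' with a SMILES column. Records are returned `RAW`; individually unreadable
#' entries become `REJECTED`/`PARSE_ERROR` rows rather than being dropped.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"smiles"`, `"sdf"`, `"csv"`. `"auto"`
#'   guesses from the file extension.
#' @param smiles_column,id_column Column names used for CSV input.
#' @return A tibble of molecule records (one row per entry).
#' @export
read_library <- function(path, format = c("auto", "smiles", "sdf", "csv"),
                         smiles_column = "smiles", id_column = "id") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", csv = "csv",
                     smi = "smiles", smiles = "smiles", txt = "smiles",
                     stop("cannot guess library format from extension: ", ext))
  }
  switch(format,
         smiles = read_library_smiles(path),
         sdf = read_library_sdf(path),
         csv = read_library_csv(path, smiles_column, id_column))
}

read_library_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(new_record_tbl(character(0), character(0)))
  parts <- strsplit(lines, "[\t ]+")
  smi <- vapply(parts, `[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  if (anyNA(ids)) ids[is.na(ids)] <- ordinal_ids(length(lines))[is.na(ids)]
  new_record_tbl(ids, smi)
}

read_library_csv <- function(path, smiles_column, id_column) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_column %in% names(tbl)) {
    stop("CSV has no column named '", smiles_column, "'")
  }
  ids <- if (id_column %in% names(tbl)) as.character(tbl[[id_column]]) else
    ordinal_ids(nrow(tbl))
  new_record_tbl(ids, tbl[[smiles_column]])
}

read_library_sdf <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (!length(blocks)) return(new_record_tbl(character(0), character(0)))
  smi <- character(length(blocks))
  ids <- character(length(blocks))
  for (i in seq_along(blocks)) {
    b <- sub("^\n+", "", blocks[i])
    title <- trimws(strsplit(b, "\n", fixed = TRUE)[[1]][1])
    ids[i] <- if (nzchar(title)) title else ordinal_ids(length(blocks))[i]
    res <- tryCatch(ob_convert(paste0(b, "\n$$$$\n"), "SDF", "CAN"),
                    error = function(e) "")
    res <- strsplit(res, "\n", fixed = TRUE)[[1]][1]
    res <- trimws(strsplit(res %||% "", "\t", fixed = TRUE)[[1]][1])
    smi[i] <- if (length(res) && !is.na(res) && nzchar(res)) res else NA_character_
  }
  out <- new_record_tbl(ids, ifelse(is.na(smi), "", smi))
  out$status[is.na(smi)] <- "REJECTED"
  out$rejection_reason[is.na(smi)] <- "PARSE_ERROR"
  out
}

ordinal_ids <- function(n, prefix = "MOL") {
  if (n == 0L) return(character(0))
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Curate a chemical library
#'
#' Applies the standardization protocol, in order: parse; keep the largest
#' fragment of multi-component structures (most heavy atoms, ties broken by
#' molecular weight then lexicographic canonical SMILES); reject molecules
#' containing elements outside H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I;
#' neutralize formal charges; canonicalize; strip stereochemistry (unless
#' `keep_stereo`); remove exact canonical-SMILES duplicates keeping the
#' first occurrence. The protocol is idempotent: curating a curated library
#' changes nothing and reports zero removals.
#'
#' Tautomers are not canonicalized: the underlying toolkit (OpenBabel) has
#' no tautomer enumerator, so tautomeric duplicates may survive. This is
#' recorded in the report metadata.
#'
#' @param records A tibble from [read_library()], or any data frame with
#'   `id` and `source_smiles` (or `smiles`) columns.
#' @param keep_stereo Keep stereochemistry annotations? Default `FALSE`.
#' @return A tibble of records with updated `canonical_smiles`, `status`
#'   and `rejection_reason`; the curation report is attached as attribute
#'   `"report"` (see [curation_report()]).
#' @export
curate_library <- function(records, keep_stereo = FALSE) {
  if (!"source_smiles" %in% names(records) && "smiles" %in% names(records)) {
    records$source_smiles <- records$smiles
  }
  if (!"id" %in% names(records)) records$id <- ordinal_ids(nrow(records))
  rec <- new_record_tbl(records$id, records$source_smiles)
  if ("status" %in% names(records)) rec$status <- records$status
  # records already rejected by an earlier pass are not molecules; they are
  # excluded up front so that curation is idempotent on its own output
  rec <- rec[rec$status != "REJECTED", , drop = FALSE]
  # a second pass starts from the canonical structure, not the raw input
  src <- rec$source_smiles
  if ("canonical_smiles" %in% names(records)) {
    prev <- records$canonical_smiles[match(rec$id, records$id)]
    use <- rec$status == "CURATED" & !is.na(prev) & nzchar(prev)
    src[use] <- prev[use]
  }
  rec$status <- "RAW"
  rec$canonical_smiles <- ""
  report <- list(n_input = nrow(rec), n_parse_failed = 0L,
                 n_multicomponent_reduced = 0L, n_element_rejected = 0L,
                 n_duplicates_removed = 0L, n_output = 0L,
                 tautomer_canonicalization = "none (toolkit has no tautomer enumerator)")
  if (nrow(rec) == 0L) {
    attr(rec, "report") <- structure(report, class = "libprof_curation_report")
    return(rec)
  }
  live <- rep(TRUE, nrow(rec))

  # 1. parse + standardize into canonical SMILES
  can <- canonical_smiles(src[live])
  failed <- is.na(can)
  idx_live <- which(live)
  rec$status[idx_live[failed]] <- "REJECTED"
  rec$rejection_reason[idx_live[failed]] <- "PARSE_ERROR"
  report$n_parse_failed <- report$n_parse_failed + sum(failed)
  live <- rec$status != "REJECTED"
  can <- can[!failed]

  if (any(live)) {
    # 2. largest fragment
    lf <- largest_fragment(can)
    report$n_multicomponent_reduced <- sum(lf != can)
    can <- lf

    # 3. element filter (after largest-fragment selection, so exotic
    # counterions do not reject the parent)
    bad_elem <- vapply(can, function(s) {
      !all(smiles_elements(s) %in% ALLOWED_ELEMENTS)
    }, logical(1), USE.NAMES = FALSE)
    idx_live <- which(live)
    rec$status[idx_live[bad_elem]] <- "REJECTED"
    rec$rejection_reason[idx_live[bad_elem]] <- "DISALLOWED_ELEMENT"
    report$n_element_rejected <- sum(bad_elem)
    live <- rec$status != "REJECTED"
    can <- can[!bad_elem]
  }

  if (any(live)) {
    # 4. neutralize + re-canonicalize
    can <- canonical_smiles(can, neutralize = TRUE)
    # 5. stereochemistry
    if (!keep_stereo) can <- strip_stereo_smiles(can)
    rec$canonical_smiles[live] <- can
    rec$status[live] <- "CURATED"

    # 6. duplicate removal (first occurrence kept, input order)
    dup <- duplicated(can)
    idx_live <- which(live)
    rec$status[idx_live[dup]] <- "REJECTED"
    rec$rejection_reason[idx_live[dup]] <- "DUPLICATE"
    rec$canonical_smiles[idx_live[dup]] <- ""
    report$n_duplicates_removed <- sum(dup)
  }
  report$n_output <- sum(rec$status == "CURATED")
  out <- rec[rec$status == "CURATED" | rec$status == "REJECTED", , drop = FALSE]
  attr(out, "report") <- structure(report, class = "libprof_curation_report")
  out
}

largest_fragment <- function(can) {
  vapply(can, function(s) {
    comps <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(comps) == 1L) return(s)
    ha <- heavy_atom_count(comps)
    cand <- comps[ha == max(ha)]
    if (length(cand) > 1L) {
      mw <- ob_properties(cand)$MW
      cand <- cand[mw == max(mw)]
      cand <- sort(cand)
    }
    cand[1]
  }, "", USE.NAMES = FALSE)
}

#' Curation report of a curated library
#'
#' @param records A tibble returned by [curate_library()].
#' @return A list with counts `n_input`, `n_parse_failed`,
#'   `n_multicomponent_reduced`, `n_element_rejected`,
#'   `n_duplicates_removed`, `n_output`. The identity
#'   `n_output == n_input - n_parse_failed - n_element_rejected -
#'   n_duplicates_removed` always holds.
#' @export
curation_report <- function(records) {
  rep <- attr(records, "report")
  if (is.null(rep)) stop("no curation report attached; run curate_library() first")
  rep
}

#' @export
print.libprof_curation_report <- function(x, ...) {
  cat("Curation report\n")
  for (f in c("n_input", "n_parse_failed", "n_multicomponent_reduced",
              "n_element_rejected", "n_duplicates_removed", "n_output")) {
    cat(sprintf("  %-26s %d\n", f, x[[f]]))
  }
  invisible(x)
}

#' Write a chemical library
#'
#' Writes curated records to a SMILES, SDF or CSV file. Reading the file
#' back with [read_library()] reproduces the canonical SMILES.
#'
#' @param records Tibble of curated records.
#' @param path Output path.
#' @param format `"smiles"`, `"sdf"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_library <- function(records, path, format = c("smiles", "sdf", "csv")) {
  format <- match.arg(format)
  keep <- records$status == "CURATED"
  smi <- records$canonical_smiles[keep]
  ids <- records$id[keep]
  if (format == "smiles") {
    writeLines(if (length(smi)) paste(smi, ids, sep = "\t") else character(0), path)
  } else if (format == "csv") {
    utils::write.csv(data.frame(id = ids, smiles = smi), path, row.names = FALSE)
  } else {
    if (!length(smi)) {
      writeLines(character(0), path)
    } else {
      sdf <- ob_quiet(ChemmineR::smiles2sdf(stats::setNames(smi, ids)))
      ChemmineR::write.SDF(sdf, file = path)
    }
  }
  invisible(path)
}
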