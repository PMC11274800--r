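# Range-based de novo scoring: each of seven descriptors contributes 1 if
# it falls inside its closed interval, the aggregate is the arithmetic mean
# of the seven contributions, and matching any penalty substructure
# multiplies the aggregate by (1 - penalty_value).

SCORE_DESCRIPTORS <- c("mw", "hbd", "hba", "logp", "esol", "sascore", "tpsa")

# Nucleoside-like substructure patterns (ribofuranose cores and
# glycosylated azapyrimidinone) used by the default penalty; configuration,
# not constants - override via score_rules().
NUCLEOSIDE_SMARTS <- c(
  "C1OC(CO)C(O)C1O",
  "C1OC(CO)CC1O",
  "n1ccnc(=O)[nH0]1C1CCCO1"
)

#' Construct de novo scoring rules
#'
#' @param ranges Named list of closed intervals `c(low, high)`; names must
#'   be descriptors of the profile table (`mw`, `hbd`, `hba`, `logp`,
#'   `esol`, `sascore`, `tpsa`).
#' @param penalty_patterns SMARTS patterns whose match triggers the
#'   penalty.
#' @param penalty_value Multiplicative penalty in `[0, 1]`; 1 (default)
#'   vetoes matching molecules outright.
#' @return A `libprof_score_rules` object.
#' @export
score_rules <- function(ranges, penalty_patterns = NUCLEOSIDE_SMARTS,
                        penalty_value = 1.0) {
  stopifnot(is.list(ranges), length(ranges) >= 1L)
  bad <- setdiff(names(ranges), SCORE_DESCRIPTORS)
  if (length(bad)) {
    stop("unknown descriptor(s) in ranges: ", paste(bad, collapse = ", "))
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) stop("invalid range for ", nm)
  }
  structure(list(ranges = ranges, penalty_patterns = penalty_patterns,
                 penalty_value = penalty_value, aggregation = "mean"),
            class = "libprof_score_rules")
}

#' Derive scoring ranges from an active set
#'
#' Sets each descriptor's closed interval to mean +/- one standard
#' deviation over the supplied profile of active compounds.
#'
#' @param profile A profile tibble from [profile_library()] of the active
#'   reference compounds.
#' @param descriptors Descriptors to include (default: all seven).
#' @param ... Passed to [score_rules()].
#' @return A `libprof_score_rules` object.
#' @export
derive_score_rules <- function(profile, descriptors = SCORE_DESCRIPTORS, ...) {
  ranges <- lapply(descriptors, function(d) {
    x <- profile[[d]]
    if (is.null(x)) stop("profile lacks descriptor: ", d)
    c(mean(x) - stats::sd(x), mean(x) + stats::sd(x))
  })
  names(ranges) <- descriptors
  score_rules(ranges, ...)
}

#' Read / write scoring rules as YAML
#'
#' @param path YAML file path.
#' @return For `read_score_rules()`, a `libprof_score_rules`; for
#'   `write_score_rules()`, the path invisibly.
#' @export
read_score_rules <- function(path) {
  y <- yaml::read_yaml(path)
  score_rules(lapply(y$ranges, as.numeric),
              penalty_patterns = as.character(y$penalty_patterns %||% character(0)),
              penalty_value = y$penalty_value %||% 1.0)
}

#' @param rules A `libprof_score_rules`.
#' @rdname read_score_rules
#' @export
write_score_rules <- function(rules, path) {
  stopifnot(inherits(rules, "libprof_score_rules"))
  yaml::write_yaml(list(ranges = lapply(rules$ranges, as.numeric),
                        penalty_patterns = rules$penalty_patterns,
                        penalty_value = rules$penalty_value), path)
  invisible(path)
}

#' Range-based de novo score
#'
#' Scores each molecule of a profiled library: the fraction of descriptors
#' inside their closed intervals (arithmetic mean of 0/1 contributions),
#' multiplied by `(1 - penalty_value)` when any penalty substructure
#' matches.
#'
#' @param profile Profile tibble from [profile_library()] (must contain a
#'   `smiles` column and the descriptors named in the rules).
#' @param rules A `libprof_score_rules`.
#' @return The profile with columns `denovo_score` and `penalized` added.
#' @export
denovo_score <- function(profile, rules) {
  stopifnot(inherits(rules, "libprof_score_rules"))
  contrib <- vapply(names(rules$ranges), function(nm) {
    x <- profile[[nm]]
    if (is.null(x)) stop("profile lacks descriptor: ", nm)
    r <- rules$ranges[[nm]]
    as.numeric(x >= r[1] & x <= r[2])
  }, numeric(nrow(profile)))
  if (nrow(profile) == 1L) contrib <- matrix(contrib, nrow = 1)
  base <- rowMeans(contrib)
  penal <- rep(FALSE, nrow(profile))
  if (length(rules$penalty_patterns)) {
    sdf <- as_sdfset(profile$smiles)
    for (p in rules$penalty_patterns) {
      cnt <- tryCatch(smarts_count(sdf, p),
                      error = function(e) rep(0L, nrow(profile)))
      penal <- penal | (cnt > 0L)
    }
  }
  score <- base * ifelse(penal, 1 - rules$penalty_value, 1)
  profile$denovo_score <- score
  profile$penalized <- penal
  profile
}
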