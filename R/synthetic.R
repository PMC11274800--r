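# Synthetic-data generators. Every generator is a pure function of its spec
# (seed included). Molecules are built from a fixed, curated table of
# (scaffold template, substituent) combinations chosen so that acyclic
# substituents attached by single bonds never alter the Bemis-Murcko
# chemotype; the generator asserts this invariant for every emitted
# molecule rather than trusting the table.

# Scaffold templates: "{1}" is a mid-chain slot (substituent is inserted as
# a parenthesized branch), "{2}" is a trailing slot (appended bare).
scaffold_chemistry <- function() {
  tibble::tibble(
    name = c("benzene", "pyridine", "pyrimidine", "naphthalene", "quinoline",
             "thiophene", "furan", "piperidine", "cyclohexane", "morpholine"),
    template = c("c1cc{1}ccc1{2}",
                 "c1cc{1}ncc1{2}",
                 "c1nc{1}cnc1{2}",
                 "c1ccc2cc{1}ccc2c1{2}",
                 "c1ccc2nc{1}ccc2c1{2}",
                 "c1cc{1}sc1{2}",
                 "c1cc{1}oc1{2}",
                 "C1CC{1}CNC1{2}",
                 "C1CC{1}CCC1{2}",
                 "C1COC{1}CN1{2}")
  )
}

substituent_chemistry <- function() {
  c("C", "CC", "CCC", "CCCC", "CC(C)C", "CO", "CCO", "OC", "OCC",
    "N", "NC", "N(C)C", "F", "Cl", "Br", "C#N", "C(F)(F)F",
    "C(=O)C", "C(=O)NC", "C(=O)OC", "S(=O)(=O)C", "CCN(C)C")
}

acyclic_chemistry <- function() {
  c("CCO", "CCCO", "CCCCO", "CCN", "CCCN", "CCOC", "CCCOC", "CC(C)O",
    "CC(C)CO", "CCC(=O)O", "CCCC(=O)O", "CCNC", "CCCNC", "CCOCC",
    "CC(C)N", "CCC(C)O", "CCCCN", "CCCCCO", "CCC(=O)N", "CCCC(=O)N",
    "CC(C)CN", "CCOCCO", "CCCOC(=O)C", "CCN(C)CC", "CCCCCN",
    "CC(C)(C)O", "CC(C)(C)CO", "CCCC(C)O", "CCCCOC", "CCCCCCO")
}

decorate_scaffold <- function(template, s1 = "", s2 = "") {
  t <- sub("{1}", if (nzchar(s1)) paste0("(", s1, ")") else "", template,
           fixed = TRUE)
  sub("{2}", s2, t, fixed = TRUE)
}

#' Specification for a synthetic scaffold library
#'
#' @param scaffold_pool Character vector of scaffold names from the built-in
#'   chemistry table (see Details) or custom template strings containing
#'   `{1}`/`{2}` slots.
#' @param frequency Integer vector (same length): how many molecules to
#'   emit per scaffold.
#' @param substituent_pool Acyclic substituent SMILES fragments.
#' @param n_acyclic Number of ring-free molecules to add.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A `libprof_library_spec` list.
#' @export
synthetic_library_spec <- function(scaffold_pool = scaffold_chemistry()$name,
                                   frequency = rep(5L, length(scaffold_pool)),
                                   substituent_pool = substituent_chemistry(),
                                   n_acyclic = 0L, seed = 1L) {
  stopifnot(length(scaffold_pool) == length(frequency), all(frequency >= 0),
            n_acyclic >= 0)
  structure(list(scaffold_pool = scaffold_pool, frequency = as.integer(frequency),
                 substituent_pool = substituent_pool,
                 n_acyclic = as.integer(n_acyclic), seed = as.integer(seed)),
            class = "libprof_library_spec")
}

#' Generate a synthetic library with controlled scaffold frequencies
#'
#' Emits, for each scaffold in the spec, the requested number of distinct
#' valid molecules sharing that Bemis-Murcko chemotype (distinct acyclic
#' substituents at ring positions), plus ring-free molecules. The chemotype
#' of every emitted molecule is asserted with [bm_scaffold()]; a substituent
#' combination that altered the chemotype would be an internal error, never
#' silently emitted.
#'
#' @param spec A [synthetic_library_spec()].
#' @return A tibble with columns `id`, `smiles` (canonical), `chemotype`
#'   (ground truth), `status`.
#' @export
gen_scaffold_library <- function(spec = synthetic_library_spec()) {
  stopifnot(inherits(spec, "libprof_library_spec"))
  chem <- scaffold_chemistry()
  withr::with_seed(spec$seed, {
    rows <- list()
    for (i in seq_along(spec$scaffold_pool)) {
      need <- spec$frequency[i]
      if (need == 0L) next
      sc <- spec$scaffold_pool[i]
      template <- if (sc %in% chem$name) chem$template[match(sc, chem$name)] else sc
      base <- canonical_smiles(decorate_scaffold(template))
      if (is.na(base)) stop("invalid scaffold template: ", template)
      base_chemotype <- bm_scaffold(base)
      subs <- spec$substituent_pool
      combos <- rbind(data.frame(s1 = "", s2 = ""),
                      data.frame(s1 = "", s2 = subs),
                      data.frame(s1 = subs, s2 = ""),
                      expand.grid(s1 = subs, s2 = subs,
                                  stringsAsFactors = FALSE))
      combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
      smi <- canonical_smiles(
        mapply(decorate_scaffold, template, combos$s1, combos$s2,
               USE.NAMES = FALSE))
      smi <- unique(smi[!is.na(smi)])
      if (length(smi) < need) {
        stop("cannot generate ", need, " distinct molecules for scaffold ", sc)
      }
      smi <- smi[seq_len(need)]
      got <- bm_scaffold(smi)
      if (!all(got == base_chemotype)) {
        stop("internal error: substituent altered the chemotype of ", sc)
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(smiles = smi, chemotype = base_chemotype)
    }
    if (spec$n_acyclic > 0L) {
      pool <- unique(canonical_smiles(acyclic_chemistry()))
      if (spec$n_acyclic > length(pool)) {
        stop("at most ", length(pool), " distinct acyclic molecules available")
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(smiles = pool[seq_len(spec$n_acyclic)],
                       chemotype = "ACYCLIC")
    }
    out <- dplyr::bind_rows(rows)
    out$id <- ordinal_ids(nrow(out), "SYN")
    out$status <- "CURATED"
    out$canonical_smiles <- out$smiles
    out[, c("id", "smiles", "canonical_smiles", "chemotype", "status")]
  })
}

#' Specification for a synthetic activity dataset
#'
#' @param n_active,n_inactive Class sizes.
#' @param separability In `[0, 1]`: 1 draws the two classes from disjoint
#'   scaffold pools (structure fully determines class), 0 mixes the pools
#'   completely (labels independent of structure).
#' @param ambiguous_fraction Fraction of rows given a non-pinning relation
#'   qualifier (e.g. `> v` with `v` below threshold).
#' @param contradictory_pairs Number of structures duplicated with values on
#'   opposite sides of the threshold.
#' @param seed Integer seed.
#' @return A `libprof_activity_spec` list.
#' @export
synthetic_activity_spec <- function(n_active = 100L, n_inactive = 100L,
                                    separability = 1, ambiguous_fraction = 0,
                                    contradictory_pairs = 0L, seed = 1L) {
  stopifnot(separability >= 0, separability <= 1,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 separability = separability,
                 ambiguous_fraction = ambiguous_fraction,
                 contradictory_pairs = as.integer(contradictory_pairs),
                 seed = as.integer(seed)),
            class = "libprof_activity_spec")
}

ACTIVE_SCAFFOLDS <- c("quinoline", "pyrimidine", "pyridine", "naphthalene")
INACTIVE_SCAFFOLDS <- c("benzene", "thiophene", "piperidine", "cyclohexane")

#' Generate a synthetic IC50 activity table
#'
#' Actives are substituted analogues of one scaffold pool, inactives of a
#' disjoint pool; `separability` mixes the pools. IC50 values are lognormal
#' around 1 uM (actives) and 100 uM (inactives), truncated to the correct
#' side of the 10 uM threshold so that ground-truth class and threshold
#' label coincide; units are a mixture of nM and uM. A fraction of rows get
#' non-pinning qualifiers, and `contradictory_pairs` structures are
#' duplicated with values on the opposite side of the threshold.
#'
#' @param spec A [synthetic_activity_spec()].
#' @return A list with `activities` (tibble: `id`, `smiles`,
#'   `standard_value`, `standard_units`, `standard_relation`) and `truth`
#'   (tibble: `id`, `smiles`, `true_class`, `planted`).
#' @export
gen_activity_dataset <- function(spec = synthetic_activity_spec()) {
  stopifnot(inherits(spec, "libprof_activity_spec"))
  chem <- scaffold_chemistry()
  withr::with_seed(spec$seed, {
    n <- spec$n_active + spec$n_inactive
    cls <- c(rep("ACTIVE", spec$n_active), rep("INACTIVE", spec$n_inactive))
    # scaffold pool per row: separability-weighted coin
    own_pool <- stats::runif(n) < (1 + spec$separability) / 2
    pool <- ifelse((cls == "ACTIVE") == own_pool,
                   "active_pool", "inactive_pool")
    smi <- character(n)
    subs <- substituent_chemistry()
    gen_one <- function(which_pool) {
      nm <- if (which_pool == "active_pool") ACTIVE_SCAFFOLDS else INACTIVE_SCAFFOLDS
      template <- chem$template[match(sample(nm, 1L), chem$name)]
      decorate_scaffold(template, sample(c("", subs), 1L), sample(c("", subs), 1L))
    }
    seen <- character(0)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        cand <- canonical_smiles(gen_one(pool[i]))
        if (!is.na(cand) && !(cand %in% seen)) break
        cand <- NA_character_
      }
      if (is.na(cand)) stop("failed to generate a distinct structure")
      smi[i] <- cand; seen <- c(seen, cand)
    }
    # IC50 in uM, truncated to the class side of the 10 uM threshold
    draw_trunc <- function(n, meanlog, keep) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        repeat { v <- stats::rlnorm(1, meanlog, 0.9); if (keep(v)) break }
        out[i] <- v
      }
      out
    }
    val_um <- numeric(n)
    val_um[cls == "ACTIVE"] <- draw_trunc(spec$n_active, log(1), function(v) v <= 10)
    val_um[cls == "INACTIVE"] <- draw_trunc(spec$n_inactive, log(100), function(v) v > 10)
    units <- sample(c("uM", "nM"), n, replace = TRUE)
    value <- ifelse(units == "nM", val_um * 1000, val_um)
    relation <- rep("=", n)
    planted <- rep("clean", n)
    # non-pinning qualifiers
    n_amb <- round(spec$ambiguous_fraction * n)
    if (n_amb > 0) {
      amb <- sample.int(n, n_amb)
      relation[amb] <- ifelse(cls[amb] == "ACTIVE", ">", "<")
      planted[amb] <- "ambiguous"
    }
    ids <- ordinal_ids(n, "ACT")
    activities <- tibble::tibble(id = ids, smiles = smi,
                                 standard_value = value,
                                 standard_units = units,
                                 standard_relation = relation)
    truth <- tibble::tibble(id = ids, smiles = smi, true_class = cls,
                            planted = planted)
    # contradictory duplicates among the clean rows
    if (spec$contradictory_pairs > 0L) {
      cand <- which(planted == "clean")
      if (length(cand) < spec$contradictory_pairs) {
        stop("not enough clean rows to plant contradictions")
      }
      pick <- sample(cand, spec$contradictory_pairs)
      dup <- activities[pick, , drop = FALSE]
      dup$id <- paste0(dup$id, "_DUP")
      flip <- truth$true_class[pick] == "ACTIVE"
      dup$standard_value <- ifelse(flip, 50 * 1000, 2 * 1000)
      dup$standard_units <- "nM"
      dup$standard_relation <- "="
      activities <- dplyr::bind_rows(activities, dup)
      truth$planted[pick] <- "contradictory"
      truth <- dplyr::bind_rows(
        truth,
        tibble::tibble(id = dup$id, smiles = dup$smiles,
                       true_class = ifelse(flip, "INACTIVE", "ACTIVE"),
                       planted = "contradictory"))
    }
    list(activities = activities, truth = truth)
  })
}

#' Generate a synthetic docking-score table
#'
#' Scores are drawn from Normal(-7, 1.5) kcal/mol and paired with plausible
#' heavy-atom counts; used to exercise ligand-efficiency post-processing.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return A tibble with `id`, `program`, `score`, `heavy_atoms`.
#' @export
gen_docking_table <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  withr::with_seed(as.integer(seed), {
    tibble::tibble(id = ordinal_ids(n, "DOCK"),
                   program = sample(c("VINA", "LEDOCK"), n, replace = TRUE),
                   score = stats::rnorm(n, -7, 1.5),
                   heavy_atoms = sample(15:40, n, replace = TRUE))
  })
}

# Deterministic reference corpus used to parameterize the default
# synthetic-accessibility fragment table: every scaffold decorated with
# every single substituent, a slice of disubstituted combinations, and the
# acyclic set.
sa_reference_corpus <- function() {
  chem <- scaffold_chemistry()
  subs <- substituent_chemistry()
  smi <- character(0)
  for (i in seq_len(nrow(chem))) {
    smi <- c(smi,
             decorate_scaffold(chem$template[i]),
             vapply(subs, function(s) decorate_scaffold(chem$template[i], s1 = s), ""),
             vapply(subs, function(s) decorate_scaffold(chem$template[i], s2 = s), ""))
  }
  for (i in seq_len(nrow(chem))) {
    for (j in seq_along(subs)) {
      smi <- c(smi, decorate_scaffold(chem$template[i], subs[j],
                                      subs[(j %% length(subs)) + 1L]))
    }
  }
  smi <- c(smi, acyclic_chemistry())
  unique(canonical_smiles(smi))
}
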