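test_that("RECAP cuts the published bond classes and tracks growing sites", {
  # amide: two fragments, one growing site each
  f <- recap_fragments("CC(=O)Nc1ccccc1", "ace")
  expect_equal(nrow(f), 2L)
  expect_setequal(f$smiles, c("*C(=O)C", "*Nc1ccccc1"))
  expect_true(all(f$n_sites == 1L))
  expect_true(all(vapply(f$growing_sites, length, 1L) == 1L))
  # growing sites index the * atoms of the fragment's atom order
  for (i in 1:2) {
    seq <- libprof:::smiles_atom_seq(f$smiles[i])
    expect_equal(which(seq$elem == "*") - 1L, f$growing_sites[[i]])
  }
  # no cleavable bond -> no fragments
  expect_equal(nrow(recap_fragments("CC")), 0L)
  expect_equal(nrow(recap_fragments("c1ccccc1")), 0L)
  # heavy-atom conservation (attachment markers excluded)
  parents <- c("c1ccccc1-c1ccc(OCCN2CCCCC2)cc1",
               "CC(=O)NCCc1ccccc1",
               "c1ccccc1S(=O)(=O)NCC=CC")
  for (p in parents) {
    fr <- recap_fragments(p)
    expect_equal(sum(fr$heavy_atoms), heavy_atom_count(p), label = p)
  }
  # a single cleavage increases the fragment count by exactly one
  one_cut <- recap_fragments("CCCC(=O)NCCC")
  expect_equal(nrow(one_cut), 2L)
})

test_that("RO3 filter applies a strict MW bound and the exclusion list", {
  frags <- tibble::tibble(
    id = c("a", "b", "c", "w"),
    smiles = c("*CC", "*CC", "*CC", "*O"),
    mw = c(299.5, 300.0, 150, 18.02))
  out <- ro3_filter(frags)
  expect_setequal(out$id, c("a", "c"))     # 299.5 kept, 300.0 dropped
  expect_false("w" %in% out$id)            # water always dropped
})

test_that("logD filter uses a closed bound and reports missing entries", {
  frags <- tibble::tibble(id = c("f1", "f2", "f3"),
                          smiles = c("*C", "*CC", "*CCC"),
                          mw = c(16, 30, 44))
  tab <- tibble::tibble(id = c("f1", "f2", "f3"), logd = c(3.0, 3.01, -1))
  out <- logd_filter(frags, tab)
  expect_setequal(out$id, c("f1", "f3"))   # 3.0 kept, 3.01 dropped
  expect_error(logd_filter(frags, tab[1:2, ]), "f3")
  expect_error(logd_filter(frags, tibble::tibble(id = character(0),
                                                 logd = numeric(0))),
               "missing logD")
})

test_that("MaxMin selection is deterministic and matches brute-force greedy", {
  lib <- fix_small_library()
  s1 <- maxmin_select(lib, 5, seed = 9)
  s2 <- maxmin_select(lib, 5, seed = 9)
  expect_identical(s1$id, s2$id)
  s3 <- maxmin_select(lib, 5, seed = 10)
  expect_equal(nrow(s3), 5L)               # different seed, same length
  # k == pool size returns everything; k == 1 the seed-designated item
  expect_equal(nrow(maxmin_select(lib, nrow(lib), seed = 1)), nrow(lib))
  one <- maxmin_select(lib, 1, seed = 3)
  expect_equal(one$id, lib$id[(3 %% nrow(lib)) + 1])
  # k > pool: whole pool plus a warning
  expect_warning(all_of <- maxmin_select(lib[1:4, ], 10, seed = 1),
                 "smaller than k")
  expect_equal(nrow(all_of), 4L)

  # brute-force greedy oracle on a pool of 6
  pool <- lib[seq(1, 18, by = 3), ]
  fps <- fp_matrix(pool$smiles, "MACCS166")
  seed <- 2
  first <- (seed %% nrow(pool)) + 1
  picked <- first
  for (step in 2:3) {
    cand <- setdiff(seq_len(nrow(pool)), picked)
    dmin <- vapply(cand, function(j) {
      min(vapply(picked, function(i) 1 - tanimoto(fps[j, ], fps[i, ]), 0))
    }, 0)
    picked <- c(picked, cand[which.max(dmin)])
  }
  got <- maxmin_select(pool, 3, seed = seed)
  expect_equal(got$id, pool$id[picked])
})

test_that("greedy MaxMin achieves at least half the optimal min-distance", {
  lib <- fix_small_library()
  pool <- lib[1:8, ]
  fps <- fp_matrix(pool$smiles, "MACCS166")
  d <- 1 - tanimoto_cross(fps, fps)
  min_pair <- function(idx) min(d[idx, idx][upper.tri(diag(length(idx)))])
  combs <- utils::combn(8, 4)
  best <- max(apply(combs, 2, min_pair))
  for (seed in 1:4) {
    sel <- maxmin_select(pool, 4, seed = seed)
    idx <- match(sel$id, pool$id)
    expect_gte(min_pair(idx), 0.5 * best)
  }
})

test_that("training-set preparation filters MW > 300 then selects", {
  lib <- fix_small_library()
  # all molecules in the small library are below 300 Da -> empty + warning
  mws <- profile_library(lib)$mw
  if (all(mws <= 300)) {
    expect_warning(out <- prepare_training_set(lib, target_size = 5),
                   "MW > 300")
    expect_equal(nrow(out), 0L)
  }
  # add heavy molecules; selection picks only from them
  heavy <- gen_scaffold_library(synthetic_library_spec(
    scaffold_pool = "naphthalene", frequency = 12L, seed = 8L,
    substituent_pool = c("CCCCCCCCCC(=O)NCCCCCC", "S(=O)(=O)CCCCCCCCCCCC",
                         "CCCCCCCCCCCCCCCC", "C(=O)NCCCCCCCCCCCN(C)C")))
  mixed <- dplyr::bind_rows(lib, heavy)
  sel <- prepare_training_set(mixed, target_size = 6, seed = 1)
  expect_equal(nrow(sel), 6L)
  expect_true(all(sel$id %in% heavy$id))
  expect_false(any(duplicated(sel$id)))
  # exactly target_size survivors -> all picked
  n_surv <- sum(profile_library(heavy)$mw > 300)
  sel_all <- prepare_training_set(heavy, target_size = n_surv, seed = 1)
  expect_equal(nrow(sel_all), n_surv)
  expect_false(any(duplicated(sel_all$id)))
})

test_that("fragment-library pipeline keeps stage counts monotone", {
  lib <- fix_small_library()
  frags <- recap_fragments(lib$smiles, lib$id)
  frags <- frags[!duplicated(frags$smiles), ]
  logd <- withr::with_seed(5, tibble::tibble(
    id = frags$id, logd = stats::runif(nrow(frags), -2, 5)))
  out <- suppressWarnings(
    prepare_fragment_library(frags, logd, intermediate_k = 12, final_k = 6))
  stages <- attr(out, "stages")
  expect_true(all(diff(stages) <= 0))
  expect_lte(nrow(out), 6L)
  # a pool smaller than final_k comes back whole (both MaxMin stages warn)
  warns <- testthat::capture_warnings(
    small <- prepare_fragment_library(frags[1:3, ], logd,
                                      intermediate_k = 10, final_k = 8))
  expect_true(any(grepl("smaller than k", warns)))
  expect_lte(nrow(small), 3L)
})
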