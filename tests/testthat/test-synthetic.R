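test_that("scaffold-library generation matches its ground truth exactly", {
  spec <- synthetic_library_spec(
    scaffold_pool = c("quinoline", "benzene", "thiophene"),
    frequency = c(5L, 3L, 2L), n_acyclic = 0L, seed = 13L)
  lib <- gen_scaffold_library(spec)
  expect_equal(nrow(lib), 10L)
  # the generator's chemotype annotations agree with scaffold perception
  perceived <- bm_scaffold(lib$smiles)
  expect_identical(perceived, lib$chemotype)
  prof <- scaffold_profile(lib)
  expect_equal(prof$M, 10L)
  expect_equal(prof$N, 3L)
  expect_equal(sort(prof$counts$n, decreasing = TRUE), c(5L, 3L, 2L))
  # SSE_3 equals the analytic entropy of (0.5, 0.3, 0.2) / log 3
  p <- c(0.5, 0.3, 0.2)
  expect_equal(scaffold_profile(lib, sse_top_n = 3)$sse,
               -sum(p * log(p)) / log(3), tolerance = 1e-12)
  # byte-identical reproducibility
  expect_identical(lib, gen_scaffold_library(spec))
  # a different seed still satisfies the contract
  lib2 <- gen_scaffold_library(synthetic_library_spec(
    scaffold_pool = c("quinoline", "benzene", "thiophene"),
    frequency = c(5L, 3L, 2L), seed = 14L))
  expect_equal(nrow(lib2), 10L)
  expect_false(identical(lib$smiles, lib2$smiles))
})

test_that("activity generation plants ambiguity and contradictions exactly", {
  spec <- synthetic_activity_spec(n_active = 50L, n_inactive = 50L,
                                  separability = 1,
                                  ambiguous_fraction = 0.1,
                                  contradictory_pairs = 3L, seed = 21L)
  gen <- gen_activity_dataset(spec)
  expect_identical(gen, gen_activity_dataset(spec))
  out <- label_activity(gen$activities)
  s <- attr(out, "summary")
  n_amb_planted <- sum(gen$truth$planted == "ambiguous")
  expect_equal(s$n_ambiguous, n_amb_planted)
  expect_equal(s$n_contradictory, 6L)    # 3 pairs -> 6 rows
  # survivors and their class split match ground truth exactly
  clean <- gen$truth[gen$truth$planted == "clean", ]
  expect_equal(s$n_active + s$n_inactive, nrow(clean))
  expect_equal(s$n_active, sum(clean$true_class == "ACTIVE"))
  expect_equal(s$n_inactive, sum(clean$true_class == "INACTIVE"))
  kept <- out[out$kept, ]
  truth_for_kept <- gen$truth$true_class[match(kept$id, gen$truth$id)]
  expect_identical(kept$label, truth_for_kept)
})

test_that("docking tables are reproducible and feed ligand efficiency", {
  tab <- gen_docking_table(10, seed = 5)
  expect_identical(tab, gen_docking_table(10, seed = 5))
  expect_equal(nrow(tab), 10L)
  expect_true(all(is.finite(tab$score)))
  expect_true(all(tab$heavy_atoms >= 1))
  le <- ligand_efficiency(tab$score, tab$heavy_atoms)
  expect_equal(le, tab$score / tab$heavy_atoms)
})
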