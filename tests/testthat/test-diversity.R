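test_that("tanimoto follows the set-overlap definition", {
  a <- integer(10); a[c(1, 2, 3)] <- 1L
  b <- integer(10); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)      # 2 shared / 4 in union
  expect_equal(tanimoto(a, a), 1)
  disjoint <- replace(integer(10), 5:7, 1L)
  expect_equal(tanimoto(a, disjoint), 0)
  expect_equal(tanimoto(integer(10), integer(10)), 1)  # both empty
  expect_error(tanimoto(a, b[1:5]), "length mismatch")
  m <- fp_matrix(c("CCO", "CCO", "c1ccccc1"), "MACCS166")
  expect_equal(ncol(m), 166L)
  expect_equal(tanimoto(m[1, ], m[2, ]), 1)
})

test_that("similarity statistics match the dense oracle", {
  lib <- fix_small_library()
  for (kind in c("MACCS166", "ECFP4_1024")) {
    st <- pairwise_similarity_stats(lib, kind)
    fps <- fp_matrix(lib$smiles, kind)
    oracle <- oracle_pairwise_tanimoto(fps)
    expect_equal(st$n, nrow(lib))
    expect_equal(st$median, median(oracle), tolerance = 1e-12)
    expect_equal(st$mean, mean(oracle), tolerance = 1e-12)
    cf <- st$cdf$cumulative_fraction
    expect_true(all(diff(cf) >= 0))
    expect_equal(cf[length(cf)], 1)
  }
  # three copies of one molecule -> all similarities 1
  st3 <- pairwise_similarity_stats(rep("CCO", 3), "MACCS166")
  expect_equal(st3$median, 1)
  expect_equal(st3$mean, 1)
  # row order does not change the statistics
  perm <- withr::with_seed(3, lib[sample.int(nrow(lib)), ])
  st_p <- pairwise_similarity_stats(perm, "MACCS166")
  st_o <- pairwise_similarity_stats(lib, "MACCS166")
  expect_equal(st_p$median, st_o$median)
  expect_error(pairwise_similarity_stats("CCO"), "at least two")
})

test_that("Bemis-Murcko chemotypes prune side chains", {
  expect_equal(bm_scaffold("Cc1ccccc1"), bm_scaffold("c1ccccc1"))
  expect_equal(bm_scaffold("CCCCCC"), "ACYCLIC")
  # different side chains, same chemotype
  expect_equal(bm_scaffold("CC(=O)Nc1ccccc1"),
               bm_scaffold("CCC(=O)Nc1ccccc1"))
  # carbonyl linker oxygen is retained
  benzophenone <- bm_scaffold("c1ccccc1C(=O)c1ccccc1C")
  expect_true(grepl("O", benzophenone))
})

test_that("scaffold profile reproduces hand-computed CSR statistics", {
  # counts [4,2,2,1,1] over 10 molecules
  chemos <- rep(c("A", "B", "C", "D", "E"), c(4, 2, 2, 1, 1))
  p <- scaffold_profile(NULL, chemotypes = chemos, sse_top_n = 5)
  expect_equal(p$M, 10L)
  expect_equal(p$N, 5L)
  expect_equal(p$auc, 0.64, tolerance = 1e-12)
  expect_equal(p$f50, 0.4, tolerance = 1e-12)
  h <- -(0.4 * log(0.4) + 2 * 0.2 * log(0.2) + 2 * 0.1 * log(0.1))
  expect_equal(p$sse, h / log(5), tolerance = 1e-12)
  # limits
  expect_equal(scaled_shannon_entropy(rep(7, 10)), 1)
  expect_equal(scaled_shannon_entropy(c(42)), 0)
  expect_equal(scaffold_profile(NULL, chemotypes = rep("X", 9))$sse, 0)
  # SSE is invariant to the log base by construction (ratio of entropies)
  p2 <- scaffold_profile(NULL, chemotypes = chemos, sse_top_n = 3)
  cnt <- c(4, 2, 2)
  pr <- cnt / sum(cnt)
  expect_equal(p2$sse, -sum(pr * log(pr)) / log(3))
})

test_that("all-unique chemotypes give the diagonal CSR curve", {
  for (m in withr::with_seed(1, sample(4:60, 5))) {
    p <- scaffold_profile(NULL, chemotypes = paste0("S", seq_len(m)))
    expect_equal(p$auc, 0.5, tolerance = 1e-12)
    expect_equal(p$nm_ratio, 1.0)
    if (m %% 2 == 0) expect_equal(p$f50, 0.5, tolerance = 1e-12)
  }
})

test_that("AUC rises when chemotypes merge and F50 respects its bound", {
  chemos <- rep(c("A", "B", "C", "D"), c(5, 3, 1, 1))
  p1 <- scaffold_profile(NULL, chemotypes = chemos)
  merged <- ifelse(chemos == "B", "A", chemos)
  p2 <- scaffold_profile(NULL, chemotypes = merged)
  expect_gt(p2$auc, p1$auc)
  expect_gte(p1$f50, 1 / p1$N)
  # top chemotype alone covers >= 50% -> F50 == 1/N
  expect_equal(p2$f50, 1 / p2$N)
})

test_that("scaffold overlap is exact set algebra without ACYCLIC", {
  a <- scaffold_profile(NULL, chemotypes = c("s1", "s1", "s2", "ACYCLIC"))
  b <- scaffold_profile(NULL, chemotypes = c("s2", "s3", "ACYCLIC"))
  ov <- scaffold_overlap(a, b)
  expect_equal(ov$shared, "s2")
  expect_setequal(ov$unique_a, "s1")
  expect_setequal(ov$unique_b, "s3")
  expect_equal(length(ov$shared) + length(ov$unique_a), a$N - 1L)
  same <- scaffold_overlap(a, a)
  expect_equal(length(same$unique_a), 0L)
  expect_equal(length(same$unique_b), 0L)
})

test_that("property distance matches a brute-force oracle and its limits", {
  lib <- fix_small_library()
  sub <- lib[1:12, ]
  pd <- property_distance(sub)
  z <- as.matrix(attr(pd, "properties"))
  # explicit pair loop oracle
  vals <- c()
  for (i in 1:(nrow(z) - 1)) for (j in (i + 1):nrow(z)) {
    vals <- c(vals, sqrt(sum((z[i, ] - z[j, ])^2)))
  }
  expect_equal(as.numeric(pd), median(vals), tolerance = 1e-12)
  # duplicate-only dataset -> 0
  expect_equal(as.numeric(property_distance(rep("CCO", 3))), 0)
  expect_error(property_distance("CCO"), "at least two")
})

test_that("CDPlot points are consistent with their component statistics", {
  lib <- fix_small_library()
  a <- lib[1:10, ]; b <- lib[11:20, ]
  cd <- cdplot_data(list(A = a, B = b))
  expect_equal(nrow(cd), 2L)
  st <- pairwise_similarity_stats(a, "MACCS166")
  expect_equal(cd$x[cd$dataset_code == "A"], st$median)
  expect_equal(cd$size_value, c(10L, 10L))
  # the same dataset twice gives identical points
  cd2 <- cdplot_data(list(P = a, Q = a))
  expect_equal(cd2$x[1], cd2$x[2])
  expect_equal(cd2$y[1], cd2$y[2])
  expect_s3_class(ggplot2::autoplot(cd), "ggplot")
})

test_that("embeddings are deterministic and respect degeneracies", {
  lib <- fix_small_library()
  sub <- lib[1:12, ]
  pca <- embed_chemspace(list(S = sub), "PROPERTIES6", "PCA")
  expect_equal(nrow(pca), 12L)
  ev <- attr(pca, "explained_variance")
  expect_true(all(ev >= 0 & ev <= 1))
  # duplicated molecule -> coincident PCA coordinates
  dup <- c(sub$smiles, sub$smiles[1])
  pca2 <- embed_chemspace(list(S = dup), "MACCS166", "PCA")
  expect_equal(unlist(pca2[1, c("dim1", "dim2")]),
               unlist(pca2[13, c("dim1", "dim2")]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical seeds give identical t-SNE output; plots build
  t1 <- embed_chemspace(list(S = sub), "MACCS166", "TSNE", seed = 5,
                        max_iter = 120)
  t2 <- embed_chemspace(list(S = sub), "MACCS166", "TSNE", seed = 5,
                        max_iter = 120)
  expect_identical(t1$dim1, t2$dim1)
  expect_s3_class(ggplot2::autoplot(t1), "ggplot")
  expect_error(embed_chemspace(list(S = sub$smiles[1:2]), "PROPERTIES6"),
               "at least three")
})
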