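test_that("activity labeling implements the threshold/qualifier rule", {
  tbl <- tibble::tibble(
    id = paste0("r", 1:8),
    smiles = c("CCO", "CCN", "CCC", "CCCC", "CCCCC", "CCOC", "c1ccccc1",
               "c1ccncc1"),
    standard_value = c(5, 5000, 1, 100, 50, 10, 10, 12),
    standard_units = c("uM", "nM", "uM", "uM", "uM", "uM", "uM", "uM"),
    standard_relation = c("=", "=", ">", "<", "=", "<=", ">=", "="))
  out <- label_activity(tbl)
  lab <- setNames(out$label, out$id)
  expect_equal(lab[["r1"]], "ACTIVE")        # = 5 uM
  expect_equal(lab[["r2"]], "ACTIVE")        # = 5000 nM == 5 uM
  expect_equal(lab[["r3"]], "AMBIGUOUS")     # > 1 uM does not pin
  expect_equal(lab[["r4"]], "AMBIGUOUS")     # < 100 uM does not pin
  expect_equal(lab[["r5"]], "INACTIVE")      # = 50 uM
  expect_equal(lab[["r6"]], "ACTIVE")        # <= 10 uM
  expect_equal(lab[["r7"]], "INACTIVE")      # >= 10 uM
  expect_equal(lab[["r8"]], "INACTIVE")      # = 12 uM
  expect_error(label_activity(dplyr::mutate(tbl, standard_units = "pM")),
               "unknown unit")
})

test_that("duplicate structures are collapsed or removed as contradictory", {
  tbl <- tibble::tibble(
    id = paste0("r", 1:5),
    smiles = c("CCO", "OCC", "CCN", "NCC", "CCC"),
    standard_value = c(1, 50, 2, 4, 3),
    standard_units = "uM",
    standard_relation = "=")
  out <- label_activity(tbl)
  # CCO/OCC: same structure, opposite sides of 10 uM -> both removed
  expect_equal(out$label[out$id %in% c("r1", "r2")],
               c("CONTRADICTORY", "CONTRADICTORY"))
  expect_false(any(out$kept[out$id %in% c("r1", "r2")]))
  # CCN/NCC concordant -> one survivor carrying the median-closest value
  kept_ccn <- out[out$id %in% c("r3", "r4") & out$kept, ]
  expect_equal(nrow(kept_ccn), 1L)
  s <- attr(out, "summary")
  expect_equal(s$n_contradictory, 2L)
  expect_equal(s$n_duplicate_collapsed, 1L)
  expect_equal(s$n_active + s$n_inactive, 2L)
})

test_that("labeling is order-invariant up to the duplicate representative", {
  act <- fix_activity()
  out1 <- label_activity(act$activities)
  perm <- withr::with_seed(2, act$activities[sample.int(nrow(act$activities)), ])
  out2 <- label_activity(perm)
  k1 <- sort(out1$canonical_smiles[out1$kept])
  k2 <- sort(out2$canonical_smiles[out2$kept])
  expect_identical(k1, k2)
})

test_that("stratified split preserves class proportions exactly", {
  dat <- tibble::tibble(
    id = as.character(1:100),
    label = rep(c("ACTIVE", "INACTIVE"), c(60, 40)))
  sp <- stratified_split(dat, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(sum(sp$train$label == "ACTIVE"), 48L)
  expect_equal(sum(sp$train$label == "INACTIVE"), 32L)
  sp2 <- stratified_split(dat, 0.8, seed = 4)
  expect_identical(sp$train$id, sp2$train$id)
  expect_setequal(c(sp$train$id, sp$test$id), dat$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_error(stratified_split(dat[1:60, ], seed = 1), "both classes")
})

test_that("balanced accuracy follows its confusion-matrix definition", {
  # TP=4, FN=1, TN=3, FP=2 -> BA = (0.8 + 0.6)/2 = 0.7
  truth <- rep(c("ACTIVE", "INACTIVE"), c(5, 5))
  pred <- c(rep("ACTIVE", 4), "INACTIVE", rep("INACTIVE", 3), "ACTIVE",
            "ACTIVE")
  cm <- libprof:::confusion_metrics(truth, pred)
  expect_equal(cm$ba, 0.7)
  expect_equal(cm$precision_active, 4 / 6)
  expect_equal(cm$recall_active, 0.8)
  # majority-class predictor scores BA 0.5 regardless of imbalance
  cm2 <- libprof:::confusion_metrics(rep(c("ACTIVE", "INACTIVE"), c(8, 2)),
                                     rep("ACTIVE", 10))
  expect_equal(cm2$ba, 0.5)
  # class-relabeling symmetry
  flip <- function(x) ifelse(x == "ACTIVE", "INACTIVE", "ACTIVE")
  expect_equal(libprof:::confusion_metrics(flip(truth), flip(pred))$ba, cm$ba)
})

test_that("DM distance is the mean Jaccard distance", {
  A <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  q <- matrix(c(1L, 1L, 0L, 0L), 1)
  # to itself 0; to the disjoint vector 1 -> mean 0.5
  expect_equal(dm_distance(q, A), 0.5)
  expect_equal(dm_distance(q, q), 0)
  expect_equal(dm_distance(matrix(c(0L, 0L, 1L, 1L), 1), A[1, , drop = FALSE]), 1)
  expect_error(dm_distance(q, A[0, , drop = FALSE]), "empty")
  # {0.2, 0.4} -> 0.3 via crafted fingerprints
  tr <- rbind(c(1L, 1L, 1L, 1L, 0L), c(1L, 1L, 1L, 0L, 1L))
  qq <- matrix(c(1L, 1L, 1L, 1L, 0L), 1)
  expect_equal(dm_distance(qq, tr), mean(c(0, 1 - 3 / 5)))
})

test_that("DM quartiles are equal occupancy with stable ties", {
  n <- 180
  recs <- withr::with_seed(8, tibble::tibble(
    truth = sample(c("ACTIVE", "INACTIVE"), n, TRUE),
    pred = sample(c("ACTIVE", "INACTIVE"), n, TRUE),
    dm = runif(n)))
  rep <- dm_quartile_report(recs)
  expect_equal(rep$rows$n_active + rep$rows$n_inactive, rep(45L, 4))
  expect_length(rep$boundaries, 3L)
  # all-identical dm: ties broken by stable input order, still 45 each
  rep2 <- dm_quartile_report(dplyr::mutate(recs, dm = 0.5))
  expect_equal(rep2$rows$n_active + rep2$rows$n_inactive, rep(45L, 4))
  # precision arithmetic: the lowest-DM quartile holds TP=6, FP=2
  r3 <- tibble::tibble(
    truth = c(rep("ACTIVE", 6), rep("INACTIVE", 2), "ACTIVE", "INACTIVE",
              rep(c("ACTIVE", "INACTIVE"), 15)),
    pred = c(rep("ACTIVE", 8), "INACTIVE", "INACTIVE",
             rep(c("ACTIVE", "INACTIVE"), 15)),
    dm = seq(0.01, 0.40, by = 0.01))
  q1 <- dm_quartile_report(r3)$rows[1, ]
  expect_equal(q1$precision, 6 / 8)
  expect_equal(q1$n_active, 7L)
  # a quartile with no predicted actives reports NA precision
  r4 <- tibble::tibble(truth = rep("INACTIVE", 8),
                       pred = rep("INACTIVE", 8),
                       dm = seq(0.1, 0.8, 0.1))
  expect_true(all(is.na(dm_quartile_report(r4)$rows$precision)))
})

test_that("grid search returns the requested single spec and tie order", {
  act <- fix_activity()
  lab <- label_activity(act$activities)
  sp <- stratified_split(lab, seed = 3)
  g <- grid_search_models(sp$train, algorithms = "KNN",
                          fingerprints = "MACCS166",
                          grids = list(KNN = list(k = 3L)), seed = 1)
  expect_equal(nrow(g), 1L)
  expect_equal(attr(g, "best_spec")$algorithm, "KNN")
  expect_equal(attr(g, "best_spec")$hyper$k, 3L)
  expect_s3_class(glance(g), "tbl_df")
})

test_that("prediction bins queries by DM and flags beyond-domain queries", {
  act <- fix_activity()
  lab <- label_activity(act$activities)
  spec <- model_spec("KNN", "MACCS166", list(k = 3L))
  queries <- c(lab$canonical_smiles[lab$kept][1:5],
               "OC(CS)C(O)CS")   # far from every scaffold in the set
  pr <- predict_with_confidence(spec, queries, lab, seed = 1)
  expect_equal(nrow(pr), 6L)
  expect_true(all(pr$confidence_bin %in% c("Q1", "Q2", "Q3", "Q4", "BEYOND")))
  # a training-set member is close to the model
  expect_true(pr$confidence_bin[1] %in% c("Q1", "Q2"))
  # per-bin counts partition the queries
  expect_equal(sum(table(pr$confidence_bin)), 6L)
})
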