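test_that("descriptor vector matches definitional values", {
  p <- profile_library(c("CCO", "c1ccccc1"))
  eth <- p[1, ]
  expect_equal(eth$hbd, 1L)
  expect_equal(eth$nrotb, 0L)
  # independent oracle: sum of standard atomic weights C2H6O
  expect_equal(eth$mw, 2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 1e-3)
  expect_equal(p$tpsa[2], 0)
  expect_true(all(p$qed >= 0 & p$qed <= 1))
  expect_true(all(p$sascore >= 1 & p$sascore <= 10))
  # ESOL regression at hand-checked inputs
  expect_equal(esol(0, 100, 0, 0), 0.16 - 0.62)
  expect_error(profile_library("not_a_smiles"), "unparseable")
})

test_that("descriptors are invariant to atom-order permutation", {
  pairs <- list(c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
                c("OCCN", "NCCO"),
                c("Cc1ccc(O)cc1", "Oc1ccc(C)cc1"))
  for (pr in pairs) {
    p <- profile_library(pr)
    for (col in c("mw", "hbd", "hba", "tpsa", "logp", "nrotb", "qed",
                  "sascore")) {
      expect_equal(p[[col]][1], p[[col]][2], tolerance = 1e-9,
                   label = paste(col, pr[1]))
    }
    fp1 <- fp_matrix(pr[1], "ECFP4_1024")
    fp2 <- fp_matrix(pr[2], "ECFP4_1024")
    expect_identical(fp1, fp2)
  }
})

test_that("QED reproduces the published parameterization", {
  # expected values computed once with the original parameterization's
  # reference implementation on molecules where the underlying property
  # definitions coincide
  probes <- c(caffeine = "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
              ethanol = "CCO",
              benzene = "c1ccccc1",
              ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  expected <- c(caffeine = 0.53846, ethanol = 0.40681,
                benzene = 0.44263, ibuprofen = 0.82160)
  q <- qed_score(unname(probes))
  expect_equal(unname(q$qed), unname(expected), tolerance = 1e-4)
  expect_equal(q$attractive, expected >= 0.67, ignore_attr = TRUE)
})

test_that("SAscore is bounded, rank-correlates with the original and flags
          complex molecules", {
  probes <- c("CCO",
              "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
              "CC(=O)Oc1ccccc1C(=O)O",
              "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
              "c1ccc2c(c1)ccc1ccccc12",
              "CC1(C)C2CCC1(C)C(=O)C2",
              "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
              "CC(C)CC1CCC2(CC1)OC1CC3C4CCC5CC(O)CCC5(C)C4CCC3(C)C1O2",
              "OCC1OC(O)C(O)C(O)C1O")
  # reference scores computed once with the original implementation
  reference <- c(1.980, 2.192, 1.580, 2.298, 1.197, 4.120, 3.585, 5.139,
                 3.595)
  s <- sa_score(probes)
  expect_true(all(s >= 1 & s <= 10))
  expect_gt(stats::cor(s, reference, method = "spearman"), 0.7)
  # monotonicity sanity: ethanol is easier than a fused polycyclic product
  expect_lt(s[1], s[8])
})

test_that("de novo score follows the range/penalty rule", {
  prof <- profile_library(c("CCO", "c1ccc2nc(ccc2c1)CCO"))
  # ranges containing every observed value -> score 1
  wide <- lapply(prof[, SCORE_DESCRIPTORS], function(x) range(x) + c(-1, 1))
  rules_all <- score_rules(wide, penalty_patterns = character(0))
  s <- denovo_score(prof, rules_all)
  expect_equal(s$denovo_score, c(1, 1))
  # ranges excluding everything -> 0
  rules_none <- score_rules(lapply(wide, function(r) r + 1e6),
                            penalty_patterns = character(0))
  expect_equal(denovo_score(prof, rules_none)$denovo_score, c(0, 0))
  # half-penalty on a matching substructure halves the score
  rules_pen <- score_rules(wide, penalty_patterns = "OCC",
                           penalty_value = 0.5)
  expect_equal(denovo_score(prof, rules_pen)$denovo_score, c(0.5, 0.5))
  # removing a penalty pattern never decreases the score
  expect_true(all(denovo_score(prof, rules_all)$denovo_score >=
                    denovo_score(prof, rules_pen)$denovo_score))
  # widening any range never decreases the score
  mid <- lapply(prof[, SCORE_DESCRIPTORS], function(x) {
    c(stats::median(x), stats::median(x))
  })
  narrow <- denovo_score(prof, score_rules(mid, penalty_patterns = character(0)))
  expect_true(all(s$denovo_score >= narrow$denovo_score))
  # unknown descriptor is a configuration error
  expect_error(score_rules(list(foo = c(0, 1))), "unknown descriptor")
  # mean +/- sd derivation covers the means
  rules_d <- derive_score_rules(prof)
  expect_true(all(vapply(SCORE_DESCRIPTORS, function(d) {
    r <- rules_d$ranges[[d]]
    m <- mean(prof[[d]])
    m >= r[1] && m <= r[2]
  }, logical(1))))
})

test_that("ligand efficiency is score over heavy atoms", {
  expect_equal(ligand_efficiency(-6.0, 30), -0.2)
  expect_equal(ligand_efficiency(-8.4, 28), -0.3)
  expect_error(ligand_efficiency(-5, 0), "heavy_atoms")
  tab <- gen_docking_table(10, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, c("id", "program", "score", "heavy_atoms")], f,
            row.names = FALSE)
  back <- read_docking_table(f)
  expect_equal(back$le, back$score / back$heavy_atoms)
  expect_true(all(abs(back$le) <= abs(back$score)))
  expect_equal(sign(back$le), sign(back$score))
})

test_that("score rules survive a YAML round trip", {
  rules <- score_rules(list(mw = c(200, 500), logp = c(-1, 5)),
                       penalty_patterns = c("C1OC(CO)C(O)C1O"),
                       penalty_value = 0.75)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_score_rules(rules, f)
  back <- read_score_rules(f)
  expect_equal(back$ranges, rules$ranges)
  expect_equal(back$penalty_patterns, rules$penalty_patterns)
  expect_equal(back$penalty_value, rules$penalty_value)
})
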