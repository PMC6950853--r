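# Evaluation metrics and the activity oracle.

test_that("success rate counts generated molecules satisfying the target predicate", {
  rec <- transform_records(c("CCO", "CC", "CCC", "CCCC"),
                           c("CCCl", "CCF", "CCI", "CCO"))
  halo <- set_definition(include_smarts = halogen_patterns())
  expect_equal(success_rate(rec, halo), 0.75)
  expect_equal(success_rate(rec, function(m) TRUE), 1)
  expect_equal(success_rate(rec, function(m) FALSE), 0)
  expect_error(success_rate(rec[0, ], halo), "non-empty")
})

test_that("non-identity and uniqueness count canonical forms", {
  rec <- transform_records(c("CCO", "CC", "CCC", "CCCC", "CCO"),
                           c("OCC", "CCF", "CCI", "CCCl", "CCBr"))
  expect_equal(non_identity(rec), 0.8)   # OCC == CCO canonically
  rec2 <- transform_records(rep("CC", 4), rep("CCO", 4))
  expect_equal(uniqueness(rec2), 0.25)
  expect_equal(diversity(rec2), 0.25)
  rec3 <- transform_records(c("CC", "CCC", "CCCC"), c("CCO", "OCC", "CCF"))
  expect_equal(uniqueness(rec3), 2 / 3)
  # bounds
  expect_gte(uniqueness(rec), 1 / nrow(rec))
  expect_lte(non_identity(rec), 1)
  # identity generator
  idrec <- transform_records(c("CCO", "CC"), c("CCO", "CC"))
  expect_equal(non_identity(idrec), 0)
  expect_equal(success_rate(idrec, function(m) m == "CCO",
                            exclude_identity = TRUE), 0)
})

test_that("constrained reports aggregate successes with the sample formulas", {
  mk <- function(success, imp = NA, sim = NA) {
    structure(list(start_molecule = "a", best_molecule = "b",
                   improvement = imp, similarity = sim, success = success,
                   path_index = 1L, start_score = 0, delta = 0.2),
              class = "constrained_result")
  }
  rep2 <- constrained_report(list(mk(TRUE, 1, 0.5), mk(TRUE, 3, 0.7),
                                  mk(FALSE)), delta = 0.2)
  expect_equal(rep2$improvement_mean, 2)
  expect_equal(rep2$improvement_sd, stats::sd(c(1, 3)))
  expect_equal(rep2$similarity_mean, 0.6)
  expect_equal(rep2$success_percent, 100 * 2 / 3)
  # all failures: success 0, means flagged undefined
  rep0 <- constrained_report(list(mk(FALSE), mk(FALSE)), delta = 0.4)
  expect_equal(rep0$success_percent, 0)
  expect_true(is.na(rep0$improvement_mean))
  expect_output(print(rep0), "undefined")
})

test_that("success percentage never increases with the similarity threshold", {
  b <- toy_backend(2, 0.5)
  scorer <- toy_scorer(b)
  gen <- shift_generator(c(2, 1))
  starts <- c("z:0,0", "z:1,-1", "z:-2,0", "z:0,2")
  prev <- Inf
  for (delta in c(0, 0.2, 0.4, 0.8)) {
    res <- lapply(starts, function(s)
      constrained_optimize(s, gen, b, scorer, delta = delta))
    sp <- constrained_report(res, delta)$success_percent
    expect_lte(sp, prev)
    prev <- sp
  }
})

test_that("the activity oracle separates a fingerprint-visible class", {
  # activity = presence of chlorine, visible to circular fingerprints
  actives <- c("CCCl", "CCCCl", "CC(C)Cl", "ClCc1ccccc1", "Clc1ccccc1",
               "ClCCCl", "CCCCCl", "ClCCC(C)C", "Clc1ccc(C)cc1", "ClCCO")
  inactives <- c("CCO", "CCCC", "CC(C)O", "OCc1ccccc1", "Oc1ccccc1",
                 "OCCO", "CCCCO", "OCCC(C)C", "Cc1ccc(O)cc1", "CCN")
  labels <- rep(c("active", "inactive"), each = 10)
  oracle <- fit_activity_oracle(c(actives, inactives), labels, seed = 7,
                                ntree = 200)
  expect_gt(oracle$cv_auc, 0.9)
  s <- oracle$score(c("CCCCCCl", "CCCCCO"))
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(s[1], s[2])
  # refit under the same seed gives identical scores
  oracle2 <- fit_activity_oracle(c(actives, inactives), labels, seed = 7,
                                 ntree = 200)
  expect_identical(oracle2$score(c("CCCCCCl", "CCCCCO")), s)
  expect_error(fit_activity_oracle(actives, rep("active", 10)),
               "two classes")
})

test_that("activity reports measure the gain and degenerate cases exactly", {
  x <- c("CCO", "CCCC", "CC(C)O")
  # identity generator: zero gain
  const_oracle <- function(m) rep(0.5, length(m))
  r <- activity_report(const_oracle, x, x)
  expect_equal(r$mean_gain, 0)
  expect_equal(r$mean_activity_start, 0.5)
  expect_equal(r$mean_activity_generated, 0.5)
  expect_equal(r$non_identity, 0)
  # a scorer that rewards chlorination sees the shift
  chloro <- function(m) as.numeric(matches_any_smarts(m, "[!#1]Cl"))
  r2 <- activity_report(chloro, x, c("CCCl", "CCCCl", "CC(C)Cl"))
  expect_equal(r2$mean_gain, 1)
  expect_equal(r2$success_rate, 1)
  expect_equal(r2$non_identity, 1)
})
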