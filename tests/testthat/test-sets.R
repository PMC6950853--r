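# X/Y set construction.

test_that("set definitions validate their criteria", {
  expect_error(set_definition(), "at least one criterion")
  expect_error(set_definition(property_rule = list(
    property = "penalized_logp", comparator = "~", threshold = 1)))
  expect_error(set_definition(property_rule = list(
    property = "penalized_logp", comparator = ">=",
    threshold = 1, quantile = 0.5)), "exactly one")
  expect_s3_class(set_definition(include_smarts = "C#N"), "set_definition")
})

test_that("halogen task sets contain only qualifying molecules", {
  lib <- toy_smiles_library()
  y_def <- set_definition(include_smarts = halogen_patterns())
  x_def <- set_definition(exclude_smarts = halogen_patterns())
  sets <- build_sets(lib, x_def, y_def,
                     sizes = c(x_train = 10, x_test = 4,
                               y_train = 10, y_test = 4), seed = 3)
  for (m in c(sets$x_train, sets$x_test))
    expect_false(matches_any_smarts(m, halogen_patterns()))
  for (m in c(sets$y_train, sets$y_test))
    expect_true(matches_any_smarts(m, halogen_patterns()))
  # train/test disjoint within each letter
  expect_length(intersect(sets$x_train, sets$x_test), 0)
  expect_length(intersect(sets$y_train, sets$y_test), 0)
  # reproducible under the seed
  sets2 <- build_sets(lib, x_def, y_def,
                      sizes = c(x_train = 10, x_test = 4,
                                y_train = 10, y_test = 4), seed = 3)
  expect_identical(sets[1:4], sets2[1:4])
})

test_that("bioisostere sets are mutually exclusive on CN / CF3", {
  lib <- toy_smiles_library()
  cn <- "C#N"; cf3 <- "C(F)(F)F"
  x_def <- set_definition(include_smarts = cn, exclude_smarts = cf3)
  y_def <- set_definition(include_smarts = cf3, exclude_smarts = cn)
  sets <- build_sets(lib, x_def, y_def,
                     sizes = c(x_train = 3, x_test = 2,
                               y_train = 3, y_test = 2), seed = 1)
  for (m in c(sets$x_train, sets$x_test)) {
    expect_true(matches_any_smarts(m, cn))
    expect_false(matches_any_smarts(m, cf3))
  }
  for (m in c(sets$y_train, sets$y_test)) {
    expect_true(matches_any_smarts(m, cf3))
    expect_false(matches_any_smarts(m, cn))
  }
})

test_that("aromatic-ring task separates {2} from {1,3}", {
  lib <- toy_smiles_library()
  x_def <- set_definition(ring_counts = 2L)
  y_def <- set_definition(ring_counts = c(1L, 3L))
  sets <- build_sets(lib, x_def, y_def,
                     sizes = c(x_train = 5, x_test = 2,
                               y_train = 8, y_test = 3), seed = 2)
  expect_true(all(count_aromatic_rings(c(sets$x_train, sets$x_test)) == 2L))
  expect_true(all(count_aromatic_rings(c(sets$y_train, sets$y_test))
                  %in% c(1L, 3L)))
})

test_that("quantile property rules reproduce the sort-based split exactly", {
  # 100 molecules with a strictly increasing mock property
  mols <- vapply(2:101, function(k) paste(rep("C", k), collapse = ""),
                 character(1))
  sizes <- vapply(mols, nchar, numeric(1))
  prop <- function(m) vapply(m, nchar, numeric(1), USE.NAMES = FALSE)
  y_def <- set_definition(property_rule = list(
    property = prop, comparator = ">=", quantile = 0.8))
  x_def <- set_definition(property_rule = list(
    property = prop, comparator = "<", quantile = 0.8))
  sets <- build_sets(mols, x_def, y_def,
                     sizes = c(x_train = 70, x_test = 10,
                               y_train = 15, y_test = 5), seed = 1)
  top20 <- canonicalize(mols[order(-sizes)][1:20])
  expect_setequal(c(sets$y_train, sets$y_test), top20)
  expect_length(intersect(c(sets$x_train, sets$x_test), top20), 0)
})

test_that("median splits balance the two sides within one molecule", {
  mols <- vapply(2:32, function(k) paste(rep("C", k), collapse = ""),
                 character(1))
  prop <- function(m) vapply(m, nchar, numeric(1), USE.NAMES = FALSE)
  x_def <- set_definition(property_rule = list(
    property = prop, comparator = "<=", quantile = 0.5))
  y_def <- set_definition(property_rule = list(
    property = prop, comparator = ">", quantile = 0.5))
  sets <- build_sets(mols, x_def, y_def,
                     sizes = c(x_train = 10, x_test = 0,
                               y_train = 10, y_test = 0), seed = 1)
  expect_lte(abs(sets$meta$n_x_pool - sets$meta$n_y_pool), 1)
})

test_that("molecules qualifying for both or neither set are excluded", {
  mols <- c("CCCl", "CCO", "CC", "CCF")
  x_def <- set_definition(exclude_smarts = "[!#1]Cl")  # CCO, CC, CCF
  y_def <- set_definition(include_smarts = c("[!#1]Cl", "[!#1]F"))
  sets <- build_sets(mols, x_def, y_def,
                     sizes = c(x_train = 2, x_test = 0,
                               y_train = 1, y_test = 0), seed = 1)
  # CCF satisfies both definitions -> in neither pool
  expect_equal(sets$meta$n_x_pool, 2)   # CCO, CC
  expect_equal(sets$meta$n_y_pool, 1)   # CCCl
})

test_that("insufficient candidates raise a sizing error with counts", {
  mols <- c("CCCl", "CCO")
  x_def <- set_definition(exclude_smarts = "[!#1]Cl")
  y_def <- set_definition(include_smarts = "[!#1]Cl")
  expect_error(
    build_sets(mols, x_def, y_def,
               sizes = c(x_train = 5, x_test = 1, y_train = 1, y_test = 0)),
    "need 6, have 1")
})

test_that("duplicates are removed by canonical form before splitting", {
  mols <- c("CCO", "OCC", "C(C)O", "CCCl", "ClCC")
  x_def <- set_definition(exclude_smarts = "[!#1]Cl")
  y_def <- set_definition(include_smarts = "[!#1]Cl")
  sets <- build_sets(mols, x_def, y_def,
                     sizes = c(x_train = 1, x_test = 0,
                               y_train = 1, y_test = 0), seed = 1)
  expect_equal(sets$meta$n_unique, 2)
})

test_that("set definitions and molecule sets round-trip through files", {
  def <- set_definition(include_smarts = c("C#N"),
                        exclude_smarts = c("C(F)(F)F"),
                        ring_counts = c(1L, 3L))
  path <- file.path(withr::local_tempdir(), "def.json")
  write_set_definition(def, path)
  back <- read_set_definition(path)
  expect_equal(back$include_smarts, def$include_smarts)
  expect_equal(back$exclude_smarts, def$exclude_smarts)
  expect_equal(back$ring_counts, def$ring_counts)

  lib <- toy_smiles_library()
  sets <- build_sets(lib,
                     set_definition(exclude_smarts = halogen_patterns()),
                     set_definition(include_smarts = halogen_patterns()),
                     sizes = c(x_train = 4, x_test = 2,
                               y_train = 4, y_test = 2), seed = 1)
  csv <- file.path(withr::local_tempdir(), "sets.csv")
  write_molecule_sets(sets, csv)
  d <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_setequal(d$label[d$smiles %in% sets$x_train], "X_train")
  expect_equal(nrow(d), 12)
})
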