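# Latent paths and optimization procedures.

test_that("latent paths are straight lines with equal steps and exact endpoints", {
  p <- latent_path(c(0, 0), c(1, 1), K = 3)
  expect_equal(p, rbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  # degenerate path: x == G(x)
  pd <- latent_path(c(2, 3), c(2, 3), K = 5)
  expect_true(all(apply(pd, 1, function(r) all(r == c(2, 3)))))
  # K = 80: all consecutive differences equal (gx - x) / 79
  x <- c(-1, 0.5, 2); gx <- c(3, -0.5, 0)
  p80 <- latent_path(x, gx, K = 80)
  expect_equal(nrow(p80), 80)
  expect_equal(p80[1, ], x)
  expect_equal(p80[80, ], gx)
  diffs <- diff(p80)
  for (i in seq_len(nrow(diffs)))
    expect_equal(diffs[i, ], (gx - x) / 79)
  expect_error(latent_path(c(0, 0), c(1, 1), K = 1), "K")
  expect_error(latent_path(c(0, 0), c(1, 1, 2), K = 3), "dimension")
})

test_that("constrained optimization fails cleanly under an identity generator", {
  b <- toy_backend(2, 0.5)
  r <- constrained_optimize("z:1,1", shift_generator(0), b,
                            toy_scorer(b), delta = 0)
  expect_false(r$success)
  expect_true(is.na(r$best_molecule))
  expect_output(print(r), "no molecule")
})

test_that("constrained optimization picks the argmax over decoded path points", {
  b <- toy_backend(2, 0.5)
  scorer <- toy_scorer(b)
  # G adds +2 along the property direction; delta 0 admits everything
  r <- constrained_optimize("z:0,0", shift_generator(c(2, 0)), b, scorer,
                            delta = 0, K = 80)
  expect_true(r$success)
  expect_identical(r$best_molecule, "z:4,0")  # endpoint cell (2, 0)
  expect_equal(r$improvement, 2)              # grid-exact here
  # enumeration oracle: best is argmax of the scorer over all decodes
  path <- latent_path(b$encode("z:0,0"), b$encode("z:0,0") + c(2, 0), 80)
  decs <- unique(vapply(1:80, function(i) b$decode(path[i, ]), character(1)))
  decs <- setdiff(decs, "z:0,0")
  expect_equal(r$improvement, max(scorer(decs)) - scorer("z:0,0"))
  # delta = 1 only admits the identical molecule, which is excluded
  r1 <- constrained_optimize("z:0,0", shift_generator(c(2, 0)), b, scorer,
                             delta = 1)
  expect_false(r1$success)
})

test_that("improvement is monotone non-increasing in the similarity threshold", {
  b <- toy_backend(2, 0.5)
  scorer <- toy_scorer(b)
  gen <- shift_generator(c(3, -1))
  prev <- Inf
  for (delta in c(0, 0.1, 0.25, 0.5)) {
    r <- constrained_optimize("z:1,0", gen, b, scorer, delta = delta)
    imp <- if (r$success) r$improvement else -Inf
    expect_lte(imp, prev)
    prev <- imp
  }
})

test_that("intermediate steps are the equal-interval decodes of the path", {
  b <- toy_backend(2, 0.5)
  gen <- shift_generator(c(2, 0))
  # steps = 2: endpoints only
  two <- intermediate_transform("z:0,0", gen, b, steps = 2)
  expect_equal(as.character(two), c("z:0,0", "z:4,0"))
  # identity generator: steps copies of the starting molecule, flagged
  idd <- intermediate_transform("z:1,1", shift_generator(0), b, steps = 4)
  expect_equal(as.character(idd), rep("z:1,1", 4))
  expect_equal(attr(idd, "duplicated"), c(FALSE, TRUE, TRUE, TRUE))
  # the distinct molecules are a subset of the K = 80 path decodes
  ten <- intermediate_transform("z:0,0", gen, b, steps = 10)
  path <- latent_path(b$encode("z:0,0"), c(2, 0), 80)
  all80 <- vapply(1:80, function(i) b$decode(path[i, ]), character(1))
  expect_true(all(unique(as.character(ten)) %in% all80))
})

test_that("iterative optimization composes the generator in latent space", {
  b <- toy_backend(4, 0.5)
  gen <- shift_generator(c(1, 0, 0, 0))
  out <- iterative_optimize("z:0,0,0,0", gen, b, iterations = 5)
  scorer <- toy_scorer(b)
  f <- scorer(out)
  # property increases by ~1 per iteration (grid-exact for this shift)
  expect_equal(f, 1:5)
  # one iteration is decode(G(encode(m)))
  one <- iterative_optimize("z:0,0,0,0", gen, b, iterations = 1)
  expect_identical(one, b$decode(gen(b$encode("z:0,0,0,0"))))
  # identity generator: copies of the starting decode
  ido <- iterative_optimize("z:2,0,0,0", shift_generator(0), b, 3)
  expect_equal(ido, rep("z:2,0,0,0", 3))
  # similarity to the start is non-increasing along iterations
  sims <- vapply(out, function(m) mol_similarity("z:0,0,0,0", m, backend = b),
                 numeric(1))
  expect_true(all(diff(sims) <= 0))
})

test_that("a fitted model plugs into the optimizers as the generator", {
  task <- make_toy_task(quick_task_spec())
  m <- mol_cyclegan(task$x_train, task$y_train, epochs = 1, seed = 1)
  start <- task$backend$decode(task$x_test[1, ])
  r <- constrained_optimize(start, m, task$backend,
                            toy_scorer(task$backend), delta = 0, K = 10)
  expect_s3_class(r, "constrained_result")
  out <- iterative_optimize(start, m, task$backend, iterations = 2)
  expect_length(out, 2)
})
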