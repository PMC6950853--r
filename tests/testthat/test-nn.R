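# Network architecture contracts and gradient correctness.

test_that("architecture specs encode the two variants", {
  gs <- generator_spec("structural")
  expect_equal(gs$residual_blocks, 1L)
  expect_true(gs$trailing_dense)
  gp <- generator_spec("physicochemical")
  expect_equal(gp$residual_blocks, 4L)
  expect_false(gp$trailing_dense)
  expect_equal(discriminator_spec("structural")$layer_sizes,
               c(56L, 42L, 28L, 14L, 7L, 1L))
  expect_equal(discriminator_spec("physicochemical")$layer_sizes,
               c(48L, 36L, 28L, 18L, 12L, 7L, 1L))
  expect_error(discriminator_spec(layer_sizes = c(8L, 4L)), "size 1")
})

test_that("generator output keeps the latent dimension and is deterministic at inference", {
  fx <- tiny_gan_fixture(d = 5L, n = 8L)
  out <- forward_generator(fx$G, fx$x[, 1:5])
  expect_equal(dim(out), dim(fx$x))
  expect_identical(out, forward_generator(fx$G, fx$x))
  # vector in, vector out
  v <- forward_generator(fx$G, fx$x[1, ])
  expect_length(v, 5L)
  expect_equal(v, out[1, ], ignore_attr = TRUE)
  expect_error(forward_generator(fx$G, fx$x[, 1:3]))
})

test_that("with zeroed residual blocks the structural generator reduces to its trailing dense layer", {
  # hand-built 2-unit example: residual path passes z through untouched
  # (dense weights 0 -> batchnorm of 0 -> leaky-ReLU(0) = 0), so the output
  # is z %*% Wo + bo
  d <- 2L
  net <- molcycle:::new_generator(d, generator_spec("structural", units = d),
                                  "gaussian")
  net$params$W1[] <- 0
  net$params$Wo <- matrix(c(2, 0, 1, -1), 2, 2)
  net$params$bo <- c(0.5, -0.5)
  z <- c(1, 3)
  expect_equal(forward_generator(net, z),
               as.numeric(z %*% net$params$Wo + net$params$bo))
})

test_that("generator and discriminator gradients match finite differences", {
  fx <- tiny_gan_fixture(d = 4L, n = 6L, seed = 42L)
  w <- loss_weights(0.3, 0.1)
  xb <- fx$x; yb <- fx$y; n <- fx$n

  loss_fn <- function(G, Fn, DY) {
    gx <- molcycle:::gen_forward(G, xb, training = TRUE,
                                 update_state = FALSE)$Y
    fy <- molcycle:::gen_forward(Fn, yb, training = TRUE,
                                 update_state = FALSE)$Y
    fgx <- molcycle:::gen_forward(Fn, gx, training = TRUE,
                                  update_state = FALSE)$Y
    gfy <- molcycle:::gen_forward(G, fy, training = TRUE,
                                  update_state = FALSE)$Y
    s <- molcycle:::disc_forward(DY, gx, training = TRUE)$S
    0.5 * mean((s - 1)^2) + w$lambda1 * cycle_loss(xb, fgx, yb, gfy) +
      w$lambda2 * identity_loss(xb, gx, yb, fy)
  }

  # analytic gradients via the package's backward passes
  fG <- molcycle:::gen_forward(fx$G, xb, training = TRUE, cache = TRUE,
                               update_state = FALSE)
  fF <- molcycle:::gen_forward(fx$F, yb, training = TRUE, cache = TRUE,
                               update_state = FALSE)
  fFG <- molcycle:::gen_forward(fx$F, fG$Y, training = TRUE, cache = TRUE,
                                update_state = FALSE)
  fGF <- molcycle:::gen_forward(fx$G, fF$Y, training = TRUE, cache = TRUE,
                                update_state = FALSE)
  sG <- molcycle:::disc_forward(fx$D_Y, fG$Y, training = TRUE, cache = TRUE)
  dbk <- molcycle:::disc_backward(fx$D_Y, sG, (sG$S - 1) / n)
  d_gx <- dbk$dX + 0.1 * sign(fG$Y - xb) / n
  bF2 <- molcycle:::gen_backward(fx$F, fFG, 0.3 * sign(fFG$Y - xb) / n)
  d_gx <- d_gx + bF2$dX
  bG1 <- molcycle:::gen_backward(fx$G, fG, d_gx)
  bG2 <- molcycle:::gen_backward(fx$G, fGF, 0.3 * sign(fGF$Y - yb) / n)
  d_fy <- bG2$dX + 0.1 * sign(fF$Y - yb) / n
  bF1 <- molcycle:::gen_backward(fx$F, fF, d_fy)
  gG <- molcycle:::.add_grads(bG1$grads, bG2$grads)
  gF <- molcycle:::.add_grads(bF1$grads, bF2$grads)

  eps <- 1e-6
  withr::local_seed(3)
  for (spec in list(list(net = "G", grads = gG),
                    list(net = "F", grads = gF))) {
    net0 <- fx[[spec$net]]
    for (pname in names(net0$params)) {
      p <- net0$params[[pname]]
      for (k in sample(length(p), min(4, length(p)))) {
        np <- net0; np$params[[pname]][k] <- p[k] + eps
        nm <- net0; nm$params[[pname]][k] <- p[k] - eps
        lp <- if (spec$net == "G") loss_fn(np, fx$F, fx$D_Y)
              else loss_fn(fx$G, np, fx$D_Y)
        lm <- if (spec$net == "G") loss_fn(nm, fx$F, fx$D_Y)
              else loss_fn(fx$G, nm, fx$D_Y)
        num <- (lp - lm) / (2 * eps)
        expect_equal(spec$grads[[pname]][k], num, tolerance = 1e-5)
      }
    }
  }

  # discriminator gradients on its own loss
  d_loss <- function(DY) {
    sr <- molcycle:::disc_forward(DY, yb, training = TRUE)$S
    sf <- molcycle:::disc_forward(DY, fG$Y, training = TRUE)$S
    discriminator_loss(sr, sf)
  }
  fr <- molcycle:::disc_forward(fx$D_Y, yb, training = TRUE, cache = TRUE)
  ff <- molcycle:::disc_forward(fx$D_Y, fG$Y, training = TRUE, cache = TRUE)
  gD <- molcycle:::.add_grads(
    molcycle:::disc_backward(fx$D_Y, fr, (fr$S - 1) / n)$grads,
    molcycle:::disc_backward(fx$D_Y, ff, ff$S / n)$grads)
  for (pname in names(fx$D_Y$params)) {
    p <- fx$D_Y$params[[pname]]
    for (k in sample(length(p), min(4, length(p)))) {
      np <- fx$D_Y; np$params[[pname]][k] <- p[k] + eps
      nm <- fx$D_Y; nm$params[[pname]][k] <- p[k] - eps
      num <- (d_loss(np) - d_loss(nm)) / (2 * eps)
      expect_equal(gD[[pname]][k], num, tolerance = 1e-5)
    }
  }
})

test_that("batched indices partition the samples and reproduce under a seed", {
  b <- make_batches(5, 2, seed = 4)
  expect_equal(lengths(b), c(`1` = 2L, `2` = 2L, `3` = 1L),
               ignore_attr = TRUE)
  expect_setequal(unlist(b), 1:5)
  expect_identical(make_batches(10, 3, seed = 9), make_batches(10, 3, seed = 9))
  expect_error(make_batches(5, 0), "batch_size")
})
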