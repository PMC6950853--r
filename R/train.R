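# Model fitting: alternating least-squares-GAN optimization of the two
# generators and two discriminators with Adam.

#' Fit a latent-space CycleGAN between two molecule sets
#'
#' Trains generators `G: X -> Y` and `F: Y -> X` together with discriminators
#' `D_X`, `D_Y` on unpaired latent embeddings of the two sets. Each training
#' step samples one batch per set, updates the discriminators on the
#' least-squares [discriminator_loss()], then updates both generators jointly
#' on the [total_generator_loss()] (adversarial + cycle + identity terms).
#' Training is fully reproducible under `seed`; batch-normalization
#' statistics are frozen at inference.
#'
#' @param x latent matrix of the X set (one row per molecule, `d` columns).
#' @param y latent matrix of the Y set (same number of columns).
#' @param variant `"structural"` (1 residual block + trailing dense in the
#'   generators; 100 epochs default) or `"physicochemical"` (4 residual
#'   blocks; 300 epochs default).
#' @param weights a [loss_weights()] object (defaults `lambda1 = 0.3`,
#'   `lambda2 = 0.1`).
#' @param epochs number of epochs; `NULL` for the variant default. 0 returns
#'   the initialized, untrained model with an empty log.
#' @param batch_size samples per step (default 32). When the sets differ in
#'   size each epoch iterates over the larger set and draws the smaller one
#'   with replacement per step.
#' @param learning_rate Adam learning rate (default 1e-4; beta1/beta2 at
#'   their conventional 0.9/0.999).
#' @param seed integer seed for initialization and batching.
#' @param init generator initialization: `"identity"` (default; the
#'   generators start as the exact identity map, so an untrained model
#'   changes nothing) or `"gaussian"` (fan-in-scaled Gaussian everywhere).
#' @param verbose print per-epoch losses.
#' @return an object of class `mol_cyclegan` with components `G`, `F`,
#'   `D_X`, `D_Y` (networks), `weights`, `dim`, `config`, and `log` (one row
#'   of loss summaries per epoch).
#' @seealso [predict.mol_cyclegan()], [constrained_optimize()],
#'   [save_cyclegan()]
#' @export
mol_cyclegan <- function(x, y,
                         variant = c("structural", "physicochemical"),
                         weights = loss_weights(),
                         epochs = NULL, batch_size = 32L,
                         learning_rate = 1e-4, seed = 1L,
                         init = c("gaussian", "identity"),
                         verbose = FALSE) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) >= 1L, nrow(y) >= 1L,
            ncol(x) == ncol(y), batch_size >= 1L, learning_rate > 0)
  if (!inherits(weights, "loss_weights"))
    weights <- do.call(loss_weights, as.list(weights))
  if (is.null(epochs))
    epochs <- if (variant == "structural") 100L else 300L
  if (epochs < 0L) stop("epochs must be >= 0")
  d <- ncol(x)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  gspec <- generator_spec(variant, units = d)
  dspec <- discriminator_spec(variant)
  G <- new_generator(d, gspec, init)
  F_ <- new_generator(d, gspec, init)
  D_X <- new_discriminator(d, dspec)
  D_Y <- new_discriminator(d, dspec)
  opt <- list(G = new_adam(G$params, learning_rate),
              F = new_adam(F_$params, learning_rate),
              D_X = new_adam(D_X$params, learning_rate),
              D_Y = new_adam(D_Y$params, learning_rate))

  log <- vector("list", epochs)
  nx <- nrow(x); ny <- nrow(y)
  nbig <- max(nx, ny)

  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    batches <- make_batches(nbig, batch_size)
    acc <- c(adv_G = 0, adv_F = 0, cyc = 0, idn = 0, total = 0,
             d_x = 0, d_y = 0)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      nb <- length(idx)
      xb <- if (nx == nbig) x[idx, , drop = FALSE]
        else x[sample.int(nx, nb, replace = TRUE), , drop = FALSE]
      yb <- if (ny == nbig) y[idx, , drop = FALSE]
        else y[sample.int(ny, nb, replace = TRUE), , drop = FALSE]

      ## ---- discriminator updates (generator outputs detached) ----
      fake_y <- gen_forward(G, xb, training = TRUE, update_state = FALSE)$Y
      fake_x <- gen_forward(F_, yb, training = TRUE, update_state = FALSE)$Y

      fy_real <- disc_forward(D_Y, yb, training = TRUE, cache = TRUE)
      fy_fake <- disc_forward(D_Y, fake_y, training = TRUE, cache = TRUE,
                              update_state = FALSE)
      l_dy <- discriminator_loss(fy_real$S, fy_fake$S)
      g_real <- disc_backward(D_Y, fy_real, (fy_real$S - 1) / nb)
      g_fake <- disc_backward(D_Y, fy_fake, fy_fake$S / nb)
      st <- adam_step(opt$D_Y, D_Y$params,
                      .add_grads(g_real$grads, g_fake$grads))
      opt$D_Y <- st$opt; D_Y$params <- st$params

      fx_real <- disc_forward(D_X, xb, training = TRUE, cache = TRUE)
      fx_fake <- disc_forward(D_X, fake_x, training = TRUE, cache = TRUE,
                              update_state = FALSE)
      l_dx <- discriminator_loss(fx_real$S, fx_fake$S)
      g_real <- disc_backward(D_X, fx_real, (fx_real$S - 1) / nb)
      g_fake <- disc_backward(D_X, fx_fake, fx_fake$S / nb)
      st <- adam_step(opt$D_X, D_X$params,
                      .add_grads(g_real$grads, g_fake$grads))
      opt$D_X <- st$opt; D_X$params <- st$params

      ## ---- joint generator update ----
      fG <- gen_forward(G, xb, training = TRUE, cache = TRUE)
      G$state <- fG$net$state
      gx <- fG$Y
      fF <- gen_forward(F_, yb, training = TRUE, cache = TRUE)
      F_$state <- fF$net$state
      fy <- fF$Y
      fFG <- gen_forward(F_, gx, training = TRUE, cache = TRUE,
                         update_state = FALSE)
      fgx <- fFG$Y
      fGF <- gen_forward(G, fy, training = TRUE, cache = TRUE,
                         update_state = FALSE)
      gfy <- fGF$Y
      sG <- disc_forward(D_Y, gx, training = TRUE, cache = TRUE,
                         update_state = FALSE)
      sF <- disc_forward(D_X, fy, training = TRUE, cache = TRUE,
                         update_state = FALSE)

      adv_G <- generator_adv_loss(sG$S)
      adv_F <- generator_adv_loss(sF$S)
      cyc <- cycle_loss(xb, fgx, yb, gfy)
      idn <- identity_loss(xb, gx, yb, fy)
      total <- adv_G + adv_F + weights$lambda1 * cyc + weights$lambda2 * idn
      if (!is.finite(total))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", step ", bi)

      # gradients into G(x): adversarial (through frozen D_Y), cycle
      # (through second use of F), identity
      dS <- (sG$S - 1) / nb
      d_gx <- disc_backward(D_Y, sG, dS)$dX
      d_fgx <- weights$lambda1 * sign(fgx - xb) / nb
      bF2 <- gen_backward(F_, fFG, d_fgx)
      d_gx <- d_gx + bF2$dX
      d_gx <- d_gx + weights$lambda2 * sign(gx - xb) / nb
      bG1 <- gen_backward(G, fG, d_gx)

      dS <- (sF$S - 1) / nb
      d_fy <- disc_backward(D_X, sF, dS)$dX
      d_gfy <- weights$lambda1 * sign(gfy - yb) / nb
      bG2 <- gen_backward(G, fGF, d_gfy)
      d_fy <- d_fy + bG2$dX
      d_fy <- d_fy + weights$lambda2 * sign(fy - yb) / nb
      bF1 <- gen_backward(F_, fF, d_fy)

      st <- adam_step(opt$G, G$params, .add_grads(bG1$grads, bG2$grads))
      opt$G <- st$opt; G$params <- st$params
      st <- adam_step(opt$F, F_$params, .add_grads(bF1$grads, bF2$grads))
      opt$F <- st$opt; F_$params <- st$params

      acc <- acc + c(adv_G, adv_F, cyc, idn, total, l_dx, l_dy)
    }
    acc <- acc / length(batches)
    log[[ep]] <- data.frame(epoch = ep, adv_G = acc[1], adv_F = acc[2],
                            cycle = acc[3], identity = acc[4],
                            total = acc[5], d_x = acc[6], d_y = acc[7],
                            seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf(
        "epoch %3d  total %.4f  cyc %.4f  id %.4f  dX %.4f  dY %.4f",
        ep, acc[5], acc[3], acc[4], acc[6], acc[7]))
  }

  log <- if (epochs > 0L) do.call(rbind, log) else
    data.frame(epoch = integer(0), adv_G = numeric(0), adv_F = numeric(0),
               cycle = numeric(0), identity = numeric(0), total = numeric(0),
               d_x = numeric(0), d_y = numeric(0), seconds = numeric(0))
  rownames(log) <- NULL
  if (any(!is.finite(as.matrix(log[, -1])))) {
    stop("training produced non-finite logged losses")
  }

  structure(list(G = G, F = F_, D_X = D_X, D_Y = D_Y,
                 weights = weights, dim = d,
                 config = list(variant = variant, epochs = epochs,
                               batch_size = as.integer(batch_size),
                               learning_rate = learning_rate,
                               seed = as.integer(seed), init = init,
                               n_x = nx, n_y = ny),
                 log = log, call = match.call()),
            class = "mol_cyclegan")
}

#' Seeded batching of sample indices
#'
#' A permutation of `1..n` chunked into consecutive batches; the last, short
#' batch is kept.
#'
#' @param n number of samples (>= 1).
#' @param batch_size batch size (>= 1).
#' @param seed optional integer seed; by default the current RNG stream is
#'   used (the trainer seeds it once per fit).
#' @return list of integer index vectors covering `1..n` exactly once.
#' @export
make_batches <- function(n, batch_size, seed = NULL) {
  stopifnot(n >= 1L)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!is.null(seed)) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(seed)
  }
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

#' @export
print.mol_cyclegan <- function(x, ...) {
  cat("Latent-space CycleGAN (", x$config$variant, " variant)\n", sep = "")
  cat("  latent dimension:", x$dim, "\n")
  cat("  lambda1 (cycle):", x$weights$lambda1,
      "  lambda2 (identity):", x$weights$lambda2, "\n")
  cat("  trained:", x$config$epochs, "epochs, batch", x$config$batch_size,
      ", lr", x$config$learning_rate, ", seed", x$config$seed, "\n")
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final losses: total %.4f (cycle %.4f, identity %.4f)\n",
                last$total, last$cycle, last$identity))
  }
  invisible(x)
}

#' @export
summary.mol_cyclegan <- function(object, ...) {
  out <- list(config = object$config, weights = object$weights,
              dim = object$dim,
              generator_spec = object$G$spec,
              discriminator_spec = object$D_X$spec,
              n_parameters = sum(vapply(
                c(object$G$params, object$F$params,
                  object$D_X$params, object$D_Y$params),
                length, numeric(1))),
              log = object$log)
  class(out) <- "summary.mol_cyclegan"
  out
}

#' @export
print.summary.mol_cyclegan <- function(x, ...) {
  cat("Latent-space CycleGAN —", x$config$variant, "variant\n")
  cat("  generators:", x$generator_spec$residual_blocks,
      "residual block(s)",
      if (x$generator_spec$trailing_dense) "+ trailing dense" else "",
      "of", x$generator_spec$units, "units\n")
  cat("  discriminators: layers",
      paste(x$discriminator_spec$layer_sizes, collapse = "-"), "\n")
  cat("  parameters:", x$n_parameters, "\n")
  cat("  lambda1:", x$weights$lambda1, " lambda2:", x$weights$lambda2, "\n")
  if (nrow(x$log) > 0) {
    cat("  loss trajectory (total): first",
        sprintf("%.4f", x$log$total[1]), "-> last",
        sprintf("%.4f", x$log$total[nrow(x$log)]), "\n")
  }
  invisible(x)
}

#' Apply a fitted CycleGAN to latent points
#'
#' `direction = "forward"` applies `G` (X to Y), `"backward"` applies `F`.
#' Inference uses frozen batch-normalization statistics, so repeated calls
#' with the same input are identical.
#'
#' @param object a fitted [mol_cyclegan()].
#' @param newdata latent vector or matrix (rows = points).
#' @param direction `"forward"` or `"backward"`.
#' @param ... unused.
#' @return generated latent points, same shape as `newdata`.
#' @export
predict.mol_cyclegan <- function(object, newdata,
                                 direction = c("forward", "backward"), ...) {
  direction <- match.arg(direction)
  net <- if (direction == "forward") object$G else object$F
  forward_generator(net, newdata)
}

#' @export
coef.mol_cyclegan <- function(object, ...) {
  list(G = object$G$params, F = object$F$params,
       D_X = object$D_X$params, D_Y = object$D_Y$params)
}

#' Plot training losses
#'
#' @param x a fitted [mol_cyclegan()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mol_cyclegan <- function(x, ...) {
  if (nrow(x$log) == 0) {
    warning("no training epochs to plot")
    return(invisible(x))
  }
  comp <- c("total", "cycle", "identity", "d_x", "d_y")
  graphics::matplot(x$log$epoch, as.matrix(x$log[comp]), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = comp, col = seq_along(comp),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' A checkpoint directory holds a JSON manifest (architecture, loss weights,
#' dimension, training configuration) plus the weight arrays; loading
#' restores bit-identical inference outputs.
#'
#' @param model a fitted [mol_cyclegan()].
#' @param dir checkpoint directory (created if missing).
#' @return `save_cyclegan` the directory invisibly; `load_cyclegan` the
#'   restored model.
#' @export
save_cyclegan <- function(model, dir) {
  stopifnot(inherits(model, "mol_cyclegan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "molcycle",
                   class = "mol_cyclegan",
                   dim = model$dim,
                   weights = unclass(model$weights),
                   config = model$config,
                   generator_spec = unclass(model$G$spec),
                   discriminator_spec = unclass(model$D_X$spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model[c("G", "F", "D_X", "D_Y", "log")],
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_cyclegan
#' @export
load_cyclegan <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$class, "mol_cyclegan"))
    stop("not a mol_cyclegan checkpoint: ", dir)
  nets <- readRDS(file.path(dir, "weights.rds"))
  structure(list(G = nets$G, F = nets$F, D_X = nets$D_X, D_Y = nets$D_Y,
                 weights = do.call(loss_weights, as.list(mf$weights)),
                 dim = mf$dim, config = mf$config, log = nets$log,
                 call = NULL),
            class = "mol_cyclegan")
}
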