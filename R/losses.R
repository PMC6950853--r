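# The training objective.
#
# Least-squares adversarial losses for both directions, an L1 cycle
# consistency term, and an L1 identity mapping term, combined as
#   L = L_adv(G, D_Y) + L_adv(F, D_X) + lambda1 * L_cyc + lambda2 * L_id .
# Discriminators are trained toward target 1 on real and 0 on generated
# points; generators minimize the least-squares distance of their fakes'
# scores to 1.

#' Loss weights
#'
#' `lambda1` weights the cycle-consistency term, `lambda2` the identity
#' mapping term. The defaults (0.3 and 0.1) are the values used throughout
#' the experiments; they control the balance between improvement of the
#' optimized property and similarity to the starting molecule.
#'
#' @param lambda1 non-negative cycle-consistency weight.
#' @param lambda2 non-negative identity-mapping weight.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.3, lambda2 = 0.1) {
  if (lambda1 < 0 || lambda2 < 0)
    stop("loss weights must be non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "loss_weights")
}

#' Least-squares adversarial loss
#'
#' `0.5 * mean((real - 1)^2) + 0.5 * mean(fake^2)`: the discriminator-side
#' least-squares GAN objective, where `real_scores` are the discriminator's
#' scores on genuine target-set points and `fake_scores` its scores on
#' generated points.
#'
#' @param real_scores,fake_scores non-empty numeric vectors of scores.
#' @return non-negative scalar loss.
#' @export
adversarial_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L)
    stop("adversarial loss needs non-empty score batches")
  0.5 * mean((real_scores - 1)^2) + 0.5 * mean(fake_scores^2)
}

#' Discriminator loss
#'
#' Identical in form to [adversarial_loss()] (real scores toward 1, generated
#' scores toward 0); kept as its own entry point because it is evaluated with
#' gradients blocked from the generator during training.
#'
#' @inheritParams adversarial_loss
#' @return non-negative scalar loss.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  adversarial_loss(real_scores, fake_scores)
}

# generator-side least-squares objective: fakes pushed toward score 1
generator_adv_loss <- function(fake_scores) {
  if (length(fake_scores) == 0L)
    stop("generator adversarial loss needs a non-empty score batch")
  0.5 * mean((fake_scores - 1)^2)
}

.check_paired <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (!all(dim(a) == dim(b)))
    stop("paired batches must have identical shape")
  list(a = a, b = b)
}

#' Cycle-consistency loss
#'
#' Mean L1 norm of `F(G(x)) - x` over the X batch plus mean L1 norm of
#' `G(F(y)) - y` over the Y batch.
#'
#' @param x_batch latent matrix of X points (rows).
#' @param fgx `F(G(x))` for the same rows.
#' @param y_batch latent matrix of Y points.
#' @param gfy `G(F(y))` for the same rows.
#' @return non-negative scalar loss.
#' @export
cycle_loss <- function(x_batch, fgx, y_batch, gfy) {
  px <- .check_paired(x_batch, fgx)
  py <- .check_paired(y_batch, gfy)
  mean(rowSums(abs(py$b - py$a))) + mean(rowSums(abs(px$b - px$a)))
}

#' Identity-mapping loss
#'
#' Mean L1 norm of `G(x) - x` over the X batch plus mean L1 norm of
#' `F(y) - y` over the Y batch; keeps generated points close to their inputs.
#'
#' @param x_batch latent matrix of X points.
#' @param gx `G(x)` for the same rows.
#' @param y_batch latent matrix of Y points.
#' @param fy `F(y)` for the same rows.
#' @return non-negative scalar loss.
#' @export
identity_loss <- function(x_batch, gx, y_batch, fy) {
  px <- .check_paired(x_batch, gx)
  py <- .check_paired(y_batch, fy)
  mean(rowSums(abs(py$b - py$a))) + mean(rowSums(abs(px$b - px$a)))
}

#' Total generator loss
#'
#' `adv_G + adv_F + lambda1 * cyc + lambda2 * idn`.
#'
#' @param adv_G,adv_F adversarial components for the two directions.
#' @param cyc cycle-consistency component.
#' @param idn identity-mapping component.
#' @param weights a [loss_weights()] object.
#' @return scalar total loss.
#' @export
total_generator_loss <- function(adv_G, adv_F, cyc, idn,
                                 weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) {
    weights <- do.call(loss_weights, as.list(weights))
  }
  adv_G + adv_F + weights$lambda1 * cyc + weights$lambda2 * idn
}
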