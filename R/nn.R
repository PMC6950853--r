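# Dense networks with batch normalization, in base R with explicit
# gradients.
#
# Two network kinds:
#   generator      — residual fully connected block(s)
#                    [dense(d->d, no bias) -> batchnorm -> leaky-ReLU, added
#                    to the input], optionally followed by a trailing linear
#                    dense layer (structural variant). Input and output share
#                    the latent dimension d.
#   discriminator  — a stack of dense layers (hidden: bias + leaky-ReLU;
#                    final: bias, linear) ending in a scalar score.
# Batch normalization lives in the generator blocks only: it uses per-batch
# statistics during training and frozen running statistics at inference.
# Discriminators are plain dense stacks — normalizing each scored batch
# would cancel the distribution shift between real and generated points
# that the discriminator has to detect, since real and fake batches are
# scored separately. Leaky-ReLU slope is 0.1 throughout. All gradients are
# hand-derived and verified against finite differences in the test suite.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9
.LRELU_ALPHA <- 0.1

#' Generator architecture specification
#'
#' The structural variant is one fully connected residual layer followed by
#' one dense layer; the physicochemical variant is four fully connected
#' residual layers. All layers have `units` units (the latent dimension).
#'
#' @param variant `"structural"` or `"physicochemical"`.
#' @param units layer width = latent dimension (default 56).
#' @return an object of class `generator_spec` with fields `variant`,
#'   `residual_blocks`, `units`, `trailing_dense`.
#' @export
generator_spec <- function(variant = c("structural", "physicochemical"),
                           units = 56L) {
  variant <- match.arg(variant)
  structure(list(variant = variant,
                 residual_blocks = if (variant == "structural") 1L else 4L,
                 units = as.integer(units),
                 trailing_dense = variant == "structural"),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Dense stacks ending in one unit: sizes 56-42-28-14-7-1 for the structural
#' variant and 48-36-28-18-12-7-1 for the physicochemical variant.
#'
#' @inheritParams generator_spec
#' @param layer_sizes integer vector of layer output sizes; last must be 1.
#' @return an object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(variant = c("structural", "physicochemical"),
                               layer_sizes = NULL) {
  variant <- match.arg(variant)
  if (is.null(layer_sizes)) {
    layer_sizes <- if (variant == "structural") c(56L, 42L, 28L, 14L, 7L, 1L)
    else c(48L, 36L, 28L, 18L, 12L, 7L, 1L)
  }
  layer_sizes <- as.integer(layer_sizes)
  if (layer_sizes[length(layer_sizes)] != 1L)
    stop("the last discriminator layer must have size 1")
  structure(list(variant = variant, layer_sizes = layer_sizes),
            class = "discriminator_spec")
}

# ---- initialization --------------------------------------------------------

# draws use the current RNG stream (the trainer seeds it)
.init_mat <- function(nin, nout, sd = 1 / sqrt(nin)) {
  matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
}

# generator parameter/state containers. "identity" initialization starts the
# network as the exact identity map (zero residual weights, identity trailing
# dense): a residual generator then deforms away from its input only as far
# as training pushes it, which is the premise of similarity-preserving
# optimization. "gaussian" is fan-in-scaled Gaussian everywhere.
new_generator <- function(d, spec, init = c("gaussian", "identity")) {
  init <- match.arg(init)
  nb <- spec$residual_blocks
  params <- list()
  state <- list()
  for (b in seq_len(nb)) {
    params[[paste0("W", b)]] <- if (init == "identity")
      matrix(0, d, d) else .init_mat(d, d)
    params[[paste0("gamma", b)]] <- rep(1, d)
    params[[paste0("beta", b)]] <- rep(0, d)
    state[[paste0("rm", b)]] <- rep(0, d)
    state[[paste0("rv", b)]] <- rep(1, d)
  }
  if (spec$trailing_dense) {
    params$Wo <- if (init == "identity") diag(d) else .init_mat(d, d)
    params$bo <- rep(0, d)
  }
  list(kind = "generator", d = d, spec = spec, params = params, state = state)
}

new_discriminator <- function(d, spec) {
  sizes <- spec$layer_sizes
  ins <- c(d, sizes[-length(sizes)])
  params <- list()
  L <- length(sizes)
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- .init_mat(ins[l], sizes[l])
    params[[paste0("b", l)]] <- rep(0, sizes[l])
  }
  list(kind = "discriminator", d = d, spec = spec, params = params,
       state = list())
}

# ---- elementary ops --------------------------------------------------------

.addrow <- function(X, v) X + matrix(v, nrow(X), length(v), byrow = TRUE)
.lrelu <- function(Z) Z * ((Z > 0) + .LRELU_ALPHA * (Z <= 0))
.lrelu_grad <- function(Z) (Z > 0) + .LRELU_ALPHA * (Z <= 0)

# batchnorm forward; returns list(Y, cache) in training mode
.bn_forward_train <- function(A, gamma, beta) {
  n <- nrow(A)
  mu <- colMeans(A)
  va <- colMeans(A * A) - mu * mu
  va <- pmax(va, 0)
  inv <- 1 / sqrt(va + .BN_EPS)
  Ah <- .addrow(A, -mu) * matrix(inv, n, length(inv), byrow = TRUE)
  Y <- .addrow(Ah * matrix(gamma, n, length(gamma), byrow = TRUE), beta)
  list(Y = Y, Ah = Ah, inv = inv, mu = mu, va = va)
}

.bn_forward_infer <- function(A, gamma, beta, rm, rv) {
  n <- nrow(A)
  inv <- 1 / sqrt(rv + .BN_EPS)
  Ah <- .addrow(A, -rm) * matrix(inv, n, length(inv), byrow = TRUE)
  .addrow(Ah * matrix(gamma, n, length(gamma), byrow = TRUE), beta)
}

# batchnorm backward: dY -> list(dA, dgamma, dbeta)
.bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  k <- length(gamma)
  dgamma <- colSums(dY * cache$Ah)
  dbeta <- colSums(dY)
  dAh <- dY * matrix(gamma, n, k, byrow = TRUE)
  s1 <- colSums(dAh)
  s2 <- colSums(dAh * cache$Ah)
  dA <- matrix(cache$inv, n, k, byrow = TRUE) / n *
    (n * dAh - matrix(s1, n, k, byrow = TRUE) -
       cache$Ah * matrix(s2, n, k, byrow = TRUE))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# ---- generator forward / backward -----------------------------------------

# training=TRUE uses batch statistics and (update_state) updates running
# stats; with cache=TRUE returns intermediates for the backward pass
gen_forward <- function(net, X, training = FALSE, cache = FALSE,
                        update_state = training) {
  stopifnot(ncol(X) == net$d)
  p <- net$params
  caches <- list()
  H <- X
  for (b in seq_len(net$spec$residual_blocks)) {
    W <- p[[paste0("W", b)]]
    gamma <- p[[paste0("gamma", b)]]
    beta <- p[[paste0("beta", b)]]
    A <- H %*% W
    if (training) {
      bn <- .bn_forward_train(A, gamma, beta)
      if (update_state) {
        net$state[[paste0("rm", b)]] <-
          .BN_MOMENTUM * net$state[[paste0("rm", b)]] +
          (1 - .BN_MOMENTUM) * bn$mu
        net$state[[paste0("rv", b)]] <-
          .BN_MOMENTUM * net$state[[paste0("rv", b)]] +
          (1 - .BN_MOMENTUM) * bn$va
      }
      Z <- bn$Y
    } else {
      Z <- .bn_forward_infer(A, gamma, beta,
                             net$state[[paste0("rm", b)]],
                             net$state[[paste0("rv", b)]])
      bn <- NULL
    }
    Hb <- .lrelu(Z)
    out <- H + Hb
    if (cache) caches[[b]] <- list(X = H, A = A, bn = bn, Z = Z)
    H <- out
  }
  Y <- H
  trail <- NULL
  if (net$spec$trailing_dense) {
    Y <- .addrow(H %*% p$Wo, p$bo)
    if (cache) trail <- list(H = H)
  }
  list(Y = Y, caches = caches, trail = trail, net = net)
}

# backward through the generator; returns grads (named like params) and dX
gen_backward <- function(net, fwd, dY) {
  p <- net$params
  grads <- list()
  if (net$spec$trailing_dense) {
    H <- fwd$trail$H
    grads$Wo <- crossprod(H, dY)
    grads$bo <- colSums(dY)
    dH <- dY %*% t(p$Wo)
  } else {
    dH <- dY
  }
  for (b in rev(seq_len(net$spec$residual_blocks))) {
    cc <- fwd$caches[[b]]
    dZ <- dH * .lrelu_grad(cc$Z)
    bnb <- .bn_backward(dZ, cc$bn, p[[paste0("gamma", b)]])
    grads[[paste0("gamma", b)]] <- bnb$dgamma
    grads[[paste0("beta", b)]] <- bnb$dbeta
    grads[[paste0("W", b)]] <- crossprod(cc$X, bnb$dA)
    dH <- dH + bnb$dA %*% t(p[[paste0("W", b)]])   # residual + branch
  }
  list(grads = grads, dX = dH)
}

# ---- discriminator forward / backward -------------------------------------

disc_forward <- function(net, X, training = FALSE, cache = FALSE,
                         update_state = training) {
  stopifnot(ncol(X) == net$d)
  p <- net$params
  L <- length(net$spec$layer_sizes)
  caches <- list()
  H <- X
  for (l in seq_len(L)) {
    Z <- .addrow(H %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    if (l < L) {
      if (cache) caches[[l]] <- list(X = H, Z = Z)
      H <- .lrelu(Z)
    } else {
      if (cache) caches[[l]] <- list(X = H)
      H <- Z
    }
  }
  list(S = H, caches = caches, net = net)
}

disc_backward <- function(net, fwd, dS) {
  p <- net$params
  L <- length(net$spec$layer_sizes)
  grads <- list()
  cc <- fwd$caches[[L]]
  grads[[paste0("W", L)]] <- crossprod(cc$X, dS)
  grads[[paste0("b", L)]] <- colSums(dS)
  dH <- dS %*% t(p[[paste0("W", L)]])
  for (l in rev(seq_len(L - 1L))) {
    cc <- fwd$caches[[l]]
    dZ <- dH * .lrelu_grad(cc$Z)
    grads[[paste0("W", l)]] <- crossprod(cc$X, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    dH <- dZ %*% t(p[[paste0("W", l)]])
  }
  list(grads = grads, dX = dH)
}

#' Apply a generator network to latent points
#'
#' Inference-mode forward pass (frozen batch-normalization statistics):
#' deterministic, and the output has the same dimension as the input.
#'
#' @param net a generator network (e.g. `model$G` of a fitted
#'   [mol_cyclegan()]).
#' @param z numeric vector or matrix of latent points (rows).
#' @return matrix (or vector, matching the input shape) of generated points.
#' @export
forward_generator <- function(net, z) {
  vec <- is.null(dim(z))
  Z <- if (vec) matrix(z, nrow = 1) else z
  out <- gen_forward(net, Z, training = FALSE)$Y
  if (vec) as.numeric(out) else out
}

# ---- Adam ------------------------------------------------------------------

new_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# elementwise sum of two gradient lists (missing entries treated as zero)
.add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
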