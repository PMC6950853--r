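# Fully synthetic tasks with the statistical structure the method assumes:
# two Gaussian latent populations with shared isotropic covariance,
# separated along a known property direction w, with a linear property
# f(z) = w . z and a threshold between the populations. Membership is
# enforced exactly by rejection sampling, so X rows always satisfy
# f(z) <= t and Y rows f(z) > t.

#' Specification of a synthetic two-population task
#'
#' Defaults describe the study conditions used throughout the package's
#' checks: dimension 8, unit isotropic spread, population means separated by
#' 4 standard deviations along the property direction (first basis vector),
#' 2000 training and 400 held-out points per set, and the midpoint threshold.
#'
#' @param dimension latent dimension (default 8).
#' @param n_train,n_test points per set (defaults 2000 / 400).
#' @param sigma isotropic standard deviation (default 1).
#' @param separation distance between the population means along `weights`,
#'   in units of `sigma` (default 4).
#' @param weights property direction (default first basis vector; normalized
#'   internally).
#' @param threshold property threshold separating X (`f <= t`) from Y
#'   (`f > t`); default the midpoint between the population means.
#' @param resolution grid resolution of the paired [toy_backend()].
#' @param seed integer seed.
#' @return an object of class `toy_task_spec`.
#' @export
toy_task_spec <- function(dimension = 8L, n_train = 2000L, n_test = 400L,
                          sigma = 1, separation = 4, weights = NULL,
                          threshold = NULL, resolution = 0.5, seed = 1L) {
  stopifnot(dimension >= 1L, n_train >= 1L, n_test >= 0L, sigma > 0,
            separation > 0)
  if (is.null(weights)) weights <- c(1, rep(0, dimension - 1L))
  stopifnot(length(weights) == dimension)
  w <- weights / sqrt(sum(weights^2))
  mu_x <- rep(0, dimension)
  mu_y <- separation * sigma * w
  if (is.null(threshold)) threshold <- sum(w * (mu_x + mu_y)) / 2
  structure(list(dimension = as.integer(dimension),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 sigma = sigma, separation = separation, weights = w,
                 mu_x = mu_x, mu_y = mu_y, threshold = threshold,
                 resolution = resolution, seed = as.integer(seed)),
            class = "toy_task_spec")
}

# rejection-sample n Gaussian points with f(z) on the requested side of t
.sample_side <- function(n, mu, sigma, w, t, side, max_rounds = 1000L) {
  d <- length(mu)
  out <- matrix(numeric(0), 0, d)
  rounds <- 0L
  while (nrow(out) < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("membership unreachable after ", max_rounds,
           " rejection rounds; check the threshold")
    m <- max(n - nrow(out), 16L)
    z <- matrix(stats::rnorm(m * d, 0, sigma), m, d) +
      matrix(mu, m, d, byrow = TRUE)
    f <- as.numeric(z %*% w)
    keep <- if (side == "low") f <= t else f > t
    out <- rbind(out, z[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic two-population latent task
#'
#' Draws the four latent matrices (train/test for X and Y) under the spec's
#' seed, enforcing exact membership by rejection, and pairs them with a
#' matching [toy_backend()] (same dimension and property direction).
#'
#' @param spec a [toy_task_spec()].
#' @return an object of class `toy_task`: matrices `x_train`, `x_test`,
#'   `y_train`, `y_test`; functions `f` (property) and `predicate`
#'   (membership in Y: molecules/tokens with `f > t`); the `backend`; and
#'   the `spec`.
#' @export
make_toy_task <- function(spec = toy_task_spec()) {
  stopifnot(inherits(spec, "toy_task_spec"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(spec$seed)
  w <- spec$weights
  t <- spec$threshold
  x_train <- .sample_side(spec$n_train, spec$mu_x, spec$sigma, w, t, "low")
  y_train <- .sample_side(spec$n_train, spec$mu_y, spec$sigma, w, t, "high")
  x_test <- if (spec$n_test > 0)
    .sample_side(spec$n_test, spec$mu_x, spec$sigma, w, t, "low")
  else matrix(numeric(0), 0, spec$dimension)
  y_test <- if (spec$n_test > 0)
    .sample_side(spec$n_test, spec$mu_y, spec$sigma, w, t, "high")
  else matrix(numeric(0), 0, spec$dimension)
  backend <- toy_backend(spec$dimension, spec$resolution, w)
  f <- function(z) if (is.matrix(z)) as.numeric(z %*% w) else sum(z * w)
  predicate <- function(m) {
    z <- if (is.character(m)) backend$encode(m) else m
    f(z) > t
  }
  structure(list(x_train = x_train, x_test = x_test,
                 y_train = y_train, y_test = y_test,
                 f = f, predicate = predicate, backend = backend,
                 spec = spec),
            class = "toy_task")
}

#' @export
print.toy_task <- function(x, ...) {
  s <- x$spec
  cat("Synthetic latent task: d =", s$dimension, ", separation",
      s$separation, "sigma along w, threshold", signif(s$threshold, 4), "\n")
  cat("  X train/test:", nrow(x$x_train), "/", nrow(x$x_test),
      "  Y train/test:", nrow(x$y_train), "/", nrow(x$y_test), "\n")
  invisible(x)
}

#' End-to-end check on the synthetic task
#'
#' Generates the task, trains the model, transforms the held-out X set and
#' evaluates it: success rate (generated tokens in the Y region),
#' non-identity, uniqueness, the cosine between the generator's mean latent
#' displacement and the known population shift `mu_y - mu_x`, and a
#' constrained-optimization summary over a subset of the held-out molecules.
#'
#' @param spec a [toy_task_spec()].
#' @param epochs,batch_size,learning_rate,weights,variant,init passed to
#'   [mol_cyclegan()].
#' @param n_constrained how many held-out molecules to run
#'   [constrained_optimize()] on (default 50; 0 skips).
#' @param delta similarity threshold for the constrained stage.
#' @param K path points for the constrained stage.
#' @return a list with the metrics, the fitted `model`, the `task`, and the
#'   transform `records`.
#' @export
end_to_end_check <- function(spec = toy_task_spec(), epochs = 100L,
                             batch_size = 32L, learning_rate = 1e-4,
                             weights = loss_weights(),
                             variant = "structural",
                             init = "gaussian",
                             n_constrained = 50L, delta = 0.2, K = 80L) {
  task <- make_toy_task(spec)
  model <- mol_cyclegan(task$x_train, task$y_train, variant = variant,
                        weights = weights, epochs = epochs,
                        batch_size = batch_size,
                        learning_rate = learning_rate,
                        seed = spec$seed, init = init)
  z <- task$x_test
  gz <- predict(model, z)
  origin <- vapply(seq_len(nrow(z)),
                   function(i) task$backend$decode(z[i, ]), character(1))
  generated <- vapply(seq_len(nrow(gz)),
                      function(i) task$backend$decode(gz[i, ]), character(1))
  records <- transform_records(origin, generated)
  disp <- colMeans(gz - z)
  shift <- task$spec$mu_y - task$spec$mu_x
  cosine <- sum(disp * shift) / sqrt(sum(disp^2) * sum(shift^2))

  constrained <- NULL
  if (n_constrained > 0L) {
    idx <- seq_len(min(n_constrained, nrow(z)))
    scorer <- toy_scorer(task$backend)
    results <- lapply(idx, function(i) {
      constrained_optimize(origin[i], model, task$backend, scorer,
                           delta = delta, K = K)
    })
    constrained <- constrained_report(results, delta)
  }

  list(success_rate = success_rate(records, task$predicate),
       non_identity = non_identity(records),
       uniqueness = uniqueness(records),
       displacement_cosine = cosine,
       mean_l1_displacement = mean(rowSums(abs(gz - z))),
       mean_f_before = mean(task$f(z)),
       mean_f_after = mean(task$f(gz)),
       constrained = constrained,
       model = model, task = task, records = records)
}
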