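# Inference-time optimization procedures: latent paths from x to G(x),
# constrained best-under-threshold selection, equal-interval intermediate
# transforms, and iterative unconstrained optimization.

#' Equally spaced latent path from x to G(x)
#'
#' `point_i = x + (i/(K-1)) * (gx - x)` for `i = 0..K-1`; the first row is
#' `x` and the last is `gx`.
#'
#' @param x,gx latent vectors of equal dimension.
#' @param K number of points (>= 2).
#' @return `K x d` matrix of path points.
#' @export
latent_path <- function(x, gx, K = 80L) {
  if (K < 2L) stop("K must be >= 2")
  x <- as.numeric(x); gx <- as.numeric(gx)
  if (length(x) != length(gx)) stop("x and G(x) dimensions differ")
  tfrac <- seq(0, 1, length.out = K)
  outer(rep(1, K), x) + outer(tfrac, gx - x)
}

# accept a fitted model or a plain latent map as the generator
.as_generator <- function(model, direction = "forward") {
  if (inherits(model, "mol_cyclegan")) {
    function(z) predict(model, z, direction = direction)
  } else if (is.function(model)) {
    model
  } else {
    stop("'model' must be a fitted mol_cyclegan or a function on latents")
  }
}

#' Constrained molecule optimization along the latent path
#'
#' Encodes the starting molecule, applies the generator, decodes `K` points
#' along the straight latent path from `x` to `G(x)`, and among the decoded
#' molecules that are distinct from the start and at least `delta`-similar to
#' it reports the one with the highest property score. The optimization
#' succeeds when at least one decoded molecule satisfies the constraint and
#' differs from the starting one; otherwise a failure result (no exception)
#' is returned. Score ties break toward higher similarity, then earlier path
#' index.
#'
#' @param m starting molecule (SMILES or backend token).
#' @param model fitted [mol_cyclegan()] (its forward generator is used) or a
#'   function mapping a latent vector to a latent vector.
#' @param backend embedding backend, e.g. [toy_backend()].
#' @param scorer function mapping molecules to property scores, e.g.
#'   [penalized_logp()] or [toy_scorer()].
#' @param delta similarity threshold in `[0, 1]`.
#' @param K number of decoded path points (default 80).
#' @param similarity two-argument similarity function; default
#'   [mol_similarity()].
#' @return an object of class `constrained_result`: fields `start_molecule`,
#'   `best_molecule` (`NA` on failure), `improvement`, `similarity`,
#'   `success`, `path_index`, `start_score`, `delta`.
#' @export
constrained_optimize <- function(m, model, backend, scorer, delta,
                                 K = 80L, similarity = NULL) {
  stopifnot(delta >= 0, delta <= 1)
  gen <- .as_generator(model)
  if (is.null(similarity))
    similarity <- function(a, b) mol_similarity(a, b, backend = backend)
  x <- backend$encode(m)
  gx <- as.numeric(gen(x))
  path <- latent_path(x, gx, K)
  decoded <- vapply(seq_len(nrow(path)),
                    function(i) backend$decode(path[i, ]), character(1))
  can <- canonicalize(decoded)
  start_can <- canonicalize(m)
  keep <- !duplicated(can) & can != start_can
  start_score <- scorer(m)

  fail <- structure(list(start_molecule = start_can,
                         best_molecule = NA_character_,
                         improvement = NA_real_, similarity = NA_real_,
                         success = FALSE, path_index = NA_integer_,
                         start_score = start_score, delta = delta),
                    class = "constrained_result")
  if (!any(keep)) return(fail)
  idx <- which(keep)
  sims <- vapply(idx, function(i) similarity(start_can, can[i]), numeric(1))
  ok <- sims >= delta
  if (!any(ok)) return(fail)
  idx <- idx[ok]; sims <- sims[ok]
  scores <- vapply(idx, function(i) scorer(can[i]), numeric(1))
  # argmax score; ties -> higher similarity -> earlier path index
  best <- order(-scores, -sims, idx)[1L]
  structure(list(start_molecule = start_can,
                 best_molecule = can[idx[best]],
                 improvement = scores[best] - start_score,
                 similarity = sims[best],
                 success = TRUE,
                 path_index = idx[best],
                 start_score = start_score, delta = delta),
            class = "constrained_result")
}

#' @export
print.constrained_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf(
      "constrained optimization: %s -> %s\n  improvement %.4f, similarity %.4f (delta %.2f), path point %d\n",
      x$start_molecule, x$best_molecule, x$improvement, x$similarity,
      x$delta, x$path_index))
  } else {
    cat(sprintf(
      "constrained optimization: %s -> no molecule satisfied delta %.2f\n",
      x$start_molecule, x$delta))
  }
  invisible(x)
}

#' Intermediate-step transform
#'
#' Decodes `steps` points taken in equal intervals along the latent path
#' from `x` to `G(x)` (both endpoints included) and returns their molecules
#' in path order. Duplicate decodes are retained and flagged in the
#' `"duplicated"` attribute.
#'
#' @inheritParams constrained_optimize
#' @param steps number of decoded points (default 10).
#' @return character vector of `steps` molecules with attribute
#'   `"duplicated"`.
#' @export
intermediate_transform <- function(m, model, backend, steps = 10L) {
  if (steps < 2L) stop("steps must be >= 2")
  gen <- .as_generator(model)
  x <- backend$encode(m)
  gx <- as.numeric(gen(x))
  path <- latent_path(x, gx, steps)
  decoded <- vapply(seq_len(nrow(path)),
                    function(i) backend$decode(path[i, ]), character(1))
  structure(canonicalize(decoded), duplicated = duplicated(decoded))
}

#' Iterative unconstrained optimization
#'
#' Applies the generator repeatedly in latent space: `z_0 = encode(m)`,
#' `z_{k+1} = G(z_k)` (by default the generated latent point is the next
#' input, with no decode/re-encode round trip), returning the decodes of
#' `z_1..z_iterations`. Set `reencode = TRUE` to decode and re-encode between
#' iterations instead.
#'
#' @inheritParams constrained_optimize
#' @param iterations number of generator applications (>= 1).
#' @param reencode decode + re-encode between iterations (default `FALSE`).
#' @return character vector of `iterations` molecules.
#' @export
iterative_optimize <- function(m, model, backend, iterations,
                               reencode = FALSE) {
  if (iterations < 1L) stop("iterations must be >= 1")
  gen <- .as_generator(model)
  z <- backend$encode(m)
  out <- character(iterations)
  for (k in seq_len(iterations)) {
    z <- as.numeric(gen(z))
    out[k] <- backend$decode(z)
    if (reencode) z <- backend$encode(out[k])
  }
  canonicalize(out)
}

#' Property scorer for the synthetic backend
#'
#' Scores a toy token by the backend's linear latent property
#' `f(z) = w . z` evaluated at the token's grid-cell centre.
#'
#' @param backend a [toy_backend()].
#' @return a function mapping tokens to numeric scores.
#' @export
toy_scorer <- function(backend) {
  function(m) {
    vapply(m, function(mm) backend$property(backend$encode(mm)), numeric(1),
           USE.NAMES = FALSE)
  }
}
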