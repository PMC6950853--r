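# Reversible embedding backends.
#
# The model operates on latent vectors and only needs a backend exposing
# encode (molecule -> latent point, deterministic: the posterior mean, not a
# sample), decode (latent point -> molecule, total: always a valid molecule)
# and the latent dimension. A grid-quantized synthetic backend provides the
# desk-scale stand-in: its "molecules" are serialized grid cells, so
# decode(encode(m)) == m exactly and every latent point decodes to a valid
# token, mirroring the 100% decoding validity the method assumes. An adapter
# for an externally trained molecular autoencoder only has to supply the same
# three fields.

#' Synthetic grid-quantized latent backend
#'
#' Emulates a reversible molecular embedding: latent space is `R^d`, the
#' "molecules" are the cells of a regular grid with spacing `resolution`,
#' serialized as tokens `"z:i1,...,id"` (cell indices). Encoding maps a token
#' to its cell centre; decoding maps any latent point to the token of its
#' nearest cell. A linear property `f(z) = w . z` plays the role of the
#' molecular property being optimized.
#'
#' @param dimension latent dimension `d` (default 56, matching the width of
#'   the generator layers).
#' @param resolution grid spacing per coordinate (default 0.5).
#' @param weights property direction `w` (default the first basis vector).
#' @return an object of class `c("toy_backend", "embedding_backend")` with
#'   fields `dimension`, `resolution`, `weights`, and functions `encode`,
#'   `decode`, `property`.
#' @export
toy_backend <- function(dimension = 56L, resolution = 0.5, weights = NULL) {
  stopifnot(dimension >= 1L, resolution > 0)
  if (is.null(weights)) {
    weights <- c(1, rep(0, dimension - 1L))
  }
  stopifnot(length(weights) == dimension, all(is.finite(weights)))
  b <- list(dimension = as.integer(dimension), resolution = resolution,
            weights = weights)
  b$encode <- function(token) toy_encode(token, b)
  b$decode <- function(z) toy_decode(z, b)
  b$property <- function(z) {
    if (is.matrix(z)) as.numeric(z %*% weights) else sum(z * weights)
  }
  class(b) <- c("toy_backend", "embedding_backend")
  b
}

#' @export
print.toy_backend <- function(x, ...) {
  cat("Grid-quantized synthetic latent backend\n")
  cat("  dimension:", x$dimension, " resolution:", x$resolution, "\n")
  cat("  property direction: w =",
      paste(signif(x$weights, 3), collapse = " "), "\n")
  invisible(x)
}

#' Encode a toy token to its latent point
#'
#' @param token token string `"z:i1,...,id"`.
#' @param backend a [toy_backend()].
#' @return numeric vector of length `backend$dimension` (the cell centre).
#' @export
toy_encode <- function(token, backend) {
  stopifnot(length(token) == 1L, is.character(token))
  if (!is_toy_token(token)) stop("malformed toy token: '", token, "'")
  idx <- suppressWarnings(as.numeric(strsplit(sub("^z:", "", token),
                                              ",")[[1]]))
  if (anyNA(idx) || any(idx != round(idx)))
    stop("malformed toy token: '", token, "'")
  if (length(idx) != backend$dimension)
    stop("token dimension ", length(idx), " != backend dimension ",
         backend$dimension)
  idx * backend$resolution
}

#' Decode a latent point to the nearest toy token
#'
#' Total map: every finite latent point of the right dimension decodes to a
#' valid token (nearest grid cell, ties resolved by round-half-to-even).
#'
#' @param z numeric vector of length `backend$dimension`.
#' @inheritParams toy_encode
#' @return token string.
#' @export
toy_decode <- function(z, backend) {
  if (length(z) != backend$dimension)
    stop("latent dimension ", length(z), " != backend dimension ",
         backend$dimension)
  if (any(!is.finite(z))) stop("latent point has non-finite coordinates")
  paste0("z:", paste(format(round(z / backend$resolution), scientific = FALSE,
                            trim = TRUE), collapse = ","))
}

#' Encode a set of molecules into a latent matrix
#'
#' @param molecules character vector of molecules the backend accepts.
#' @param backend an embedding backend (e.g. [toy_backend()]).
#' @return numeric matrix with one row per molecule, in input order.
#' @export
encode_set <- function(molecules, backend) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (length(molecules) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = backend$dimension))
  rows <- lapply(seq_along(molecules), function(i) {
    tryCatch(backend$encode(molecules[i]),
             error = function(e) stop("cannot encode molecule ", i, " ('",
                                      molecules[i], "'): ",
                                      conditionMessage(e), call. = FALSE))
  })
  do.call(rbind, rows)
}

#' Write / read a latent matrix as CSV
#'
#' Columns are `z0..z{d-1}`; an optional sidecar column `molecule` keeps the
#' row-to-molecule mapping.
#'
#' @param z numeric matrix (rows = molecules).
#' @param path CSV path.
#' @param molecules optional character vector of molecules/tokens per row.
#' @return `write_latents` the path invisibly; `read_latents` a list with
#'   matrix `z` and (possibly `NULL`) `molecules`.
#' @export
write_latents <- function(z, path, molecules = NULL) {
  stopifnot(is.matrix(z))
  d <- as.data.frame(z)
  names(d) <- paste0("z", seq_len(ncol(z)) - 1L)
  if (!is.null(molecules)) d$molecule <- molecules
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mols <- if ("molecule" %in% names(d)) d$molecule else NULL
  zc <- grep("^z[0-9]+$", names(d), value = TRUE)
  list(z = as.matrix(d[zc]), molecules = mols)
}
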