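# Construction of the X / Y compound sets.
#
# A set is defined by SMARTS inclusion/exclusion lists, an optional allowed
# set of aromatic-ring counts, and an optional property rule (threshold or
# quantile on a molecular property). X and Y memberships are made mutually
# exclusive: molecules satisfying both or neither definition are dropped.

#' Define a compound set by structural and property criteria
#'
#' @param include_smarts character vector of SMARTS; a member must match at
#'   least one (`NULL` to skip).
#' @param exclude_smarts character vector of SMARTS; a member must match none.
#' @param ring_counts integer vector of allowed aromatic-ring counts, e.g.
#'   `c(1, 3)` (`NULL` to skip).
#' @param property_rule optional list with elements `property` (a function of
#'   SMILES, or the name of one such as `"penalized_logp"`), `comparator` (one
#'   of `"<", "<=", ">", ">="`), and exactly one of `threshold` (absolute) or
#'   `quantile` (in `[0,1]`, resolved on the full input collection before
#'   splitting).
#' @return an object of class `set_definition`.
#' @examples
#' halogens <- set_definition(
#'   include_smarts = c("[!#1]Cl", "[!#1]F", "[!#1]I", "C#N"))
#' no_halogens <- set_definition(
#'   exclude_smarts = c("[!#1]Cl", "[!#1]F", "[!#1]I", "C#N"))
#' @export
set_definition <- function(include_smarts = NULL, exclude_smarts = NULL,
                           ring_counts = NULL, property_rule = NULL) {
  if (is.null(include_smarts) && is.null(exclude_smarts) &&
      is.null(ring_counts) && is.null(property_rule))
    stop("a set definition needs at least one criterion")
  if (!is.null(property_rule)) {
    stopifnot(is.list(property_rule),
              !is.null(property_rule$property),
              property_rule$comparator %in% c("<", "<=", ">", ">="))
    if (is.null(property_rule$threshold) == is.null(property_rule$quantile))
      stop("property_rule needs exactly one of 'threshold' or 'quantile'")
  }
  structure(list(include_smarts = include_smarts,
                 exclude_smarts = exclude_smarts,
                 ring_counts = ring_counts,
                 property_rule = property_rule),
            class = "set_definition")
}

#' @export
print.set_definition <- function(x, ...) {
  cat("Set definition:\n")
  if (!is.null(x$include_smarts))
    cat("  include any of:", paste(x$include_smarts, collapse = ", "), "\n")
  if (!is.null(x$exclude_smarts))
    cat("  exclude all of:", paste(x$exclude_smarts, collapse = ", "), "\n")
  if (!is.null(x$ring_counts))
    cat("  aromatic rings in {", paste(x$ring_counts, collapse = ", "), "}\n")
  if (!is.null(x$property_rule)) {
    pr <- x$property_rule
    nm <- if (is.character(pr$property)) pr$property else "property"
    bound <- if (!is.null(pr$threshold)) pr$threshold
             else paste0("quantile ", pr$quantile)
    cat("  ", nm, " ", pr$comparator, " ", bound, "\n", sep = "")
  }
  invisible(x)
}

.resolve_property <- function(property) {
  if (is.function(property)) return(property)
  switch(property,
         penalized_logp = penalized_logp,
         logp = mol_logp,
         sa = sa_score,
         stop("unknown property: ", property))
}

# membership of molecules in a set definition; property values/threshold may
# be pre-resolved (quantile rules must be resolved on the full collection)
set_membership <- function(smiles, def, property_values = NULL,
                           threshold = NULL) {
  stopifnot(inherits(def, "set_definition"))
  ok <- rep(TRUE, length(smiles))
  if (!is.null(def$include_smarts))
    ok <- ok & matches_any_smarts(smiles, def$include_smarts)
  if (!is.null(def$exclude_smarts))
    ok <- ok & !matches_any_smarts(smiles, def$exclude_smarts)
  if (!is.null(def$ring_counts))
    ok <- ok & count_aromatic_rings(smiles) %in% def$ring_counts
  if (!is.null(def$property_rule)) {
    pr <- def$property_rule
    if (is.null(property_values))
      property_values <- .resolve_property(pr$property)(smiles)
    if (is.null(threshold)) {
      threshold <- if (!is.null(pr$threshold)) pr$threshold
      else as.numeric(stats::quantile(property_values, pr$quantile, type = 7))
    }
    cmp <- match.fun(pr$comparator)
    ok <- ok & cmp(property_values, threshold)
  }
  ok
}

#' Build the X/Y train and test sets
#'
#' Deduplicates the input by canonical SMILES, resolves any quantile-based
#' property rules on the full deduplicated collection, assigns each molecule
#' to X or Y (molecules qualifying for both or neither are dropped, keeping
#' the sets mutually exclusive), and draws the four requested samples without
#' replacement under `seed`. Train and test sets of the same letter are
#' disjoint.
#'
#' @param molecules character vector of SMILES.
#' @param x_def,y_def [set_definition()] objects for the two sets.
#' @param sizes named numeric vector/list with entries `x_train`, `x_test`,
#'   `y_train`, `y_test` (a size of 0 skips that set).
#' @param seed integer seed making the split reproducible.
#' @return an object of class `molecule_sets`: a list with character vectors
#'   `x_train`, `x_test`, `y_train`, `y_test` plus a `meta` record (counts and
#'   any resolved property thresholds).
#' @export
build_sets <- function(molecules, x_def, y_def,
                       sizes = c(x_train = 100, x_test = 20,
                                 y_train = 100, y_test = 20),
                       seed = 1L) {
  stopifnot(inherits(x_def, "set_definition"),
            inherits(y_def, "set_definition"))
  sizes <- unlist(sizes)
  need <- c("x_train", "x_test", "y_train", "y_test")
  if (!all(need %in% names(sizes)))
    stop("sizes must name x_train, x_test, y_train, y_test")
  can <- unique(canonicalize(molecules))

  # resolve quantile thresholds on the full collection before splitting
  thresholds <- list(x = NULL, y = NULL)
  prop_vals <- list(x = NULL, y = NULL)
  for (side in c("x", "y")) {
    def <- if (side == "x") x_def else y_def
    pr <- def$property_rule
    if (!is.null(pr)) {
      vals <- .resolve_property(pr$property)(can)
      thr <- if (!is.null(pr$threshold)) pr$threshold
      else as.numeric(stats::quantile(vals, pr$quantile, type = 7))
      thresholds[[side]] <- thr
      prop_vals[[side]] <- vals
    }
  }

  in_x <- set_membership(can, x_def, prop_vals$x, thresholds$x)
  in_y <- set_membership(can, y_def, prop_vals$y, thresholds$y)
  x_pool <- can[in_x & !in_y]
  y_pool <- can[in_y & !in_x]

  nx <- sizes[["x_train"]] + sizes[["x_test"]]
  ny <- sizes[["y_train"]] + sizes[["y_test"]]
  if (length(x_pool) < nx)
    stop("not enough X molecules: need ", nx, ", have ", length(x_pool))
  if (length(y_pool) < ny)
    stop("not enough Y molecules: need ", ny, ", have ", length(y_pool))

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  xs <- sample(x_pool, nx)
  ys <- sample(y_pool, ny)
  out <- list(
    x_train = if (sizes[["x_train"]] > 0)
      xs[seq_len(sizes[["x_train"]])] else character(0),
    x_test = if (sizes[["x_test"]] > 0)
      xs[sizes[["x_train"]] + seq_len(sizes[["x_test"]])] else character(0),
    y_train = if (sizes[["y_train"]] > 0)
      ys[seq_len(sizes[["y_train"]])] else character(0),
    y_test = if (sizes[["y_test"]] > 0)
      ys[sizes[["y_train"]] + seq_len(sizes[["y_test"]])] else character(0),
    meta = list(n_input = length(molecules), n_unique = length(can),
                n_x_pool = length(x_pool), n_y_pool = length(y_pool),
                thresholds = thresholds, seed = seed)
  )
  class(out) <- "molecule_sets"
  out
}

#' @export
print.molecule_sets <- function(x, ...) {
  cat("Molecule sets (", x$meta$n_unique, " unique molecules, ",
      x$meta$n_x_pool, " X candidates, ", x$meta$n_y_pool,
      " Y candidates)\n", sep = "")
  for (nm in c("x_train", "x_test", "y_train", "y_test"))
    cat(sprintf("  %-8s %d\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write molecule sets to CSV
#'
#' One row per molecule with columns `smiles` and `label`
#' (`X_train`/`X_test`/`Y_train`/`Y_test`).
#'
#' @param sets a `molecule_sets` object from [build_sets()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_molecule_sets <- function(sets, path) {
  stopifnot(inherits(sets, "molecule_sets"))
  lab <- c(x_train = "X_train", x_test = "X_test",
           y_train = "Y_train", y_test = "Y_test")
  rows <- do.call(rbind, lapply(names(lab), function(nm) {
    if (length(sets[[nm]]) == 0L) return(NULL)
    data.frame(smiles = sets[[nm]], label = lab[[nm]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a set definition as JSON
#'
#' @param def a [set_definition()].
#' @param path JSON file path.
#' @return `write_set_definition` returns the path invisibly;
#'   `read_set_definition` returns a `set_definition`.
#' @export
write_set_definition <- function(def, path) {
  stopifnot(inherits(def, "set_definition"))
  if (!is.null(def$property_rule) && is.function(def$property_rule$property))
    stop("only named properties can be serialized")
  jsonlite::write_json(unclass(def), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_set_definition
#' @export
read_set_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  set_definition(include_smarts = x$include_smarts,
                 exclude_smarts = x$exclude_smarts,
                 ring_counts = x$ring_counts,
                 property_rule = x$property_rule)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
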