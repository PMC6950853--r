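# Evaluation metrics: structural success predicates, non-identity,
# uniqueness/diversity, similarity distributions, constrained-optimization
# summaries, and the pluggable random-forest activity oracle.

#' Pair origin and generated molecules
#'
#' @param origin,generated character vectors of equal length (SMILES or
#'   backend tokens); canonicalized on construction.
#' @param direction label, e.g. `"X->G(X)"`.
#' @return a `transform_records` data frame with columns `origin`,
#'   `generated`, `direction`.
#' @export
transform_records <- function(origin, generated, direction = "X->G(X)") {
  stopifnot(length(origin) == length(generated), length(origin) >= 1L)
  out <- data.frame(origin = canonicalize(origin),
                    generated = canonicalize(generated),
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("transform_records", class(out))
  out
}

.check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("origin", "generated") %in% names(records)))
    stop("records must be a transform_records data frame")
  if (nrow(records) == 0L) stop("records must be non-empty")
  records
}

#' Success rate of a transformation
#'
#' Fraction of records whose generated molecule satisfies the target-set
#' predicate (the fraction of times the desired modification occurs).
#'
#' @param records a [transform_records()] data frame.
#' @param predicate a [set_definition()] for the target set, or a function
#'   mapping molecules to logicals.
#' @param exclude_identity drop records whose generated molecule equals the
#'   origin before computing the rate (default `FALSE`).
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(records, predicate, exclude_identity = FALSE) {
  records <- .check_records(records)
  if (exclude_identity) {
    records <- records[records$generated != records$origin, , drop = FALSE]
    if (nrow(records) == 0L) return(0)
  }
  ok <- if (inherits(predicate, "set_definition"))
    set_membership(records$generated, predicate)
  else vapply(records$generated, function(m) isTRUE(predicate(m)),
              logical(1), USE.NAMES = FALSE)
  mean(ok)
}

#' Non-identity rate
#'
#' Fraction of records whose generated molecule differs from the starting
#' one (by canonical form).
#'
#' @inheritParams success_rate
#' @return fraction in `[0, 1]`.
#' @export
non_identity <- function(records) {
  records <- .check_records(records)
  mean(records$generated != records$origin)
}

#' Uniqueness of the generated set
#'
#' Number of distinct generated molecules divided by the number of records;
#' always at least `1/n`.
#'
#' @inheritParams success_rate
#' @return fraction in `(0, 1]`.
#' @export
uniqueness <- function(records) {
  records <- .check_records(records)
  length(unique(records$generated)) / nrow(records)
}

#' Diversity of the generated set
#'
#' Reported alongside success rate and non-identity; computed as the
#' fraction of unique generated molecules, i.e. identically to
#' [uniqueness()], and labelled as such in reports.
#'
#' @inheritParams success_rate
#' @return fraction in `(0, 1]`.
#' @export
diversity <- function(records) {
  uniqueness(records)
}

#' Summarize constrained-optimization results
#'
#' Mean and standard deviation of improvement and of similarity over the
#' successful results, plus the success percentage over all results. With
#' zero successes the means are `NA` (flagged, not an error).
#'
#' @param results list of `constrained_result` objects from
#'   [constrained_optimize()], all at the same `delta`.
#' @param delta the similarity threshold the results were computed at.
#' @return an object of class `evaluation_report` with fields
#'   `improvement_mean`, `improvement_sd`, `similarity_mean`,
#'   `similarity_sd`, `success_percent`, `n`, `delta`.
#' @export
constrained_report <- function(results, delta) {
  stopifnot(length(results) >= 1L)
  ok <- vapply(results, function(r) isTRUE(r$success), logical(1))
  imp <- vapply(results[ok], `[[`, numeric(1), "improvement")
  sim <- vapply(results[ok], `[[`, numeric(1), "similarity")
  out <- list(
    improvement_mean = if (any(ok)) mean(imp) else NA_real_,
    improvement_sd = if (sum(ok) > 1) stats::sd(imp) else NA_real_,
    similarity_mean = if (any(ok)) mean(sim) else NA_real_,
    similarity_sd = if (sum(ok) > 1) stats::sd(sim) else NA_real_,
    success_percent = 100 * mean(ok),
    n = length(results),
    delta = delta)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Constrained optimization at delta = %.2f (n = %d)\n",
              x$delta, x$n))
  cat(sprintf("  success: %.2f%%\n", x$success_percent))
  if (!is.na(x$improvement_mean)) {
    cat(sprintf("  improvement: %.3f +/- %.3f\n", x$improvement_mean,
                if (is.na(x$improvement_sd)) 0 else x$improvement_sd))
    cat(sprintf("  similarity:  %.3f +/- %.3f\n", x$similarity_mean,
                if (is.na(x$similarity_sd)) 0 else x$similarity_sd))
  } else {
    cat("  improvement/similarity: undefined (no successes)\n")
  }
  invisible(x)
}

# ---- activity oracle -------------------------------------------------------

.fp_matrix <- function(smiles, radius, bits) {
  m <- matrix(0L, length(smiles), bits)
  for (i in seq_along(smiles)) {
    m[i, morgan_fp(smiles[i], radius, bits)] <- 1L
  }
  # constant columns carry no information and slow the forest down
  m
}

#' Fit a random-forest activity oracle on circular fingerprints
#'
#' Trains a random-forest classifier on Morgan fingerprint bit vectors from a
#' labelled SMILES table and reports the threefold cross-validated ROC AUC.
#' The fitted oracle scores any molecule with the predicted probability of
#' the active class, deterministically.
#'
#' @param smiles character vector of SMILES.
#' @param labels factor/character vector with two classes; the active class
#'   is `"active"` (or the second level).
#' @param seed integer seed (forest and fold assignment).
#' @param ntree number of trees (default 500).
#' @param radius,bits fingerprint parameters (default ECFP4-style 2/2048).
#' @return an object of class `activity_oracle`: fields `score` (function
#'   SMILES -> probability of activity), `cv_auc`, `forest`, and the
#'   fingerprint parameters.
#' @export
fit_activity_oracle <- function(smiles, labels, seed = 1L, ntree = 500L,
                                radius = 2L, bits = 2048L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("activity oracle needs exactly two classes, got: ",
         paste(classes, collapse = ", "))
  active <- if ("active" %in% classes) "active" else classes[2L]
  y <- factor(labels, levels = c(setdiff(classes, active), active))
  X <- .fp_matrix(smiles, radius, bits)
  keep <- which(colSums(X) > 0L)
  X <- X[, keep, drop = FALSE]
  colnames(X) <- paste0("b", keep)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  folds <- sample(rep_len(1:3, length(smiles)))
  cv_pred <- numeric(length(smiles))
  for (f in 1:3) {
    tr <- folds != f
    rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                     ntree = ntree)
    cv_pred[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE],
                                   type = "prob")[, active]
  }
  cv_auc <- as.numeric(pROC::auc(pROC::roc(response = y,
                                           predictor = cv_pred,
                                           levels = levels(y),
                                           direction = "<", quiet = TRUE)))
  set.seed(seed)
  forest <- randomForest::randomForest(X, y, ntree = ntree)

  score <- function(m) {
    Xm <- .fp_matrix(m, radius, bits)[, keep, drop = FALSE]
    colnames(Xm) <- paste0("b", keep)
    as.numeric(stats::predict(forest, Xm, type = "prob")[, active])
  }
  structure(list(score = score, cv_auc = cv_auc, forest = forest,
                 active_class = active, radius = radius, bits = bits,
                 ntree = ntree, seed = seed),
            class = "activity_oracle")
}

#' @export
print.activity_oracle <- function(x, ...) {
  cat("Random-forest activity oracle on Morgan fingerprints\n")
  cat("  radius", x$radius, ", ", x$bits, "bits, ", x$ntree, "trees\n")
  cat(sprintf("  threefold CV ROC AUC: %.3f\n", x$cv_auc))
  invisible(x)
}

#' Activity-optimization summary
#'
#' Mean predicted activity of the starting set and of the generated set,
#' their difference (mean gain), the success rate (generated molecules
#' predicted active above `threshold`), and diversity/non-identity of the
#' generated set.
#'
#' @param oracle a fitted [fit_activity_oracle()] (or any function mapping
#'   molecules to scores).
#' @param x_set character vector of starting molecules.
#' @param generated character vector of generated molecules, same length.
#' @param threshold activity-probability cutoff for success (default 0.5).
#' @return an object of class `activity_report` (a list of the statistics).
#' @export
activity_report <- function(oracle, x_set, generated, threshold = 0.5) {
  scorer <- if (inherits(oracle, "activity_oracle")) oracle$score else oracle
  records <- transform_records(x_set, generated)
  a_x <- vapply(records$origin, function(m) scorer(m), numeric(1),
                USE.NAMES = FALSE)
  a_g <- vapply(records$generated, function(m) scorer(m), numeric(1),
                USE.NAMES = FALSE)
  out <- list(mean_activity_start = mean(a_x),
              mean_activity_generated = mean(a_g),
              mean_gain = mean(a_g) - mean(a_x),
              success_rate = mean(a_g > threshold),
              diversity = diversity(records),
              non_identity = non_identity(records),
              threshold = threshold, n = nrow(records))
  class(out) <- "activity_report"
  out
}

#' @export
print.activity_report <- function(x, ...) {
  cat("Activity optimization report (n =", x$n, ")\n")
  cat(sprintf("  mean predicted activity: %.3f -> %.3f (gain %.3f)\n",
              x$mean_activity_start, x$mean_activity_generated,
              x$mean_gain))
  cat(sprintf("  success rate (> %.2f): %.3f\n", x$threshold,
              x$success_rate))
  cat(sprintf("  diversity %.3f, non-identity %.3f\n", x$diversity,
              x$non_identity))
  invisible(x)
}

#' Plot the similarity distribution between origins and generated molecules
#'
#' Kernel density of pairwise similarities, in the style of the similarity
#' distribution figures used to assess how close generated molecules stay to
#' their progenitors.
#'
#' @param records a [transform_records()] data frame.
#' @param backend optional backend (for token records).
#' @param exclude_identity drop identity mappings first (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @return the numeric vector of similarities, invisibly.
#' @export
plot_similarity <- function(records, backend = NULL,
                            exclude_identity = TRUE, ...) {
  records <- .check_records(records)
  if (exclude_identity)
    records <- records[records$generated != records$origin, , drop = FALSE]
  if (nrow(records) == 0L) stop("no non-identity records to plot")
  sims <- vapply(seq_len(nrow(records)), function(i) {
    mol_similarity(records$origin[i], records$generated[i],
                   backend = backend)
  }, numeric(1))
  graphics::plot(stats::density(sims, from = 0, to = 1),
                 xlab = "similarity", main = "origin vs generated", ...)
  invisible(sims)
}
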