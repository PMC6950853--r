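# Synthetic-accessibility score.
#
# Follows the classic fragment-plus-complexity construction: the score of a
# molecule combines (a) how common its circular atom environments are in a
# reference corpus of synthesizable molecules and (b) structural complexity
# penalties (size, stereo centres, spiro and bridged ring atoms, macrocycles),
# mapped onto a 1 (easy) .. 10 (hard) scale. The fragment-frequency table is
# calibrated at first use from a reference SMILES set bundled with the package
# (inst/extdata/sa_reference_smiles.smi) rather than from a large public
# compound database, so absolute values are package-specific; the scale,
# monotonicity and the 1..10 range follow the established construction.

.SA_RADIUS <- 2L
.SA_UNSEEN <- -4        # contribution of an environment absent from the corpus

.sa_calibration <- function() {
  hit <- .cache_get("sa_calibration")
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "sa_reference_smiles.smi",
                      package = "molcycle")
  if (!nzchar(path) || !file.exists(path))
    stop("SA reference corpus not found; package installation is incomplete")
  ref <- read_smiles(path)
  counts <- new.env(parent = emptyenv())
  per_mol_ids <- vector("list", length(ref))
  for (i in seq_along(ref)) {
    ids <- as.character(.morgan_ids(ref[i], .SA_RADIUS))
    per_mol_ids[[i]] <- ids
    for (id in ids) {
      prev <- if (exists(id, envir = counts, inherits = FALSE))
        get(id, envir = counts) else 0
      assign(id, prev + 1, envir = counts)
    }
  }
  all_counts <- unlist(as.list(counts))
  center <- mean(log10(all_counts + 1))
  contrib <- function(ids) {
    vapply(ids, function(id) {
      if (exists(id, envir = counts, inherits = FALSE))
        log10(get(id, envir = counts) + 1) - center
      else .SA_UNSEEN
    }, numeric(1), USE.NAMES = FALSE)
  }
  # raw (uncalibrated) scores of the corpus fix the scaling window
  raw <- vapply(seq_along(ref), function(i) {
    .sa_raw(ref[i], contrib)
  }, numeric(1))
  cal <- list(contrib = contrib,
              raw_min = as.numeric(stats::quantile(raw, 0.05)),
              raw_max = as.numeric(stats::quantile(raw, 0.95)))
  .cache_set("sa_calibration", cal)
}

# uncalibrated score: fragment commonness minus complexity penalties
.sa_raw <- function(smiles, contrib) {
  g <- .mol_graph(smiles)
  if (g$n == 0L) stop("SA score undefined for an empty molecule: ", smiles)
  ids <- as.character(.morgan_ids(smiles, .SA_RADIUS))
  frag <- mean(contrib(ids))

  n_atoms <- g$n
  size_penalty <- n_atoms^1.005 - n_atoms
  can <- canonicalize(smiles)
  n_stereo <- length(gregexpr("@{1,2}", can)[[1]][gregexpr("@{1,2}",
                                                           can)[[1]] > 0])
  ss <- .sssr(smiles)
  ring_sizes <- lengths(ss$rings)
  macro_penalty <- if (any(ring_sizes > 8)) log10(2) else 0
  n_spiro <- 0L
  n_bridge <- 0L
  if (length(ss$rings) >= 2L) {
    spiro_atoms <- character(0)
    bridge_atoms <- character(0)
    for (i in seq_len(length(ss$rings) - 1L)) {
      for (j in (i + 1L):length(ss$rings)) {
        shared <- intersect(ss$rings[[i]], ss$rings[[j]])
        if (length(shared) == 1L) spiro_atoms <- union(spiro_atoms, shared)
        if (length(shared) >= 3L) bridge_atoms <- union(bridge_atoms, shared)
      }
    }
    n_spiro <- length(spiro_atoms)
    n_bridge <- length(bridge_atoms)
  }
  stereo_penalty <- log10(n_stereo + 1)
  spiro_penalty <- log10(n_spiro + 1)
  bridge_penalty <- log10(n_bridge + 1)
  # symmetry correction: repeated environments make large molecules easier
  n_unique <- length(unique(ids))
  sym <- if (n_atoms > n_unique) 0.5 * log(n_atoms / n_unique) else 0

  frag - size_penalty - stereo_penalty - spiro_penalty - bridge_penalty -
    macro_penalty + sym
}

#' Synthetic-accessibility (SA) score
#'
#' Heuristic ease-of-synthesis score on a 1 (easy) to 10 (hard) scale, built
#' from the commonness of the molecule's circular atom environments in a
#' bundled reference corpus and from structural complexity penalties. Used as
#' the penalty term of [penalized_logp()]. Deterministic per molecule.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of SA scores in `[1, 10]`.
#' @export
sa_score <- function(smiles) {
  cal <- .sa_calibration()
  vapply(smiles, function(s) {
    raw <- .sa_raw(s, cal$contrib)
    sa <- 11 - (raw - cal$raw_min + 1) / (cal$raw_max - cal$raw_min) * 9
    if (sa > 8) sa <- 8 + log(sa - 8 + 1)
    min(10, max(1, sa))
  }, numeric(1), USE.NAMES = FALSE)
}
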