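# SMILES handling, structure predicates and molecular properties.
#
# All parsing goes through OpenBabel (ChemmineOB) via ChemmineR. Parsed
# structures and computed properties are cached per input string, since the
# same molecules are revisited many times during set construction and
# evaluation.

#' Is a string a synthetic-backend token?
#'
#' Tokens produced by the grid-quantized toy backend are serialized as
#' `"z:i1,i2,..."`. Several generic operations (similarity, canonical forms)
#' dispatch on this.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_toy_token <- function(x) {
  is.character(x) & startsWith(x, "z:")
}

# parse a single SMILES; returns a length-1 SDFset; errors name the string
.parse_one <- function(smiles) {
  key <- paste0("sdf1|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m1"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) < 1L ||
      nrow(ChemmineR::atomblock(sdf[[1]])) < 1L) {
    stop("cannot parse SMILES: '", smiles, "'", call. = FALSE)
  }
  .cache_set(key, sdf)
}

# parse a vector of SMILES into one SDFset (all must be valid); on failure
# identifies the offending string. OpenBabel silently truncates a batch at the
# first invalid entry, which is how invalid entries are detected here.
.parse_many <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  nms <- paste0("m", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nms))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != length(smiles)) {
    for (s in smiles) .parse_one(s)   # raises at the offender
    stop("SMILES batch parsing failed for an unidentified entry")
  }
  sdf
}

# OpenBabel properties (canonical SMILES, logP, ...) for one molecule, cached
.ob_props <- function(smiles) {
  key <- paste0("prop|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- .parse_one(smiles)
  p <- ChemmineR::propOB(sdf)
  .cache_set(key, as.list(p[1L, ]))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit-canonical form, so that the same chemical
#' graph always yields the same string. Canonicalization is idempotent.
#' Synthetic-backend tokens (`"z:..."`) are their own canonical form and pass
#' through unchanged.
#'
#' @param smiles character vector of SMILES strings (or toy tokens).
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize("C1=CC=CC=C1")   # "c1ccccc1"
#' }
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  if (any(!nzchar(smiles))) stop("empty SMILES string")
  vapply(smiles, function(s) {
    if (is_toy_token(s)) return(s)
    trimws(.ob_props(s)$cansmi)
  }, character(1), USE.NAMES = FALSE)
}

#' Octanol-water partition coefficient (logP)
#'
#' Computed logP of each molecule, from the toolkit's atom-contribution model.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
mol_logp <- function(smiles) {
  vapply(smiles, function(s) as.numeric(.ob_props(s)$logP), numeric(1),
         USE.NAMES = FALSE)
}

#' Match a molecule against a list of SMARTS patterns
#'
#' @param smiles character vector of SMILES.
#' @param patterns character vector of SMARTS; a molecule matches if at least
#'   one pattern has one or more substructure matches.
#' @return logical vector, `TRUE` where any pattern matches.
#' @export
matches_any_smarts <- function(smiles, patterns) {
  stopifnot(is.character(patterns), length(patterns) >= 1L)
  res <- rep(FALSE, length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- .parse_one(smiles[i])
    for (p in patterns) {
      n <- tryCatch(
        ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE),
        error = function(e) stop("invalid SMARTS pattern: '", p, "' (",
                                 conditionMessage(e), ")", call. = FALSE)
      )
      if (n > 0) { res[i] <- TRUE; break }
    }
  }
  res
}

# ---- ring perception -------------------------------------------------------

# smallest set of smallest rings, greedily selected from ChemmineR's ring
# perception up to the cyclomatic number; returns list(rings=<list of atom-name
# vectors>, aromatic=<logical>)
.sssr <- function(smiles) {
  key <- paste0("sssr|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- .parse_one(smiles)[[1]]
  bb <- ChemmineR::bondblock(sdf)
  ab <- ChemmineR::atomblock(sdf)
  n_atoms <- nrow(ab)
  n_bonds <- if (is.null(dim(bb))) 0L else nrow(bb)
  out <- list(rings = list(), aromatic = logical(0))
  if (n_bonds > 0L) {
    # cyclomatic number = bonds - atoms + components
    comp <- .graph_components(n_atoms, cbind(bb[, 1], bb[, 2]))
    n_sssr <- n_bonds - n_atoms + length(unique(comp))
    if (n_sssr > 0L) {
      r <- ChemmineR::rings(sdf, type = "all", arom = TRUE)
      rg <- r$RINGS
      ar <- as.logical(r$AROMATIC)
      ord <- order(lengths(rg))
      seen_edges <- character(0)
      keep <- integer(0)
      for (i in ord) {
        ring <- rg[[i]]
        e <- .ring_edges(ring)
        if (!all(e %in% seen_edges)) {
          keep <- c(keep, i)
          seen_edges <- union(seen_edges, e)
        }
        if (length(keep) == n_sssr) break
      }
      out <- list(rings = rg[keep], aromatic = ar[keep])
    }
  }
  .cache_set(key, out)
}

# edges of a ring given as an ordered atom-name vector, as sorted "a|b" keys
.ring_edges <- function(ring) {
  k <- length(ring)
  a <- ring
  b <- ring[c(2:k, 1)]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "|")
}

# connected components of an undirected graph over 1..n; edges: 2-col matrix
.graph_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
}

#' Count aromatic rings
#'
#' Number of aromatic rings in the smallest set of smallest rings (so
#' naphthalene counts 2, benzene 1). Deterministic per molecule.
#'
#' @param smiles character vector of SMILES.
#' @return non-negative integer vector.
#' @export
count_aromatic_rings <- function(smiles) {
  vapply(smiles, function(s) {
    r <- .sssr(s)
    sum(r$aromatic)
  }, integer(1), USE.NAMES = FALSE)
}

# ---- penalized logP --------------------------------------------------------

#' Penalized logP
#'
#' The physicochemical optimization objective: `logP(m) - SA(m)`, the computed
#' octanol-water partition coefficient minus the synthetic-accessibility
#' score. Both terms can be swapped out (e.g. for mock scorers in tests or a
#' different SA implementation).
#'
#' @param smiles character vector of SMILES.
#' @param logp_fun function mapping SMILES to logP; default [mol_logp()].
#' @param sa_fun function mapping SMILES to an SA score; default [sa_score()].
#' @return numeric vector of penalized logP values.
#' @export
penalized_logp <- function(smiles, logp_fun = mol_logp, sa_fun = sa_score) {
  logp_fun(smiles) - sa_fun(smiles)
}

#' Read molecules from a .smi or CSV file
#'
#' `.smi` files carry one SMILES per line with an optional
#' whitespace-separated name; CSV files must have a SMILES column.
#'
#' @param path file path.
#' @param smiles_col name of the SMILES column for CSV input.
#' @return character vector of SMILES (named when names are present).
#' @export
read_smiles <- function(path, smiles_col = "smiles") {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_col %in% names(d))
      stop("CSV has no column '", smiles_col, "'")
    return(as.character(d[[smiles_col]]))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  out <- vapply(parts, `[[`, character(1), 1L)
  nm <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
               character(1))
  if (any(!is.na(nm))) names(out) <- nm
  out
}
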