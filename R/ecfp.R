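# Circular (Morgan / ECFP-style) fingerprints computed from the molecular
# graph. Atom environments of radius 0..r are hashed with FNV-1a and folded
# onto a fixed-width bit vector. The resulting bits are toolkit-independent
# (they are not numerically identical to any other program's Morgan bits) but
# have the defining ECFP property: identical local environments collide,
# different ones almost never do.

# 32-bit FNV-1a over the UTF-8 bytes of a string; multiplication is done in
# 16-bit halves to stay exact in doubles
.fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- .xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of two numbers in [0, 2^32) held as doubles
.xor32 <- function(a, b) {
  r <- 0
  bit <- 1
  for (i in 1:32) {
    r <- r + bit * as.numeric((a %% 2) != (b %% 2))
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

# standard valences used to estimate implicit hydrogen counts
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, Si = 4)

# molecular graph with per-atom invariants; cached per SMILES
.mol_graph <- function(smiles) {
  key <- paste0("graph|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- .parse_one(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- rownames(ab)
  element <- sub("_.*$", "", atoms)
  n <- length(atoms)
  chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, n)
  charge <- vapply(chg_code, function(cc) {
    switch(as.character(cc), "1" = 3, "2" = 2, "3" = 1,
           "5" = -1, "6" = -2, "7" = -3, 0)
  }, numeric(1))
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- matrix(numeric(0), ncol = 3)
  } else {
    bonds <- cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  nb <- vector("list", n)          # neighbour indices
  nbo <- vector("list", n)         # matching bond orders
  degree <- integer(n)
  bondsum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]; o <- bonds[r, 3]
      nb[[a]] <- c(nb[[a]], b); nbo[[a]] <- c(nbo[[a]], o)
      nb[[b]] <- c(nb[[b]], a); nbo[[b]] <- c(nbo[[b]], o)
      degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
      bondsum[a] <- bondsum[a] + o; bondsum[b] <- bondsum[b] + o
    }
  }
  ss <- .sssr(smiles)
  in_ring <- atoms %in% unique(unlist(ss$rings))
  arom_atoms <- unique(unlist(ss$rings[ss$aromatic]))
  aromatic <- atoms %in% arom_atoms
  dv <- .default_valence[element]
  dv[is.na(dv)] <- 0
  n_h <- pmax(0, dv - bondsum + charge)
  g <- list(n = n, element = element, charge = charge, degree = degree,
            bondsum = bondsum, n_h = n_h, in_ring = in_ring,
            aromatic = aromatic, nb = nb, nbo = nbo)
  .cache_set(key, g)
}

# unfolded environment identifiers for radii 0..radius; returns numeric vector
# (one id per atom per radius)
.morgan_ids <- function(smiles, radius = 2L) {
  key <- paste0("mids|", radius, "|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- .mol_graph(smiles)
  ids <- vapply(seq_len(g$n), function(i) {
    .fnv1a(paste(g$element[i], g$degree[i], g$bondsum[i], g$charge[i],
                 g$n_h[i], as.integer(g$in_ring[i]),
                 as.integer(g$aromatic[i]), sep = ","))
  }, numeric(1))
  all_ids <- ids
  if (radius >= 1L && g$n > 0L) {
    cur <- ids
    for (r in seq_len(radius)) {
      nxt <- vapply(seq_len(g$n), function(i) {
        if (length(g$nb[[i]]) == 0L) {
          .fnv1a(paste("r", r, cur[i], sep = ","))
        } else {
          pairs <- paste(g$nbo[[i]], cur[g$nb[[i]]], sep = ":")
          .fnv1a(paste("r", r, cur[i],
                       paste(sort(pairs), collapse = ";"), sep = ","))
        }
      }, numeric(1))
      all_ids <- c(all_ids, nxt)
      cur <- nxt
    }
  }
  .cache_set(key, all_ids)
}

#' Morgan (ECFP-style) fingerprint
#'
#' Circular fingerprint of the molecular graph: atom environments of radius 0
#' up to `radius` are hashed and folded onto `bits` positions. The default
#' radius 2 / 2048 bits corresponds to common ECFP4 practice.
#'
#' @param smiles a single SMILES string.
#' @param radius maximum environment radius (default 2).
#' @param bits fingerprint width (default 2048).
#' @return sorted integer vector of set bit positions in `1..bits`.
#' @export
morgan_fp <- function(smiles, radius = 2L, bits = 2048L) {
  stopifnot(length(smiles) == 1L, bits >= 1L, radius >= 0L)
  key <- paste0("fp|", radius, "|", bits, "|", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  ids <- .morgan_ids(smiles, radius)
  .cache_set(key, sort(unique(as.integer(ids %% bits) + 1L)))
}

#' Tanimoto similarity on Morgan fingerprints
#'
#' Intersection over union of the two molecules' fingerprint bit sets.
#' If both fingerprints are empty the similarity is defined as 1 when the
#' canonical forms agree and 0 otherwise (with a warning).
#'
#' @param m1,m2 SMILES strings.
#' @inheritParams morgan_fp
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(m1, m2, radius = 2L, bits = 2048L) {
  f1 <- morgan_fp(m1, radius, bits)
  f2 <- morgan_fp(m2, radius, bits)
  u <- length(union(f1, f2))
  if (u == 0L) {
    warning("both fingerprints empty; similarity defined by canonical equality")
    return(if (identical(canonicalize(m1), canonicalize(m2))) 1 else 0)
  }
  length(intersect(f1, f2)) / u
}

#' Similarity between two molecules or backend tokens
#'
#' Dispatches on the representation: real molecules are compared by Tanimoto
#' similarity on Morgan fingerprints; synthetic-backend tokens (`"z:..."`) by
#' `1 / (1 + L1 distance)` between their grid-cell centres, which is 1 exactly
#' on identical tokens and decays with latent distance.
#'
#' @param a,b SMILES strings or toy tokens (both must be the same kind).
#' @param backend a [toy_backend()] when comparing tokens; defaults to a unit
#'   backend inferred from the token dimension.
#' @inheritParams morgan_fp
#' @return similarity in `[0, 1]`.
#' @export
mol_similarity <- function(a, b, backend = NULL, radius = 2L, bits = 2048L) {
  ta <- is_toy_token(a); tb <- is_toy_token(b)
  if (ta != tb) stop("cannot compare a molecule with a backend token")
  if (ta) {
    if (is.null(backend)) {
      d <- length(strsplit(sub("^z:", "", a), ",")[[1]])
      backend <- toy_backend(dimension = d)
    }
    za <- toy_encode(a, backend)
    zb <- toy_encode(b, backend)
    return(1 / (1 + sum(abs(za - zb))))
  }
  tanimoto(a, b, radius, bits)
}
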