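## Atom-centred circular fragments (ECFP4-style environments).
##
## Each heavy atom gets an identifier per radius 0..2 by iterative
## neighbourhood hashing, exactly as in extended-connectivity fingerprint
## generation but with unfolded identifiers: the identifier is a full-width
## integer derived from the environment invariants, not a folded bit
## position, so distinct environments essentially never collide.

HASH_MOD <- 2147483647  # 2^31 - 1; exact in doubles, fits R's 32-bit ints

## Polynomial rolling hash of a non-negative integer stream, modulo
## 2^31 - 1.  All intermediates stay below 2^52, so double arithmetic is
## exact and the result is identical across platforms.
hash_stream <- function(xs) {
  h <- 5381
  for (x in xs) {
    h <- (h * 131 + (x %% HASH_MOD)) %% HASH_MOD
  }
  h
}

## Initial (radius-0) atom invariants: element, heavy degree, implicit H,
## charge, aromaticity, ring membership.
atom_seed_ids <- function(mol) {
  n <- n_heavy_atoms(mol)
  inring <- ring_membership(mol)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  vapply(seq_len(n), function(i) {
    hash_stream(c(
      ELEMENT_NUMBERS[[mol$atoms$element[i]]], deg[i], mol$atoms$nH[i],
      mol$atoms$charge[i] + 8, as.integer(mol$atoms$aromatic[i]),
      as.integer(inring[i])
    ))
  }, numeric(1))
}

#' Per-atom circular environment identifiers
#'
#' Computes, for every heavy atom, the canonical identifier of its circular
#' environment at radii `0..max_radius` (ECFP-style iterative hashing over
#' sorted `(bond order, neighbour identifier)` pairs). The scoring policy
#' retains one fragment per heavy atom: the identifier at the radius-2 slot,
#' which for atoms whose full radius-2 ball exceeds the molecule holds the
#' largest realizable environment (radius = the atom's eccentricity). An
#' isolated atom only realizes a radius-0 environment, which the
#' radius-0/1 exclusion removes, so it retains nothing.
#'
#' @param mol A `molecule`.
#' @param max_radius Maximum environment radius (default 2, i.e. ECFP4).
#' @return A tibble with one row per atom and radius: `atom`, `radius`,
#'   `id` (environment identifier), and `retained` (TRUE for the one
#'   fragment per atom kept for scoring).
#' @examples
#' atom_environments(parse_molecule("CCO"))
#' @export
atom_environments <- function(mol, max_radius = 2L) {
  stopifnot(inherits(mol, "molecule"), max_radius >= 0L)
  n <- n_heavy_atoms(mol)
  if (n == 0L) {
    return(tibble::tibble(
      atom = integer(0), radius = integer(0),
      id = numeric(0), retained = logical(0)
    ))
  }
  ids <- matrix(0, nrow = n, ncol = max_radius + 1L)
  ids[, 1] <- atom_seed_ids(mol)

  b <- mol$bonds
  nbrs <- vector("list", n)
  bord <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbrs[[b$a1[k]]] <- c(nbrs[[b$a1[k]]], b$a2[k])
    bord[[b$a1[k]]] <- c(bord[[b$a1[k]]], b$order[k])
    nbrs[[b$a2[k]]] <- c(nbrs[[b$a2[k]]], b$a1[k])
    bord[[b$a2[k]]] <- c(bord[[b$a2[k]]], b$order[k])
  }

  if (max_radius >= 1L) {
    for (r in seq_len(max_radius)) {
      prev <- ids[, r]
      for (i in seq_len(n)) {
        if (length(nbrs[[i]]) == 0L) {
          ids[i, r + 1L] <- hash_stream(c(r, prev[i]))
        } else {
          pairs <- order(bord[[i]], prev[nbrs[[i]]])
          stream <- c(r, prev[i], rbind(
            bord[[i]][pairs], prev[nbrs[[i]]][pairs]
          ))
          ids[i, r + 1L] <- hash_stream(stream)
        }
      }
    }
  }

  ecc <- mol_eccentricity(mol)
  retained_radius <- pmin(max_radius, ecc)
  out <- tibble::tibble(
    atom = rep(seq_len(n), each = max_radius + 1L),
    radius = rep(0L:max_radius, times = n),
    id = as.numeric(t(ids))
  )
  out$retained <- out$radius == retained_radius[out$atom] & ecc[out$atom] > 0
  out
}

#' Retained scoring fragments of a molecule
#'
#' The one-fragment-per-heavy-atom set used for scoring, after excluding
#' radius-0/1 environments (which would otherwise dominate the corpus with
#' uninformative small fragments).
#'
#' @param mol A `molecule`.
#' @param max_radius Environment radius of the retained slot (default 2).
#' @return A tibble `atom`, `radius`, `id`; zero rows for molecules whose
#'   atoms are all isolated (e.g. methane).
#' @export
retained_fragments <- function(mol, max_radius = 2L) {
  env <- atom_environments(mol, max_radius)
  env[env$retained, c("atom", "radius", "id")]
}
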