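## Structural complexity penalty: size + stereo + ring + macrocycle.
##
##   size       = n_atoms^1.005 - n_atoms
##   stereo     = log10(n_chiral + 1)          (assigned centres only)
##   ring       = log10(n_bridgehead + 1) + log10(n_spiro + 1)
##   macrocycle = log10(n_macrocycle + 1)      (SSSR rings of size > 8)

#' Structural complexity penalty of a molecule
#'
#' Computes the four-term complexity penalty used alongside the fragment
#' score: molecule size, assigned stereocentres, bridgehead/spiro ring
#' atoms, and macrocycles. Counts are taken on the canonicalized molecule;
#' only explicitly assigned tetrahedral centres count as stereocentres
#' (the drawn structure is what gets scored), and a macrocycle is any SSSR
#' ring with more than 8 atoms.
#'
#' @param mol A `molecule`, or a SMILES string.
#' @return A one-row tibble (`complexity_breakdown`): the four counts
#'   (`n_atoms`, `n_chiral`, `n_bridgehead`, `n_spiro`, `n_macrocycle`),
#'   the four penalty terms (`size`, `stereo`, `ring`, `macrocycle`) and
#'   their sum `total`.
#' @examples
#' complexity_penalty("C1CCCCCCCCC1") # cyclodecane: macrocycle term log10(2)
#' @export
complexity_penalty <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "molecule"))
  n_atoms <- n_heavy_atoms(mol)
  n_chiral <- sum(mol$atoms$chiral > 0L)
  rings <- mol_rings(mol)
  rs <- ring_system_atoms(mol, rings)
  n_macro <- sum(lengths(rings) > 8L)

  size <- n_atoms^1.005 - n_atoms
  stereo <- log10(n_chiral + 1)
  ring <- log10(rs$n_bridgehead + 1) + log10(rs$n_spiro + 1)
  macrocycle <- log10(n_macro + 1)

  structure(
    tibble::tibble(
      n_atoms = n_atoms, n_chiral = n_chiral,
      n_bridgehead = rs$n_bridgehead, n_spiro = rs$n_spiro,
      n_macrocycle = n_macro,
      size = size, stereo = stereo, ring = ring, macrocycle = macrocycle,
      total = size + stereo + ring + macrocycle
    ),
    class = c("complexity_breakdown", "tbl_df", "tbl", "data.frame")
  )
}

## Bridgehead and spiro atoms from pairwise SSSR ring overlap:
## two rings sharing exactly one atom make it a spiro atom; two rings
## sharing two or more bonds (a bridge path) make the junction atoms --
## the shared atoms with degree >= 3 inside the ring-system subgraph --
## bridgeheads.  Ordinary fused rings (one shared bond) yield neither.
ring_system_atoms <- function(mol, rings = mol_rings(mol)) {
  if (length(rings) < 2L) return(list(n_bridgehead = 0L, n_spiro = 0L))
  edge_key <- function(r) {
    nxt <- c(r[-1], r[1])
    paste(pmin(r, nxt), pmax(r, nxt))
  }
  spiro <- integer(0)
  bridge <- integer(0)
  b <- mol$bonds
  deg_in <- function(atoms_set, atom) {
    sel <- (b$a1 == atom & b$a2 %in% atoms_set) | (b$a2 == atom & b$a1 %in% atoms_set)
    sum(sel)
  }
  for (i in seq_along(rings)) {
    for (j in seq_len(i - 1L)) {
      shared_atoms <- intersect(rings[[i]], rings[[j]])
      if (length(shared_atoms) == 1L) {
        spiro <- c(spiro, shared_atoms)
      } else if (length(shared_atoms) >= 2L) {
        shared_bonds <- intersect(edge_key(rings[[i]]), edge_key(rings[[j]]))
        if (length(shared_bonds) >= 2L) {
          union_atoms <- union(rings[[i]], rings[[j]])
          cand <- shared_atoms[vapply(
            shared_atoms, function(a) deg_in(union_atoms, a) >= 3L, logical(1)
          )]
          bridge <- c(bridge, cand)
        }
      }
    }
  }
  list(
    n_bridgehead = length(unique(bridge)),
    n_spiro = length(unique(setdiff(spiro, bridge)))
  )
}
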