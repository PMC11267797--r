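## Graph utilities on the molecule representation: adjacency, ring
## perception (SSSR), topological distances and eccentricities.

mol_igraph <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  }
  g
}

molecule_graph <- function(mol) mol_igraph(n_heavy_atoms(mol), mol$bonds)

adjacency_list <- function(mol) {
  n <- n_heavy_atoms(mol)
  adj <- vector("list", n)
  nbr_order <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  adj
}

## Smallest set of smallest rings.  For each cycle edge, the shortest cycle
## through it is found by deleting the edge and taking the shortest
## remaining path between its endpoints; candidates are deduplicated and
## accepted smallest-first until |E| - |V| + #components rings cover the
## cycle space.  Exact for the fused/bridged/spiro systems this package
## works with.
sssr_rings <- function(n, bonds) {
  n_edges <- nrow(bonds)
  if (n_edges == 0L) return(list())
  comp <- graph_components(n, bonds)
  n_rings <- n_edges - n + length(unique(comp))
  if (n_rings <= 0L) return(list())
  g <- mol_igraph(n, bonds)
  candidates <- list()
  for (k in seq_len(n_edges)) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds$a1[k], to = bonds$a2[k], mode = "all"
    )$vpath[[1]])
    if (length(sp) >= 3L) candidates[[length(candidates) + 1L]] <- as.integer(sp)
  }
  if (length(candidates) == 0L) return(list())
  keys <- vapply(candidates, function(r) paste(sort(r), collapse = ","), character(1))
  keep <- !duplicated(keys)
  candidates <- candidates[keep]
  sizes <- lengths(candidates)
  ord <- order(sizes, vapply(candidates, function(r) paste(sort(r), collapse = ","), character(1)))
  candidates <- candidates[ord]

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  covered <- character(0)
  chosen <- list()
  for (ring in candidates) {
    if (length(chosen) >= n_rings) break
    nxt <- c(ring[-1], ring[1])
    ekeys <- edge_key(ring, nxt)
    if (any(!ekeys %in% covered)) {
      chosen[[length(chosen) + 1L]] <- ring
      covered <- union(covered, ekeys)
    }
  }
  chosen
}

mol_rings <- function(mol) sssr_rings(n_heavy_atoms(mol), mol$bonds)

ring_membership <- function(mol) {
  inring <- rep(FALSE, n_heavy_atoms(mol))
  for (r in mol_rings(mol)) inring[r] <- TRUE
  inring
}

## All-pairs topological (bond-count) distances; Inf across components.
mol_distances <- function(mol) {
  igraph::distances(molecule_graph(mol))
}

## Eccentricity of each atom within its connected component.
mol_eccentricity <- function(mol) {
  d <- mol_distances(mol)
  d[is.infinite(d)] <- NA_real_
  apply(d, 1L, function(row) max(row, na.rm = TRUE))
}
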