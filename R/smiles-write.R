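## Canonical SMILES writing.
##
## Canonical atom ranks come from iterative invariant refinement
## (Morgan/Weisfeiler-Lehman style) seeded with (element, aromaticity,
## degree, H count, charge, ring membership) and tie-broken
## deterministically; the writer then emits a depth-first string with
## neighbours visited in rank order.  Tetrahedral stereo symbols are
## re-oriented by permutation parity so the written neighbour order encodes
## the same configuration that was parsed.

canonical_ranks <- function(mol) {
  n <- n_heavy_atoms(mol)
  if (n == 1L) return(1L)
  inring <- ring_membership(mol)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  seed_key <- paste(
    sprintf("%03d", ELEMENT_NUMBERS[mol$atoms$element]),
    as.integer(mol$atoms$aromatic), deg, mol$atoms$nH,
    sprintf("%+03d", mol$atoms$charge), as.integer(inring),
    mol$atoms$isotope,
    sep = "|"
  )
  rank <- match(seed_key, sort(unique(seed_key)))

  nbrs <- vector("list", n)
  bords <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nbrs[[b$a1[k]]] <- c(nbrs[[b$a1[k]]], b$a2[k])
    bords[[b$a1[k]]] <- c(bords[[b$a1[k]]], b$order[k])
    nbrs[[b$a2[k]]] <- c(nbrs[[b$a2[k]]], b$a1[k])
    bords[[b$a2[k]]] <- c(bords[[b$a2[k]]], b$order[k])
  }

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        if (length(nbrs[[i]]) == 0L) {
          sprintf("%04d|", rank[i])
        } else {
          pair <- sprintf("%d:%04d", bords[[i]], rank[nbrs[[i]]])
          sprintf("%04d|%s", rank[i], paste(sort(pair), collapse = ","))
        }
      }, character(1))
      new_rank <- match(key, sort(unique(key)))
      if (identical(new_rank, rank)) return(rank)
      rank <- new_rank
    }
  }

  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tied <- which(tabulate(rank) > 1L)
    target <- min(tied)
    i <- which(rank == target)[1]
    rank <- rank + as.integer(rank > target | (rank == target & seq_len(n) != i))
    rank[i] <- target
    rank <- refine(rank)
  }
  rank
}

#' Write a molecule as canonical SMILES
#'
#' @param mol A `molecule`.
#' @param with_maps Emit atom-map numbers (`[CH3:1]`-style) for atoms that
#'   carry them. Default drops maps.
#' @return A single SMILES string. Components of a multi-component molecule
#'   are written in sorted order joined by `.`.
#' @examples
#' write_smiles(parse_molecule("OCC")) # same as for "CCO"
#' @export
write_smiles <- function(mol, with_maps = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  rank <- canonical_ranks(mol)
  comps <- split(seq_len(n_heavy_atoms(mol)), mol$atoms$component)
  pieces <- vapply(
    comps,
    function(atoms) write_component(mol, atoms, rank, with_maps),
    character(1)
  )
  paste(sort(unname(pieces)), collapse = ".")
}

write_component <- function(mol, atoms, rank, with_maps) {
  n <- n_heavy_atoms(mol)
  b <- mol$bonds
  nbrs <- vector("list", n)
  bord <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbrs[[b$a1[k]]] <- c(nbrs[[b$a1[k]]], b$a2[k])
    bord[[b$a1[k]]] <- c(bord[[b$a1[k]]], b$order[k])
    nbrs[[b$a2[k]]] <- c(nbrs[[b$a2[k]]], b$a1[k])
    bord[[b$a2[k]]] <- c(bord[[b$a2[k]]], b$order[k])
  }

  start <- atoms[which.min(rank[atoms])]

  ## DFS pass to classify tree vs ring-closure bonds in emission order
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  ring_pairs <- list()
  order_children <- vector("list", n)
  dfs_stack <- list(start)
  visited[start] <- TRUE
  seen_edges <- character(0)
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  dfs <- function(v) {
    nb <- nbrs[[v]]
    if (length(nb) == 0L) return(invisible())
    for (u in nb[order(rank[nb])]) {
      ek <- edge_key(v, u)
      if (ek %in% seen_edges) next
      seen_edges <<- c(seen_edges, ek)
      if (!visited[u]) {
        visited[u] <<- TRUE
        parent[u] <<- v
        order_children[[v]] <<- c(order_children[[v]], u)
        dfs(u)
      } else {
        ring_pairs[[length(ring_pairs) + 1L]] <<- c(v, u)
      }
    }
  }
  dfs(start)

  ## assign ring-closure digits in the order the opening atom is written
  emit_order <- integer(0)
  walk <- function(v) {
    emit_order <<- c(emit_order, v)
    for (u in order_children[[v]]) walk(u)
  }
  walk(start)
  pos_of <- match(seq_len(n), emit_order)

  ring_at <- vector("list", n)   # per atom: partner list in digit order
  digit_of <- list()
  next_digit <- 1L
  if (length(ring_pairs) > 0L) {
    firsts <- vapply(ring_pairs, function(p) min(pos_of[p], na.rm = TRUE), numeric(1))
    for (p in ring_pairs[order(firsts)]) {
      a <- p[1]; b2 <- p[2]
      d <- next_digit
      next_digit <- next_digit + 1L
      digit_of[[edge_key(a, b2)]] <- d
      ring_at[[a]] <- c(ring_at[[a]], b2)
      ring_at[[b2]] <- c(ring_at[[b2]], a)
    }
  }

  bond_sym <- function(order, a, u) {
    if (order == 1L) {
      ## explicit single between two aromatic atoms (e.g. biphenyl)
      if (mol$atoms$aromatic[a] && mol$atoms$aromatic[u]) "-" else ""
    } else if (order == 2L) "=" else if (order == 3L) "#" else ""
  }
  order_between <- function(a, u) {
    sel <- (b$a1 == a & b$a2 == u) | (b$a1 == u & b$a2 == a)
    b$order[sel][1]
  }

  out <- character(0)
  emitted_digits <- character(0)
  write_atom <- function(v) {
    ## written neighbour order, for stereo parity
    ord_out <- character(0)
    if (!is.na(parent[v])) ord_out <- c(ord_out, as.character(parent[v]))
    has_h_slot <- mol$atoms$chiral[v] > 0L && mol$atoms$nH[v] > 0L
    if (has_h_slot) ord_out <- c(ord_out, "H")
    ring_partners <- ring_at[[v]]
    if (length(ring_partners) > 0L) {
      ring_partners <- ring_partners[order(vapply(
        ring_partners, function(u) digit_of[[edge_key(v, u)]], integer(1)
      ))]
      ord_out <- c(ord_out, as.character(ring_partners))
    }
    ord_out <- c(ord_out, as.character(order_children[[v]]))

    out <<- c(out, atom_token(mol, v, ord_out, with_maps))

    for (u in ring_partners) {
      d <- digit_of[[edge_key(v, u)]]
      dtok <- if (d < 10L) as.character(d) else sprintf("%%%02d", d)
      sym <- if (dtok %in% emitted_digits) "" else bond_sym(order_between(v, u), v, u)
      emitted_digits <<- c(emitted_digits, dtok)
      out <<- c(out, sym, dtok)
    }
    kids <- order_children[[v]]
    if (length(kids) > 0L) {
      for (j in seq_along(kids)) {
        u <- kids[j]
        piece <- c(bond_sym(order_between(v, u), v, u))
        if (j < length(kids)) {
          out <<- c(out, "(", piece)
          write_atom(u)
          out <<- c(out, ")")
        } else {
          out <<- c(out, piece)
          write_atom(u)
        }
      }
    }
  }
  write_atom(start)
  paste(out, collapse = "")
}

## Atom token, bracketed only when necessary; chiral symbol re-oriented to
## the written neighbour order via permutation parity.
atom_token <- function(mol, v, ord_out, with_maps) {
  a <- mol$atoms[v, ]
  elem <- a$element
  sym <- if (a$aromatic) tolower(elem) else elem
  chiral <- a$chiral
  if (chiral > 0L) {
    ord_in <- mol$stereo_order[[v]]
    if (length(ord_in) == length(ord_out) && length(ord_in) == 4L &&
        setequal(ord_in, ord_out)) {
      if (permutation_parity(match(ord_out, ord_in)) == -1L) {
        chiral <- if (chiral == 1L) 2L else 1L
      }
    }
  }
  map <- if (with_maps) a$map else 0L
  default_h <- implied_h_for_token(mol, v)
  needs_bracket <- a$charge != 0L || a$isotope != 0L || chiral > 0L ||
    map > 0L || !elem %in% ORGANIC_SUBSET || is.na(default_h) ||
    default_h != a$nH
  if (!needs_bracket) return(sym)
  h <- a$nH
  paste0(
    "[",
    if (a$isotope > 0L) a$isotope else "",
    sym,
    if (chiral == 1L) "@" else if (chiral == 2L) "@@" else "",
    if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
    charge_token(a$charge),
    if (map > 0L) paste0(":", map) else "",
    "]"
  )
}

charge_token <- function(chg) {
  if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
  else if (chg > 1L) paste0("+", chg) else paste0("-", abs(chg))
}

## H count a reader would infer for the unbracketed token, or NA if the
## atom cannot be written without a bracket.
implied_h_for_token <- function(mol, v) {
  elem <- mol$atoms$element[v]
  if (!elem %in% ORGANIC_SUBSET) return(NA_integer_)
  sel <- mol$bonds$a1 == v | mol$bonds$a2 == v
  ord <- mol$bonds$order[sel]
  if (mol$atoms$aromatic[v]) {
    if (!tolower(elem) %in% AROMATIC_SUBSET) return(NA_integer_)
    deg <- sum(sel)
    if (elem == "C") {
      extra <- sum(ord[ord %in% c(2L, 3L)] - 1L)
      return(max(0L, 3L - deg - extra))
    }
    return(0L)
  }
  bsum <- sum(ifelse(ord == 4L, 1L, ord))
  val <- DEFAULT_VALENCES[[elem]]
  v2 <- val[val >= bsum]
  if (length(v2) == 0L) return(0L)
  as.integer(v2[1] - bsum)
}

permutation_parity <- function(perm) {
  n <- length(perm)
  visited <- rep(FALSE, n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (visited[i]) next
    len <- 0L
    j <- i
    while (!visited[j]) {
      visited[j] <- TRUE
      j <- perm[j]
      len <- len + 1L
    }
    if (len %% 2L == 0L) sign <- -sign
  }
  sign
}

#' Canonical SMILES of a SMILES string
#'
#' Convenience wrapper: parse then write canonically.
#' @param smiles A SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) write_smiles(parse_molecule(smiles))
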