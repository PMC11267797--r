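## Atom-mapped reactions: parsing/validation, reaction-centre detection and
## reaction-driven fragment (RFrag) extraction.

#' Parse an atom-mapped reaction SMILES
#'
#' Accepts `reactants>>products` (an empty agents field, as in
#' `reactants>agents>products`, is tolerated and agents are ignored).
#' Validation enforces the atom-map contract RFrag extraction relies on:
#' every product heavy atom carries a map number, map numbers are unique
#' within each side, and every product map number occurs on a reactant
#' atom.
#'
#' @param text A reaction SMILES string with atom maps.
#' @return An object of class `mapped_reaction`: lists `reactants` and
#'   `products` of `molecule` objects plus the source text.
#' @examples
#' rxn <- parse_mapped_reaction(
#'   "[CH3:1][C:2](=[O:3])[OH:4].[OH:5][CH3:6]>>[CH3:1][C:2](=[O:3])[O:5][CH3:6]"
#' )
#' @export
parse_mapped_reaction <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("parse_mapped_reaction() needs a single non-empty reaction SMILES", call. = FALSE)
  }
  text <- trimws(text)
  sides <- strsplit(text, ">", fixed = TRUE)[[1]]
  sides <- if (length(sides) == 3L && !nzchar(sides[2])) {
    sides[c(1, 3)]
  } else if (grepl(">>", text, fixed = TRUE)) {
    parts <- strsplit(text, ">>", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("reaction '%s' must have exactly one '>>' separator", text), call. = FALSE)
    }
    parts
  } else {
    stop(sprintf("reaction '%s' lacks a '>>' separator", text), call. = FALSE)
  }
  if (!nzchar(sides[1]) || !nzchar(sides[2])) {
    stop(sprintf("reaction '%s' has an empty side", text), call. = FALSE)
  }
  parse_side <- function(s) {
    lapply(strsplit(s, ".", fixed = TRUE)[[1]], parse_molecule)
  }
  reactants <- parse_side(sides[1])
  products <- parse_side(sides[2])

  side_maps <- function(mols) unlist(lapply(mols, function(m) m$atoms$map))
  rmaps <- side_maps(reactants)
  pmaps <- side_maps(products)
  dup_r <- unique(rmaps[rmaps > 0][duplicated(rmaps[rmaps > 0])])
  dup_p <- unique(pmaps[pmaps > 0][duplicated(pmaps[pmaps > 0])])
  if (length(dup_r) > 0L || length(dup_p) > 0L) {
    stop(sprintf(
      "reaction '%s': duplicate atom-map number(s) %s on one side",
      text, paste(c(dup_r, dup_p), collapse = ", ")
    ), call. = FALSE)
  }
  if (any(pmaps == 0L)) {
    stop(sprintf("reaction '%s': product atom(s) without atom-map numbers", text), call. = FALSE)
  }
  orphans <- setdiff(pmaps, rmaps)
  if (length(orphans) > 0L) {
    stop(sprintf(
      "reaction '%s': product map(s) %s have no reactant counterpart",
      text, paste(orphans, collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(reactants = reactants, products = products, source_text = text),
    class = "mapped_reaction"
  )
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat(
    "<mapped_reaction> ", length(x$reactants), " reactant(s) >> ",
    length(x$products), " product(s): ", x$source_text, "\n",
    sep = ""
  )
  invisible(x)
}

## map number -> (molecule index, atom index) lookup for one side
map_index <- function(mols) {
  out <- list()
  for (j in seq_along(mols)) {
    mp <- mols[[j]]$atoms$map
    for (i in which(mp > 0L)) out[[as.character(mp[i])]] <- c(j, i)
  }
  out
}

## For one atom: the multiset of (neighbour map number, bond order) pairs,
## as a sorted character key.  Unmapped neighbours appear as map 0.
atom_bond_signature <- function(mol, i) {
  b <- mol$bonds
  sel <- b$a1 == i | b$a2 == i
  if (!any(sel)) return("")
  other <- ifelse(b$a1[sel] == i, b$a2[sel], b$a1[sel])
  paste(sort(paste0(mol$atoms$map[other], ":", b$order[sel])), collapse = ",")
}

#' Detect the reaction centre of a mapped reaction
#'
#' A product atom belongs to the centre iff, matched to its reactant
#' counterpart through the atom map, its set of (neighbour map number,
#' bond order) pairs or its attached-hydrogen count differs, or it has no
#' reactant counterpart at all.
#'
#' @param rxn A validated `mapped_reaction`.
#' @return A tibble of centre atoms: `product` (index into `rxn$products`),
#'   `atom` (atom index within that product), `map`. Zero rows for an
#'   identity reaction.
#' @export
detect_reaction_center <- function(rxn) {
  stopifnot(inherits(rxn, "mapped_reaction"))
  rmap <- map_index(rxn$reactants)
  rows <- list()
  for (j in seq_along(rxn$products)) {
    prod <- rxn$products[[j]]
    for (i in seq_len(n_heavy_atoms(prod))) {
      m <- prod$atoms$map[i]
      loc <- rmap[[as.character(m)]]
      changed <- if (is.null(loc)) {
        TRUE
      } else {
        react <- rxn$reactants[[loc[1]]]
        ri <- loc[2]
        atom_bond_signature(prod, i) != atom_bond_signature(react, ri) ||
          prod$atoms$nH[i] != react$atoms$nH[ri] ||
          prod$atoms$charge[i] != react$atoms$charge[ri]
      }
      if (changed) rows[[length(rows) + 1L]] <- c(j, i, m)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(product = integer(0), atom = integer(0), map = integer(0)))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(product = m[, 1], atom = m[, 2], map = m[, 3])
}

#' Extract reaction-driven fragments (RFrags) from one reaction
#'
#' Every product atom at shortest topological distance `d` in {0, 1, 2}
#' from the nearest reaction-centre atom contributes its retained radius-2
#' fragment with weight `2^-d`; atoms further than two bonds contribute
#' nothing. The weighted total accumulates into the corpus total `N_R`.
#'
#' @param rxn A `mapped_reaction`.
#' @param center Centre tibble from [detect_reaction_center()]; computed if
#'   missing.
#' @return A `fragment_counts` object with `source = "reactions"`.
#' @export
extract_rfrags <- function(rxn, center = detect_reaction_center(rxn)) {
  stopifnot(inherits(rxn, "mapped_reaction"))
  if (nrow(center) == 0L) {
    warning("reaction has an empty centre; no RFrags extracted", call. = FALSE)
    return(new_fragment_counts(source = "reactions"))
  }
  ids <- numeric(0)
  radii <- integer(0)
  weights <- numeric(0)
  for (j in seq_along(rxn$products)) {
    catoms <- center$atom[center$product == j]
    if (length(catoms) == 0L) next
    prod <- rxn$products[[j]]
    d <- mol_distances(prod)
    dmin <- apply(d[, catoms, drop = FALSE], 1L, min)
    frags <- retained_fragments(prod)
    sel <- match(frags$atom, seq_len(n_heavy_atoms(prod)))
    dist <- dmin[frags$atom]
    keep <- is.finite(dist) & dist <= 2
    ids <- c(ids, frags$id[keep])
    radii <- c(radii, frags$radius[keep])
    weights <- c(weights, 2^(-dist[keep]))
  }
  counts_from_occurrences(ids, radii, weights, source = "reactions",
                          total = sum(weights), n_records = 1L)
}
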