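## SMILES parsing into a molecular graph.
##
## The graph representation is deliberately small: a data frame of heavy
## atoms, a data frame of bonds, and per-atom neighbour orderings kept for
## tetrahedral stereo bookkeeping.  Hydrogens are implicit throughout; only
## heavy atoms define fragment centres.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

ELEMENT_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Zn = 30, Se = 34, Br = 35,
  Sn = 50, I = 53
)

## Default valences used for implicit-hydrogen inference (Daylight rules);
## multi-valent entries are tried smallest-first.
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecule
#'
#' Parses a (possibly multi-component, possibly atom-mapped) SMILES string
#' into a heavy-atom molecular graph with implicit hydrogen counts, formal
#' charges, aromaticity flags and assigned tetrahedral stereocentres.
#' Six-membered carbon/nitrogen rings written in Kekule form with
#' alternating double bonds are perceived as aromatic so that both
#' spellings of e.g. benzene canonicalize identically.
#'
#' @param text A single SMILES string.
#' @return An object of class `molecule`: a list with an `atoms` tibble
#'   (element, aromatic, charge, nH, map, chiral, isotope, component),
#'   a `bonds` tibble (`a1`, `a2`, `order`; order 4 denotes aromatic),
#'   stereo neighbour orderings, and the original input in `source_text`.
#' @examples
#' mol <- parse_molecule("CC(=O)Oc1ccccc1C(=O)O") # aspirin
#' n_heavy_atoms(mol)
#' @export
parse_molecule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("parse_molecule() needs a single non-empty SMILES string", call. = FALSE)
  }
  text <- trimws(text)
  g <- parse_smiles_graph(text)
  g <- perceive_kekule_aromaticity(g)
  g$atoms$nH <- compute_implicit_h(g)
  g$atoms$component <- graph_components(nrow(g$atoms), g$bonds)
  structure(
    list(
      atoms = tibble::as_tibble(g$atoms),
      bonds = tibble::as_tibble(g$bonds),
      stereo_order = g$stereo_order,
      source_text = text
    ),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(
    "<molecule> ", n_heavy_atoms(x), " heavy atoms, ", nrow(x$bonds),
    " bonds: ", x$source_text, "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer heavy-atom count.
#' @export
n_heavy_atoms <- function(mol) nrow(mol$atoms)

## --- low-level SMILES scanner -------------------------------------------

parse_smiles_graph <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)
  pos <- 1L

  elements <- character(0)
  aromatic <- logical(0)
  charge <- integer(0)
  h_explicit <- integer(0)   # NA when not bracket-specified
  map <- integer(0)
  chiral <- integer(0)       # 0 none, 1 @, 2 @@
  isotope <- integer(0)
  is_bracket <- logical(0)

  bond_a1 <- integer(0)
  bond_a2 <- integer(0)
  bond_order <- integer(0)

  stereo_order <- list()

  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NA_integer_
  ring_open <- list()  # digit -> list(atom, order, slot-resolved later)

  peek <- function() if (pos <= n_ch) chars[pos] else ""

  add_atom <- function(elem, arom, chg, hx, mp, chi, iso, bracket) {
    elements[length(elements) + 1L] <<- elem
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    h_explicit[length(h_explicit) + 1L] <<- hx
    map[length(map) + 1L] <<- mp
    chiral[length(chiral) + 1L] <<- chi
    isotope[length(isotope) + 1L] <<- iso
    is_bracket[length(is_bracket) + 1L] <<- bracket
    idx <- length(elements)
    stereo_order[[idx]] <<- character(0)
    idx
  }

  add_bond <- function(a, b, order) {
    bond_a1[length(bond_a1) + 1L] <<- a
    bond_a2[length(bond_a2) + 1L] <<- b
    bond_order[length(bond_order) + 1L] <<- order
  }

  bond_order_between <- function(a, b) {
    if (!is.na(pending_bond)) {
      o <- pending_bond
      pending_bond <<- NA_integer_
      return(o)
    }
    if (aromatic[a] && aromatic[b]) 4L else 1L
  }

  fail <- function(why) {
    stop(sprintf("invalid SMILES '%s': %s", text, why), call. = FALSE)
  }

  while (pos <= n_ch) {
    ch <- chars[pos]
    if (ch == "[") {
      close_i <- pos + 1L
      while (close_i <= n_ch && chars[close_i] != "]") close_i <- close_i + 1L
      if (close_i > n_ch) fail("unclosed bracket atom")
      body <- paste(chars[(pos + 1L):(close_i - 1L)], collapse = "")
      at <- parse_bracket_atom(body, fail)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$hcount, at$map,
                      at$chiral, at$isotope, TRUE)
      if (!is.na(prev)) {
        add_bond(prev, idx, bond_order_between(prev, idx))
        stereo_order[[prev]] <- c(stereo_order[[prev]], as.character(idx))
        stereo_order[[idx]] <- c(stereo_order[[idx]], as.character(prev))
      }
      if (at$hcount > 0L && at$chiral > 0L) {
        stereo_order[[idx]] <- c(stereo_order[[idx]], "H")
      }
      prev <- idx
      pos <- close_i + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- paste0(ch, peek_at(chars, pos + 1L))
      if (two %in% c("Cl", "Br")) {
        elem <- two
        pos <- pos + 2L
      } else {
        elem <- ch
        pos <- pos + 1L
      }
      idx <- add_atom(elem, FALSE, 0L, NA_integer_, 0L, 0L, 0L, FALSE)
      if (!is.na(prev)) {
        add_bond(prev, idx, bond_order_between(prev, idx))
        stereo_order[[prev]] <- c(stereo_order[[prev]], as.character(idx))
        stereo_order[[idx]] <- c(stereo_order[[idx]], as.character(prev))
      }
      prev <- idx
    } else if (ch %in% AROMATIC_SUBSET) {
      pos <- pos + 1L
      idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, 0L, 0L, FALSE)
      if (!is.na(prev)) {
        add_bond(prev, idx, bond_order_between(prev, idx))
        stereo_order[[prev]] <- c(stereo_order[[prev]], as.character(idx))
        stereo_order[[idx]] <- c(stereo_order[[idx]], as.character(prev))
      }
      prev <- idx
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L,
                             "/" = 1L, "\\" = 1L)
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (pos + 2L > n_ch) fail("truncated %% ring closure")
        digit <- paste(chars[(pos + 1L):(pos + 2L)], collapse = "")
        pos <- pos + 3L
      } else {
        digit <- ch
        pos <- pos + 1L
      }
      if (is.na(prev)) fail("ring closure before any atom")
      key <- digit
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        if (op$atom == prev) fail(sprintf("ring bond %s closes on itself", key))
        order <- if (!is.na(pending_bond)) {
          o <- pending_bond; pending_bond <- NA_integer_; o
        } else if (!is.na(op$order)) {
          op$order
        } else if (aromatic[op$atom] && aromatic[prev]) 4L else 1L
        add_bond(op$atom, prev, order)
        ## fill the placeholder slot on the opening atom, append on closer
        slot <- match(paste0("ring", key), stereo_order[[op$atom]])
        stereo_order[[op$atom]][slot] <- as.character(prev)
        stereo_order[[prev]] <- c(stereo_order[[prev]], as.character(op$atom))
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, order = pending_bond)
        pending_bond <- NA_integer_
        stereo_order[[prev]] <- c(stereo_order[[prev]], paste0("ring", key))
      }
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pos <- pos + 1L
    } else if (ch == " " || ch == "\t") {
      break  # trailing title field
    } else {
      fail(sprintf("unexpected character '%s' at position %d", ch, pos))
    }
  }
  if (length(ring_open) > 0L) fail("unclosed ring bond")
  if (length(stack) > 0L) fail("unmatched '('")
  if (length(elements) == 0L) fail("no atoms")

  list(
    atoms = data.frame(
      element = elements, aromatic = aromatic, charge = charge,
      nH = h_explicit, map = map, chiral = chiral, isotope = isotope,
      bracket = is_bracket, stringsAsFactors = FALSE
    ),
    bonds = data.frame(a1 = bond_a1, a2 = bond_a2, order = bond_order),
    stereo_order = stereo_order
  )
}

peek_at <- function(chars, i) if (i <= length(chars)) chars[i] else ""

parse_bracket_atom <- function(body, fail) {
  rx <- paste0(
    "^(?<iso>[0-9]*)",
    "(?<elem>[A-Z][a-z]?|b|c|n|o|p|s|se|as)",
    "(?<chi>@{1,2})?",
    "(?<h>H[0-9]*)?",
    "(?<chg>\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?",
    "(?<map>:[0-9]+)?$"
  )
  m <- regexpr(rx, body, perl = TRUE)
  if (m == -1L) fail(sprintf("cannot parse bracket atom '[%s]'", body))
  cap <- function(name) {
    st <- attr(m, "capture.start")[, name]
    ln <- attr(m, "capture.length")[, name]
    if (ln == 0L) "" else substr(body, st, st + ln - 1L)
  }
  elem_raw <- cap("elem")
  arom <- elem_raw %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  elem <- if (arom) {
    paste0(toupper(substr(elem_raw, 1, 1)), substring(elem_raw, 2))
  } else {
    elem_raw
  }
  if (!elem %in% names(ELEMENT_NUMBERS)) fail(sprintf("unsupported element '%s'", elem_raw))
  hstr <- cap("h")
  hcount <- if (hstr == "") 0L else if (hstr == "H") 1L else as.integer(substring(hstr, 2))
  chgstr <- cap("chg")
  chg <- if (chgstr == "") {
    0L
  } else if (grepl("^[+-][0-9]$", chgstr)) {
    as.integer(chgstr)
  } else {
    sgn <- if (substr(chgstr, 1, 1) == "+") 1L else -1L
    sgn * nchar(chgstr)
  }
  chistr <- cap("chi")
  chi <- if (chistr == "") 0L else if (chistr == "@") 1L else 2L
  mapstr <- cap("map")
  mp <- if (mapstr == "") 0L else as.integer(substring(mapstr, 2))
  iso <- cap("iso")
  list(
    element = elem, aromatic = arom, charge = chg, hcount = hcount,
    map = mp, chiral = chi, isotope = if (iso == "") 0L else as.integer(iso)
  )
}

## --- perception helpers --------------------------------------------------

## Aromatize benzene/pyridine-type rings written in Kekule form: 6-membered
## rings of C/N with strictly alternating single/double ring bonds.
perceive_kekule_aromaticity <- function(g) {
  if (nrow(g$bonds) == 0L) return(g)
  rings <- sssr_rings(nrow(g$atoms), g$bonds)
  if (length(rings) == 0L) return(g)
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  order_of <- stats::setNames(g$bonds$order, bond_key(g$bonds$a1, g$bonds$a2))
  for (ring in rings) {
    if (length(ring) != 6L) next
    if (!all(g$atoms$element[ring] %in% c("C", "N"))) next
    if (any(g$atoms$aromatic[ring])) next
    nxt <- c(ring[-1], ring[1])
    orders <- unname(order_of[bond_key(ring, nxt)])
    if (any(is.na(orders))) next
    ok <- identical(orders %% 2L, c(0L, 1L, 0L, 1L, 0L, 1L) ) ||
      identical(orders %% 2L, c(1L, 0L, 1L, 0L, 1L, 0L))
    ok <- ok && all(orders %in% c(1L, 2L))
    if (!ok) next
    g$atoms$aromatic[ring] <- TRUE
    keys <- bond_key(ring, nxt)
    g$bonds$order[bond_key(g$bonds$a1, g$bonds$a2) %in% keys] <- 4L
  }
  g
}

## Implicit hydrogen counts.  Bracket atoms keep their explicit count;
## organic-subset atoms get Daylight default-valence inference; unbracketed
## aromatic atoms follow the usual convention (c: 3 - degree, n/o/s: 0).
compute_implicit_h <- function(g) {
  n <- nrow(g$atoms)
  nH <- g$atoms$nH
  deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = n)
  for (i in seq_len(n)) {
    if (g$atoms$bracket[i]) next  # explicit in bracket (possibly 0)
    elem <- g$atoms$element[i]
    if (g$atoms$aromatic[i]) {
      if (elem == "C") {
        extra <- bond_order_excess(g, i)
        nH[i] <- max(0L, 3L - deg[i] - extra)
      } else {
        nH[i] <- 0L
      }
    } else {
      bsum <- sum_bond_orders(g, i)
      val <- DEFAULT_VALENCES[[elem]]
      if (is.null(val)) {
        nH[i] <- 0L
      } else {
        v <- val[val >= bsum]
        nH[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - bsum)
      }
    }
  }
  as.integer(nH)
}

sum_bond_orders <- function(g, i) {
  sel <- g$bonds$a1 == i | g$bonds$a2 == i
  if (!any(sel)) return(0L)
  ord <- g$bonds$order[sel]
  sum(ifelse(ord == 4L, 1L, ord))
}

## number of "extra" valence units from non-aromatic multiple bonds on an
## aromatic atom (e.g. an exocyclic carbonyl)
bond_order_excess <- function(g, i) {
  sel <- (g$bonds$a1 == i | g$bonds$a2 == i) & g$bonds$order %in% c(2L, 3L)
  if (!any(sel)) 0L else sum(g$bonds$order[sel] - 1L)
}

graph_components <- function(n, bonds) {
  comp <- seq_len(n)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      ra <- find(bonds$a1[k]); rb <- find(bonds$a2[k])
      if (ra != rb) comp[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
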