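## Deterministic synthetic corpus generation: a desk-scale stand-in for a
## purchasable-reagent catalog and an atom-mapped reaction dataset.
##
## Building blocks are assembled combinatorially from small substituent
## pools (acids, alcohols, amines, alkyl halides, aldehydes over shared
## alkyl/aryl substituents), reactions apply four classic families
## (esterification, amide coupling, SN2 substitution, reductive amination)
## to those blocks with atom maps constructed alongside the product, and
## the labeled query set pairs products of those families (easy to
## synthesize, "ES") against exotic structures absent from the corpus
## (hard, "HS").

SUB_ALKYL <- c("C", "CC", "CCC", "CCCC", "CC(C)")
SUB_ARYL <- c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(F)cc1", "c1ccncc1")
SUB_BENZYL <- c("c1ccccc1C", "c1ccc(C)cc1C")
TAIL_NUCLEOPHILE <- c("C", "CC", "CCC", "CC(C)", "c1ccccc1", "(C)C", "(C)CC")

## homologous substituents used only to pad the building-block catalog:
## chains and rings sharing circular environments with the reaction pools,
## the way real catalogs carry long homologous series
BLOCK_ALKYL <- c(SUB_ALKYL, "CCCCC", "CCCCCC", "CCCCCCC", "CCC(C)", "CCCC(C)")
BLOCK_ARYL <- c(SUB_ARYL, "c1ccc(Cl)cc1", "c1ccc(OC)cc1", "c1ccc(CC)cc1")
BLOCK_BENZYL <- c(SUB_BENZYL, "c1ccc(F)cc1C", "c1ccc(Cl)cc1C")

## Exotic structures used as hard-to-synthesize queries: spiro and bridged
## cages, macrocycles, cumulated/strained systems, dense halogenation,
## stereocentre clusters -- motifs deliberately absent from the
## building-block and reaction corpora.
HS_POOL <- c(
  "C1CC2(CC1)CCOC2",
  "C1CC2(CCC1)CCNC2",
  "C1CC2CCC1C2",
  "C1CC2CCC1CC2",
  "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  "FC1(F)C(F)(F)C(F)(F)C1(F)F",
  "C1CCCCCCCCCCC1",
  "O1CCCCCCCCCCC1",
  "C1CCCCCCCCCC1",
  "CC=C=C=CC#N",
  "CC(=C=C)C#CC#N",
  "CCOP(=O)(OCC)OP(=O)(OCC)OCC",
  "IC(I)C(I)C(I)I",
  "C[C@H](N)[C@@H](O)[C@H](S)C(F)(F)F",
  "O[C@H]1CC[C@@H](O)[C@H](O)C1",
  "C[C@@H]1CC[C@H](C(F)(F)F)C[C@@H]1N",
  "S1CCC2(CC1)COC2",
  "N1=C=NC=C1I",
  "CC1(C)C2CCC1(C)C(=O)C2",
  "BrC1=C=C1Br",
  "C1OC2(OC1)OCCO2",
  "CC12CC3(C)CC(C)(C1)CC(C)(C2)C3",
  "O=S(=O)(C=C=C)S(=O)(=O)C#C",
  "[C@H]1(O)[C@@H](O)[C@H](O)[C@@H](O)[C@H](O)C1"
)

#' Fixture specification
#'
#' @param seed Integer random seed. Required: the corpus is a study
#'   condition, so there is no nondeterministic default.
#' @param n_building_blocks Number of building blocks (default 60).
#' @param n_reactions Number of atom-mapped reactions (default 40).
#' @param n_queries Number of labeled query molecules, split evenly
#'   between ES and HS (default 40).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_building_blocks = 60L, n_reactions = 40L,
                         n_queries = 40L) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("fixture_spec() requires an integer seed", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_building_blocks = as.integer(n_building_blocks),
      n_reactions = as.integer(n_reactions),
      n_queries = as.integer(n_queries)
    ),
    class = "fixture_spec"
  )
}

## count heavy atoms of a substituent string (tails may start with a
## branch, so count them attached to a carbon)
sub_n_atoms <- function(sub) {
  if (startsWith(sub, "(")) {
    n_heavy_atoms(parse_molecule(paste0("C", sub))) - 1L
  } else {
    n_heavy_atoms(parse_molecule(sub))
  }
}

## write a SMILES string with maps assigned by token (= atom index) order
mapped_smiles <- function(smiles, maps) {
  mol <- parse_molecule(smiles)
  stopifnot(length(maps) == n_heavy_atoms(mol))
  mol$atoms$map <- as.integer(maps)
  write_smiles(mol, with_maps = TRUE)
}

## Assemble one atom-mapped reaction of the given family.  Maps are known
## by construction because the parser assigns atom indices in token order.
build_mapped_reaction <- function(family, sub, tail) {
  k <- sub_n_atoms(sub)
  nt <- sub_n_atoms(tail)
  parts <- switch(
    family,
    esterification = list(
      r1 = paste0(sub, "C(=O)O"), m1 = seq_len(k + 3L),
      r2 = paste0("O", tail), m2 = (k + 4L):(k + 4L + nt),
      p = paste0(sub, "C(=O)O", tail),
      mp = c(seq_len(k + 2L), k + 4L, if (nt > 0L) (k + 5L):(k + 4L + nt))
    ),
    amidation = list(
      r1 = paste0(sub, "C(=O)O"), m1 = seq_len(k + 3L),
      r2 = paste0("N", tail), m2 = (k + 4L):(k + 4L + nt),
      p = paste0(sub, "C(=O)N", tail),
      mp = c(seq_len(k + 2L), k + 4L, if (nt > 0L) (k + 5L):(k + 4L + nt))
    ),
    sn2 = list(
      r1 = paste0(sub, "Br"), m1 = seq_len(k + 1L),
      r2 = paste0("N", tail), m2 = (k + 2L):(k + 2L + nt),
      p = paste0(sub, "N", tail),
      mp = c(seq_len(k), k + 2L, if (nt > 0L) (k + 3L):(k + 2L + nt))
    ),
    reductive_amination = list(
      r1 = paste0(sub, "C=O"), m1 = seq_len(k + 2L),
      r2 = paste0("N", tail), m2 = (k + 3L):(k + 3L + nt),
      p = paste0(sub, "CN", tail),
      mp = c(seq_len(k + 1L), k + 3L, if (nt > 0L) (k + 4L):(k + 3L + nt))
    ),
    stop(sprintf("unknown reaction family '%s'", family), call. = FALSE)
  )
  text <- paste0(
    mapped_smiles(parts$r1, parts$m1), ".",
    mapped_smiles(parts$r2, parts$m2), ">>",
    mapped_smiles(parts$p, parts$mp)
  )
  list(
    family = family,
    text = text,
    reactants = c(parts$r1, parts$r2),
    product = parts$p
  )
}

fixture_family_subs <- function(family) {
  switch(
    family,
    esterification = list(sub = c(SUB_ALKYL, SUB_ARYL, SUB_BENZYL),
                          tail = c(SUB_ALKYL, SUB_ARYL)),
    amidation = list(sub = c(SUB_ALKYL, SUB_ARYL, SUB_BENZYL),
                     tail = TAIL_NUCLEOPHILE),
    sn2 = list(sub = c(SUB_ALKYL, SUB_BENZYL), tail = TAIL_NUCLEOPHILE),
    reductive_amination = list(sub = c(SUB_ALKYL, SUB_ARYL, SUB_BENZYL),
                               tail = TAIL_NUCLEOPHILE)
  )
}

#' Generate the deterministic fixture corpus
#'
#' Emits three plain-text files into `dir`: `building_blocks.smi` (one
#' SMILES + name per line), `reactions.rsmi` (one atom-mapped reaction
#' SMILES per line; every line passes [parse_mapped_reaction()] by
#' construction) and `queries.tsv` (`id`, `smiles`, `label` with labels ES
#' or HS). The same `fixture_spec` always produces byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the three file paths and the in-memory
#'   tibbles `building_blocks`, `reactions`, `queries`.
#' @export
generate_fixture_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr_seed <- .Random.seed_exists()
  set.seed(spec$seed)

  families <- c("esterification", "amidation", "sn2", "reductive_amination")
  fam_draw <- sample(families, spec$n_reactions, replace = TRUE)
  rxns <- vector("list", spec$n_reactions)
  for (i in seq_len(spec$n_reactions)) {
    pools <- fixture_family_subs(fam_draw[i])
    rxns[[i]] <- build_mapped_reaction(
      fam_draw[i],
      sample(pools$sub, 1L),
      sample(pools$tail, 1L)
    )
  }
  rxn_text <- vapply(rxns, `[[`, character(1), "text")

  ## building blocks: the reactants actually used, padded with further
  ## combinatorial members of the same families
  reactants <- unique(unlist(lapply(rxns, `[[`, "reactants")))
  extra_pool <- unique(c(
    paste0(c(BLOCK_ALKYL, BLOCK_ARYL, BLOCK_BENZYL), "C(=O)O"),
    paste0("O", c(BLOCK_ALKYL, BLOCK_ARYL)),
    paste0("N", c(BLOCK_ALKYL, "(C)C", "(C)CC", "c1ccccc1")),
    paste0(c(BLOCK_ALKYL, BLOCK_BENZYL), "Br"),
    paste0(c(BLOCK_ALKYL, BLOCK_ARYL, BLOCK_BENZYL), "C=O")
  ))
  blocks <- unique(c(reactants, setdiff(extra_pool, reactants)))
  if (length(blocks) > spec$n_building_blocks) {
    blocks <- blocks[seq_len(spec$n_building_blocks)]
  }

  n_es <- spec$n_queries %/% 2L
  n_hs <- spec$n_queries - n_es
  products <- unique(vapply(rxns, `[[`, character(1), "product"))
  es <- if (length(products) >= n_es) {
    sample(products, n_es)
  } else {
    c(products, sample(products, n_es - length(products), replace = TRUE))
  }
  hs <- sample(HS_POOL, n_hs, replace = n_hs > length(HS_POOL))

  building_blocks <- tibble::tibble(
    smiles = blocks,
    name = sprintf("BB%03d", seq_along(blocks))
  )
  reactions <- tibble::tibble(reaction = rxn_text)
  queries <- tibble::tibble(
    id = sprintf("Q%03d", seq_len(n_es + n_hs)),
    smiles = c(es, hs),
    label = c(rep("ES", n_es), rep("HS", n_hs))
  )

  bb_path <- file.path(dir, "building_blocks.smi")
  rx_path <- file.path(dir, "reactions.rsmi")
  q_path <- file.path(dir, "queries.tsv")
  writeLines(paste(building_blocks$smiles, building_blocks$name, sep = "\t"), bb_path)
  writeLines(reactions$reaction, rx_path)
  writeLines(
    c("id\tsmiles\tlabel", paste(queries$id, queries$smiles, queries$label, sep = "\t")),
    q_path
  )

  invisible(list(
    building_blocks = bb_path,
    reactions = rx_path,
    queries = q_path,
    building_blocks_tbl = building_blocks,
    reactions_tbl = reactions,
    queries_tbl = queries,
    spec = spec
  ))
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Read the labeled query file of a fixture corpus
#' @param path Path to `queries.tsv`.
#' @return Tibble `id`, `smiles`, `label`.
#' @export
read_queries <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
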