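# Shared fixtures and independent oracles for the suite.

.fixture_cache <- new.env(parent = emptyenv())

# seed-7 fixture corpus plus derived counts/table, built once per run
seed7_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "sabr-fixture-seed7")
    fx <- generate_fixture_corpus(fixture_spec(seed = 7), dir)
    fx$bcounts <- suppressWarnings(index_building_blocks(fx$building_blocks))
    fx$rcounts <- suppressWarnings(index_reactions(fx$reactions))
    fx$table <- build_score_table(fx$bcounts, fx$rcounts)
    .fixture_cache$fx <- fx
  }
  .fixture_cache$fx
}

# a score table with prescribed merged scores, for scorer unit tests
make_test_table <- function(ids, scores, missing = -6) {
  key <- as.character(ids)
  structure(
    list(
      bscores = stats::setNames(scores, key),
      rscores = stats::setNames(numeric(0), character(0)),
      radii = stats::setNames(rep(2L, length(ids)), key),
      missing_score = missing,
      metadata = list(
        version = 1L, log_base = "natural",
        scaling = list(b_min = 0, b_max = 1, r_min = 0, r_max = 1),
        n_b = 1, n_r = 1, n_building_blocks = 1L, n_reactions = 1L
      )
    ),
    class = "score_table"
  )
}

# Brute-force reaction-centre oracle: for every mapped product atom,
# rebuild the full map-keyed adjacency (neighbour map, bond order) on both
# sides from scratch, plus H count and charge, and diff them.
oracle_reaction_center <- function(rxn) {
  side_adjacency <- function(mols) {
    adj <- list()
    for (mol in mols) {
      maps <- mol$atoms$map
      for (i in seq_len(nrow(mol$atoms))) {
        if (maps[i] == 0L) next
        b <- mol$bonds
        sel <- b$a1 == i | b$a2 == i
        other <- ifelse(b$a1[sel] == i, b$a2[sel], b$a1[sel])
        adj[[as.character(maps[i])]] <- list(
          nbrs = sort(paste(maps[other], b$order[sel], sep = "/")),
          h = mol$atoms$nH[i],
          q = mol$atoms$charge[i]
        )
      }
    }
    adj
  }
  radj <- side_adjacency(rxn$reactants)
  out <- integer(0)
  for (j in seq_along(rxn$products)) {
    prod <- rxn$products[[j]]
    padj <- side_adjacency(list(prod))
    for (i in seq_len(nrow(prod$atoms))) {
      m <- as.character(prod$atoms$map[i])
      if (is.null(radj[[m]]) || !identical(padj[[m]], radj[[m]])) {
        out <- c(out, prod$atoms$map[i])
      }
    }
  }
  sort(out)
}

# Brute-force ROC-AUC over all positive-negative pairs (ties half)
oracle_roc_auc <- function(score, pos) {
  ps <- score[pos]
  ns <- score[!pos]
  tot <- 0
  for (p in ps) for (n in ns) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# First-principles PR-AUC: precision/recall at every distinct threshold,
# step integration of precision over recall increments
oracle_pr_auc <- function(score, pos) {
  ths <- sort(unique(score), decreasing = TRUE)
  prev_r <- 0
  auc <- 0
  for (t in ths) {
    sel <- score >= t
    tp <- sum(sel & pos)
    prec <- tp / sum(sel)
    rec <- tp / sum(pos)
    auc <- auc + (rec - prev_r) * prec
    prev_r <- rec
  }
  auc
}

run_rdkit_oracle <- function(smiles, n_random = 0) {
  req <- jsonlite::toJSON(list(smiles = smiles, n_random = n_random),
                          auto_unbox = TRUE)
  out <- suppressWarnings(system2(
    "python", test_path("oracle_rdkit.py"),
    input = as.character(req), stdout = TRUE, stderr = FALSE
  ))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}
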