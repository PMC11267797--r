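## The synthetic-accessibility scorer: fragment score, raw score, 1-10
## normalization and per-atom attributions.

#' Scorer configuration
#'
#' @param penalty_buffer Non-negative slack added to the normalization
#'   denominator (default 1). It differentiates molecules whose fragments
#'   are all unknown but whose structural complexity differs: the
#'   normalization anchors are a best raw score of 0 and a worst of
#'   `-6 - penalty_buffer`.
#' @return A `scorer_config` list.
#' @export
scorer_config <- function(penalty_buffer = 1) {
  if (!is.numeric(penalty_buffer) || length(penalty_buffer) != 1L ||
      is.na(penalty_buffer) || penalty_buffer < 0) {
    stop("penalty_buffer must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(
      penalty_buffer = penalty_buffer,
      missing_score = MISSING_SCORE,
      raw_best = 0,
      raw_worst = MISSING_SCORE - penalty_buffer,
      clip = c(1, 10)
    ),
    class = "scorer_config"
  )
}

#' Fragment score of a molecule
#'
#' Enumerates the n retained fragments (one per heavy atom), looks up each
#' `Score_i` in the table, and averages the negative terms over n:
#' `sum(Score_i[Score_i < 0]) / n`. A molecule whose fragments all score
#' >= 0 gets 0; a molecule with zero retained fragments gets 0 with a
#' warning.
#'
#' @param mol A `molecule` or SMILES string.
#' @param table A `score_table`.
#' @return A list: `score` (non-positive number) and `fragments`, a tibble
#'   with `atom`, `radius`, `id`, `score`, `contribution` (the negative
#'   part of `score`).
#' @export
br_fragment_score <- function(mol, table) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "molecule"), inherits(table, "score_table"))
  frags <- retained_fragments(mol)
  if (nrow(frags) == 0L) {
    warning("molecule has no retained fragments; fragment score is 0", call. = FALSE)
    frags$score <- numeric(0)
    frags$contribution <- numeric(0)
    return(list(score = 0, fragments = frags))
  }
  frags$score <- lookup_score(table, frags$id)
  frags$contribution <- pmin(frags$score, 0)
  list(score = sum(frags$contribution) / nrow(frags), fragments = frags)
}

#' Full synthetic-accessibility score of one molecule
#'
#' Combines the fragment score with the structural complexity penalty:
#' `raw = fragment score - complexity total`, then normalizes onto the
#' 1 (easy) to 10 (hard) scale with anchors 0 (best) and
#' `-6 - penalty_buffer` (worst), clipping into \[1, 10\]:
#' `normalized = 10 - 9 * (raw - raw_worst) / (0 - raw_worst)`.
#'
#' @param mol A `molecule` or SMILES string.
#' @param table A `score_table`.
#' @param config A [scorer_config()] (or pass `penalty_buffer` directly).
#' @param penalty_buffer Shortcut for `scorer_config(penalty_buffer)`.
#' @return An `sa_score` object: the molecule, per-fragment scores,
#'   `br_fragment_score`, `complexity` breakdown, `raw`, `normalized`, and
#'   per-atom `contributions`.
#' @examples
#' \dontrun{
#' fx <- generate_fixture_corpus(fixture_spec(seed = 7), tempdir())
#' tab <- build_score_table(
#'   index_building_blocks(fx$building_blocks),
#'   index_reactions(fx$reactions)
#' )
#' br_sascore("CCOC(=O)c1ccccc1", tab)
#' }
#' @export
br_sascore <- function(mol, table, config = scorer_config(penalty_buffer),
                       penalty_buffer = 1) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(config, "scorer_config"))
  fs <- br_fragment_score(mol, table)
  cx <- complexity_penalty(mol)
  raw <- fs$score - cx$total
  span <- 0 - config$raw_worst
  normalized <- 10 - 9 * (raw - config$raw_worst) / span
  normalized <- min(max(normalized, config$clip[1]), config$clip[2])
  contributions <- stats::setNames(rep(0, n_heavy_atoms(mol)), seq_len(n_heavy_atoms(mol)))
  if (nrow(fs$fragments) > 0L) {
    contributions[fs$fragments$atom] <- fs$fragments$contribution
  }
  structure(
    list(
      molecule = mol,
      fragments = fs$fragments,
      br_fragment_score = fs$score,
      complexity = cx,
      raw = raw,
      normalized = normalized,
      contributions = contributions,
      config = config
    ),
    class = "sa_score"
  )
}

#' @export
print.sa_score <- function(x, ...) {
  cat(
    "<sa_score> ", write_smiles(x$molecule), "\n",
    "  fragment score: ", format(round(x$br_fragment_score, 4)),
    "  complexity: ", format(round(x$complexity$total, 4)),
    "  raw: ", format(round(x$raw, 4)),
    "  score (1-10): ", format(round(x$normalized, 2)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-atom score attributions
#'
#' Each atom receives the negative part of the `Score_i` of the fragment
#' centred on it (0 when the fragment scores >= 0): darker rendering =
#' more negative = centred on a fragment rarely seen in building blocks or
#' at reaction centres.
#'
#' @param result An `sa_score`.
#' @return A tibble `atom`, `element`, `contribution` (non-positive).
#' @export
atom_contributions <- function(result) {
  stopifnot(inherits(result, "sa_score"))
  tibble::tibble(
    atom = seq_len(n_heavy_atoms(result$molecule)),
    element = result$molecule$atoms$element,
    contribution = unname(result$contributions)
  )
}

#' Tidy an sa_score into one row per fragment
#' @param x An `sa_score`.
#' @param ... Unused.
#' @return Tibble `atom`, `element`, `radius`, `id`, `score`,
#'   `contribution`.
#' @export
tidy.sa_score <- function(x, ...) {
  fr <- x$fragments
  fr$element <- x$molecule$atoms$element[fr$atom]
  fr[, c("atom", "element", "radius", "id", "score", "contribution")]
}

#' One-row summary of an sa_score
#' @param x An `sa_score`.
#' @param ... Unused.
#' @return One-row tibble with the score decomposition.
#' @export
glance.sa_score <- function(x, ...) {
  tibble::tibble(
    canonical_smiles = write_smiles(x$molecule),
    n_atoms = n_heavy_atoms(x$molecule),
    n_fragments = nrow(x$fragments),
    n_rare_fragments = sum(x$fragments$score < 0),
    br_fragment_score = x$br_fragment_score,
    complexity = x$complexity$total,
    raw = x$raw,
    score = x$normalized
  )
}

#' Score a table of molecules
#'
#' The main tidy entry point: takes a data frame with a `smiles` column
#' (or a character vector), scores each molecule, and returns one row per
#' input with the full decomposition. Unparsable SMILES yield NA scores
#' and a single warning with the skip count, mirroring the corpus
#' indexers.
#'
#' @param data Data frame with a `smiles` column, or character vector.
#' @param table A `score_table`.
#' @param penalty_buffer Normalization slack, default 1.
#' @return A tibble: input columns plus `canonical_smiles`, `n_atoms`,
#'   `n_fragments`, `br_fragment_score`, `size`, `stereo`, `ring`,
#'   `macrocycle`, `complexity`, `raw`, `score`.
#' @export
score_molecules <- function(data, table, penalty_buffer = 1) {
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  cfg <- scorer_config(penalty_buffer)
  res <- purrr::map(data$smiles, function(s) {
    tryCatch(
      suppressWarnings(br_sascore(s, table, cfg)),
      error = function(e) NULL
    )
  })
  n_bad <- sum(vapply(res, is.null, logical(1)))
  if (n_bad > 0L) {
    warning(sprintf("skipped %d unparsable molecule(s)", n_bad), call. = FALSE)
  }
  na_row <- tibble::tibble(
    canonical_smiles = NA_character_, n_atoms = NA_integer_,
    n_fragments = NA_integer_, br_fragment_score = NA_real_,
    size = NA_real_, stereo = NA_real_, ring = NA_real_,
    macrocycle = NA_real_, complexity = NA_real_, raw = NA_real_,
    score = NA_real_
  )
  rows <- purrr::map(res, function(r) {
    if (is.null(r)) return(na_row)
    tibble::tibble(
      canonical_smiles = write_smiles(r$molecule),
      n_atoms = n_heavy_atoms(r$molecule),
      n_fragments = nrow(r$fragments),
      br_fragment_score = r$br_fragment_score,
      size = r$complexity$size,
      stereo = r$complexity$stereo,
      ring = r$complexity$ring,
      macrocycle = r$complexity$macrocycle,
      complexity = r$complexity$total,
      raw = r$raw,
      score = r$normalized
    )
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(rows))
}
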