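## Score table: corpus counts -> scaled BScores/RScores and the merged
## per-fragment lookup.
##
## Raw scores are log(count / (0.001 * N)) with N the corpus total (N_B or
## N_R); fragments with aggregated count <= 1 are excluded as unreliably
## rare; each table is then linearly min-max rescaled onto [-3, 3]
## (independently for B and R).  A fragment found in neither table scores
## the missing-fragment floor of -6.

MISSING_SCORE <- -6

#' Raw fragment score before scaling
#'
#' `log(count / (0.001 * total))`, natural logarithm: the fragment's count
#' relative to 0.1% of the corpus total. Callers exclude counts <= 1
#' before scoring.
#'
#' @param count Aggregated (possibly fractional/weighted) fragment count.
#' @param total Corpus total (N_B or N_R); must be positive.
#' @return Numeric raw score (vectorized over `count`).
#' @export
raw_score <- function(count, total) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0) {
    stop("corpus total must be a positive number", call. = FALSE)
  }
  log(count / (0.001 * total))
}

minmax_scale <- function(x, lo = -3, hi = 3) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(list(scaled = rep(0, length(x)), min = rng[1], max = rng[2]))
  }
  scaled <- lo + (hi - lo) * ((x - rng[1]) / (rng[2] - rng[1]))
  list(
    scaled = pmin(pmax(scaled, lo), hi),  # guard 1-ulp overshoot
    min = rng[1], max = rng[2]
  )
}

#' Build the merged fragment score table
#'
#' Filters out fragments with aggregated count <= 1, computes raw log
#' scores against 0.1% of each corpus total, and min-max rescales each
#' table independently onto \[-3, 3\] (a degenerate constant table maps to
#' 0). Scaling anchors and corpus totals are kept in `metadata` so a
#' serialized table is fully reproducible.
#'
#' @param bcounts `fragment_counts` from [index_building_blocks()].
#' @param rcounts `fragment_counts` from [index_reactions()].
#' @return A `score_table` object.
#' @export
build_score_table <- function(bcounts, rcounts) {
  stopifnot(inherits(bcounts, "fragment_counts"), inherits(rcounts, "fragment_counts"))
  if (bcounts$source != "building_blocks" || rcounts$source != "reactions") {
    stop("build_score_table() expects building-block counts then reaction counts", call. = FALSE)
  }
  one_table <- function(fc, label) {
    keep <- fc$counts > 1
    if (!any(keep)) {
      stop(sprintf(
        "no %s fragment has aggregated count > 1; corpus too small to score", label
      ), call. = FALSE)
    }
    raw <- raw_score(fc$counts[keep], fc$total)
    sc <- minmax_scale(raw)
    list(
      scores = stats::setNames(sc$scaled, names(fc$counts)[keep]),
      radii = fc$radii[keep],
      raw_min = sc$min, raw_max = sc$max
    )
  }
  b <- one_table(bcounts, "building-block")
  r <- one_table(rcounts, "reaction")
  structure(
    list(
      bscores = b$scores,
      rscores = r$scores,
      radii = c(b$radii, r$radii[setdiff(names(r$radii), names(b$radii))]),
      missing_score = MISSING_SCORE,
      metadata = list(
        version = 1L,
        log_base = "natural",
        scaling = list(b_min = b$raw_min, b_max = b$raw_max,
                       r_min = r$raw_min, r_max = r$raw_max),
        n_b = bcounts$total, n_r = rcounts$total,
        n_building_blocks = bcounts$n_records,
        n_reactions = rcounts$n_records
      )
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(
    "<score_table> ", length(x$bscores), " BScores, ", length(x$rscores),
    " RScores (N_B=", format(x$metadata$n_b), ", N_R=", format(x$metadata$n_r),
    "), missing fragments score ", x$missing_score, "\n", sep = ""
  )
  invisible(x)
}

#' Look up per-fragment scores
#'
#' The merged rule: `Score_i = max(BScore_i, RScore_i)` over the entries
#' that exist, and the missing-fragment floor (-6) when the fragment is in
#' neither table.
#'
#' @param table A `score_table`.
#' @param ids Numeric vector of fragment identifiers.
#' @return Numeric vector of Score_i values in \[-3, 3\] or -6.
#' @export
lookup_score <- function(table, ids) {
  stopifnot(inherits(table, "score_table"))
  key <- as.character(ids)
  b <- unname(table$bscores[key])
  r <- unname(table$rscores[key])
  out <- pmax(b, r, na.rm = TRUE)
  out[is.na(out)] <- table$missing_score
  out
}

#' Tidy a score table into one row per fragment
#' @param x A `score_table`.
#' @param ... Unused.
#' @return Tibble with `id`, `radius`, `bscore`, `rscore`, `score` (the
#'   merged max rule).
#' @export
tidy.score_table <- function(x, ...) {
  ids <- union(names(x$bscores), names(x$rscores))
  ids <- ids[order(as.numeric(ids))]
  b <- unname(x$bscores[ids])
  r <- unname(x$rscores[ids])
  tibble::tibble(
    id = as.numeric(ids),
    radius = unname(x$radii[ids]),
    bscore = b,
    rscore = r,
    score = pmax(b, r, na.rm = TRUE)
  )
}

#' One-row summary of a score table
#' @param x A `score_table`.
#' @param ... Unused.
#' @return A one-row tibble with table sizes, corpus totals and score
#'   ranges.
#' @export
glance.score_table <- function(x, ...) {
  tibble::tibble(
    n_bfrags = length(x$bscores),
    n_rfrags = length(x$rscores),
    n_b = x$metadata$n_b,
    n_r = x$metadata$n_r,
    bscore_min = min(x$bscores), bscore_max = max(x$bscores),
    rscore_min = min(x$rscores), rscore_max = max(x$rscores),
    missing_score = x$missing_score
  )
}

#' Serialize a score table to versioned JSON
#'
#' Entries are written sorted by identifier, so identical corpora give a
#' byte-identical file.
#' @param table A `score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  td <- tidy.score_table(table)
  doc <- list(
    version = table$metadata$version,
    log_base = table$metadata$log_base,
    scaling = table$metadata$scaling,
    missing_score = table$missing_score,
    n_b = table$metadata$n_b,
    n_r = table$metadata$n_r,
    n_building_blocks = table$metadata$n_building_blocks,
    n_reactions = table$metadata$n_reactions,
    entries = unname(purrr::pmap(td, function(id, radius, bscore, rscore, score) {
      list(
        id = id, radius = radius,
        bscore = if (is.na(bscore)) NULL else bscore,
        rscore = if (is.na(rscore)) NULL else rscore
      )
    }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a score table from JSON
#' @param path Path written by [write_score_table()].
#' @return A `score_table`.
#' @export
read_score_table <- function(path) {
  doc <- jsonlite::read_json(path)
  ids <- vapply(doc$entries, function(e) as.numeric(e$id), numeric(1))
  key <- as.character(ids)
  radii <- stats::setNames(
    vapply(doc$entries, function(e) as.integer(e$radius), integer(1)), key
  )
  getcol <- function(field) {
    v <- vapply(doc$entries, function(e) {
      if (is.null(e[[field]])) NA_real_ else as.numeric(e[[field]])
    }, numeric(1))
    stats::setNames(v, key)[!is.na(v)]
  }
  structure(
    list(
      bscores = getcol("bscore"),
      rscores = getcol("rscore"),
      radii = radii,
      missing_score = as.numeric(doc$missing_score),
      metadata = list(
        version = as.integer(doc$version),
        log_base = doc$log_base,
        scaling = lapply(doc$scaling, as.numeric),
        n_b = as.numeric(doc$n_b), n_r = as.numeric(doc$n_r),
        n_building_blocks = as.integer(doc$n_building_blocks),
        n_reactions = as.integer(doc$n_reactions)
      )
    ),
    class = "score_table"
  )
}
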