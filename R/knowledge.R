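## Fragment-frequency corpora: BFrags from building blocks, RFrags from
## reactions, plus the .smi/.rsmi readers and the JSON count format.

new_fragment_counts <- function(counts = numeric(0), radii = integer(0),
                                total = 0, source = c("building_blocks", "reactions"),
                                n_records = 0L, n_skipped = 0L) {
  source <- match.arg(source)
  structure(
    list(counts = counts, radii = radii, total = total, source = source,
         n_records = n_records, n_skipped = n_skipped),
    class = "fragment_counts"
  )
}

counts_from_occurrences <- function(ids, radii, weights, source, total,
                                    n_records = 1L, n_skipped = 0L) {
  if (length(ids) == 0L) {
    return(new_fragment_counts(source = source, total = total,
                               n_records = n_records, n_skipped = n_skipped))
  }
  key <- as.character(ids)
  agg <- rowsum(weights, group = key)
  counts <- stats::setNames(as.numeric(agg), rownames(agg))
  rad <- stats::setNames(radii[!duplicated(key)], key[!duplicated(key)])
  new_fragment_counts(counts, rad[names(counts)], total, source,
                      n_records, n_skipped)
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(
    "<fragment_counts> source=", x$source, ": ", length(x$counts),
    " distinct fragments, total=", format(x$total), " from ", x$n_records,
    " record(s)", if (x$n_skipped > 0L) paste0(" (", x$n_skipped, " skipped)"),
    "\n", sep = ""
  )
  invisible(x)
}

#' Merge fragment-count tables of the same source
#'
#' Additive in both the per-fragment counts and the corpus total.
#' @param x,y `fragment_counts` with identical `source`.
#' @return A merged `fragment_counts`.
#' @export
merge_fragment_counts <- function(x, y) {
  stopifnot(inherits(x, "fragment_counts"), inherits(y, "fragment_counts"))
  if (x$source != y$source) {
    stop("cannot merge fragment counts from different sources", call. = FALSE)
  }
  keys <- union(names(x$counts), names(y$counts))
  counts <- stats::setNames(rep(0, length(keys)), keys)
  counts[names(x$counts)] <- counts[names(x$counts)] + x$counts
  counts[names(y$counts)] <- counts[names(y$counts)] + y$counts
  radii <- stats::setNames(rep(NA_integer_, length(keys)), keys)
  radii[names(y$radii)] <- y$radii
  radii[names(x$radii)] <- x$radii
  new_fragment_counts(counts, radii, x$total + y$total, x$source,
                      x$n_records + y$n_records, x$n_skipped + y$n_skipped)
}

#' Index a building-block corpus into BFrag counts
#'
#' For each building block with `m` retained fragments, every fragment
#' occurrence contributes `1/m` to its count, so that fragments from large
#' blocks (less versatile starting materials) weigh less. The corpus total
#' `N_B` accumulates the unnormalized number of extracted fragment
#' occurrences. Unparsable records are skipped with a warning count, never
#' fatal mid-stream.
#'
#' @param smiles Character vector of SMILES, or a data frame with a
#'   `smiles` column, or a path to a `.smi` file (one record per line,
#'   optional tab-separated name).
#' @return A `fragment_counts` with `source = "building_blocks"`.
#' @export
index_building_blocks <- function(smiles) {
  smiles <- as_smiles_vector(smiles)
  if (length(smiles) == 0L) {
    stop("building-block corpus is empty", call. = FALSE)
  }
  ids <- numeric(0); radii <- integer(0); weights <- numeric(0)
  total <- 0; n_ok <- 0L; n_skip <- 0L
  for (s in smiles) {
    frags <- tryCatch(retained_fragments(parse_molecule(s)), error = function(e) NULL)
    if (is.null(frags)) {
      n_skip <- n_skip + 1L
      next
    }
    m <- nrow(frags)
    n_ok <- n_ok + 1L
    if (m == 0L) next
    ids <- c(ids, frags$id)
    radii <- c(radii, frags$radius)
    weights <- c(weights, rep(1 / m, m))
    total <- total + m
  }
  if (n_ok == 0L) stop("no parsable building blocks in corpus", call. = FALSE)
  if (n_skip > 0L) {
    warning(sprintf("skipped %d unparsable building-block record(s)", n_skip), call. = FALSE)
  }
  counts_from_occurrences(ids, radii, weights, "building_blocks", total,
                          n_records = n_ok, n_skipped = n_skip)
}

#' Index a reaction corpus into RFrag counts
#'
#' Sums [extract_rfrags()] over all reactions; invalid records are skipped
#' and counted, never fatal mid-stream.
#'
#' @param reactions Character vector of atom-mapped reaction SMILES, or a
#'   path to a `.rsmi` file (one reaction per line).
#' @return A `fragment_counts` with `source = "reactions"`.
#' @export
index_reactions <- function(reactions) {
  reactions <- as_rsmi_vector(reactions)
  if (length(reactions) == 0L) stop("reaction corpus is empty", call. = FALSE)
  acc <- new_fragment_counts(source = "reactions")
  n_skip <- 0L
  for (r in reactions) {
    fc <- tryCatch(
      suppressWarnings(extract_rfrags(parse_mapped_reaction(r))),
      error = function(e) NULL
    )
    if (is.null(fc)) {
      n_skip <- n_skip + 1L
      next
    }
    acc <- merge_fragment_counts(acc, fc)
  }
  if (acc$n_records == 0L) stop("no valid reactions in corpus", call. = FALSE)
  if (n_skip > 0L) {
    warning(sprintf("skipped %d invalid reaction record(s)", n_skip), call. = FALSE)
  }
  acc$n_skipped <- acc$n_skipped + n_skip
  acc
}

as_smiles_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("smiles" %in% names(x))
    return(as.character(x$smiles))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_smi(x)$smiles)
  }
  as.character(x)
}

as_rsmi_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("reaction" %in% names(x))
    return(as.character(x$reaction))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_rsmi(x)$reaction)
  }
  as.character(x)
}

#' Read a .smi file
#' @param path Path to a SMILES file, one record per line, optional
#'   tab-separated name field.
#' @return A tibble with `smiles` and `name` columns.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, character(1))
  )
}

#' Read a .rsmi file
#' @param path Path to a reaction-SMILES file, one reaction per line.
#' @return A tibble with a `reaction` column.
#' @export
read_rsmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tibble::tibble(reaction = trimws(lines[nzchar(trimws(lines))]))
}

#' Write fragment counts as versioned JSON
#' @param x A `fragment_counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_counts <- function(x, path) {
  stopifnot(inherits(x, "fragment_counts"))
  ord <- order(as.numeric(names(x$counts)))
  doc <- list(
    version = 1L,
    source = x$source,
    total = x$total,
    n_records = x$n_records,
    n_skipped = x$n_skipped,
    counts = unname(purrr::map(ord, function(i) {
      list(as.numeric(names(x$counts)[i]), unname(x$radii[i]), unname(x$counts[i]))
    }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read fragment counts from JSON
#' @param path Path written by [write_fragment_counts()].
#' @return A `fragment_counts`.
#' @export
read_fragment_counts <- function(path) {
  doc <- jsonlite::read_json(path)
  ids <- vapply(doc$counts, function(e) as.numeric(e[[1]]), numeric(1))
  radii <- vapply(doc$counts, function(e) as.integer(e[[2]]), integer(1))
  cnts <- vapply(doc$counts, function(e) as.numeric(e[[3]]), numeric(1))
  new_fragment_counts(
    stats::setNames(cnts, as.character(ids)),
    stats::setNames(radii, as.character(ids)),
    total = as.numeric(doc$total), source = doc$source,
    n_records = as.integer(doc$n_records), n_skipped = as.integer(doc$n_skipped)
  )
}
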