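# Curated genomic-event catalog: loaders for mutation / copy-number / lineage
# tables and construction of the binary cell-line x locus event matrix.

#' Read a gene-level mutation table
#'
#' Reads a tab-separated table with columns `cell_line`, `locus` and
#' `mutated`. A locus is any gene-level identifier; sub-loci such as
#' `"CDKN2A(p14)"` are treated as loci in their own right and are never
#' merged with their parent symbol. Booleans are accepted as `0`/`1` or
#' `true`/`false` in any case. Rows that duplicate an existing
#' (cell line, locus) pair with the same value are dropped; duplicates with
#' conflicting values are an error.
#'
#' @param path Path to a headered, UTF-8, tab-separated file.
#' @return A data frame with columns `cell_line`, `locus` (character) and
#'   `mutated` (logical), one row per unique (cell line, locus) pair.
#' @export
load_mutation_table <- function(path) {
  tab <- read_tsv_checked(path, c("cell_line", "locus"))
  if (!"mutated" %in% names(tab)) {
    stop("mutation table is missing required column 'mutated'", call. = FALSE)
  }
  mutated <- parse_boolean(tab$mutated, path)
  rec <- data.frame(
    cell_line = as.character(tab$cell_line),
    locus = as.character(tab$locus),
    mutated = mutated,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$locus))) {
    stop("mutation table contains an empty locus identifier", call. = FALSE)
  }
  dedupe_records(rec, c("cell_line", "locus"), "mutated")
}

#' Read a gene-level total copy-number table
#'
#' Reads a tab-separated table with columns `cell_line`, `locus` and
#' `total_copy_number`. Copy numbers must be non-negative integers; the
#' value is the PICNIC-style total copy number of the gene, with 0 denoting
#' homozygous deletion. Records are returned in file order.
#'
#' @inheritParams load_mutation_table
#' @return A data frame with columns `cell_line`, `locus` and
#'   `total_copy_number` (integer).
#' @export
load_copy_number_table <- function(path) {
  tab <- read_tsv_checked(path, c("cell_line", "locus", "total_copy_number"))
  cn_raw <- suppressWarnings(as.numeric(tab$total_copy_number))
  bad <- which(is.na(cn_raw) | cn_raw < 0 | cn_raw != round(cn_raw))
  if (length(bad)) {
    stop(sprintf(
      "copy-number table row %d (+ header): total_copy_number '%s' is not a non-negative integer",
      bad[1], as.character(tab$total_copy_number[bad[1]])
    ), call. = FALSE)
  }
  data.frame(
    cell_line = as.character(tab$cell_line),
    locus = as.character(tab$locus),
    total_copy_number = as.integer(cn_raw),
    stringsAsFactors = FALSE
  )
}

#' Write a copy-number table (paired writer for [load_copy_number_table()])
#' @param records Data frame as returned by [load_copy_number_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_copy_number_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cell-line lineage annotation table
#'
#' Reads a tab-separated table with columns `cell_line` and `lineage`
#' (tissue of origin, e.g. melanoma, colon). Exact duplicate rows are
#' tolerated; two different lineages for the same cell line are an error.
#' Lookups for cell lines absent from the table yield the `"unknown"`
#' sentinel rather than failing (see [lineage_of()]).
#'
#' @inheritParams load_mutation_table
#' @return A named character vector mapping cell line to lineage.
#' @export
load_lineage_table <- function(path) {
  tab <- read_tsv_checked(path, c("cell_line", "lineage"))
  cl <- as.character(tab$cell_line)
  lin <- as.character(tab$lineage)
  first <- !duplicated(cl)
  conflict <- lin != lin[match(cl, cl)]
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop(sprintf("conflicting lineages for cell line '%s'", cl[i]),
         call. = FALSE)
  }
  stats::setNames(lin[first], cl[first])
}

#' Look up lineages with an "unknown" sentinel
#'
#' @param lineage Named character vector from [load_lineage_table()].
#' @param cell_lines Cell-line identifiers to look up.
#' @return Character vector of lineage labels; `"unknown"` where the cell
#'   line is not annotated.
#' @export
lineage_of <- function(lineage, cell_lines) {
  out <- unname(lineage[cell_lines])
  out[is.na(out)] <- "unknown"
  out
}

#' Build the binary genomic-event matrix
#'
#' A genomic event in a locus for a cell line is a mutation (coding-sequence
#' variant) and/or a copy-number aberration: homozygous deletion (total copy
#' number equal to `deletion_value`, default 0) or amplification (total copy
#' number at or above `amplification_threshold`, default 8). Cell lines and
#' loci are the union of identifiers appearing in either input table and are
#' sorted lexicographically, the package-wide canonical ordering.
#'
#' @param mutations Data frame from [load_mutation_table()] (may have 0 rows).
#' @param copy_numbers Data frame from [load_copy_number_table()] (may have
#'   0 rows).
#' @param amplification_threshold Total copy number at or above which a gene
#'   counts as amplified. Default 8.
#' @param deletion_value Total copy number that counts as homozygous
#'   deletion. Default 0. Must be below `amplification_threshold`.
#' @param lineage Optional named character vector of lineage labels.
#' @return An object of class `event_matrix`: a list with `events` (logical
#'   cell-line x locus matrix with dimnames) and `lineage`.
#' @export
build_event_matrix <- function(mutations = NULL, copy_numbers = NULL,
                               amplification_threshold = 8L,
                               deletion_value = 0L,
                               lineage = NULL) {
  if (!is.null(mutations) && nrow(mutations) == 0) mutations <- NULL
  if (!is.null(copy_numbers) && nrow(copy_numbers) == 0) copy_numbers <- NULL
  if (deletion_value >= amplification_threshold) {
    stop("deletion_value must be smaller than amplification_threshold",
         call. = FALSE)
  }
  cl <- sort(unique(c(
    character(0),
    if (!is.null(mutations)) mutations$cell_line,
    if (!is.null(copy_numbers)) copy_numbers$cell_line
  )))
  loci <- sort(unique(c(
    character(0),
    if (!is.null(mutations)) mutations$locus,
    if (!is.null(copy_numbers)) copy_numbers$locus
  )))
  ev <- matrix(FALSE, nrow = length(cl), ncol = length(loci),
               dimnames = list(cl, loci))
  if (!is.null(mutations)) {
    hit <- mutations[mutations$mutated, , drop = FALSE]
    ev[cbind(match(hit$cell_line, cl), match(hit$locus, loci))] <- TRUE
  }
  if (!is.null(copy_numbers)) {
    aberrant <- copy_numbers$total_copy_number == deletion_value |
      copy_numbers$total_copy_number >= amplification_threshold
    hit <- copy_numbers[aberrant, , drop = FALSE]
    ev[cbind(match(hit$cell_line, cl), match(hit$locus, loci))] <- TRUE
  }
  new_event_matrix(ev, lineage)
}

#' Construct an event matrix from a prebuilt logical matrix
#'
#' @param events Logical matrix, rows cell lines, columns loci, with
#'   dimnames. Rows and columns are re-sorted into the canonical
#'   lexicographic order.
#' @param lineage Optional named character vector of lineage labels.
#' @return An `event_matrix` object.
#' @export
new_event_matrix <- function(events, lineage = NULL) {
  stopifnot(is.matrix(events), is.logical(events))
  if (nrow(events) > 0 && is.null(rownames(events))) {
    stop("events matrix needs cell-line rownames", call. = FALSE)
  }
  if (ncol(events) > 0 && is.null(colnames(events))) {
    stop("events matrix needs locus colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(events))) {
    stop("duplicate cell-line identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(events))) {
    stop("duplicate locus identifiers", call. = FALSE)
  }
  if (nrow(events) > 0 && ncol(events) > 0) {
    events <- events[order(rownames(events)), order(colnames(events)),
                     drop = FALSE]
  }
  structure(list(events = events, lineage = lineage),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d cell lines x %d loci, %d events (%s lineage)\n",
              nrow(x$events), ncol(x$events), sum(x$events),
              if (is.null(x$lineage)) "no" else "with"))
  invisible(x)
}

#' Cell-line identifiers of an event matrix
#' @param matrix An `event_matrix`.
#' @return Character vector in canonical order.
#' @export
cell_lines <- function(matrix) rownames(matrix$events)

#' Locus identifiers of an event matrix
#' @param matrix An `event_matrix`.
#' @return Character vector in canonical order.
#' @export
loci <- function(matrix) colnames(matrix$events)

#' Per-locus event frequencies
#'
#' @param matrix An `event_matrix`.
#' @param subset Optional character vector of cell lines; frequencies are
#'   computed over this subset (must be non-empty and contained in the
#'   matrix).
#' @return Named numeric vector of event frequencies in `[0, 1]`, in
#'   canonical locus order.
#' @export
locus_frequencies <- function(matrix, subset = NULL) {
  ev <- matrix$events
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("empty cell-line subset", call. = FALSE)
    missing <- setdiff(subset, rownames(ev))
    if (length(missing)) {
      stop(sprintf("cell lines not in matrix: %s",
                   paste(utils::head(missing, 3), collapse = ", ")),
           call. = FALSE)
    }
    ev <- ev[subset, , drop = FALSE]
  }
  colMeans(ev)
}

#' Restrict an event matrix to a cell-line subset and/or drop empty loci
#'
#' @param matrix An `event_matrix`.
#' @param cell_lines Optional cell lines to keep.
#' @param drop_empty_loci Drop loci with no event in the kept cell lines
#'   (the default for co-event enumeration, recorded in the `dropped_loci`
#'   attribute).
#' @return A new `event_matrix`.
#' @export
subset_event_matrix <- function(matrix, cell_lines = NULL,
                                drop_empty_loci = TRUE) {
  ev <- matrix$events
  if (!is.null(cell_lines)) {
    keep <- intersect(rownames(ev), cell_lines)
    ev <- ev[keep, , drop = FALSE]
  }
  dropped <- character(0)
  if (drop_empty_loci) {
    empty <- colSums(ev) == 0
    dropped <- colnames(ev)[empty]
    ev <- ev[, !empty, drop = FALSE]
  }
  out <- new_event_matrix(ev, matrix$lineage)
  attr(out, "dropped_loci") <- dropped
  out
}

#' Write the long-format event table
#'
#' One row per true entry, columns `cell_line` and `locus`.
#'
#' @param matrix An `event_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(matrix, path) {
  idx <- which(matrix$events, arr.ind = TRUE)
  tab <- data.frame(
    cell_line = rownames(matrix$events)[idx[, 1]],
    locus = colnames(matrix$events)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cell_line, tab$locus), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format event table into an event matrix
#'
#' @param path Path to a TSV with columns `cell_line`, `locus`.
#' @param lineage Optional named lineage vector.
#' @return An `event_matrix`.
#' @export
read_events_tsv <- function(path, lineage = NULL) {
  tab <- read_tsv_checked(path, c("cell_line", "locus"))
  cl <- sort(unique(as.character(tab$cell_line)))
  lc <- sort(unique(as.character(tab$locus)))
  ev <- matrix(FALSE, length(cl), length(lc), dimnames = list(cl, lc))
  ev[cbind(match(tab$cell_line, cl), match(tab$locus, lc))] <- TRUE
  new_event_matrix(ev, lineage)
}

# --- internal helpers --------------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tab
}

parse_boolean <- function(x, path) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("1", "true")] <- TRUE
  out[lx %in% c("0", "false")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("%s row %d (+ header): cannot parse boolean '%s'",
                 basename(path), bad[1], as.character(x[bad[1]])),
         call. = FALSE)
  }
  out
}

dedupe_records <- function(rec, key_cols, value_col) {
  key <- do.call(paste, c(rec[key_cols], sep = "\r"))
  first <- match(key, key)
  conflict <- rec[[value_col]] != rec[[value_col]][first]
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop(sprintf("conflicting values for duplicated key (%s)",
                 paste(unlist(rec[i, key_cols]), collapse = ", ")),
         call. = FALSE)
  }
  rec[!duplicated(key), , drop = FALSE]
}
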