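## Character matrices are integer matrices with taxa in rows and sites in
## columns, states coded 0..a-1, plus an attribute "nstates" (a). Class
## "char_matrix" on top of "matrix" so base subsetting etc. keep working.

#' Construct a character matrix
#'
#' @param states integer matrix, taxa in rows, sites in columns; entries in
#'   `0..nstates-1`.
#' @param nstates number of character states `a`. Defaults to the largest
#'   observed state + 1; may be set larger to model states that are legal
#'   but unobserved (needed for birth-and-death ladders and the correction
#'   for unobservable patterns).
#' @return a `char_matrix`.
#' @export
char_matrix <- function(states, nstates = NULL) {
  states <- as.matrix(states)
  if (length(states) == 0L) stop("empty character matrix", call. = FALSE)
  if (any(!is.finite(states)) || any(states != round(states)))
    stop("character states must be finite integers", call. = FALSE)
  if (any(states < 0))
    stop("character states must be nonnegative (missing-data codes are ",
         "not supported)", call. = FALSE)
  storage.mode(states) <- "integer"
  if (is.null(nstates)) nstates <- max(states) + 1L
  nstates <- as.integer(nstates)
  if (nstates < 2L) stop("need at least 2 character states", call. = FALSE)
  if (max(states) > nstates - 1L)
    stop("state ", max(states), " exceeds nstates - 1 = ", nstates - 1L,
         call. = FALSE)
  if (is.null(rownames(states)))
    rownames(states) <- paste0("t", seq_len(nrow(states)))
  structure(states, nstates = nstates,
            class = c("char_matrix", "matrix", "array"))
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("char_matrix:", nrow(x), "taxa x", ncol(x), "sites,",
      attr(x, "nstates"), "states\n")
  invisible(x)
}

n_states <- function(m) attr(m, "nstates")

#' Read a character matrix from a delimited text file
#'
#' Accepts whitespace- or comma-delimited tables of nonnegative integers,
#' optionally with a header row of taxon labels (and a label column when
#' taxa are in rows). Gene-family tables are commonly written with one
#' column per genome and one row per family; `orientation` says which way
#' the file is laid out, and the result is always taxa x sites.
#'
#' @param path file path.
#' @param orientation `"taxa_in_columns"` (e.g. one row per gene family) or
#'   `"taxa_in_rows"`.
#' @param nstates optional override of the state count `a` (upward only).
#' @param header does the file start with a row of taxa labels? The
#'   default `"auto"` treats the first row as a header when every token in
#'   it contains a letter.
#' @return a `char_matrix` with taxa in rows.
#' @export
read_character_matrix <- function(path,
                                  orientation = c("taxa_in_columns",
                                                  "taxa_in_rows"),
                                  nstates = NULL, header = "auto") {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  if (identical(header, "auto")) {
    tokens <- strsplit(trimws(first),
                       if (sep == ",") "," else "[[:space:]]+")[[1L]]
    header <- length(tokens) > 0L && all(grepl("[A-Za-z]", tokens))
  }
  tab <- tryCatch(
    read.table(path, header = header, sep = sep, colClasses = "character",
               row.names = NULL, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot read table (ragged rows?): ",
                             conditionMessage(e), call. = FALSE))
  labels <- NULL
  if (ncol(tab) > 1L && any(grepl("[A-Za-z]", tab[[1L]]))) {
    labels <- tab[[1L]]                      # leading label column
    tab <- tab[, -1L, drop = FALSE]
  }
  for (j in seq_len(ncol(tab))) {
    bad <- !grepl("^[0-9]+$", tab[[j]])
    if (any(bad))
      stop("non-integer or negative state '", tab[[j]][which(bad)[1L]],
           "' at row ", which(bad)[1L], ", column ", j, call. = FALSE)
  }
  m <- vapply(tab, as.integer, integer(nrow(tab)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(tab))
  if (orientation == "taxa_in_columns") {
    colnames(m) <- NULL
    taxa <- if (header) names(tab) else paste0("t", seq_len(ncol(m)))
    m <- t(m)
    rownames(m) <- taxa
  } else {
    if (!is.null(labels)) rownames(m) <- labels
  }
  char_matrix(m, nstates = nstates)
}

#' Write a character matrix to a delimited text file
#'
#' @param m a `char_matrix` (taxa in rows).
#' @param path output path.
#' @param orientation layout of the written file (see
#'   [read_character_matrix()]).
#' @export
write_character_matrix <- function(m, path,
                                   orientation = c("taxa_in_columns",
                                                   "taxa_in_rows")) {
  orientation <- match.arg(orientation)
  out <- unclass(m)
  if (orientation == "taxa_in_columns") {
    out <- t(out)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  } else {
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Collapse a multistate matrix to presence/absence
#'
#' Maps every nonzero state to 1 (`x -> min(x, 1)`), giving a binary matrix
#' with `a = 2`. Idempotent.
#'
#' @param m a `char_matrix`.
#' @return a binary `char_matrix`.
#' @export
simplify_to_binary <- function(m) {
  out <- unclass(m)
  out[out > 1L] <- 1L
  char_matrix(out, nstates = 2L)
}

#' Compress a character matrix into unique site patterns
#'
#' The likelihood is a product over sites, so identical columns share one
#' evaluation. Returns the unique patterns with their multiplicities.
#'
#' @param m a `char_matrix`.
#' @return a `pattern_set`: list with `patterns` (taxa x npattern integer
#'   matrix), `weights` (multiplicities summing to the site count),
#'   `site_index` (pattern id per original site), `nstates`, `taxa`.
#' @export
compress_patterns <- function(m) {
  key <- apply(unclass(m), 2L, paste, collapse = ",")
  first <- !duplicated(key)
  ids <- match(key, key[first])
  pat <- unclass(m)[, first, drop = FALSE]
  w <- tabulate(ids, nbins = sum(first))
  structure(list(patterns = pat, weights = w, site_index = ids,
                 nstates = n_states(m), taxa = rownames(m)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("pattern_set:", ncol(x$patterns), "patterns over",
      sum(x$weights), "sites,", length(x$taxa), "taxa\n")
  invisible(x)
}
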