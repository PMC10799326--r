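# Consensus sequences and the longest-uninterrupted-phrase motif extraction.
# The consensus caller is a documented deterministic rule (the external
# conservation-scoring web tool it stands in for is not reproducible
# bit-for-bit); the phrase extraction operates on any consensus entries.

#' Build a per-column consensus of a protein alignment
#'
#' Per column, over its non-gap residues and only where column coverage (the
#' fraction of rows with a residue) reaches `min_coverage`: a single residue
#' carrying at least `fixed_frac` of the residues becomes a fixed call; else
#' if at most `alt_max` distinct residues jointly carry `fixed_frac` the
#' column becomes an alternative set (ordered by descending frequency, ties
#' alphabetical); otherwise `X`. Under-covered columns are `X`.
#'
#' @param aln an `aa_alignment`.
#' @param fixed_frac fraction a call must cover (default 1, i.e. unanimity).
#' @param alt_max largest alternative set (default 4).
#' @param min_coverage minimum column coverage (default 0.8).
#' @return a `consensus_seq`: list with `entries` (list of character vectors;
#'   length one = fixed or `X`, longer = alternative set) and `m`.
#' @export
build_consensus <- function(aln, fixed_frac = 1.0, alt_max = 4, min_coverage = 0.8) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  entries <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col %in% AA_LETTERS]
    if (length(res) / n < min_coverage) return("X")
    tab <- sort(table(res), decreasing = TRUE)
    # deterministic order: frequency desc, then alphabetical
    tab <- tab[order(-tab, names(tab))]
    freq <- tab / length(res)
    if (freq[1] >= fixed_frac) return(names(tab)[1])
    k <- min(length(tab), alt_max)
    if (sum(freq[seq_len(k)]) >= fixed_frac && length(tab) >= 2) {
      take <- which(cumsum(freq) >= fixed_frac)[1]
      if (take < 2) take <- 2
      return(names(tab)[seq_len(take)])
    }
    "X"
  })
  structure(list(entries = entries, m = length(entries)), class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("<consensus_seq> ", x$m, " columns: ", format_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Render consensus entries as a string with `{...}` alternative groups
#' @param cons a `consensus_seq` (or its `entries`).
#' @return character scalar.
#' @export
format_consensus <- function(cons) {
  entries <- if (inherits(cons, "consensus_seq")) cons$entries else cons
  paste(vapply(entries, function(e) {
    if (length(e) == 1) e else paste0("{", paste(e, collapse = ""), "}")
  }, character(1)), collapse = "")
}

#' Parse a formatted consensus string back to entries
#' @param x string as produced by [format_consensus()].
#' @return a `consensus_seq`.
#' @export
parse_consensus <- function(x) {
  entries <- list()
  i <- 1; chars <- strsplit(x, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "{") {
      j <- which(chars == "}" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced '{' in consensus string")
      entries[[length(entries) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else {
      entries[[length(entries) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  structure(list(entries = entries, m = length(entries)), class = "consensus_seq")
}

is_x <- function(entries) vapply(entries, function(e) identical(e, "X"), logical(1))

#' Longest uninterrupted consensus phrase
#'
#' The longest contiguous column window containing no more than one
#' consecutive `X`. A window may not contain two adjacent `X` entries, and a
#' leading/trailing `X` is only allowed when it does not form an adjacent `X`
#' pair with the column just outside the window. Ties are broken leftmost. An
#' all-`X` consensus degenerates to the single first column.
#'
#' @param cons a `consensus_seq`.
#' @return a `consensus_phrase`: list with `start_col`, `end_col` (1-based,
#'   inclusive), `entries`, `formatted`.
#' @export
longest_phrase <- function(cons) {
  x <- is_x(cons$entries)
  m <- cons$m
  if (all(x)) {
    ph <- list(start_col = 1L, end_col = 1L, entries = cons$entries[1],
               formatted = "X", degenerate = TRUE)
    class(ph) <- "consensus_phrase"
    message("all-X consensus: returning degenerate single-column phrase")
    return(ph)
  }
  # adjacent-XX pair at (i, i+1): no window may contain both columns, and a
  # window may not begin/end with an X that pairs with an X just outside it
  pair_at <- which(x[-m] & x[-1])
  starts <- c(1L, pair_at + 1L)
  ends <- c(pair_at, m)
  for (w in seq_along(starts)) {
    while (starts[w] <= ends[w] && x[starts[w]] &&
           starts[w] > 1 && x[starts[w] - 1]) starts[w] <- starts[w] + 1L
    while (ends[w] >= starts[w] && x[ends[w]] &&
           ends[w] < m && x[ends[w] + 1]) ends[w] <- ends[w] - 1L
  }
  len <- ends - starts + 1L
  best <- which.max(len)                    # which.max is leftmost on ties
  ph <- list(start_col = starts[best], end_col = ends[best],
             entries = cons$entries[starts[best]:ends[best]],
             formatted = format_consensus(cons$entries[starts[best]:ends[best]]),
             degenerate = FALSE)
  class(ph) <- "consensus_phrase"
  ph
}

#' @export
print.consensus_phrase <- function(x, ...) {
  cat("<consensus_phrase> columns ", x$start_col, "-", x$end_col, ": ",
      x$formatted, "\n", sep = "")
  if (!is.null(x$ref_start)) {
    cat("  ", x$reference_id, " positions ", x$ref_start, "-", x$ref_end,
        "; ", round(100 * x$fraction_of_alignment), "% of alignment, ",
        round(100 * x$fraction_of_reference), "% of reference\n", sep = "")
  }
  invisible(x)
}

#' Report a phrase in reference-sequence coordinates
#'
#' Maps the phrase's alignment columns to 1-based, inclusive residue positions
#' on a named reference row (gaps in the reference are skipped; a phrase
#' starting on a reference gap maps to the next reference residue) and
#' computes the fraction of the alignment the phrase spans and the fraction of
#' the reference it covers.
#'
#' @param phrase a `consensus_phrase` from [longest_phrase()].
#' @param aln the `aa_alignment` the consensus came from.
#' @param reference_id row to report coordinates on.
#' @return the completed `consensus_phrase` with `ref_start`, `ref_end`,
#'   `fraction_of_alignment`, `fraction_of_reference`, `reference_id`.
#' @export
phrase_report <- function(phrase, aln, reference_id) {
  if (!reference_id %in% aln$taxa) stop("reference '", reference_id, "' not in alignment")
  ref <- strsplit(aln$seqs[[reference_id]], "")[[1]]
  res <- ref != "-"
  pos <- cumsum(res)                         # residue index at each column
  cols <- phrase$start_col:phrase$end_col
  covered <- sum(res[cols])
  if (covered == 0) stop("phrase covers no residues of the reference")
  first_res_col <- cols[res[cols]][1]
  last_res_col <- rev(cols[res[cols]])[1]
  phrase$reference_id <- reference_id
  phrase$ref_start <- pos[first_res_col]
  phrase$ref_end <- pos[last_res_col]
  phrase$fraction_of_alignment <- length(cols) / aln$m
  phrase$fraction_of_reference <- covered / sum(res)
  phrase
}

#' @exportS3Method
tidy.consensus_phrase <- function(x, ...) {
  tibble::tibble(
    start_col = x$start_col, end_col = x$end_col, formatted = x$formatted,
    reference_id = x$reference_id %||% NA_character_,
    ref_start = x$ref_start %||% NA_integer_,
    ref_end = x$ref_end %||% NA_integer_,
    fraction_of_alignment = x$fraction_of_alignment %||% NA_real_,
    fraction_of_reference = x$fraction_of_reference %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
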