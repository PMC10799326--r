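# Readers and writers for the formats the pipeline consumes: newick gene and
# species trees with internal-node supports, aligned/unaligned protein FASTA,
# 12-column BLAST tabular hit files, and the TSV metadata sidecar.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

#' Read a gene tree from newick with internal-node supports
#'
#' Supports are read from internal-node labels (the IQ-TREE / PhyloBayes
#' convention). The support scale is auto-detected when not declared: if every
#' numeric support is <= 1 the scale is `"probability"` (Bayesian posterior),
#' otherwise `"percent"` (ultrafast bootstrap). A tree mixing values on both
#' sides of 1 is ambiguous and rejected unless `declared_scale` is given.
#' Unlabelled internal nodes carry absent support (`NA`), which downstream
#' operations never treat as low. Unary (single-child) internal nodes are
#' suppressed on read.
#'
#' @param file path to a newick file (give exactly one of `file`/`text`).
#' @param text newick string.
#' @param declared_scale optional `"probability"` or `"percent"`.
#' @return an ape `phylo` with supports in `node.label` and
#'   `attr(., "support_scale")` set (`NA` if the tree has no numeric supports).
#' @export
#' @examples
#' tr <- read_gene_tree(text = "((A,B)0.95,C);")
#' attr(tr, "support_scale")
read_gene_tree <- function(file = NULL, text = NULL, declared_scale = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  if (grepl("\\)\\s*:\\s*[0-9.eE+-]+\\s*:", text)) {
    stop("colon-separated branch-support dialect ('):support:length') is not supported; ",
         "encode supports as internal-node labels")
  }
  phy <- tryCatch(ape::read.tree(text = text),
    error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed newick: parser returned no tree")
  phy <- ape::collapse.singles(phy)
  sup <- node_support(phy)
  have <- sup[!is.na(sup)]
  if (!is.null(declared_scale)) {
    declared_scale <- match.arg(declared_scale, c("probability", "percent"))
    check_support_range(have, declared_scale)
    return(set_support_scale(phy, declared_scale))
  }
  if (!length(have)) return(set_support_scale(phy, NA_character_))
  if (all(have <= 1)) return(set_support_scale(phy, "probability"))
  if (all(have >= 1)) {
    check_support_range(have, "percent")
    return(set_support_scale(phy, "percent"))
  }
  stop("mixed support scales (values on both sides of 1); pass declared_scale")
}

check_support_range <- function(vals, scale) {
  lim <- if (scale == "probability") 1 else 100
  if (any(vals < 0 | vals > lim)) {
    stop("support values outside [0, ", lim, "] for scale '", scale, "'")
  }
  invisible(TRUE)
}

# balanced-parenthesis / terminator check with character offsets, so syntax
# errors name a position rather than deferring to the downstream parser
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L) stop("malformed newick: ", depth, " unclosed '(' at character ",
                       length(chars))
  if (!grepl(";", text)) stop("malformed newick: missing ';' terminator at character ",
                              length(chars))
  invisible(TRUE)
}

#' Write a gene tree to newick, supports as internal-node labels
#'
#' @param phy a `phylo` (supports in `node.label`).
#' @param file optional path; when `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to file.
#' @export
write_gene_tree <- function(phy, file = NULL) {
  txt <- phylo_to_newick(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a protein alignment from aligned FASTA
#'
#' Rows must be equal length over the 20 amino-acid letters plus `X` and the
#' gap `-`. Lowercase residues are uppercased; `U`, `.` and other characters
#' are rejected rather than coerced.
#'
#' @param file path to an aligned FASTA file.
#' @param text FASTA content as a string (alternative to `file`).
#' @return an `aa_alignment`: list with `taxa` (character), `seqs` (named
#'   character, original order), `m` (alignment length).
#' @export
read_alignment <- function(file = NULL, text = NULL) {
  seqs <- read_fasta_chr(file = file, text = text)
  make_alignment(seqs)
}

#' Construct an alignment from named sequences
#'
#' @param seqs named character vector of equal-length aligned rows.
#' @return an `aa_alignment`.
#' @export
make_alignment <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all alignment rows need names")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  bad_alpha <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    any(!ch %in% c(AA_LETTERS, "X", "-"))
  }, logical(1))
  if (any(bad_alpha)) {
    offender <- ids[which(bad_alpha)[1]]
    ch <- setdiff(unique(strsplit(seqs[[which(bad_alpha)[1]]], "")[[1]]),
                  c(AA_LETTERS, "X", "-"))
    stop("record '", offender, "' contains non-amino-acid characters: ",
         paste(ch, collapse = " "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    m <- lens[[1]]
    offender <- ids[which(lens != m)[1]]
    stop("ragged alignment: record '", offender, "' has length ", nchar(seqs[[offender]]),
         ", expected ", m)
  }
  if (length(seqs) < 2) stop("an alignment needs at least 2 sequences")
  structure(list(taxa = ids, seqs = seqs, m = unname(lens[[1]])),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", length(x$taxa), " taxa x ", x$m, " columns\n", sep = "")
  invisible(x)
}

# alignment as a character matrix (taxa x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$taxa
  m
}

# FASTA in/out via Biostrings, returned as plain named character
read_fasta_chr <- function(file = NULL, text = NULL) {
  if (is.null(file)) {
    stopifnot(!is.null(text))
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  ss <- Biostrings::readBStringSet(file)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param file output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, file, width = 70) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(file)
}

#' Read a 12-column BLAST tabular (outfmt 6) hit table
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Scientific-notation e-values are parsed; `evalue = 0`
#' is valid (the strongest possible hit).
#'
#' @param file path, or `text` for literal content.
#' @param text character scalar of TSV content.
#' @return tibble with one row per hit, columns as above plus a
#'   `subject_family` column of `NA` (fill via [annotate_hits()]).
#' @export
read_hit_table <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines)) {
    out <- tibble::as_tibble(stats::setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), cols))
    out$subject_family <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("line ", bad, ": expected 12 tab-separated columns, found ", nf[bad])
  }
  mat <- do.call(rbind, fields)
  out <- tibble::tibble(
    qseqid = mat[, 1], sseqid = mat[, 2],
    pident = as.numeric(mat[, 3]), length = as.numeric(mat[, 4]),
    mismatch = as.numeric(mat[, 5]), gapopen = as.numeric(mat[, 6]),
    qstart = as.numeric(mat[, 7]), qend = as.numeric(mat[, 8]),
    sstart = as.numeric(mat[, 9]), send = as.numeric(mat[, 10]),
    evalue = as.numeric(mat[, 11]), bitscore = as.numeric(mat[, 12])
  )
  num_cols <- c("pident", "length", "evalue", "bitscore")
  bad_num <- vapply(num_cols, function(cn) anyNA(out[[cn]]), logical(1))
  if (any(bad_num)) {
    cn <- num_cols[which(bad_num)[1]]
    stop("line ", which(is.na(out[[cn]]))[1], ": non-numeric value in column '", cn, "'")
  }
  if (any(out$evalue < 0)) stop("negative e-value in hit table")
  if (any(out$length < 1)) stop("alignment length < 1 in hit table")
  out$subject_family <- NA_character_
  out
}

#' Annotate hits with the known family of each subject
#'
#' @param hits tibble from [read_hit_table()].
#' @param family_map named character vector (or two-column data frame
#'   `sseqid`, `family`) mapping subject ids to family labels.
#' @return `hits` with `subject_family` filled (`NA` where unknown).
#' @export
annotate_hits <- function(hits, family_map) {
  if (is.data.frame(family_map)) {
    family_map <- stats::setNames(family_map$family, family_map$sseqid)
  }
  hits$subject_family <- unname(family_map[hits$sseqid])
  hits
}

#' Read the TSV metadata sidecar for sequence records
#'
#' Expected columns: `seq_id`, `genus`, `sample_id`, and optionally
#' `coverage_depth` (x), `completeness` (fraction in `[0,1]`, BUSCO-style),
#' `provenance` (`new`/`prior`), `family_label`.
#'
#' @param file path to the TSV.
#' @return tibble, validated.
#' @export
read_metadata <- function(file) {
  md <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  need <- c("seq_id", "genus", "sample_id")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$seq_id)) stop("duplicate seq_id in metadata")
  if ("coverage_depth" %in% names(md) &&
      any(md$coverage_depth < 0, na.rm = TRUE)) stop("negative coverage_depth")
  if ("completeness" %in% names(md) &&
      any(md$completeness < 0 | md$completeness > 1, na.rm = TRUE)) {
    stop("completeness must lie in [0, 1]")
  }
  md
}

#' Read a genus-level species cladogram, optionally with habitat states
#'
#' @param file newick path (or `text`). Leaves are genus names, must be unique.
#' @param text newick string.
#' @param habitats optional named character vector or TSV path with columns
#'   `genus`, `habitat` (levels marine / freshwater / limnoterrestrial).
#' @return a rooted `phylo`; habitat states, if given, attached as
#'   `attr(., "habitat")` (named character over leaves).
#' @export
read_species_tree <- function(file = NULL, text = NULL, habitats = NULL) {
  phy <- read_gene_tree(file = file, text = text)
  if (anyDuplicated(phy$tip.label)) stop("duplicate genus names in species tree")
  if (!ape::is.rooted(phy)) stop("species cladogram must be rooted")
  if (!is.null(habitats)) {
    if (is.character(habitats) && length(habitats) == 1 && file.exists(habitats)) {
      tab <- readr::read_tsv(habitats, show_col_types = FALSE, progress = FALSE)
      habitats <- stats::setNames(tab$habitat, tab$genus)
    }
    miss <- setdiff(phy$tip.label, names(habitats))
    if (length(miss)) stop("habitat state missing for: ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(habitats), c("marine", "freshwater", "limnoterrestrial"))
    if (length(bad)) stop("unknown habitat states: ", paste(bad, collapse = ", "))
    attr(phy, "habitat") <- habitats[phy$tip.label]
  }
  phy
}
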