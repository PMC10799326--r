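# Packaged fixtures: the 13-genus habitat cladogram, synthetic stand-in gene
# trees whose clade structure encodes the published textual description of
# each family's duplication pattern, and generators for synthetic consensus
# alignments and low-coverage paralog sets. All synthetic objects are labelled
# as such; none contain real sequence data.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "famhist")
  if (!nzchar(p)) stop("fixture '", name, "' not found")
  p
}

#' The default genus-level species cladogram with habitat states
#'
#' A 13-genus tardigrade cladogram (two heterotardigrade families plus the
#' Echiniscidae; Apochela and Parachela within Eutardigrada) with each genus
#' scored marine, freshwater or limnoterrestrial. Users may substitute their
#' own via [read_species_tree()].
#'
#' @return rooted `phylo` with `attr(., "habitat")`.
#' @export
default_species_tree <- function() {
  read_species_tree(file = fixture_path("tardigrade_genera.nwk"),
                    habitats = fixture_path("genus_habitats.tsv"))
}

#' Synthetic stand-in gene trees for the studied families
#'
#' Rooted newick trees whose clade structure mirrors the described duplication
#' pattern of each family (e.g. a four-copy *Ramazzottius* MRE11 clade, the
#' seven-*Ramazzottius* SAHS subfamily, four *Viridiscus* EtAHS alpha copies).
#' They are constructed, not inferred from sequence data, and exist to
#' exercise and document the inference rules.
#'
#' @param family one of `"mre11"`, `"etahs_alpha"`, `"cahs6"`,
#'   `"sahs_subfamily1"`, `"cahs2"`, `"mahs"`.
#' @return rooted `phylo`.
#' @export
synthetic_family_tree <- function(family = c("mre11", "etahs_alpha", "cahs6",
                                             "sahs_subfamily1", "cahs2", "mahs")) {
  family <- match.arg(family)
  read_gene_tree(file = fixture_path(paste0("synthetic_", family, ".nwk")))
}

#' Synthetic low-coverage paralog set (15 sequences, 7 true homologs)
#'
#' Emulates a family recovered from one poorly covered assembly: 7 distinct
#' homolog sequences, several of which appear as 2-3 near-identical
#' (>99% identity) assembly variants, 15 sequences in all. Group sizes are
#' 3, 3, 2, 2, 2, 2, 1.
#'
#' @param seed integer seed (sequence content is random; the grouping is not).
#' @param len sequence length.
#' @return named character vector of 15 protein sequences
#'   (`Paramacrobiotus|lc1|CAHS_01` ...).
#' @export
synthetic_low_coverage_family <- function(seed = 1, len = 240) {
  set.seed(seed)
  sizes <- c(3L, 3L, 2L, 2L, 2L, 2L, 1L)
  seqs <- character(0)
  k <- 0
  for (g in seq_along(sizes)) {
    base <- paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
    for (v in seq_len(sizes[g])) {
      k <- k + 1
      s <- strsplit(base, "")[[1]]
      if (v > 1) {
        # assembly variant: one substitution per extra copy (> 99% identity)
        pos <- sample.int(len, v - 1)
        s[pos] <- vapply(s[pos], function(a) sample(setdiff(AA_LETTERS, a), 1),
                         character(1))
      }
      seqs[sprintf("Paramacrobiotus|lc1|CAHS_%02d", k)] <- paste(s, collapse = "")
    }
  }
  seqs
}

# descending positive counts for an alternative set: k letters over n rows,
# printed order = frequency order
alt_counts <- function(n, k) {
  base <- rev(seq_len(k))
  extra <- n - sum(base)
  stopifnot(extra >= 0)
  cnt <- base + extra %/% k
  cnt[1] <- cnt[1] + extra %% k
  cnt
}

#' Synthetic alignment reproducing a conserved consensus block
#'
#' Builds an alignment with one fully analysable conserved block embedded in
#' otherwise hyper-variable columns: inside the block every column is either
#' unanimous or covered by a small alternative set (frequency-ordered to match
#' `entries`); outside it every column shows 20 distinct residues so the
#' consensus is `X` throughout. The reference row carries `ref_before`
#' residues before the block (so the block starts at reference position
#' `ref_before + 1`) and `ref_len` residues in total. The published EtAHS
#' alpha/beta motif geometries are available as presets.
#'
#' @param family `"alpha"` or `"beta"` for the preset geometries, or `NULL`
#'   to pass everything explicitly.
#' @param entries consensus entries for the block (a `consensus_seq`, a
#'   formatted string, or list of character vectors).
#' @param n_rows,m,ref_before,ref_len alignment geometry.
#' @param reference_id name of the reference row.
#' @return list with `aln` (an `aa_alignment`), `reference_id`, `block_start`,
#'   `block_end` (alignment columns).
#' @export
synthetic_consensus_alignment <- function(family = NULL, entries = NULL,
                                          n_rows = NULL, m = NULL,
                                          ref_before = NULL, ref_len = NULL,
                                          reference_id = NULL) {
  if (!is.null(family)) {
    family <- match.arg(family, c("alpha", "beta"))
    preset <- etahs_motif_presets()[[family]]
    entries <- preset$entries; n_rows <- preset$n_rows; m <- preset$m
    ref_before <- preset$ref_before; ref_len <- preset$ref_len
    reference_id <- preset$reference_id
  }
  if (is.character(entries)) entries <- parse_consensus(entries)$entries
  if (inherits(entries, "consensus_seq")) entries <- entries$entries
  b <- length(entries)
  stopifnot(m >= b + 4, ref_len >= ref_before + b, n_rows >= 8)
  block_start <- ref_before + 3L  # >= 2 all-X columns on each side
  stopifnot(block_start + b - 1 <= m - 2, block_start >= 3,
            ref_before <= block_start - 1)
  block_cols <- seq(block_start, length.out = b)
  mat <- matrix("", n_rows, m)
  # hyper-variable outside columns: 20 distinct residues per column
  for (j in setdiff(seq_len(m), block_cols)) {
    mat[, j] <- AA_LETTERS[(seq_len(n_rows) + j) %% 20 + 1]
  }
  for (i in seq_along(block_cols)) {
    e <- entries[[i]]
    col <- if (length(e) == 1) rep(e, n_rows) else
      rep(e, times = alt_counts(n_rows, length(e)))
    mat[, block_cols[i]] <- col
  }
  # reference row: residues before/inside/after the block, gaps elsewhere
  ref <- rep("-", m)
  before_cols <- seq_len(block_start - 1)
  ref_before_cols <- utils::tail(before_cols, ref_before)
  ref[ref_before_cols] <- mat[1, ref_before_cols]
  ref[block_cols] <- vapply(entries, `[[`, character(1), 1)
  after_n <- ref_len - ref_before - b
  after_cols <- seq(max(block_cols) + 1, m)
  stopifnot(after_n <= length(after_cols))
  ref_after_cols <- after_cols[seq_len(after_n)]
  ref[ref_after_cols] <- mat[1, ref_after_cols]
  mat[1, ] <- ref
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- c(reference_id,
                   paste0(sub("_1$", "_", reference_id), seq_len(n_rows - 1) + 1))
  list(aln = make_alignment(rows), reference_id = reference_id,
       block_start = block_start, block_end = max(block_cols))
}

# geometries under which the published EtAHS alpha/beta motifs span 4%/7%
# (alpha) and 15%/20% (beta) of alignment/reference
etahs_motif_presets <- function() {
  alpha <- paste0("FYNN{RG}TY{IT}{FY}{MLT}LE{LV}PC{DE}AYL{GST}{GQP}{RA}G{GV}")
  beta <- paste0("DGVK{QKL}PIDLTRVLA{IRN}TP{DE}VLE{QK}{IV}{DN}{DV}V{FY}FFFPN",
                 "{KG}Q{IS}GR{IV}EFE{HQ}GQ{PA}{NED}EL{EA}RITCR{PA}PCRGGP",
                 "{RSK}{NSTQ}{AT}")
  list(
    alpha = list(entries = parse_consensus(alpha)$entries, n_rows = 22L,
                 m = 600L, ref_before = 44L, ref_len = 343L,
                 reference_id = "EtAHS_alpha_1"),
    beta = list(entries = parse_consensus(beta)$entries, n_rows = 21L,
                m = 427L, ref_before = 139L, ref_len = 320L,
                reference_id = "EtAHS_beta_1"))
}
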