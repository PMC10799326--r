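# Relative Composition Frequency Variability (RCFV) screening. Per-taxon
# amino-acid frequencies are compared against the dataset mean composition;
# taxa whose normalized score exceeds the dataset value by more than k
# standard deviations are flagged as compositionally heterogeneous.

#' Per-taxon amino-acid composition of an alignment
#'
#' Frequencies are computed over the 20 amino acids; gaps and `X` are excluded
#' from the counts, so each taxon's frequency vector sums to 1 whenever the
#' row has at least one unambiguous residue.
#'
#' @param aln an `aa_alignment`.
#' @return a `composition_profile`: list with `freq` (taxa x 20 matrix), `mu`
#'   (mean frequency per state), `n` taxa, `m` columns.
#' @export
composition_profile <- function(aln) {
  m <- aln_matrix(aln)
  counts <- t(apply(m, 1, function(row) {
    row <- row[row %in% AA_LETTERS]
    tabulate(factor(row, levels = AA_LETTERS), nbins = 20)
  }))
  colnames(counts) <- AA_LETTERS
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("taxon '", aln$taxa[which(tot == 0)[1]], "' has no unambiguous residues")
  }
  freq <- counts / tot
  structure(list(freq = freq, mu = colMeans(freq),
                 n = nrow(freq), m = aln$m),
            class = "composition_profile")
}

#' RCFV scores with square-root-of-length normalization
#'
#' The un-normalized scores are the classical definitions: per-taxon
#' `tRCFV_t = sum_s |f_st - mu_s| / n`, per-state
#' `csRCFV_s = sum_t |f_st - mu_s| / n`, and `RCFV = sum_t tRCFV_t =
#' sum_s csRCFV_s`. Frequency deviations shrink like `1/sqrt(m)` with
#' alignment length, so the default normalization multiplies every per-taxon
#' score by `sqrt(m)`: `ntRCFV_t = tRCFV_t * sqrt(m)`, with the dataset value
#' `nRCFV` the mean of the `ntRCFV_t`. The normalization is pluggable — any
#' one common positive scaling leaves the outlier screen unchanged (it
#' depends only on relative scores), so swapping in another convention cannot
#' alter screening outcomes.
#'
#' @param profile a [composition_profile()] (or an `aa_alignment`, profiled
#'   on the fly).
#' @param normalization function mapping `(tRCFV, m, n)` to the normalized
#'   per-taxon scores; default multiplies by `sqrt(m)`.
#' @return an `rcfv_profile`: the profile plus a per-taxon tibble (`taxon`,
#'   `tRCFV`, `ntRCFV`, `sd_units`, `quartile`), `csRCFV`, `RCFV`, `nRCFV`,
#'   and `sd` (population SD of the `ntRCFV_t`).
#' @export
rcfv_scores <- function(profile,
                        normalization = function(t, m, n) t * sqrt(m)) {
  if (inherits(profile, "aa_alignment")) profile <- composition_profile(profile)
  stopifnot(inherits(profile, "composition_profile"))
  dev <- abs(sweep(profile$freq, 2, profile$mu))
  n <- profile$n
  trcfv <- rowSums(dev) / n
  csrcfv <- colSums(dev) / n
  ntrcfv <- normalization(trcfv, profile$m, n)
  if (any(ntrcfv < 0) || (any(trcfv > 0) && all(ntrcfv == 0))) {
    stop("normalization must be a positive scaling of the tRCFV values")
  }
  nrcfv <- mean(ntrcfv)
  sdv <- stats::sd(ntrcfv) * sqrt((n - 1) / n)  # population form
  sd_units <- if (sdv > 0) (ntrcfv - nrcfv) / sdv else rep(0, n)
  # inclusive-quartile assignment (Tukey hinges: median in both halves)
  q <- stats::fivenum(ntrcfv)[2:4]
  quart <- findInterval(ntrcfv, q, left.open = TRUE) + 1L
  out <- profile
  out$scores <- tibble::tibble(
    taxon = rownames(profile$freq), tRCFV = unname(trcfv),
    ntRCFV = unname(ntrcfv), sd_units = unname(sd_units), quartile = quart)
  out$csRCFV <- csrcfv
  out$RCFV <- sum(trcfv)
  out$nRCFV <- nrcfv
  out$sd <- sdv
  class(out) <- c("rcfv_profile", class(profile))
  out
}

#' @export
print.rcfv_profile <- function(x, ...) {
  cat("<rcfv_profile> ", x$n, " taxa, RCFV = ", signif(x$RCFV, 5),
      ", nRCFV = ", signif(x$nRCFV, 5), " (sd ", signif(x$sd, 5), ")\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Flag compositionally heterogeneous taxa
#'
#' A taxon is flagged iff `ntRCFV_t > nRCFV + k_sd * sd`, one-sided: low
#' heterogeneity is never significant. `sd` is the population standard
#' deviation of the per-taxon `ntRCFV` values. When `sd` is 0 (e.g. identical
#' rows) nothing can be flagged.
#'
#' @param profile an `rcfv_profile` (or alignment/composition profile, scored
#'   with defaults on the fly).
#' @param k_sd flagging threshold in SD units (default 3).
#' @return tibble: the per-taxon score table plus a logical `flagged` column.
#' @export
flag_heterogeneous <- function(profile, k_sd = 3) {
  stopifnot(k_sd > 0)
  if (!inherits(profile, "rcfv_profile")) profile <- rcfv_scores(profile)
  if (profile$n < 3) stop("need at least 3 taxa to screen for outliers")
  sc <- profile$scores
  sc$flagged <- if (profile$sd > 0) sc$ntRCFV > profile$nRCFV + k_sd * profile$sd
                else rep(FALSE, nrow(sc))
  sc
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method
tidy.rcfv_profile <- function(x, ...) x$scores

#' @exportS3Method
glance.rcfv_profile <- function(x, ...) {
  tibble::tibble(n_taxa = x$n, m = x$m, RCFV = x$RCFV, nRCFV = x$nRCFV, sd = x$sd)
}
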