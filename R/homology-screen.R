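# Candidate-identification decision rules applied to precomputed similarity
# search hit tables. Searches themselves (BLAST/HMMER) are run outside the
# package; these functions encode the retain/reject logic only.

#' Screening thresholds
#'
#' `e_primary` and `e_reciprocal` default to 1e-10. The source protocol's
#' printed threshold "10e-10" literally equals 1e-9; the conventional intent
#' (1e-10) is the default and both are reachable through this config.
#' `literal_reciprocal_ge` selects the literal reading of the reciprocal rule
#' (best hit retained when its e-value is *at least* the threshold) instead of
#' the conventional `<=`.
#'
#' @param e_primary e-value cutoff for the primary screen.
#' @param e_reciprocal e-value cutoff for the reciprocal-best-hit confirmation.
#' @param min_length_divergent minimum sequence length (aa) in the divergent
#'   (sensitivity) screen; sequences must be strictly longer.
#' @param e_divergent_max maximum qualifying e-value in the divergent screen.
#' @param literal_reciprocal_ge logical; see Details.
#' @param literal_divergent_gt logical; retain divergent-screen hits with
#'   e-value strictly greater than `e_divergent_max` (the literal protocol
#'   wording) instead of `<=`.
#' @return a `screen_config` list.
#' @export
screen_config <- function(e_primary = 1e-10, e_reciprocal = 1e-10,
                          min_length_divergent = 80L, e_divergent_max = 1.0,
                          literal_reciprocal_ge = FALSE,
                          literal_divergent_gt = FALSE) {
  stopifnot(e_primary > 0, e_reciprocal > 0, e_divergent_max > 0,
            min_length_divergent >= 1)
  structure(list(e_primary = e_primary, e_reciprocal = e_reciprocal,
                 min_length_divergent = as.integer(min_length_divergent),
                 e_divergent_max = e_divergent_max,
                 literal_reciprocal_ge = literal_reciprocal_ge,
                 literal_divergent_gt = literal_divergent_gt),
            class = "screen_config")
}

#' Primary homology screen against known family members
#'
#' A query is a candidate if any hit against the known-family set reaches the
#' primary e-value cutoff.
#'
#' @param hits hit tibble ([read_hit_table()] layout); subjects are known
#'   family members.
#' @param cfg a [screen_config()].
#' @return character vector of candidate query ids (input order of first
#'   qualifying hit).
#' @export
primary_screen <- function(hits, cfg = screen_config()) {
  keep <- hits$evalue <= cfg$e_primary
  unique(hits$qseqid[keep])
}

# best hit per query: lowest evalue, tie -> highest bitscore, tie -> first in
# input order
best_hits <- function(hits) {
  hits |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$.row,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' Reciprocal-best-hit confirmation against an nr-style hit table
#'
#' Each candidate's best nr hit (lowest e-value; ties by bitscore, then input
#' order) must be annotated with the target family and reach the reciprocal
#' e-value cutoff; otherwise the candidate is rejected with a reason.
#'
#' @param candidates character vector of candidate seq_ids.
#' @param nr_hits hit tibble with `subject_family` filled for annotated
#'   subjects (see [annotate_hits()]).
#' @param family target family label.
#' @param cfg a [screen_config()].
#' @return tibble of decisions: `seq_id`, `verdict` (retained/rejected),
#'   `reason`, `best_hit`, `best_evalue`.
#' @export
reciprocal_confirm <- function(candidates, nr_hits, family, cfg = screen_config()) {
  bh <- best_hits(nr_hits[nr_hits$qseqid %in% candidates, , drop = FALSE])
  purrr::map_dfr(candidates, function(id) {
    row <- bh[bh$qseqid == id, , drop = FALSE]
    if (!nrow(row)) {
      return(tibble::tibble(seq_id = id, verdict = "rejected",
                            reason = "no_reciprocal_hit",
                            best_hit = NA_character_, best_evalue = NA_real_))
    }
    e_ok <- if (cfg$literal_reciprocal_ge) row$evalue >= cfg$e_reciprocal
            else row$evalue <= cfg$e_reciprocal
    in_family <- !is.na(row$subject_family) && row$subject_family == family
    if (in_family && e_ok) {
      tibble::tibble(seq_id = id, verdict = "retained",
                     reason = "passed_primary_and_reciprocal",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    } else if (!in_family) {
      tibble::tibble(seq_id = id, verdict = "rejected",
                     reason = "reciprocal_best_hit_other_family",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    } else {
      tibble::tibble(seq_id = id, verdict = "rejected", reason = "failed_primary",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    }
  })
}

#' Divergent (sensitivity) screen for highly diverged family members
#'
#' Used where ordinary similarity search fails: retain sequences strictly
#' longer than `min_length_divergent` amino acids whose best annotated hit is
#' not another family and whose best-hit e-value qualifies (by default
#' `<= e_divergent_max`; the literal "greater than 1" protocol reading is
#' selectable in the config).
#'
#' @param seqs named character vector of candidate protein sequences (or a
#'   tibble with `seq_id` and `residues`).
#' @param hits hit tibble with `subject_family` annotations.
#' @param family target family label.
#' @param cfg a [screen_config()].
#' @return decision tibble as in [reciprocal_confirm()].
#' @export
divergent_screen <- function(seqs, hits, family, cfg = screen_config()) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$residues, seqs$seq_id)
  bh <- best_hits(hits)
  purrr::map_dfr(names(seqs), function(id) {
    len <- nchar(seqs[[id]])
    if (len <= cfg$min_length_divergent) {
      return(tibble::tibble(seq_id = id, verdict = "rejected", reason = "too_short",
                            best_hit = NA_character_, best_evalue = NA_real_))
    }
    row <- bh[bh$qseqid == id, , drop = FALSE]
    if (!nrow(row)) {
      return(tibble::tibble(seq_id = id, verdict = "rejected",
                            reason = "no_reciprocal_hit",
                            best_hit = NA_character_, best_evalue = NA_real_))
    }
    other_family <- !is.na(row$subject_family) && row$subject_family != family
    e_ok <- if (cfg$literal_divergent_gt) row$evalue > cfg$e_divergent_max
            else row$evalue <= cfg$e_divergent_max
    if (other_family) {
      tibble::tibble(seq_id = id, verdict = "rejected",
                     reason = "reciprocal_best_hit_other_family",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    } else if (e_ok) {
      tibble::tibble(seq_id = id, verdict = "retained", reason = "passed_divergent",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    } else {
      tibble::tibble(seq_id = id, verdict = "rejected", reason = "failed_primary",
                     best_hit = row$sseqid, best_evalue = row$evalue)
    }
  })
}
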