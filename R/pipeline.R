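# One-config orchestration: screen -> RCFV -> collapse -> root -> merge ->
# duplication/loss inference -> consensus, over one or many families, with a
# reproducible, self-describing report.

#' Validate a pipeline configuration
#'
#' The configuration is a plain named list (typically from a YAML file):
#' `species_tree` (path) and `habitats` (path, optional); `families`, a named
#' list where each entry may carry `tree` (newick path, required),
#' `alignment` (aligned FASTA path), `metadata` (TSV path), `outgroup`
#' (character vector), `rooting` (`"outgroup"`, `"min_duplications"`, or
#' `"asis"`), `reference` (row for consensus reporting), `anchors` (named
#' list); and `params` overriding any of the defaults listed in
#' [pipeline_defaults()]. Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed_top <- c("species_tree", "habitats", "families", "params", "seed")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$species_tree)) stop("config needs 'species_tree'")
  if (!file.exists(config$species_tree)) {
    stop("species_tree path does not exist: ", config$species_tree)
  }
  allowed_fam <- c("tree", "alignment", "metadata", "outgroup", "rooting",
                   "reference", "anchors")
  for (fam in names(config$families)) {
    fc <- config$families[[fam]]
    unknown <- setdiff(names(fc), allowed_fam)
    if (length(unknown)) {
      stop("family '", fam, "': unknown keys: ", paste(unknown, collapse = ", "))
    }
    if (is.null(fc$tree)) stop("family '", fam, "' needs a 'tree' path")
    for (key in c("tree", "alignment", "metadata")) {
      if (!is.null(fc[[key]]) && !file.exists(fc[[key]])) {
        stop("family '", fam, "': ", key, " path does not exist: ", fc[[key]])
      }
    }
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config$params), names(defaults))
  if (length(unknown)) stop("unknown params: ", paste(unknown, collapse = ", "))
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config
}

#' Default pipeline parameters
#'
#' `collapse_threshold` (`NULL` = 0.7/70 by scale), `k_sd` (RCFV flag, 3),
#' `id_threshold` (0.98), `cov_threshold` (40), `completeness_guard` (0.8),
#' `fixed_frac`/`alt_max`/`min_coverage` (consensus caller), `max_exact`
#' (polytomy refinement).
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(collapse_threshold = NULL, k_sd = 3, id_threshold = 0.98,
       cov_threshold = 40, completeness_guard = 0.8,
       fixed_frac = 1.0, alt_max = 4, min_coverage = 0.8, max_exact = 6)
}

#' Run the full analysis pipeline
#'
#' Stages run in fixed order per family — RCFV screen (if an alignment is
#' given), support collapse, rooting, low-coverage merge (if metadata carries
#' coverage), genus-exclusive duplications plus LCA reconciliation, homolog
#' groups and completeness-guarded losses, consensus phrase (if an alignment
#' is given) — and failures are isolated per family. Every tie-break and
#' guard trigger is logged in the report.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return a `run_report`: list with `config` (defaults printed in),
#'   `families` (per-family results), `copy_counts`, `errors`, `log` (tibble).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  habitats <- config$habitats
  species <- read_species_tree(file = config$species_tree, habitats = habitats)
  p <- config$params
  logs <- list()
  note <- function(family, stage, msg) {
    logs[[length(logs) + 1]] <<- tibble::tibble(family = family, stage = stage,
                                                message = msg)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  results <- list(); errors <- list(); trees <- list(); merges <- list()
  for (fam in names(config$families)) {
    fc <- config$families[[fam]]
    res <- tryCatch({
      out <- list()
      gene <- read_gene_tree(file = fc$tree)
      aln <- if (!is.null(fc$alignment)) read_alignment(fc$alignment)
      md <- if (!is.null(fc$metadata)) read_metadata(fc$metadata)
      if (!is.null(aln)) {
        out$rcfv <- flag_heterogeneous(rcfv_scores(aln), k_sd = p$k_sd)
        for (tx in out$rcfv$taxon[out$rcfv$flagged]) {
          note(fam, "rcfv", paste0("flagged compositionally heterogeneous: ", tx))
        }
      }
      gene <- collapse_low_support(gene, threshold = p$collapse_threshold)
      rooting <- fc$rooting %||%
        (if (!is.null(fc$outgroup)) "outgroup" else "asis")
      gene <- switch(rooting,
        outgroup = root_by_outgroup(gene, fc$outgroup),
        min_duplications = {
          r <- root_min_duplications(gene, species)
          if (length(r$trees) > 1) {
            note(fam, "root", paste0(length(r$trees),
              " rootings tie at ", r$count, " duplications; using the first"))
          }
          r$trees[[1]]
        },
        asis = {
          if (!ape::is.rooted(gene)) stop("tree is unrooted; set rooting")
          gene
        },
        stop("unknown rooting mode: ", rooting))
      if (!is.null(md) && "coverage_depth" %in% names(md) && !is.null(aln)) {
        seqs <- gsub("-", "", aln$seqs, fixed = TRUE)
        fam_merges <- list()
        for (smp in unique(md$sample_id)) {
          ids <- intersect(md$seq_id[md$sample_id == smp], names(seqs))
          if (length(ids) < 2) next
          cov <- md$coverage_depth[md$sample_id == smp][1]
          mg <- merge_low_coverage(seqs[ids], coverage = cov,
                                   id_threshold = p$id_threshold,
                                   cov_threshold = p$cov_threshold)
          for (i in which(mg$merged)) {
            note(fam, "merge", paste0("sample ", smp, " (", cov, "x): merged ",
              mg$n_members[i], " sequences into ", mg$representative[i]))
          }
          fam_merges[[smp]] <- mg
        }
        if (length(fam_merges)) {
          out$merges <- dplyr::bind_rows(fam_merges)
          gene <- apply_merges(gene, out$merges)
        }
      }
      out$tree <- gene
      out$independent <- genus_exclusive_duplications(gene)
      out$reconciliation <- lca_reconcile(gene, species, max_exact = p$max_exact)
      anchors <- if (!is.null(fc$anchors)) unlist(fc$anchors)
      hg <- homolog_groups(gene, species, family = fam, anchors = anchors)
      out$groups <- hg$groups
      out$presence <- hg$presence
      if (!is.null(md) && "completeness" %in% names(md)) {
        comp <- tapply(md$completeness, md$genus, max, na.rm = TRUE)
        out$losses <- infer_losses(hg$presence, comp, g = p$completeness_guard,
                                   genera_considered = names(comp))
        for (i in which(out$losses$confidence == "unknown_low_completeness")) {
          note(fam, "losses", paste0("absence in ", out$losses$genus[i],
            " not interpreted (completeness below guard)"))
        }
      }
      if (!is.null(aln) && !is.null(fc$reference)) {
        cons <- build_consensus(aln, fixed_frac = p$fixed_frac,
                                alt_max = p$alt_max,
                                min_coverage = p$min_coverage)
        out$motif <- phrase_report(longest_phrase(cons), aln, fc$reference)
      }
      trees[[fam]] <- gene
      out
    }, error = function(e) {
      errors[[fam]] <<- conditionMessage(e)
      note(fam, "error", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[fam]] <- res
  }
  report <- list(
    config = config,
    families = results,
    copy_counts = if (length(trees)) copy_counts(trees) else NULL,
    errors = errors,
    log = if (length(logs)) dplyr::bind_rows(logs) else
      tibble::tibble(family = character(), stage = character(),
                     message = character()))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$families), " families analysed, ",
      length(x$errors), " failed\n", sep = "")
  for (fam in names(x$families)) {
    r <- x$families[[fam]]
    cat("  ", fam, ": ", sum(r$independent$n_duplications),
        " independent duplications, ",
        r$reconciliation$n_duplications, " total (reconciliation), ",
        r$reconciliation$n_losses, " losses\n", sep = "")
  }
  invisible(x)
}

#' Write a run report to disk as TSV/JSON artifacts
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$copy_counts)) {
    readr::write_tsv(report$copy_counts, file.path(dir, "copycounts.tsv"))
  }
  events <- purrr::map_dfr(names(report$families), function(fam) {
    dplyr::mutate(tidy(report$families[[fam]]$reconciliation), family = fam)
  })
  readr::write_tsv(events, file.path(dir, "events.tsv"))
  readr::write_tsv(report$log, file.path(dir, "log.tsv"))
  summary <- list(
    params = report$config$params,
    families = lapply(report$families, function(r) list(
      n_independent_duplications = sum(r$independent$n_duplications),
      n_duplications = r$reconciliation$n_duplications,
      n_losses = r$reconciliation$n_losses,
      n_groups = nrow(r$groups),
      rcfv_flagged = if (!is.null(r$rcfv)) r$rcfv$taxon[r$rcfv$flagged],
      motif = if (!is.null(r$motif)) unclass(tidy(r$motif)))),
    errors = report$errors)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
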