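# Supporting inference around reconciliation: the >98%-identity paralog merge
# for low-coverage samples, homolog-group naming with presence/absence, the
# completeness-guarded loss call, copy-count tables, and Fitch small parsimony
# for habitat mapping.

#' Global pairwise identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5 — the conventional protein defaults); identity is matching columns over
#' aligned columns (a pairwise alignment has no double-gap columns).
#'
#' @param a,b protein sequence strings.
#' @param gap_opening,gap_extension gap penalties.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::pid(al, type = "PID1") / 100
}

#' Merge near-identical paralogs from low-coverage samples
#'
#' Independent duplications are not called from poorly covered assemblies:
#' when a sample's coverage depth is below `cov_threshold` (default 40x), the
#' family's sequences from that sample are clustered by single linkage at
#' pairwise identity strictly above `id_threshold` (default 0.98) and each
#' cluster is collapsed to one representative (the longest member; ties by
#' lexicographic seq_id). At or above the coverage threshold nothing is
#' merged.
#'
#' @param seqs named character vector of protein sequences, one sample and one
#'   family.
#' @param coverage the sample's coverage depth (x); required.
#' @param id_threshold single-linkage identity threshold (strict `>`).
#' @param cov_threshold coverage guard (merge only below this).
#' @return tibble of merge groups: `representative`, `n_members`, `merged`,
#'   and list columns `members`, `identities` (the pairwise identities within
#'   the group that drove the linkage).
#' @export
merge_low_coverage <- function(seqs, coverage, id_threshold = 0.98,
                               cov_threshold = 40) {
  if (missing(coverage) || is.null(coverage) || is.na(coverage)) {
    stop("sample coverage is required to decide whether to merge")
  }
  ids <- names(seqs)
  if (coverage >= cov_threshold || length(seqs) < 2) {
    return(tibble::tibble(representative = ids, n_members = 1L, merged = FALSE,
                          members = as.list(ids), identities = list(numeric())))
  }
  n <- length(seqs)
  pid <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pid[i, j] <- pid[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
    }
  }
  # single linkage: connected components of the >threshold graph
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (pid[i, j] > id_threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  purrr::map_dfr(unique(comp), function(cc) {
    mem <- ids[comp == cc]
    rep_id <- mem[order(-nchar(seqs[mem]), mem)][1]
    within <- if (length(mem) > 1) pid[mem, mem][upper.tri(matrix(0, length(mem), length(mem)))]
              else numeric()
    tibble::tibble(representative = rep_id, n_members = length(mem),
                   merged = length(mem) > 1, members = list(mem),
                   identities = list(unname(within)))
  })
}

#' Drop merged-away paralogs from a gene tree
#'
#' @param gene `phylo`; @param merges tibble from [merge_low_coverage()].
#' @return `phylo` with non-representative members of merged groups pruned.
#' @export
apply_merges <- function(gene, merges) {
  drop <- setdiff(unlist(merges$members), merges$representative)
  drop <- intersect(drop, gene$tip.label)
  if (!length(drop)) return(gene)
  out <- ape::drop.tip(gene, drop)
  set_support_scale(out, support_scale(gene))
}

#' Homolog groups from a processed gene tree
#'
#' After genus-exclusive clades are fused to single tips, homolog groups are
#' the maximal clades in which every genus occurs at most once. Groups are
#' auto-named `<family><k>` in root-to-tip, left-to-right traversal order;
#' `anchors` (name -> member seq_id) pin curated names to the clade containing
#' that sequence.
#'
#' @param gene rooted, collapsed, post-merge `phylo`.
#' @param species rooted species `phylo` (defines the genus universe of the
#'   presence matrix).
#' @param family family label used as the auto-name stem.
#' @param anchors optional named character vector, name -> seq_id.
#' @return list with `groups` (tibble: `name`, `node`, `n_members`, `genera`
#'   and `members` list columns) and `presence` (logical genus x group
#'   matrix over the genera of `species`).
#' @export
homolog_groups <- function(gene, species, family = "HG", anchors = NULL) {
  excl <- genus_exclusive_duplications(gene)
  fused <- gene
  # fuse each multi-leaf genus-exclusive clade to its first member tip
  for (i in seq_len(nrow(excl))) {
    mem <- excl$members[[i]]
    if (length(mem) > 1) fused <- ape::drop.tip(fused, mem[-1])
  }
  n_tip <- ape::Ntip(fused)
  genera <- leaf_genus(fused$tip.label)
  kids <- node_children(fused)
  par <- node_parent(fused)
  desc <- descendant_tips(fused)
  ok <- rep(FALSE, n_tip + fused$Nnode)  # clade has each genus at most once
  for (v in postorder_nodes(fused)) {
    g <- genera[desc[[v]]]
    ok[v] <- !anyDuplicated(g)
  }
  maximal <- which(ok & vapply(seq_along(ok), function(v) {
    is.na(par[v]) || !ok[par[v]]
  }, logical(1)))
  # root-to-tip, left-to-right = preorder over the fused tree
  pre <- rev(postorder_nodes(fused))
  maximal <- maximal[order(match(maximal, pre))]
  # map fused tips back to full membership (fused representative -> clade)
  expand <- stats::setNames(as.list(c(gene$tip.label)), gene$tip.label)
  for (i in seq_len(nrow(excl))) {
    mem <- excl$members[[i]]
    if (length(mem) > 1) expand[[mem[1]]] <- mem
  }
  groups <- purrr::map_dfr(seq_along(maximal), function(k) {
    v <- maximal[k]
    reps <- fused$tip.label[desc[[v]]]
    members <- unlist(expand[reps], use.names = FALSE)
    tibble::tibble(name = paste0(family, k), node = v,
                   n_members = length(members),
                   genera = list(sort(unique(genera[desc[[v]]]))),
                   members = list(members))
  })
  if (!is.null(anchors)) {
    for (nm in names(anchors)) {
      hit <- which(vapply(groups$members, function(m) anchors[[nm]] %in% m,
                          logical(1)))
      if (!length(hit)) stop("anchor sequence '", anchors[[nm]],
                             "' not found in any homolog group")
      groups$name[hit[1]] <- nm
    }
  }
  pres <- vapply(groups$genera, function(g) species$tip.label %in% g,
                 logical(ape::Ntip(species)))
  pres <- matrix(pres, nrow = ape::Ntip(species),
                 dimnames = list(species$tip.label, groups$name))
  list(groups = groups, presence = pres)
}

#' Infer losses from a presence matrix, guarded by assembly completeness
#'
#' A genus absent from a homolog group is called a loss only when that genus'
#' best assembly completeness reaches the guard `g`; below it the absence is
#' reported as `unknown_low_completeness` (poor assemblies cannot evidence
#' absence).
#'
#' @param presence logical genus x group matrix (see [homolog_groups()]).
#' @param completeness named numeric vector, per-genus best completeness in
#'   `[0, 1]`.
#' @param g guard threshold (default 0.8).
#' @param genera_considered optional subset of genera for which absence is
#'   interpretable at all (e.g. families known to carry the protein).
#' @return tibble of loss events: `genus`, `group`, `confidence`.
#' @export
infer_losses <- function(presence, completeness, g = 0.8,
                         genera_considered = rownames(presence)) {
  empty <- tibble::tibble(genus = character(), group = character(),
                          confidence = character())
  rows <- purrr::map_dfr(intersect(rownames(presence), genera_considered),
                         function(gen) {
    absent <- colnames(presence)[!presence[gen, ]]
    if (!length(absent)) return(NULL)
    comp <- if (gen %in% names(completeness)) completeness[[gen]] else NA_real_
    conf <- if (!is.null(comp) && !is.na(comp) && comp >= g) "inferred"
            else "unknown_low_completeness"
    tibble::tibble(genus = gen, group = absent, confidence = conf)
  })
  dplyr::bind_rows(empty, rows)
}

#' Copy-count table per genus and family
#'
#' Counts post-merge leaves of each family's gene tree per genus.
#'
#' @param trees named list of rooted `phylo` (name = family label).
#' @param merges optional named list of merge tibbles, parallel to `trees`.
#' @return tibble `genus` x one column per family, integer counts; a
#'   `copy_count_table`.
#' @export
copy_counts <- function(trees, merges = NULL) {
  fams <- names(trees)
  counts <- purrr::map_dfr(fams, function(f) {
    tr <- trees[[f]]
    if (!is.null(merges) && !is.null(merges[[f]])) {
      tr <- apply_merges(tr, merges[[f]])
    }
    tibble::tibble(family = f, genus = leaf_genus(tr$tip.label))
  }) |>
    dplyr::count(.data$genus, .data$family) |>
    tidyr::pivot_wider(names_from = "family", values_from = "n",
                       values_fill = 0L)
  class(counts) <- c("copy_count_table", class(counts))
  counts
}

#' Fitch small parsimony on the species tree
#'
#' Bottom-up/top-down pass over a rooted tree with unordered states; exact
#' for multifurcating trees as well (unit-cost Sankoff recursion). Returns the
#' minimum number of state changes and, per node, the set of states occurring
#' in at least one minimum-change assignment.
#'
#' @param species rooted `phylo`.
#' @param tip_states named character vector, genus -> state (or `NULL` to use
#'   `attr(species, "habitat")`).
#' @param root_state optional state the root is constrained to (e.g. from
#'   outgroup evidence).
#' @return list with `n_changes` and `state_sets` (list over nodes, tips
#'   first).
#' @export
fitch_ancestral <- function(species, tip_states = NULL, root_state = NULL) {
  if (is.null(tip_states)) tip_states <- attr(species, "habitat")
  if (is.null(tip_states)) stop("no tip states given")
  miss <- setdiff(species$tip.label, names(tip_states))
  if (length(miss)) stop("missing tip state for: ", paste(miss, collapse = ", "))
  states <- sort(unique(unname(tip_states[species$tip.label])))
  if (!is.null(root_state)) states <- sort(unique(c(states, root_state)))
  n_tip <- ape::Ntip(species)
  kids <- node_children(species)
  ns <- length(states)
  INF <- 1e9
  cost <- matrix(INF, n_tip + species$Nnode, ns, dimnames = list(NULL, states))
  for (v in postorder_nodes(species)) {
    if (v <= n_tip) {
      cost[v, tip_states[[species$tip.label[v]]]] <- 0
    } else {
      for (s in seq_len(ns)) {
        cost[v, s] <- sum(vapply(kids[[v]], function(k) {
          min(cost[k, ] + (states != states[s]))
        }, numeric(1)))
      }
    }
  }
  r <- root_node(species)
  root_costs <- cost[r, ]
  if (!is.null(root_state)) {
    keep <- states == root_state
    root_costs[!keep] <- INF
  }
  n_changes <- min(root_costs)
  # top-down: states usable at each node in some optimal assignment
  usable <- vector("list", n_tip + species$Nnode)
  usable[[r]] <- states[root_costs == n_changes]
  for (v in rev(postorder_nodes(species))) {
    if (v <= n_tip) next
    for (k in kids[[v]]) {
      opts <- character()
      for (s in usable[[v]]) {
        sub <- cost[k, ] + (states != s)
        opts <- c(opts, states[sub == min(sub)])
      }
      usable[[k]] <- sort(unique(opts))
    }
  }
  for (v in seq_len(n_tip)) usable[[v]] <- tip_states[[species$tip.label[v]]]
  list(n_changes = unname(n_changes), state_sets = usable, states = states)
}

#' Minimum number of a specific state transition among optimal assignments
#'
#' Among all minimum-change assignments (optionally with the root constrained,
#' e.g. to marine on outgroup evidence), the smallest possible number of
#' `from -> to` changes. Used to ask how many independent
#' marine-to-limnoterrestrial transitions the habitat cladogram requires.
#'
#' @inheritParams fitch_ancestral
#' @param from,to states of the transition of interest.
#' @return list with `n_changes` (total) and `n_transition` (minimum count of
#'   the named transition among optima).
#' @export
count_transitions <- function(species, tip_states = NULL, from, to,
                              root_state = NULL) {
  if (is.null(tip_states)) tip_states <- attr(species, "habitat")
  fit <- fitch_ancestral(species, tip_states, root_state)
  states <- fit$states
  n_tip <- ape::Ntip(species)
  kids <- node_children(species)
  ns <- length(states)
  INF <- 1e9
  # lexicographic DP: minimize (total changes, from->to changes)
  cost <- array(INF, c(n_tip + species$Nnode, ns))
  ft <- array(INF, c(n_tip + species$Nnode, ns))
  for (v in postorder_nodes(species)) {
    if (v <= n_tip) {
      s0 <- tip_states[[species$tip.label[v]]]
      cost[v, ] <- INF; ft[v, ] <- INF
      cost[v, match(s0, states)] <- 0
      ft[v, match(s0, states)] <- 0
    } else {
      for (s in seq_len(ns)) {
        tot <- 0; trans <- 0
        for (k in kids[[v]]) {
          ck <- cost[k, ] + (states != states[s])
          fk <- ft[k, ] + (states[s] == from & states == to)
          best <- min(ck)
          tot <- tot + best
          trans <- trans + min(fk[ck == best])
        }
        cost[v, s] <- tot; ft[v, s] <- trans
      }
    }
  }
  r <- root_node(species)
  rc <- cost[r, ]; rf <- ft[r, ]
  if (!is.null(root_state)) {
    rc[states != root_state] <- INF
  }
  best <- min(rc)
  list(n_changes = unname(best), n_transition = unname(min(rf[rc == best])))
}
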