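# Gene-family birth-death simulator with ground truth. Copies duplicate
# (rate dup_rate) and die (rate loss_rate) along the branches of a fixed
# species tree; surviving copies become gene-tree leaves. Every event is
# recorded so inference stages can be scored against the truth.

#' Simulate a gene family along a species tree
#'
#' A birth-death copy process runs along each species branch (unit branch
#' lengths are assumed where the cladogram has none): a duplication splits a
#' gene lineage in two, a loss kills it; at each species-tree node every
#' surviving lineage enters all child branches (speciation). Surviving copies
#' become leaves named `Genus|sim|k`. Internal nodes of the returned tree
#' carry full support (1.0, probability scale); use [distort_tree()] to
#' emulate poorly supported consensus trees.
#'
#' @param species rooted species `phylo`.
#' @param dup_rate,loss_rate per-copy event rates per unit branch length.
#' @param seed optional integer seed; recorded in the truth.
#' @return list with `tree` (a `phylo`, or `NULL` if fewer than 2 copies
#'   survive), `truth`: list with `events` tibble (`event`, `branch` =
#'   species-node label of the branch it happened on, `time` from the top of
#'   that branch), `copy_counts` tibble per genus, `n_duplications`,
#'   `n_losses`, `terminal_duplications` tibble per genus, and `seed`.
#' @export
simulate_gene_tree <- function(species, dup_rate = 0.1, loss_rate = 0.05,
                               seed = NULL) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species$edge.length)) species$edge.length <- rep(1, nrow(species$edge))
  n_tip <- ape::Ntip(species)
  kids <- node_children(species)
  elen <- rep(NA_real_, n_tip + species$Nnode)
  elen[species$edge[, 2]] <- species$edge.length
  slab <- species_node_labels(species)
  ev <- new.env()
  ev$rows <- list()
  ev$leaf_n <- stats::setNames(integer(n_tip), species$tip.label)
  note <- function(event, branch, time) {
    is_term <- branch <= n_tip
    ev$rows[[length(ev$rows) + 1]] <- tibble::tibble(
      event = event, branch = slab[branch], terminal = is_term, time = time)
  }
  total <- dup_rate + loss_rate
  # one lineage evolving down the branch above species node `v`, entering at
  # `t_in` from the branch top; returns a newick fragment or NULL (extinct)
  evolve <- function(v, t_in) {
    t <- t_in
    repeat {
      wait <- if (total > 0) stats::rexp(1, total) else Inf
      if (t + wait >= elen[v] || is.na(elen[v])) break
      t <- t + wait
      if (stats::runif(1) < dup_rate / total) {
        note("duplication", v, t)
        a <- evolve(v, t)
        b <- evolve(v, t)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(paste0("(", a, ",", b, ")1.0"))
      } else {
        note("loss", v, t)
        return(NULL)
      }
    }
    arrive(v)
  }
  # a lineage reaching the bottom of the branch above `v`
  arrive <- function(v) {
    if (v <= n_tip) {
      g <- species$tip.label[v]
      ev$leaf_n[[g]] <- ev$leaf_n[[g]] + 1L
      return(paste0(g, "|sim|", ev$leaf_n[[g]]))
    }
    parts <- purrr::compact(lapply(kids[[v]], function(k) evolve(k, 0)))
    if (!length(parts)) return(NULL)
    if (length(parts) == 1) return(parts[[1]])
    paste0("(", paste(unlist(parts), collapse = ","), ")1.0")
  }
  frag <- arrive(root_node(species))
  events <- if (length(ev$rows)) dplyr::bind_rows(ev$rows) else
    tibble::tibble(event = character(), branch = character(),
                   terminal = logical(), time = numeric())
  term_dups <- events |>
    dplyr::filter(.data$event == "duplication", .data$terminal) |>
    dplyr::count(genus = .data$branch, name = "n_duplications")
  truth <- list(
    events = events,
    copy_counts = tibble::tibble(genus = species$tip.label,
                                 n = unname(ev$leaf_n)),
    n_duplications = sum(events$event == "duplication"),
    n_losses = sum(events$event == "loss"),
    terminal_duplications = term_dups,
    seed = seed)
  n_leaves <- sum(ev$leaf_n)
  tree <- if (!is.null(frag) && n_leaves >= 2) {
    set_support_scale(ape::read.tree(text = paste0(frag, ";")), "probability")
  } else NULL
  list(tree = tree, truth = truth)
}

#' Degrade internal-edge supports (and optionally topology)
#'
#' Assigns a fraction `support_noise` of internal (non-root) edges supports
#' below the collapse threshold (uniform on `[0.3, 0.65]` at probability
#' scale) so that [collapse_low_support()] produces soft polytomies; remaining
#' edges get high supports (`[0.9, 1]`). With `nni = TRUE` each low-support
#' edge is additionally perturbed by one random nearest-neighbour interchange,
#' leaving well-supported bipartitions intact.
#'
#' @param tree a `phylo` (probability-scale supports).
#' @param support_noise fraction in `[0, 1]` of internal edges degraded.
#' @param nni perturb topology on the degraded edges.
#' @param seed optional seed.
#' @return the distorted `phylo`.
#' @export
distort_tree <- function(tree, support_noise = 0, nni = FALSE, seed = NULL) {
  stopifnot(support_noise >= 0, support_noise <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  internal <- seq(n_tip + 1L, n_tip + tree$Nnode)
  internal <- internal[internal != root_node(tree)]  # root split has no edge
  n_low <- round(support_noise * length(internal))
  low <- sort(internal[sample.int(length(internal), n_low)])
  if (nni && n_low > 0) {
    for (v in low) tree <- nni_at(tree, v)
  }
  lab <- rep(NA_character_, tree$Nnode)
  keep_high <- setdiff(internal, low)
  lab[keep_high - n_tip] <- format(stats::runif(length(keep_high), 0.9, 1), digits = 3)
  lab[low - n_tip] <- format(stats::runif(n_low, 0.3, 0.65), digits = 3)
  tree$node.label <- lab
  set_support_scale(tree, "probability")
}

# one random nearest-neighbour interchange across the edge above node v:
# swap one child subtree of v with v's sibling subtree
nni_at <- function(tree, v) {
  kids <- node_children(tree)
  par <- node_parent(tree)
  p <- par[v]
  if (is.na(p)) return(tree)
  sib <- setdiff(kids[[p]], v)
  if (!length(sib) || length(kids[[v]]) < 2) return(tree)
  sib <- sib[1]
  child <- sample(kids[[v]], 1)
  # re-emit newick with the two subtrees swapped
  n_tip <- ape::Ntip(tree)
  rec <- function(u) {
    u_eff <- if (u == child) sib else if (u == sib) child else u
    if (u_eff <= n_tip) return(tree$tip.label[u_eff])
    paste0("(", paste(vapply(kids[[u_eff]], rec, character(1)), collapse = ","), ")")
  }
  out <- ape::read.tree(text = paste0(rec(root_node(tree)), ";"))
  set_support_scale(out, support_scale(tree))
}

#' Simulate a protein alignment with optional compositional bias
#'
#' Sites are i.i.d.: a root sequence is drawn uniformly over the 20 amino
#' acids and each taxon independently resamples each site with probability
#' `subst_prob` from its own target composition (a star process — sufficient
#' for compositional-screen test beds; phylogenetic realism is a non-goal).
#' Taxa in `biased_taxa` (matched by leaf label or genus) draw substitutions
#' from a mixture placing weight `bias_strength` on a small preferred-state
#' subset, emulating the lineage-specific compositional bias that the RCFV
#' screen exists to catch.
#'
#' @param tree a `phylo` (supplies the taxon set) or character vector of taxa.
#' @param m number of columns.
#' @param biased_taxa character vector of taxa or genera to bias.
#' @param bias_strength mixture weight in `[0, 1]` on the preferred subset.
#' @param subst_prob per-site substitution probability.
#' @param preferred the preferred-state subset for biased taxa.
#' @param seed optional seed.
#' @return an `aa_alignment`.
#' @export
simulate_alignment <- function(tree, m = 500, biased_taxa = character(),
                               bias_strength = 0.8, subst_prob = 0.5,
                               preferred = c("K", "E", "Q", "P"), seed = NULL) {
  stopifnot(m >= 1, bias_strength >= 0, bias_strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  taxa <- if (inherits(tree, "phylo")) tree$tip.label else tree
  root <- sample(AA_LETTERS, m, replace = TRUE)
  pref_w <- rep(bias_strength / length(preferred), length(preferred))
  base_w <- rep(1 / 20, 20)
  biased_w <- (1 - bias_strength) * base_w +
    bias_strength * (AA_LETTERS %in% preferred) / length(preferred)
  rows <- vapply(taxa, function(tx) {
    biased <- tx %in% biased_taxa || leaf_genus(tx) %in% biased_taxa
    w <- if (biased) biased_w else base_w
    s <- root
    hit <- stats::runif(m) < subst_prob
    s[hit] <- sample(AA_LETTERS, sum(hit), replace = TRUE, prob = w)
    paste(s, collapse = "")
  }, character(1))
  make_alignment(rows)
}

#' Construct a hit table exercising every screening decision path
#'
#' Builds a BLAST-tabular-shaped tibble: every query receives a strong
#' in-family hit; queries in `decoy_best` additionally receive a stronger
#' out-of-family hit (so the best-hit rule rejects them); queries in
#' `boundary` get their in-family e-value exactly at `e_primary` (probing the
#' `<=` contract); queries in `no_hit` receive no rows at all.
#'
#' @param seq_ids query ids.
#' @param family target family label (subjects annotated with it).
#' @param decoy_best,boundary,no_hit subsets of `seq_ids`.
#' @param e_primary the threshold the boundary probes sit on.
#' @return hit tibble with `subject_family` filled.
#' @export
make_hit_table <- function(seq_ids, family, decoy_best = character(),
                           boundary = character(), no_hit = character(),
                           e_primary = 1e-10) {
  rows <- purrr::map_dfr(setdiff(seq_ids, no_hit), function(id) {
    e_in <- if (id %in% boundary) e_primary else 1e-30
    out <- tibble::tibble(
      qseqid = id, sseqid = paste0(family, "_ref1"), pident = 85,
      length = 150, mismatch = 20, gapopen = 1, qstart = 1, qend = 150,
      sstart = 1, send = 150, evalue = e_in, bitscore = 200,
      subject_family = family)
    if (id %in% decoy_best) {
      out <- dplyr::bind_rows(tibble::tibble(
        qseqid = id, sseqid = "OTHERFAM_ref1", pident = 90,
        length = 150, mismatch = 12, gapopen = 0, qstart = 1, qend = 150,
        sstart = 1, send = 150, evalue = 1e-40, bitscore = 300,
        subject_family = "OTHERFAM"), out)
    }
    out
  })
  rows
}
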