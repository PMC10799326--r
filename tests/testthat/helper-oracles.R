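# Independent oracles used to check the implementation on small instances.
# They deliberately use different algorithms from the package code paths.

# Minimum duplication+loss cost (and minimum duplication count) over ALL valid
# reconciliation maps of a binary rooted gene tree, by dynamic programming
# over every (gene node, species node) pair. Independent of the LCA-mapping
# shortcut used by lca_reconcile().
oracle_reconcile <- function(gene, species) {
  idx <- famhist:::tree_index(species)
  n_tip <- ape::Ntip(gene)
  kids <- famhist:::node_children(gene)
  genera <- leaf_genus(gene$tip.label)
  ns <- ape::Ntip(species) + species$Nnode
  leafmap <- match(genera, species$tip.label)
  INF <- 1e9
  n_node <- n_tip + gene$Nnode
  costC <- matrix(INF, n_node, ns)   # min dup + loss
  costD <- matrix(INF, n_node, ns)   # min dup
  anc_of <- function(s, t) s %in% idx$ancestors[[t]]
  for (v in famhist:::postorder_nodes(gene)) {
    if (v <= n_tip) {
      costC[v, leafmap[v]] <- 0
      costD[v, leafmap[v]] <- 0
      next
    }
    ch <- kids[[v]]
    stopifnot(length(ch) == 2)
    a <- ch[1]; b <- ch[2]
    sa_opts <- which(costC[a, ] < INF)
    sb_opts <- which(costC[b, ] < INF)
    for (s in seq_len(ns)) {
      for (sa in sa_opts) {
        if (!anc_of(s, sa)) next
        for (sb in sb_opts) {
          if (!anc_of(s, sb)) next
          l <- famhist:::lca_pair(idx, sa, sb)
          dup <- (s == sa) || (s == sb) || (s != l)
          loss <- (idx$depth[sa] - idx$depth[s]) + (idx$depth[sb] - idx$depth[s]) -
            2 + 2 * dup
          cc <- costC[a, sa] + costC[b, sb] + dup + loss
          dd <- costD[a, sa] + costD[b, sb] + dup
          if (cc < costC[v, s]) costC[v, s] <- cc
          if (dd < costD[v, s]) costD[v, s] <- dd
        }
      }
    }
  }
  r <- famhist:::root_node(gene)
  list(min_total = min(costC[r, ]), min_dups = min(costD[r, ]))
}

# brute-force Fitch: enumerate every assignment of states to internal nodes
oracle_parsimony <- function(species, tip_states, root_state = NULL) {
  states <- sort(unique(c(unname(tip_states), root_state)))
  n_tip <- ape::Ntip(species)
  n_int <- species$Nnode
  par <- famhist:::node_parent(species)
  assign_state <- function(v, asg) {
    if (v <= n_tip) tip_states[[species$tip.label[v]]] else asg[v - n_tip]
  }
  grid <- do.call(expand.grid, c(rep(list(states), n_int),
                                 stringsAsFactors = FALSE))
  best <- Inf
  root <- famhist:::root_node(species)
  for (i in seq_len(nrow(grid))) {
    asg <- unlist(grid[i, ], use.names = FALSE)
    if (!is.null(root_state) && asg[root - n_tip] != root_state) next
    changes <- 0
    for (v in seq_len(n_tip + n_int)) {
      p <- par[v]
      if (is.na(p)) next
      if (assign_state(v, asg) != assign_state(p, asg)) changes <- changes + 1
    }
    best <- min(best, changes)
  }
  best
}

# brute-force longest phrase: try every window against the validity predicate
oracle_phrase <- function(entries) {
  x <- vapply(entries, function(e) identical(e, "X"), logical(1))
  m <- length(x)
  if (all(x)) return(c(1L, 1L))
  valid <- function(a, b) {
    if (a > 1 && x[a] && x[a - 1]) return(FALSE)
    if (b < m && x[b] && x[b + 1]) return(FALSE)
    if (b > a && any(x[a:(b - 1)] & x[(a + 1):b])) return(FALSE)
    TRUE
  }
  best <- c(1L, 0L)
  for (a in seq_len(m)) {
    for (b in a:m) {
      if (valid(a, b) && (b - a) > (best[2] - best[1])) best <- c(a, b)
    }
  }
  best
}

# random rooted binary gene tree whose leaves carry genera of `species`
random_gene_tree <- function(species, n_leaves) {
  tr <- ape::rtree(n_leaves)
  genera <- sample(species$tip.label, n_leaves, replace = TRUE)
  tr$tip.label <- paste0(genera, "|sim|", seq_len(n_leaves))
  tr$node.label <- NULL
  tr
}

random_species_tree <- function(n_genera) {
  tr <- ape::rtree(n_genera)
  tr$tip.label <- paste0("G", seq_len(n_genera))
  tr$node.label <- NULL
  tr
}

# random consensus entries mixing fixed residues, alternative sets and X
random_consensus <- function(m, p_x = 0.3, p_alt = 0.15) {
  entries <- lapply(seq_len(m), function(i) {
    u <- stats::runif(1)
    if (u < p_x) "X"
    else if (u < p_x + p_alt) sample(LETTERS[1:20], sample(2:4, 1))
    else sample(LETTERS[1:20], 1)
  })
  structure(list(entries = entries, m = m), class = "consensus_seq")
}
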