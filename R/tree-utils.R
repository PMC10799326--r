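# Internal helpers shared by the tree-facing modules. Gene trees are ape
# `phylo` objects; internal-node supports live in `node.label` (IQ-TREE /
# PhyloBayes convention) and the support scale in attr "support_scale".

#' Extract the genus from sequence/leaf identifiers
#'
#' Leaf names follow the pipe-delimited `"Genus|sample|localid"` convention; a
#' label without pipes is treated as a bare genus name. The analysis works at
#' the genus level throughout, so this is the single place the convention is
#' interpreted.
#'
#' @param x character vector of leaf labels or seq_ids.
#' @return character vector of genus names.
#' @export
#' @examples
#' leaf_genus(c("Hypsibius|s1|CAHS2a", "Milnesium"))
leaf_genus <- function(x) {
  stopifnot(is.character(x))
  vapply(strsplit(x, "|", fixed = TRUE), `[[`, character(1), 1L)
}

#' Split pipe-delimited sequence identifiers into metadata columns
#'
#' @param x character vector of `"Genus|sample|localid"` identifiers.
#' @return tibble with columns `seq_id`, `genus`, `sample_id`, `local_id`
#'   (`sample_id`/`local_id` are `NA` when the label has no pipes).
#' @export
parse_seq_id <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  tibble::tibble(
    seq_id = x,
    genus = vapply(parts, `[[`, character(1), 1L),
    sample_id = vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, character(1)),
    local_id = vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, character(1))
  )
}

# numeric supports aligned with internal node numbering (n_tip + 1 .. n_tip +
# Nnode); "" and NA labels mean "support absent", never low.
node_support <- function(phy) {
  n_int <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) return(rep(NA_real_, n_int))
  lab[lab == ""] <- NA_character_
  suppressWarnings(as.numeric(lab))
}

support_scale <- function(phy) {
  sc <- attr(phy, "support_scale")
  if (is.null(sc)) NA_character_ else sc
}

set_support_scale <- function(phy, scale) {
  attr(phy, "support_scale") <- scale
  phy
}

# children list indexed by node id (tips 1..n, internals n+1..n+Nnode)
node_children <- function(phy) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  kids
}

node_parent <- function(phy) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  par <- rep(NA_integer_, n_node)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

root_node <- function(phy) ape::Ntip(phy) + 1L

# postorder sequence of node ids (children before parents)
postorder_nodes <- function(phy) {
  ord <- ape::reorder.phylo(phy, "postorder")
  unique(c(ord$edge[, 2], root_node(phy)))
}

# tip ids (indices into phy$tip.label) descending from each node
descendant_tips <- function(phy) {
  n_tip <- ape::Ntip(phy)
  kids <- node_children(phy)
  desc <- vector("list", n_tip + phy$Nnode)
  for (v in postorder_nodes(phy)) {
    if (v <= n_tip) desc[[v]] <- v
    else desc[[v]] <- unlist(lapply(kids[[v]], function(k) desc[[k]]))
  }
  desc
}

# Serialize a rooted phylo to newick with node supports as internal labels.
# Used where edge contraction / refinement makes renumbering awkward: we emit
# and re-read rather than patching ape's edge matrix in place.
phylo_to_newick <- function(phy, digits = 10) {
  n_tip <- ape::Ntip(phy)
  kids <- node_children(phy)
  lab <- phy$node.label
  has_len <- !is.null(phy$edge.length)
  elen <- rep(NA_real_, n_tip + phy$Nnode)
  if (has_len) elen[phy$edge[, 2]] <- phy$edge.length
  rec <- function(v) {
    if (v <= n_tip) {
      s <- phy$tip.label[v]
    } else {
      s <- paste0("(", paste(vapply(kids[[v]], rec, character(1)), collapse = ","), ")")
      if (!is.null(lab)) {
        l <- lab[v - n_tip]
        if (!is.na(l) && nzchar(l)) s <- paste0(s, l)
      }
    }
    if (has_len && !is.na(elen[v])) s <- paste0(s, ":", format(elen[v], digits = digits))
    s
  }
  paste0(rec(root_node(phy)), ";")
}

# lowest common ancestor machinery on a rooted species tree ------------------

# ancestor sets (self included) and depths, indexed by node id
tree_index <- function(phy) {
  par <- node_parent(phy)
  n_node <- ape::Ntip(phy) + phy$Nnode
  depth <- rep(NA_integer_, n_node)
  anc <- vector("list", n_node)
  # breadth-first from root
  r <- root_node(phy)
  depth[r] <- 0L
  anc[[r]] <- r
  queue <- r
  kids <- node_children(phy)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (k in kids[[v]]) {
      depth[k] <- depth[v] + 1L
      anc[[k]] <- c(k, anc[[v]])
      queue <- c(queue, k)
    }
  }
  list(parent = par, depth = depth, ancestors = anc, children = kids,
       n_tip = ape::Ntip(phy), root = r)
}

lca_pair <- function(idx, a, b) {
  if (a == b) return(a)
  aa <- idx$ancestors[[a]]
  bb <- idx$ancestors[[b]]
  common <- intersect(aa, bb)
  common[which.max(idx$depth[common])]
}

lca_many <- function(idx, nodes) {
  Reduce(function(a, b) lca_pair(idx, a, b), nodes)
}

is_ancestor_or_equal <- function(idx, anc, desc) anc %in% idx$ancestors[[desc]]
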