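# Support-aware tree processing: collapse of poorly supported edges to soft
# polytomies, taxonomic (outgroup) rooting, and rooting at the edge that
# minimizes the number of inferred gene duplications.

#' Collapse poorly supported edges to polytomies
#'
#' Every internal edge whose child node's support is strictly below the
#' threshold is contracted and the children promoted to the parent. Nodes with
#' absent support are never collapsed (absence of evidence is not low
#' support); boundary values (support exactly at the threshold) survive.
#' Thresholds default to the conventional 0.7 posterior probability / 70
#' ultrafast bootstrap.
#'
#' @param phy a `phylo` from [read_gene_tree()] with a known support scale.
#' @param threshold collapse threshold; default 0.7 or 70 by scale.
#' @return the collapsed `phylo` (same leaf set, supports of surviving nodes
#'   unchanged).
#' @export
collapse_low_support <- function(phy, threshold = NULL) {
  scale <- support_scale(phy)
  sup <- node_support(phy)
  if (is.null(threshold)) {
    if (is.na(scale)) {
      if (all(is.na(sup))) return(phy)  # nothing to judge, nothing to collapse
      stop("support scale unknown; read the tree with declared_scale or pass threshold")
    }
    threshold <- if (scale == "probability") 0.7 else 70
  }
  n_tip <- ape::Ntip(phy)
  root <- root_node(phy)
  low <- which(!is.na(sup) & sup < threshold) + n_tip
  low <- setdiff(low, root)
  if (!length(low)) return(phy)
  kids <- node_children(phy)
  lab <- phy$node.label
  drop <- rep(FALSE, n_tip + phy$Nnode)
  drop[low] <- TRUE
  # frag(v): newick fragments contributed by v to its parent — a single
  # subtree when v is kept, v's (recursively expanded) children when dropped
  frag <- function(v) {
    if (v <= n_tip) return(phy$tip.label[v])
    parts <- unlist(lapply(kids[[v]], frag))
    if (drop[v]) return(parts)
    l <- if (!is.null(lab)) lab[v - n_tip] else ""
    if (is.na(l)) l <- ""
    paste0("(", paste(parts, collapse = ","), ")", l)
  }
  txt <- paste0(frag(root), ";")
  out <- ape::read.tree(text = txt)
  set_support_scale(out, scale)
}

#' Root an unrooted gene tree on the edge separating a monophyletic outgroup
#'
#' @param phy unrooted `phylo`.
#' @param outgroup character vector of leaf labels.
#' @return rooted `phylo`, supports preserved (treated as edge labels while
#'   rerooting, so they stay attached to the same bipartition).
#' @export
root_by_outgroup <- function(phy, outgroup) {
  miss <- setdiff(outgroup, phy$tip.label)
  if (length(miss)) stop("outgroup leaves not in tree: ", paste(miss, collapse = ", "))
  if (length(outgroup) >= ape::Ntip(phy)) stop("outgroup cannot cover all leaves")
  scale <- support_scale(phy)
  if (!unrooted_monophyletic(phy, outgroup)) {
    stop("outgroup is not monophyletic: no edge separates {",
         paste(outgroup, collapse = ","), "} from {",
         paste(setdiff(phy$tip.label, outgroup), collapse = ","), "}")
  }
  out <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
  set_support_scale(out, scale)
}

# does the leaf set form one side of a bipartition of the unrooted tree?
unrooted_monophyletic <- function(phy, leaves) {
  other <- setdiff(phy$tip.label, leaves)
  anchor <- other[1]
  ref <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
  tips <- match(leaves, ref$tip.label)
  if (length(tips) == 1) return(TRUE)
  mrca <- ape::getMRCA(ref, tips)
  desc <- descendant_tips(ref)[[mrca]]
  setequal(desc, tips)
}

#' Root a gene tree to minimize the number of inferred duplications
#'
#' Used for families with no usable outgroup: every edge of the unrooted tree
#' is tried as the root position, the duplication count under LCA
#' reconciliation with the genus-level species tree is computed for each
#' rooting, and all rootings achieving the minimum are returned (ties are
#' never silently broken).
#'
#' @param phy unrooted (or rooted; it is unrooted first) `phylo`; leaf genera
#'   must appear in `species`.
#' @param species rooted genus-level species `phylo`.
#' @return list with `count` (the minimum duplication count) and `trees`
#'   (list of rooted `phylo`, one per optimal edge).
#' @export
root_min_duplications <- function(phy, species) {
  genera <- unique(leaf_genus(phy$tip.label))
  if (!length(intersect(genera, species$tip.label))) {
    stop("no leaf genus of the gene tree occurs in the species tree")
  }
  scale <- support_scale(phy)
  un <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  if (is.null(un$edge.length)) un$edge.length <- rep(1, nrow(un$edge))
  rootings <- all_rootings(un)
  counts <- vapply(rootings, function(r) {
    lca_reconcile(r, species)$n_duplications
  }, numeric(1))
  best <- min(counts)
  trees <- lapply(rootings[counts == best], set_support_scale, scale = scale)
  list(count = best, trees = trees)
}

# one rooted tree per edge of the unrooted tree (root bisects the edge)
all_rootings <- function(un) {
  lapply(seq_len(nrow(un$edge)), function(i) {
    child <- un$edge[i, 2]
    r <- phytools::reroot(un, child, position = un$edge.length[i] / 2)
    ape::collapse.singles(r)
  })
}
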