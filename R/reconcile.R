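# Duplication-loss inference by LCA (last-common-ancestor) reconciliation of
# a rooted gene tree against the genus-level species tree, with soft
# polytomies (from support collapse) resolved to the duplication-minimizing
# binary refinement. The genus-exclusive independent-duplication rule is the
# clade-counting procedure used throughout the analysis.

#' Human-readable label for a species-tree node
#'
#' Tips are the genus name; internal nodes are the sorted descendant genera
#' joined with `+`.
#' @param species rooted species `phylo`.
#' @return character vector indexed by node id.
#' @export
species_node_labels <- function(species) {
  desc <- descendant_tips(species)
  vapply(seq_along(desc), function(v) {
    paste(sort(species$tip.label[desc[[v]]]), collapse = "+")
  }, character(1))
}

#' LCA reconciliation of a gene tree with the species tree
#'
#' Each gene-tree node is mapped to the last common ancestor (in the species
#' tree) of its descendant genera. A binary gene node is a duplication iff its
#' mapping equals the mapping of at least one child; every other internal node
#' is a speciation. Losses are counted per gene-tree edge as
#' `dist(M(parent), M(child)) - 1 + [parent is duplication]` and placed on the
#' species branch where the unobserved lineage disappeared. Soft polytomies
#' are resolved to the binary refinement minimizing duplications (then
#' losses): exact search over all rooted binary arrangements for polytomy
#' degree <= 6, a greedy deepest-speciation-first pairing (with a warning)
#' above that.
#'
#' @param gene rooted `phylo`; leaf genera (see [leaf_genus()]) must occur in
#'   `species`.
#' @param species rooted genus-level species `phylo`.
#' @param max_exact largest polytomy degree resolved by exact search.
#' @return a `reconciliation`: list with `mapping` (tibble gene node ->
#'   species node), `duplications` (tibble with `species_node`, `kind`
#'   independent/shared, `genus` for independent events), `losses` (tibble
#'   with `species_node`, `n`), `n_duplications`, `n_losses`, and the
#'   (possibly refined) binary `gene` tree used.
#' @export
lca_reconcile <- function(gene, species, max_exact = 6) {
  # the tree is interpreted as rooted at its root node; a multifurcating root
  # (e.g. after support collapse) is a soft polytomy, not an unrooted tree
  idx <- tree_index(species)
  genera <- leaf_genus(gene$tip.label)
  miss <- setdiff(unique(genera), species$tip.label)
  if (length(miss)) stop("gene-tree genera absent from species tree: ",
                         paste(miss, collapse = ", "))
  leafmap <- match(genera, species$tip.label)
  names(leafmap) <- gene$tip.label
  gene_bin <- refine_polytomies(gene, idx, leafmap, max_exact = max_exact)
  reconcile_binary(gene_bin, species, idx)
}

# plain reconciliation of a fully binary rooted gene tree
reconcile_binary <- function(gene, species, idx = tree_index(species)) {
  n_tip <- ape::Ntip(gene)
  kids <- node_children(gene)
  genera <- leaf_genus(gene$tip.label)
  M <- integer(n_tip + gene$Nnode)
  M[seq_len(n_tip)] <- match(genera, species$tip.label)
  for (v in postorder_nodes(gene)) {
    if (v > n_tip) M[v] <- lca_many(idx, M[kids[[v]]])
  }
  slab <- species_node_labels(species)
  dup_rows <- list(); loss_nodes <- integer()
  spar <- idx$parent
  for (v in (n_tip + 1):(n_tip + gene$Nnode)) {
    ch <- kids[[v]]
    is_dup <- any(M[ch] == M[v])
    if (is_dup) {
      s <- M[v]
      dup_rows[[length(dup_rows) + 1]] <- tibble::tibble(
        gene_node = v, species_node = slab[s],
        kind = if (s <= idx$n_tip) "independent" else "shared",
        genus = if (s <= idx$n_tip) species$tip.label[s] else NA_character_)
    }
    for (c in ch) {
      # path M[v] -> M[c]; lost lineages sit on the sibling branches
      path <- rev(idx$ancestors[[M[c]]])          # root .. M[c]
      path <- path[idx$depth[path] >= idx$depth[M[v]]]
      k <- length(path) - 1                        # edge count M[v] -> M[c]
      from <- if (is_dup) 1 else 2                 # dup: split at M[v] too
      for (i in seq(from, length.out = k - from + 1)) {
        s_i <- path[i]
        lost <- setdiff(idx$children[[s_i]], path[i + 1])
        # the lineage vanished in the sibling subtree; attribute the loss to
        # its root (unique in a binary species tree)
        loss_nodes <- c(loss_nodes, lost[1])
      }
    }
  }
  dups <- if (length(dup_rows)) dplyr::bind_rows(dup_rows) else
    tibble::tibble(gene_node = integer(), species_node = character(),
                   kind = character(), genus = character())
  losses <- if (length(loss_nodes)) {
    tibble::as_tibble(table(species_node = slab[loss_nodes])) |>
      dplyr::mutate(n = as.integer(.data$n))
  } else tibble::tibble(species_node = character(), n = integer())
  structure(list(
    mapping = tibble::tibble(
      gene_node = seq_len(n_tip + gene$Nnode),
      gene_label = c(gene$tip.label, rep(NA_character_, gene$Nnode)),
      species_node = slab[M]),
    duplications = dups, losses = losses,
    n_duplications = nrow(dups), n_losses = length(loss_nodes),
    gene = gene, species = species), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation> ", x$n_duplications, " duplications (",
      sum(x$duplications$kind == "shared"), " shared), ",
      x$n_losses, " losses\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.reconciliation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$duplications, event = "duplication", n = 1L) |>
      dplyr::select("event", "species_node", "kind", "genus", "n"),
    dplyr::mutate(x$losses, event = "loss", kind = NA_character_,
                  genus = NA_character_) |>
      dplyr::select("event", "species_node", "kind", "genus", "n"))
}

#' @exportS3Method
glance.reconciliation <- function(x, ...) {
  tibble::tibble(n_duplications = x$n_duplications,
                 n_shared = sum(x$duplications$kind == "shared"),
                 n_independent = sum(x$duplications$kind == "independent"),
                 n_losses = x$n_losses)
}

# --- polytomy refinement ----------------------------------------------------

refine_polytomies <- function(gene, idx, leafmap, max_exact = 6) {
  kids <- node_children(gene)
  n_tip <- ape::Ntip(gene)
  if (all(lengths(kids[(n_tip + 1):(n_tip + gene$Nnode)]) <= 2)) return(gene)
  rec <- function(v) {
    if (v <= n_tip) {
      return(list(frag = gene$tip.label[v], map = unname(leafmap[gene$tip.label[v]])))
    }
    items <- lapply(kids[[v]], rec)
    if (length(items) == 1) return(items[[1]])
    if (length(items) == 2) {
      return(list(
        frag = paste0("(", items[[1]]$frag, ",", items[[2]]$frag, ")"),
        map = lca_pair(idx, items[[1]]$map, items[[2]]$map)))
    }
    if (length(items) <= max_exact) resolve_exact(items, idx)
    else resolve_greedy(items, idx)
  }
  top <- rec(root_node(gene))
  out <- ape::read.tree(text = paste0(top$frag, ";"))
  set_support_scale(out, support_scale(gene))
}

# join cost of combining two mapped subtrees under one binary node
join_eval <- function(idx, a, b) {
  s <- lca_pair(idx, a, b)
  dup <- (s == a) || (s == b)
  loss <- (idx$depth[a] - idx$depth[s]) + (idx$depth[b] - idx$depth[s]) -
    2 + 2 * dup
  list(map = s, dup = as.integer(dup), loss = loss)
}

# exact search: all rooted binary arrangements of the items, scored by
# (duplications, losses) added inside the refinement; first optimum kept
resolve_exact <- function(items, idx) {
  k <- length(items)
  shapes <- binary_shapes(k)
  best <- NULL
  for (sh in shapes) {
    sc <- score_shape(sh, items, idx)
    if (is.null(best) || sc$dup < best$dup ||
        (sc$dup == best$dup && sc$loss < best$loss)) best <- sc
  }
  best
}

# rooted binary tree shapes over k labelled items, as nested index pairs
binary_shapes <- function(k) {
  grow <- function(shape, leaf) {
    # insert `leaf` on every edge (including above the root)
    out <- list(list(shape, leaf))
    if (is.list(shape)) {
      for (side in 1:2) {
        for (sub in grow(shape[[side]], leaf)) {
          new <- shape
          new[[side]] <- sub
          out <- c(out, list(new))
        }
      }
    }
    out
  }
  shapes <- list(1L)
  for (leaf in seq_len(k)[-1]) {
    shapes <- unlist(lapply(shapes, grow, leaf = leaf), recursive = FALSE)
  }
  shapes
}

score_shape <- function(shape, items, idx) {
  if (!is.list(shape)) {
    it <- items[[shape]]
    return(list(frag = it$frag, map = it$map, dup = 0L, loss = 0L))
  }
  a <- score_shape(shape[[1]], items, idx)
  b <- score_shape(shape[[2]], items, idx)
  j <- join_eval(idx, a$map, b$map)
  list(frag = paste0("(", a$frag, ",", b$frag, ")"), map = j$map,
       dup = a$dup + b$dup + j$dup, loss = a$loss + b$loss + j$loss)
}

# greedy pairing for large polytomies: repeatedly join the pair whose joint
# mapping avoids a duplication if possible and is deepest in the species tree
resolve_greedy <- function(items, idx) {
  warning("polytomy of degree ", length(items),
          " resolved greedily (exact search limited to smaller degrees)")
  dup <- 0L; loss <- 0L
  while (length(items) > 1) {
    best <- NULL
    for (i in seq_along(items)[-length(items)]) {
      for (j in seq((i + 1), length(items))) {
        ev <- join_eval(idx, items[[i]]$map, items[[j]]$map)
        key <- c(ev$dup, -idx$depth[ev$map], ev$loss)
        if (is.null(best) || best$key[1] > key[1] ||
            (best$key[1] == key[1] && (best$key[2] > key[2] ||
             (best$key[2] == key[2] && best$key[3] > key[3])))) {
          best <- list(i = i, j = j, ev = ev, key = key)
        }
      }
    }
    a <- items[[best$i]]; b <- items[[best$j]]
    joined <- list(frag = paste0("(", a$frag, ",", b$frag, ")"),
                   map = best$ev$map)
    dup <- dup + best$ev$dup; loss <- loss + best$ev$loss
    items <- c(items[-c(best$i, best$j)], list(joined))
  }
  c(items[[1]], list(dup = dup, loss = loss))
}

# --- genus-exclusive independent duplications -------------------------------

#' Independent duplications from genus-exclusive clades
#'
#' Finds the maximal clades whose leaves all belong to one genus; a clade of
#' `n >= 2` leaves evidences `n - 1` independent duplications attributed to
#' that genus (singleton leaves contribute none).
#'
#' @param gene rooted `phylo` (post low-coverage merge).
#' @return tibble with one row per maximal genus-exclusive clade: `genus`,
#'   `node` (gene-tree node id), `n_leaves`, `n_duplications`, and the member
#'   leaf labels in a list column `members`.
#' @export
genus_exclusive_duplications <- function(gene) {
  n_tip <- ape::Ntip(gene)
  genera <- leaf_genus(gene$tip.label)
  kids <- node_children(gene)
  par <- node_parent(gene)
  # genus of a node if its clade is pure, else NA
  pure <- rep(NA_character_, n_tip + gene$Nnode)
  pure[seq_len(n_tip)] <- genera
  for (v in postorder_nodes(gene)) {
    if (v > n_tip) {
      g <- unique(pure[kids[[v]]])
      if (length(g) == 1 && !is.na(g)) pure[v] <- g
    }
  }
  desc <- descendant_tips(gene)
  # maximal pure clades: pure node whose parent is absent or not pure (a pure
  # parent always shares the genus, so no tie-breaking is needed)
  maximal <- which(!is.na(pure) & vapply(seq_along(pure), function(v) {
    is.na(par[v]) || is.na(pure[par[v]])
  }, logical(1)))
  purrr::map_dfr(maximal, function(v) {
    tips <- desc[[v]]
    tibble::tibble(genus = pure[v], node = v, n_leaves = length(tips),
                   n_duplications = length(tips) - 1L,
                   members = list(gene$tip.label[tips]))
  })
}
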