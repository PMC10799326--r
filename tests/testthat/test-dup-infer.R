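sp13 <- default_species_tree()

test_that("pairwise identity behaves on the documented examples", {
  expect_equal(pairwise_identity("MKVLW", "MKVLW"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  set.seed(51)
  a <- paste(sample(c("A", "C", "D", "E"), 120, TRUE), collapse = "")
  b <- paste(sample(c("K", "R", "W", "Y"), 120, TRUE), collapse = "")
  expect_lt(pairwise_identity(a, b), 0.25)
  expect_error(pairwise_identity("", "AAA"), "empty")
})

test_that("the low-coverage merge honours the coverage guard and linkage", {
  seqs <- synthetic_low_coverage_family(seed = 5)
  expect_length(seqs, 15)
  merged <- merge_low_coverage(seqs, coverage = 30)
  expect_equal(nrow(merged), 7)
  expect_equal(sort(merged$n_members, decreasing = TRUE),
               c(3L, 3L, 2L, 2L, 2L, 2L, 1L))
  # representative is the longest member (ties lexicographic)
  for (i in which(merged$merged)) {
    mem <- merged$members[[i]]
    expect_equal(merged$representative[i], mem[order(-nchar(seqs[mem]), mem)][1])
  }
  # at adequate coverage nothing merges, even for identical sequences
  pair <- c(x = strrep("ACDE", 30), y = strrep("ACDE", 30))
  expect_false(any(merge_low_coverage(pair, coverage = 50)$merged))
  expect_true(any(merge_low_coverage(pair, coverage = 30)$merged))
  expect_error(merge_low_coverage(pair, coverage = NA), "coverage")
})

test_that("genus-exclusive clades convert to independent duplication counts", {
  g <- read_gene_tree(
    text = "(((H|a|1,H|a|2),(H|a|3,R|b|1)),((R|b|2,R|b|3),M|c|1));")
  ex <- genus_exclusive_duplications(g)
  tot <- dplyr::count(ex, genus, wt = n_duplications, name = "n")
  expect_equal(tot$n[tot$genus == "H"], 1)   # only the pure (H,H) cherry
  expect_equal(tot$n[tot$genus == "R"], 1)
  # fully single-copy tree: all zero
  single <- read_gene_tree(text = "((A|x|1,B|x|1),(C|x|1,D|x|1));")
  expect_equal(sum(genus_exclusive_duplications(single)$n_duplications), 0)
})

test_that("clade totals equal exhaustive clade enumeration on small trees", {
  set.seed(61)
  sp <- random_species_tree(4)
  for (i in 1:25) {
    g <- random_gene_tree(sp, sample(4:12, 1))
    ex <- genus_exclusive_duplications(g)
    # enumerate every clade directly
    desc <- famhist:::descendant_tips(g)
    genera <- leaf_genus(g$tip.label)
    n_tip <- ape::Ntip(g)
    pure_sizes <- integer()
    for (v in (n_tip + 1):(n_tip + g$Nnode)) {
      gg <- unique(genera[desc[[v]]])
      if (length(gg) == 1) {
        par <- famhist:::node_parent(g)[v]
        par_pure <- !is.na(par) &&
          length(unique(genera[desc[[par]]])) == 1
        if (!par_pure) pure_sizes <- c(pure_sizes, length(desc[[v]]))
      }
    }
    expect_equal(sum(ex$n_duplications), sum(pmax(pure_sizes - 1, 0)))
  }
})

test_that("LCA reconciliation reproduces the shared-duplication-plus-loss pattern", {
  rec <- lca_reconcile(synthetic_family_tree("mahs"), sp13)
  expect_equal(rec$n_duplications, 1)
  expect_equal(rec$duplications$kind, "shared")
  expect_equal(rec$duplications$species_node, "Acutuncus+Hypsibius")
  expect_equal(rec$n_losses, 1)
  expect_equal(rec$losses$species_node, "Acutuncus")

  # congruent single-copy tree over the full genus set: no events
  clean <- read_gene_tree(
    text = "(Milnesium|a|1,((Hypsibius|b|1,Acutuncus|c|1),Ramazzottius|d|1));")
  sp4 <- ape::keep.tip(sp13, c("Milnesium", "Hypsibius", "Acutuncus",
                               "Ramazzottius"))
  rec0 <- lca_reconcile(clean, sp4)
  expect_equal(rec0$n_duplications, 0)
  expect_equal(rec0$n_losses, 0)
})

test_that("reconciliation equals the mapping-enumeration oracle on random instances", {
  set.seed(71)
  sp <- random_species_tree(5)
  for (i in 1:60) {
    g <- random_gene_tree(sp, sample(4:8, 1))
    rec <- lca_reconcile(g, sp)
    orc <- oracle_reconcile(g, sp)
    expect_equal(rec$n_duplications, orc$min_dups)
    expect_equal(rec$n_duplications + rec$n_losses, orc$min_total)
    # mapping dominance invariant
    par <- famhist:::node_parent(rec$gene)
    idx <- famhist:::tree_index(sp)
    slab <- species_node_labels(sp)
    for (v in seq_along(par)) {
      if (is.na(par[v])) next
      mv <- match(rec$mapping$species_node[v], slab)
      mp <- match(rec$mapping$species_node[par[v]], slab)
      expect_true(famhist:::is_ancestor_or_equal(idx, mp, mv))
    }
  }
})

test_that("soft polytomies resolve to the duplication-minimizing refinement", {
  set.seed(81)
  sp <- random_species_tree(5)
  for (i in 1:15) {
    g <- random_gene_tree(sp, sample(6:9, 1))
    d <- distort_tree(g, support_noise = 0.6)
    poly <- collapse_low_support(d)
    rec_poly <- lca_reconcile(poly, sp)
    rec_bin <- lca_reconcile(g, sp)
    # a refinement of the collapsed tree can never need more duplications
    # than the original binary tree that produced it
    expect_lte(rec_poly$n_duplications, rec_bin$n_duplications)
  }
  # adding one duplicated leaf adds exactly one duplication
  sp3 <- read_gene_tree(text = "((G1,G2),G3);")
  base <- read_gene_tree(text = "((G1|a|1,G2|b|1),G3|c|1);")
  plus <- read_gene_tree(text = "(((G1|a|1,G1|a|2),G2|b|1),G3|c|1);")
  expect_equal(lca_reconcile(plus, sp3)$n_duplications,
               lca_reconcile(base, sp3)$n_duplications + 1)
})

test_that("homolog groups fuse duplications, respect anchors, and track presence", {
  g <- synthetic_family_tree("cahs2")
  hg <- homolog_groups(g, sp13, family = "CAHS")
  expect_equal(nrow(hg$groups), 1)
  expect_equal(hg$groups$n_members, 6)
  expect_setequal(hg$groups$genera[[1]],
                  c("Acutuncus", "Hypsibius", "Ramazzottius"))
  expect_true(all(hg$presence[c("Hypsibius", "Acutuncus", "Ramazzottius"), 1]))
  expect_false(hg$presence["Milnesium", 1])

  anchored <- homolog_groups(g, sp13, family = "CAHS",
                             anchors = c(CAHS2 = "Hypsibius|h1|CAHS2a"))
  expect_equal(anchored$groups$name, "CAHS2")
  expect_error(homolog_groups(g, sp13, anchors = c(Z = "missing|x|1")),
               "not found")

  # two clean orthogroups over three genera
  two <- read_gene_tree(text = paste0(
    "(((Hypsibius|a|g1,Acutuncus|b|g1),Ramazzottius|c|g1),",
    "((Hypsibius|a|g2,Acutuncus|b|g2),Ramazzottius|c|g2));"))
  hg2 <- homolog_groups(two, sp13, family = "HG")
  expect_equal(nrow(hg2$groups), 2)
  expect_equal(hg2$groups$name, c("HG1", "HG2"))
})

test_that("loss calls respect the completeness guard", {
  pres <- matrix(c(TRUE, FALSE, FALSE, TRUE), nrow = 2,
                 dimnames = list(c("Hypsibius", "Dactylobiotus"),
                                 c("G1", "G2")))
  comp <- c(Hypsibius = 0.95, Dactylobiotus = 0.4)
  ev <- infer_losses(pres, comp)
  expect_equal(ev$confidence[ev$genus == "Hypsibius"], "inferred")
  expect_equal(ev$confidence[ev$genus == "Dactylobiotus"],
               "unknown_low_completeness")
  full <- matrix(TRUE, 2, 2, dimnames = dimnames(pres))
  expect_equal(nrow(infer_losses(full, comp)), 0)
})

test_that("copy counts reflect merges and never increase after merging", {
  trees <- list(FAM = synthetic_family_tree("cahs2"))
  cc <- copy_counts(trees)
  expect_equal(cc$FAM[cc$genus == "Hypsibius"], 3L)
  seqs <- c("Hypsibius|h1|CAHS2b" = strrep("ACDE", 40),
            "Hypsibius|h1|CAHS2c" = strrep("ACDE", 40))
  merges <- list(FAM = merge_low_coverage(seqs, coverage = 20))
  cc2 <- copy_counts(trees, merges)
  expect_equal(cc2$FAM[cc2$genus == "Hypsibius"], 2L)
  expect_true(all(cc2$FAM <= cc$FAM[match(cc2$genus, cc$genus)]))
})

test_that("Fitch counts equal brute-force enumeration and handle constraints", {
  # all-same tips need no changes
  sp <- read_gene_tree(text = "((A,B),(C,D));")
  expect_equal(fitch_ancestral(sp, c(A = "x", B = "x", C = "x", D = "x"))$n_changes, 0)
  set.seed(91)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- random_species_tree(n)
    states <- stats::setNames(sample(c("m", "f", "l"), n, TRUE), tr$tip.label)
    f <- fitch_ancestral(tr, states)
    expect_equal(f$n_changes, oracle_parsimony(tr, states))
    # constrained root can only cost at least as much
    f_con <- fitch_ancestral(tr, states, root_state = "m")
    expect_equal(f_con$n_changes, oracle_parsimony(tr, states, root_state = "m"))
    expect_gte(f_con$n_changes, f$n_changes)
    expect_error(fitch_ancestral(tr, states[-1]), "missing tip state")
  }
})

test_that("the habitat cladogram needs two marine-to-limnoterrestrial origins", {
  ct <- count_transitions(sp13, from = "marine", to = "limnoterrestrial",
                          root_state = "marine")
  expect_equal(ct$n_transition, 2)
  expect_gte(ct$n_transition, 2)
})
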