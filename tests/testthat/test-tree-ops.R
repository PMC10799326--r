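test_that("low-support edges collapse to polytomies with a strict boundary", {
  tr <- read_gene_tree(text = "((A,B)0.65,(C,D)0.95);")
  out <- collapse_low_support(tr)
  expect_equal(out$Nnode, 2)              # root + the surviving cherry
  expect_setequal(out$tip.label, tr$tip.label)

  kept <- collapse_low_support(read_gene_tree(text = "((A,B)0.7,(C,D)0.95);"))
  expect_equal(kept$Nnode, 3)             # exactly 0.7 survives ("below" is strict)

  high <- read_gene_tree(text = "((A,B)0.9,(C,D)0.95);")
  expect_equal(write_gene_tree(collapse_low_support(high)),
               write_gene_tree(high))

  # unlabeled nodes are never treated as low support
  absent <- read_gene_tree(text = "((A,B),(C,D)0.95);")
  expect_equal(collapse_low_support(absent, threshold = 0.7)$Nnode, 3)

  # percent scale uses the 70 default
  pct <- read_gene_tree(text = "((A,B)65,(C,D)95);")
  expect_equal(collapse_low_support(pct)$Nnode, 2)
})

test_that("collapse is idempotent, identity at threshold 0, and node-reducing", {
  set.seed(31)
  for (i in 1:15) {
    sim <- simulate_gene_tree(default_species_tree(), dup_rate = 0.1,
                              loss_rate = 0.05)
    if (is.null(sim$tree)) next
    tr <- distort_tree(sim$tree, support_noise = 0.4)
    once <- collapse_low_support(tr)
    twice <- collapse_low_support(once)
    expect_equal(write_gene_tree(once), write_gene_tree(twice))
    expect_setequal(once$tip.label, tr$tip.label)
    expect_lte(once$Nnode, tr$Nnode)
    expect_equal(write_gene_tree(collapse_low_support(tr, threshold = 0)),
                 write_gene_tree(tr))
  }
})

test_that("outgroup rooting places the root on the separating edge", {
  un <- ape::unroot(read_gene_tree(text = "((A,B),(C,M));"))
  rooted <- root_by_outgroup(un, "M")
  kids <- famhist:::node_children(rooted)[[famhist:::root_node(rooted)]]
  sides <- lapply(kids, function(k) {
    rooted$tip.label[famhist:::descendant_tips(rooted)[[k]]]
  })
  expect_true(any(vapply(sides, function(s) identical(s, "M"), logical(1))))

  # two-leaf outgroup cherry
  un2 <- ape::unroot(read_gene_tree(text = "((A,B),(C,(M1,M2)));"))
  rooted2 <- root_by_outgroup(un2, c("M1", "M2"))
  sides2 <- lapply(famhist:::node_children(rooted2)[[famhist:::root_node(rooted2)]],
                   function(k) rooted2$tip.label[famhist:::descendant_tips(rooted2)[[k]]])
  expect_true(any(vapply(sides2, setequal, logical(1), y = c("M1", "M2"))))

  # scattered outgroup is rejected with the conflict spelled out
  un3 <- ape::unroot(read_gene_tree(text = "((M1,B),(C,(M2,D)));"))
  expect_error(root_by_outgroup(un3, c("M1", "M2")), "not monophyletic")
})

test_that("min-duplication rooting matches exhaustive per-edge enumeration", {
  sp <- random_species_tree(5)
  set.seed(41)
  for (i in 1:12) {
    g <- random_gene_tree(sp, sample(5:9, 1))
    un <- ape::unroot(g)
    if (is.null(un$edge.length)) un$edge.length <- rep(1, nrow(un$edge))
    res <- root_min_duplications(un, sp)
    # independent enumeration over every edge
    counts <- vapply(seq_len(nrow(un$edge)), function(e) {
      r <- phytools::reroot(un, un$edge[e, 2], position = un$edge.length[e] / 2)
      lca_reconcile(ape::collapse.singles(r), sp)$n_duplications
    }, numeric(1))
    expect_equal(res$count, min(counts))
    expect_equal(length(res$trees), sum(counts == min(counts)))
    for (tr in res$trees) {
      expect_equal(lca_reconcile(tr, sp)$n_duplications, res$count)
    }
  }
})

test_that("a congruent single-copy tree roots with zero duplications", {
  sp <- read_gene_tree(text = "((A,B),(C,D));")
  un <- ape::unroot(read_gene_tree(text = "((A,B),(C,D));"))
  res <- root_min_duplications(un, sp)
  expect_equal(res$count, 0)
  # one duplicated genus cherry forces one duplication under every rooting
  un2 <- ape::unroot(read_gene_tree(
    text = "(((A|x|1,A|x|2),B|x|1),(C|x|1,D|x|1));"))
  res2 <- root_min_duplications(un2, sp)
  expect_equal(res2$count, 1)
})
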