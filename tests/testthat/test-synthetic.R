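sp <- default_species_tree()

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rate-zero simulation reproduces the species tree exactly", {
  sim <- simulate_gene_tree(sp, dup_rate = 0, loss_rate = 0, seed = 1)
  expect_equal(sort(leaf_genus(sim$tree$tip.label)), sort(sp$tip.label))
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(all(sim$truth$copy_counts$n == 1))
  expect_true(ape::all.equal.phylo(
    ape::read.tree(text = gsub("\\|sim\\|1", "", write_gene_tree(sim$tree))),
    sp, use.edge.length = FALSE))
})

test_that("identical seeds give identical artifacts", {
  a <- simulate_gene_tree(sp, dup_rate = 0.2, loss_rate = 0.1, seed = 99)
  b <- simulate_gene_tree(sp, dup_rate = 0.2, loss_rate = 0.1, seed = 99)
  expect_identical(write_gene_tree(a$tree), write_gene_tree(b$tree))
  expect_identical(a$truth$events, b$truth$events)
  x <- simulate_alignment(sp$tip.label, m = 60, seed = 7)
  y <- simulate_alignment(sp$tip.label, m = 60, seed = 7)
  expect_identical(x$seqs, y$seqs)
})

test_that("duplication totals follow the birth-death expectation", {
  set.seed(121)
  n_rep <- 400
  tot <- replicate(n_rep,
    simulate_gene_tree(sp, dup_rate = 0.02, loss_rate = 0)$truth$n_duplications)
  expected <- 0.02 * 24            # rate x total tree length (24 unit branches)
  se <- stats::sd(tot) / sqrt(n_rep)
  expect_lt(abs(mean(tot) - expected), 3 * se + 0.05)
})

test_that("truth bookkeeping matches the produced tree", {
  set.seed(131)
  for (i in 1:20) {
    sim <- simulate_gene_tree(sp, dup_rate = 0.15, loss_rate = 0.05)
    counted <- table(factor(leaf_genus(sim$tree$tip.label %||% character()),
                            levels = sp$tip.label))
    expect_equal(unname(c(counted)), sim$truth$copy_counts$n)
  }
})

test_that("distortion controls support levels and collapse behaviour", {
  sim <- simulate_gene_tree(sp, dup_rate = 0.1, loss_rate = 0, seed = 5)
  clean <- distort_tree(sim$tree, support_noise = 0, seed = 6)
  expect_equal(write_gene_tree(collapse_low_support(clean)),
               write_gene_tree(clean))        # noise 0: collapse is identity
  star <- collapse_low_support(distort_tree(sim$tree, support_noise = 1, seed = 6))
  expect_equal(star$Nnode, 1)                 # noise 1: star tree
  half <- distort_tree(sim$tree, support_noise = 0.5, seed = 6)
  sup <- famhist:::node_support(half)
  low <- sum(sup < 0.7, na.rm = TRUE)
  internal <- half$Nnode - 1                  # root split carries no support edge
  expect_equal(low, round(0.5 * internal))
})

test_that("NNI on a low-support edge leaves the leaf set intact", {
  sim <- simulate_gene_tree(sp, dup_rate = 0.1, loss_rate = 0, seed = 15)
  d <- distort_tree(sim$tree, support_noise = 0.4, nni = TRUE, seed = 16)
  expect_setequal(d$tip.label, sim$tree$tip.label)
})

test_that("hit-table generator exercises every decision path", {
  hits <- make_hit_table(c("a", "b", "c", "d"), "CAHS", decoy_best = "b",
                         boundary = "c", no_hit = "d")
  cand <- primary_screen(hits)
  dec <- reciprocal_confirm(c("a", "b", "c", "d"), hits, "CAHS")
  expect_equal(dec$reason[dec$seq_id == "a"], "passed_primary_and_reciprocal")
  expect_equal(dec$reason[dec$seq_id == "b"], "reciprocal_best_hit_other_family")
  expect_equal(dec$verdict[dec$seq_id == "c"], "retained")
  expect_equal(dec$reason[dec$seq_id == "d"], "no_reciprocal_hit")
  # no decoys: everything with hits is retained
  all_in <- reciprocal_confirm(c("a", "c"),
                               make_hit_table(c("a", "c"), "CAHS"), "CAHS")
  expect_true(all(all_in$verdict == "retained"))
})

test_that("full-loop recovery: undistorted, loss-free families are recovered exactly", {
  set.seed(141)
  for (i in 1:25) {
    sim <- simulate_gene_tree(sp, dup_rate = 0.1, loss_rate = 0)
    if (is.null(sim$tree)) next
    rec <- lca_reconcile(sim$tree, sp)
    expect_equal(rec$n_duplications, sim$truth$n_duplications)
    expect_equal(rec$n_losses, 0)
    ex <- dplyr::count(genus_exclusive_duplications(sim$tree), genus,
                       wt = n_duplications, name = "n_duplications")
    ex <- dplyr::filter(ex, n_duplications > 0)
    td <- dplyr::arrange(sim$truth$terminal_duplications, genus)
    expect_equal(as.data.frame(dplyr::arrange(ex, genus)), as.data.frame(td))
  }
})

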