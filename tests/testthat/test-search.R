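test_that("mp_search on 4 taxa equals exhaustive search over 3 topologies", {
  set.seed(5)
  for (rep in 1:8) {
    cells <- random_cells(c("A", "B", "C", "D"), 12, k = sample(2:3, 1))
    heur <- mp_search(cells, search_config(n_addition_replicates = 4,
                                           seed = rep))
    exact <- exhaustive_search(cells)
    expect_identical(exact$n_topologies, 3L)
    expect_identical(heur$length, exact$length)
    # topology sets agree up to representation: compare via RF distance
    expect_identical(length(heur$trees), length(exact$trees))
    for (t1 in heur$trees) {
      expect_true(any(vapply(exact$trees, function(t2) {
        ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
      }, logical(1))))
    }
  }
})

test_that("mp_search matches exhaustive search on 6-7 taxa", {
  set.seed(6)
  for (n in 6:7) {
    cells <- random_cells(paste0("t", 1:n), 15, k = 2)
    heur <- mp_search(cells, search_config(n_addition_replicates = 10,
                                           swap = "spr", seed = n,
                                           max_trees = 200))
    exact <- exhaustive_search(cells)
    expect_identical(heur$length, exact$length)
    for (t1 in heur$trees) {
      expect_true(any(vapply(exact$trees, function(t2) {
        ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
      }, logical(1))))
    }
  }
})

test_that("search length never exceeds the best addition tree and duplicating columns doubles it", {
  set.seed(9)
  cells <- random_cells(paste0("t", 1:8), 20, k = 2)
  res <- mp_search(cells, search_config(n_addition_replicates = 5, seed = 2))
  expect_true(all(res$length <= res$replicate_lengths))
  res2 <- mp_search(cbind(cells, cells),
                    search_config(n_addition_replicates = 5, seed = 2))
  expect_identical(res2$length, 2L * res$length)
  expect_error(mp_search(cells[1:3, ]), "at least 4")
})

test_that("low-homoplasy fixture search recovers the generating topology", {
  fx <- fixture_study()
  comb <- concatenate(fx$morph, fx$partitions)
  res <- mp_search(comb, search_config(n_addition_replicates = 2, seed = 3))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(res$trees[[1]]),
                                         ape::unroot(fx$true_tree))), 0)
})

test_that("collapse_unsupported matches the brute-force forced-change test", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 6
    taxa <- paste0("t", 1:n)
    cells <- random_cells(taxa, 6, k = 2)
    tr <- ape::rtree(n)
    tr$tip.label <- taxa
    ct <- collapse_unsupported(tr, cells)
    # brute force: an internal edge is retained iff some character forces a
    # change on it in every MP labeling
    phy <- ape::root(ape::unroot(tr), outgroup = taxa[1], resolve.root = TRUE)
    index <- swimpars:::.tree_index(phy)
    forced_splits <- character(0)
    all_splits <- character(0)
    for (v in index$post) {
      if (v == index$root || index$parent[v] == index$root) next
      tips <- phy$tip.label[swimpars:::.phylo_clade_tips(index, v)]
      if (length(tips) < 2 || length(tips) > n - 2) next
      key <- paste(sort(tips), collapse = "|")
      all_splits <- c(all_splits, key)
      forced <- FALSE
      for (j in seq_len(ncol(cells))) {
        col <- setNames(cells[, j], taxa)
        e <- enumerate_parsimony(phy, col)
        # zero-change reconstruction on edge exists iff some state is in the
        # MPR of the child AND pinning both endpoints to it stays optimal
        ca <- swimpars:::.column_allowed(col, phy$tip.label)
        ok <- FALSE
        for (s in seq_along(ca$alphabet)) {
          pin <- swimpars:::.sankoff_pin_edge(index, ca$allowed,
                                              length(ca$alphabet), v, s)
          if (pin == e$length) { ok <- TRUE; break }
        }
        if (!ok) { forced <- TRUE; break }
      }
      if (forced) forced_splits <- c(forced_splits, key)
    }
    kept <- swimpars:::.split_keys(ct, sort(taxa))
    # same splits, modulo key orientation (anchor is t1 both times)
    expect_setequal(kept, forced_splits)
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(as.numeric(ape::dist.topo(strict_consensus(list(t1, t1)),
                                         ape::unroot(t1))), 0)
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  cons <- strict_consensus(list(t1, t2))
  keys <- swimpars:::.split_keys(cons, sort(t1$tip.label))
  expect_identical(keys, "C|D|E")   # only the shared split away from A,B
  t3 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  t4 <- ape::read.tree(text = "((A,D),(E,(B,C)));")
  star <- strict_consensus(list(t3, t4))
  expect_identical(star$Nnode, 1L)
  expect_error(strict_consensus(list(t1, ape::rtree(4))), "identical leaf sets")
})

test_that("root_on_outgroup places the outgroup basally and is length-safe", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  r <- root_on_outgroup(tr, "C")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  expect_true(match("C", r$tip.label) %in% kids)
  expect_error(root_on_outgroup(tr, "Z"), "not a tip")
  cells <- random_cells(tr$tip.label, 10)
  expect_identical(tree_length(r, cells), tree_length(tr, cells))
})

test_that("bootstrap gives certainty to an unconflicted split and is deterministic", {
  taxa <- c("A", "B", "C", "D", "E", "F")
  cells <- matrix(rep(c("0", "0", "0", "1", "1", "1"), 30), nrow = 6,
                  dimnames = list(taxa, NULL))
  bs <- bootstrap_support(cells, search_config(seed = 11), n_reps = 60)
  expect_identical(bs$percent[bs$split == "D|E|F"], 100)
  bs2 <- bootstrap_support(cells, search_config(seed = 11), n_reps = 60)
  expect_identical(bs, bs2)
  expect_error(bootstrap_support(cells, search_config(seed = 1), n_reps = 0),
               "n_reps")
  # single-column matrix: replicate support is all-or-nothing by construction
  one <- cells[, 1, drop = FALSE]
  bs1 <- bootstrap_support(one, search_config(seed = 3), n_reps = 10)
  expect_true(all(bs1$percent[bs1$split == "D|E|F"] %in% seq(0, 100, by = 10)))
})
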