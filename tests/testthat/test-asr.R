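mini_catalog <- function(n_char, k = 2) {
  cfg <- sim_config(n_taxa = 4, morph = list(n_char = n_char, k = k))
  swimpars:::.sim_catalog(cfg$morph)
}

test_that("reconstruct handles constant and hand-checked characters", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cells <- matrix(c("0", "0", "0", "0",
                    "0", "1", "0", "0"), 4, 2,
                  dimnames = list(c("A", "B", "C", "D"), c("1", "2")))
  asr <- reconstruct(tr, morph_matrix(cells), mini_catalog(2))
  # constant character: every node {0}, no transformation
  for (nd in asr$node_labels) expect_identical(asr$states[["1"]][[nd]], "0")
  # autapomorphy of B: all ancestors {0}
  for (nd in c("N5", "N6", "N7")) {
    expect_identical(asr$states[["2"]][[nd]], "0")
  }
  tra <- transformations(asr)
  expect_identical(nrow(tra), 1L)
  expect_identical(tra$child, "B")
  expect_identical(tra$char_id, 2L)
})

test_that("reconstruct matches exhaustive enumeration on 5-taxon cases", {
  set.seed(23)
  for (rep in 1:10) {
    tr <- ape::rtree(5)
    tr$tip.label <- c("A", "B", "C", "D", "E")
    cells <- random_cells(tr$tip.label, 6, k = 3)
    colnames(cells) <- as.character(1:6)
    asr <- reconstruct(tr, morph_matrix(cells), mini_catalog(6, k = 3))
    for (j in 1:6) {
      e <- enumerate_parsimony(tr, setNames(cells[, j], rownames(cells)))
      for (v in 6:9) {
        expect_identical(sort(asr$states[[as.character(j)]][[paste0("N", v)]]),
                         sort(e$states[[v]]))
      }
    }
  }
})

test_that("reconstruct refuses an invalid matrix and never alters leaf scores", {
  fx <- fixture_study()
  tr <- root_on_outgroup(fx$true_tree, "Outgroup")
  asr <- reconstruct(tr, fx$morph, fx$catalog)
  for (t in fx$morph$taxa) {
    for (key in colnames(fx$morph$cells)) {
      obs <- fx$morph$cells[t, key]
      if (!obs %in% c("?", "-")) {
        expect_identical(asr$states[[key]][[t]], unname(obs))
      }
    }
  }
  bad <- fx$morph
  bad$cells["S1", "43"] <- "7"
  expect_error(reconstruct(tr, bad, fx$catalog), "validation")
})

test_that("transformations are disjoint-set changes ordered by preorder", {
  fx <- fixture_study()
  tr <- root_on_outgroup(fx$true_tree, "Outgroup")
  asr <- reconstruct(tr, fx$morph, fx$catalog)
  tra <- transformations(asr)
  expect_true(nrow(tra) > 0)
  for (i in seq_len(nrow(tra))) {
    from <- strsplit(tra$from[i], "/")[[1]]
    to <- strsplit(tra$to[i], "/")[[1]]
    expect_length(intersect(from, to), 0)
  }
  # loss branch carries the designed reversals of 46/47/48
  loss <- tra[tra$child == fx$loss_taxon, ]
  expect_true(all(c(46, 47, 48) %in% loss$char_id))
})

test_that("stem_state returns MRCA sets and enforces monophyly", {
  fx <- fixture_study()
  tr <- root_on_outgroup(fx$true_tree, "Outgroup")
  asr <- reconstruct(tr, fx$morph, fx$catalog)
  clade <- c(fx$swimmer_taxa, fx$loss_taxon)
  expect_identical(stem_state(asr, clade, 34), "2")
  expect_identical(stem_state(asr, clade, 47), "1")
  # whole-tree clade = root set
  expect_identical(stem_state(asr, tr$tip.label, 42),
                   asr$states[["42"]][[paste0("N", length(tr$tip.label) + 1L)]])
  # cherry with identical states
  expect_identical(stem_state(asr, c("S3", "S4"), 47), "1")
  expect_error(stem_state(asr, fx$swimmer_taxa, 34), "monophyletic.*L1")
  expect_error(stem_state(asr, c("S1", "nope"), 34), "unknown leaves")
})

test_that("ASR state recovery improves as the simulated change rate drops", {
  rates <- c(0.05, 0.3, 1.5)
  recovery <- vapply(seq_along(rates), function(i) {
    cfg <- sim_config(n_taxa = 16, seed = 400 + i,
                      morph = list(n_char = 120, k = 2, rate = rates[i]))
    tree <- simulate_tree(cfg)
    sim <- simulate_morphology(tree, cfg)
    asr <- reconstruct(tree, sim$matrix, sim$catalog, validate = FALSE)
    ntip <- length(tree$tip.label)
    hits <- 0L; tot <- 0L
    for (v in (ntip + 1):(2 * ntip - 1)) {
      nd <- paste0("N", v)
      for (j in seq_len(120)) {
        truth <- as.character(sim$truth$node_states[v, j])
        tot <- tot + 1L
        if (truth %in% asr$states[[as.character(j)]][[nd]]) hits <- hits + 1L
      }
    }
    hits / tot
  }, numeric(1))
  expect_true(all(diff(recovery) <= 0))       # monotone non-increasing in rate
  expect_gt(recovery[1], 0.95)                # near-perfect at low rate
})

test_that("inapplicable-context pairs are annotated when the controller is absent", {
  cat2 <- structure(list(characters = list(
    "1" = list(char_id = 1L, locus = "ctrl", statement = "controller",
               states = c("0" = "absent", "1" = "present"),
               inapplicable_if = list()),
    "2" = list(char_id = 2L, locus = "dep", statement = "dependent",
               states = c("0" = "a", "1" = "b"),
               inapplicable_if = list(list(controller = 1L, states = 0L)))),
    provenance = "test"), class = "character_catalog")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cells <- matrix(c("0", "0", "0", "0",
                    "-", "-", "-", "-"), 4, 2,
                  dimnames = list(c("A", "B", "C", "D"), c("1", "2")))
  asr <- reconstruct(tr, morph_matrix(cells), cat2)
  expect_true(all(asr$inapplicable_context[, "2"]))
  expect_false(any(asr$inapplicable_context[, "1"]))
})
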