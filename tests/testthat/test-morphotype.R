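test_that("shipped rule matches the published state combination", {
  rule <- load_rule(catalog = catalog59())
  expect_setequal(names(rule),
                  c("11", "15", "16", "18", "23", "34", "43", "45", "46",
                    "47", "48", "50"))
  expect_identical(rule[["34"]], c("2", "3"))
  expect_identical(rule[["18"]], "2")
  # merus length (44) is deliberately not part of the rule
  expect_false("44" %in% names(rule))
})

test_that("exemplar terminals classify as in the study", {
  rule <- load_rule()
  rows <- exemplar_rows()
  expect_identical(classify_terminal(rows[["Liocarcinus_depurator"]], rule)$verdict,
                   "SWIMMER")
  expect_identical(classify_terminal(rows[["Polybius_henslowii"]], rule)$verdict,
                   "SWIMMER")
  cm <- classify_terminal(rows[["Carcinus_maenas"]], rule)
  expect_identical(cm$verdict, "NON_SWIMMER")
  expect_true(all(c(34, 46, 47, 48) %in% cm$failing))
  expect_identical(classify_terminal(rows[["Chaceon_mediterraneus"]], rule)$verdict,
                   "NON_SWIMMER")
})

test_that("classify_terminal three-valued semantics", {
  rule <- load_rule()
  row <- exemplar_rows()[["Liocarcinus_depurator"]]
  # single-rule breach
  row2 <- row; row2[["46"]] <- "0"
  call <- classify_terminal(row2, rule)
  expect_identical(call$verdict, "NON_SWIMMER")
  expect_identical(call$failing, 46L)
  # missing rule character => POSSIBLE
  row3 <- row; row3[["47"]] <- "?"
  expect_identical(classify_terminal(row3, rule)$verdict, "POSSIBLE")
  # inapplicable counts as failing (the required state cannot hold)
  row4 <- row; row4[["43"]] <- "-"
  expect_identical(classify_terminal(row4, rule)$verdict, "NON_SWIMMER")
  # uncovered rule character errors
  expect_error(classify_terminal(row[setdiff(names(row), "50")], rule),
               "rule character 50")
})

test_that("classify_terminal is monotone under rule relaxation", {
  rule <- load_rule()
  rows <- exemplar_rows()
  relaxed <- rule
  for (key in names(relaxed)) {
    relaxed[[key]] <- union(relaxed[[key]], c("0", "1", "2", "3"))
  }
  class(relaxed) <- "morphotype_rule"
  for (row in rows) {
    v1 <- classify_terminal(row, rule)$verdict
    v2 <- classify_terminal(row, relaxed)$verdict
    if (v1 == "SWIMMER") expect_identical(v2, "SWIMMER")
  }
})

test_that("classify_node subset/intersection semantics and leaf agreement", {
  fx <- fixture_study()
  tr <- root_on_outgroup(fx$true_tree, "Outgroup")
  asr <- reconstruct(tr, fx$morph, fx$catalog)
  rule <- fx$rule
  # leaves with determinate scores agree with classify_terminal
  for (t in fx$morph$taxa) {
    row <- setNames(fx$morph$cells[t, ], colnames(fx$morph$cells))
    if (any(row[names(rule)] == "-")) next
    expect_identical(classify_node(asr, t, rule)$verdict,
                     classify_terminal(row, rule, subject = t)$verdict,
                     label = t)
  }
  # swimmer-clade MRCA is a SWIMMER; the loss tip is not
  mrca <- ape::getMRCA(tr, c(fx$swimmer_taxa, fx$loss_taxon))
  expect_identical(classify_node(asr, mrca, rule)$verdict, "SWIMMER")
  expect_identical(classify_node(asr, fx$loss_taxon, rule)$verdict,
                   "NON_SWIMMER")
  expect_error(classify_node(asr, "N999", rule), "node not found")
})

test_that("a POSSIBLE node arises from intersecting non-subset MPR sets", {
  # two swimmer tips and one non-swimmer tip under a 4-taxon tree make the
  # deeper ancestors ambiguous for the flipped character
  rule <- structure(list("1" = "1"), class = "morphotype_rule")
  cat1 <- structure(list(characters = list(
    "1" = list(char_id = 1L, locus = "x", statement = "x",
               states = c("0" = "a", "1" = "b"), inapplicable_if = list())),
    provenance = "test"), class = "character_catalog")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cells <- matrix(c("1", "1", "0", "0"), 4, 1,
                  dimnames = list(c("A", "B", "C", "D"), "1"))
  asr <- reconstruct(tr, morph_matrix(cells), cat1)
  expect_identical(classify_node(asr, "N6", rule)$verdict, "SWIMMER")
  expect_identical(classify_node(asr, "N7", rule)$verdict, "NON_SWIMMER")
  expect_identical(classify_node(asr, "N5", rule)$verdict, "POSSIBLE")
})

test_that("annotate_tree flips exactly the loss subtree in the fixture", {
  fx <- fixture_study()
  tr <- root_on_outgroup(fx$true_tree, "Outgroup")
  asr <- reconstruct(tr, fx$morph, fx$catalog)
  ann <- annotate_tree(asr, fx$rule)
  tips <- ann[ann$is_tip, ]
  expect_setequal(tips$node[tips$verdict == "SWIMMER"], fx$swimmer_taxa)
  expect_identical(tips$verdict[tips$node == fx$loss_taxon], "NON_SWIMMER")
  # rule-character state sets are serialized for every node
  expect_true(all(paste0("char", names(fx$rule)) %in% colnames(ann)))
  expect_identical(nrow(ann), 2L * length(tr$tip.label) - 1L)
})
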