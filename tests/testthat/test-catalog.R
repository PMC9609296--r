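test_that("shipped catalog loads with 59 characters and verbatim dependencies", {
  w <- capture_warnings(cat59 <- load_catalog())
  expect_length(w, 2)
  expect_true(all(grepl("UNDECLARED_CONTROLLING_STATE", w)))
  expect_length(cat59$characters, 59)
  expect_identical(as.integer(names(cat59$characters)), 1:59)
  # char 8 depends on 7(0)
  dep8 <- cat59$characters[["8"]]$inapplicable_if
  expect_identical(lapply(dep8, unlist), list(c(controller = 7L, states = 0L)))
  # char 12 keeps all five conditions incl. the undeclared 8(3)
  dep12 <- cat59$characters[["12"]]$inapplicable_if
  got <- vapply(dep12, function(d) sprintf("%d(%d)", d$controller, d$states),
                character(1))
  expect_identical(got, c("7(0)", "8(0)", "8(2)", "8(3)", "15(0)"))
  # both paper inconsistencies surface as warnings, nothing else
  w <- attr(cat59, "warnings")
  expect_length(w, 2)
  expect_true(any(grepl("char 12 condition 8\\(3\\)", w)))
  expect_true(any(grepl("char 27 condition 9\\(2\\)", w)))
})

test_that("catalog parse and structural errors are reported", {
  bad <- tempfile(fileext = ".txt")
  writeLines(c("char: 1", "locus: x", "statement: y",
               "states: 0=a | 1=b", "inapplicable_if: 2(0)",
               "", "char: 2", "locus: x", "statement: y",
               "states: 0=a | 1=b", "inapplicable_if: 1(0)"), bad)
  expect_error(load_catalog(bad), "cyclic")
  bad2 <- tempfile(fileext = ".txt")
  writeLines(c("char: 1", "locus: x", "statement: y",
               "states: 0=a", "inapplicable_if:"), bad2)
  expect_error(load_catalog(bad2), "0..k-1")
  expect_error(load_catalog(tempfile()), "not found")
})

test_that("is_applicable follows the inapplicable-if semantics", {
  cat59 <- catalog59()
  row <- setNames(rep("?", 59), 1:59)
  row[["7"]] <- "0"
  expect_false(is_applicable(row, 8, cat59))    # 8 inapplicable if 7(0)
  expect_false(is_applicable(row, 13, cat59))
  row[["7"]] <- "1"; row[["8"]] <- "1"
  expect_false(is_applicable(row, 13, cat59))   # 13 inapplicable if 8(1)
  expect_true(is_applicable(row, 14, cat59))    # 14 needs 8(2)
  # missing controller => applicable
  row[["8"]] <- "?"
  expect_true(is_applicable(row, 13, cat59))
  # undeclared-state condition can never match
  row[["8"]] <- "2"; row[["15"]] <- "1"
  expect_false(is_applicable(row, 12, cat59))   # via 8(2)
  expect_error(is_applicable(row, 99, cat59), "unknown character")
})

test_that("is_applicable is monotone under missing-to-state resolution", {
  cat59 <- catalog59()
  set.seed(20)
  for (rep in 1:25) {
    row <- setNames(rep("?", 59), 1:59)
    for (key in names(row)) {
      states <- names(cat59$characters[[key]]$states)
      if (runif(1) < 0.5) row[[key]] <- sample(states, 1)
    }
    target <- sample(c(8:17, 20, 22, 23, 27, 35, 36, 40, 41, 43), 1)
    before <- is_applicable(row, target, cat59)
    # resolve one missing controller
    ctrls <- vapply(cat59$characters[[as.character(target)]]$inapplicable_if,
                    function(c) as.character(c$controller), character(1))
    open <- ctrls[row[ctrls] == "?"]
    if (length(open) == 0) next
    pick <- open[1]
    row[[pick]] <- sample(names(cat59$characters[[pick]]$states), 1)
    after <- is_applicable(row, target, cat59)
    # resolution can only flip applicable -> inapplicable
    if (!before) expect_false(after)
  }
})

test_that("validate_matrix flags each violation kind deterministically", {
  cat59 <- catalog59()
  taxa <- c("tax1", "tax2", "tax3")
  cells <- matrix("?", 3, 59, dimnames = list(taxa, as.character(1:59)))
  # consistent rows: 7(0) with dependents '-'
  dependents_of7 <- c("8", "9", "10", "11", "12", "13", "14", "15", "16",
                      "17", "23", "27", "36", "40")
  cells[, "7"] <- "0"
  cells[, dependents_of7] <- "-"
  m <- morph_matrix(cells)
  expect_identical(nrow(validate_matrix(m, cat59)), 0L)
  # breach: state where inapplicable; '-' where applicable; undeclared code
  cells["tax1", "8"] <- "1"
  cells["tax2", "19"] <- "-"
  cells["tax3", "42"] <- "9"
  rep <- validate_matrix(morph_matrix(cells), cat59)
  expect_identical(rep$kind[rep$taxon == "tax1" & rep$char_id == 8],
                   "SHOULD_BE_INAPPLICABLE")
  expect_identical(rep$kind[rep$taxon == "tax2" & rep$char_id == 19],
                   "SHOULD_BE_APPLICABLE")
  expect_identical(rep$kind[rep$taxon == "tax3" & rep$char_id == 42],
                   "UNDECLARED_STATE")
  # ordered by (taxon, char_id)
  expect_false(is.unsorted(order(rep$taxon, rep$char_id)))
})

test_that("a '-' under a matching controller is not a violation", {
  cat59 <- catalog59()
  cells <- matrix("?", 1, 59, dimnames = list("tax", as.character(1:59)))
  cells[, "7"] <- "0"
  cells[, "8"] <- "-"
  cells[, c("9", "10", "11", "12", "13", "14", "15", "16", "17",
            "23", "27", "36", "40")] <- "-"
  rep <- validate_matrix(morph_matrix(cells), cat59)
  expect_identical(nrow(rep[rep$char_id == 8, ]), 0L)
})
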