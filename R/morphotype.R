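# The P5-swimming-crab morphotype rule and three-valued classification of
# terminals and reconstructed ancestors.
#
# A P5-swimmer is identified by a fixed combination of states (convex
# median-plate margin, free interosternites 6/7 and 7/8, the P5 anterior
# coxa muscle originating at the median plate, dense setal fringes, carpal
# propodus insertion, propodus lobe, broad paddle-shaped dactylus with a
# concave proximo-ventral margin, broad carapace).  Merus length only
# grades swimming effectiveness and is deliberately not part of the rule.

.verdicts <- c("SWIMMER", "POSSIBLE", "NON_SWIMMER")

#' Classify a terminal taxon against a morphotype rule
#'
#' `SWIMMER` iff every rule character's score is among the allowed states;
#' a MISSING (`?`) score on a rule character makes the call `POSSIBLE`
#' (unless another character already fails); any disallowed state — and any
#' inapplicable (`-`) score, since the required state then cannot hold —
#' gives `NON_SWIMMER` with the failing characters listed.
#'
#' @param row named character vector of scores covering all rule characters
#'   (names are char ids).
#' @param rule a `morphotype_rule` from [load_rule()].
#' @param subject label for the report.
#' @return a `morphotype_call`: list with `subject`, `verdict`, `failing`.
#' @export
classify_terminal <- function(row, rule, subject = "terminal") {
  failing <- integer(0)
  any_missing <- FALSE
  for (key in names(rule)) {
    val <- if (key %in% names(row)) row[[key]] else NA_character_
    if (is.na(val)) {
      stop("row does not cover rule character ", key)
    }
    if (val == "?") {
      any_missing <- TRUE
    } else if (!val %in% rule[[key]]) {
      failing <- c(failing, as.integer(key))
    }
  }
  verdict <- if (length(failing) > 0) "NON_SWIMMER"
             else if (any_missing) "POSSIBLE" else "SWIMMER"
  structure(list(subject = subject, verdict = verdict, failing = failing),
            class = "morphotype_call")
}

#' Classify a reconstructed node against a morphotype rule
#'
#' `SWIMMER` iff for every rule character the node's MPR state set is a
#' non-empty subset of the allowed states; `POSSIBLE` iff every MPR set at
#' least intersects the allowed states but some set is not a subset (the
#' reconstruction is compatible with, but does not require, the
#' morphotype); otherwise `NON_SWIMMER`.
#'
#' @param asr an `asr_result` covering all rule characters.
#' @param node node label (tip label or `N<number>`) or node number.
#' @param rule a `morphotype_rule`.
#' @return a `morphotype_call`.
#' @export
classify_node <- function(asr, node, rule) {
  if (is.numeric(node)) node <- asr$node_labels[node]
  if (!node %in% asr$node_labels) stop("node not found: ", node)
  failing <- integer(0)
  all_subset <- TRUE
  for (key in names(rule)) {
    if (!key %in% names(asr$states)) {
      stop("reconstruction does not cover rule character ", key)
    }
    set <- asr$states[[key]][[node]]
    if (length(intersect(set, rule[[key]])) == 0) {
      failing <- c(failing, as.integer(key))
    } else if (!all(set %in% rule[[key]])) {
      all_subset <- FALSE
    }
  }
  verdict <- if (length(failing) > 0) "NON_SWIMMER"
             else if (all_subset) "SWIMMER" else "POSSIBLE"
  structure(list(subject = node, verdict = verdict, failing = failing),
            class = "morphotype_call")
}

#' @export
print.morphotype_call <- function(x, ...) {
  cat(x$subject, ":", x$verdict)
  if (length(x$failing) > 0) cat(" (failing:", paste(x$failing, collapse = ","), ")")
  cat("\n")
  invisible(x)
}

#' Morphotype verdicts for every terminal and internal node
#'
#' @param asr an `asr_result` covering all rule characters.
#' @param rule a `morphotype_rule`.
#' @return data frame: `node`, `is_tip`, `verdict`, `failing` and one
#'   serialized state-set column per rule character.
#' @export
annotate_tree <- function(asr, rule) {
  rows <- lapply(asr$node_labels, function(nd) {
    call <- classify_node(asr, nd, rule)
    rec <- data.frame(node = nd,
                      is_tip = match(nd, asr$node_labels) <= asr$ntip,
                      verdict = call$verdict,
                      failing = paste(call$failing, collapse = ","),
                      stringsAsFactors = FALSE)
    for (key in names(rule)) {
      rec[[paste0("char", key)]] <- paste(asr$states[[key]][[nd]],
                                          collapse = "/")
    }
    rec
  })
  do.call(rbind, rows)
}
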