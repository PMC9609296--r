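# Unordered-parsimony ancestral state reconstruction for morphological
# characters on a rooted binary tree, per-branch transformation extraction,
# and MRCA ("stem species") state queries.

#' Ancestral state reconstruction under unordered parsimony
#'
#' Computes, for every node and every catalog character, the MPR state set
#' (states attained in at least one most-parsimonious reconstruction).
#' Missing and inapplicable cells enter as full ambiguity over the
#' character's declared states.  Node-character pairs whose controlling
#' character is reconstructed entirely in a controlling ("absent") state are
#' annotated `INAPPLICABLE_CONTEXT` — a reporting convention, not a scoring
#' change.
#'
#' @param tree rooted binary `phylo` whose tips are all scored in `matrix`.
#' @param matrix a `morph_matrix` with columns named by catalog char ids.
#' @param catalog the `character_catalog`; the matrix must validate against
#'   it (hard violations abort with a pointer to [validate_matrix()]).
#' @param validate set `FALSE` to skip matrix validation.
#' @return an `asr_result`: list with `tree`, `node_labels`, `states`
#'   (list char id -> list node -> character vector), `ambiguous` (logical
#'   matrix nodes x chars), `lengths` (per-char parsimony length),
#'   `inapplicable_context` (logical matrix).
#' @export
reconstruct <- function(tree, matrix, catalog, validate = TRUE) {
  if (!ape::is.rooted(tree)) stop("reconstruct requires a rooted tree")
  if (!ape::is.binary(tree)) stop("reconstruct requires a binary tree")
  if (validate) {
    rep <- validate_matrix(matrix, catalog)
    hard <- rep[rep$kind %in% c("UNDECLARED_STATE", "SHOULD_BE_INAPPLICABLE",
                                "SHOULD_BE_APPLICABLE"), , drop = FALSE]
    if (nrow(hard) > 0) {
      stop("matrix fails validation (", nrow(hard),
           " violation(s)); run validate_matrix() for the report")
    }
  }
  index <- .tree_index(tree)
  if (!all(index$labels %in% matrix$taxa)) {
    stop("tree tips missing from matrix: ",
         paste(setdiff(index$labels, matrix$taxa), collapse = ", "))
  }
  ids <- colnames(matrix$cells)
  nn <- index$nnode
  node_labels <- c(index$labels, paste0("N", (index$ntip + 1):nn))
  states <- list()
  lengths <- setNames(integer(length(ids)), ids)
  ambiguous <- matrix(FALSE, nn, length(ids), dimnames = list(node_labels, ids))
  for (key in ids) {
    ch <- catalog$characters[[key]]
    declared <- if (!is.null(ch)) names(ch$states) else NULL
    col <- setNames(matrix$cells[, key], matrix$taxa)
    ca <- .column_allowed(col, index$labels, declared = declared)
    res <- .sankoff_column(index, ca$allowed, length(ca$alphabet))
    lengths[key] <- as.integer(res$length)
    sets <- apply(res$mpr, 1, function(r) ca$alphabet[r], simplify = FALSE)
    names(sets) <- node_labels
    states[[key]] <- sets
    ambiguous[, key] <- vapply(sets, length, integer(1)) > 1
  }
  inap <- matrix(FALSE, nn, length(ids), dimnames = list(node_labels, ids))
  for (key in ids) {
    ch <- catalog$characters[[key]]
    if (is.null(ch) || length(ch$inapplicable_if) == 0) next
    for (cond in ch$inapplicable_if) {
      ctrl <- as.character(cond$controller)
      if (!ctrl %in% ids) next
      ctrl_states <- as.character(cond$states)
      hit <- vapply(states[[ctrl]], function(s) all(s %in% ctrl_states),
                    logical(1))
      inap[, key] <- inap[, key] | hit
    }
  }
  structure(list(tree = tree, node_labels = node_labels, states = states,
                 ambiguous = ambiguous, lengths = lengths,
                 inapplicable_context = inap, ntip = index$ntip),
            class = "asr_result")
}

#' Per-branch state transformations implied by every MPR
#'
#' One record per (branch, character) where the parent and child MPR sets
#' are disjoint, i.e. every most-parsimonious reconstruction places at
#' least one change of that character on that branch.  Records are ordered
#' by preorder traversal, then char id.
#'
#' @param asr an `asr_result`.
#' @return data frame with columns `parent`, `child`, `char_id`,
#'   `from` and `to` (state sets serialized with `/`).
#' @export
transformations <- function(asr) {
  index <- .tree_index(asr$tree)
  pre <- rev(index$post)
  out <- list()
  for (v in pre) {
    for (c in index$children[[as.character(v)]]) {
      pv <- asr$node_labels[v]
      cv <- asr$node_labels[c]
      for (key in names(asr$states)) {
        sp <- asr$states[[key]][[pv]]
        sc <- asr$states[[key]][[cv]]
        if (length(intersect(sp, sc)) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            parent = pv, child = cv, char_id = as.integer(key),
            from = paste(sp, collapse = "/"), to = paste(sc, collapse = "/"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(parent = character(0), child = character(0),
                      char_id = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # preorder is already the outer loop; sort char within branch
  res
}

#' MPR state set at the most recent common ancestor of a clade
#'
#' @param asr an `asr_result`.
#' @param clade character vector of leaf labels; must be monophyletic in
#'   the reconstruction's tree.
#' @param char_id character id to query.
#' @return character vector of states.
#' @export
stem_state <- function(asr, clade, char_id) {
  tree <- asr$tree
  if (!all(clade %in% tree$tip.label)) {
    stop("unknown leaves: ", paste(setdiff(clade, tree$tip.label), collapse = ", "))
  }
  if (length(clade) == length(tree$tip.label)) {
    mrca <- length(tree$tip.label) + 1L
  } else if (length(clade) == 1) {
    mrca <- match(clade, tree$tip.label)
  } else {
    mrca <- ape::getMRCA(tree, clade)
  }
  index <- .tree_index(tree)
  desc <- tree$tip.label[.phylo_clade_tips(index, mrca)]
  intruders <- setdiff(desc, clade)
  if (length(intruders) > 0) {
    stop("clade is not monophyletic; intruding taxa: ",
         paste(intruders, collapse = ", "))
  }
  key <- as.character(char_id)
  if (!key %in% names(asr$states)) stop("unknown character id: ", char_id)
  asr$states[[key]][[asr$node_labels[mrca]]]
}

#' Export ASR state sets as a per-node table
#'
#' @param asr an `asr_result`.
#' @return data frame: one row per node, one column per character, sets
#'   serialized with `/`.
#' @export
asr_table <- function(asr) {
  ids <- names(asr$states)
  out <- data.frame(node = asr$node_labels, stringsAsFactors = FALSE)
  for (key in ids) {
    out[[paste0("char", key)]] <- vapply(asr$states[[key]],
                                         paste, character(1), collapse = "/")
  }
  out
}
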