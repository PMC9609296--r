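# Heuristic maximum-parsimony tree search with random addition sequences
# and NNI/SPR branch swapping, plus exhaustive enumeration for tiny taxon
# sets, TNT-style collapsing of unsupported branches, strict consensus,
# outgroup rooting and the nonparametric bootstrap.
#
# Internally trees are held in an "anchored" rooted-binary array form:
# tips 1..n, internals n+1..2n-1, the root's first child always tip 1.
# The root then marks the pendant edge of tip 1, so every rooted tree is a
# faithful representation of an unrooted topology and canonical newick
# strings (children sorted by smallest descendant tip) identify unrooted
# topologies uniquely.

# ---- anchored tree struct ------------------------------------------------

.st_new <- function(ntip, labels) {
  nn <- 2L * ntip - 1L
  list(ntip = ntip, labels = labels, par = integer(nn),
       kid1 = integer(nn), kid2 = integer(nn), root = ntip + 1L)
}

.st_index <- function(tr) {
  nn <- 2L * tr$ntip - 1L
  post <- integer(tr$ntip - 1L)
  stack <- tr$root
  seen <- integer(0)
  # iterative postorder over internal nodes
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    for (c in c(tr$kid1[v], tr$kid2[v])) {
      if (c > tr$ntip) stack <- c(stack, c)
    }
  }
  post <- rev(seen)
  children <- setNames(lapply(post, function(v) c(tr$kid1[v], tr$kid2[v])),
                       post)
  list(ntip = tr$ntip, labels = tr$labels, post = post, children = children,
       parent = tr$par, root = tr$root, nnode = nn)
}

.st_score <- function(tr, patM, weights) {
  sum(.fitch_engine(.st_index(tr), patM) * weights)
}

.st_replace_child <- function(tr, p, old, new) {
  if (tr$kid1[p] == old) tr$kid1[p] <- new else tr$kid2[p] <- new
  tr
}

# insert tip (or a floating internal node m carrying a subtree) on the edge
# above node c
.st_insert_tip <- function(tr, tip, c, m) {
  p <- tr$par[c]
  tr <- .st_replace_child(tr, p, c, m)
  tr$par[m] <- p
  tr$kid1[m] <- c
  tr$kid2[m] <- tip
  tr$par[c] <- m
  tr$par[tip] <- m
  tr
}

.st_nodes_in <- function(tr) {
  # nodes currently attached (search builds trees incrementally)
  out <- integer(0)
  stack <- tr$root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    if (v > tr$ntip) stack <- c(stack, tr$kid1[v], tr$kid2[v])
  }
  out
}

.st_descendant_tips <- function(tr, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= tr$ntip) out <- c(out, x) else stack <- c(stack, tr$kid1[x], tr$kid2[x])
  }
  out
}

.st_newick_node <- function(tr, v) {
  if (v <= tr$ntip) return(tr$labels[v])
  a <- .st_newick_node(tr, tr$kid1[v])
  b <- .st_newick_node(tr, tr$kid2[v])
  paste0("(", a, ",", b, ")")
}

.st_to_phylo <- function(tr) {
  ape::read.tree(text = paste0(.st_newick_node(tr, tr$root), ";"))
}

.st_canonical_node <- function(tr, v) {
  if (v <= tr$ntip) return(list(str = tr$labels[v], min = v))
  a <- .st_canonical_node(tr, tr$kid1[v])
  b <- .st_canonical_node(tr, tr$kid2[v])
  if (a$min > b$min) { tmp <- a; a <- b; b <- tmp }
  list(str = paste0("(", a$str, ",", b$str, ")"), min = min(a$min, b$min))
}

.st_canonical <- function(tr) .st_canonical_node(tr, tr$root)$str

.phylo_to_st <- function(phy, labels) {
  # anchored form: reroot so tip labels[1] is the root's first child
  phy <- ape::root(ape::unroot(phy), outgroup = labels[1], resolve.root = TRUE)
  if (!ape::is.binary(phy)) stop("tree must be binary")
  ntip <- length(labels)
  tr <- .st_new(ntip, labels)
  map <- integer(ntip + phy$Nnode)
  map[seq_len(ntip)] <- match(phy$tip.label, labels)
  nxt <- ntip + 2L
  for (v in unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])) {
    map[v] <- if (v == ntip + 1L) tr$root else { id <- nxt; nxt <- nxt + 1L; id }
  }
  for (i in seq_len(nrow(phy$edge))) {
    p <- map[phy$edge[i, 1]]
    c <- map[phy$edge[i, 2]]
    tr$par[c] <- p
    if (tr$kid1[p] == 0L) tr$kid1[p] <- c else tr$kid2[p] <- c
  }
  # enforce anchor as first child of root
  anchor <- 1L
  if (tr$kid1[tr$root] != anchor) {
    if (tr$kid2[tr$root] != anchor) stop("internal error: anchor not at root")
    tmp <- tr$kid1[tr$root]
    tr$kid1[tr$root] <- anchor
    tr$kid2[tr$root] <- tmp
  }
  tr
}

# ---- neighborhoods -------------------------------------------------------

.st_nni_neighbors <- function(tr) {
  out <- list()
  for (v in .st_nodes_in(tr)) {
    if (v <= tr$ntip || v == tr$root) next
    p <- tr$par[v]
    if (p == tr$root) next
    s <- if (tr$kid1[p] == v) tr$kid2[p] else tr$kid1[p]
    for (child in c(tr$kid1[v], tr$kid2[v])) {
      nb <- tr
      nb <- .st_replace_child(nb, p, s, child)
      nb <- .st_replace_child(nb, v, child, s)
      nb$par[s] <- v
      nb$par[child] <- p
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

.st_spr_neighbors <- function(tr) {
  out <- list()
  nodes <- .st_nodes_in(tr)
  for (v in nodes) {
    if (v == tr$root) next
    p <- tr$par[v]
    if (p == tr$root) next
    g <- tr$par[p]
    w <- if (tr$kid1[p] == v) tr$kid2[p] else tr$kid1[p]
    base <- .st_replace_child(tr, g, p, w)
    base$par[w] <- g
    sub_tips <- .st_descendant_tips(tr, v)
    in_sub <- logical(2L * tr$ntip - 1L)
    in_sub[sub_tips] <- TRUE
    if (v > tr$ntip) {
      stack <- v
      while (length(stack) > 0) {
        x <- stack[length(stack)]; stack <- stack[-length(stack)]
        in_sub[x] <- TRUE
        if (x > tr$ntip) stack <- c(stack, tr$kid1[x], tr$kid2[x])
      }
    }
    for (c in nodes) {
      if (c == tr$root || in_sub[c] || c == w || c == p || c == 1L) next
      nb <- .st_insert_tip(base, v, c, p)
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

.st_neighbors <- function(tr, swap) {
  switch(tolower(swap),
         nni = .st_nni_neighbors(tr),
         spr = .st_spr_neighbors(tr),
         tbr = .st_spr_neighbors(tr),   # TBR falls back to the SPR set
         stop("unknown swap type: ", swap))
}

# ---- search --------------------------------------------------------------

#' Search configuration
#'
#' @param n_addition_replicates number of random addition sequences.
#' @param swap branch-swapping neighborhood: `"nni"`, `"spr"` or `"tbr"`
#'   (the latter uses the SPR neighborhood).
#' @param seed integer seed; fixing it makes the search reproducible.
#' @param keep_all_optimal collect all distinct optimal topologies found.
#' @param max_trees cap on the number of stored optimal trees.
#' @return a `search_config` list.
#' @export
search_config <- function(n_addition_replicates = 10, swap = "spr", seed = 1L,
                          keep_all_optimal = TRUE, max_trees = 100L) {
  stopifnot(n_addition_replicates >= 1, max_trees >= 1)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 swap = swap, seed = as.integer(seed),
                 keep_all_optimal = isTRUE(keep_all_optimal),
                 max_trees = as.integer(max_trees)),
            class = "search_config")
}

.prepare_patterns <- function(matrix, labels) {
  cells <- .as_cells(matrix)[labels, , drop = FALSE]
  mm <- .matrix_masks(cells, labels)
  pat <- .compress_patterns(mm$M)
  pat
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise-addition starting trees followed by first-improvement
#' branch swapping; all distinct equally optimal topologies encountered are
#' collected (up to `max_trees`), including an equal-length plateau sweep
#' around the optima.  Deterministic given `config$seed`.
#'
#' @param matrix a `combined_matrix`, `morph_matrix` or character matrix
#'   (rows = taxa) with at least 4 taxa.
#' @param config a [search_config()].
#' @return list with `trees` (list of unrooted `phylo`), `length` (best
#'   parsimony score) and `replicate_lengths`.
#' @export
mp_search <- function(matrix, config = search_config()) {
  cells <- .as_cells(matrix)
  labels <- rownames(cells)
  n <- length(labels)
  if (n < 4) stop("mp_search needs at least 4 taxa")
  set.seed(config$seed)
  pat <- .prepare_patterns(matrix, labels)
  score <- function(tr) .st_score(tr, pat$M, pat$weights)
  pool <- list()          # canonical string -> struct
  best <- Inf
  rep_lengths <- numeric(config$n_addition_replicates)
  add_pool <- function(tr, len) {
    if (len < best) {
      best <<- len
      pool <<- list()
    }
    if (len == best && length(pool) < config$max_trees) {
      key <- .st_canonical(tr)
      if (is.null(pool[[key]])) pool[[key]] <<- tr
    }
  }
  for (rep in seq_len(config$n_addition_replicates)) {
    tr <- .st_addition_tree(labels, pat, score)
    res <- .st_hill_climb(tr, score, config$swap)
    rep_lengths[rep] <- res$length
    add_pool(res$tree, res$length)
  }
  if (config$keep_all_optimal) {
    # plateau sweep: collect distinct equal-length neighbors of the optima
    frontier <- pool
    guard <- 0L
    while (length(frontier) > 0 && length(pool) < config$max_trees &&
           guard < 25L) {
      guard <- guard + 1L
      new_frontier <- list()
      for (tr in frontier) {
        for (nb in .st_neighbors(tr, config$swap)) {
          len <- score(nb)
          if (len < best) {
            res <- .st_hill_climb(nb, score, config$swap)
            add_pool(res$tree, res$length)
            new_frontier <- pool
          } else if (len == best) {
            key <- .st_canonical(nb)
            if (is.null(pool[[key]]) && length(pool) < config$max_trees) {
              pool[[key]] <- nb
              new_frontier[[key]] <- nb
            }
          }
        }
      }
      frontier <- new_frontier
    }
  }
  trees <- lapply(pool, function(tr) ape::unroot(.st_to_phylo(tr)))
  names(trees) <- NULL
  list(trees = trees, length = as.integer(best),
       replicate_lengths = as.integer(rep_lengths))
}

.st_addition_tree <- function(labels, pat, score) {
  n <- length(labels)
  order <- c(1L, sample(2:n))
  tr <- .st_new(n, labels)
  root <- tr$root
  tr$kid1[root] <- order[1]
  tr$kid2[root] <- order[2]
  tr$par[order[1]] <- root
  tr$par[order[2]] <- root
  nxt <- n + 2L
  for (i in 3:n) {
    tip <- order[i]
    candidates <- setdiff(.st_nodes_in(tr), c(root, 1L))
    best_len <- Inf
    best_trees <- list()
    for (c in candidates) {
      cand <- .st_insert_tip(tr, tip, c, nxt)
      len <- score(cand)
      if (len < best_len) {
        best_len <- len
        best_trees <- list(cand)
      } else if (len == best_len) {
        best_trees[[length(best_trees) + 1L]] <- cand
      }
    }
    tr <- best_trees[[sample.int(length(best_trees), 1)]]
    nxt <- nxt + 1L
  }
  tr
}

.st_hill_climb <- function(tr, score, swap) {
  len <- score(tr)
  repeat {
    improved <- FALSE
    nbs <- .st_neighbors(tr, swap)
    if (length(nbs) > 1) nbs <- nbs[sample.int(length(nbs))]
    for (nb in nbs) {
      nl <- score(nb)
      if (nl < len) {
        tr <- nb
        len <- nl
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = tr, length = len)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (by recursive stepwise
#' addition) and returns all optimal trees.  Feasible up to about 9 taxa
#' ((2n-5)!! topologies); used as the independent oracle for [mp_search()].
#'
#' @inheritParams mp_search
#' @return list with `trees`, `length` and `n_topologies` examined.
#' @export
exhaustive_search <- function(matrix) {
  cells <- .as_cells(matrix)
  labels <- rownames(cells)
  n <- length(labels)
  if (n < 4) stop("need at least 4 taxa")
  if (n > 9) stop("exhaustive search limited to 9 taxa")
  pat <- .prepare_patterns(matrix, labels)
  best <- Inf
  out <- list()
  count <- 0L
  recurse <- function(tr, nxt, i) {
    if (i > n) {
      count <<- count + 1L
      len <- .st_score(tr, pat$M, pat$weights)
      if (len < best) {
        best <<- len
        out <<- list()
      }
      if (len == best) out[[.st_canonical(tr)]] <<- tr
      return(invisible())
    }
    for (c in setdiff(.st_nodes_in(tr), c(tr$root, 1L))) {
      recurse(.st_insert_tip(tr, i, c, nxt), nxt + 1L, i + 1L)
    }
  }
  tr <- .st_new(n, labels)
  tr$kid1[tr$root] <- 1L
  tr$kid2[tr$root] <- 2L
  tr$par[1:2] <- tr$root
  recurse(tr, n + 2L, 3L)
  list(trees = lapply(unname(out), function(t) ape::unroot(.st_to_phylo(t))),
       length = as.integer(best), n_topologies = count)
}

# ---- collapsing, consensus, rooting --------------------------------------

#' Collapse unsupported branches
#'
#' Contracts every internal branch whose minimum possible number of changes
#' over all most-parsimonious reconstructions is zero (the conservative
#' "may be zero length" rule, applied simultaneously to all such branches
#' of the binary input tree).  Headline tree lengths are always those of
#' binary trees; rescoring a collapsed tree softly can exceed them, because
#' two branches may each admit a change-free reconstruction without any
#' single reconstruction freeing both.
#'
#' @param tree a binary `phylo` (rooted or unrooted).
#' @param matrix matrix the tree was scored against.
#' @return a `phylo`, possibly with polytomies, unrooted.
#' @export
collapse_unsupported <- function(tree, matrix) {
  cells <- .as_cells(matrix)
  labels <- tree$tip.label
  cellsub <- cells[labels, , drop = FALSE]
  # informative unique column patterns
  cols <- lapply(seq_len(ncol(cellsub)), function(j) {
    setNames(cellsub[, j], labels)
  })
  keys <- vapply(cols, paste, character(1), collapse = "\r")
  cols <- cols[!duplicated(keys)]
  phy <- ape::root(ape::unroot(tree), outgroup = labels[1],
                   resolve.root = TRUE)
  index <- .tree_index(phy)
  ntip <- index$ntip
  free <- rep(TRUE, index$nnode)
  for (col in cols) {
    ca <- .column_allowed(col, index$labels)
    if (length(ca$alphabet) < 2) next
    res <- .sankoff_column(index, ca$allowed, length(ca$alphabet))
    free <- free & (res$edge_free | is.na(res$edge_free))
  }
  cand <- which(free)
  cand <- cand[cand > ntip & cand != index$root &
                 index$parent[cand] != index$root]
  if (length(cand) > 0) {
    el <- rep(1, nrow(phy$edge))
    el[phy$edge[, 2] %in% cand] <- 0
    phy$edge.length <- el
    phy <- ape::di2multi(phy, tol = 0.5)
  }
  phy$edge.length <- NULL
  ape::unroot(phy)
}

#' Strict consensus of a set of trees
#'
#' The consensus contains exactly the bipartitions present in every input
#' tree.
#'
#' @param trees list (or `multiPhylo`) of trees over identical leaf sets.
#' @return an unrooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(lapply(sets, paste, collapse = "\r"))) != 1) {
    stop("strict_consensus requires identical leaf sets")
  }
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' Root a tree on an outgroup taxon
#'
#' @param tree a `phylo`.
#' @param outgroup tip label to place as sister to all remaining taxa.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
}

# ---- bootstrap -----------------------------------------------------------

.split_keys <- function(phy, labels) {
  # nontrivial splits as sorted label strings of the side not containing
  # the anchor (labels[1])
  tr <- tryCatch(.phylo_to_st(phy, labels), error = function(e) NULL)
  if (is.null(tr)) {
    # non-binary tree: use clade sets from a rooted copy
    phy2 <- ape::root(ape::unroot(phy), outgroup = labels[1],
                      resolve.root = TRUE)
    idx <- .tree_index(phy2)
    keys <- character(0)
    for (v in idx$post) {
      tips <- phy2$tip.label[.phylo_clade_tips(idx, v)]
      if (labels[1] %in% tips) tips <- setdiff(labels, tips)
      if (length(tips) >= 2 && length(tips) <= length(labels) - 2) {
        keys <- c(keys, paste(sort(tips), collapse = "|"))
      }
    }
    return(unique(keys))
  }
  keys <- character(0)
  for (v in .st_nodes_in(tr)) {
    if (v <= tr$ntip || v == tr$root || tr$par[v] == tr$root) next
    tips <- sort(tr$labels[.st_descendant_tips(tr, v)])
    if (length(tips) >= 2 && length(tips) <= tr$ntip - 2L) {
      keys <- c(keys, paste(tips, collapse = "|"))
    }
  }
  unique(keys)
}

.phylo_clade_tips <- function(idx, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= idx$ntip) out <- c(out, x)
    else stack <- c(stack, idx$children[[as.character(x)]])
  }
  out
}

#' Nonparametric bootstrap support for bipartitions
#'
#' Per replicate, resamples all matrix columns with replacement, runs a
#' reduced search (one addition sequence, NNI swapping), and credits each
#' nontrivial split fractionally when the replicate holds several optimal
#' trees.  Deterministic given `config$seed`.
#'
#' @param matrix the combined matrix.
#' @param config a [search_config()]; its seed drives all resampling.
#' @param n_reps number of bootstrap replicates.
#' @return a data frame with columns `split` (pipe-separated labels of the
#'   side away from the first taxon) and `percent`.
#' @export
bootstrap_support <- function(matrix, config = search_config(), n_reps = 100) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  cells <- .as_cells(matrix)
  labels <- rownames(cells)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  credit <- list()
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(cells), ncol(cells), replace = TRUE)
    boot_cells <- cells[, idx, drop = FALSE]
    colnames(boot_cells) <- paste0("c", seq_len(ncol(boot_cells)))
    cfg <- search_config(n_addition_replicates = 1, swap = "nni",
                         seed = rep_seeds[r], keep_all_optimal = TRUE,
                         max_trees = 16L)
    res <- mp_search(boot_cells, cfg)
    ntrees <- length(res$trees)
    seen <- list()
    for (t in res$trees) {
      for (key in .split_keys(t, labels)) {
        seen[[key]] <- (if (is.null(seen[[key]])) 0 else seen[[key]]) + 1 / ntrees
      }
    }
    for (key in names(seen)) {
      credit[[key]] <- (if (is.null(credit[[key]])) 0 else credit[[key]]) +
        min(1, seen[[key]])
    }
  }
  if (length(credit) == 0) {
    return(data.frame(split = character(0), percent = numeric(0)))
  }
  out <- data.frame(split = names(credit),
                    percent = 100 * unlist(credit) / n_reps,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$percent, out$split), , drop = FALSE]
}

#' Attach bootstrap percentages to a tree's internal nodes
#'
#' @param tree a `phylo`.
#' @param support data frame from [bootstrap_support()].
#' @param min_percent only label nodes at or above this support.
#' @return the tree with `node.label` set (empty where below threshold).
#' @export
apply_support <- function(tree, support, min_percent = 50) {
  labels <- sort(tree$tip.label)
  anchor <- labels[1]
  phy <- ape::root(ape::unroot(tree), outgroup = anchor, resolve.root = TRUE)
  idx <- .tree_index(phy)
  node_lab <- rep("", phy$Nnode)
  lookup <- setNames(support$percent, support$split)
  for (v in idx$post) {
    tips <- phy$tip.label[.phylo_clade_tips(idx, v)]
    if (anchor %in% tips) tips <- setdiff(labels, tips)
    key <- paste(sort(tips), collapse = "|")
    pct <- lookup[key]
    if (!is.na(pct) && pct >= min_percent) {
      node_lab[v - idx$ntip] <- sprintf("%.0f", pct)
    }
  }
  phy$node.label <- node_lab
  phy
}
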