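# Equal-weights unordered parsimony: Fitch lengths on (multifurcating)
# trees via Hartigan-style state counting, and a uniform-cost Sankoff
# dynamic program for most-parsimonious-reconstruction (MPR) state sets
# and per-edge forced-change queries.

# ---- tree indexing -------------------------------------------------------

.tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  po <- ape::reorder.phylo(phy, "postorder")
  post <- unique(po$edge[, 1])
  children <- split(po$edge[, 2], po$edge[, 1])
  parent <- integer(max(po$edge))
  parent[po$edge[, 2]] <- po$edge[, 1]
  root <- post[length(post)]
  list(ntip = length(phy$tip.label), labels = phy$tip.label,
       post = post, children = children, parent = parent, root = root,
       nnode = max(po$edge))
}

# ---- column encodings ----------------------------------------------------

# Encode one column (named by taxon) over its observed alphabet.
# Symbols not in the alphabet (?, -, N, ambiguity codes) become full masks:
# gaps and inapplicable cells are scored as missing, ambiguity collapses to
# missing.  Returns tip masks in the order of `labels` plus the alphabet.
.column_alphabet <- function(values, declared = NULL) {
  obs <- setdiff(unique(values), c("?", "-", "N", "n", NA))
  if (!is.null(declared)) obs <- union(declared, obs)
  obs <- sort(obs)
  if (length(obs) == 0) obs <- "0"          # wholly missing column
  if (length(obs) > 30) stop("column alphabet too large for bitmask scoring")
  obs
}

.column_masks <- function(values, labels, declared = NULL) {
  if (is.null(names(values))) stop("column must be named by taxon")
  if (!all(labels %in% names(values))) {
    stop("leaf without data: ", paste(setdiff(labels, names(values)), collapse = ", "))
  }
  values <- toupper(as.character(values[labels]))
  alpha <- .column_alphabet(values, declared)
  full <- bitwShiftL(1L, length(alpha)) - 1L
  idx <- match(values, alpha)
  masks <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  list(masks = as.integer(masks), alphabet = alpha)
}

# Build a tips x sites mask matrix (plus per-site alphabets) from a
# character matrix of cells (rows taxa, cols sites).
.matrix_masks <- function(cells, labels) {
  S <- ncol(cells)
  M <- matrix(0L, length(labels), S)
  alphabets <- vector("list", S)
  for (j in seq_len(S)) {
    cm <- .column_masks(setNames(cells[, j], rownames(cells)), labels)
    M[, j] <- cm$masks
    alphabets[[j]] <- cm$alphabet
  }
  list(M = M, alphabets = alphabets)
}

# ---- Fitch engine --------------------------------------------------------

# Per-site minimum change counts; exact on binary trees, and the soft
# (resolve-free) generalized counting rule on multifurcations.
.fitch_engine <- function(index, tipmask) {
  S <- ncol(tipmask)
  maxk <- 0L
  masks <- matrix(0L, index$nnode, S)
  masks[seq_len(index$ntip), ] <- tipmask
  maxbit <- max(tipmask)
  while (bitwShiftL(1L, maxk) <= maxbit) maxk <- maxk + 1L
  len <- integer(S)
  for (v in index$post) {
    kids <- index$children[[as.character(v)]]
    m <- length(kids)
    K <- integer(S)
    newmask <- integer(S)
    for (s in seq_len(maxk) - 1L) {
      bit <- bitwShiftL(1L, s)
      cnt <- integer(S)
      for (c in kids) cnt <- cnt + as.integer(bitwAnd(masks[c, ], bit) > 0L)
      gt <- cnt > K
      eqv <- (cnt == K) & (cnt > 0L)
      newmask <- ifelse(gt, bit, newmask + bit * eqv)
      K <- pmax(K, cnt)
    }
    len <- len + (m - K)
    masks[v, ] <- newmask
  }
  len
}

#' Fitch parsimony length of a single character on a tree
#'
#' Minimum number of unordered state changes needed to explain one column
#' of data on a tree.  Missing (`?`) and inapplicable (`-`) cells (and any
#' nucleotide ambiguity symbol) carry no information and force no change.
#' Unrooted trees are scored as given (the length is invariant under
#' rooting); multifurcations are scored softly.
#'
#' @param tree an `ape::phylo` tree whose tips are all scored in `column`.
#' @param column named character vector mapping taxon label to a state
#'   symbol.
#' @return non-negative integer.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_length(tr, c(A = "0", B = "0", C = "1", D = "1"))  # 1
#' @export
fitch_length <- function(tree, column) {
  index <- .tree_index(tree)
  cm <- .column_masks(column, index$labels)
  as.integer(.fitch_engine(index, matrix(cm$masks, ncol = 1)))
}

#' Total parsimony tree length of a matrix
#'
#' Sum of per-column Fitch lengths under equal weights.  Site patterns are
#' compressed before scoring.
#'
#' @param tree an `ape::phylo`; its tips must be a subset of the matrix
#'   taxa.
#' @param matrix a `combined_matrix`, a `morph_matrix`, or a plain character
#'   matrix with taxa as rownames.
#' @return non-negative integer.
#' @export
tree_length <- function(tree, matrix) {
  cells <- .as_cells(matrix)
  index <- .tree_index(tree)
  if (!all(index$labels %in% rownames(cells))) {
    stop("tree tips missing from matrix: ",
         paste(setdiff(index$labels, rownames(cells)), collapse = ", "))
  }
  mm <- .matrix_masks(cells, index$labels)
  pat <- .compress_patterns(mm$M)
  sum(.fitch_engine(index, pat$M) * pat$weights)
}

.compress_patterns <- function(M) {
  keys <- apply(M, 2, paste, collapse = ",")
  first <- !duplicated(keys)
  w <- as.integer(table(factor(keys, levels = keys[first])))
  list(M = M[, first, drop = FALSE], weights = w)
}

.as_cells <- function(matrix) {
  if (inherits(matrix, "combined_matrix")) return(combined_cells(matrix))
  if (inherits(matrix, "morph_matrix")) return(matrix$cells)
  if (is.matrix(matrix)) {
    storage.mode(matrix) <- "character"
    return(matrix)
  }
  stop("unsupported matrix type")
}

# ---- uniform-cost Sankoff ------------------------------------------------

# Down-pass / up-pass dynamic program over one column.
# allowed: list per tip (index order) of 1-based allowed state indices.
# Returns min length, per-node MPR sets, and per-edge minimum free cost
# (whether the edge parent(v) -> v admits a change-free MP reconstruction).
.sankoff_column <- function(index, allowed, k) {
  nn <- index$nnode
  INF <- 1e9
  down <- matrix(INF, nn, k)
  for (i in seq_len(index$ntip)) down[i, allowed[[i]]] <- 0
  post <- index$post
  for (v in post) {
    kids <- index$children[[as.character(v)]]
    acc <- numeric(k)
    for (c in kids) {
      mc <- min(down[c, ])
      acc <- acc + pmin(down[c, ], mc + 1)
    }
    down[v, ] <- acc
  }
  root <- index$root
  L <- min(down[root, ])
  up <- matrix(INF, nn, k)
  up[root, ] <- 0
  edge_free <- rep(NA, nn)        # indexed by child node
  edge_pin <- matrix(NA_real_, nn, k)  # both edge endpoints pinned to s
  for (v in rev(post)) {
    kids <- index$children[[as.character(v)]]
    # transformed child contributions at v
    tc <- lapply(kids, function(c) {
      mc <- min(down[c, ])
      pmin(down[c, ], mc + 1)
    })
    total_tc <- Reduce(`+`, tc)
    for (i in seq_along(kids)) {
      c <- kids[i]
      contrib <- up[v, ] + total_tc - tc[[i]]
      up[c, ] <- pmin(contrib, min(contrib) + 1)
      edge_pin[c, ] <- contrib + down[c, ]
      edge_free[c] <- min(edge_pin[c, ]) <= L
    }
  }
  total <- down + up
  mpr <- total <= L + 1e-9
  # leaves report their observed/allowed sets verbatim
  for (i in seq_len(index$ntip)) {
    mpr[i, ] <- FALSE
    mpr[i, allowed[[i]]] <- TRUE
  }
  list(length = L, mpr = mpr, edge_free = edge_free, total = total,
       edge_pin = edge_pin)
}

# min length with both endpoints of edge (parent(v), v) pinned to state s
.sankoff_pin_edge <- function(index, allowed, k, v, s) {
  res <- .sankoff_column(index, allowed, k)
  as.integer(res$edge_pin[v, s])
}

# constrained minimum: best length over reconstructions with node v pinned
# to state s (1-based index into the column alphabet)
.sankoff_column_pinned <- function(index, allowed, k, v, s) {
  res <- .sankoff_column(index, allowed, k)
  as.integer(res$total[v, s])
}

.column_allowed <- function(values, labels, declared = NULL) {
  values <- toupper(as.character(values[labels]))
  alpha <- .column_alphabet(values, declared)
  idx <- match(values, alpha)
  allowed <- lapply(idx, function(i) if (is.na(i)) seq_along(alpha) else i)
  list(allowed = allowed, alphabet = alpha)
}

#' MPR state sets for one character on a rooted tree
#'
#' For every node, the set of states that appear at that node in at least
#' one most-parsimonious reconstruction under the unordered model, computed
#' by a down-pass/up-pass dynamic program.  Leaves report their observed
#' state (or the full state set when missing/inapplicable).
#'
#' @param tree rooted `ape::phylo`.
#' @param column named character vector of states per taxon.
#' @return list with `length` (the minimum number of changes) and `states`,
#'   a list (indexed by node number, tips first as in `ape`) of character
#'   vectors of state symbols.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' mpr_sets(tr, c(A = "0", B = "1", C = "0", D = "1"))$states[[5]]  # root: "0" "1"
#' @export
mpr_sets <- function(tree, column) {
  if (!ape::is.rooted(tree)) stop("mpr_sets requires a rooted tree")
  index <- .tree_index(tree)
  ca <- .column_allowed(column, index$labels)
  res <- .sankoff_column(index, ca$allowed, length(ca$alphabet))
  states <- apply(res$mpr, 1, function(row) ca$alphabet[row], simplify = FALSE)
  list(length = as.integer(res$length), states = states,
       alphabet = ca$alphabet)
}

# Brute-force oracle: exhaustive enumeration over internal labelings.
# Exported for use in tests and method validation on tiny trees only.
#' Exhaustive parsimony oracle (tiny trees)
#'
#' Enumerates all internal-node labelings to find the minimum number of
#' changes and the exact MPR set per node.  Exponential; intended as an
#' independent check of [fitch_length()] and [mpr_sets()] on trees with at
#' most about 7 tips.
#'
#' @inheritParams mpr_sets
#' @return list with `length` and `states` as in [mpr_sets()].
#' @export
enumerate_parsimony <- function(tree, column) {
  index <- .tree_index(tree)
  ca <- .column_allowed(column, index$labels)
  k <- length(ca$alphabet)
  internals <- index$post
  ni <- length(internals)
  if (k^ni > 5e6) stop("enumeration too large")
  best <- Inf
  sets <- vector("list", index$nnode)
  assign_states <- rep(1L, ni)
  repeat {
    lab <- integer(index$nnode)
    lab[internals] <- assign_states
    # cost: for each tip, 0 if parent-state consistent choice exists
    cost <- 0
    for (i in seq_len(index$ntip)) {
      p <- index$parent[i]
      if (!(lab[p] %in% ca$allowed[[i]])) cost <- cost + 1
    }
    for (v in internals) {
      p <- index$parent[v]
      if (p != 0 && lab[p] != lab[v]) cost <- cost + 1
    }
    if (cost < best) {
      best <- cost
      sets <- vector("list", index$nnode)
    }
    if (cost == best) {
      for (v in internals) sets[[v]] <- union(sets[[v]], lab[v])
    }
    # next assignment
    j <- 1
    while (j <= ni && assign_states[j] == k) {
      assign_states[j] <- 1L
      j <- j + 1
    }
    if (j > ni) break
    assign_states[j] <- assign_states[j] + 1L
  }
  states <- vector("list", index$nnode)
  for (i in seq_len(index$ntip)) states[[i]] <- ca$alphabet[ca$allowed[[i]]]
  for (v in internals) states[[v]] <- ca$alphabet[sort(sets[[v]])]
  list(length = as.integer(best), states = states, alphabet = ca$alphabet)
}
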