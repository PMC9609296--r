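# Synthetic data: Yule trees, dependency-respecting morphological
# characters with recorded ancestral truth, GTR+G+I nucleotide partitions,
# and a miniature end-to-end fixture study.  Everything is reproducible
# from one seed, so the whole pipeline is testable with no download.

#' Simulation configuration
#'
#' Defaults mirror the study's stated world: four partitions of 671, 657,
#' 426 and 328 bp (2082 sites), GTR+G+I site evolution, and a morphology
#' block of hierarchically coded discrete characters.  GTR parameters are
#' not printed in the study; the defaults are a transition-biased,
#' AT-rich parameterization typical of arthropod mitochondrial data
#' (exchangeabilities AC,AG,AT,CG,CT,GT = 1,4,1,1,4,1; frequencies
#' A,C,G,T = 0.3,0.2,0.2,0.3; gamma shape 0.5; invariant fraction 0.3).
#'
#' @param n_taxa number of tips (>= 4).
#' @param seed integer seed.
#' @param birth_rate Yule speciation rate per unit time.
#' @param morph list: `n_char`, `k` states, `rate` expected changes per
#'   unit branch length, `dependencies` (data frame `char`, `controller`,
#'   `controlling_state`).
#' @param mol list: `lengths` (named partition lengths), `rates`
#'   (6 GTR exchangeabilities), `freqs` (4 base frequencies), `alpha`
#'   (gamma shape), `p_inv` (invariant fraction), `scale` (tree scaling,
#'   expected substitutions per unit branch length).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 34, seed = 1L, birth_rate = 1,
                       morph = list(), mol = list()) {
  stopifnot(n_taxa >= 4, birth_rate > 0)
  morph_def <- list(n_char = 59, k = 2L, rate = 0.3,
                    dependencies = data.frame(char = integer(0),
                                              controller = integer(0),
                                              controlling_state = integer(0)))
  morph_def[names(morph)] <- morph
  mol_def <- list(lengths = c("16S" = 671L, "COI" = 657L,
                              "NADH1" = 426L, "H3" = 328L),
                  rates = c(1, 4, 1, 1, 4, 1),
                  freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                  alpha = 0.5, p_inv = 0.3, scale = 0.1)
  mol_def[names(mol)] <- mol
  if (abs(sum(mol_def$freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (any(mol_def$lengths <= 0)) stop("partition lengths must be positive")
  if (morph_def$rate < 0) stop("rates must be non-negative")
  structure(list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 birth_rate = birth_rate, morph = morph_def, mol = mol_def),
            class = "sim_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree conditioned on the number of tips, with tips relabelled
#' `T1..Tn`.
#'
#' @param config a [sim_config()].
#' @return rooted binary `phylo` with branch lengths.
#' @export
simulate_tree <- function(config) {
  if (config$n_taxa < 4) stop("n_taxa must be >= 4")
  set.seed(config$seed)
  phy <- ape::rphylo(config$n_taxa, birth = config$birth_rate, death = 0)
  phy$tip.label <- paste0("T", seq_len(config$n_taxa))
  phy
}

# symmetric k-state Markov chain along one branch by uniformization;
# returns new state and the number of real changes
.mk_branch <- function(state, k, rate, len) {
  lambda <- rate * k / (k - 1)
  nev <- stats::rpois(1, lambda * len)
  changes <- 0L
  for (i in seq_len(nev)) {
    new <- sample.int(k, 1) - 1L
    if (new != state) changes <- changes + 1L
    state <- new
  }
  list(state = state, changes = changes)
}

#' Simulate morphological characters with hierarchical applicability
#'
#' Each character evolves under a symmetric k-state Markov chain along the
#' tree.  Controllers are simulated first; wherever a taxon's controller
#' score lies in the controlling state set, the dependent character is
#' masked to `-` (its hidden evolution is discarded).  The emitted matrix
#' always passes [validate_matrix()] against the returned catalog.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param config a [sim_config()]; `config$morph$dependencies` must be
#'   acyclic.
#' @return list with `matrix` (a `morph_matrix`), `truth` (true tree, true
#'   node states, per-branch change counts) and `catalog` (a matching
#'   `character_catalog`).
#' @export
simulate_morphology <- function(tree, config) {
  m <- config$morph
  set.seed(config$seed + 1L)
  deps <- m$dependencies
  catalog <- .sim_catalog(m)
  order <- catalog_topo_order(catalog)
  index <- .tree_index(tree)
  nn <- index$nnode
  pre <- rev(index$post)
  edge_len <- numeric(nn)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_len[po$edge[, 2]] <- po$edge.length
  node_states <- matrix(0L, nn, m$n_char)
  branch_changes <- matrix(0L, nn, m$n_char)   # indexed by child node
  for (j in seq_len(m$n_char)) {
    node_states[index$root, j] <- sample.int(m$k, 1) - 1L
    for (v in pre) {
      for (c in index$children[[as.character(v)]]) {
        r <- .mk_branch(node_states[v, j], m$k, m$rate, edge_len[c])
        node_states[c, j] <- r$state
        branch_changes[c, j] <- r$changes
      }
    }
  }
  cells <- matrix(as.character(node_states[seq_len(index$ntip), , drop = FALSE]),
                  index$ntip, m$n_char,
                  dimnames = list(index$labels, as.character(seq_len(m$n_char))))
  # mask dependents, controllers first
  for (id in order) {
    ch <- catalog$characters[[as.character(id)]]
    for (cond in ch$inapplicable_if) {
      ctrl <- as.character(cond$controller)
      hit <- cells[, ctrl] %in% as.character(cond$states)
      cells[hit, as.character(id)] <- "-"
    }
  }
  truth <- list(tree = tree, node_states = node_states,
                branch_changes = branch_changes,
                node_labels = c(index$labels, paste0("N", (index$ntip + 1):nn)))
  list(matrix = morph_matrix(cells), truth = truth, catalog = catalog)
}

.sim_catalog <- function(m) {
  deps <- m$dependencies
  chars <- lapply(seq_len(m$n_char), function(id) {
    sel <- deps[deps$char == id, , drop = FALSE]
    conds <- lapply(seq_len(nrow(sel)), function(i) {
      list(controller = as.integer(sel$controller[i]),
           states = as.integer(sel$controlling_state[i]))
    })
    list(char_id = id, locus = paste("simulated character", id),
         statement = paste("simulated", m$k, "state character", id),
         states = setNames(paste("state", 0:(m$k - 1)),
                           0:(m$k - 1)),
         inapplicable_if = conds)
  })
  names(chars) <- as.character(seq_len(m$n_char))
  catalog <- structure(list(characters = chars, provenance = "simulated"),
                       class = "character_catalog")
  check_catalog(catalog)
  catalog
}

#' Simulate nucleotide partitions under GTR+G+I
#'
#' Site rates are 0 with probability `p_inv` and gamma(`alpha`, `alpha`)
#' otherwise; sites evolve independently under the normalized GTR process
#' scaled by `mol$scale` substitutions per unit branch length.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param config a [sim_config()].
#' @return named list of `aligned_partition` objects in the order of
#'   `config$mol$lengths`.
#' @export
simulate_sequences <- function(tree, config) {
  mol <- config$mol
  set.seed(config$seed + 2L)
  Q <- .gtr_q(mol$rates, mol$freqs)
  eig <- .gtr_eigen(Q, mol$freqs)
  index <- .tree_index(tree)
  pre <- rev(index$post)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_len <- numeric(index$nnode)
  edge_len[po$edge[, 2]] <- po$edge.length * mol$scale
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (nm in names(mol$lengths)) {
    S <- mol$lengths[[nm]]
    rate <- ifelse(stats::runif(S) < mol$p_inv, 0,
                   stats::rgamma(S, shape = mol$alpha, rate = mol$alpha))
    states <- matrix(0L, index$nnode, S)
    states[index$root, ] <- sample.int(4, S, replace = TRUE, prob = mol$freqs)
    for (v in pre) {
      for (c in index$children[[as.character(v)]]) {
        states[c, ] <- .gtr_evolve(states[v, ], edge_len[c] * rate, eig)
      }
    }
    rows <- apply(states[seq_len(index$ntip), , drop = FALSE], 1,
                  function(s) paste(bases[s], collapse = ""))
    names(rows) <- index$labels
    out[[nm]] <- aligned_partition(nm, rows)
  }
  out
}

.gtr_q <- function(rates, freqs) {
  if (length(rates) != 6) stop("need 6 GTR exchangeabilities")
  if (any(freqs <= 0)) stop("invalid frequencies")
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- rates[c(1, 2, 4, 3, 5, 6)]  # AC,AG,AT,CG,CT,GT
  R <- R + t(R)
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

.gtr_eigen <- function(Q, freqs) {
  # symmetrize the reversible generator for a stable real decomposition
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(V = diag(1 / d) %*% e$vectors, Vinv = t(e$vectors) %*% diag(d),
       lambda = e$values)
}

.gtr_evolve <- function(parent, dist, eig) {
  S <- length(parent)
  child <- integer(S)
  E <- exp(outer(eig$lambda, dist))        # 4 x S
  for (st in 1:4) {
    sel <- which(parent == st)
    if (length(sel) == 0) next
    M <- eig$V[st, ] * E[, sel, drop = FALSE]     # 4 x m
    P <- t(M) %*% eig$Vinv                        # m x 4
    P[P < 0] <- 0
    child[sel] <- vapply(seq_along(sel), function(i) {
      sample.int(4, 1, prob = P[i, ])
    }, integer(1))
  }
  child
}

#' Build a miniature end-to-end fixture study
#'
#' A 12-taxon study with a designated "swimmer" clade whose terminals
#' satisfy the shipped morphotype rule, one within-clade loss branch whose
#' descendant reverses several swimming-leg states, an outgroup lacking
#' the median plate (so dependent characters are inapplicable), simulated
#' extra morphological characters, and four GTR+G+I partitions carrying
#' the phylogenetic signal of the true tree.
#'
#' @param seed integer seed.
#' @param part_lengths named partition lengths (defaults scaled down for
#'   fast tests).
#' @return list with `catalog`, `morph`, `partitions`, `otu_map`,
#'   `true_tree`, `rule`, `swimmer_taxa`, `loss_taxon`, `outgroup`.
#' @export
make_fixture_study <- function(seed = 1L,
                               part_lengths = c("16S" = 300L, "COI" = 300L,
                                                "NADH1" = 200L, "H3" = 150L)) {
  rule_chars <- c("7", "8", "11", "15", "16", "18", "23", "34", "42", "43",
                  "44", "45", "46", "47", "48", "50")
  full <- suppressWarnings(load_catalog())
  chars <- full$characters[rule_chars]
  n_extra <- 30L
  extra_ids <- 60:(60 + n_extra - 1L)
  for (id in extra_ids) {
    chars[[as.character(id)]] <- list(
      char_id = id, locus = paste("simulated filler character", id),
      statement = paste("simulated binary character", id),
      states = setNames(c("state 0", "state 1"), 0:1),
      inapplicable_if = list())
  }
  catalog <- structure(list(characters = chars,
                            provenance = "fixture study (synthetic)"),
                       class = "character_catalog")
  check_catalog(catalog)
  newick <- paste0(
    "(Outgroup:1,(((N1:0.2,N2:0.2):0.2,((N3:0.2,N5:0.2):0.08,N4:0.25):0.15):0.3,",
    "((S1:0.15,S2:0.15):0.2,((S3:0.1,S4:0.1):0.15,",
    "(S5:0.12,L1:0.12):0.13):0.1):0.45):0.5);")
  true_tree <- ape::read.tree(text = newick)
  taxa <- true_tree$tip.label
  swimmer_taxa <- c("S1", "S2", "S3", "S4", "S5")
  loss_taxon <- "L1"
  swimmer_row <- c("7" = "1", "8" = "1", "11" = "1", "15" = "1", "16" = "1",
                   "18" = "2", "23" = "0", "34" = "2", "42" = "0", "43" = "0",
                   "44" = "1", "45" = "1", "46" = "1", "47" = "1", "48" = "1",
                   "50" = "0")
  nonswimmer_row <- c("7" = "1", "8" = "0", "11" = "0", "15" = "0", "16" = "0",
                      "18" = "0", "23" = "1", "34" = "1", "42" = "0",
                      "43" = "1", "44" = "0", "45" = "0", "46" = "0",
                      "47" = "0", "48" = "0", "50" = "0")
  outgroup_row <- c("7" = "0", "8" = "-", "11" = "-", "15" = "-", "16" = "-",
                    "18" = "0", "23" = "-", "34" = "0", "42" = "1", "43" = "-",
                    "44" = "0", "45" = "0", "46" = "0", "47" = "0", "48" = "0",
                    "50" = "1")
  loss_row <- swimmer_row
  loss_row[c("34", "46", "47", "48")] <- c("1", "0", "0", "0")
  cells <- matrix("?", length(taxa), length(rule_chars),
                  dimnames = list(taxa, rule_chars))
  for (t in taxa) {
    cells[t, ] <- if (t %in% swimmer_taxa) swimmer_row[rule_chars]
                  else if (t == loss_taxon) loss_row[rule_chars]
                  else if (t == "Outgroup") outgroup_row[rule_chars]
                  else nonswimmer_row[rule_chars]
  }
  cfg_extra <- sim_config(n_taxa = length(taxa), seed = seed,
                          morph = list(n_char = n_extra, k = 2L, rate = 0.25))
  sim <- simulate_morphology(true_tree, cfg_extra)
  extra_cells <- sim$matrix$cells
  colnames(extra_cells) <- as.character(extra_ids)
  morph <- morph_matrix(cbind(cells, extra_cells[taxa, , drop = FALSE]))
  cfg_mol <- sim_config(n_taxa = length(taxa), seed = seed + 7L,
                        mol = list(lengths = part_lengths, scale = 0.35))
  partitions <- simulate_sequences(true_tree, cfg_mol)
  otu_map <- do.call(rbind, lapply(taxa, function(t) {
    data.frame(otu = t, gene = names(part_lengths), source_taxon = t,
               accession = "synthetic", stringsAsFactors = FALSE)
  }))
  class(otu_map) <- c("otu_map", class(otu_map))
  list(catalog = catalog, morph = morph, partitions = partitions,
       otu_map = otu_map, true_tree = true_tree, rule = load_rule(),
       swimmer_taxa = swimmer_taxa, loss_taxon = loss_taxon,
       outgroup = "Outgroup")
}
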