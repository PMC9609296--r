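# Shared helpers: tiny trees, random columns/matrices, and a cached
# fixture study (built once per test run).

quartet <- function() ape::read.tree(text = "((A,B),(C,D));")

random_column <- function(tree, k = 2, p_missing = 0.15) {
  n <- length(tree$tip.label)
  col <- as.character(sample(0:(k - 1), n, replace = TRUE))
  mask <- runif(n) < p_missing
  col[mask] <- sample(c("?", "-"), sum(mask), replace = TRUE)
  setNames(col, tree$tip.label)
}

random_cells <- function(taxa, n_char, k = 2) {
  matrix(as.character(sample(0:(k - 1), length(taxa) * n_char, replace = TRUE)),
         length(taxa), n_char, dimnames = list(taxa, NULL))
}

fixture_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_study(seed = 101)
    cache
  }
})

catalog59 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(load_catalog())
    cache
  }
})

exemplar_rows <- function() {
  tab <- read.table(system.file("extdata", "exemplar_scores_synthetic.tsv",
                                package = "swimpars"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    setNames(as.character(tab[i, -1]), colnames(tab)[-1])
  })
  names(rows) <- tab$taxon
  rows
}
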