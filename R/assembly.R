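# Supermatrix assembly: aligned gene partitions, chimeric OTU assembly
# (morphology of one species + sequences of close relatives), and
# concatenation into a combined morphology + molecular matrix with a
# partition map.  NEXUS in/out with CHARSETs.

#' Read one aligned gene partition from FASTA
#'
#' @param path aligned FASTA file; all records must have equal length.
#' @param name partition label (e.g. `"16S"`).
#' @return an `aligned_partition`: list with `name`, `length` and `rows`
#'   (named character vector of upper-case aligned sequences).
#' @export
read_alignment <- function(path, name) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    rows <- setNames(toupper(as.character(set)), names(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0) stop("not a FASTA file: ", path)
    ids <- sub("^>\\s*", "", lines[hdr])
    ends <- c(hdr[-1] - 1L, length(lines))
    rows <- setNames(vapply(seq_along(hdr), function(i) {
      toupper(paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
    }, character(1)), ids)
  }
  if (length(rows) == 0) stop("empty alignment: ", path)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    bad <- names(rows)[widths != widths[1]][1]
    stop("ragged alignment in ", path, ": record '", bad,
         "' has length ", nchar(rows[bad]), " != ", widths[1])
  }
  aligned_partition(name, rows)
}

#' @rdname read_alignment
#' @param rows named character vector of equal-length aligned sequences.
#' @export
aligned_partition <- function(name, rows) {
  widths <- unique(nchar(rows))
  stopifnot(length(widths) == 1, widths > 0)
  structure(list(name = name, length = unname(widths),
                 rows = setNames(toupper(rows), names(rows))),
            class = "aligned_partition")
}

#' Read an OTU map
#'
#' Tab-separated file with columns `otu`, `gene`, `source_taxon` (and
#' optionally `accession`).  A row with gene `NA` records an OTU that has
#' no molecular data (it still enters the analysis on morphology alone).
#' The shipped fixture transcribes the study's OTU table: 34
#' morphology-scored OTUs, 33 of which carry sequences.
#'
#' @param path map file; defaults to the shipped fixture.
#' @return an `otu_map` data frame.
#' @export
load_otu_map <- function(path = system.file("extdata", "otu_map_table1.tsv",
                                            package = "swimpars")) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", na.strings = "NA")
  keep <- !is.na(tab$gene)
  dup <- duplicated(tab[keep, c("otu", "gene")])
  if (any(dup)) {
    stop("OTU map assigns a partition twice: ",
         paste(unique(tab$otu[keep][dup]), collapse = ", "))
  }
  class(tab) <- c("otu_map", class(tab))
  tab
}

#' Assemble per-OTU molecular rows from source-taxon partitions
#'
#' For each OTU, pulls the mapped source taxon's row from each partition.
#' Genes with no mapped source become all-missing rows; OTUs with no
#' sequenced gene at all are dropped from the molecular set (they remain
#' available to the morphology block at concatenation).
#'
#' @param map an `otu_map`.
#' @param partitions list of `aligned_partition` whose rows are keyed by
#'   source taxon labels.
#' @return named list of `aligned_partition` objects re-keyed by OTU.
#' @export
assemble_otus <- function(map, partitions) {
  names(partitions) <- vapply(partitions, `[[`, character(1), "name")
  mol <- map[!is.na(map$gene), , drop = FALSE]
  unknown_gene <- setdiff(unique(mol$gene), names(partitions))
  mol <- mol[mol$gene %in% names(partitions), , drop = FALSE]
  otus <- unique(mol$otu)
  out <- lapply(partitions, function(part) {
    rows <- setNames(rep(strrep("?", part$length), length(otus)), otus)
    sel <- mol[mol$gene == part$name, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      src <- sel$source_taxon[i]
      if (!src %in% names(part$rows)) {
        stop("OTU map source taxon '", src, "' not found in partition ",
             part$name)
      }
      rows[sel$otu[i]] <- part$rows[[src]]
    }
    aligned_partition(part$name, rows)
  })
  attr(out, "otus") <- otus
  attr(out, "unmapped_genes") <- unknown_gene
  out
}

#' Concatenate morphology and molecular partitions into a combined matrix
#'
#' Taxon sets are unioned; a taxon absent from a block gets an all-`?` row
#' there (this is how a morphology-only species enters the combined
#' analysis).  The partition map records 1-based closed column intervals in
#' the order given, after the morphology block.
#'
#' @param morph a `morph_matrix` or `NULL`.
#' @param partitions list of `aligned_partition` (possibly empty).
#' @return a `combined_matrix`: list with `taxa`, `cells` (character matrix
#'   taxa x total columns), `partition_map` (named list of `c(start, end)`),
#'   `morph_width`, `total_characters`.
#' @export
concatenate <- function(morph = NULL, partitions = list()) {
  taxa <- character(0)
  if (!is.null(morph)) taxa <- morph$taxa
  for (p in partitions) taxa <- union(taxa, names(p$rows))
  if (length(taxa) == 0) stop("nothing to concatenate")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  blocks <- list()
  pmap <- list()
  pos <- 0L
  morph_width <- 0L
  if (!is.null(morph)) {
    morph_width <- ncol(morph$cells)
    blk <- matrix("?", length(taxa), morph_width,
                  dimnames = list(taxa, colnames(morph$cells)))
    blk[morph$taxa, ] <- morph$cells
    blocks[[length(blocks) + 1L]] <- blk
    pmap[["morphology"]] <- c(1L, morph_width)
    pos <- morph_width
  }
  for (p in partitions) {
    blk <- matrix("?", length(taxa), p$length, dimnames = list(taxa, NULL))
    present <- intersect(taxa, names(p$rows))
    blk[present, ] <- do.call(rbind, strsplit(unname(p$rows[present]), ""))
    colnames(blk) <- paste0(p$name, "_", seq_len(p$length))
    blocks[[length(blocks) + 1L]] <- blk
    pmap[[p$name]] <- c(pos + 1L, pos + p$length)
    pos <- pos + p$length
  }
  cells <- do.call(cbind, blocks)
  structure(list(taxa = taxa, cells = cells, partition_map = pmap,
                 morph_width = morph_width,
                 total_characters = ncol(cells)),
            class = "combined_matrix")
}

#' Cell matrix of a combined matrix
#' @param x a `combined_matrix`.
#' @return character matrix, taxa as rownames.
#' @export
combined_cells <- function(x) x$cells

#' @export
print.combined_matrix <- function(x, ...) {
  cat("combined_matrix:", length(x$taxa), "taxa x", x$total_characters,
      "characters\n")
  for (nm in names(x$partition_map)) {
    iv <- x$partition_map[[nm]]
    cat(sprintf("  %-12s %d-%d (%d)\n", nm, iv[1], iv[2], iv[2] - iv[1] + 1L))
  }
  invisible(x)
}

# ---- NEXUS in/out --------------------------------------------------------

#' Write a combined (or morphology-only) matrix as NEXUS
#'
#' Sequential DATA block with `DATATYPE=STANDARD`, explicit SYMBOLS,
#' `MISSING=?` and `GAP=-` (for the morphology block the `-` symbol carries
#' the inapplicable meaning), plus a SETS block with one CHARSET per
#' partition.
#'
#' @param x a `combined_matrix` or `morph_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  if (inherits(x, "morph_matrix")) x <- concatenate(x, list())
  cells <- x$cells
  syms <- sort(setdiff(unique(as.vector(cells)), c("?", "-")))
  lab <- gsub("[^A-Za-z0-9_.]", "_", rownames(cells))
  width <- max(nchar(lab)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cells), ncol(cells)),
               sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                       paste(syms, collapse = "")),
               "  MATRIX"), con)
  for (i in seq_len(nrow(cells))) {
    writeLines(sprintf("  %-*s%s", width, lab[i],
                       paste(cells[i, ], collapse = "")), con)
  }
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  for (nm in names(x$partition_map)) {
    iv <- x$partition_map[[nm]]
    writeLines(sprintf("  CHARSET %s = %d-%d;", nm, iv[1], iv[2]), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' Read a NEXUS matrix written by [write_nexus_matrix()]
#'
#' Parses a sequential DATA block and an optional SETS block with CHARSETs.
#'
#' @param path NEXUS file.
#' @return a `combined_matrix`.
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)[1]
  if (is.na(mstart)) stop("no MATRIX block in ", path)
  mend <- mstart + grep("^\\s*;\\s*$", up[(mstart + 1):length(up)])[1]
  rows <- lines[(mstart + 1):(mend - 1)]
  rows <- rows[nzchar(trimws(rows))]
  parts <- regmatches(rows, regexec("^\\s*(\\S+)\\s+(\\S+)\\s*$", rows))
  taxa <- vapply(parts, `[`, character(1), 2)
  seqs <- vapply(parts, `[`, character(1), 3)
  cells <- do.call(rbind, strsplit(seqs, ""))
  rownames(cells) <- taxa
  cs_lines <- grep("^\\s*CHARSET\\s", up)
  pmap <- list()
  for (i in cs_lines) {
    m <- regmatches(lines[i],
                    regexec("CHARSET\\s+(\\S+)\\s*=\\s*([0-9]+)\\s*-\\s*([0-9]+)",
                            lines[i], ignore.case = TRUE))[[1]]
    pmap[[m[2]]] <- c(as.integer(m[3]), as.integer(m[4]))
  }
  morph_width <- if ("morphology" %in% names(pmap)) {
    pmap[["morphology"]][2] - pmap[["morphology"]][1] + 1L
  } else 0L
  structure(list(taxa = taxa, cells = cells, partition_map = pmap,
                 morph_width = morph_width, total_characters = ncol(cells)),
            class = "combined_matrix")
}
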