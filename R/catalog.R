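#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

MISSING <- "?"
INAPPLICABLE <- "-"

#' Load a morphological character catalog
#'
#' Reads a structured plain-text catalog (one record per character with
#' fields `char`, `locus`, `statement`, `states`, `inapplicable_if`) into a
#' `character_catalog` object.  A character's `inapplicable_if` conditions
#' are pairs of a controlling character id and a set of controlling state
#' codes; a character is inapplicable for a taxon whenever any condition
#' matches the taxon's score on the controller.
#'
#' Invariants checked at load time: state codes are `0..k-1` with `k >= 2`,
#' character ids are unique, every controller exists, and the directed
#' controller-to-dependent graph is acyclic.  Conditions citing a state that
#' the controller does not declare are retained verbatim (they can never
#' match) and surfaced as `UNDECLARED_CONTROLLING_STATE` warnings in the
#' `warnings` attribute.
#'
#' @param source path to the catalog file.  The default is the shipped
#'   59-character catalog of brachyuran axial-skeleton, pereiopod
#'   musculature and external characters.
#' @return an object of class `character_catalog`: a list with elements
#'   `characters` (named list of character definitions) and `provenance`.
#' @examples
#' cat59 <- load_catalog()
#' length(cat59$characters)        # 59
#' cat59$characters[["12"]]$inapplicable_if
#' @export
load_catalog <- function(source = system.file("extdata", "characters_59.txt",
                                              package = "swimpars")) {
  if (!file.exists(source)) stop("catalog file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(grepl("^char:", lines)))
  blocks <- blocks[names(blocks) != "0"]
  chars <- lapply(blocks, parse_char_block)
  ids <- vapply(chars, function(ch) ch$char_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate character ids in catalog: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  names(chars) <- as.character(ids)
  catalog <- structure(list(characters = chars,
                            provenance = basename(source)),
                       class = "character_catalog")
  check_catalog(catalog)
}

parse_char_block <- function(block) {
  field <- function(name) {
    ln <- grep(paste0("^", name, ":"), block, value = TRUE)
    if (length(ln) == 0) stop("catalog parse error: missing field '", name, "'")
    trimws(sub(paste0("^", name, ":"), "", ln[1]))
  }
  id <- suppressWarnings(as.integer(field("char")))
  if (is.na(id)) stop("catalog parse error: non-integer char id")
  states_raw <- strsplit(field("states"), "|", fixed = TRUE)[[1]]
  states_raw <- trimws(states_raw)
  codes <- suppressWarnings(as.integer(sub("=.*$", "", states_raw)))
  descs <- sub("^[0-9]+=", "", states_raw)
  if (anyNA(codes)) stop("catalog parse error: bad state list for char ", id)
  if (length(codes) < 2 || !identical(sort(codes), 0:(length(codes) - 1L))) {
    stop("catalog parse error: state codes of char ", id,
         " must be 0..k-1 with k >= 2")
  }
  dep_raw <- field("inapplicable_if")
  deps <- list()
  if (nzchar(dep_raw)) {
    for (tok in trimws(strsplit(dep_raw, ",")[[1]])) {
      m <- regmatches(tok, regexec("^([0-9]+)\\(([0-9]+)\\)$", tok))[[1]]
      if (length(m) != 3) {
        stop("catalog parse error: bad condition '", tok, "' for char ", id)
      }
      deps[[length(deps) + 1L]] <- list(controller = as.integer(m[2]),
                                        states = as.integer(m[3]))
    }
  }
  list(char_id = id, locus = field("locus"), statement = field("statement"),
       states = setNames(descs, codes), inapplicable_if = deps)
}

check_catalog <- function(catalog) {
  chars <- catalog$characters
  ids <- as.integer(names(chars))
  warnings <- character(0)
  edges <- matrix(integer(0), ncol = 2)
  for (ch in chars) {
    for (cond in ch$inapplicable_if) {
      ctrl <- as.character(cond$controller)
      if (!ctrl %in% names(chars)) {
        stop("catalog error: char ", ch$char_id,
             " depends on unknown controller ", ctrl)
      }
      declared <- as.integer(names(chars[[ctrl]]$states))
      undecl <- setdiff(cond$states, declared)
      if (length(undecl) > 0) {
        warnings <- c(warnings, sprintf(
          "UNDECLARED_CONTROLLING_STATE: char %d condition %s(%s) cites a state the controller does not declare; it can never match",
          ch$char_id, ctrl, paste(undecl, collapse = ",")))
      }
      edges <- rbind(edges, c(cond$controller, ch$char_id))
    }
  }
  # cycle check on controller -> dependent edges (Kahn's algorithm)
  if (nrow(edges) > 0) {
    indeg <- setNames(integer(length(ids)), ids)
    for (i in seq_len(nrow(edges))) {
      key <- as.character(edges[i, 2])
      indeg[key] <- indeg[key] + 1L
    }
    queue <- ids[indeg[as.character(ids)] == 0L]
    seen <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      out <- edges[edges[, 1] == v, 2]
      for (w in out) {
        key <- as.character(w)
        indeg[key] <- indeg[key] - 1L
        if (indeg[key] == 0L) queue <- c(queue, w)
      }
    }
    if (seen < length(ids)) {
      cyc <- names(indeg)[indeg > 0]
      stop("catalog error: cyclic character dependencies involving chars ",
           paste(cyc, collapse = ", "))
    }
  }
  if (length(warnings) > 0) attr(catalog, "warnings") <- warnings
  for (w in warnings) warning(w, call. = FALSE)
  invisible(catalog)
}

#' Topological order of catalog characters (controllers first)
#' @param catalog a `character_catalog`.
#' @return integer vector of char ids, every controller before its dependents.
#' @export
catalog_topo_order <- function(catalog) {
  chars <- catalog$characters
  ids <- as.integer(names(chars))
  placed <- logical(length(ids)); names(placed) <- names(chars)
  order <- integer(0)
  while (length(order) < length(ids)) {
    progressed <- FALSE
    for (key in names(chars)[!placed]) {
      ctrls <- vapply(chars[[key]]$inapplicable_if,
                      function(cond) cond$controller, integer(1))
      if (all(placed[as.character(ctrls)] | !as.character(ctrls) %in% names(chars))) {
        order <- c(order, as.integer(key)); placed[key] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cyclic character dependencies")
  }
  order
}

#' Is a character applicable for a taxon's row of scores?
#'
#' A character is inapplicable when any of its `inapplicable_if` conditions
#' matches the row's score on the controlling character.  A MISSING (`?`) or
#' inapplicable (`-`) score on a controller cannot prove inapplicability, so
#' the character is treated as applicable.
#'
#' @param row named character vector of scores (names are char ids; values
#'   are state codes as character, `"?"` or `"-"`).
#' @param char_id integer id of the character to test.
#' @param catalog a `character_catalog`.
#' @return `TRUE` if applicable, `FALSE` otherwise.
#' @export
is_applicable <- function(row, char_id, catalog) {
  key <- as.character(char_id)
  ch <- catalog$characters[[key]]
  if (is.null(ch)) stop("unknown character id: ", char_id)
  for (cond in ch$inapplicable_if) {
    ctrl <- as.character(cond$controller)
    sc <- if (ctrl %in% names(row)) row[[ctrl]] else NA_character_
    if (is.na(sc)) {
      stop("row does not cover controlling character ", cond$controller)
    }
    if (sc %in% as.character(cond$states)) return(FALSE)
  }
  TRUE
}

#' Construct a morphological matrix object
#'
#' @param cells character matrix (rows = taxa, columns = characters named by
#'   char id) of state codes, `"?"` (missing) or `"-"` (inapplicable).
#' @return a `morph_matrix` object.
#' @export
morph_matrix <- function(cells) {
  stopifnot(is.matrix(cells), !is.null(rownames(cells)), !is.null(colnames(cells)))
  if (anyDuplicated(rownames(cells))) stop("duplicate taxon labels")
  storage.mode(cells) <- "character"
  structure(list(taxa = rownames(cells), cells = cells), class = "morph_matrix")
}

#' Validate a morphological matrix against a catalog
#'
#' Flags every cell scored with a state where the character is inapplicable
#' (`SHOULD_BE_INAPPLICABLE`), every `-` where it is applicable
#' (`SHOULD_BE_APPLICABLE`), and every state code the character does not
#' declare (`UNDECLARED_STATE`).  All problems are report entries, never
#' errors; the report is ordered by (taxon, char_id).
#'
#' @param matrix a `morph_matrix`.
#' @param catalog a `character_catalog` whose characters match the matrix
#'   columns.
#' @return a data frame with columns `taxon`, `char_id`, `kind`, `message`;
#'   zero rows iff the matrix is consistent with the catalog.
#' @export
validate_matrix <- function(matrix, catalog) {
  cells <- matrix$cells
  want <- as.character(sort(as.integer(names(catalog$characters))))
  if (!all(want %in% colnames(cells))) {
    stop("matrix columns do not cover catalog characters: missing ",
         paste(setdiff(want, colnames(cells)), collapse = ", "))
  }
  out <- list()
  add <- function(taxon, id, kind, msg) {
    out[[length(out) + 1L]] <<- data.frame(taxon = taxon, char_id = id,
                                           kind = kind, message = msg,
                                           stringsAsFactors = FALSE)
  }
  for (taxon in matrix$taxa) {
    row <- setNames(as.character(cells[taxon, want]), want)
    for (key in want) {
      val <- row[[key]]
      ch <- catalog$characters[[key]]
      if (val %in% c(MISSING, INAPPLICABLE)) {
        if (val == INAPPLICABLE && is_applicable(row, as.integer(key), catalog)) {
          add(taxon, as.integer(key), "SHOULD_BE_APPLICABLE",
              sprintf("%s char %s scored '-' but no inapplicability condition matches", taxon, key))
        }
        next
      }
      if (!val %in% names(ch$states)) {
        add(taxon, as.integer(key), "UNDECLARED_STATE",
            sprintf("%s char %s scored undeclared state '%s'", taxon, key, val))
        next
      }
      if (!is_applicable(row, as.integer(key), catalog)) {
        add(taxon, as.integer(key), "SHOULD_BE_INAPPLICABLE",
            sprintf("%s char %s scored '%s' although inapplicable", taxon, key, val))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(taxon = character(0), char_id = integer(0),
                      kind = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  rep <- do.call(rbind, out)
  rep[order(rep$taxon, rep$char_id), , drop = FALSE]
}

#' Read the shipped morphotype rule or a user rule file
#'
#' The rule file is tab-separated with columns `char_id` and
#' `allowed_states` (codes separated by `/`).  The shipped fixture encodes
#' the state combination present in all P5-swimming crabs of the study
#' sample.
#'
#' @param path rule file; default is the shipped P5-swimmer rule.
#' @param catalog optional `character_catalog` to check the rule against.
#' @return a `morphotype_rule`: named list mapping char id to a character
#'   vector of allowed state codes.
#' @export
load_rule <- function(path = system.file("extdata", "p5_swimmer_rule.tsv",
                                         package = "swimpars"),
                      catalog = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character")
  rule <- setNames(strsplit(tab$allowed_states, "/", fixed = TRUE), tab$char_id)
  if (!is.null(catalog)) {
    for (key in names(rule)) {
      ch <- catalog$characters[[key]]
      if (is.null(ch)) stop("rule cites unknown character ", key)
      bad <- setdiff(rule[[key]], names(ch$states))
      if (length(bad) > 0) {
        stop("rule allows undeclared state(s) ", paste(bad, collapse = ","),
             " for character ", key)
      }
    }
  }
  structure(rule, class = "morphotype_rule")
}
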