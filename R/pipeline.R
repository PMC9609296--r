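# Pipeline front end: one declarative run configuration drives
# validate -> assemble -> search -> collapse -> consensus -> bootstrap ->
# root -> ancestral states -> morphotype classification, writing plain-text
# artifacts plus a checksummed manifest.  A thin argv-style CLI wraps the
# same entry points.

#' Run configuration for the full pipeline
#'
#' @param catalog path to a catalog file (default: shipped 59-character
#'   catalog).
#' @param morphology path to a morphology NEXUS matrix (columns are catalog
#'   characters in order), or an in-memory `morph_matrix`.
#' @param partitions named character vector of aligned-FASTA paths, or a
#'   list of `aligned_partition` objects; may be empty for a
#'   morphology-only run.
#' @param otu_map path to an OTU map file, an `otu_map` data frame, or
#'   `NULL` when partition rows are already keyed by matrix taxa.
#' @param rule path to a morphotype rule file or a `morphotype_rule`.
#' @param outgroup taxon set as the most basal outgroup.
#' @param out_dir output directory.
#' @param seed integer seed recorded in all outputs.
#' @param search list overriding [search_config()] fields.
#' @param bootstrap_reps bootstrap replicates (0 disables the bootstrap).
#' @return a `run_config` list.
#' @export
run_config <- function(morphology, outgroup, out_dir,
                       catalog = system.file("extdata", "characters_59.txt",
                                             package = "swimpars"),
                       partitions = list(), otu_map = NULL,
                       rule = system.file("extdata", "p5_swimmer_rule.tsv",
                                          package = "swimpars"),
                       seed = 1L, search = list(), bootstrap_reps = 50L) {
  structure(list(catalog = catalog, morphology = morphology,
                 partitions = partitions, otu_map = otu_map, rule = rule,
                 outgroup = outgroup, out_dir = out_dir,
                 seed = as.integer(seed), search = search,
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "run_config")
}

#' Run the full total-evidence pipeline
#'
#' Stages, in the analysis order of the study design: validate morphology
#' against the catalog; read and assemble molecular partitions into OTUs;
#' concatenate the supermatrix; heuristic MP search; collapse unsupported
#' branches; strict consensus; bootstrap; outgroup rooting; unordered
#' ancestral state reconstruction on a fully resolved optimal tree;
#' morphotype classification of terminals and ancestors.  All randomness
#' derives from `config$seed` via fixed per-stage offsets.
#'
#' @param config a [run_config()].
#' @return manifest data frame (file, md5) of every artifact written,
#'   also saved as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[swimpars] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  catalog <- stage("catalog", {
    if (inherits(config$catalog, "character_catalog")) config$catalog
    else suppressWarnings(load_catalog(config$catalog))
  })
  morph <- stage("morphology", {
    if (inherits(config$morphology, "morph_matrix")) config$morphology
    else {
      cm <- read_nexus_matrix(config$morphology)
      cells <- cm$cells
      colnames(cells) <- names(catalog$characters)[seq_len(ncol(cells))]
      morph_matrix(cells)
    }
  })
  report <- stage("validate", validate_matrix(morph, catalog))
  if (nrow(report) > 0) {
    stop("morphology matrix fails validation (", nrow(report),
         " violations); first: ", report$message[1])
  }
  partitions <- stage("partitions", {
    p <- config$partitions
    if (is.character(p)) {
      mapply(function(path, nm) read_alignment(path, nm), p, names(p),
             SIMPLIFY = FALSE)
    } else p
  })
  if (length(partitions) > 0 && !is.null(config$otu_map)) {
    map <- if (is.data.frame(config$otu_map)) config$otu_map
           else load_otu_map(config$otu_map)
    partitions <- stage("assemble", assemble_otus(map, partitions))
  }
  combined <- stage("concatenate", concatenate(morph, partitions))
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }
  emit("combined.nex", function(p) write_nexus_matrix(combined, p))
  scfg <- do.call(search_config, utils::modifyList(
    list(seed = config$seed), config$search))
  log_msg("MP search (", scfg$n_addition_replicates, " addition replicates, ",
          scfg$swap, " swapping)")
  res <- stage("search", mp_search(combined, scfg))
  log_msg("best length ", res$length, " (", length(res$trees), " tree(s))")
  emit("mp_trees.nwk", function(p) ape::write.tree(res$trees, file = p))
  emit("tree_length.txt", function(p) writeLines(as.character(res$length), p))
  collapsed <- stage("collapse", lapply(res$trees, collapse_unsupported,
                                        matrix = combined))
  cons <- stage("consensus", strict_consensus(collapsed))
  support <- NULL
  if (config$bootstrap_reps > 0) {
    log_msg("bootstrap (", config$bootstrap_reps, " replicates)")
    support <- stage("bootstrap", bootstrap_support(
      combined, search_config(seed = config$seed + 1000L),
      n_reps = config$bootstrap_reps))
    emit("bootstrap.tsv", function(p) write.table(
      support, p, sep = "\t", quote = FALSE, row.names = FALSE))
    cons <- apply_support(cons, support)
  }
  emit("consensus.nwk", function(p) ape::write.tree(cons, file = p))
  asr_tree <- stage("root", root_on_outgroup(res$trees[[1]], config$outgroup))
  if (length(res$trees) > 1) {
    log_msg("note: ", length(res$trees), " optimal trees; ancestral states ",
            "are reconstructed on the first (fully resolved) one")
  }
  emit("asr_tree.nwk", function(p) ape::write.tree(asr_tree, file = p))
  asr <- stage("asr", reconstruct(asr_tree, morph, catalog, validate = FALSE))
  emit("asr_states.tsv", function(p) write.table(
    asr_table(asr), p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("transformations.tsv", function(p) write.table(
    transformations(asr), p, sep = "\t", quote = FALSE, row.names = FALSE))
  rule <- stage("rule", {
    if (inherits(config$rule, "morphotype_rule")) config$rule
    else load_rule(config$rule, catalog)
  })
  emit("morphotype.tsv", function(p) write.table(
    annotate_tree(asr, rule), p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("run_info.json", function(p) jsonlite::write_json(
    list(seed = config$seed, outgroup = config$outgroup,
         best_length = res$length, n_optimal_trees = length(res$trees),
         total_characters = combined$total_characters,
         partition_map = combined$partition_map),
    p, auto_unbox = TRUE, pretty = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}

#' Command-line entry point
#'
#' Dispatches `validate-matrix`, `assemble`, `mpsearch`, `consensus`,
#' `root`, `asr`, `classify`, `simulate` and `run` subcommands.  Intended
#' to be called from the installed `cli/swimpars` script, but callable
#' directly with an argv vector for testing.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
swimpars_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: swimpars <command> [options]",
    "commands:",
    "  validate-matrix --morphology M.nex [--catalog C.txt]",
    "  run --morphology M.nex --outgroup LABEL --out DIR",
    "      [--catalog C.txt] [--rule R.tsv] [--otu-map MAP.tsv]",
    "      [--partition NAME=FILE.fasta ...] [--seed N] [--boot N]",
    "  simulate --out DIR [--taxa N] [--seed N]",
    sep = "\n")
  if (length(args) == 0) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- .parse_cli_opts(args[-1])
  get <- function(key, default = NULL) {
    if (key %in% names(opts)) opts[[key]] else default
  }
  if (cmd == "validate-matrix") {
    catalog <- suppressWarnings(load_catalog(
      get("catalog", system.file("extdata", "characters_59.txt",
                                 package = "swimpars"))))
    cm <- read_nexus_matrix(get("morphology"))
    cells <- cm$cells
    colnames(cells) <- names(catalog$characters)[seq_len(ncol(cells))]
    rep <- validate_matrix(morph_matrix(cells), catalog)
    if (nrow(rep) == 0) {
      cat("OK: matrix consistent with catalog\n")
      return(invisible(0L))
    }
    write.table(rep, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(1L))
  }
  if (cmd == "run") {
    parts <- opts[names(opts) == "partition"]
    pvec <- character(0)
    for (p in parts) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      pvec[kv[1]] <- kv[2]
    }
    cfg <- run_config(morphology = get("morphology"),
                      outgroup = get("outgroup"),
                      out_dir = get("out"),
                      catalog = get("catalog",
                                    system.file("extdata", "characters_59.txt",
                                                package = "swimpars")),
                      partitions = pvec,
                      otu_map = get("otu-map"),
                      rule = get("rule",
                                 system.file("extdata", "p5_swimmer_rule.tsv",
                                             package = "swimpars")),
                      seed = as.integer(get("seed", "1")),
                      bootstrap_reps = as.integer(get("boot", "50")))
    run_pipeline(cfg)
    return(invisible(0L))
  }
  if (cmd == "simulate") {
    out <- get("out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cfg <- sim_config(n_taxa = as.integer(get("taxa", "12")),
                      seed = as.integer(get("seed", "1")))
    tree <- simulate_tree(cfg)
    sim <- simulate_morphology(tree, cfg)
    parts <- simulate_sequences(tree, cfg)
    ape::write.tree(tree, file.path(out, "true_tree.nwk"))
    write_nexus_matrix(sim$matrix, file.path(out, "morphology.nex"))
    for (nm in names(parts)) {
      p <- parts[[nm]]
      writeLines(paste0(">", names(p$rows), "\n", unname(p$rows)),
                 file.path(out, paste0(nm, ".fasta")))
    }
    write.table(data.frame(node = sim$truth$node_labels, sim$truth$node_states),
                file.path(out, "true_states.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cat("simulated study written to ", out, "\n", sep = "")
    return(invisible(0L))
  }
  cat("unknown command: ", cmd, "\n", usage, "\n", sep = "")
  invisible(1L)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[length(opts) + 1L]] <- args[i + 1]
        names(opts)[length(opts)] <- key
        i <- i + 2
      } else {
        opts[[length(opts) + 1L]] <- "TRUE"
        names(opts)[length(opts)] <- key
        i <- i + 1
      }
    } else i <- i + 1
  }
  opts
}
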