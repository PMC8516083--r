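#' Configuration for a full demarcation pipeline run
#'
#' Collects the input manifests, parameter overrides and thresholds for
#' [run_pipeline()]. Genomes/proteomes/16S may be given either as named
#' file paths (FASTA) or as already-loaded named lists of Biostrings
#' objects. Thresholds default to the published cut-offs (genus AAI 70,
#' POCP 65, ANI 74; species ANI 95, AAI 95).
#'
#' @param genomes Named character vector of FASTA paths, or named list of
#'   `DNAStringSet`.
#' @param proteomes Optional; same conventions (`AAStringSet`).
#' @param ssu Optional; named paths or a named `DNAStringSet`/character
#'   vector of 16S sequences.
#' @param labels A data frame (`genome_id`, `genus`, optionally `species`,
#'   `family`) or a TSV path with those columns.
#' @param tree Optional `phylo` object or newick path; when absent, the
#'   tree is built by neighbor joining on K2P distances of the 16S set.
#' @param outdir Output directory for the report bundle.
#' @param genus_thresholds,species_thresholds See [GENUS_THRESHOLDS].
#' @param index_params Named list of per-index parameter overrides, e.g.
#'   `list(ANI = list(fragment_len = 1020), AAI = list(backend = "blast"))`.
#' @param seed Seed recorded in the log (the pipeline itself is
#'   deterministic given fixed inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, labels, proteomes = NULL, ssu = NULL,
                            tree = NULL, outdir = "genotax_out",
                            genus_thresholds = GENUS_THRESHOLDS,
                            species_thresholds = SPECIES_THRESHOLDS,
                            index_params = list(), seed = 1L) {
  if (any(genus_thresholds <= 0 | genus_thresholds >= 100) ||
      any(species_thresholds <= 0 | species_thresholds >= 100)) {
    abort("thresholds must lie strictly between 0 and 100")
  }
  structure(list(genomes = genomes, proteomes = proteomes, ssu = ssu,
                 labels = labels, tree = tree, outdir = outdir,
                 genus_thresholds = genus_thresholds,
                 species_thresholds = species_thresholds,
                 index_params = index_params, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_seq_input <- function(x, alphabet) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (is.null(names(x))) abort("file manifests must be named by genome_id")
    return(lapply(setNames(x, names(x)), read_fasta, alphabet = alphabet))
  }
  x
}

load_ssu_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && all(file.exists(x))) {
    seqs <- vapply(x, function(p) as.character(read_fasta(p, "nucleotide"))[1],
                   character(1))
    return(setNames(seqs, names(x)))
  }
  setNames(as.character(x), names(x))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full taxon-demarcation pipeline
#'
#' Orchestrates stats, similarity matrices, threshold inference,
#' clustering, tree concordance and reassignment proposals, writing a
#' report bundle to `config$outdir`: `genome_stats.tsv`, one matrix TSV
#' per computed index, `thresholds.json`, `clusters.tsv`,
#' `monophyly.tsv`, `proposals.tsv`, `regression.json`, and `run.log`
#' recording every parameter. Missing data degrades gracefully: indices
#' whose inputs are absent are skipped and noted. Percentages in TSVs are
#' written with one decimal; JSON keeps full precision. All outputs are
#' deterministic given fixed inputs and parameters.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`stats`,
#'   `matrices`, `thresholds`, `clusters`, `monophyly`, `proposals`,
#'   `regressions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_lines <- c(
    "genotax pipeline run",
    paste0("package version: ",
           as.character(utils::packageVersion("genotax"))),
    paste0("seed: ", config$seed),
    paste0("genus thresholds: ",
           paste(names(config$genus_thresholds), config$genus_thresholds,
                 sep = "=", collapse = ", ")),
    paste0("species thresholds: ",
           paste(names(config$species_thresholds), config$species_thresholds,
                 sep = "=", collapse = ", ")),
    "defaults: ANIb fragments 1020 bp, min identity 30%, min fragment coverage 70%;",
    "          AAI RBH min identity 30%, min coverage 70% of shorter protein;",
    "          POCP evalue < 1e-5, identity > 40%, query coverage > 50%;",
    "          clustering: average linkage (UPGMA) on 100 - similarity;",
    "          tie-breaks: best hit by score then id; hclust order deterministic"
  )

  genomes <- pipeline_stage("load_genomes",
                            load_seq_input(config$genomes, "nucleotide"))
  if (length(genomes) < 2L) abort("pipeline needs at least 2 genomes")
  proteomes <- pipeline_stage("load_proteomes",
                              load_seq_input(config$proteomes, "protein"))
  ssu <- pipeline_stage("load_ssu", load_ssu_input(config$ssu))
  labels <- config$labels
  if (is.character(labels)) {
    labels <- utils::read.table(labels, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  labels <- as_tibble(labels)

  stats <- pipeline_stage("genome_stats", genome_stats(genomes))
  stats_out <- stats %>% mutate(gc_percent = round(.data$gc_percent, 1))
  utils::write.table(stats_out, file.path(config$outdir, "genome_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # per-genus ranges of the descriptive stats (size / G+C comparison)
  group_ranges <- stats %>%
    left_join(labels[, c("genome_id", "genus")], by = "genome_id") %>%
    group_by(.data$genus) %>%
    summarise(min_size_bp = min(.data$size_bp),
              max_size_bp = max(.data$size_bp),
              min_gc = round(min(.data$gc_percent), 1),
              max_gc = round(max(.data$gc_percent), 1),
              gc_span = round(max(.data$gc_percent) - min(.data$gc_percent), 1),
              n = n())
  utils::write.table(group_ranges,
                     file.path(config$outdir, "genus_ranges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  matrices <- list()
  skipped <- character(0)
  mat_args <- function(index) {
    c(list(), config$index_params[[index]])
  }
  matrices$ANI <- pipeline_stage("ani_matrix", do.call(
    build_matrix, c(list(genomes, index = "ANI"), mat_args("ANI"))))
  if (!is.null(proteomes)) {
    matrices$AAI <- pipeline_stage("aai_matrix", do.call(
      build_matrix, c(list(proteomes, index = "AAI"), mat_args("AAI"))))
    matrices$POCP <- pipeline_stage("pocp_matrix", do.call(
      build_matrix, c(list(proteomes, index = "POCP"), mat_args("POCP"))))
  } else {
    skipped <- c(skipped, "AAI (no proteomes)", "POCP (no proteomes)")
  }
  if (!is.null(ssu)) {
    matrices$SSU <- pipeline_stage("ssu_matrix",
                                   build_matrix(ssu, index = "SSU"))
  } else {
    skipped <- c(skipped, "SSU (no 16S set)")
  }
  for (ix in names(matrices)) {
    x <- matrices[[ix]]
    x$values <- round(x$values, 1)
    write_matrix_tsv(x, file.path(config$outdir,
                                  paste0("matrix_", ix, ".tsv")))
  }
  if (length(skipped) > 0) {
    log_lines <- c(log_lines, paste0("skipped indices: ",
                                     paste(skipped, collapse = "; ")))
  }

  thresholds <- pipeline_stage("thresholds", lapply(matrices, function(m) {
    glance(infer_threshold(m, labels))
  }))
  jsonlite::write_json(thresholds,
                       file.path(config$outdir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  cluster_index <- if (!is.null(matrices$AAI)) "AAI" else "ANI"
  cluster_threshold <- config$genus_thresholds[[cluster_index]]
  clusters <- pipeline_stage("clustering",
                             cluster_and_cut(matrices[[cluster_index]],
                                             cluster_threshold))
  utils::write.table(clusters$clusters,
                     file.path(config$outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
                 paste0("clustering index: ", cluster_index, " at ",
                        cluster_threshold, "%"))

  tree <- config$tree
  if (is.character(tree)) tree <- pipeline_stage("read_tree", read_newick(tree))
  if (is.null(tree)) {
    if (is.null(ssu)) {
      abort("pipeline stage 'tree' failed: no tree given and no 16S set to build one")
    }
    tree <- pipeline_stage("nj_tree", nj_tree(k2p_matrix(ssu)))
    log_lines <- c(log_lines,
                   "tree: neighbor joining on K2P distances of the 16S set")
  } else {
    log_lines <- c(log_lines, "tree: user-supplied")
  }
  monophyly <- pipeline_stage("monophyly", check_monophyly(tree, labels))
  utils::write.table(monophyly, file.path(config$outdir, "monophyly.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  proposals <- pipeline_stage("proposals",
                              consensus_reassignment(clusters, monophyly,
                                                     labels, tree))
  utils::write.table(proposals, file.path(config$outdir, "proposals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  regressions <- list()
  combos <- utils::combn(names(matrices), 2, simplify = FALSE)
  for (cm in combos) {
    key <- paste0(cm[1], "_vs_", cm[2])
    regressions[[key]] <- pipeline_stage(
      paste0("regression_", key),
      index_regression(matrices[[cm[1]]], matrices[[cm[2]]]))
  }
  jsonlite::write_json(regressions,
                       file.path(config$outdir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  writeLines(log_lines, log_path)
  invisible(list(stats = stats, matrices = matrices,
                 thresholds = thresholds, clusters = clusters, tree = tree,
                 monophyly = monophyly, proposals = proposals,
                 regressions = regressions))
}
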