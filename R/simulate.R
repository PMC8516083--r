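#' Configuration for the synthetic genome-evolution generator
#'
#' Defines the planted genus/species hierarchy and the evolutionary
#' parameters of a simulated genome collection. Defaults describe the
#' standard study conditions used throughout the package tests: 3 genera of
#' 3 species, 200 kb single-contig genomes carrying 200 protein-coding
#' genes (mean 250 aa), G+C 60%, intra-genus branch substitution
#' probability 0.02, inter-genus 0.10, 15% gene loss per inter-genus
#' branch, and a 1,500 nt 16S-like marker evolving at one tenth of the
#' genomic rate.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species (tips) per genus.
#' @param genome_len_bp Genome length in bp (single contig).
#' @param n_genes Number of protein-coding genes.
#' @param gene_len_aa Mean protein length in residues.
#' @param gc_target Target G+C content as a fraction in (0, 1).
#' @param p_intra Substitution probability per site on intra-genus
#'   (species) branches.
#' @param p_inter Substitution probability per site on inter-genus
#'   branches; must exceed `p_intra`.
#' @param gene_loss_prob Per-gene loss probability on each inter-genus
#'   branch (losses only occur on inter-genus branches, so conserved-gene
#'   sharing separates ranks cleanly).
#' @param ssu_len Length of the 16S-like marker in nt.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genera = 3L, species_per_genus = 3L,
                       genome_len_bp = 200000L, n_genes = 200L,
                       gene_len_aa = 250L, gc_target = 0.60,
                       p_intra = 0.02, p_inter = 0.10,
                       gene_loss_prob = 0.15, ssu_len = 1500L,
                       seed = 1L) {
  cfg <- list(n_genera = as.integer(n_genera),
              species_per_genus = as.integer(species_per_genus),
              genome_len_bp = as.integer(genome_len_bp),
              n_genes = as.integer(n_genes),
              gene_len_aa = as.integer(gene_len_aa),
              gc_target = gc_target, p_intra = p_intra, p_inter = p_inter,
              gene_loss_prob = gene_loss_prob, ssu_len = as.integer(ssu_len),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_genera, species_per_genus, genome_len_bp, n_genes,
              gene_len_aa, ssu_len) < 1L)) {
      abort("all counts must be >= 1")
    }
    if (!(p_intra >= 0 && p_intra < p_inter && p_inter < 0.75)) {
      abort("need 0 <= p_intra < p_inter < 0.75")
    }
    if (gene_loss_prob < 0 || gene_loss_prob >= 1) {
      abort("gene_loss_prob must lie in [0, 1)")
    }
    if (gc_target <= 0 || gc_target >= 1) {
      abort("gc_target must lie strictly between 0 and 1")
    }
  })
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = base_probs(gc))
}

# sample n body codons (non-stop) with per-base G+C bias; because the
# excluded stop codons are A/T-rich the raw base bias is recalibrated so
# the expected G+C of non-stop codons equals the target
random_codons <- function(n, gc) {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  keep <- !(codons %in% STOP_CODONS)
  codon_gc <- vapply(strsplit(codons, ""), function(b) {
    sum(b %in% c("G", "C")) / 3
  }, numeric(1))
  nonstop_gc <- function(g) {
    p <- base_probs(g)
    cp <- as.vector(outer(outer(p, p), p))
    sum(cp[keep] * codon_gc[keep]) / sum(cp[keep])
  }
  g_adj <- stats::uniroot(function(g) nonstop_gc(g) - gc,
                          interval = c(0.01, 0.99), tol = 1e-9)$root
  p <- base_probs(g_adj)
  cp <- as.vector(outer(outer(p, p), p))
  sample(codons[keep], n, replace = TRUE, prob = cp[keep] / sum(cp[keep]))
}

#' Simulate the planted taxonomy and ancestor genome
#'
#' Builds the two-level hierarchy (genera, then species), the true tree
#' with per-branch substitution probabilities as branch lengths, the true
#' label table, and the ancestor genome: `n_genes` protein-coding genes
#' (ATG + non-stop body codons + stop) laid end-to-end with intergenic
#' filler at the target G+C content, plus a 16S-like marker sequence.
#' Seeds the RNG from `config$seed`; [evolve_collection()] continues the
#' same stream, so the [simulate_collection()] pipeline is reproducible
#' end to end.
#'
#' @param config A [sim_config()].
#' @return A list: `ancestor` (char vector genome), `genes` (tibble
#'   `gene_id`, `start`, `end`, `aa_len`), `ssu` (char vector), `tree`
#'   (`phylo` with branch lengths = substitution probabilities), `labels`
#'   (tibble `genome_id`, `genus`, `species`).
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa_len <- pmax(100L, round(stats::rgamma(config$n_genes, shape = 25,
                                           scale = config$gene_len_aa / 25)))
  gene_nt <- 3L * (aa_len + 1L)
  total_gene_nt <- sum(gene_nt)
  if (total_gene_nt > 0.9 * config$genome_len_bp) {
    abort("genes exceed 90% of genome_len_bp; enlarge the genome")
  }
  filler_total <- config$genome_len_bp - total_gene_nt
  n_gaps <- config$n_genes + 1L
  gap_len <- rep(filler_total %/% n_gaps, n_gaps)
  extra <- filler_total %% n_gaps
  if (extra > 0) gap_len[seq_len(extra)] <- gap_len[seq_len(extra)] + 1L

  pieces <- character(0)
  starts <- integer(config$n_genes)
  pos <- 0L
  for (i in seq_len(config$n_genes)) {
    pieces <- c(pieces, paste(random_bases(gap_len[i], config$gc_target),
                              collapse = ""))
    pos <- pos + gap_len[i]
    starts[i] <- pos + 1L
    gene <- paste0("ATG",
                   paste(random_codons(aa_len[i] - 1L, config$gc_target),
                         collapse = ""),
                   sample(STOP_CODONS, 1L))
    pieces <- c(pieces, gene)
    pos <- pos + gene_nt[i]
  }
  pieces <- c(pieces, paste(random_bases(gap_len[n_gaps], config$gc_target),
                            collapse = ""))
  ancestor <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    start = starts, end = starts + gene_nt - 1L, aa_len = aa_len
  )
  ssu <- random_bases(config$ssu_len, config$gc_target)

  tips <- outer(seq_len(config$n_genera), seq_len(config$species_per_genus),
                function(i, j) sprintf("g%02d_s%02d", i, j))
  clades <- vapply(seq_len(config$n_genera), function(i) {
    paste0("(", paste(sprintf("%s:%g", tips[i, ], config$p_intra),
                      collapse = ","),
           "):", config$p_inter)
  }, character(1))
  tree <- ape::read.tree(text = paste0("(", paste(clades, collapse = ","),
                                       ");"))
  labels <- tibble(
    genome_id = as.vector(t(tips)),
    genus = rep(sprintf("genus%02d", seq_len(config$n_genera)),
                each = config$species_per_genus),
    species = as.vector(t(tips))
  )
  list(ancestor = ancestor, genes = genes, ssu = ssu, tree = tree,
       labels = labels)
}

# substitute each site independently with probability p;
# transition:transversion ratio 2:1
mutate_bases <- function(chars, p) {
  if (p <= 0) return(chars)
  idx <- which(runif(length(chars)) < p)
  if (length(idx) == 0L) return(chars)
  old <- chars[idx]
  u <- runif(length(idx))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1_map <- c(A = "C", G = "C", C = "A", T = "A")
  tv2_map <- c(A = "T", G = "T", C = "G", T = "G")
  new <- ifelse(u < 2 / 3, ts_map[old],
                ifelse(u < 5 / 6, tv1_map[old], tv2_map[old]))
  chars[idx] <- new
  chars
}

# revert body codons that became stops, and start codons that are no
# longer ATG (purifying selection against nonsense and start-loss
# substitutions keeps the reading frames intact)
revert_nonsense <- function(child, parent, genes) {
  for (k in seq_len(nrow(genes))) {
    body_start <- genes$start[k]
    body_end <- genes$end[k] - 3L  # final stop codon excluded
    if (paste(child[body_start:(body_start + 2L)], collapse = "") != "ATG") {
      child[body_start:(body_start + 2L)] <- parent[body_start:(body_start + 2L)]
    }
    cpos <- seq.int(body_start, body_end - 2L, by = 3L)
    cod <- paste0(child[cpos], child[cpos + 1L], child[cpos + 2L])
    bad <- which(cod %in% STOP_CODONS)
    for (b in bad) {
      p <- cpos[b]
      child[p:(p + 2L)] <- parent[p:(p + 2L)]
    }
  }
  child
}

evolve_genome_chars <- function(parent, p, genes) {
  child <- mutate_bases(parent, p)
  revert_nonsense(child, parent, genes)
}

translate_gene_region <- function(chars, start, end) {
  cpos <- seq.int(start, end - 3L - 2L, by = 3L)
  translate_codons(paste0(chars[cpos], chars[cpos + 1L], chars[cpos + 2L]))
}

proteome_from_chars <- function(chars, genes, surviving) {
  g <- genes[surviving, , drop = FALSE]
  prots <- vapply(seq_len(nrow(g)), function(k) {
    translate_gene_region(chars, g$start[k], g$end[k])
  }, character(1))
  Biostrings::AAStringSet(setNames(prots, g$gene_id))
}

#' Evolve the collection down the planted tree
#'
#' Applies i.i.d. per-site nucleotide substitutions along each branch at
#' the branch's probability (transition:transversion 2:1, so the K2P model
#' applies), rejecting substitutions that would introduce an in-frame stop
#' codon inside a gene. Gene losses are sampled per inter-genus branch at
#' `gene_loss_prob`: lost genes are removed from the proteome and their
#' genomic span replaced by neutral filler. Proteomes are re-derived by
#' translating the surviving genes of each tip; the 16S-like marker
#' evolves at one tenth of the genomic rate.
#'
#' @param sim Output of [simulate_taxonomy()].
#' @param config The same [sim_config()].
#' @return A list: `genomes` (named list of `DNAStringSet`), `proteomes`
#'   (named list of `AAStringSet`), `ssu` (`DNAStringSet`), `labels`,
#'   `tree`, `genes`, and `internal` (genus ancestors and surviving gene
#'   indices, used for held-out tip generation).
#' @export
evolve_collection <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- list()
  proteomes <- list()
  ssu_out <- character(0)
  internal <- list(genus_ancestor = list(), genus_ssu = list(),
                   surviving = list())
  # with a single genus there are no inter-genus contrasts: the (one)
  # genus branch carries no divergence or loss
  p_g <- if (config$n_genera == 1L) 0 else config$p_inter
  loss_p <- if (config$n_genera == 1L) 0 else config$gene_loss_prob
  for (gi in seq_len(config$n_genera)) {
    genus_id <- sprintf("genus%02d", gi)
    ganc <- evolve_genome_chars(sim$ancestor, p_g, sim$genes)
    lost <- which(runif(config$n_genes) < loss_p)
    surviving <- setdiff(seq_len(config$n_genes), lost)
    for (k in lost) {
      span <- sim$genes$start[k]:sim$genes$end[k]
      ganc[span] <- random_bases(length(span), config$gc_target)
    }
    gssu <- mutate_bases(sim$ssu, p_g / 10)
    internal$genus_ancestor[[genus_id]] <- ganc
    internal$genus_ssu[[genus_id]] <- gssu
    internal$surviving[[genus_id]] <- surviving
    genes_surv <- sim$genes[surviving, , drop = FALSE]
    for (si in seq_len(config$species_per_genus)) {
      tip <- sprintf("g%02d_s%02d", gi, si)
      chars <- evolve_genome_chars(ganc, config$p_intra, genes_surv)
      genomes[[tip]] <- Biostrings::DNAStringSet(
        setNames(paste(chars, collapse = ""), paste0(tip, "_contig1")))
      proteomes[[tip]] <- proteome_from_chars(chars, sim$genes, surviving)
      ssu_out[tip] <- paste(mutate_bases(gssu, config$p_intra / 10),
                            collapse = "")
    }
  }
  list(genomes = genomes, proteomes = proteomes,
       ssu = Biostrings::DNAStringSet(ssu_out),
       labels = sim$labels, tree = sim$tree, genes = sim$genes,
       internal = internal, config = config)
}

#' One-call synthetic collection
#'
#' Runs [simulate_taxonomy()] then [evolve_collection()] under the
#' config's seed; identical configs give byte-identical collections.
#'
#' @param config A [sim_config()].
#' @return See [evolve_collection()].
#' @export
simulate_collection <- function(config = sim_config()) {
  sim <- simulate_taxonomy(config)
  evolve_collection(sim, config)
}

#' Generate a held-out query tip from a simulated collection
#'
#' `"conspecific"` evolves a new strain from an existing species tip at a
#' small within-species divergence (`p_conspecific`); `"congeneric"`
#' evolves a new species from a genus ancestor at the intra-genus rate.
#' Used to exercise [classify_genome()] with known truth.
#'
#' @param collection Output of [simulate_collection()].
#' @param kind `"conspecific"` or `"congeneric"`.
#' @param genus,species Which planted genus (and, for conspecific, which
#'   species tip) to descend from.
#' @param p_conspecific Within-species branch substitution probability.
#' @param seed Seed for the held-out draw.
#' @return A list: `genome_id`, `genome` (`DNAStringSet`), `proteome`
#'   (`AAStringSet`), `ssu` (character), `truth` (genus/species of the
#'   parent).
#' @export
simulate_holdout <- function(collection, kind = c("conspecific", "congeneric"),
                             genus = 1L, species = 1L,
                             p_conspecific = 0.005,
                             seed = collection$config$seed + 1000L) {
  kind <- match.arg(kind)
  set.seed(seed)
  cfg <- collection$config
  genus_id <- sprintf("genus%02d", genus)
  surviving <- collection$internal$surviving[[genus_id]]
  genes_surv <- collection$genes[surviving, , drop = FALSE]
  if (kind == "conspecific") {
    tip <- sprintf("g%02d_s%02d", genus, species)
    parent <- strsplit(as.character(collection$genomes[[tip]][[1]]), "")[[1]]
    p <- p_conspecific
    parent_ssu <- strsplit(as.character(collection$ssu[[tip]]), "")[[1]]
    truth <- list(genus = genus_id, species = tip)
    qid <- paste0(tip, "_holdout")
  } else {
    parent <- collection$internal$genus_ancestor[[genus_id]]
    p <- cfg$p_intra
    parent_ssu <- collection$internal$genus_ssu[[genus_id]]
    truth <- list(genus = genus_id, species = NA_character_)
    qid <- paste0(genus_id, "_holdout")
  }
  chars <- evolve_genome_chars(parent, p, genes_surv)
  list(
    genome_id = qid,
    genome = Biostrings::DNAStringSet(
      setNames(paste(chars, collapse = ""), paste0(qid, "_contig1"))),
    proteome = proteome_from_chars(chars, collection$genes, surviving),
    ssu = paste(mutate_bases(parent_ssu, p / 10), collapse = ""),
    truth = truth
  )
}

#' Write a simulated collection to disk
#'
#' Emits `genomes/*.fna`, `proteomes/*.faa`, `ssu/*.fna`,
#' `truth/labels.tsv` and `truth/tree.nwk` under `outdir`.
#'
#' @param collection Output of [simulate_collection()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_collection <- function(collection, outdir) {
  for (d in c("genomes", "proteomes", "ssu", "truth")) {
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (id in names(collection$genomes)) {
    write_fasta(collection$genomes[[id]],
                file.path(outdir, "genomes", paste0(id, ".fna")))
    write_fasta(collection$proteomes[[id]],
                file.path(outdir, "proteomes", paste0(id, ".faa")))
    write_fasta(collection$ssu[id],
                file.path(outdir, "ssu", paste0(id, ".fna")))
  }
  utils::write.table(collection$labels,
                     file.path(outdir, "truth", "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(collection$tree, file.path(outdir, "truth", "tree.nwk"))
  invisible(outdir)
}
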