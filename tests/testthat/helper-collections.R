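# Shared simulated collections, built once per test run.

.collection_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.collection_cache[[key]])) {
    .collection_cache[[key]] <- builder()
  }
  .collection_cache[[key]]
}

# small, fast collection for unit tests (blast-backed but light)
small_config <- function() {
  sim_config(n_genera = 2L, species_per_genus = 3L, genome_len_bp = 20000L,
             n_genes = 25L, gene_len_aa = 150L, seed = 11L)
}

small_collection <- function() {
  memo("small", function() simulate_collection(small_config()))
}

# the standard study conditions (3 genera x 3 species, 200 kb, 200 genes)
study_collection <- function() {
  memo("study", function() simulate_collection(sim_config(seed = 1L)))
}

study_aai_matrix <- function() {
  memo("study_aai", function() {
    build_matrix(study_collection()$proteomes, index = "AAI")
  })
}

small_pipeline_run <- function() {
  memo("small_pipeline", function() {
    col <- small_collection()
    outdir <- file.path(tempdir(), "genotax_pipeline_small")
    cfg <- pipeline_config(genomes = col$genomes, proteomes = col$proteomes,
                           ssu = col$ssu, labels = col$labels,
                           tree = col$tree, outdir = outdir)
    list(result = run_pipeline(cfg), outdir = outdir, config = cfg)
  })
}
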