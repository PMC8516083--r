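# Internal wrappers around the BLAST+ command-line suite, the default
# search backend behind the similarity indices. A pure-R alignment backend
# implementing the same hit contract exists for small inputs (see
# similarity-indices.R); BLAST is required for genome-scale searches.

has_blast <- function() {
  all(nzchar(Sys.which(c("blastn", "blastp", "makeblastdb"))))
}

require_blast <- function() {
  if (!has_blast()) {
    abort(paste0(
      "the BLAST+ executables (blastn/blastp/makeblastdb) were not found ",
      "on PATH; install BLAST+ or use backend = \"alignment\" for small inputs"))
  }
}

BLAST_FMT <- "6 qseqid sseqid pident length qlen slen qstart qend sstart send evalue bitscore"
BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

make_blast_db <- function(seqs, dbtype, workdir) {
  fa <- file.path(workdir, paste0("db_", dbtype, ".fasta"))
  Biostrings::writeXStringSet(seqs, fa)
  out <- system2("makeblastdb",
                 c("-in", shQuote(fa), "-dbtype", dbtype,
                   "-out", shQuote(fa)),
                 stdout = FALSE, stderr = FALSE)
  if (out != 0L) abort("makeblastdb failed")
  fa
}

read_blast_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) {
    tab <- as.data.frame(matrix(nrow = 0, ncol = length(BLAST_COLS)))
    names(tab) <- BLAST_COLS
    return(as_tibble(tab))
  }
  tab <- utils::read.table(path, sep = "\t", col.names = BLAST_COLS,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  as_tibble(tab)
}

# query fragments (DNAStringSet) vs subject genome; returns all hits
blast_nt_search <- function(query, subject, evalue = 1e-15) {
  require_blast()
  workdir <- tempfile("blastnt")
  dir.create(workdir)
  on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  db <- make_blast_db(subject, "nucl", workdir)
  qfa <- file.path(workdir, "query.fasta")
  Biostrings::writeXStringSet(query, qfa)
  outtab <- file.path(workdir, "hits.tsv")
  status <- system2("blastn",
                    c("-task", "blastn", "-query", shQuote(qfa),
                      "-db", shQuote(db), "-outfmt", shQuote(BLAST_FMT),
                      "-dust", "no", "-xdrop_gap_final", "150",
                      "-evalue", format(evalue, scientific = TRUE),
                      "-num_threads", "1", "-out", shQuote(outtab)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) abort("blastn failed")
  read_blast_table(outtab)
}

# query proteome vs subject proteome; returns all hits passing evalue
blast_prot_search <- function(query, subject, evalue = 1e-5) {
  require_blast()
  workdir <- tempfile("blastp")
  dir.create(workdir)
  on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  db <- make_blast_db(subject, "prot", workdir)
  qfa <- file.path(workdir, "query.fasta")
  Biostrings::writeXStringSet(query, qfa)
  outtab <- file.path(workdir, "hits.tsv")
  status <- system2("blastp",
                    c("-query", shQuote(qfa), "-db", shQuote(db),
                      "-outfmt", shQuote(BLAST_FMT), "-seg", "no",
                      "-evalue", format(evalue, scientific = TRUE),
                      "-max_target_seqs", "500",
                      "-num_threads", "1", "-out", shQuote(outtab)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) abort("blastp failed")
  read_blast_table(outtab)
}

# best hit per query by bitscore (ties: first in BLAST output order)
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits %>%
    group_by(.data$qseqid) %>%
    slice_max(.data$bitscore, n = 1, with_ties = FALSE) %>%
    ungroup()
}
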