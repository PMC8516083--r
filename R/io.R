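#' Read a FASTA file into a validated sequence set
#'
#' Reads nucleotide or protein FASTA into a [Biostrings::DNAStringSet] /
#' [Biostrings::AAStringSet]. Record ids are the first whitespace-delimited
#' token of each header (the full headers are kept in the element metadata
#' column `header`). Sequences are uppercased and gap characters (`-`, `.`)
#' are stripped before validation.
#'
#' Nucleotide records may use the IUPAC ambiguity codes; protein records are
#' restricted to the 20 standard residues plus `X` (a single trailing `*`,
#' as emitted by some gene callers, is silently removed). Offending records
#' are named in the error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A `DNAStringSet` (nucleotide) or `AAStringSet` (protein) named by
#'   record id.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) {
    abort(paste0("FASTA record with empty id in ", path))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("[-.]", "", seqs)
  if (alphabet == "protein") {
    seqs <- sub("\\*$", "", seqs)
  }
  allowed <- if (alphabet == "nucleotide") NT_ALPHABET else AA_ALPHABET_X
  bad_pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- grepl(bad_pat, seqs)
  if (any(bad)) {
    abort(paste0("record(s) with characters outside the ", alphabet,
                 " alphabet: ", paste(ids[bad], collapse = ", ")))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("record(s) with empty sequence: ",
                 paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  }
  out <- if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out)$header <- headers
  out
}

NT_ALPHABET <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")
AA_ALPHABET_X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Write a sequence set to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are reproduced exactly.
#'
#' @param records A named `XStringSet` (or named character vector).
#' @param path Output path.
#' @param line_width Maximum characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (length(records) == 0L) {
    abort("cannot write an empty record set")
  }
  if (is.character(records)) {
    records <- Biostrings::BStringSet(records)
  }
  if (is.null(names(records)) || any(names(records) == "")) {
    abort("all records must be named")
  }
  Biostrings::writeXStringSet(records, filepath = path, width = line_width)
  invisible(path)
}

#' Per-genome descriptive statistics
#'
#' Computes assembly size, G+C content and contig count for one or more
#' genomes. The G+C percentage is `100 * (G + C) / (A + C + G + T)`:
#' ambiguous bases (N and other IUPAC codes) are excluded from both
#' numerator and denominator, so the value is insensitive to N padding,
#' while `size_bp` counts all bases including N.
#'
#' @param genomes A `DNAStringSet` (one genome, possibly multi-contig) or a
#'   named list of `DNAStringSet` objects (one per genome).
#' @param genome_id Id used when `genomes` is a single `DNAStringSet`.
#' @return A tibble with columns `genome_id`, `size_bp`, `gc_percent`,
#'   `n_contigs`.
#' @export
genome_stats <- function(genomes, genome_id = "genome") {
  if (methods::is(genomes, "DNAStringSet")) {
    genomes <- setNames(list(genomes), genome_id)
  }
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    abort("genome list must be named by genome_id")
  }
  rows <- imap(genomes, function(g, id) {
    if (length(g) == 0L) abort(paste0("genome ", id, " has no contigs"))
    af <- colSums(Biostrings::alphabetFrequency(g, baseOnly = TRUE))
    acgt <- sum(af[c("A", "C", "G", "T")])
    if (acgt == 0) {
      abort(paste0("genome ", id, " contains no unambiguous bases"))
    }
    tibble(
      genome_id = id,
      size_bp = sum(Biostrings::width(g)),
      gc_percent = 100 * sum(af[c("G", "C")]) / acgt,
      n_contigs = length(g)
    )
  })
  bind_rows(rows)
}

#' Call open reading frames on a genome
#'
#' A minimal six-frame ORF scanner so that synthetic genomes yield
#' proteomes without an external annotator; it is a stand-in, not a gene
#' annotator (no RBS model, no partial genes at contig ends). An ORF runs
#' from an ATG to the next in-frame stop codon; within a frame, overlapping
#' candidates are resolved by keeping the longest (the first ATG after the
#' preceding stop). Proteins are returned translated without the stop;
#' ordering is deterministic by (contig, strand, start), `+` strand first.
#' Start coordinates on the `-` strand refer to the reverse-complemented
#' contig.
#'
#' @param genome A `DNAStringSet` of contigs.
#' @param min_len_nt Minimum ORF length in nucleotides, stop codon
#'   included; must be a multiple of 3.
#' @param translation_table Genetic code table; only table 11 (bacterial,
#'   identical to the standard code for ATG-initiated frames) is supported.
#' @return An `AAStringSet` of proteins named `<contig>_<strand><start>`.
#' @export
find_orfs <- function(genome, min_len_nt = 300L, translation_table = 11L) {
  if (min_len_nt < 9L || min_len_nt %% 3L != 0L) {
    abort("min_len_nt must be a positive multiple of 3 (>= 9)")
  }
  if (!translation_table %in% c(1L, 11L)) {
    abort("only translation tables 1 and 11 are supported")
  }
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  out_ids <- character(0)
  out_seq <- character(0)
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    fwd <- as.character(genome[[ci]])
    rev <- as.character(Biostrings::reverseComplement(genome[[ci]]))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      orfs <- scan_orfs_one_strand(s, min_len_nt)
      if (nrow(orfs) == 0) next
      orfs <- orfs[order(orfs$start), , drop = FALSE]
      out_ids <- c(out_ids, sprintf("%s_%s%d", contig, strand, orfs$start))
      out_seq <- c(out_seq, orfs$protein)
    }
  }
  prot <- Biostrings::AAStringSet(setNames(out_seq, out_ids))
  prot
}

# three-frame scan of one strand; returns data.frame(start, protein) with
# start as 1-based position of the A of ATG on this strand's sequence
scan_orfs_one_strand <- function(s, min_len_nt) {
  n <- nchar(s)
  starts_out <- integer(0)
  prots_out <- character(0)
  for (f in 0:2) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(pos) == 0L) next
    codons <- substring(s, pos, pos + 2L)
    stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
    atg_i <- which(codons == "ATG")
    if (length(stop_i) == 0L || length(atg_i) == 0L) next
    prev_stop <- 0L
    for (si in stop_i) {
      cand <- atg_i[atg_i > prev_stop & atg_i < si]
      if (length(cand) > 0L) {
        a <- cand[1L]  # earliest ATG = longest ORF in this segment
        len_nt <- (si - a + 1L) * 3L
        if (len_nt >= min_len_nt) {
          starts_out <- c(starts_out, pos[a])
          prots_out <- c(prots_out,
                         translate_codons(codons[a:(si - 1L)]))
        }
      }
      prev_stop <- si
    }
  }
  data.frame(start = starts_out, protein = prots_out,
             stringsAsFactors = FALSE)
}

# codon -> amino acid with X for ambiguous codons
translate_codons <- function(codons) {
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[gc == "*"] <- NA_character_  # stops never translated here
  gc
})
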