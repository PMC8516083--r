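#' Global nucleotide alignment with affine gaps
#'
#' Needleman–Wunsch global alignment (affine gap penalties) of two
#' nucleotide sequences. Identity is computed over aligned columns after
#' excluding terminal gap columns, the convention used for pairwise 16S
#' rRNA gene identity.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or `DNAString`).
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap
#'   of length L costs `gap_open + L * gap_extend`).
#' @param query_id,subject_id Ids recorded in the result.
#' @return A one-row tibble with columns `query_id`, `subject_id`,
#'   `identity_percent`, `aln_len`, `query_cov_percent`, `score`, `evalue`
#'   (`NA` for global mode).
#' @export
align_global_nt <- function(seq_a, seq_b, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2,
                            query_id = "query", subject_id = "subject") {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    abort("cannot align an empty sequence")
  }
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  core <- trim_terminal_gaps(pa, sa)
  ncol_core <- length(core$a)
  ident <- if (ncol_core > 0) 100 * sum(core$a == core$b) / ncol_core else NA_real_
  tibble(
    query_id = query_id, subject_id = subject_id,
    identity_percent = ident,
    aln_len = ncol_core,
    query_cov_percent = 100,
    score = Biostrings::score(aln),
    evalue = NA_real_
  )
}

# drop leading/trailing alignment columns in which either row has a gap
trim_terminal_gaps <- function(a, b) {
  gap <- a == "-" | b == "-"
  keep <- which(!gap)
  if (length(keep) == 0L) return(list(a = character(0), b = character(0)))
  lo <- min(keep)
  hi <- max(keep)
  list(a = a[lo:hi], b = b[lo:hi])
}

# Karlin-Altschul parameters per scoring scheme (published BLAST values for
# the gapped regimes used here)
KA_PARAMS <- list(
  BLOSUM62_11_1 = list(lambda = 0.267, K = 0.041),
  NT_1_m2_5_2 = list(lambda = 1.28, K = 0.46)
)

#' Local alignment with E-value statistics
#'
#' Smith–Waterman local alignment via [Biostrings::pairwiseAlignment()],
#' with the expectation value computed from the score by Karlin–Altschul
#' statistics, `E = K * m * n * exp(-lambda * S)`, using published gapped
#' parameters for the supported scoring schemes (BLOSUM62 with affine
#' 11/1 for protein; match/mismatch +1/-2 with affine 5/2 for nucleotide).
#' Identity in local mode is measured over the full alignment length.
#'
#' @param seq_a,seq_b Sequences (character or `XString`); `seq_a` is the
#'   query for coverage purposes.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param scoring Scoring scheme: `"BLOSUM62"` (protein) or `"NT_1_m2"`
#'   (nucleotide +1/-2).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param query_id,subject_id Ids recorded in the result.
#' @return A tibble of alignment hits (zero rows when no positive-scoring
#'   local alignment exists), columns as in [align_global_nt()].
#' @export
align_local <- function(seq_a, seq_b, alphabet = c("protein", "nucleotide"),
                        scoring = NULL, gap_open = NULL, gap_extend = NULL,
                        query_id = "query", subject_id = "subject") {
  alphabet <- match.arg(alphabet)
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    abort("cannot align an empty sequence")
  }
  if (is.null(scoring)) scoring <- if (alphabet == "protein") "BLOSUM62" else "NT_1_m2"
  if (alphabet == "protein") {
    if (!identical(scoring, "BLOSUM62")) {
      abort(paste0("unknown protein scoring scheme: ", scoring))
    }
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    sub_mat <- blosum62_matrix()
    ka <- KA_PARAMS$BLOSUM62_11_1
    xa <- Biostrings::AAString(seq_a)
    xb <- Biostrings::AAString(seq_b)
  } else {
    if (!identical(scoring, "NT_1_m2")) {
      abort(paste0("unknown nucleotide scoring scheme: ", scoring))
    }
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
    ka <- KA_PARAMS$NT_1_m2_5_2
    xa <- Biostrings::DNAString(seq_a)
    xb <- Biostrings::DNAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(
    xa, xb, type = "local", substitutionMatrix = sub_mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(aln)
  if (s <= 0) {
    return(empty_hits())
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aln_len <- length(pa)
  ident <- 100 * sum(pa == sa & pa != "-") / aln_len
  q_res <- sum(pa != "-")
  ev <- ka$K * nchar(seq_a) * nchar(seq_b) * exp(-ka$lambda * s)
  tibble(
    query_id = query_id, subject_id = subject_id,
    identity_percent = ident,
    aln_len = aln_len,
    query_cov_percent = 100 * q_res / nchar(seq_a),
    score = s,
    evalue = ev
  )
}

empty_hits <- function() {
  tibble(
    query_id = character(0), subject_id = character(0),
    identity_percent = numeric(0), aln_len = integer(0),
    query_cov_percent = numeric(0), score = numeric(0), evalue = numeric(0)
  )
}

# BLOSUM62 restricted to the residues this package admits (20 standard + X,
# plus the gap-adjacent '*' never used in practice)
blosum62_matrix <- function() {
  m <- get_blosum62()
  m
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # lazy-load from Biostrings' bundled matrix
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Kimura two-parameter distance from an aligned pair
#'
#' Computes the K2P distance `d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`
#' where `P` and `Q` are the proportions of aligned sites differing by a
#' transition and a transversion, respectively. Gap columns and columns
#' containing ambiguous bases are dropped before computing `P` and `Q`.
#' Saturated pairs (log/sqrt argument non-positive) give `NA` with a
#' warning.
#'
#' @param aligned_a,aligned_b Equal-length aligned nucleotide strings.
#' @return The distance in substitutions/site, or `NA_real_` on saturation.
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(as.character(aligned_a)), "")[[1]]
  b <- strsplit(toupper(as.character(aligned_b)), "")[[1]]
  if (length(a) != length(b)) {
    abort("aligned sequences must have equal length")
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]
  b <- b[ok]
  if (length(a) == 0L) abort("no unambiguous aligned columns")
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                          (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(transition) / length(a)
  Q <- sum(diff & !transition) / length(a)
  k2p_from_pq(P, Q)
}

#' @rdname k2p_distance
#' @param P,Q Proportions of transition- and transversion-differing sites.
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warn("K2P distance undefined (saturation); returning NA")
    return(NA_real_)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix for a set of sequences
#'
#' Aligns every unordered pair globally (see [align_global_nt()]) and
#' computes the K2P distance on the aligned pair. Intended for 16S rRNA
#' gene sets prior to neighbor-joining.
#'
#' @param seqs A named `DNAStringSet` or named character vector.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(seqs) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2L) abort("need at least two sequences")
  if (is.null(names(seqs))) abort("sequences must be named")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
        type = "global", substitutionMatrix = sub_mat,
        gapOpening = 5, gapExtension = 2)
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
      d[i, j] <- d[j, i] <- suppressWarnings(k2p_distance(pa, sa))
    }
  }
  d
}
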