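#' Similarity indices for genome-based taxon demarcation
#'
#' @description
#' The four pairwise indices on which genus and species demarcation rests:
#'
#' * `compute_anib()` — fragment-based average nucleotide identity (ANIb):
#'   the query genome is chopped into consecutive fragments (default
#'   1020 bp; a final short fragment is kept when at least 100 bp), each
#'   fragment is searched against the other genome on both strands, and
#'   fragments are retained when the best hit reaches `min_identity`
#'   percent identity over at least `min_frag_cov` percent of the fragment.
#'   The directional ANI is the mean identity of retained fragments and the
#'   reported value is the mean of the two directions.
#' * `compute_aai()` — average amino acid identity: mean identity over
#'   reciprocal best-hit (RBH) protein pairs passing `min_identity` and
#'   `min_cov` (coverage of the shorter sequence).
#' * `compute_pocp()` — percentage of conserved proteins:
#'   `100 * (C1 + C2) / (T1 + T2)` where `C1` is the number of proteins of
#'   one proteome with a hit in the other passing `evalue < max_evalue`,
#'   `identity > min_identity` and an aligned region longer than
#'   `min_query_cov` percent of the query protein, `C2` the reverse count,
#'   and `T1`, `T2` the total protein counts.
#' * `compute_16s_identity()` — global-alignment identity of two 16S rRNA
#'   gene sequences over aligned columns excluding terminal gaps.
#'
#' When no fragment (ANIb) or no RBH pair (AAI) passes the filters the
#' value is undefined and reported as `NA`, never as 0; a POCP of 0 is a
#' valid value.
#'
#' All indices return a one-row tibble with columns `genome_a`, `genome_b`,
#' `index`, `value`, `n_units` and `direction`.
#'
#' @param genome_a,genome_b `DNAStringSet` genome assemblies (contig sets).
#' @param prot_a,prot_b `AAStringSet` proteomes.
#' @param ssu_a,ssu_b 16S rRNA gene sequences (character or `DNAString`).
#' @param ids Length-2 character: ids recorded for the two members.
#' @param fragment_len Fragment length in bp for ANIb.
#' @param min_identity Minimum percent identity for a unit to count.
#' @param min_frag_cov Minimum percent of the fragment covered by its best
#'   hit (ANIb).
#' @param min_cov Minimum percent coverage of the shorter protein (AAI).
#' @param max_evalue Maximum E-value for a POCP hit.
#' @param min_query_cov Minimum percent of the query protein covered
#'   (POCP).
#' @param backend `"blast"` (BLAST+ command-line suite; default, required
#'   for genome-scale inputs) or `"alignment"` (pure-R full dynamic
#'   programming via [align_local()]; intended for small inputs and used by
#'   the oracle tests).
#' @name similarity_indices
NULL

index_row <- function(a, b, index, value, n_units, direction = "symmetric") {
  tibble(genome_a = a, genome_b = b, index = index,
         value = value, n_units = as.integer(n_units),
         direction = direction)
}

# chop a genome into consecutive fragments; final piece kept when >= 100 bp
chop_genome <- function(genome, fragment_len) {
  frags <- character(0)
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    n <- nchar(s)
    starts <- seq.int(1L, n, by = fragment_len)
    ends <- pmin(starts + fragment_len - 1L, n)
    keep <- (ends - starts + 1L) >= 100L
    frags <- c(frags, substring(s, starts[keep], ends[keep]))
  }
  if (length(frags) == 0L) abort("genome shorter than one fragment")
  Biostrings::DNAStringSet(setNames(frags, sprintf("frag%06d", seq_along(frags))))
}

# directional ANIb: mean identity of retained fragments + count
anib_direction <- function(query_genome, subject_genome, fragment_len,
                           min_identity, min_frag_cov, backend) {
  frags <- chop_genome(query_genome, fragment_len)
  if (backend == "blast") {
    hits <- blast_nt_search(frags, subject_genome)
    if (nrow(hits) == 0) return(list(ani = NA_real_, n = 0L))
    best <- best_hit_per_query(hits)
    cov <- 100 * (abs(best$qend - best$qstart) + 1) / best$qlen
    keep <- best$pident >= min_identity & cov >= min_frag_cov
    best <- best[keep, , drop = FALSE]
    if (nrow(best) == 0) return(list(ani = NA_real_, n = 0L))
    list(ani = mean(best$pident), n = nrow(best))
  } else {
    subj <- c(as.character(subject_genome),
              as.character(Biostrings::reverseComplement(subject_genome)))
    ids <- numeric(0)
    for (fi in seq_along(frags)) {
      f <- as.character(frags[[fi]])
      best <- NULL
      for (s in subj) {
        h <- align_local(f, s, alphabet = "nucleotide")
        if (nrow(h) == 1 && (is.null(best) || h$score > best$score)) best <- h
      }
      if (!is.null(best)) {
        if (best$identity_percent >= min_identity &&
            best$query_cov_percent >= min_frag_cov) {
          ids <- c(ids, best$identity_percent)
        }
      }
    }
    if (length(ids) == 0) return(list(ani = NA_real_, n = 0L))
    list(ani = mean(ids), n = length(ids))
  }
}

#' @rdname similarity_indices
#' @export
compute_anib <- function(genome_a, genome_b, ids = c("genome_a", "genome_b"),
                         fragment_len = 1020L, min_identity = 30,
                         min_frag_cov = 70,
                         backend = c("blast", "alignment")) {
  backend <- match.arg(backend)
  d_ab <- anib_direction(genome_a, genome_b, fragment_len, min_identity,
                         min_frag_cov, backend)
  d_ba <- anib_direction(genome_b, genome_a, fragment_len, min_identity,
                         min_frag_cov, backend)
  vals <- c(d_ab$ani, d_ba$ani)
  value <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  if (is.na(value)) {
    warn(paste0("no fragment passed the ANIb filters for ", ids[1], " vs ",
                ids[2], "; value undefined"))
  }
  index_row(ids[1], ids[2], "ANI", value, d_ab$n + d_ba$n)
}

# best hits of every query protein against a subject proteome, with the
# quantities the AAI/POCP filters need; one row per query with any hit
protein_best_hits <- function(query, subject, backend, max_evalue = 1e-5) {
  if (backend == "blast") {
    hits <- blast_prot_search(query, subject, evalue = max_evalue)
    return(hits)
  }
  rows <- list()
  qn <- names(query)
  sn <- names(subject)
  for (i in seq_along(query)) {
    for (j in seq_along(subject)) {
      h <- align_local(as.character(query[[i]]), as.character(subject[[j]]),
                       alphabet = "protein",
                       query_id = qn[i], subject_id = sn[j])
      if (nrow(h) == 1) {
        rows[[length(rows) + 1L]] <- tibble(
          qseqid = qn[i], sseqid = sn[j],
          pident = h$identity_percent, length = h$aln_len,
          qlen = Biostrings::width(query)[i],
          slen = Biostrings::width(subject)[j],
          qstart = NA_integer_, qend = NA_integer_,
          sstart = NA_integer_, send = NA_integer_,
          evalue = h$evalue, bitscore = h$score,
          q_res = round(h$query_cov_percent / 100 * Biostrings::width(query)[i])
        )
      }
    }
  }
  if (length(rows) == 0) {
    out <- read_blast_table(tempfile())  # canonical empty table
    out$q_res <- integer(0)
    return(out)
  }
  bind_rows(rows) %>% filter(.data$evalue < max_evalue)
}

# aligned query residues for coverage; blast rows use the query span
hit_query_span <- function(hits) {
  if ("q_res" %in% names(hits)) {
    ifelse(is.na(hits$qstart), hits$q_res, abs(hits$qend - hits$qstart) + 1)
  } else {
    abs(hits$qend - hits$qstart) + 1
  }
}

#' @rdname similarity_indices
#' @export
compute_aai <- function(prot_a, prot_b, ids = c("genome_a", "genome_b"),
                        min_identity = 30, min_cov = 70,
                        backend = c("blast", "alignment")) {
  backend <- match.arg(backend)
  if (length(prot_a) == 0L || length(prot_b) == 0L) {
    abort("both proteomes must be nonempty")
  }
  ab <- best_hit_per_query(protein_best_hits(prot_a, prot_b, backend))
  ba <- best_hit_per_query(protein_best_hits(prot_b, prot_a, backend))
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    warn(paste0("no reciprocal best hits for ", ids[1], " vs ", ids[2],
                "; AAI undefined"))
    return(index_row(ids[1], ids[2], "AAI", NA_real_, 0L))
  }
  ba_best <- setNames(ba$sseqid, ba$qseqid)
  rbh <- ab[!is.na(ba_best[ab$sseqid]) & ba_best[ab$sseqid] == ab$qseqid, ,
            drop = FALSE]
  if (nrow(rbh) > 0) {
    cov_ab <- 100 * hit_query_span(rbh) / pmin(rbh$qlen, rbh$slen)
    rbh <- rbh[rbh$pident >= min_identity & cov_ab >= min_cov, , drop = FALSE]
  }
  if (nrow(rbh) == 0) {
    warn(paste0("no reciprocal best hits passed the AAI filters for ",
                ids[1], " vs ", ids[2], "; AAI undefined"))
    return(index_row(ids[1], ids[2], "AAI", NA_real_, 0L))
  }
  ba_ident <- setNames(ba$pident, ba$qseqid)
  value <- mean((rbh$pident + ba_ident[rbh$sseqid]) / 2)
  index_row(ids[1], ids[2], "AAI", value, nrow(rbh))
}

pocp_conserved_count <- function(query, subject, backend, max_evalue,
                                 min_identity, min_query_cov) {
  hits <- protein_best_hits(query, subject, backend, max_evalue = max_evalue)
  if (nrow(hits) == 0) return(0L)
  cov <- 100 * hit_query_span(hits) / hits$qlen
  pass <- hits$evalue < max_evalue & hits$pident > min_identity &
    cov > min_query_cov
  length(unique(hits$qseqid[pass]))
}

#' @rdname similarity_indices
#' @export
compute_pocp <- function(prot_a, prot_b, ids = c("genome_a", "genome_b"),
                         max_evalue = 1e-5, min_identity = 40,
                         min_query_cov = 50,
                         backend = c("blast", "alignment")) {
  backend <- match.arg(backend)
  if (length(prot_a) == 0L || length(prot_b) == 0L) {
    abort("both proteomes must be nonempty")
  }
  c1 <- pocp_conserved_count(prot_a, prot_b, backend, max_evalue,
                             min_identity, min_query_cov)
  c2 <- pocp_conserved_count(prot_b, prot_a, backend, max_evalue,
                             min_identity, min_query_cov)
  value <- 100 * (c1 + c2) / (length(prot_a) + length(prot_b))
  index_row(ids[1], ids[2], "POCP", value, c1 + c2)
}

#' @rdname similarity_indices
#' @export
compute_16s_identity <- function(ssu_a, ssu_b, ids = c("genome_a", "genome_b")) {
  ssu_a <- as.character(ssu_a)
  ssu_b <- as.character(ssu_b)
  if (nchar(ssu_a) == 0L || nchar(ssu_b) == 0L) {
    abort("cannot compare empty 16S sequences")
  }
  if (nchar(ssu_a) < 1200L || nchar(ssu_b) < 1200L) {
    warn("16S sequence shorter than 1,200 nt; identity may be unreliable")
  }
  hit <- align_global_nt(ssu_a, ssu_b, query_id = ids[1], subject_id = ids[2])
  index_row(ids[1], ids[2], "SSU", hit$identity_percent, hit$aln_len)
}
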