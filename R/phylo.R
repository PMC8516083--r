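#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via [ape::nj()]) on a symmetric
#' zero-diagonal distance matrix. Negative branch-length estimates, which
#' NJ can produce on non-additive data, are clamped to zero and flagged on
#' the returned tree (`attr(tree, "clamped_edges")`).
#'
#' @param distances Square symmetric numeric matrix, zero diagonal,
#'   `n >= 3`; asymmetry beyond `1e-9` is an error.
#' @param labels Optional taxon labels overriding the matrix dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances, labels = NULL) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    abort("distances must be a square matrix")
  }
  if (nrow(distances) < 3L) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(distances - t(distances))) > 1e-9) {
    abort("distance matrix is not symmetric (tolerance 1e-9)")
  }
  if (any(abs(diag(distances)) > 1e-9)) {
    abort("distance matrix must have a zero diagonal")
  }
  if (anyNA(distances)) abort("distance matrix contains missing values")
  if (!is.null(labels)) dimnames(distances) <- list(labels, labels)
  if (is.null(rownames(distances))) {
    abort("distance matrix must carry taxon labels")
  }
  tree <- ape::nj(distances)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped_edges") <- sum(neg)
  tree
}

#' Read / write newick trees
#'
#' Thin validated wrappers over [ape::read.tree()] / [ape::write.tree()];
#' round-trips preserve topology, labels, branch lengths and node support
#' values.
#'
#' @param path Path to a newick file.
#' @param tree A `phylo` object.
#' @return `read_newick()`: a `phylo`; `write_newick()`: `path` invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("newick file does not exist: ", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("newick parse error in ",
                                                    path, ": ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort(paste0("newick parse error in ", path))
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf labels in ", path, ": ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# leaf sets below each node of a phylo tree (list indexed by node number)
node_leaf_sets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

# all non-trivial bipartition sides of an unrooted tree, as a list of leaf
# label vectors (each internal edge contributes the child-side set)
tree_bipartitions <- function(tree) {
  sets <- node_leaf_sets(tree)
  children <- tree$edge[, 2]
  lapply(children, function(ch) sets[[ch]])
}

#' Test per-genus monophyly on an unrooted tree
#'
#' On an unrooted tree a genus is monophyletic iff some edge bipartition
#' separates exactly its leaves from all others (singletons are trivially
#' monophyletic); the verdict is therefore independent of rooting and of
#' leaf order. For a non-monophyletic genus the report lists the intruding
#' leaves: the foreign leaves inside the smallest bipartition side that
#' contains the whole genus.
#'
#' @param tree A `phylo` tree.
#' @param labeling Data frame with columns `genome_id` and `genus`, or a
#'   named character vector leaf -> genus. Every leaf must be labelled.
#' @return A tibble: `genus`, `n_leaves`, `monophyletic`, `intruders`
#'   (comma-separated, empty when monophyletic).
#' @export
check_monophyly <- function(tree, labeling) {
  genus <- as_genus_lookup(labeling)
  unlabeled <- setdiff(tree$tip.label, names(genus))
  if (length(unlabeled) > 0) {
    abort(paste0("unlabeled leaves: ", paste(unlabeled, collapse = ", ")))
  }
  genus <- genus[tree$tip.label]
  all_leaves <- tree$tip.label
  sides <- tree_bipartitions(tree)
  rows <- lapply(unique(genus), function(g) {
    lg <- all_leaves[genus == g]
    if (length(lg) <= 1L || length(lg) == length(all_leaves)) {
      return(tibble(genus = g, n_leaves = length(lg),
                    monophyletic = TRUE, intruders = ""))
    }
    mono <- any(vapply(sides, function(s) {
      setequal(s, lg) || setequal(setdiff(all_leaves, s), lg)
    }, logical(1)))
    intr <- ""
    if (!mono) {
      containing <- keep(sides, function(s) all(lg %in% s))
      containing <- c(containing,
                      keep(lapply(sides, function(s) setdiff(all_leaves, s)),
                           function(s) all(lg %in% s)))
      sizes <- vapply(containing, length, integer(1))
      best <- containing[[which.min(sizes)]]
      intr <- paste(sort(setdiff(best, lg)), collapse = ",")
    }
    tibble(genus = g, n_leaves = length(lg), monophyletic = mono,
           intruders = intr)
  })
  bind_rows(rows)
}

# is the leaf set `grp` a clade (bipartition side) of the unrooted tree?
is_clade <- function(tree, grp) {
  all_leaves <- tree$tip.label
  if (length(grp) <= 1L || length(grp) >= length(all_leaves)) return(TRUE)
  sides <- tree_bipartitions(tree)
  any(vapply(sides, function(s) {
    setequal(s, grp) || setequal(setdiff(all_leaves, s), grp)
  }, logical(1)))
}

#' The four MLSA housekeeping markers, in concatenation order
#' @export
MLSA_MARKERS <- c("fusA", "gyrB", "recA", "rpoB")

#' Extract MLSA marker proteins from a proteome
#'
#' For each reference marker query, finds the best local-alignment hit in
#' the proteome passing the identity and coverage filters (tie-break:
#' higher score, then lexicographically smaller protein id). Missing
#' markers are flagged, never fabricated.
#'
#' @param proteome An `AAStringSet`.
#' @param queries Named `AAStringSet` of reference marker sequences (e.g.
#'   from a well-annotated genome), names = marker names.
#' @param min_identity Minimum percent identity.
#' @param min_cov Minimum percent of the query marker covered.
#' @param backend `"alignment"` (default) or `"blast"`.
#' @return A tibble: `marker`, `found`, `protein_id`, `identity_percent`,
#'   `score`, `sequence`.
#' @export
extract_markers <- function(proteome, queries, min_identity = 30,
                            min_cov = 50,
                            backend = c("alignment", "blast")) {
  backend <- match.arg(backend)
  if (length(queries) == 0L) abort("query marker set must be nonempty")
  if (is.null(names(queries))) abort("queries must be named by marker")
  rows <- lapply(seq_along(queries), function(qi) {
    marker <- names(queries)[qi]
    hits <- protein_best_hits(queries[qi], proteome, backend,
                              max_evalue = 1e-5)
    if (nrow(hits) > 0) {
      cov <- 100 * hit_query_span(hits) / hits$qlen
      hits <- hits[hits$pident >= min_identity & cov >= min_cov, ,
                   drop = FALSE]
    }
    if (nrow(hits) == 0) {
      return(tibble(marker = marker, found = FALSE,
                    protein_id = NA_character_,
                    identity_percent = NA_real_, score = NA_real_,
                    sequence = NA_character_))
    }
    hits <- hits[order(-hits$bitscore, hits$sseqid), , drop = FALSE]
    best <- hits[1, ]
    tibble(marker = marker, found = TRUE, protein_id = best$sseqid,
           identity_percent = best$pident, score = best$bitscore,
           sequence = as.character(proteome[[best$sseqid]]))
  })
  bind_rows(rows)
}

#' Concatenate aligned marker blocks into a supermatrix
#'
#' Binds per-marker aligned blocks in fixed marker order into one aligned
#' supermatrix and reports the column range of each block. A genome
#' missing any marker is excluded with a warning.
#'
#' @param marker_sets Named list (one element per genome) of named
#'   character vectors marker -> aligned sequence; within a marker all
#'   sequences must have equal length.
#' @param markers Marker order; defaults to [MLSA_MARKERS].
#' @return A list: `supermatrix` (`AAStringSet`, one concatenated sequence
#'   per genome) and `blocks` (tibble `marker`, `start`, `end`, `width`).
#' @export
concatenate_markers <- function(marker_sets, markers = MLSA_MARKERS) {
  complete <- vapply(marker_sets, function(ms) all(markers %in% names(ms)),
                     logical(1))
  if (any(!complete)) {
    warn(paste0("excluding genome(s) with missing markers: ",
                paste(names(marker_sets)[!complete], collapse = ", ")))
    marker_sets <- marker_sets[complete]
  }
  if (length(marker_sets) == 0L) abort("no genome has all markers")
  widths <- vapply(markers, function(m) {
    w <- unique(vapply(marker_sets, function(ms) nchar(ms[[m]]), integer(1)))
    if (length(w) != 1L) {
      abort(paste0("marker ", m, " has unequal aligned lengths across genomes"))
    }
    w
  }, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  concat <- vapply(marker_sets, function(ms) {
    paste(vapply(markers, function(m) ms[[m]], character(1)), collapse = "")
  }, character(1))
  list(
    supermatrix = Biostrings::AAStringSet(concat),
    blocks = tibble(marker = markers, start = unname(starts),
                    end = unname(ends), width = unname(widths))
  )
}
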