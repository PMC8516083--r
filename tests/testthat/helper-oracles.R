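# Independent oracles used to cross-check the package implementation.
# Deliberately written as plain, obviously-correct dynamic programming /
# enumeration, sharing no code with the package.

# full-matrix Gotoh alignment score; gap of length L costs
# gap_open + L * gap_extend (the Biostrings convention)
oracle_align_score <- function(a, b, score_fun, gap_open, gap_extend,
                               type = c("global", "local")) {
  type <- match.arg(type)
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  go <- gap_open + gap_extend  # cost of the first gapped residue
  ge <- gap_extend
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * ge)
    for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * ge)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- score_fun(a[i - 1], b[j - 1])
      d <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (type == "local") d <- max(d, 0)
      M[i, j] <- d
      X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge)
      if (type == "local" && M[i, j] > best_local) best_local <- M[i, j]
    }
  }
  if (type == "global") {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  } else {
    best_local
  }
}

nt_score_fun <- function(match = 1, mismatch = -2) {
  function(x, y) if (x == y) match else mismatch
}

blosum62_score_fun <- function() {
  mat <- NULL
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  function(x, y) mat[x, y]
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# monophyly oracle by exhaustive bipartition enumeration: delete each edge
# in turn and compare the resulting component leaf sets with the genus
# (graph-component mechanics, independent of the package's postorder scan)
oracle_monophyletic <- function(tree, leaves) {
  nt <- length(tree$tip.label)
  if (length(leaves) <= 1L || length(leaves) == nt) return(TRUE)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  for (k in seq_len(nrow(tree$edge))) {
    cut <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(tree$edge[k, ])))
    comp <- igraph::components(cut)$membership
    for (side in unique(comp)) {
      vs <- as.integer(names(comp)[comp == side])
      side_leaves <- tree$tip.label[vs[vs <= nt]]
      if (setequal(side_leaves, leaves)) return(TRUE)
    }
  }
  FALSE
}

# random unrooted binary tree topology with given tip labels
random_tree <- function(tips) {
  ape::rtree(length(tips), tip.label = sample(tips))
}
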