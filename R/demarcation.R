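#' Build a pairwise similarity matrix over a collection
#'
#' Computes the chosen index for every unordered pair of members, once,
#' symmetrizes, and sets the diagonal to 100 (self-comparison). Undefined
#' pair values are stored as `NA` and flagged.
#'
#' @param collection A named list: `DNAStringSet` genomes for `"ANI"`,
#'   `AAStringSet` proteomes for `"AAI"`/`"POCP"`, or a named
#'   `DNAStringSet`/character vector of 16S sequences for `"SSU"`.
#' @param index One of `"ANI"`, `"AAI"`, `"POCP"`, `"SSU"`.
#' @param ... Passed to the underlying `compute_*` function (filters,
#'   `backend`, ...).
#' @return A `similarity_matrix`: labelled square matrix plus index kind.
#' @seealso [compute_anib()], [compute_aai()], [compute_pocp()],
#'   [compute_16s_identity()]
#' @export
build_matrix <- function(collection, index = c("ANI", "AAI", "POCP", "SSU"),
                         ...) {
  index <- match.arg(index)
  if (index == "SSU" && (is.character(collection) ||
                         methods::is(collection, "XStringSet"))) {
    nm <- names(collection)
    collection <- as.list(setNames(as.character(collection), nm))
  }
  labels <- names(collection)
  if (is.null(labels) || any(labels == "")) {
    abort("collection must be named by genome_id")
  }
  n <- length(collection)
  if (n < 2L) abort("need at least two members")
  fun <- switch(index,
                ANI = compute_anib, AAI = compute_aai,
                POCP = compute_pocp, SSU = compute_16s_identity)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(m) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      row <- fun(collection[[i]], collection[[j]],
                 ids = c(labels[i], labels[j]), ...)
      m[i, j] <- m[j, i] <- row$value
    }
  }
  new_similarity_matrix(m, index)
}

new_similarity_matrix <- function(values, index) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(list(values = values, index = index),
            class = "similarity_matrix")
}

#' Construct a similarity matrix from raw values
#'
#' Symmetrizes a square matrix of (possibly directional) percentages by
#' averaging `m` and `t(m)`, forces the diagonal to 100 and tags the index
#' kind. Useful for wrapping externally computed matrices.
#'
#' @param values Square numeric matrix with row/column names.
#' @param index Index kind tag (`"ANI"`, `"AAI"`, `"POCP"`, `"SSU"`).
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, index) {
  if (is.null(rownames(values))) abort("matrix must have row/column names")
  sym <- (values + t(values)) / 2
  diag(sym) <- 100
  new_similarity_matrix(sym, index)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> index:", x$index,
      " n =", nrow(x$values), "genomes\n")
  print(round(x$values, 1))
  invisible(x)
}

#' @export
as.matrix.similarity_matrix <- function(x, ...) x$values

#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- x$values
  labs <- rownames(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    genome_a = labs[pairs[, 1]],
    genome_b = labs[pairs[, 2]],
    index = x$index,
    value = m[pairs]
  )
}

#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(
    genome_a = rownames(object$values),
    genome_b = colnames(object$values)) %>%
    mutate(value = as.vector(t(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_a, .data$genome_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0(object$index, " (%)")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Write / read a similarity matrix as labelled TSV
#'
#' First row and first column hold genome ids.
#'
#' @param x A `similarity_matrix`.
#' @param path Output (or input) path.
#' @param index Index kind tag used when reading.
#' @return `path` invisibly (write); a `similarity_matrix` (read).
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(genome_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, index) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_similarity_matrix(m, index)
}

#' Average-linkage clustering of a similarity matrix, cut at a threshold
#'
#' Agglomerates on dissimilarity `100 - similarity` with average linkage
#' (UPGMA) and cuts the dendrogram at dissimilarity `100 - threshold`,
#' yielding disjoint clusters covering all labels. Rows/columns with any
#' missing pair value are dropped with a warning (clustering requires a
#' complete matrix).
#'
#' @param x A `similarity_matrix`.
#' @param threshold Similarity threshold in percent, inside (0, 100).
#' @return A `genome_clusters` object: tibble of assignments (`tidy()`),
#'   the `hclust` tree, and the threshold used.
#' @export
cluster_and_cut <- function(x, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 100) {
    abort("threshold must lie strictly between 0 and 100")
  }
  m <- x$values
  incomplete <- apply(m, 1, function(r) any(is.na(r)))
  if (any(incomplete)) {
    warn(paste0("dropping genomes with missing pair values: ",
                paste(rownames(m)[incomplete], collapse = ", ")))
    m <- m[!incomplete, !incomplete, drop = FALSE]
  }
  if (nrow(m) < 2L) abort("fewer than two genomes with complete values")
  hc <- hclust(as.dist(100 - m), method = "average")
  grp <- cutree(hc, h = 100 - threshold)
  structure(
    list(
      clusters = tibble(genome_id = names(grp), cluster = unname(grp)),
      hclust = hc,
      threshold = threshold,
      index = x$index
    ),
    class = "genome_clusters"
  )
}

#' @export
print.genome_clusters <- function(x, ...) {
  cat("<genome_clusters>", x$index, "threshold", x$threshold, "->",
      length(unique(x$clusters$cluster)), "clusters\n")
  print(x$clusters, n = Inf)
  invisible(x)
}

#' @method tidy genome_clusters
#' @export
tidy.genome_clusters <- function(x, ...) x$clusters

#' Infer a demarcation threshold from labelled pairs ("parting line")
#'
#' Partitions the off-diagonal pair values of a similarity matrix into
#' intra- and inter-genus sets using a genome-to-genus labelling. When the
#' two distributions are separable (`max_inter < min_intra`) the threshold
#' is the midpoint of the gap and there are no violations; otherwise the
#' threshold is the observed value minimizing the number of misclassified
#' pairs (a pair counts as same-genus when its value is at or above the
#' threshold; ties resolved toward the lower threshold), and the violation
#' count is reported.
#'
#' @param x A `similarity_matrix`.
#' @param labeling A data frame with columns `genome_id` and `genus`, or a
#'   named character vector mapping genome ids to genera. Every matrix
#'   label must be covered.
#' @return A `threshold_report`; see `tidy()` for the labelled pair values
#'   and `glance()` for the one-row summary.
#' @export
infer_threshold <- function(x, labeling) {
  genus <- as_genus_lookup(labeling)
  labs <- rownames(x$values)
  missing_ids <- setdiff(labs, names(genus))
  if (length(missing_ids) > 0) {
    abort(paste0("labeling is missing genome(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  pairs <- tidy(x) %>%
    filter(!is.na(.data$value)) %>%
    mutate(pair_type = ifelse(genus[.data$genome_a] == genus[.data$genome_b],
                              "intra", "inter"))
  intra <- pairs$value[pairs$pair_type == "intra"]
  inter <- pairs$value[pairs$pair_type == "inter"]
  if (length(intra) == 0L || length(inter) == 0L) {
    abort("need at least one intra-genus and one inter-genus pair")
  }
  min_intra <- min(intra)
  max_inter <- max(inter)
  if (max_inter < min_intra) {
    threshold <- (max_inter + min_intra) / 2
    n_violations <- 0L
  } else {
    cand <- sort(unique(pairs$value))
    viol <- vapply(cand, function(t) {
      sum(intra < t) + sum(inter >= t)
    }, numeric(1))
    threshold <- cand[which.min(viol)]  # which.min takes the lowest tie
    n_violations <- as.integer(min(viol))
  }
  structure(
    list(index = x$index, pairs = pairs, min_intra = min_intra,
         max_inter = max_inter, threshold = threshold,
         n_violations = n_violations),
    class = "threshold_report"
  )
}

as_genus_lookup <- function(labeling) {
  if (is.data.frame(labeling)) {
    if (!all(c("genome_id", "genus") %in% names(labeling))) {
      abort("labeling data frame needs columns genome_id and genus")
    }
    setNames(as.character(labeling$genus), labeling$genome_id)
  } else if (is.character(labeling) && !is.null(names(labeling))) {
    labeling
  } else {
    abort("labeling must be a data frame or a named character vector")
  }
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>", x$index, "\n")
  cat("  min intra:", round(x$min_intra, 2),
      " max inter:", round(x$max_inter, 2), "\n")
  cat("  threshold:", round(x$threshold, 2),
      " violations:", x$n_violations, "\n")
  invisible(x)
}

#' @method tidy threshold_report
#' @export
tidy.threshold_report <- function(x, ...) x$pairs

#' @method glance threshold_report
#' @export
glance.threshold_report <- function(x, ...) {
  tibble(index = x$index, threshold = x$threshold,
         min_intra = x$min_intra, max_inter = x$max_inter,
         n_violations = x$n_violations,
         n_intra = sum(x$pairs$pair_type == "intra"),
         n_inter = sum(x$pairs$pair_type == "inter"))
}

#' @method autoplot threshold_report
#' @export
autoplot.threshold_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$value, fill = .data$pair_type)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = paste0(object$index, " (%)"), y = "pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ordinary least squares between two similarity indices
#'
#' Regresses the pair values of one index on another over the matched
#' lower-triangle pairs (self-pairs excluded); quantifies the linear
#' concordance between indices.
#'
#' @param matrix_x,matrix_y `similarity_matrix` objects over identical
#'   label sets; `matrix_x` is the predictor.
#' @return A one-row tibble: `index_x`, `index_y`, `slope`, `intercept`,
#'   `r_squared`, `n_pairs`.
#' @export
index_regression <- function(matrix_x, matrix_y) {
  lx <- rownames(matrix_x$values)
  if (!setequal(lx, rownames(matrix_y$values))) {
    abort("the two matrices must cover identical label sets")
  }
  my <- matrix_y$values[lx, lx]
  px <- tidy(matrix_x)
  py <- tidy(new_similarity_matrix(my, matrix_y$index))
  df <- tibble(x = px$value, y = py$value) %>% filter(complete.cases(.))
  if (nrow(distinct(df)) < 3L) abort("need at least three distinct pairs")
  if (stats::var(df$x) == 0) abort("predictor index has zero variance")
  fit <- lm(y ~ x, data = df)
  tibble(
    index_x = matrix_x$index, index_y = matrix_y$index,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = stats::cor(df$x, df$y)^2, n_pairs = nrow(df)
  )
}
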