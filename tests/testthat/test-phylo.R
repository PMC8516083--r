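test_that("NJ solves the three-point equations on 3 taxa", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  expect_equal(ape::Ntip(tree), 3)
  pl <- ape::cophenetic.phylo(tree)
  expect_equal(pl[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # terminal branches solve the three-point equations exactly
  edge_len <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                       tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(edge_len[["A"]], 1)
  expect_equal(edge_len[["B"]], 2)
  expect_equal(edge_len[["C"]], 4)
})

test_that("NJ recovers the planted 4-taxon split with exact branch lengths", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tree <- nj_tree(d)
  expect_true(is_clade_oracle <- oracle_monophyletic(tree, c("A", "B")))
  expect_equal(ape::cophenetic.phylo(tree)[labs, labs], d,
               tolerance = 1e-10)
})

test_that("NJ is consistent on random additive 8-taxon matrices", {
  set.seed(90)
  for (i in 1:20) {
    true_tree <- ape::rtree(8, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(true_tree)
    est <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true_tree), est), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("nj_tree validates its input", {
  d <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "not symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("newick IO round-trips and rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:1,C:1)95:0.1);", p)
  tree <- read_newick(p)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  expect_equal(tree$node.label[2], "95")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, p2)
  back <- read_newick(p2)
  expect_equal(back$tip.label, tree$tip.label)
  expect_equal(back$edge.length, tree$edge.length)
  expect_equal(back$node.label, tree$node.label)
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B)", bad)
  expect_error(read_newick(bad))
  dup <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(A:1,C:1):1);", dup)
  expect_error(read_newick(dup), "duplicate")
})

test_that("monophyly verdicts match the stated small cases", {
  tree <- ape::read.tree(text = "((A1,A2),(B1,(B2,C1)));")
  lab <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C")
  res <- check_monophyly(tree, lab)
  verd <- setNames(res$monophyletic, res$genus)
  expect_true(verd[["A"]])
  expect_false(verd[["B"]])
  expect_true(verd[["C"]])  # singleton, trivially monophyletic
  expect_match(res$intruders[res$genus == "B"], "C1")
  # one shared label: monophyletic
  one <- check_monophyly(tree, setNames(rep("X", 5), names(lab)))
  expect_true(all(one$monophyletic))
  expect_error(check_monophyly(tree, lab[-1]), "unlabeled")
})

test_that("monophyly equals the exhaustive path oracle on random trees", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:50) {
    tips <- sprintf("t%02d", 1:10)
    tree <- random_tree(tips)
    genus <- setNames(sample(c("X", "Y", "Z"), 10, replace = TRUE),
                      tree$tip.label)
    res <- check_monophyly(tree, genus)
    for (g in unique(genus)) {
      expect_equal(
        res$monophyletic[res$genus == g],
        oracle_monophyletic(tree, names(genus)[genus == g]),
        info = paste("seeded tree", i, "genus", g))
    }
  }
})

test_that("monophyly is invariant under re-rooting", {
  set.seed(71)
  tree <- random_tree(sprintf("t%02d", 1:8))
  genus <- setNames(sample(c("X", "Y"), 8, replace = TRUE), tree$tip.label)
  base <- check_monophyly(tree, genus) %>% dplyr::arrange(genus)
  for (tip in tree$tip.label[1:3]) {
    rerooted <- ape::root(tree, outgroup = tip, resolve.root = TRUE)
    alt <- check_monophyly(rerooted, genus) %>% dplyr::arrange(genus)
    expect_equal(alt$monophyletic, base$monophyletic)
  }
})

test_that("marker extraction selects the best-scoring candidate", {
  set.seed(23)
  fusa <- random_aa(196)
  gyrb <- random_aa(295)
  queries <- Biostrings::AAStringSet(c(fusA = fusa, gyrB = gyrb))
  paralog <- strsplit(fusa, "")[[1]]
  paralog[seq(5, 190, by = 4)] <- "A"  # diverged copy
  proteome <- Biostrings::AAStringSet(c(
    p1 = fusa,                                  # exact fusA
    p2 = paste(paralog, collapse = ""),         # diverged fusA paralog
    p3 = random_aa(150)))
  res <- extract_markers(proteome, queries)
  fus <- res[res$marker == "fusA", ]
  expect_true(fus$found)
  expect_equal(fus$protein_id, "p1")  # exhaustive scoring picks the exact copy
  gyr <- res[res$marker == "gyrB", ]
  expect_false(gyr$found)  # nothing gyrB-like above the filters
})

test_that("marker concatenation reports the published block ranges", {
  set.seed(3)
  widths <- c(fusA = 196L, gyrB = 295L, recA = 225L, rpoB = 200L)
  blocks <- lapply(c("g1", "g2", "g3"), function(g) {
    vapply(widths, random_aa, character(1))
  })
  names(blocks) <- c("g1", "g2", "g3")
  out <- concatenate_markers(blocks)
  expect_equal(out$blocks$start, c(1L, 197L, 492L, 717L))
  expect_equal(out$blocks$end, c(196L, 491L, 716L, 916L))
  expect_equal(unique(Biostrings::width(out$supermatrix)), 916L)
  # single marker: supermatrix is that block
  single <- concatenate_markers(lapply(blocks, function(b) b["fusA"]),
                                markers = "fusA")
  expect_equal(as.character(single$supermatrix[["g2"]]), blocks$g2[["fusA"]])
  # a genome missing a marker is excluded with a warning
  blocks$g3 <- blocks$g3[c("fusA", "gyrB", "recA")]
  expect_warning(partial <- concatenate_markers(blocks), "g3")
  expect_equal(length(partial$supermatrix), 2L)
})
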