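ref_tax <- tibble::tibble(
  genome_id = c("ref1", "ref2", "ref3"),
  genus = c("Alphagenus", "Alphagenus", "Betagenus"),
  species = c("Alphagenus one", "Alphagenus two", "Betagenus one")
)

qidx <- function(ani, aai, pocp = NA, ref = "ref1") {
  rows <- tibble::tibble(
    reference = ref,
    index = c("ANI", "AAI", "POCP"),
    value = c(ani, aai, pocp)
  )
  rows[!is.na(rows$value), ]
}

test_that("species assignment requires both ANI and AAI above threshold", {
  res <- classify_genome(qidx(96.8, 96.2, 80), ref_tax, genome_id = "q")
  expect_equal(res$genus_call, "assigned:Alphagenus")
  expect_equal(res$species_call, "assigned:Alphagenus one")
  expect_equal(res$nearest_reference, "ref1")
})

test_that("genus-level match below species thresholds is a novel species", {
  res <- classify_genome(qidx(80, 80, 70), ref_tax)
  expect_equal(res$genus_call, "assigned:Alphagenus")
  expect_equal(res$species_call, "novel_species")
})

test_that("all verdicts below thresholds give a novel genus", {
  res <- classify_genome(qidx(72, 66, 60), ref_tax)
  expect_equal(res$genus_call, "novel_genus")
  expect_equal(res$species_call, "n/a")
})

test_that("disagreeing verdicts surface as conflict, 16S stays advisory", {
  # AAI says genus, ANI and POCP below: conflict, never silently resolved
  res <- classify_genome(qidx(70, 75, 60), ref_tax)
  expect_equal(res$genus_call, "conflict")
  expect_match(res$evidence, "AAI=75.0\\(genus\\)")
  expect_match(res$evidence, "ANI=70.0\\(below\\)")
  # a high 16S value alone never assigns a genus
  ssu_only_plus <- dplyr::bind_rows(
    qidx(72, 66, 60),
    tibble::tibble(reference = "ref1", index = "SSU", value = 99.2))
  res2 <- classify_genome(ssu_only_plus, ref_tax)
  expect_equal(res2$genus_call, "novel_genus")
  expect_match(res2$evidence, "advisory")
})

test_that("classification is idempotent for a reference against itself", {
  idx <- dplyr::bind_rows(
    tibble::tibble(reference = "ref2", index = c("ANI", "AAI", "POCP"),
                   value = c(100, 100, 100)),
    tibble::tibble(reference = "ref3", index = c("ANI", "AAI", "POCP"),
                   value = c(72, 65, 55)))
  res <- classify_genome(idx, ref_tax, genome_id = "ref2")
  expect_equal(res$genus_call, "assigned:Alphagenus")
  expect_equal(res$species_call, "assigned:Alphagenus two")
})

# --- consensus reassignment -------------------------------------------------

consistent_case <- function() {
  labs <- tibble::tibble(
    genome_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    genus = rep(c("A", "B"), each = 3),
    family = rep("Fam1", 6))
  tree <- ape::read.tree(text = "((a1:1,a2:1,a3:1):2,(b1:1,b2:1,b3:1):2);")
  clusters <- tibble::tibble(genome_id = labs$genome_id,
                             cluster = rep(1:2, each = 3))
  list(labs = labs, tree = tree, clusters = clusters,
       mono = check_monophyly(tree, labs))
}

test_that("a fully consistent collection is a fixed point", {
  cc <- consistent_case()
  res <- consensus_reassignment(cc$clusters, cc$mono, cc$labs, cc$tree)
  expect_true(all(res$proposal == "keep"))
  expect_equal(res$proposed_genus, res$original_genus)
})

test_that("an isolated genome on its own branch is proposed a novel genus", {
  # replica of a species sitting alone between two genera, below all
  # genus thresholds to both
  labs <- tibble::tibble(
    genome_id = c("a1", "a2", "x1", "b1", "b2"),
    genus = c("A", "A", "A", "B", "B"),  # x1 nominally in A
    family = rep("Fam1", 5))
  tree <- ape::read.tree(text = "((a1:1,a2:1):2,(x1:3,(b1:1,b2:1):2):1);")
  clusters <- tibble::tibble(genome_id = labs$genome_id,
                             cluster = c(1, 1, 3, 2, 2))
  mono <- check_monophyly(tree, labs)
  res <- consensus_reassignment(clusters, mono, labs, tree)
  expect_equal(res$proposal[res$genome_id == "x1"], "novel_genus")
  # its former genus-mates, coherent and monophyletic minus x1, may still
  # be flagged because their nominal genus is non-monophyletic on paper
  expect_true(all(res$proposal[res$genome_id %in% c("b1", "b2")] == "keep"))
})

test_that("a coherent genus nested in the other family is a transfer", {
  # genus O is monophyletic and one cluster, but sits inside family Fam2's
  # clade while labelled Fam1
  labs <- tibble::tibble(
    genome_id = c("g1", "g2", "h1", "h2", "o1", "o2", "p1", "p2", "z1"),
    genus = c("G", "G", "H", "H", "O", "O", "P", "P", "Z"),
    family = c("Fam1", "Fam1", "Fam1", "Fam1", "Fam1", "Fam1",
               "Fam2", "Fam2", "Fam3"))
  tree <- ape::read.tree(text = paste0(
    "(((g1:1,g2:1):1,(h1:1,h2:1):1):1,",
    "((o1:1,o2:1):1,(p1:1,p2:1):1):1,z1:3);"))
  clusters <- tibble::tibble(genome_id = labs$genome_id,
                             cluster = c(1, 1, 2, 2, 3, 3, 4, 4, 5))
  mono <- check_monophyly(tree, labs)
  res <- consensus_reassignment(clusters, mono, labs, tree)
  o_rows <- res[res$genome_id %in% c("o1", "o2"), ]
  expect_true(all(o_rows$proposal == "transfer"))
  expect_true(all(o_rows$proposed_genus == "O"))      # genus retained
  expect_true(all(o_rows$proposed_family == "Fam2"))  # family changes
  expect_true(all(res$proposal[res$genome_id %in% c("g1", "g2")] == "keep"))
})

test_that("a mislabelled tip is flagged as a conflict", {
  cc <- consistent_case()
  wrong <- cc$labs
  wrong$genus[wrong$genome_id == "a3"] <- "B"
  mono <- check_monophyly(cc$tree, wrong)
  res <- consensus_reassignment(cc$clusters, mono, wrong, cc$tree)
  expect_equal(res$proposal[res$genome_id == "a3"], "conflict")
  expect_match(res$evidence[res$genome_id == "a3"], "spans genera")
})
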