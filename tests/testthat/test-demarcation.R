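toy_matrix <- function(values, index = "AAI") {
  similarity_matrix(values, index)
}

test_that("build_matrix matches element-wise recomputation and symmetrizes", {
  set.seed(4)
  base <- random_nt(1400)
  chars <- strsplit(base, "")[[1]]
  ssu <- c(s1 = base,
           s2 = paste(genotax:::mutate_bases(chars, 0.01), collapse = ""),
           s3 = paste(genotax:::mutate_bases(chars, 0.05), collapse = ""),
           s4 = paste(genotax:::mutate_bases(chars, 0.10), collapse = ""))
  suppressWarnings({
    m <- build_matrix(ssu, index = "SSU")
    v <- as.matrix(m)
    expect_equal(diag(v), c(s1 = 100, s2 = 100, s3 = 100, s4 = 100))
    expect_equal(v, t(v))
    for (pair in list(c("s1", "s2"), c("s2", "s4"), c("s3", "s4"))) {
      direct <- compute_16s_identity(ssu[[pair[1]]], ssu[[pair[2]]])$value
      expect_equal(v[pair[1], pair[2]], direct)
    }
  })
  # identical members give all-100 matrices
  suppressWarnings(
    m100 <- build_matrix(c(a = base, b = base, c = base), index = "SSU"))
  expect_true(all(as.matrix(m100) == 100))
})

test_that("similarity_matrix symmetrizes directional raw values", {
  raw <- matrix(c(100, 80, 90, 100), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  m <- similarity_matrix(raw, "ANI")
  expect_equal(as.matrix(m)["a", "b"], 85)
  expect_equal(as.matrix(m)["b", "a"], 85)
})

block_matrix <- function() {
  labs <- c("a1", "a2", "a3", "b1", "b2", "b3")
  v <- matrix(60, 6, 6, dimnames = list(labs, labs))
  v[1:3, 1:3] <- 90
  v[4:6, 4:6] <- 90
  diag(v) <- 100
  toy_matrix(v)
}

test_that("cluster_and_cut separates planted blocks at the threshold", {
  m <- block_matrix()
  cl <- cluster_and_cut(m, 70)
  grp <- tidy(cl)
  expect_equal(length(unique(grp$cluster)), 2L)
  expect_equal(length(unique(grp$cluster[1:3])), 1L)
  expect_equal(length(unique(grp$cluster[4:6])), 1L)
  expect_error(cluster_and_cut(m, 101), "between 0 and 100")
  ident <- toy_matrix(matrix(100, 3, 3,
                             dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(length(unique(tidy(cluster_and_cut(ident, 50))$cluster)), 1L)
})

test_that("cluster hierarchy is monotone: higher thresholds refine lower", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 8
    labs <- paste0("g", 1:n)
    v <- matrix(runif(n * n, 50, 100), n, n, dimnames = list(labs, labs))
    m <- similarity_matrix(v, "AAI")
    lo <- tidy(cluster_and_cut(m, 60))
    hi <- tidy(cluster_and_cut(m, 85))
    joined <- dplyr::left_join(hi, lo, by = "genome_id",
                               suffix = c("_hi", "_lo"))
    # every fine (high-threshold) cluster sits inside one coarse cluster
    spans <- tapply(joined$cluster_lo, joined$cluster_hi,
                    function(x) length(unique(x)))
    expect_true(all(spans == 1L))
  }
})

test_that("threshold inference uses the gap midpoint when separable", {
  labs <- c("a1", "a2", "a3", "b1")
  v <- matrix(0, 4, 4, dimnames = list(labs, labs))
  v["a1", "a2"] <- v["a2", "a1"] <- 80
  v["a1", "a3"] <- v["a3", "a1"] <- 85
  v["a2", "a3"] <- v["a3", "a2"] <- 90
  v["a1", "b1"] <- v["b1", "a1"] <- 60
  v["a2", "b1"] <- v["b1", "a2"] <- 65
  v["a3", "b1"] <- v["b1", "a3"] <- 70
  diag(v) <- 100
  tr <- infer_threshold(toy_matrix(v),
                        c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
  out <- glance(tr)
  expect_equal(out$threshold, 75)
  expect_equal(out$n_violations, 0L)
  expect_equal(out$min_intra, 80)
  expect_equal(out$max_inter, 70)
  expect_error(infer_threshold(toy_matrix(v), c(a1 = "A", a2 = "A", a3 = "A")),
               "missing genome")
})

test_that("overlapping distributions minimize violations (scan oracle)", {
  labs <- c("a1", "a2", "b1", "b2")
  v <- matrix(72, 4, 4, dimnames = list(labs, labs))
  v["a1", "a2"] <- v["a2", "a1"] <- 70
  v["b1", "b2"] <- v["b2", "b1"] <- 80
  diag(v) <- 100
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  tr <- infer_threshold(toy_matrix(v), lab)
  expect_gte(tr$n_violations, 1L)
  # exhaustive scan over all candidate cut points
  intra <- c(70, 80)
  inter <- rep(72, 4)
  cand <- sort(unique(c(intra, inter)))
  best <- min(vapply(cand, function(t) sum(intra < t) + sum(inter >= t),
                     numeric(1)))
  expect_equal(tr$n_violations, as.integer(best))
})

test_that("index regression recovers exact and planted linear relations", {
  set.seed(33)
  n <- 15
  labs <- paste0("g", 1:n)
  x <- matrix(runif(n * n, 60, 95), n, n, dimnames = list(labs, labs))
  mx <- similarity_matrix(x, "ANI")
  my <- similarity_matrix(as.matrix(mx), "AAI")
  exact <- index_regression(mx, my)
  expect_equal(exact$slope, 1.0)
  expect_equal(exact$r_squared, 1.0)
  # independent noise: r^2 stays near zero (10 seeds)
  r2 <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y <- matrix(runif(n * n, 60, 95), n, n, dimnames = list(labs, labs))
    index_regression(mx, similarity_matrix(y, "POCP"))$r_squared
  }, numeric(1))
  expect_lt(mean(r2), 0.1)
  # planted slope
  set.seed(77)
  vy <- 0.8 * as.matrix(mx) + 10 +
    matrix(stats::rnorm(n * n, 0, 0.5), n, n)
  vy <- (vy + t(vy)) / 2
  dimnames(vy) <- list(labs, labs)
  planted <- index_regression(mx, similarity_matrix(vy, "AAI"))
  expect_lt(abs(planted$slope - 0.8), 0.05)
  # degenerate predictor
  flat <- similarity_matrix(matrix(80, n, n, dimnames = list(labs, labs)),
                            "ANI")
  expect_error(index_regression(flat, my), "zero variance")
})
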