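test_that("p-distance uses pairwise deletion and is bounded", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance(c(a = "AA-A", b = "AAAA"))["a", "b"], 0)
  d <- p_distance(c(a = "AARNDC", b = "CRANDC", c = "AA--DC"))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_error(p_distance(c(a = "--AA", b = "AA--")), "no comparable sites")
  expect_error(p_distance(c(a = "AAA", b = "AAAA")), "equal length")
})

test_that("the quartet tree matches the input metric and the least-squares best topology", {
  taxa <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, taxa)
  pm <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(pm, d, tolerance = 1e-12)
  # exhaustive least squares over the three quartet topologies picks AB|CD
  rss <- c(
    ABCD = ls_fit_quartet(d, list(c("A", "B"), c("C", "D"))),
    ACBD = ls_fit_quartet(d, list(c("A", "C"), c("B", "D"))),
    ADBC = ls_fit_quartet(d, list(c("A", "D"), c("B", "C")))
  )
  expect_identical(names(which.min(rss)), "ABCD")
  expect_lt(rss[["ABCD"]], 1e-18)
  key <- kinomevo:::tree_bipartitions(tr)
  expect_true("C|D" %in% key || "A|B" %in% key)
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(tr$Nnode, 1L)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["x"]], (2 + 3 - 5) / 2)
  expect_equal(len[["y"]], (2 + 5 - 3) / 2)
  expect_equal(len[["z"]], (3 + 5 - 2) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d2 <- d
  d2[1, 2] <- 99
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("additive metrics are recovered exactly, matching ape's NJ topology", {
  skip_if_not_installed("phangorn")
  withr::with_seed(99, {
    for (r in 1:50) {
      n <- sample(4:12, 1)
      true_tree <- random_additive_tree(n)
      d <- ape::cophenetic.phylo(true_tree)
      mine <- neighbor_joining(d)
      expect_equal(phangorn::RF.dist(ape::unroot(true_tree), mine), 0)
      expect_equal(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)], d,
                   tolerance = 1e-9)
      ref <- ape::nj(d)
      expect_equal(phangorn::RF.dist(ref, mine), 0)
    }
  })
})

test_that("branch lengths are never negative", {
  withr::with_seed(17, {
    for (r in 1:10) {
      n <- sample(4:9, 1)
      d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
      d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 1)
      d <- d + t(d)
      tr <- neighbor_joining(d) # noisy, non-additive matrices
      expect_true(all(tr$edge.length >= 0))
      expect_setequal(tr$tip.label, rownames(d))
    }
  })
})

test_that("bootstrap supports behave at the extremes and are deterministic", {
  # every column carries the same split pattern: resampling cannot change
  # the matrix, so every internal edge is supported in all replicates
  aln <- c(a = strrep("A", 30), b = strrep("A", 30),
           c = strrep("T", 30), d = strrep("T", 30),
           e = strrep("C", 30), f = strrep("C", 30))
  tr <- bootstrap_support(aln, replicates = 25, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  withr::with_seed(8, {
    taxa <- paste0("t", 1:6)
    aln2 <- setNames(vapply(taxa, function(x) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1)), taxa)
  })
  one <- bootstrap_support(aln2, replicates = 1, seed = 5)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  t1 <- bootstrap_support(aln2, replicates = 20, seed = 7)
  t2 <- bootstrap_support(aln2, replicates = 20, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  sup2 <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup2[!is.na(sup2)] >= 0 & sup2[!is.na(sup2)] <= 100))
})
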