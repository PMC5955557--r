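ranked_genes <- function(n_per_chrom, chroms = c("chr1", "chr2")) {
  do.call(rbind, lapply(chroms, function(ch) {
    tibble::tibble(gene_id = sprintf("%s_g%03d", ch, seq_len(n_per_chrom)),
                   chromosome = ch, start = seq_len(n_per_chrom) * 1000L)
  }))
}

test_that("homology filtering keeps, canonicalizes and deduplicates", {
  pairs <- tibble::tibble(
    gene_a = c("a", "b", "x", "m", "self"),
    gene_b = c("b", "a", "y", "n", "self"),
    evalue = c(1e-120, 1e-150, 1e-50, 1e-200, 1e-300)
  )
  got <- filter_homology(pairs)
  expect_equal(nrow(got), 2)
  expect_true(all(got$gene_a < got$gene_b))
  expect_equal(got$evalue[got$gene_a == "a"], 1e-150) # best E-value kept
  expect_false("x" %in% c(got$gene_a, got$gene_b))    # 1e-50 fails the cutoff
  expect_equal(nrow(filter_homology(pairs, evalue_max = 1e-40)), 3)
})

test_that("tandem clusters chain consecutive homologs on one chromosome", {
  genes <- ranked_genes(20)
  g <- function(i, ch = "chr1") sprintf("%s_g%03d", ch, i)
  pairs <- tibble::tibble(
    gene_a = c(g(5), g(6), g(5), g(9), g(3)),
    gene_b = c(g(6), g(7), g(7), g(5), g(3, "chr2")),
    evalue = 1e-150
  )
  tc <- tandem_clusters(genes, pairs, max_gap = 1)
  expect_equal(nrow(tc), 3)
  expect_identical(tc$gene_id, c(g(5), g(6), g(7))) # one cluster, rank order
  expect_equal(unique(tc$cluster_id), 1L)
  # gap above max_gap: no link; different chromosomes: no link
  expect_false(g(9) %in% tc$gene_id)
  expect_false(g(3) %in% tc$gene_id)
  # widening the gap captures the rank-5/9 pair
  tc2 <- tandem_clusters(genes, pairs, max_gap = 4)
  expect_true(g(9) %in% tc2$gene_id)
  # clusters partition their members: no duplicates, no cross-chromosome cluster
  expect_false(anyDuplicated(tc2$gene_id) > 0)
  expect_equal(dplyr::n_distinct(paste(tc2$cluster_id, tc2$chromosome)),
               dplyr::n_distinct(tc2$cluster_id))
})

test_that("collinear blocks recover planted diagonals in both orientations", {
  genes <- ranked_genes(60)
  g <- function(i, ch) sprintf("%s_g%03d", ch, i)
  diag_pairs <- tibble::tibble(
    gene_a = g(10:15, "chr1"), gene_b = g(20:25, "chr2"), evalue = 1e-150
  )
  anti_pairs <- tibble::tibble(
    gene_a = g(40:45, "chr1"), gene_b = g(45:40, "chr2"), evalue = 1e-150
  )
  bl <- collinear_blocks(genes, dplyr::bind_rows(diag_pairs, anti_pairs))
  expect_equal(dplyr::n_distinct(bl$block_id), 2)
  ors <- bl |> dplyr::distinct(block_id, orientation)
  expect_setequal(ors$orientation, c("same", "inverted"))
  # anchors are monotone in rank on both axes
  for (b in split(bl, bl$block_id)) {
    expect_true(all(diff(b$rank_a) > 0))
    expect_true(all(diff(b$rank_b) > 0) || all(diff(b$rank_b) < 0))
  }
  # a 4-anchor diagonal stays below the default min_anchors
  short <- tibble::tibble(gene_a = g(30:33, "chr1"), gene_b = g(30:33, "chr2"),
                          evalue = 1e-150)
  expect_equal(nrow(collinear_blocks(genes, short)), 0)
  expect_equal(nrow(collinear_blocks(genes, short, min_anchors = 4)), 4)
  # anchors further apart than max_rank_gap do not chain
  sparse <- tibble::tibble(gene_a = g(seq(1, 60, by = 12), "chr1"),
                           gene_b = g(seq(1, 60, by = 12), "chr2"),
                           evalue = 1e-150)
  expect_equal(nrow(collinear_blocks(genes, sparse, min_anchors = 5,
                                     max_rank_gap = 10)), 0)
})

test_that("single-correspondence counts genes appearing in exactly one pair", {
  p <- function(a, b) tibble::tibble(gene_a = a, gene_b = b)
  expect_equal(single_correspondence(p(c("a1", "a2"), c("b1", "b2")))$fraction, 1)
  expect_equal(single_correspondence(p(c("a1", "a1"), c("b1", "b2")))$fraction, 0)
  got <- single_correspondence(p(c("a1", "a2", "a2"), c("b1", "b2", "b3")))
  expect_equal(got$fraction, 1 / 3)
  expect_identical(got$pairs$single, c(TRUE, FALSE, FALSE))
})

test_that("Ks histograms bin correctly and expose local modes", {
  ks <- c(0.01, 0.05, 0.07, 0.45, 0.5, 0.55, 0.52, 1.7, NA)
  h <- ks_histogram(ks)
  expect_equal(sum(h$count), 8)
  expect_equal(h$count[h$bin_start == 0], 3)
  expect_equal(h$count[abs(h$bin_start - 0.4) < 1e-9], 1)
  expect_equal(h$count[abs(h$bin_start - 0.5) < 1e-9], 3)
  modes <- ks_local_modes(h)
  expect_true(any(modes$bin_start < 0.1))
  expect_true(any(modes$bin_start >= 0.4 & modes$bin_start < 0.6))
})
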