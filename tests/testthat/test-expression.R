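counts_tbl <- function(mat) {
  tibble::as_tibble(cbind(tibble::tibble(gene_id = rownames(mat)),
                          as.data.frame(mat)))
}

test_that("RPKM follows its definition with column-sum library sizes", {
  m <- matrix(c(10, 1e6 - 10), nrow = 2, dimnames = list(c("g1", "fill"), "s1"))
  len <- c(g1 = 1000, fill = 2000)
  expect_equal(rpkm(m, len)["g1", "s1"], 10)
  m2 <- matrix(c(5, 2e6 - 5), nrow = 2, dimnames = list(c("g", "fill"), "s1"))
  expect_equal(rpkm(m2, c(g = 500, fill = 1000))["g", "s1"], 5)
  expect_equal(rpkm(matrix(c(0, 100), 2, dimnames = list(c("a", "b"), "s")),
                    c(a = 700, b = 100))["a", "s"], 0)
  # tibble in, tibble out
  tb <- counts_tbl(m)
  got <- rpkm(tb, tibble::tibble(gene_id = c("g1", "fill"), length = c(1000, 2000)))
  expect_s3_class(got, "tbl_df")
  expect_equal(got$s1[1], 10)
  expect_error(rpkm(m, c(g1 = 0, fill = 10)), "positive")
  expect_error(rpkm(matrix(0, 1, 1, dimnames = list("g", "s")), c(g = 100)),
               "library")
})

test_that("RPKM is linear in counts at fixed library size", {
  withr::with_seed(33, {
    m <- matrix(rpois(60, 100), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    m["g4", ] <- 10000 # deep filler row absorbs compensation
    len <- setNames(sample(500:2000, 6), rownames(m))
    r1 <- rpkm(m, len)
    m2 <- m
    m2["g3", "s2"] <- 2 * m["g3", "s2"]
    m2["g4", "s2"] <- m2["g4", "s2"] - m["g3", "s2"] # keep the column sum
    r2 <- rpkm(m2, len)
    expect_equal(r2["g3", "s2"], 2 * r1["g3", "s2"])
    expect_equal(r2["g3", "s1"], r1["g3", "s1"])
  })
})

test_that("log2 fold change uses the pseudo-count symmetrically", {
  m <- matrix(c(8, 8, 2, 2,
                0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "zero"), c("t1", "t2", "c1", "c2")))
  samples <- tibble::tibble(sample = c("t1", "t2", "c1", "c2"),
                            group = c("treatment", "treatment", "control", "control"))
  exact <- log2_fold_change(m, samples, pseudo = 0)
  expect_equal(exact$log2fc[exact$gene_id == "up"], 2)
  withp <- log2_fold_change(m, samples, pseudo = 1)
  expect_equal(withp$log2fc[withp$gene_id == "zero"], 0)
  expect_equal(log2_fold_change(m[, c(1, 2, 1, 2)] |>
                                  `colnames<-`(c("t1", "t2", "c1", "c2")),
                                samples)$log2fc[1], 0)
})

test_that("the screen gates on both fold change and p-value", {
  withr::with_seed(44, {
    n <- 6
    mk <- function(t_mu, c_mu, sd) {
      c(rnorm(4, t_mu, sd), rnorm(4, c_mu, sd))
    }
    m <- rbind(
      strong = 2^mk(10, 8, 0.05),     # |log2fc| ~ 2, tiny p -> retained
      small_fc = 2^mk(8.3, 8, 0.01),  # p tiny but FC ~ 1.23 -> rejected
      noisy = 2^mk(12, 8, 6),         # big FC but unstable -> p too large
      flat = 2^mk(8, 8, 0.05)
    )
    colnames(m) <- c(paste0("t", 1:4), paste0("c", 1:4))
    samples <- tibble::tibble(sample = colnames(m),
                              group = rep(c("treatment", "control"), each = 4))
    de <- differential_screen(m, samples)
    got <- setNames(de$retained, de$gene_id)
    expect_true(got[["strong"]])
    expect_false(got[["small_fc"]])
    expect_false(got[["flat"]])
    # the retained flag is exactly the conjunction of the two gates
    expect_identical(de$retained,
                     abs(de$log2fc) > log2(1.5) & de$p_value < 0.01)
    expect_true(de$p_value[de$gene_id == "noisy"] >= 0.01 || got[["noisy"]])
  })
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  withr::with_seed(55, {
    m <- matrix(2^rnorm(80, 8, 1), 10, 8,
                dimnames = list(paste0("g", 1:10),
                                c(paste0("t", 1:4), paste0("c", 1:4))))
    samples <- tibble::tibble(sample = colnames(m),
                              group = rep(c("treatment", "control"), each = 4))
    flipped <- dplyr::mutate(samples, group = ifelse(group == "treatment",
                                                     "control", "treatment"))
    a <- differential_screen(m, samples, pseudo = 0)
    b <- differential_screen(m, flipped, pseudo = 0)
    expect_equal(a$log2fc, -b$log2fc)
    expect_equal(a$p_value, b$p_value)
  })
})

test_that("screen validates its inputs and supports BH adjustment", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  samples <- tibble::tibble(sample = paste0("s", 1:4),
                            group = c("treatment", "treatment", "control", "control"))
  too_few <- tibble::tibble(sample = paste0("s", 1:4),
                            group = c("treatment", rep("control", 3)))
  expect_error(differential_screen(m, too_few), "2 samples")
  adj <- differential_screen(m, samples, adjust = TRUE)
  expect_true("p_adj" %in% names(adj))
  expect_true(all(adj$p_adj >= adj$p_value))
  expect_s3_class(glance(adj), "tbl_df")
  expect_equal(glance(adj)$n_genes, 2)
})
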