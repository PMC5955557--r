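hit_row <- function(gene_id, cov, evalue, seq_start = 1L, seq_end = 200L,
                    model_length = 200L) {
  tibble::tibble(
    gene_id = gene_id, model_name = "Pkinase",
    model_start = 1L, model_end = as.integer(round(cov * model_length)),
    model_length = model_length,
    seq_start = seq_start, seq_end = seq_end, evalue = evalue
  )
}

test_that("coverage fraction is the covered share of the model", {
  h <- tibble::tibble(model_start = c(1, 51, 10), model_end = c(200, 150, 12),
                      model_length = c(200, 200, 300))
  expect_equal(coverage_fraction(h), c(1, 0.5, 0.01))
  expect_error(coverage_fraction(tibble::tibble(model_start = 1, model_end = 1,
                                                model_length = 0)), "positive")
  expect_error(coverage_fraction(tibble::tibble(model_start = 5, model_end = 3,
                                                model_length = 10)), "invalid")
})

test_that("the typicality gate applies coverage and E-value jointly per hit", {
  hits <- dplyr::bind_rows(
    hit_row("typ", 0.6, 1e-30),
    hit_row("boundary", 0.5, 1e-30),            # exactly 50% coverage
    hit_row("joint", 0.9, 0.5),                 # high coverage, bad E-value
    hit_row("joint", 0.3, 1e-10),               # good E-value, low coverage
    hit_row("nohit_pass", 0.9, 0.02)            # only an E-value failure
  )
  got <- gate_typical(hits)
  lab <- setNames(got$typicality, got$gene_id)
  expect_identical(lab[["typ"]], "typical")
  expect_identical(lab[["boundary"]], "atypical")  # strict > 0.5
  expect_identical(lab[["joint"]], "atypical")
  expect_identical(lab[["nohit_pass"]], "non_kinase")
})

test_that("typicality partitions the gene universe", {
  hits <- dplyr::bind_rows(hit_row("a", 0.7, 1e-40), hit_row("b", 0.2, 1e-40))
  uni <- c("a", "b", "c", "d")
  got <- gate_typical(hits, universe = uni)
  expect_identical(got$gene_id, uni)
  expect_identical(got$typicality, c("typical", "atypical", "non_kinase", "non_kinase"))
  expect_equal(sum(table(got$typicality)), length(uni))
  # empty table: everything is non-kinase
  empty <- gate_typical(hits[0, ], universe = c("x", "y"))
  expect_true(all(empty$typicality == "non_kinase"))
})

test_that("raising a hit's coverage never demotes its gene", {
  withr::with_seed(5, {
    for (r in 1:20) {
      hits <- dplyr::bind_rows(lapply(1:3, function(i) {
        hit_row("g", runif(1, 0.1, 0.9), 10^-runif(1, 0, 40))
      }))
      before <- gate_typical(hits)$typicality
      hits$model_end <- pmin(hits$model_length,
                             hits$model_end + sample(0:50, nrow(hits), replace = TRUE))
      after <- gate_typical(hits)$typicality
      if (before == "typical") expect_identical(after, "typical")
    }
  })
})

test_that("kinase-domain counting resolves overlaps greedily by E-value", {
  two <- dplyr::bind_rows(
    hit_row("g", 0.8, 1e-50, seq_start = 1, seq_end = 250),
    hit_row("g", 0.8, 1e-40, seq_start = 400, seq_end = 650)
  )
  expect_equal(count_kinase_domains(two)$n_kinase_domains, 2L)
  overlapping <- dplyr::bind_rows(
    hit_row("g", 0.8, 1e-50, seq_start = 1, seq_end = 250),
    hit_row("g", 0.8, 1e-40, seq_start = 200, seq_end = 450)
  )
  expect_equal(count_kinase_domains(overlapping)$n_kinase_domains, 1L)
  single <- hit_row("g", 0.8, 1e-50)
  expect_equal(count_kinase_domains(single)$n_kinase_domains, 1L)
  # non-qualifying hits never contribute
  with_junk <- dplyr::bind_rows(two, hit_row("g", 0.3, 1e-60, 700, 800),
                                hit_row("g", 0.9, 0.5, 900, 1000))
  expect_equal(count_kinase_domains(with_junk)$n_kinase_domains, 2L)
})

test_that("subfamily assignment takes the top score with a lexicographic tie-break", {
  cat <- subfamily_catalog()
  sc <- tibble::tibble(gene_id = "g",
                       subfamily = c("RLK-Pelle_DLSV", "CMGC_MAPK"),
                       bit_score = c(310.2, 120.5))
  got <- assign_subfamily(sc, cat)
  expect_identical(got$subfamily, "RLK-Pelle_DLSV")
  expect_identical(got$group, "RLK")
  tie <- tibble::tibble(gene_id = "g", subfamily = c("CAMK_AMPK", "AGC_NDR"),
                        bit_score = c(100, 100))
  expect_identical(assign_subfamily(tie, cat)$subfamily, "AGC_NDR")
  expect_identical(assign_subfamily(tie[2:1, ], cat)$subfamily, "AGC_NDR")
  one <- tibble::tibble(gene_id = "g", subfamily = "STE_STE11", bit_score = 50)
  expect_identical(assign_subfamily(one, cat)$subfamily, "STE_STE11")
  bad <- tibble::tibble(gene_id = "g", subfamily = "NOT_A_SUBFAMILY", bit_score = 1)
  expect_error(assign_subfamily(bad, cat), "catalog")
})

test_that("representative sampling follows the subfamily-size rule", {
  expect_length(select_representatives(paste0("g", 1:5), seed = 1), 1)
  expect_length(select_representatives(paste0("g", 1:6), seed = 1), 1)
  expect_length(select_representatives(paste0("g", 1:7), seed = 1), 2)
  expect_length(select_representatives(paste0("g", 1:30), seed = 1), 2)
  expect_length(select_representatives(paste0("g", 1:31), seed = 1), 3)
  members <- paste0("g", 1:31)
  r1 <- select_representatives(members, seed = 42)
  expect_identical(r1, select_representatives(members, seed = 42))
  expect_true(all(r1 %in% members))
  df <- tibble::tibble(subfamily = rep(c("A", "B"), c(5, 31)),
                       gene_id = paste0("g", 1:36))
  got <- select_representatives(df, seed = 1)
  expect_equal(as.integer(table(got$subfamily)), c(1L, 3L))
})
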