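small_cfg <- function(seed = 1, gpc = 50) {
  sim_config(seed = seed, n_chromosomes = 2, genes_per_chromosome = gpc,
             tandem_arrays = tibble::tibble(
               chromosome = "chr1", start_rank = 5L, size = 3L,
               subfamily = "RLK-Pelle_LRR-XI-1"
             ),
             collinear_blocks = tibble::tibble(
               chr_a = "chr1", chr_b = "chr2", start_a = 20L, start_b = 25L,
               n_anchors = 5L, target_ks = 0.5, orientation = "same"
             ))
}

test_that("gene counts are conserved and identifiers unique", {
  sim <- simulate_genome(small_cfg())
  expect_equal(nrow(sim$genes), 100)
  expect_false(anyDuplicated(sim$genes$gene_id) > 0)
  expect_length(sim$cds, 100)
  expect_length(sim$proteins, 100)
  expect_true(all(sim$genes$strand %in% c("+", "-")))
  # coordinate order equals rank order, genes never overlap
  for (ch in unique(sim$genes$chromosome)) {
    g <- sim$genes[sim$genes$chromosome == ch, ]
    g <- g[order(g$rank), ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("the simulator is a pure function of its configuration", {
  s1 <- simulate_genome(small_cfg(seed = 7))
  s2 <- simulate_genome(small_cfg(seed = 7))
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$homology, s2$homology)
  s3 <- simulate_genome(small_cfg(seed = 8))
  expect_false(identical(s1$cds, s3$cds))
  # written files are byte-identical for equal seeds
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1, hits = simulate_domain_hits(s1),
                   counts = simulate_counts(s1))
  write_simulation(s2, d2, hits = simulate_domain_hits(s2),
                   counts = simulate_counts(s2))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("every coding sequence translates without internal stops", {
  sim <- simulate_genome(small_cfg(seed = 2))
  expect_false(any(grepl("\\*", sim$proteins)))
  expect_true(all(nchar(sim$cds) %% 3 == 0))
  expect_equal(unname(nchar(sim$proteins)), unname(nchar(sim$cds)) / 3)
  # CDS segment lengths agree with the sequence length
  seg_len <- tapply(sim$cds_segments$end - sim$cds_segments$start + 1,
                    sim$cds_segments$gene_id, sum)
  expect_equal(as.numeric(seg_len[names(sim$cds)]), as.numeric(nchar(sim$cds)))
})

test_that("planted tandem arrays occupy consecutive ranks with one subfamily", {
  sim <- simulate_genome(small_cfg(seed = 3))
  tc <- sim$truth$tandem_clusters
  expect_equal(tc$rank, 5:7)
  labs <- sim$truth$labels
  expect_true(all(labs$subfamily[match(tc$gene_id, labs$gene_id)] == "RLK-Pelle_LRR-XI-1"))
  expect_true(all(labs$typicality[match(tc$gene_id, labs$gene_id)] == "typical"))
})

test_that("collinear duplicates preserve exon structure and hit their Ks target", {
  sim <- simulate_genome(small_cfg(seed = 4))
  cb <- sim$truth$collinear_blocks
  ph <- sim$truth$phases
  expect_identical(ph$phase_string[match(cb$gene_a, ph$gene_id)],
                   ph$phase_string[match(cb$gene_b, ph$gene_id)])
  kk <- kaks_pairs(cb[, c("gene_a", "gene_b")], sim$cds)
  expect_true(all(kk$ks >= 0.4 & kk$ks < 0.6))
})

test_that("overlapping planted structures are a configuration error", {
  expect_error(
    sim_config(tandem_arrays = tibble::tibble(
      chromosome = c("chr1", "chr1"), start_rank = c(5L, 6L), size = c(3L, 3L),
      subfamily = "RLK-Pelle_DLSV"
    )),
    "overlap"
  )
  expect_error(small_cfg(gpc = 20), "bounds")
})

test_that("hit evidence matches planted typicality exactly", {
  sim <- simulate_genome(sim_config(seed = 5, atypical_fraction = 0.1))
  hs <- simulate_domain_hits(sim)
  labs <- sim$truth$labels
  n_kin <- sum(labs$kinase)
  expect_equal(sum(labs$typicality == "atypical"), round(0.1 * n_kin))
  cov <- coverage_fraction(hs$hits)
  by_gene <- split(cov, hs$hits$gene_id)
  for (g in labs$gene_id[labs$typicality == "atypical"]) {
    expect_true(all(by_gene[[g]] <= 0.5), info = g)
  }
  # the boundary gene sits exactly on half coverage
  atyp1 <- labs$gene_id[labs$typicality == "atypical"][1]
  expect_true(any(abs(by_gene[[atyp1]] - 0.5) < 1e-12))
  # multi-domain genes have as many non-overlapping qualifying hits as planted
  doms <- count_kinase_domains(hs$hits)
  planted <- labs[labs$typicality == "typical", ]
  expect_equal(doms$n_kinase_domains[match(planted$gene_id, doms$gene_id)],
               planted$n_domains)
  # the score table ranks the true subfamily first for every typical gene
  top <- assign_subfamily(hs$scores, sim$config$subfamily_catalog)
  expect_identical(top$subfamily[match(planted$gene_id, top$gene_id)],
                   planted$subfamily)
})

test_that("simulated counts carry the planted effects and nothing else", {
  cfg0 <- sim_config(seed = 6, expression = list(
    n_samples_per_group = 4L, planted_log2fc = 0, dispersion = 0.05, n_de_genes = 0L
  ))
  sim0 <- simulate_genome(cfg0)
  cn0 <- simulate_counts(sim0)
  m <- as.matrix(cn0$counts[, -1])
  trt <- cn0$samples$sample[cn0$samples$group == "treatment"]
  ctl <- cn0$samples$sample[cn0$samples$group == "control"]
  pv <- apply(m, 1, function(x) {
    tryCatch(t.test(x[trt], x[ctl])$p.value, error = function(e) 1)
  })
  expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.12) # near the nominal rate
  expect_identical(simulate_counts(sim0)$counts, cn0$counts)

  # deterministic limit: tiny dispersion, strong effect -> mean ratio near 4
  cfg2 <- sim_config(seed = 6, expression = list(
    n_samples_per_group = 4L, planted_log2fc = 2, dispersion = 1e-9, n_de_genes = 30L
  ))
  sim2 <- simulate_genome(cfg2)
  cn2 <- simulate_counts(sim2)
  m2 <- as.matrix(cn2$counts[, -1])
  rownames(m2) <- cn2$counts$gene_id
  de <- sim2$truth$de_genes
  up <- de$gene_id[de$log2fc > 0]
  ratio <- rowMeans(m2[up, trt, drop = FALSE]) / rowMeans(m2[up, ctl, drop = FALSE])
  expect_equal(unname(ratio), rep(4, length(up)), tolerance = 0.2)
})

test_that("GFF3 and FASTA round-trip through the readers", {
  sim <- simulate_genome(small_cfg(seed = 9))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  segs <- read_gene_models(file.path(dir, "genome.gff3"))
  orig <- sim$cds_segments[order(sim$cds_segments$gene_id, sim$cds_segments$start), ]
  back <- segs[order(segs$gene_id, segs$start), ]
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$chromosome, orig$chromosome)
  prot <- read_fasta(file.path(dir, "proteins.fasta"), "AA")
  expect_identical(prot, sim$proteins)
  cds <- read_fasta(file.path(dir, "cds.fasta"), "DNA")
  expect_identical(cds, sim$cds)
})
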