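#' Simulate a multi-chromosome genome with a planted kinome
#'
#' Generates gene models, coding and protein sequences, homology pairs and a
#' complete ground truth for a synthetic genome: a configurable fraction of
#' genes are kinases with subfamily labels drawn from the catalog, tandem
#' arrays occupy consecutive gene ranks and share a subfamily, collinear
#' duplicate blocks pair anchor genes across chromosomes with coding
#' sequences diverged to a target Ks ([evolve_duplicate()]), and every gene
#' has a multi-exon structure with known intron phases. Genes never overlap
#' and intergenic gaps are fixed, so coordinate order equals rank order.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `kinome_sim`: a list with elements `config`,
#'   `genes` (one row per gene), `cds_segments` (one row per CDS segment, in
#'   genomic order), `cds` and `proteins` (named character vectors),
#'   `homology` (gene_a, gene_b, evalue) and `truth` (labels, phases, tandem
#'   clusters, collinear blocks, differentially expressed genes).
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(seed = 1, genes_per_chromosome = 60,
#'                                   collinear_blocks = NULL))
#' nrow(sim$genes)
simulate_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.random_cds <- function(n_codons) {
  .ng86_init_sites()
  sense <- .ng86$codons[!.ng86$is_stop]
  paste(c("ATG", sense[sample.int(length(sense), n_codons - 1L, replace = TRUE)]),
        collapse = "")
}

.translate_cds <- function(cds) {
  gc <- .genetic_code()
  paste(gc[.split_codons(cds)], collapse = "")
}

# protein-coordinate layout of the k kinase domains of a gene
.domain_layout <- function(n_codons, k) {
  part <- (n_codons - 20L) %/% k
  list(starts = 21L + (seq_len(k) - 1L) * part,
       len = min(200L, part - 10L))
}

# sample with replacement, safe for length-1 ranges
.sample_from <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]

# random composition of `total` into `k` parts, each >= min_part
.random_partition <- function(total, k, min_part) {
  if (k == 1L) return(total)
  extra <- total - k * min_part
  if (extra < 0) abort("coding length too short for requested exon count")
  alloc <- tabulate(sample.int(k, extra, replace = TRUE), nbins = k)
  min_part + alloc
}

.simulate_genome_impl <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  plan <- tidyr::expand_grid(chromosome = chroms,
                             rank = seq_len(config$genes_per_chromosome))
  plan$gene_id <- sprintf("%s_g%04d", plan$chromosome, plan$rank)
  n <- nrow(plan)
  key <- function(chrom, rank) match(paste0(chrom, ":", rank),
                                     paste0(plan$chromosome, ":", plan$rank))

  # --- planted membership -------------------------------------------------
  ta <- config$tandem_arrays
  cb <- config$collinear_blocks
  tandem_rows <- list()
  for (i in seq_len(nrow(ta))) {
    tandem_rows[[i]] <- key(ta$chromosome[i], seq(ta$start_rank[i], length.out = ta$size[i]))
  }
  coll_a <- list()
  coll_b <- list()
  for (i in seq_len(nrow(cb))) {
    ranks_a <- seq(cb$start_a[i], length.out = cb$n_anchors[i])
    ranks_b <- if (cb$orientation[i] == "same") {
      seq(cb$start_b[i], length.out = cb$n_anchors[i])
    } else {
      rev(seq(cb$start_b[i], length.out = cb$n_anchors[i]))
    }
    coll_a[[i]] <- key(cb$chr_a[i], ranks_a)
    coll_b[[i]] <- key(cb$chr_b[i], ranks_b)
  }
  planted <- unique(c(unlist(tandem_rows), unlist(coll_a), unlist(coll_b)))

  # --- kinase labels ------------------------------------------------------
  n_kinase <- max(length(planted), round(config$kinase_fraction * n))
  free <- setdiff(seq_len(n), planted)
  extra_kinase <- free[sample.int(length(free), n_kinase - length(planted))]
  kinase <- sort(c(planted, extra_kinase))
  n_atypical <- round(config$atypical_fraction * length(kinase))
  atyp_pool <- setdiff(kinase, planted)
  if (length(atyp_pool) < n_atypical) abort("not enough unplanted kinases for atypical_fraction")
  atypical <- atyp_pool[sample.int(length(atyp_pool), n_atypical)]

  typicality <- rep("non_kinase", n)
  typicality[kinase] <- "typical"
  typicality[atypical] <- "atypical"

  subfam <- rep(NA_character_, n)
  cat_sub <- config$subfamily_catalog$subfamily
  subfam[kinase] <- cat_sub[sample.int(length(cat_sub), length(kinase), replace = TRUE)]
  for (i in seq_len(nrow(ta))) subfam[tandem_rows[[i]]] <- ta$subfamily[i]

  n_domains <- rep(NA_integer_, n)
  n_domains[typicality == "typical"] <- 1L
  multi_pool <- setdiff(which(typicality == "typical"), planted)
  n_multi <- min(config$n_multi_domain, length(multi_pool))
  multi <- multi_pool[sample.int(length(multi_pool), n_multi)]
  n_domains[multi] <- sample(2:4, n_multi, replace = TRUE)

  # --- per-gene structure and sequence ------------------------------------
  codons <- .sample_from(seq(config$codon_range[1], config$codon_range[2]), n)
  codons[multi] <- n_domains[multi] * 250L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- .sample_from(seq(config$exon_range[1], config$exon_range[2]), n)
  exon_lens <- vector("list", n)   # coding lengths in translation order
  intron_lens <- vector("list", n)
  cds <- character(n)
  for (i in seq_len(n)) {
    exon_lens[[i]] <- .random_partition(3L * codons[i], n_exons[i], config$min_exon_nt)
    intron_lens[[i]] <- if (n_exons[i] > 1L) {
      .sample_from(seq(config$intron_range[1], config$intron_range[2]), n_exons[i] - 1L)
    } else integer(0)
    cds[i] <- .random_cds(codons[i])
  }

  # splice a diverged copy of the subfamily founder domain into each kinase
  # (one copy per planted kinase domain), giving subfamily members a shared,
  # recoverable sequence signal
  kin_idx <- which(typicality != "non_kinase")
  founders <- list()
  for (sf in unique(subfam[kin_idx])) founders[[sf]] <- .random_cds(201L)
  for (i in kin_idx) {
    k <- if (!is.na(n_domains[i])) n_domains[i] else 1L
    lay <- .domain_layout(codons[i], k)
    member_dom <- .split_codons(
      evolve_duplicate(founders[[subfam[i]]], config$subfamily_ks, ka_ks = 0.5)
    )[seq_len(lay$len) + 1L]
    cod_i <- .split_codons(cds[i])
    for (s0 in lay$starts) {
      cod_i[seq(s0, length.out = lay$len)] <- member_dom
    }
    cds[i] <- paste(cod_i, collapse = "")
  }

  copy_structure <- function(src, dst, target_ks) {
    codons[dst] <<- codons[src]
    n_exons[dst] <<- n_exons[src]
    exon_lens[dst] <<- exon_lens[src]
    subfam[dst] <<- subfam[src]
    intron_lens[dst] <<- lapply(n_exons[dst] - 1L, function(k) {
      if (k > 0L) .sample_from(seq(config$intron_range[1], config$intron_range[2]), k) else integer(0)
    })
    for (d in dst) {
      cds[d] <<- evolve_duplicate(cds[src[match(d, dst)]], target_ks, ka_ks = config$ka_ks_ratio)
    }
  }

  truth_tandem <- list()
  for (i in seq_len(nrow(ta))) {
    rows <- tandem_rows[[i]]
    copy_structure(rep(rows[1], length(rows) - 1L), rows[-1], config$tandem_ks)
    truth_tandem[[i]] <- tibble(
      cluster_id = i, chromosome = ta$chromosome[i], subfamily = ta$subfamily[i],
      gene_id = plan$gene_id[rows], rank = plan$rank[rows]
    )
  }
  truth_coll <- list()
  for (i in seq_len(nrow(cb))) {
    a <- coll_a[[i]]
    b <- coll_b[[i]]
    copy_structure(a, b, cb$target_ks[i])
    truth_coll[[i]] <- tibble(
      block_id = i, chr_a = cb$chr_a[i], chr_b = cb$chr_b[i],
      orientation = cb$orientation[i], target_ks = cb$target_ks[i],
      anchor_index = seq_along(a),
      gene_a = plan$gene_id[a], gene_b = plan$gene_id[b],
      rank_a = plan$rank[a], rank_b = plan$rank[b]
    )
  }

  # --- genomic coordinates -------------------------------------------------
  seg_rows <- vector("list", n)
  gene_start <- integer(n)
  gene_end <- integer(n)
  for (chrom in chroms) {
    pos <- 1L
    for (i in which(plan$chromosome == chrom)) {
      lens_tx <- exon_lens[[i]]
      lens_gen <- if (strand[i] == "+") lens_tx else rev(lens_tx)
      intr <- intron_lens[[i]]
      intr_gen <- if (strand[i] == "+") intr else rev(intr)
      starts <- integer(length(lens_gen))
      ends <- integer(length(lens_gen))
      p <- pos
      for (e in seq_along(lens_gen)) {
        starts[e] <- p
        ends[e] <- p + lens_gen[e] - 1L
        p <- ends[e] + 1L + if (e < length(lens_gen)) intr_gen[e] else 0L
      }
      seg_rows[[i]] <- tibble(
        gene_id = plan$gene_id[i], species = config$species,
        chromosome = chrom, strand = strand[i],
        start = starts, end = ends
      )
      gene_start[i] <- starts[1]
      gene_end[i] <- ends[length(ends)]
      pos <- gene_end[i] + config$intergenic_gap
    }
  }

  proteins <- vapply(cds, .translate_cds, character(1), USE.NAMES = FALSE)
  names(cds) <- plan$gene_id
  names(proteins) <- plan$gene_id

  # --- homology -----------------------------------------------------------
  pair_rows <- list()
  add_pairs <- function(ga, gb, lo, hi) {
    if (length(ga) == 0L) return(invisible(NULL))
    pair_rows[[length(pair_rows) + 1L]] <<- tibble(
      gene_a = ga, gene_b = gb, evalue = 10^-runif(length(ga), lo, hi)
    )
  }
  for (tc in truth_tandem) {
    cmb <- utils::combn(tc$gene_id, 2)
    add_pairs(cmb[1, ], cmb[2, ], 120, 180)
  }
  for (bl in truth_coll) add_pairs(bl$gene_a, bl$gene_b, 120, 180)
  n_true <- sum(vapply(pair_rows, nrow, integer(1)))
  n_decoy <- round(config$decoy_homology_fraction * n_true)
  if (n_decoy > 0) {
    da <- sample.int(n, n_decoy, replace = TRUE)
    db <- sample.int(n, n_decoy, replace = TRUE)
    keep <- da != db
    add_pairs(plan$gene_id[da[keep]], plan$gene_id[db[keep]], 101, 115)
  }
  if (config$n_subthreshold_homology > 0) {
    da <- sample.int(n, config$n_subthreshold_homology, replace = TRUE)
    db <- sample.int(n, config$n_subthreshold_homology, replace = TRUE)
    keep <- da != db
    add_pairs(plan$gene_id[da[keep]], plan$gene_id[db[keep]], 20, 80)
  }
  homology <- dplyr::bind_rows(pair_rows)

  # --- expression truth ---------------------------------------------------
  n_de <- min(config$expression$n_de_genes, n)
  de_idx <- sample.int(n, n_de)
  de <- tibble(
    gene_id = plan$gene_id[de_idx],
    log2fc = config$expression$planted_log2fc * rep_len(c(1, -1), n_de)
  )

  phases <- tibble(
    gene_id = plan$gene_id,
    n_exons = n_exons,
    phase_string = vapply(exon_lens, function(l) {
      paste(head(cumsum(l), -1L) %% 3, collapse = "")
    }, character(1))
  )

  groups <- config$subfamily_catalog$group[match(subfam, config$subfamily_catalog$subfamily)]
  genes <- tibble(
    gene_id = plan$gene_id, species = config$species,
    chromosome = plan$chromosome, rank = plan$rank, strand = strand,
    start = gene_start, end = gene_end,
    n_exons = n_exons, cds_length = 3L * codons
  )
  labels <- tibble(
    gene_id = plan$gene_id,
    kinase = typicality != "non_kinase",
    typicality = typicality,
    subfamily = subfam,
    group = groups,
    n_domains = n_domains
  )
  out <- list(
    config = config,
    genes = genes,
    cds_segments = dplyr::bind_rows(seg_rows),
    cds = cds,
    proteins = proteins,
    homology = homology,
    truth = list(
      labels = labels,
      phases = phases,
      tandem_clusters = dplyr::bind_rows(truth_tandem),
      collinear_blocks = dplyr::bind_rows(truth_coll),
      de_genes = de
    )
  )
  class(out) <- "kinome_sim"
  out
}

#' @export
print.kinome_sim <- function(x, ...) {
  cat("<kinome_sim> ", nrow(x$genes), " genes on ", x$config$n_chromosomes,
      " chromosomes; ", sum(x$truth$labels$kinase), " kinases (",
      sum(x$truth$labels$typicality == "typical"), " typical)\n", sep = "")
  invisible(x)
}
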