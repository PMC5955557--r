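#' Configuration for the synthetic kinome simulator
#'
#' Defines the study conditions emulated by [simulate_genome()]: a small
#' multi-chromosome genome in which a configurable fraction of genes are
#' protein kinases, some kinases are atypical (their domain evidence covers at
#' most half of the Pfam model), tandem arrays and collinear duplicate blocks
#' are planted at known gene ranks, duplicate coding sequences diverge to a
#' target synonymous distance, and a treatment/control count matrix carries
#' planted fold changes.
#'
#' @param seed Integer seed; all simulator output is a pure function of the
#'   configuration, so a fixed seed gives byte-identical files.
#' @param n_chromosomes,genes_per_chromosome Genome dimensions.
#' @param species Species label attached to every gene.
#' @param kinase_fraction Fraction of genes that are kinases (gene ranks are
#'   computed over all genes, so non-kinase genes matter for tandem and
#'   collinearity detection).
#' @param atypical_fraction Fraction of kinase genes whose domain hits all
#'   cover at most 50 percent of the model.
#' @param subfamily_catalog Subfamily-to-group table, see [subfamily_catalog()].
#' @param codon_range Range of coding lengths (codons) for ordinary genes.
#' @param exon_range Range of exon counts per gene.
#' @param min_exon_nt Minimum coding length of an exon (nucleotides).
#' @param intron_range Range of intron lengths (nucleotides).
#' @param intergenic_gap Fixed gap between consecutive genes (keeps coordinate
#'   order equal to rank order).
#' @param n_multi_domain Number of typical kinases given 2-4 kinase domains.
#' @param n_evalue_decoys Number of non-kinase genes given a high-coverage hit
#'   that fails the E-value gate (exercises the joint gate).
#' @param tandem_arrays Tibble with columns `chromosome`, `start_rank`,
#'   `size`, `subfamily`: members occupy consecutive ranks and share the
#'   subfamily.
#' @param tandem_ks Target Ks separating tandem-array members.
#' @param collinear_blocks Tibble with columns `chr_a`, `chr_b`, `start_a`,
#'   `start_b`, `n_anchors`, `target_ks`, `orientation` (`"same"` or
#'   `"inverted"`).
#' @param ka_ks_ratio Ka/Ks ratio used when evolving duplicates (purifying
#'   selection; 0.2 is typical of conserved plant gene families).
#' @param subfamily_ks Synonymous divergence of each member's kinase-domain
#'   sequence from its subfamily founder. Members of a subfamily carry
#'   diverged copies of a common founder domain, so HMM-score classification
#'   and domain-sequence phylogeny agree on synthetic data.
#' @param decoy_homology_fraction Fraction (of true pairs) of random decoy
#'   homology pairs passing the E-value filter.
#' @param n_subthreshold_homology Number of homology rows with E-values above
#'   the 1e-100 filter (must be discarded downstream).
#' @param expression List with `n_samples_per_group`, `planted_log2fc`,
#'   `dispersion` and `n_de_genes` for [simulate_counts()].
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, genes_per_chromosome = 60,
#'                   tandem_arrays = NULL, collinear_blocks = NULL)
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       genes_per_chromosome = 120L,
                       species = "simcotton",
                       kinase_fraction = 0.55,
                       atypical_fraction = 0.1,
                       subfamily_catalog = kinomevo::subfamily_catalog(),
                       codon_range = c(250L, 500L),
                       exon_range = c(1L, 6L),
                       min_exon_nt = 30L,
                       intron_range = c(80L, 300L),
                       intergenic_gap = 2000L,
                       n_multi_domain = 6L,
                       n_evalue_decoys = 4L,
                       tandem_arrays = default_tandem_arrays(),
                       tandem_ks = 0.05,
                       collinear_blocks = default_collinear_blocks(),
                       ka_ks_ratio = 0.2,
                       subfamily_ks = 0.3,
                       decoy_homology_fraction = 0.05,
                       n_subthreshold_homology = 4L,
                       expression = list(n_samples_per_group = 4L,
                                         planted_log2fc = 2,
                                         dispersion = 0.05,
                                         n_de_genes = 40L)) {
  if (is.null(tandem_arrays)) {
    tandem_arrays <- tibble(chromosome = character(), start_rank = integer(),
                            size = integer(), subfamily = character())
  }
  if (is.null(collinear_blocks)) {
    collinear_blocks <- tibble(chr_a = character(), chr_b = character(),
                               start_a = integer(), start_b = integer(),
                               n_anchors = integer(), target_ks = double(),
                               orientation = character())
  }
  if (!"orientation" %in% names(collinear_blocks)) {
    collinear_blocks$orientation <- "same"
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    species = species,
    kinase_fraction = kinase_fraction,
    atypical_fraction = atypical_fraction,
    subfamily_catalog = subfamily_catalog,
    codon_range = as.integer(codon_range),
    exon_range = as.integer(exon_range),
    min_exon_nt = as.integer(min_exon_nt),
    intron_range = as.integer(intron_range),
    intergenic_gap = as.integer(intergenic_gap),
    n_multi_domain = as.integer(n_multi_domain),
    n_evalue_decoys = as.integer(n_evalue_decoys),
    tandem_arrays = tibble::as_tibble(tandem_arrays),
    tandem_ks = tandem_ks,
    collinear_blocks = tibble::as_tibble(collinear_blocks),
    ka_ks_ratio = ka_ks_ratio,
    subfamily_ks = subfamily_ks,
    decoy_homology_fraction = decoy_homology_fraction,
    n_subthreshold_homology = as.integer(n_subthreshold_homology),
    expression = expression
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_tandem_arrays <- function() {
  tibble(
    chromosome = c("chr1", "chr1", "chr2"),
    start_rank = c(5L, 40L, 20L),
    size = c(3L, 4L, 3L),
    subfamily = c("RLK-Pelle_LRR-XI-1", "RLK-Pelle_CrRLK1L-1", "RLK-Pelle_DLSV")
  )
}

#' @rdname sim_config
#' @export
default_collinear_blocks <- function() {
  tibble(
    chr_a = "chr1", chr_b = "chr2",
    start_a = c(10L, 60L, 95L),
    start_b = c(10L, 60L, 100L),
    n_anchors = c(6L, 6L, 7L),
    target_ks = c(0.5, 0.05, 0.5),
    orientation = c("same", "same", "inverted")
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$genes_per_chromosome >= 1L)
  if (cfg$atypical_fraction < 0 || cfg$atypical_fraction > 1) {
    abort("atypical_fraction must lie in [0, 1]")
  }
  if (cfg$kinase_fraction <= 0 || cfg$kinase_fraction > 1) {
    abort("kinase_fraction must lie in (0, 1]")
  }
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  used <- list()
  claim <- function(chrom, ranks, what) {
    if (!chrom %in% chroms) abort(paste0(what, " references unknown chromosome ", chrom))
    if (any(ranks < 1L | ranks > cfg$genes_per_chromosome)) {
      abort(paste0(what, " exceeds chromosome bounds on ", chrom))
    }
    key <- paste0(chrom, ":", ranks)
    if (any(key %in% unlist(used))) abort("planted structures overlap")
    used[[length(used) + 1L]] <<- key
  }
  ta <- cfg$tandem_arrays
  for (i in seq_len(nrow(ta))) {
    claim(ta$chromosome[i], seq(ta$start_rank[i], length.out = ta$size[i]), "tandem array")
    if (!ta$subfamily[i] %in% cfg$subfamily_catalog$subfamily) {
      abort(paste0("tandem array subfamily not in catalog: ", ta$subfamily[i]))
    }
  }
  cb <- cfg$collinear_blocks
  for (i in seq_len(nrow(cb))) {
    claim(cb$chr_a[i], seq(cb$start_a[i], length.out = cb$n_anchors[i]), "collinear block")
    claim(cb$chr_b[i], seq(cb$start_b[i], length.out = cb$n_anchors[i]), "collinear block")
    if (!cb$orientation[i] %in% c("same", "inverted")) {
      abort("collinear block orientation must be 'same' or 'inverted'")
    }
    if (cb$target_ks[i] < 0) abort("target_ks must be non-negative")
  }
  ex <- cfg$expression
  if (ex$n_samples_per_group < 2L) abort("expression$n_samples_per_group must be >= 2")
  invisible(cfg)
}
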