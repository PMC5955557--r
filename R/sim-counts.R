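#' Simulate a treatment/control count matrix with planted fold changes
#'
#' Draws negative-binomial counts for every simulated gene in a two-group
#' design. Each gene has a log-normal base mean; genes planted as
#' differentially expressed have their treatment-group mean scaled by
#' `2^log2fc` (the signed effects recorded in the ground truth). The
#' gene-wise dispersion is shared; a dispersion near zero approaches Poisson
#' (and for large means, deterministic) counts.
#'
#' @param sim A `kinome_sim` object from [simulate_genome()].
#' @return A list with `counts` (tibble: `gene_id` plus one column per
#'   sample), `samples` (tibble: `sample`, `group` with levels `treatment`
#'   and `control`), `gene_lengths` (tibble: `gene_id`, `length` in coding
#'   bases) and `library_sizes` (named numeric).
#' @export
simulate_counts <- function(sim) {
  stopifnot(inherits(sim, "kinome_sim"))
  withr::with_seed(sim$config$seed + 2L, .simulate_counts_impl(sim))
}

.simulate_counts_impl <- function(sim) {
  ex <- sim$config$expression
  genes <- sim$genes$gene_id
  n <- length(genes)
  m <- ex$n_samples_per_group
  base <- rlnorm(n, meanlog = log(100), sdlog = 1)
  lfc <- setNames(rep(0, n), genes)
  de <- sim$truth$de_genes
  lfc[de$gene_id] <- de$log2fc
  mu_trt <- base * 2^lfc
  size <- if (ex$dispersion <= 1e-8) 1e8 else 1 / ex$dispersion
  draw <- function(mu) matrix(rnbinom(n * m, mu = rep(mu, m), size = size), nrow = n)
  mat <- cbind(draw(mu_trt), draw(base))
  samples <- tibble(
    sample = c(paste0("trt_", seq_len(m)), paste0("ctl_", seq_len(m))),
    group = rep(c("treatment", "control"), each = m)
  )
  colnames(mat) <- samples$sample
  counts <- dplyr::bind_cols(tibble(gene_id = genes), tibble::as_tibble(mat))
  list(
    counts = counts,
    samples = samples,
    gene_lengths = tibble(gene_id = genes, length = sim$genes$cds_length),
    library_sizes = colSums(mat)
  )
}
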