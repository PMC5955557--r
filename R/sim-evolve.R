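# Divergence of a duplicated coding sequence to a target synonymous distance.

.ng86_init_neighbors <- function() {
  if (!is.null(.ng86$syn_neighbors)) return(invisible(NULL))
  .ng86_init_sites()
  gc <- .ng86$aa
  bases <- c("A", "C", "G", "T")
  syn_nb <- list()
  nonsyn_nb <- list()
  for (cd in .ng86$codons) {
    if (.ng86$is_stop[cd]) next
    chars <- strsplit(cd, "")[[1]]
    sn <- character(0)
    nn <- character(0)
    for (pos in 1:3) {
      for (b in setdiff(bases, chars[pos])) {
        alt <- chars
        alt[pos] <- b
        alt_cd <- paste(alt, collapse = "")
        if (gc[[alt_cd]] == "*") next
        if (gc[[alt_cd]] == gc[[cd]]) sn <- c(sn, alt_cd) else nn <- c(nn, alt_cd)
      }
    }
    syn_nb[[cd]] <- sn
    nonsyn_nb[[cd]] <- nn
  }
  .ng86$syn_neighbors <- syn_nb
  .ng86$nonsyn_neighbors <- nonsyn_nb
  invisible(NULL)
}

#' Evolve a duplicated coding sequence to a target Ks
#'
#' Introduces single-nucleotide substitutions into a coding sequence so that
#' the Nei-Gojobori synonymous distance between input and output hits a
#' target. The number of synonymous (and, via the `ka_ks` ratio,
#' nonsynonymous) codon changes is derived from the target through the
#' Jukes-Cantor relation `p = (3/4) (1 - exp(-4 K / 3))` applied to the
#' source's NG86 site counts; each selected codon receives exactly one
#' substitution of the required class, which guarantees that the estimator in
#' [kaks()] measures the target back (up to site-count drift of a few
#' percent). Synonymous and nonsynonymous changes are placed on disjoint
#' codons; the start codon is never touched.
#'
#' @param cds Coding sequence (character scalar), length divisible by 3, no
#'   internal stop codons.
#' @param target_ks Non-negative target synonymous distance.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param ka_ks Ratio of the nonsynonymous to the synonymous target rate.
#' @return A coding sequence of the same length.
#' @export
#' @examples
#' cds <- paste(c("ATG", rep(c("GGA", "CTT", "AAA"), 100)), collapse = "")
#' out <- evolve_duplicate(cds, target_ks = 0.5, seed = 1)
#' kaks(cds, out)$ks
evolve_duplicate <- function(cds, target_ks, seed = NULL, ka_ks = 0.2) {
  if (target_ks < 0) abort("target_ks must be non-negative")
  .ng86_init_neighbors()
  codons <- .split_codons(cds)
  if (any(.ng86$is_stop[codons])) abort("coding sequence contains a stop codon")
  if (target_ks == 0) return(cds)
  run <- function() {
    n <- length(codons)
    S <- sum(.ng86$syn_sites[codons])
    N <- 3 * n - S
    jc_p <- function(k) 0.75 * (1 - exp(-4 * k / 3))
    sd_target <- round(jc_p(target_ks) * S)
    nd_target <- round(jc_p(ka_ks * target_ks) * N)
    mutable <- setdiff(seq_len(n), 1L) # preserve the start codon
    if (nd_target > length(mutable)) abort("target Ks unreachable (saturation)")
    nd_idx <- mutable[sample.int(length(mutable), nd_target)]
    syn_ok <- mutable[lengths(.ng86$syn_neighbors[codons[mutable]]) > 0]
    syn_pool <- setdiff(syn_ok, nd_idx)
    if (length(syn_pool) < sd_target) abort("target Ks unreachable (saturation)")
    sd_idx <- syn_pool[sample.int(length(syn_pool), sd_target)]
    for (i in nd_idx) {
      nb <- .ng86$nonsyn_neighbors[[codons[i]]]
      codons[i] <- nb[sample.int(length(nb), 1L)]
    }
    for (i in sd_idx) {
      nb <- .ng86$syn_neighbors[[codons[i]]]
      codons[i] <- nb[sample.int(length(nb), 1L)]
    }
    paste(codons, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
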