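# Ka/Ks over tables of gene pairs, with codon alignment via protein
# alignment when sequences differ in length.

.codon_align <- function(cds_a, cds_b) {
  prot <- function(x) {
    gc <- .genetic_code()
    cod <- .split_codons(x)
    aa <- gc[cod]
    aa[is.na(aa)] <- "X"
    paste(ifelse(aa == "*", "X", aa), collapse = "")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot(cds_a)), Biostrings::AAString(prot(cds_b)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  expand <- function(aln, cds) {
    chars <- strsplit(as.character(aln), "")[[1]]
    cod <- .split_codons(cds)
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- cod[k]
      }
    }
    paste(out, collapse = "")
  }
  list(
    a = expand(Biostrings::pattern(pa), cds_a),
    b = expand(Biostrings::subject(pa), cds_b)
  )
}

#' Ka/Ks for a table of gene pairs
#'
#' Runs [kaks()] on each homologous pair, pulling the coding sequences from a
#' named vector. Pairs of equal length are compared codon-by-codon directly;
#' unequal-length pairs are first codon-aligned through a global protein
#' alignment.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param cds Named character vector of coding sequences.
#' @param ks_bins Epoch bins, see [ks_epoch_bins()].
#' @return The input pairs with the [kaks()] columns (`ka`, `ks`, `epoch`,
#'   ...) appended; pairs with a missing sequence get NA rates and epoch
#'   `"unassigned"`.
#' @export
kaks_pairs <- function(pairs, cds, ks_bins = ks_epoch_bins()) {
  if (nrow(pairs) == 0) {
    return(dplyr::bind_cols(pairs, tibble(
      n_codons = integer(), syn_sites = double(), nonsyn_sites = double(),
      syn_diffs = double(), nonsyn_diffs = double(), ps = double(),
      pn = double(), ka = double(), ks = double(), epoch = character()
    )))
  }
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    if (!a %in% names(cds) || !b %in% names(cds)) {
      return(tibble(n_codons = NA_integer_, syn_sites = NA_real_,
                    nonsyn_sites = NA_real_, syn_diffs = NA_real_,
                    nonsyn_diffs = NA_real_, ps = NA_real_, pn = NA_real_,
                    ka = NA_real_, ks = NA_real_, epoch = "unassigned"))
    }
    sa <- cds[[a]]
    sb <- cds[[b]]
    if (nchar(sa) != nchar(sb)) {
      al <- .codon_align(sa, sb)
      sa <- al$a
      sb <- al$b
    }
    kaks(sa, sb, ks_bins = ks_bins)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}

#' Subfamily-clade congruence of a phylogeny
#'
#' Checks, for every subfamily with at least two representatives in the
#' tree, whether its tips form a clade (a bipartition of the unrooted tree).
#' Used to validate HMM-score classification against the phylogeny.
#'
#' @param tree A `phylo` object.
#' @param labels Tibble with columns `gene_id` (matching tip labels) and
#'   `subfamily`.
#' @return Tibble with columns `subfamily`, `n_tips`, `monophyletic`, plus
#'   attribute `fraction` (proportion of testable subfamilies that are
#'   monophyletic).
#' @export
clade_congruence <- function(tree, labels) {
  keys <- tree_bipartitions(tree)
  tips <- tree$tip.label
  labs <- labels[labels$gene_id %in% tips, ]
  res <- labs |>
    dplyr::group_by(.data$subfamily) |>
    dplyr::summarise(n_tips = dplyr::n(), members = list(.data$gene_id), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(monophyletic = {
      s <- .data$members
      if (.data$n_tips < 2 || .data$n_tips > length(tips) - 2) {
        .data$n_tips >= length(tips) - 1 # whole-tree or (n-1)-tip sets are trivially clades
      } else {
        side <- if (tips[1] %in% s) setdiff(tips, s) else s
        paste(sort(side), collapse = "|") %in% keys
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::select("subfamily", "n_tips", "monophyletic")
  testable <- res$n_tips >= 2
  attr(res, "fraction") <- if (any(testable)) mean(res$monophyletic[testable]) else NA_real_
  res
}
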