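# Exon-intron phase computation and kinase-domain phase fingerprints.

#' Intron phases of gene models
#'
#' Orders each gene's CDS segments in translation direction (reversed for
#' minus-strand genes) and computes the phase of every intron as the
#' cumulative coding length of the preceding exons modulo 3 — the standard
#' intron-phase convention where phase 0 falls between codons, phase 1 after
#' the first base of a codon and phase 2 after the second.
#'
#' @param gene_models Tibble with columns `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` (one row per CDS segment, 1-based inclusive), e.g. from
#'   [read_gene_models()].
#' @return Tibble with one row per intron: `gene_id`, `intron` (index in
#'   translation order), `coding_pos` (cumulative coding nucleotides before
#'   the intron) and `phase` (0, 1 or 2). Single-exon genes contribute no
#'   rows; genes whose total CDS length is not a multiple of 3 are skipped
#'   with a warning.
#' @export
intron_phases <- function(gene_models) {
  req <- c("gene_id", "strand", "start", "end")
  if (!all(req %in% names(gene_models))) {
    abort(paste0("gene_models needs columns: ", paste(req, collapse = ", ")))
  }
  bad <- character(0)
  out <- gene_models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$start), ]
      lens <- df$end - df$start + 1L
      if (any(df$strand == "-")) lens <- rev(lens)
      if (sum(lens) %% 3L != 0L) {
        bad <<- c(bad, key$gene_id)
        return(tibble(intron = integer(), coding_pos = integer(), phase = integer()))
      }
      if (length(lens) == 1L) {
        return(tibble(intron = integer(), coding_pos = integer(), phase = integer()))
      }
      cum <- cumsum(lens)[-length(lens)]
      tibble(intron = seq_along(cum), coding_pos = cum, phase = as.integer(cum %% 3L))
    }) |>
    dplyr::ungroup()
  if (length(bad) > 0) {
    warn(paste0("CDS length not a multiple of 3; skipped: ", paste(bad, collapse = ", ")))
  }
  out
}

#' Exon-phase fingerprint of the kinase-domain span
#'
#' Restricts each gene's intron phases to the introns falling inside the
#' kinase domain and concatenates them into a phase string (e.g. `"1000"`).
#' An intron lies inside the domain when its coding-nucleotide position (in
#' translation order) falls in `[3 (domain_start - 1) + 1, 3 domain_end]`;
#' both boundaries are inclusive, so an intron exactly at a domain edge
#' counts as in-domain.
#'
#' @inheritParams intron_phases
#' @param domains Tibble with columns `gene_id`, `domain_start`,
#'   `domain_end` (protein coordinates, 1-based inclusive), typically the
#'   protein span of the best qualifying domain hit.
#' @return Tibble with columns `gene_id`, `domain_start`, `domain_end`,
#'   `n_introns_in_domain`, `phase_string` (empty string when the domain is
#'   confined to one exon).
#' @export
domain_fingerprint <- function(gene_models, domains) {
  phases <- intron_phases(gene_models)
  cds_len <- gene_models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cds_length = sum(.data$end - .data$start + 1L), .groups = "drop")
  dom <- dplyr::inner_join(domains, cds_len, by = "gene_id")
  outside <- dom$gene_id[3L * dom$domain_end > dom$cds_length | dom$domain_start < 1L]
  if (length(outside) > 0) {
    abort(paste0("domain outside protein for: ", paste(outside, collapse = ", ")))
  }
  dom |>
    dplyr::rowwise() |>
    dplyr::mutate(fp = {
      lo <- 3L * (.data$domain_start - 1L) + 1L
      hi <- 3L * .data$domain_end
      ph <- phases$phase[phases$gene_id == .data$gene_id &
                           phases$coding_pos >= lo & phases$coding_pos <= hi]
      paste(ph, collapse = "")
    }) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      domain_start = .data$domain_start, domain_end = .data$domain_end,
      n_introns_in_domain = nchar(.data$fp),
      phase_string = .data$fp
    )
}

#' Group genes by conserved kinase-domain exon-phase structure
#'
#' Exact-match grouping on (subfamily, phase string): genes of the same
#' subfamily sharing an identical in-domain phase string form a conserved
#' structure group. Groups spanning at least `min_species` species are
#' retained, since structural conservation across species is the signal of
#' interest.
#'
#' @param fingerprints Tibble with columns `gene_id`, `species`, `subfamily`,
#'   `phase_string` (see [domain_fingerprint()]).
#' @param min_species Minimum number of distinct species per reported group.
#' @param allow_intronless Should genes with an empty phase string (domain
#'   confined to one exon) be grouped too? Off by default because an empty
#'   fingerprint carries no positional signal.
#' @return Tibble with one row per group: `subfamily`, `phase_string`,
#'   `n_genes`, `n_species`, `species` (comma-separated), `gene_ids`
#'   (comma-separated, in input order).
#' @export
conserved_structure_groups <- function(fingerprints, min_species = 2L,
                                       allow_intronless = FALSE) {
  fp <- fingerprints
  if (!allow_intronless) fp <- fp[fp$phase_string != "", ]
  fp |>
    dplyr::group_by(.data$subfamily, .data$phase_string) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      species = paste(sort(unique(.data$species)), collapse = ","),
      gene_ids = paste(.data$gene_id, collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_species >= min_species)
}
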