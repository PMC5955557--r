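#' Model coverage of a domain hit
#'
#' The fraction of the profile model covered by one alignment:
#' `(model_end - model_start + 1) / model_length`. A typical kinase must have
#' a hit covering more than half of the Pkinase or Pkinase_Tyr model.
#'
#' @param hits Tibble of domain hits with columns `model_start`, `model_end`,
#'   `model_length`.
#' @return Numeric vector of coverage fractions in \[0, 1\].
#' @export
#' @examples
#' coverage_fraction(tibble::tibble(model_start = 51, model_end = 150, model_length = 200))
coverage_fraction <- function(hits) {
  if (any(hits$model_length <= 0)) abort("model_length must be positive")
  if (any(hits$model_start < 1 | hits$model_start > hits$model_end |
            hits$model_end > hits$model_length)) {
    abort("invalid model coordinates: need 1 <= model_start <= model_end <= model_length")
  }
  (hits$model_end - hits$model_start + 1) / hits$model_length
}

#' Partition genes into typical, atypical and non-kinase
#'
#' A gene is *typical* if at least one of its hits passes both gates
#' (E-value strictly below `evalue_max` and model coverage strictly above
#' `coverage_min`); *atypical* if it has hits passing the E-value gate but
#' none of them exceeds the coverage gate; *non-kinase* otherwise. Both gates
#' are applied jointly per hit, so a high-coverage hit with a poor E-value
#' cannot make a gene typical.
#'
#' @param hits Domain-hit tibble (see [read_domain_hits()] for columns).
#' @param evalue_max E-value gate (default 0.01, strict `<`).
#' @param coverage_min Coverage gate (default 0.5, strict `>`).
#' @param universe Optional character vector of all gene identifiers; genes
#'   without any hit are reported as non-kinase so that the three classes
#'   partition the universe.
#' @return Tibble with columns `gene_id` and
#'   `typicality` (`"typical"`, `"atypical"` or `"non_kinase"`).
#' @export
gate_typical <- function(hits, evalue_max = 0.01, coverage_min = 0.5, universe = NULL) {
  if (nrow(hits) == 0) {
    res <- tibble(gene_id = character(), typicality = character())
  } else {
    res <- hits |>
      dplyr::mutate(
        coverage = coverage_fraction(hits),
        pass_e = .data$evalue < evalue_max,
        qualifies = .data$pass_e & .data$coverage > coverage_min
      ) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        typicality = dplyr::case_when(
          any(.data$qualifies) ~ "typical",
          any(.data$pass_e) ~ "atypical",
          TRUE ~ "non_kinase"
        ),
        .groups = "drop"
      )
  }
  if (!is.null(universe)) {
    missing <- setdiff(universe, res$gene_id)
    res <- dplyr::bind_rows(res, tibble(gene_id = missing, typicality = "non_kinase"))
    res <- res[match(universe, res$gene_id), ]
  }
  res
}

#' Count kinase domains per typical gene
#'
#' Retains qualifying hits (both gates as in [gate_typical()]) and resolves
#' overlaps on protein coordinates greedily: hits are visited in ascending
#' E-value order and kept only if they overlap no previously kept hit. The
#' number of kept hits is the gene's kinase-domain count.
#'
#' @inheritParams gate_typical
#' @return Tibble with columns `gene_id` and `n_kinase_domains` (genes with
#'   no qualifying hit are omitted).
#' @export
count_kinase_domains <- function(hits, evalue_max = 0.01, coverage_min = 0.5) {
  q <- hits[coverage_fraction(hits) > coverage_min & hits$evalue < evalue_max, ]
  if (nrow(q) == 0) return(tibble(gene_id = character(), n_kinase_domains = integer()))
  q |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$evalue, df$seq_start), ]
      kept_s <- integer(0)
      kept_e <- integer(0)
      for (i in seq_len(nrow(df))) {
        if (!any(df$seq_start[i] <= kept_e & df$seq_end[i] >= kept_s)) {
          kept_s <- c(kept_s, df$seq_start[i])
          kept_e <- c(kept_e, df$seq_end[i])
        }
      }
      tibble(n_kinase_domains = length(kept_s))
    }) |>
    dplyr::ungroup()
}

#' Assign subfamily and group from HMM bit scores
#'
#' Each gene receives the subfamily with the maximal bit score; ties are
#' broken towards the lexicographically smaller subfamily name. The group is
#' looked up in the subfamily catalog.
#'
#' @param scores Tibble with columns `gene_id`, `subfamily`, `bit_score`.
#' @param catalog Subfamily-to-group table, see [subfamily_catalog()].
#' @return Tibble with columns `gene_id`, `subfamily`, `group`.
#' @export
assign_subfamily <- function(scores, catalog = subfamily_catalog()) {
  if (any(!is.finite(scores$bit_score))) abort("bit scores must be finite")
  missing <- setdiff(unique(scores$subfamily), catalog$subfamily)
  if (length(missing) > 0) {
    abort(paste0("subfamilies missing from catalog: ", paste(missing, collapse = ", ")))
  }
  scores |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$bit_score), .data$subfamily) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      subfamily = .data$subfamily,
      group = catalog$group[match(.data$subfamily, catalog$subfamily)]
    )
}

#' Classify a kinome from hit and score tables
#'
#' Combines [gate_typical()], [count_kinase_domains()] and
#' [assign_subfamily()] into one classification table. Atypical genes are
#' reported as `unclassified` (the subfamily HMM library scores only typical
#' kinases); genes absent from the hit table appear (as non-kinase) only when
#' a `universe` is supplied.
#'
#' @inheritParams gate_typical
#' @inheritParams assign_subfamily
#' @return Tibble with columns `gene_id`, `typicality`, `typical` (logical),
#'   `subfamily`, `group`, `n_kinase_domains`.
#' @export
classify_kinases <- function(hits, scores, catalog = subfamily_catalog(),
                             evalue_max = 0.01, coverage_min = 0.5, universe = NULL) {
  gate <- gate_typical(hits, evalue_max, coverage_min, universe)
  doms <- count_kinase_domains(hits, evalue_max, coverage_min)
  subf <- assign_subfamily(scores, catalog)
  gate |>
    dplyr::left_join(doms, by = "gene_id") |>
    dplyr::left_join(subf, by = "gene_id") |>
    dplyr::mutate(
      typical = .data$typicality == "typical",
      subfamily = dplyr::if_else(.data$typical & !is.na(.data$subfamily),
                                 .data$subfamily,
                                 dplyr::if_else(.data$typicality == "atypical",
                                                "unclassified", NA_character_)),
      group = dplyr::if_else(.data$typical, .data$group, NA_character_),
      n_kinase_domains = dplyr::if_else(.data$typical, .data$n_kinase_domains, NA_integer_)
    ) |>
    dplyr::select("gene_id", "typicality", "typical", "subfamily", "group",
                  "n_kinase_domains")
}

#' Sample tree representatives per subfamily
#'
#' Applies the representative-sampling rule used for subfamily-validation
#' phylogenies: subfamilies with at most 6 members contribute 1
#' representative, those with 7-30 members contribute 2, and larger ones 3,
#' sampled uniformly at random under a fixed seed.
#'
#' @param members Either a character vector of member gene identifiers (one
#'   subfamily) or a tibble with columns `subfamily` and `gene_id`.
#' @param seed Integer seed for reproducible sampling.
#' @return For a vector input, a character vector of representatives; for a
#'   tibble input, a tibble with columns `subfamily`, `gene_id`.
#' @export
#' @examples
#' select_representatives(paste0("g", 1:31), seed = 1)
select_representatives <- function(members, seed = 1L) {
  n_reps <- function(size) if (size <= 6) 1L else if (size <= 30) 2L else 3L
  if (is.character(members)) {
    return(withr::with_seed(seed, members[sample.int(length(members), n_reps(length(members)))]))
  }
  withr::with_seed(seed, {
    members |>
      dplyr::group_by(.data$subfamily) |>
      dplyr::group_modify(function(df, key) {
        df[sample.int(nrow(df), n_reps(nrow(df))), "gene_id", drop = FALSE]
      }) |>
      dplyr::ungroup()
  })
}
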