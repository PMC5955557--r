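#' Simulate kinase-domain hit evidence and subfamily score tables
#'
#' Emits a domain-hit table (one row per alignment of a protein to the
#' Pkinase or Pkinase_Tyr model) and a subfamily bit-score table consistent
#' with the simulated ground truth: typical genes receive one qualifying hit
#' per planted kinase domain (model coverage above 0.5, E-value far below
#' 0.01) at non-overlapping protein positions, atypical genes receive only
#' hits with coverage at or below 0.5 (the first atypical gene sits exactly
#' on the 0.5 boundary), a few non-kinase genes receive a high-coverage hit
#' that fails the E-value gate, and each typical gene's labeled subfamily
#' carries the highest bit score.
#'
#' @param sim A `kinome_sim` object from [simulate_genome()].
#' @return A list with tibbles `hits` (columns `gene_id`, `model_name`,
#'   `model_start`, `model_end`, `model_length`, `seq_start`, `seq_end`,
#'   `evalue`) and `scores` (`gene_id`, `subfamily`, `bit_score`).
#' @export
simulate_domain_hits <- function(sim) {
  stopifnot(inherits(sim, "kinome_sim"))
  withr::with_seed(sim$config$seed + 1L, .simulate_hits_impl(sim))
}

.model_lengths <- c(Pkinase = 264L, Pkinase_Tyr = 258L)

.simulate_hits_impl <- function(sim) {
  labels <- sim$truth$labels
  plen <- nchar(sim$proteins)[labels$gene_id]
  rows <- list()
  emit <- function(gene_id, coverage, seq_start, seq_end, evalue, exact_span = NULL) {
    model <- names(.model_lengths)[sample.int(2L, 1L, prob = c(0.8, 0.2))]
    ml <- .model_lengths[[model]]
    span <- exact_span %||% max(1L, floor(coverage * ml))
    ms <- sample.int(ml - span + 1L, 1L)
    rows[[length(rows) + 1L]] <<- tibble(
      gene_id = gene_id, model_name = model,
      model_start = ms, model_end = ms + span - 1L, model_length = ml,
      seq_start = seq_start, seq_end = seq_end, evalue = evalue
    )
  }

  for (i in seq_len(nrow(labels))) {
    g <- labels$gene_id[i]
    P <- plen[i]
    if (labels$typicality[i] == "typical") {
      k <- labels$n_domains[i]
      lay <- .domain_layout(P, k)
      for (s in lay$starts) {
        emit(g, runif(1, 0.55, 0.98), s, s + lay$len - 1L, 10^-runif(1, 30, 120))
      }
      if (runif(1) < 0.3) {
        # fragmented secondary hit below the coverage gate; must not change
        # typicality or the domain count
        emit(g, runif(1, 0.1, 0.45), 1L, 20L, 10^-runif(1, 5, 20))
      }
    } else if (labels$typicality[i] == "atypical") {
      emit(g, runif(1, 0.15, 0.49), 10L, 10L + 100L, 10^-runif(1, 10, 40))
    }
  }

  # pin the first atypical gene exactly on the 50% coverage boundary
  atyp <- labels$gene_id[labels$typicality == "atypical"]
  hits <- dplyr::bind_rows(rows)
  if (length(atyp) > 0) {
    b <- match(atyp[1], hits$gene_id)
    hits$model_name[b] <- "Pkinase"
    hits$model_length[b] <- 264L
    hits$model_start[b] <- 1L
    hits$model_end[b] <- 132L
  }

  nk <- labels$gene_id[labels$typicality == "non_kinase"]
  n_dec <- min(sim$config$n_evalue_decoys, length(nk))
  if (n_dec > 0) {
    dec <- nk[sample.int(length(nk), n_dec)]
    rows <- list()
    for (g in dec) emit(g, runif(1, 0.8, 0.95), 5L, 204L, runif(1, 0.02, 0.9))
    hits <- dplyr::bind_rows(hits, dplyr::bind_rows(rows))
  }

  cat_sub <- sim$config$subfamily_catalog$subfamily
  typ <- labels[labels$typicality == "typical", ]
  scores <- purrr::pmap(list(typ$gene_id, typ$subfamily), function(g, sf) {
    others <- setdiff(cat_sub, sf)
    others <- others[sample.int(length(others), 2L)]
    top <- runif(1, 250, 400)
    tibble(
      gene_id = g,
      subfamily = c(sf, others),
      bit_score = c(top, top - runif(2, 30, 150))
    )
  })
  list(hits = hits, scores = dplyr::bind_rows(scores))
}
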