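# Tandem-cluster and collinear-block detection from gene order + homology.

#' Filter and canonicalize homology pairs
#'
#' Keeps pairs at or below the E-value threshold (the stringent cutoff used
#' for duplication analysis), removes self-pairs, orders each pair
#' lexicographically, and deduplicates keeping the best E-value.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`, `evalue`.
#' @param evalue_max E-value threshold (default 1e-100, inclusive).
#' @return Canonicalized tibble of unique pairs.
#' @export
filter_homology <- function(pairs, evalue_max = 1e-100) {
  pairs |>
    dplyr::filter(.data$evalue <= evalue_max, .data$gene_a != .data$gene_b) |>
    dplyr::mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(evalue = min(.data$evalue), .groups = "drop") |>
    dplyr::transmute(gene_a = .data$a, gene_b = .data$b, evalue = .data$evalue)
}

#' Gene ranks from coordinate order
#'
#' Ranks are computed per chromosome over *all* genes in the annotation (not
#' only kinases), since tandem and collinearity definitions operate on
#' whole-genome gene order.
#'
#' @param genes Tibble with columns `gene_id`, `chromosome`, `start`.
#' @return Tibble with columns `gene_id`, `chromosome`, `rank`.
#' @export
gene_ranks <- function(genes) {
  genes |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chromosome", "rank")
}

#' Tandem duplication clusters
#'
#' Two genes are tandem-linked when they are homologous, lie on the same
#' chromosome, and their gene ranks differ by at most `max_gap`. Clusters are
#' the connected components of tandem links, reported with members in rank
#' order.
#'
#' @param genes Tibble with columns `gene_id`, `chromosome`, `start` (all
#'   genes of the annotation).
#' @param pairs Filtered homology pairs, see [filter_homology()].
#' @param max_gap Maximum rank difference of a tandem link (default 1:
#'   strictly consecutive genes).
#' @return Tibble with one row per cluster member: `cluster_id`,
#'   `chromosome`, `gene_id`, `rank`.
#' @export
tandem_clusters <- function(genes, pairs, max_gap = 1L) {
  ranks <- gene_ranks(genes)
  linked <- pairs |>
    dplyr::inner_join(ranks, by = c(gene_a = "gene_id")) |>
    dplyr::rename(chrom_a = "chromosome", rank_a = "rank") |>
    dplyr::inner_join(ranks, by = c(gene_b = "gene_id")) |>
    dplyr::rename(chrom_b = "chromosome", rank_b = "rank") |>
    dplyr::filter(.data$chrom_a == .data$chrom_b,
                  abs(.data$rank_a - .data$rank_b) <= max_gap)
  if (nrow(linked) == 0) {
    return(tibble(cluster_id = integer(), chromosome = character(),
                  gene_id = character(), rank = integer()))
  }
  g <- igraph::graph_from_data_frame(linked[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- tibble(
    gene_id = names(comp$membership),
    cluster_id = as.integer(comp$membership)
  )
  membership |>
    dplyr::inner_join(ranks, by = "gene_id") |>
    dplyr::arrange(.data$cluster_id, .data$rank) |>
    dplyr::select("cluster_id", "chromosome", "gene_id", "rank")
}

# longest monotone chain among matches (rank_a strictly increasing;
# rank_b strictly increasing for "same", strictly decreasing for
# "inverted"); consecutive anchors must differ by <= max_rank_gap on both
# axes. Returns indices into the match table.
.best_chain <- function(ra, rb, orientation, max_rank_gap) {
  ord <- order(ra, if (orientation == "same") rb else -rb)
  ra <- ra[ord]
  rb <- rb[ord]
  m <- length(ra)
  len <- rep(1L, m)
  prev <- rep(NA_integer_, m)
  gap <- rep(0L, m) # rank gap to the chosen predecessor, for tie-breaking
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "same") rb[i] - rb[j] else rb[j] - rb[i]
      if (da >= 1L && da <= max_rank_gap && db >= 1L && db <= max_rank_gap) {
        better <- len[j] + 1L > len[i] ||
          (len[j] + 1L == len[i] && !is.na(prev[i]) && da + db < gap[i])
        if (better) {
          len[i] <- len[j] + 1L
          prev[i] <- j
          gap[i] <- da + db
        }
      }
    }
  }
  ends <- which(len == max(len))
  chains <- lapply(ends, function(e) {
    idx <- integer(0)
    while (!is.na(e)) {
      idx <- c(e, idx)
      e <- prev[e]
    }
    idx
  })
  span <- vapply(chains, function(idx) {
    diff(range(ra[idx])) + diff(range(rb[idx]))
  }, numeric(1))
  best <- chains[[which.min(span)]]
  ord[best]
}

#' Collinear (synteny) blocks from gene order and homology
#'
#' For every chromosome pair with homologous genes, anchors (homologous gene
#' pairs placed at their gene ranks) are chained by dynamic programming:
#' chains must be strictly monotone in rank on both chromosomes — in the
#' same direction (`orientation = "same"`) or opposite directions
#' (`"inverted"`) — with consecutive anchors at most `max_rank_gap` ranks
#' apart on either axis. The best chain (most anchors; ties broken towards
#' the smaller total rank span) is extracted, its anchors removed, and the
#' search repeated until no chain reaches `min_anchors`.
#'
#' @inheritParams tandem_clusters
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return Tibble with one row per anchor: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `anchor_index`, `gene_a`, `gene_b`,
#'   `rank_a`, `rank_b`. Class `collinear_blocks`.
#' @export
collinear_blocks <- function(genes, pairs, min_anchors = 5L, max_rank_gap = 25L) {
  ranks <- gene_ranks(genes)
  matches <- pairs |>
    dplyr::inner_join(ranks, by = c(gene_a = "gene_id")) |>
    dplyr::rename(chrom_a = "chromosome", rank_a = "rank") |>
    dplyr::inner_join(ranks, by = c(gene_b = "gene_id")) |>
    dplyr::rename(chrom_b = "chromosome", rank_b = "rank")
  # canonical chromosome pair orientation
  flip <- matches$chrom_a > matches$chrom_b |
    (matches$chrom_a == matches$chrom_b & matches$rank_a > matches$rank_b)
  matches[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
    matches[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]

  out <- list()
  block_id <- 0L
  for (cp in split(matches, paste(matches$chrom_a, matches$chrom_b))) {
    repeat {
      if (nrow(cp) < min_anchors) break
      cand <- lapply(c("same", "inverted"), function(o) {
        idx <- .best_chain(cp$rank_a, cp$rank_b, o, max_rank_gap)
        list(orientation = o, idx = idx)
      })
      lens <- vapply(cand, function(x) length(x$idx), integer(1))
      pick <- cand[[which.max(lens)]]
      if (length(pick$idx) < min_anchors) break
      block_id <- block_id + 1L
      chain <- cp[pick$idx, ]
      out[[block_id]] <- tibble(
        block_id = block_id,
        chrom_a = chain$chrom_a, chrom_b = chain$chrom_b,
        orientation = pick$orientation,
        n_anchors = nrow(chain),
        anchor_index = seq_len(nrow(chain)),
        gene_a = chain$gene_a, gene_b = chain$gene_b,
        rank_a = chain$rank_a, rank_b = chain$rank_b
      )
      cp <- cp[-pick$idx, ]
    }
  }
  res <- if (length(out) == 0) {
    tibble(block_id = integer(), chrom_a = character(), chrom_b = character(),
           orientation = character(), n_anchors = integer(),
           anchor_index = integer(), gene_a = character(), gene_b = character(),
           rank_a = integer(), rank_b = integer())
  } else {
    dplyr::bind_rows(out)
  }
  class(res) <- c("collinear_blocks", class(res))
  res
}

#' Single-gene-correspondence fraction of duplicate pairs
#'
#' A pair is single-correspondence when each of its members appears in
#' exactly one pair of the table — the signature of gene pairs that did not
#' expand further after the genomes (or subgenomes) split.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return List with `pairs` (the input plus a logical `single` column) and
#'   `fraction` (singles over all pairs).
#' @export
#' @examples
#' single_correspondence(tibble::tibble(gene_a = c("a1", "a2", "a2"),
#'                                      gene_b = c("b1", "b2", "b3")))
single_correspondence <- function(pairs) {
  occ <- table(c(pairs$gene_a, pairs$gene_b))
  single <- occ[pairs$gene_a] == 1L & occ[pairs$gene_b] == 1L
  out <- dplyr::mutate(pairs, single = as.vector(single))
  list(pairs = out, fraction = if (nrow(pairs) == 0) NA_real_ else mean(out$single))
}

#' Histogram of Ks values
#'
#' @param ks Numeric vector of synonymous distances (NA for saturated pairs
#'   is dropped).
#' @param bin_width Histogram bin width (default 0.1, matching the epoch
#'   binning resolution).
#' @param max_ks Upper bound of the histogram (default 3).
#' @return Tibble with columns `bin_start`, `bin_end`, `count`; class
#'   `ks_profile`.
#' @export
ks_histogram <- function(ks, bin_width = 0.1, max_ks = 3) {
  ks <- as.numeric(ks %||% numeric(0))
  ks <- ks[!is.na(ks) & ks >= 0 & ks < max_ks]
  edges <- seq(0, max_ks, by = bin_width)
  idx <- findInterval(ks, edges, rightmost.closed = FALSE)
  out <- tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = tabulate(idx, nbins = length(edges) - 1L)
  )
  class(out) <- c("ks_profile", class(out))
  out
}

#' Local modes of a Ks histogram
#'
#' A bin is a local mode when its count is positive and at least as large as
#' both neighbouring bins.
#'
#' @param profile A `ks_profile` tibble from [ks_histogram()].
#' @return The rows of `profile` that are local modes.
#' @export
ks_local_modes <- function(profile) {
  cnt <- profile$count
  left <- c(-1, cnt[-length(cnt)])
  right <- c(cnt[-1], -1)
  profile[cnt > 0 & cnt >= left & cnt >= right, ]
}
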