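# RPKM normalization, log2 fold changes, and the |FC| & p differential screen.

# coerce a counts tibble (gene_id + sample columns) or matrix to a matrix
.counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

.matrix_tibble <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

#' RPKM normalization
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `count / ((length / 1000) * (library_size / 1e6))`, with the library size
#' taken as the per-sample column sum of the supplied matrix.
#'
#' @param counts Tibble with a `gene_id` column plus one numeric column per
#'   sample (or a numeric matrix with gene rownames).
#' @param gene_lengths Tibble with columns `gene_id` and `length` (coding
#'   length in bases), or a named numeric vector.
#' @return Normalized values in the same shape as `counts`.
#' @export
#' @examples
#' rpkm(tibble::tibble(gene_id = "g1", s1 = 10),
#'      tibble::tibble(gene_id = "g1", length = 1000))
rpkm <- function(counts, gene_lengths) {
  m <- .counts_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene_id)
  }
  len <- gene_lengths[rownames(m)]
  if (any(is.na(len))) abort("missing gene lengths")
  if (any(len <= 0)) abort("gene lengths must be positive")
  lib <- colSums(m)
  if (any(lib <= 0)) abort("zero library size")
  norm <- sweep(m / (len / 1000), 2, lib / 1e6, "/")
  if (is.matrix(counts)) norm else .matrix_tibble(norm)
}

.group_means <- function(m, samples) {
  if (!all(samples$group %in% c("treatment", "control"))) {
    abort("sample groups must be 'treatment' or 'control'")
  }
  trt <- samples$sample[samples$group == "treatment"]
  ctl <- samples$sample[samples$group == "control"]
  if (length(trt) == 0 || length(ctl) == 0) abort("both groups must be non-empty")
  list(trt = trt, ctl = ctl,
       mean_trt = unname(rowMeans(m[, trt, drop = FALSE])),
       mean_ctl = unname(rowMeans(m[, ctl, drop = FALSE])))
}

#' Treatment-versus-control log2 fold change
#'
#' `log2((mean treatment + pseudo) / (mean control + pseudo))` on normalized
#' values. The pseudo-count keeps all-zero genes at a fold change of zero and
#' stabilises ratios of small values.
#'
#' @param normalized Normalized expression (tibble with `gene_id` + sample
#'   columns, or matrix), e.g. from [rpkm()].
#' @param samples Tibble with columns `sample` and `group` (levels
#'   `treatment`, `control`).
#' @param pseudo Pseudo-count added to both means (default 1).
#' @return Tibble with columns `gene_id`, `mean_treatment`, `mean_control`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(normalized, samples, pseudo = 1) {
  m <- .counts_matrix(normalized)
  g <- .group_means(m, samples)
  tibble(
    gene_id = rownames(m),
    mean_treatment = g$mean_trt,
    mean_control = g$mean_ctl,
    log2fc = log2((g$mean_trt + pseudo) / (g$mean_ctl + pseudo))
  )
}

#' Differential expression screen
#'
#' Computes per-gene log2 fold changes and a two-sided Welch two-sample test
#' on `log2(normalized + 1)`, and retains genes with `|FC| > fc_min` (on the
#' linear scale, i.e. `|log2fc| > log2(fc_min)`) and `p < p_max`. The raw
#' p-value is gated by default; Benjamini-Hochberg adjusted p-values are
#' available via `adjust = TRUE`.
#'
#' @inheritParams log2_fold_change
#' @param fc_min Linear fold-change gate (default 1.5).
#' @param p_max P-value gate (default 0.01, strict `<`).
#' @param adjust Gate on BH-adjusted p-values instead of raw ones.
#' @return Tibble of class `kinome_de` with columns `gene_id`, `log2fc`,
#'   `p_value` (and `p_adj` when `adjust`), `retained`.
#' @export
differential_screen <- function(normalized, samples, fc_min = 1.5, p_max = 0.01,
                                pseudo = 1, adjust = FALSE) {
  m <- .counts_matrix(normalized)
  g <- .group_means(m, samples)
  if (length(g$trt) < 2 || length(g$ctl) < 2) {
    abort("differential_screen needs at least 2 samples per group")
  }
  lm2 <- log2(m + 1)
  pvals <- vapply(seq_len(nrow(lm2)), function(i) {
    x <- lm2[i, g$trt]
    y <- lm2[i, g$ctl]
    tryCatch(
      t.test(x, y, var.equal = FALSE)$p.value,
      error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    )
  }, numeric(1))
  lfc <- log2_fold_change(m, samples, pseudo = pseudo)
  out <- tibble(
    gene_id = rownames(m),
    log2fc = lfc$log2fc,
    p_value = pvals
  )
  gate_p <- if (adjust) {
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out$p_adj
  } else {
    out$p_value
  }
  out$retained <- abs(out$log2fc) > log2(fc_min) & gate_p < p_max
  class(out) <- c("kinome_de", class(out))
  out
}
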