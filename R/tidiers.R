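# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a differential-screen result
#'
#' @param x A `kinome_de` tibble from [differential_screen()].
#' @param ... Unused.
#' @return The result as a plain tibble (one row per gene).
#' @method tidy kinome_de
#' @export
tidy.kinome_de <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential-screen result
#'
#' @inheritParams tidy.kinome_de
#' @return Tibble with `n_genes`, `n_retained`, `prop_retained`,
#'   `n_up`, `n_down`.
#' @method glance kinome_de
#' @export
glance.kinome_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_retained = sum(x$retained),
    prop_retained = mean(x$retained),
    n_up = sum(x$retained & x$log2fc > 0),
    n_down = sum(x$retained & x$log2fc < 0)
  )
}

#' Volcano plot of a differential screen
#'
#' @param object A `kinome_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinome_de
#' @export
autoplot.kinome_de <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$retained)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (treatment vs control)",
                  y = "-log10 p", colour = "retained") +
    ggplot2::theme_minimal()
}

#' Bar plot of a Ks histogram
#'
#' Bins attributed to the recent whole-genome duplication (Ks 0.4-0.6) and
#' to tetraploidization (Ks 0-0.1) are highlighted, mirroring the
#' conventional colouring of duplication-epoch histograms.
#'
#' @param object A `ks_profile` tibble from [ks_histogram()].
#' @param bins Epoch bins used for colouring, see [ks_epoch_bins()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ks_profile
#' @export
autoplot.ks_profile <- function(object, bins = ks_epoch_bins(), ...) {
  df <- tibble::as_tibble(unclass(object))
  df$epoch <- assign_epoch(df$bin_start, bins = bins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
                                   y = .data$count, fill = .data$epoch)) +
    ggplot2::geom_col(width = (df$bin_end - df$bin_start) * 0.95) +
    ggplot2::labs(x = "Ks", y = "duplicate pairs", fill = "epoch") +
    ggplot2::theme_minimal()
}

#' Dot plot of collinear blocks
#'
#' Anchors are drawn at their gene ranks, one panel per chromosome pair,
#' coloured by block.
#'
#' @param object A `collinear_blocks` tibble from [collinear_blocks()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot collinear_blocks
#' @export
autoplot.collinear_blocks <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                   colour = factor(.data$block_id))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ paste(.data$chrom_a, "vs", .data$chrom_b), scales = "free") +
    ggplot2::labs(x = "gene rank (chromosome A)", y = "gene rank (chromosome B)",
                  colour = "block") +
    ggplot2::theme_minimal()
}

#' Tidy a pipeline report into a long counts table
#'
#' @param x A `kinome_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with columns `metric` and `value` for every scalar summary
#'   entry.
#' @method tidy kinome_report
#' @export
tidy.kinome_report <- function(x, ...) {
  s <- x$summary
  flat <- list()
  for (nm in names(s)) {
    v <- s[[nm]]
    if (is.list(v)) {
      for (k in names(v)) flat[[paste0(nm, ".", k)]] <- as.numeric(v[[k]])
    } else if (is.numeric(v) || is.integer(v)) {
      flat[[nm]] <- as.numeric(v)
    }
  }
  tibble(metric = names(flat), value = unlist(flat, use.names = FALSE))
}

#' One-row summary of a pipeline report
#'
#' @inheritParams tidy.kinome_report
#' @return A one-row tibble of headline counts.
#' @method glance kinome_report
#' @export
glance.kinome_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_genes = s$n_genes %||% NA_integer_,
    n_typical = s$n_typical %||% NA_integer_,
    n_atypical = s$n_atypical %||% NA_integer_,
    n_tandem_clusters = s$n_tandem_clusters %||% NA_integer_,
    n_collinear_blocks = s$n_collinear_blocks %||% NA_integer_,
    n_de_retained = s$n_de_retained %||% NA_integer_
  )
}
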