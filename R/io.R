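# File input/output: FASTA via Biostrings, GFF3 via rtracklayer, tables via
# readr, ground truth as JSON.

#' Read and write sequence sets as FASTA
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path) else Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one mRNA per gene) with 1-based
#' inclusive coordinates.
#'
#' @param cds_segments Tibble with columns `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` (one row per CDS segment).
#' @param path Output path.
#' @export
write_gff3 <- function(cds_segments, path) {
  seg <- dplyr::arrange(cds_segments, .data$chromosome, .data$start)
  # GFF3 CDS phase: bases to trim from the segment's 5' end (translation
  # order) to reach a codon boundary
  seg <- seg |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      lens <- df$end - df$start + 1L
      idx <- if (any(df$strand == "-")) rev(seq_along(lens)) else seq_along(lens)
      before <- cumsum(c(0L, lens[idx]))[seq_along(lens)]
      ph <- (3L - before %% 3L) %% 3L
      df$phase <- ph[order(idx)]
      df
    }) |>
    dplyr::ungroup()
  gene <- seg |>
    dplyr::group_by(.data$gene_id, .data$chromosome, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  mk <- function(df, type, id, parent, phase = NA_integer_) {
    GenomicRanges::GRanges(
      seqnames = df$chromosome,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand,
      type = type, ID = id, Parent = parent, phase = phase
    )
  }
  gr <- c(
    mk(gene, "gene", gene$gene_id, NA_character_),
    mk(gene, "mRNA", paste0(gene$gene_id, ".t1"), gene$gene_id),
    mk(seg, "CDS", NA_character_, paste0(seg$gene_id, ".t1"), seg$phase)
  )
  gr$source <- "kinomevo"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps CDS features and resolves their parent mRNA to a gene identifier.
#' When a gene has several transcripts, the one with the longest total CDS is
#' kept.
#'
#' @param path GFF3 file path.
#' @param species Optional species label added as a column.
#' @return Tibble with columns `gene_id`, `species`, `chromosome`, `strand`,
#'   `start`, `end`, one row per CDS segment in genomic order.
#' @export
read_gene_models <- function(path, species = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = as.character(gr$ID),
    Parent = vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  )
  mrna <- df[df$type == "mRNA", c("ID", "Parent")]
  cds <- df[df$type == "CDS", ]
  cds$transcript_id <- cds$Parent
  cds$gene_id <- mrna$Parent[match(cds$Parent, mrna$ID)]
  cds$gene_id[is.na(cds$gene_id)] <- cds$transcript_id[is.na(cds$gene_id)]
  # longest-CDS transcript per gene
  keep <- cds |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start + 1), .groups = "drop_last") |>
    dplyr::slice_max(.data$len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cds <- cds[cds$transcript_id %in% keep$transcript_id, ]
  cds |>
    dplyr::transmute(
      gene_id = .data$gene_id, species = species,
      chromosome = .data$chromosome, strand = .data$strand,
      start = .data$start, end = .data$end
    ) |>
    dplyr::arrange(.data$gene_id, .data$start)
}

#' Read a domain-hit table
#'
#' Reads either the package's tab-separated hit format (columns `gene_id`,
#' `model_name`, `model_start`, `model_end`, `model_length`, `seq_start`,
#' `seq_end`, `evalue`) or HMMER's `--domtblout` column order.
#'
#' @param path File path.
#' @param format `"tsv"` or `"domtblout"`.
#' @return Tibble in the package's hit format.
#' @export
read_domain_hits <- function(path, format = c("tsv", "domtblout")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), model_name = readr::col_character(),
      .default = readr::col_double()
    )))
  }
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE)
  tibble(
    gene_id = as.character(raw[[1]]),
    model_name = as.character(raw[[4]]),
    model_start = as.integer(raw[[16]]),
    model_end = as.integer(raw[[17]]),
    model_length = as.integer(raw[[6]]),
    seq_start = as.integer(raw[[18]]),
    seq_end = as.integer(raw[[19]]),
    evalue = as.numeric(raw[[13]])
  )
}

#' Write all simulator outputs to a directory
#'
#' Writes `proteins.fasta`, `cds.fasta`, `genome.gff3`, `homology.tsv` and
#' `truth.json`; when hit and count simulations are supplied, also
#' `hits.tsv`, `scores.tsv`, `counts.tsv` and `samples.tsv`.
#'
#' @param sim A `kinome_sim` object.
#' @param dir Output directory (created if needed).
#' @param hits Optional result of [simulate_domain_hits()].
#' @param counts Optional result of [simulate_counts()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, hits = NULL, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"), type = "AA")
  write_fasta(sim$cds, file.path(dir, "cds.fasta"), type = "DNA")
  write_gff3(sim$cds_segments, file.path(dir, "genome.gff3"))
  readr::write_tsv(sim$homology, file.path(dir, "homology.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       digits = NA, na = "null")
  if (!is.null(hits)) {
    readr::write_tsv(hits$hits, file.path(dir, "hits.tsv"))
    readr::write_tsv(hits$scores, file.path(dir, "scores.tsv"))
  }
  if (!is.null(counts)) {
    readr::write_tsv(counts$counts, file.path(dir, "counts.tsv"))
    readr::write_tsv(counts$samples, file.path(dir, "samples.tsv"))
  }
  invisible(dir)
}
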