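#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end kinome pipeline in one
#' object, surfacing each analysis threshold under a named argument with its
#' conventional default: the 0.5 model-coverage and 0.01 E-value gates for
#' typicality, the 1e-100 homology cutoff for duplication analysis, MCScanX-
#' style chaining parameters, the Ks epoch bins, and the |FC| > 1.5 with
#' p < 0.01 differential screen.
#'
#' @param sim A [sim_config()]; set to `NULL` to read inputs from
#'   `input_dir` instead.
#' @param input_dir Directory holding `proteins.fasta`, `cds.fasta`,
#'   `genome.gff3`, `hits.tsv`, `scores.tsv`, `homology.tsv`, `counts.tsv`
#'   and `samples.tsv` (the layout written by [write_simulation()]).
#' @param stages Character vector of stages to run, a subset of
#'   `c("classify", "phylogeny", "structure", "duplication", "expression")`.
#' @param catalog Subfamily-to-group catalog.
#' @param evalue_max,coverage_min Typicality gates, see [gate_typical()].
#' @param homology_evalue_max Homology filter, see [filter_homology()].
#' @param tandem_max_gap,min_anchors,max_rank_gap Duplication-detection
#'   parameters, see [tandem_clusters()] and [collinear_blocks()].
#' @param ks_bins Ks epoch bins, see [ks_epoch_bins()].
#' @param bootstrap_replicates Bootstrap replicates for the representative
#'   tree (0 skips supports; 1000 is the conventional full analysis).
#' @param representative_seed Seed for representative sampling.
#' @param fc_min,p_max,pseudo Differential-screen parameters, see
#'   [differential_screen()].
#' @param min_species Minimum species per conserved-structure group.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            stages = c("classify", "phylogeny", "structure",
                                       "duplication", "expression"),
                            catalog = subfamily_catalog(),
                            evalue_max = 0.01,
                            coverage_min = 0.5,
                            homology_evalue_max = 1e-100,
                            tandem_max_gap = 1L,
                            min_anchors = 5L,
                            max_rank_gap = 25L,
                            ks_bins = ks_epoch_bins(),
                            bootstrap_replicates = 0L,
                            representative_seed = 1L,
                            fc_min = 1.5,
                            p_max = 0.01,
                            pseudo = 1,
                            min_species = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    abort("either a simulation config or an input directory is required")
  }
  bad <- setdiff(stages, c("classify", "phylogeny", "structure", "duplication", "expression"))
  if (length(bad) > 0) abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar parameters in the file override [pipeline_config()] defaults; a
#' `sim:` section overrides [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  cfg_args <- y
  if (!isTRUE(cfg_args$no_sim)) {
    cfg_args$sim <- do.call(sim_config, sim_args)
  } else {
    cfg_args$sim <- NULL
  }
  cfg_args$no_sim <- NULL
  do.call(pipeline_config, cfg_args)
}

.load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_genome(config$sim)
    hs <- simulate_domain_hits(sim)
    cn <- simulate_counts(sim)
    list(
      genes = sim$genes, cds_segments = sim$cds_segments,
      proteins = sim$proteins, cds = sim$cds, homology = sim$homology,
      hits = hs$hits, scores = hs$scores,
      counts = cn$counts, samples = cn$samples, gene_lengths = cn$gene_lengths,
      truth = sim$truth
    )
  } else {
    dir <- config$input_dir
    segs <- read_gene_models(file.path(dir, "genome.gff3"))
    genes <- segs |>
      dplyr::group_by(.data$gene_id, .data$chromosome, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       cds_length = sum(.data$end - .data$start + 1),
                       .groups = "drop")
    cts <- readr::read_tsv(file.path(dir, "counts.tsv"), show_col_types = FALSE)
    list(
      genes = genes, cds_segments = segs,
      proteins = read_fasta(file.path(dir, "proteins.fasta"), "AA"),
      cds = read_fasta(file.path(dir, "cds.fasta"), "DNA"),
      homology = readr::read_tsv(file.path(dir, "homology.tsv"), show_col_types = FALSE),
      hits = read_domain_hits(file.path(dir, "hits.tsv")),
      scores = readr::read_tsv(file.path(dir, "scores.tsv"), show_col_types = FALSE),
      counts = cts,
      samples = readr::read_tsv(file.path(dir, "samples.tsv"), show_col_types = FALSE),
      gene_lengths = tibble(gene_id = genes$gene_id,
                            length = genes$cds_length),
      truth = NULL
    )
  }
}

# best qualifying hit per typical gene -> protein-coordinate domain span
.best_domains <- function(hits, evalue_max, coverage_min) {
  hits |>
    dplyr::mutate(coverage = coverage_fraction(hits)) |>
    dplyr::filter(.data$evalue < evalue_max, .data$coverage > coverage_min) |>
    dplyr::arrange(.data$gene_id, .data$evalue) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::transmute(gene_id = .data$gene_id,
                     domain_start = .data$seq_start, domain_end = .data$seq_end)
}

#' Run the kinome pipeline end to end
#'
#' Wires the simulator (or files on disk) through classification, the
#' representative phylogeny, exon-phase fingerprinting, tandem/collinearity
#' detection with Ka/Ks and Ks-epoch attribution, and the differential
#' expression screen, and assembles a machine-readable report. All stages
#' are deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, every stage output
#'   is written as TSV/Newick/JSON.
#' @return A list of class `kinome_report` with elements `classification`,
#'   `representatives`, `tree`, `congruence`, `fingerprints`,
#'   `conserved_groups`, `tandem`, `blocks`, `kaks`, `ks_profile`,
#'   `single_correspondence`, `rpkm`, `de`, `summary` and (for simulated
#'   inputs) `truth`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(seed = 1, genes_per_chromosome = 60))
#' rep <- run_pipeline(cfg)
#' rep$summary$n_typical
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- .load_inputs(config)
  res <- list(truth = inp$truth)
  stages <- config$stages
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if ("classify" %in% stages) {
    res$classification <- run_stage("classify", classify_kinases(
      inp$hits, inp$scores, config$catalog,
      evalue_max = config$evalue_max, coverage_min = config$coverage_min,
      universe = inp$genes$gene_id
    ))
  }

  if ("phylogeny" %in% stages) {
    res <- c(res, run_stage("phylogeny", {
      cls <- res$classification
      if (is.null(cls)) abort("phylogeny requires the classify stage")
      typical <- cls[cls$typical & !is.na(cls$subfamily), ]
      reps <- select_representatives(typical[, c("subfamily", "gene_id")],
                                     seed = config$representative_seed)
      doms <- .best_domains(inp$hits, config$evalue_max, config$coverage_min)
      doms <- doms[doms$gene_id %in% reps$gene_id, ]
      seqs <- substr(inp$proteins[doms$gene_id], doms$domain_start, doms$domain_end)
      width <- max(nchar(seqs))
      seqs <- stringr::str_pad(seqs, width, side = "right", pad = "-")
      names(seqs) <- doms$gene_id
      tree <- if (config$bootstrap_replicates > 0) {
        bootstrap_support(seqs, replicates = config$bootstrap_replicates,
                          seed = config$representative_seed)
      } else {
        neighbor_joining(p_distance(seqs))
      }
      cong <- clade_congruence(tree, typical[, c("gene_id", "subfamily")])
      list(representatives = reps, tree = tree, congruence = cong)
    }))
  }

  if ("structure" %in% stages) {
    res <- c(res, run_stage("structure", {
      cls <- res$classification
      if (is.null(cls)) abort("structure requires the classify stage")
      doms <- .best_domains(inp$hits, config$evalue_max, config$coverage_min)
      fps <- domain_fingerprint(inp$cds_segments, doms)
      species <- if ("species" %in% names(inp$cds_segments)) {
        inp$cds_segments$species[match(fps$gene_id, inp$cds_segments$gene_id)]
      } else NA_character_
      fps$species <- species
      fps$subfamily <- cls$subfamily[match(fps$gene_id, cls$gene_id)]
      groups <- conserved_structure_groups(fps, min_species = config$min_species)
      list(fingerprints = fps, conserved_groups = groups)
    }))
  }

  if ("duplication" %in% stages) {
    res <- c(res, run_stage("duplication", {
      fh <- filter_homology(inp$homology, evalue_max = config$homology_evalue_max)
      tand <- tandem_clusters(inp$genes, fh, max_gap = config$tandem_max_gap)
      blocks <- collinear_blocks(inp$genes, fh,
                                 min_anchors = config$min_anchors,
                                 max_rank_gap = config$max_rank_gap)
      anchor_pairs <- dplyr::distinct(blocks[, c("gene_a", "gene_b")])
      kk <- kaks_pairs(anchor_pairs, inp$cds, ks_bins = config$ks_bins)
      sc <- single_correspondence(anchor_pairs)
      list(
        tandem = tand, blocks = blocks, kaks = kk,
        ks_profile = ks_histogram(kk$ks),
        single_correspondence = sc
      )
    }))
  }

  if ("expression" %in% stages) {
    res <- c(res, run_stage("expression", {
      norm <- rpkm(inp$counts, inp$gene_lengths)
      de <- differential_screen(norm, inp$samples,
                                fc_min = config$fc_min, p_max = config$p_max,
                                pseudo = config$pseudo)
      list(rpkm = norm, de = de)
    }))
  }

  res$summary <- .report_summary(res, inp)
  res$config <- config
  class(res) <- "kinome_report"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

.report_summary <- function(res, inp) {
  s <- list(n_genes = nrow(inp$genes))
  if (!is.null(res$classification)) {
    cls <- res$classification
    s$n_typical <- sum(cls$typicality == "typical")
    s$n_atypical <- sum(cls$typicality == "atypical")
    s$n_non_kinase <- sum(cls$typicality == "non_kinase")
    s$group_counts <- as.list(table(cls$group[cls$typical]))
    s$n_multi_domain <- sum(cls$n_kinase_domains > 1, na.rm = TRUE)
  }
  if (!is.null(res$congruence)) {
    s$congruence_fraction <- attr(res$congruence, "fraction")
  }
  if (!is.null(res$conserved_groups)) {
    s$n_conserved_groups <- nrow(res$conserved_groups)
  }
  if (!is.null(res$tandem)) {
    s$n_tandem_genes <- nrow(res$tandem)
    s$n_tandem_clusters <- dplyr::n_distinct(res$tandem$cluster_id)
    s$largest_tandem_cluster <- if (nrow(res$tandem) > 0) {
      max(table(res$tandem$cluster_id))
    } else 0L
    s$n_collinear_blocks <- dplyr::n_distinct(res$blocks$block_id)
    s$n_collinear_events <- nrow(res$kaks)
    s$epoch_counts <- as.list(table(res$kaks$epoch))
    s$single_correspondence_fraction <- res$single_correspondence$fraction
  }
  if (!is.null(res$de)) {
    s$n_de_retained <- sum(res$de$retained)
  }
  s
}

#' Write a pipeline report to disk
#'
#' @param report A `kinome_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x)) readr::write_tsv(x, file.path(dir, f))
  wt(report$classification, "classification.tsv")
  wt(report$representatives, "representatives.tsv")
  wt(report$congruence, "congruence.tsv")
  wt(report$fingerprints, "fingerprints.tsv")
  wt(report$conserved_groups, "conserved_groups.tsv")
  wt(report$tandem, "tandem_clusters.tsv")
  wt(report$blocks, "blocks.tsv")
  wt(report$kaks, "kaks.tsv")
  wt(report$ks_profile, "ks_histogram.tsv")
  wt(report$de, "de_results.tsv")
  if (!is.null(report$tree)) {
    ape::write.tree(report$tree, file.path(dir, "representatives.nwk"))
  }
  jsonlite::write_json(report$summary, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.kinome_report <- function(x, ...) {
  cat("<kinome_report>\n")
  s <- x$summary
  for (nm in setdiff(names(s), c("group_counts", "epoch_counts"))) {
    cat("  ", nm, ": ", paste(unlist(s[[nm]]), collapse = " "), "\n", sep = "")
  }
  if (!is.null(s$group_counts)) {
    cat("  groups: ", paste(names(s$group_counts), unlist(s$group_counts),
                            sep = "=", collapse = " "), "\n", sep = "")
  }
  if (!is.null(s$epoch_counts)) {
    cat("  epochs: ", paste(names(s$epoch_counts), unlist(s$epoch_counts),
                            sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
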