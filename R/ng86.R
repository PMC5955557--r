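# Nei-Gojobori (1986) site and difference counting with Jukes-Cantor
# correction. Single-step changes to stop codons count as nonsynonymous in
# the site tally; multi-step pathways passing through a stop codon are
# skipped and the remaining pathways renormalized.

.ng86 <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.ng86_init_sites <- function() {
  if (!is.null(.ng86$codons)) return(invisible(NULL))
  gc <- .genetic_code()
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  syn <- numeric(length(codons))
  names(syn) <- codons
  for (cd in codons) {
    if (gc[[cd]] == "*") next
    chars <- strsplit(cd, "")[[1]]
    n_syn <- 0L
    for (pos in 1:3) {
      for (b in setdiff(bases, chars[pos])) {
        alt <- chars
        alt[pos] <- b
        alt_cd <- paste(alt, collapse = "")
        # a change producing a stop is nonsynonymous by convention
        if (gc[[alt_cd]] != "*" && gc[[alt_cd]] == gc[[cd]]) n_syn <- n_syn + 1L
      }
    }
    syn[cd] <- n_syn / 3
  }
  .ng86$codons <- codons
  .ng86$aa <- gc
  .ng86$syn_sites <- syn
  .ng86$is_stop <- gc == "*"
  invisible(NULL)
}

# pathway-averaged (sd, nd) for one codon pair
.ng86_pair <- function(codon_a, codon_b) {
  gc <- .ng86$aa
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k,
    `1` = list(diffs),
    `2` = list(diffs, rev(diffs)),
    `3` = {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) diffs[o])
    }
  )
  sds <- numeric(0)
  nds <- numeric(0)
  for (ord in perms) {
    cur <- a
    s <- 0
    n <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      nxt_cd <- paste(nxt, collapse = "")
      if (gc[[nxt_cd]] == "*") {
        ok <- FALSE
        break
      }
      if (gc[[nxt_cd]] == gc[[paste(cur, collapse = "")]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) {
      sds <- c(sds, s)
      nds <- c(nds, n)
    }
  }
  if (length(sds) == 0L) {
    # no stop-free pathway exists (cannot occur for standard-code non-stop
    # endpoints, kept as a defensive fallback): count over all pathways
    for (ord in perms) {
      cur <- a
      s <- 0
      n <- 0
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- b[pos]
        nxt_cd <- paste(nxt, collapse = "")
        if (gc[[nxt_cd]] != "*" && gc[[nxt_cd]] == gc[[paste(cur, collapse = "")]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      sds <- c(sds, s)
      nds <- c(nds, n)
    }
  }
  c(sd = mean(sds), nd = mean(nds))
}

.ng86_init_pairs <- function() {
  if (!is.null(.ng86$sd_mat)) return(invisible(NULL))
  .ng86_init_sites()
  codons <- .ng86$codons
  nc <- length(codons)
  sd_mat <- matrix(0, nc, nc, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  sense <- codons[!.ng86$is_stop]
  for (ca in sense) {
    for (cb in sense) {
      if (ca == cb) next
      x <- .ng86_pair(ca, cb)
      sd_mat[ca, cb] <- x[["sd"]]
      nd_mat[ca, cb] <- x[["nd"]]
    }
  }
  .ng86$sd_mat <- sd_mat
  .ng86$nd_mat <- nd_mat
  invisible(NULL)
}

.check_codons <- function(codons, arg = "codon") {
  .ng86_init_sites()
  bad <- !codons %in% .ng86$codons
  if (any(bad)) {
    abort(paste0("invalid ", arg, ": ", paste(unique(codons[bad]), collapse = ", ")))
  }
  if (any(.ng86$is_stop[codons])) {
    abort(paste0("stop ", arg, " not allowed: ",
                 paste(unique(codons[.ng86$is_stop[codons]]), collapse = ", ")))
  }
  invisible(NULL)
}

#' Synonymous and nonsynonymous site counts of codons
#'
#' Counts, for each codon, the fraction of single-nucleotide changes that are
#' synonymous: each of the three positions contributes (number of synonymous
#' one-step changes at that position)/3 synonymous sites, so the synonymous
#' and nonsynonymous sites of a codon always sum to 3. Changes producing a
#' stop codon are counted as nonsynonymous.
#'
#' @param codons Character vector of non-stop codons (e.g. `"TTT"`).
#' @return A tibble with columns `codon`, `syn_sites`, `nonsyn_sites`.
#' @export
#' @examples
#' ng86_sites(c("TTT", "ATG"))
ng86_sites <- function(codons) {
  codons <- toupper(codons)
  .check_codons(codons)
  s <- unname(.ng86$syn_sites[codons])
  tibble(codon = codons, syn_sites = s, nonsyn_sites = 3 - s)
}

#' Pathway-averaged synonymous and nonsynonymous differences between codons
#'
#' For each codon pair, the substitutions along every minimal mutational
#' pathway between the two codons are classified as synonymous or
#' nonsynonymous and averaged over the 1, 2 or 6 pathways. Pathways that pass
#' through a stop codon are skipped, renormalizing over those that remain.
#'
#' @param codon_a,codon_b Character vectors (recycled) of non-stop codons.
#' @return A tibble with columns `codon_a`, `codon_b`, `syn_diffs`,
#'   `nonsyn_diffs`.
#' @export
#' @examples
#' ng86_counts("TTT", "GTA")
ng86_counts <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n)
  codon_b <- rep_len(codon_b, n)
  .check_codons(codon_a, "codon_a")
  .check_codons(codon_b, "codon_b")
  .ng86_init_pairs()
  tibble(
    codon_a = codon_a, codon_b = codon_b,
    syn_diffs = .ng86$sd_mat[cbind(codon_a, codon_b)],
    nonsyn_diffs = .ng86$nd_mat[cbind(codon_a, codon_b)]
  )
}

.split_codons <- function(cds) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) abort("coding sequence length is not a multiple of 3")
  substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
}

#' Nei-Gojobori Ka/Ks for an aligned pair of coding sequences
#'
#' Computes synonymous (`S`) and nonsynonymous (`N`) site totals averaged over
#' the two sequences, pathway-averaged synonymous (`Sd`) and nonsynonymous
#' (`Nd`) differences, the proportions `pS = Sd/S` and `pN = Nd/N`, and the
#' Jukes-Cantor corrected rates `Ks = -(3/4) log(1 - (4/3) pS)` (and
#' likewise `Ka`). Codon columns containing a gap, an ambiguous base or a stop
#' codon in either sequence are dropped before counting. When `pS` or `pN`
#' reaches 3/4 the correction is undefined and the pair is flagged as
#' saturated.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length (character
#'   scalars; gaps as `-`).
#' @param ks_bins Passed to [assign_epoch()] for the epoch label.
#' @return A one-row tibble with columns `n_codons`, `syn_sites` (S),
#'   `nonsyn_sites` (N), `syn_diffs` (Sd), `nonsyn_diffs` (Nd), `ps`, `pn`,
#'   `ka`, `ks` and `epoch`.
#' @export
#' @examples
#' kaks("ATGTTTAAA", "ATGTTCAAA")
kaks <- function(cds_a, cds_b, ks_bins = ks_epoch_bins()) {
  if (length(cds_a) != 1L || length(cds_b) != 1L) abort("kaks() expects single sequences")
  if (nchar(cds_a) != nchar(cds_b)) abort("aligned sequences differ in length")
  .ng86_init_pairs()
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  sense <- .ng86$codons[!.ng86$is_stop]
  keep <- ca %in% sense & cb %in% sense
  ca <- ca[keep]
  cb <- cb[keep]
  n_codons <- length(ca)
  if (n_codons == 0L) abort("no comparable codons after removing gaps/stops")
  s_a <- sum(.ng86$syn_sites[ca])
  s_b <- sum(.ng86$syn_sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S
  Sd <- sum(.ng86$sd_mat[cbind(ca, cb)])
  Nd <- sum(.ng86$nd_mat[cbind(ca, cb)])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(ps)
  ka <- jc(pn)
  saturated <- is.na(ks) || is.na(ka)
  tibble(
    n_codons = n_codons,
    syn_sites = S, nonsyn_sites = N,
    syn_diffs = Sd, nonsyn_diffs = Nd,
    ps = ps, pn = pn, ka = ka, ks = ks,
    epoch = if (saturated) "saturated" else assign_epoch(ks, bins = ks_bins)
  )
}

#' Ks epoch bin edges
#'
#' Duplication events are attributed to evolutionary epochs by their
#' synonymous distance: Ks in \[0, 0.1) corresponds to the recent cotton
#' tetraploidization, \[0.4, 0.6) to the ~16.6 Mya whole-genome duplication,
#' and \[0.6, 3) to older (ancient) duplications.
#'
#' @return Named list of half-open `c(lower, upper)` Ks intervals.
#' @export
ks_epoch_bins <- function() {
  list(
    tetraploid = c(0, 0.1),
    wgd_recent = c(0.4, 0.6),
    ancient = c(0.6, 3)
  )
}

#' Attribute a Ks value to a duplication epoch
#'
#' @param ks Numeric vector of synonymous distances; `NA` marks saturated
#'   pairs.
#' @param bins Named list of half-open intervals, see [ks_epoch_bins()].
#' @return Character vector of epoch labels (`"tetraploid"`, `"wgd_recent"`,
#'   `"ancient"`, `"unassigned"` or `"saturated"`).
#' @export
#' @examples
#' assign_epoch(c(0.05, 0.5, 2, 0.25, NA))
assign_epoch <- function(ks, bins = ks_epoch_bins()) {
  out <- rep("unassigned", length(ks))
  for (nm in names(bins)) {
    b <- bins[[nm]]
    out[!is.na(ks) & ks >= b[1] & ks < b[2]] <- nm
  }
  out[is.na(ks)] <- "saturated"
  if (any(!is.na(ks) & ks < 0)) abort("negative Ks")
  out
}
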