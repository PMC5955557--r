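# Independent oracles used to validate the package's implementations.

# genetic code as a lookup, built through Biostrings translation of a
# DNAString (a different route than the package's own table)
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

oracle_code <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("A", "C", "G", "T")
      cods <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
      tab <<- setNames(vapply(cods, oracle_translate, character(1)), cods)
    }
    tab
  }
})

oracle_neighbors <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      alt <- chars
      alt[pos] <- b
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

# brute-force NG86 synonymous site count of one codon
oracle_sites <- function(codon) {
  code <- oracle_code()
  nb <- oracle_neighbors(codon)
  syn <- sum(code[nb] != "*" & code[nb] == code[codon])
  c(s = syn / 3, n = 3 - syn / 3)
}

# brute-force pathway enumeration for (sd, nd), skipping stop pathways
oracle_counts <- function(a, b) {
  code <- oracle_code()
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  diffs <- which(ac != bc)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- gtools_permutations(diffs)
  paths <- list()
  for (ord in perms) {
    cur <- ac
    steps <- character(0)
    blocked <- FALSE
    s <- 0
    n <- 0
    for (pos in ord) {
      prev_cd <- paste(cur, collapse = "")
      cur[pos] <- bc[pos]
      cur_cd <- paste(cur, collapse = "")
      if (code[cur_cd] == "*") {
        blocked <- TRUE
        break
      }
      if (code[cur_cd] == code[prev_cd]) s <- s + 1 else n <- n + 1
    }
    if (!blocked) paths[[length(paths) + 1]] <- c(s, n)
  }
  if (length(paths) == 0) return(NULL)
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

# all permutations of a small vector (recursive, no dependencies)
gtools_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in gtools_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

all_sense_codons <- function() {
  code <- oracle_code()
  names(code)[code != "*"]
}

# brute-force Ka/Ks of two equal-length coding sequences, assembled only
# from the oracle primitives above
oracle_kaks <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a)
  cb <- split3(cds_b)
  S <- 0
  N <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i])
    sb <- oracle_sites(cb[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    cnt <- oracle_counts(ca[i], cb[i])
    Sd <- Sd + cnt["sd"]
    Nd <- Nd + cnt["nd"]
  }
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  c(ks = unname(jc(ps)), ka = unname(jc(pn)))
}

# random additive tree and its exact path metric
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  tr
}

# least-squares fit of a 4-taxon topology: returns the residual sum of
# squares of the best branch-length assignment for the path-metric equations
ls_fit_quartet <- function(d, split) {
  taxa <- rownames(d)
  pair1 <- split[[1]]
  pair2 <- split[[2]]
  # edges: e1..e4 pendant (in taxa order), e5 internal
  pendant <- setNames(1:4, taxa)
  rows <- list()
  y <- c()
  for (i in 1:3) {
    for (j in (i + 1):4) {
      r <- rep(0, 5)
      r[pendant[taxa[i]]] <- 1
      r[pendant[taxa[j]]] <- 1
      same_side <- (taxa[i] %in% pair1 && taxa[j] %in% pair1) ||
        (taxa[i] %in% pair2 && taxa[j] %in% pair2)
      if (!same_side) r[5] <- 1
      rows[[length(rows) + 1]] <- r
      y <- c(y, d[taxa[i], taxa[j]])
    }
  }
  X <- do.call(rbind, rows)
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# random sense coding sequence for tests
random_test_cds <- function(n_codons, seed = NULL) {
  draw <- function() {
    sense <- setdiff(all_sense_codons(), c("TAA", "TAG", "TGA"))
    paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
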