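# Neighbor-joining phylogenies from p-distances with bootstrap supports.

# coerce an alignment to a character matrix (taxa x sites)
as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment) && is.character(alignment)) {
    m <- alignment
  } else {
    if (inherits(alignment, "AAStringSet") || inherits(alignment, "DNAStringSet")) {
      alignment <- setNames(as.character(alignment), names(alignment))
    }
    if (is.data.frame(alignment)) {
      alignment <- setNames(alignment$sequence, alignment$taxon)
    }
    if (!is.character(alignment)) abort("cannot interpret alignment input")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1) abort("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("alignment requires unique taxon names")
  }
  m
}

#' Pairwise p-distances from an alignment
#'
#' The p-distance between two aligned sequences is the proportion of
#' mismatching sites among the sites where neither sequence has a gap
#' (pairwise deletion; `-`, `.`, `?` and `X` are treated as missing).
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   a tibble with columns `taxon` and `sequence`, an `AAStringSet`/
#'   `DNAStringSet`, or a character matrix.
#' @return Symmetric numeric matrix of distances in \[0, 1\] with zero
#'   diagonal.
#' @export
#' @examples
#' p_distance(c(a = "AAAA", b = "AAAT", c = "AA-A"))
p_distance <- function(alignment) {
  m <- as_aln_matrix(alignment)
  if (nrow(m) < 2) abort("p_distance needs at least 2 taxa")
  valid <- !(m %in% c("-", ".", "?", "X"))
  dim(valid) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cmp <- valid[i, ] & valid[j, ]
      if (!any(cmp)) {
        abort(paste0("no comparable sites between ", rownames(m)[i], " and ", rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- mean(m[i, cmp] != m[j, cmp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion is joined (ties broken towards the smallest taxon-index pair),
#' branch lengths follow the usual NJ formulas with negative estimates
#' clamped to zero and the deficit transferred to the sibling edge, and the
#' matrix is reduced until three nodes remain, which are joined in a final
#' trifurcation. For an additive input metric the tree's leaf-to-leaf path
#' lengths reproduce the input exactly.
#'
#' @param d Symmetric distance matrix with taxon names (or a `dist`).
#' @return An unrooted `phylo` object (package \pkg{ape}).
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' neighbor_joining(d)
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("distance matrix must be symmetric")
  }
  n_tips <- nrow(m)
  if (n_tips < 3) abort("neighbor joining needs at least 3 taxa")
  labels <- rownames(m)

  # node bookkeeping: tips 1..n, internal nodes numbered onwards
  nodes <- seq_len(n_tips)
  next_id <- n_tips + 1L
  edge_parent <- integer(0)
  edge_child <- integer(0)
  edge_len <- numeric(0)
  add_edge <- function(p, c, l) {
    edge_parent <<- c(edge_parent, p)
    edge_child <<- c(edge_child, c)
    edge_len <<- c(edge_len, max(l, 0))
  }

  while (length(nodes) > 3) {
    r <- nrow(m)
    rs <- rowSums(m)
    best <- c(NA, NA)
    best_q <- Inf
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        q <- (r - 2) * m[i, j] - rs[i] - rs[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    vi <- m[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- m[i, j] - vi
    if (vi < 0) {
      vj <- vj + vi
      vi <- 0
    }
    if (vj < 0) {
      vi <- vi + vj
      vj <- 0
    }
    u <- next_id
    next_id <- next_id + 1L
    add_edge(u, nodes[i], vi)
    add_edge(u, nodes[j], vj)
    others <- setdiff(seq_len(r), c(i, j))
    du <- (m[i, others] + m[j, others] - m[i, j]) / 2
    m <- rbind(cbind(m[others, others, drop = FALSE], du), c(du, 0))
    nodes <- c(nodes[others], u)
  }

  root <- next_id
  if (length(nodes) == 3) {
    la <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
    lb <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
    lc <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
    add_edge(root, nodes[1], la)
    add_edge(root, nodes[2], lb)
    add_edge(root, nodes[3], lc)
  }

  # renumber: tips keep 1..n; root becomes n+1; other internals follow
  internals <- sort(unique(edge_parent[edge_parent > n_tips]))
  internals <- c(root, setdiff(internals, root))
  remap <- integer(max(internals))
  remap[internals] <- n_tips + seq_along(internals)
  map_node <- function(x) ifelse(x <= n_tips, x, remap[x])
  tr <- list(
    edge = cbind(map_node(edge_parent), map_node(edge_child)),
    edge.length = edge_len,
    tip.label = labels,
    Nnode = length(internals)
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# bipartitions of a phylo tree, as canonical keys (side not containing the
# first tip, sorted labels). Trivial splits are excluded.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  internal <- setdiff(unique(tree$edge[, 1]), root)
  internal <- internal[internal > n]
  keys <- character(0)
  nodes <- integer(0)
  for (node in internal) {
    side <- tips_below(node)
    if (length(side) < 2 || length(side) > n - 2) next
    if (tree$tip.label[1] %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  setNames(keys, nodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement (same length) `replicates` times, rebuilds the
#' tree for each replicate, and annotates each internal edge of the original
#' tree with the percentage of replicates whose tree contains the same
#' bipartition. Supports are stored as node labels of the returned tree.
#'
#' @inheritParams p_distance
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `phylo` object whose `node.label` holds bootstrap percentages
#'   (the root label is empty).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L) {
  m <- as_aln_matrix(alignment)
  if (nrow(m) < 4) abort("bootstrap supports need at least 4 taxa")
  tree <- neighbor_joining(p_distance(m))
  bp <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(bp)), names(bp))
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      rep_keys <- NULL
      for (attempt in 1:100) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        rep_keys <- tryCatch(
          tree_bipartitions(neighbor_joining(p_distance(m[, cols, drop = FALSE]))),
          error = function(e) NULL
        )
        if (!is.null(rep_keys)) break
      }
      if (is.null(rep_keys)) abort("bootstrap replicate failed repeatedly")
      hits <- hits + (bp %in% rep_keys)
    }
  })
  support <- round(100 * hits / replicates)
  n <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  labs[as.integer(names(bp)) - n] <- as.character(support)
  tree$node.label <- labs
  tree
}
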