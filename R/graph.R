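#' Partition descriptor alignments into building blocks and extensions
#'
#' Descriptor alignments whose aligned portion has at least three perceived
#' segments in *both* structures are large enough to anchor a structural
#' similarity by themselves; they form the set `S3` of building blocks.
#' All remaining alignments form `S1` and are used only to extend
#' alignments assembled from `S3`.
#'
#' @param alignments list of `ldal_desc_alignment`.
#' @return list with components `s3` and `s1`.
#' @export
partition_s3_s1 <- function(alignments) {
  if (length(alignments) == 0) return(list(s3 = list(), s1 = list()))
  in3 <- vapply(alignments, function(a) a$nseg_a >= 3 && a$nseg_b >= 3,
                logical(1))
  list(s3 = alignments[in3], s1 = alignments[!in3])
}

#' Are two descriptor alignments consistent?
#'
#' Two partial alignments can be combined when they agree wherever they
#' overlap, or do not overlap at all: the union of their residue-pair sets
#' must still be a partial bijection (no residue of either structure mapped
#' to two different partners).
#'
#' @param u,v `ldal_desc_alignment` objects over the same structure pair.
#' @return logical.
#' @export
consistent <- function(u, v) {
  is_partial_bijection(c(u$ia, v$ia), c(u$ib, v$ib))
}

#' Build the alignment graph over the S3 building blocks
#'
#' Nodes are descriptor alignments; an undirected edge joins two nodes
#' exactly when they are consistent. Any clique of this graph is then a
#' valid (conflict-free) alignment of the two structures. No geometric
#' compatibility is required across nodes: geometry is enforced within
#' descriptors and, at scoring time, through the tension term.
#'
#' @param s3 list of `ldal_desc_alignment` (the building blocks).
#' @param s1 optional list of extension alignments, carried along.
#' @return object of class `ldal_graph`: list with `nodes`, `adjacency`
#'   (symmetric logical matrix, no self edges), `s1_pool`, and per-node
#'   `coverage` (number of aligned residue pairs).
#' @export
build_graph <- function(s3, s1 = list()) {
  m <- length(s3)
  cov <- vapply(s3, function(a) length(a$ia), integer(1))
  rms <- vapply(s3, function(a) a$rmsd, numeric(1))
  # search-tree node order: descending coverage, ties by rmsd ascending,
  # for better early bounds during branch and bound
  ord <- order(-cov, rms)
  s3 <- s3[ord]; cov <- cov[ord]
  adj <- matrix(FALSE, m, m)
  if (m > 1) {
    for (u in seq_len(m - 1)) {
      for (v in (u + 1):m) {
        if (consistent(s3[[u]], s3[[v]]))
          adj[u, v] <- adj[v, u] <- TRUE
      }
    }
  }
  structure(list(nodes = s3, adjacency = adj, s1_pool = s1,
                 coverage = cov),
            class = "ldal_graph")
}

# encode residue pairs of an alignment as single integer keys (for fast
# union/coverage computations); key = (ia - 1) * 2^16 + ib
pair_keys <- function(a) {
  a$ia * 65536 + a$ib
}

#' @export
print.ldal_graph <- function(x, ...) {
  m <- length(x$nodes)
  e <- if (m > 1) sum(x$adjacency) / 2 else 0
  cat("ldal_graph: ", m, " S3 node(s), ", e, " edge(s), ",
      length(x$s1_pool), " S1 extension block(s)\n", sep = "")
  invisible(x)
}
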