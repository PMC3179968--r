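# Shared fixtures and independent oracles for the test suite.

# bare in-memory structure (no file round trip) for constructed geometries
mk_struct <- function(ca, sc = ca, chain = NULL, id = "synthetic") {
  n <- nrow(ca)
  if (is.null(chain)) chain <- rep("A", n)
  st <- structure(
    list(id = id, n = n, chain = chain,
         resno = seq_len(n), ins = rep("", n),
         seq_label = as.character(seq_len(n)),
         aa = rep("ALA", n), ca = ca, sc = sc, breaks = integer(0),
         atoms = NULL),
    class = "ldal_structure")
  if (n > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    st$breaks <- which(chain[-1] != chain[-n] | d > 4.5)
  }
  st
}

# abstract alignment-graph instance: consistency-derived edges over random
# co-linear residue blocks, as produced by real descriptor comparisons
mk_instance <- function(seed, m = 14L, nres = 40L) {
  set.seed(seed)
  nodes <- lapply(seq_len(m), function(i) {
    len <- sample(3:7, 1)
    sa <- sample.int(nres - len, 1)
    sb <- sample.int(nres - len, 1)
    structure(list(central_a = sa, central_b = sb,
                   ia = sa:(sa + len - 1L), ib = sb:(sb + len - 1L),
                   rmsd = stats::runif(1, 0, 2),
                   nseg_a = 3L, nseg_b = 3L,
                   el_a = sa, el_b = sb),
              class = "ldal_desc_alignment")
  })
  build_graph(nodes)
}

# instance with an underlying consistent mapping: half the nodes are
# windows of one global correspondence (so they overlap and agree, as
# descriptor alignments over a genuinely similar region do), the rest are
# random blocks
mk_instance_overlapping <- function(seed, m = 12L, nres = 40L) {
  set.seed(seed)
  shift <- sample(0:5, 1)
  nodes <- lapply(seq_len(m), function(i) {
    len <- sample(3:7, 1)
    if (i <= m / 2) {
      sa <- sample.int(nres - len - shift, 1)
      sb <- sa + shift
    } else {
      sa <- sample.int(nres - len, 1)
      sb <- sample.int(nres - len, 1)
    }
    structure(list(central_a = sa, central_b = sb,
                   ia = sa:(sa + len - 1L), ib = sb:(sb + len - 1L),
                   rmsd = stats::runif(1, 0, 2),
                   nseg_a = 3L, nseg_b = 3L,
                   el_a = sa, el_b = sb),
              class = "ldal_desc_alignment")
  })
  build_graph(nodes)
}

# exhaustive maximal-clique oracle via igraph (independent of tree_search)
oracle_max_cliques <- function(graph) {
  m <- length(graph$nodes)
  if (m == 1) return(list(1L))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected")
  lapply(igraph::max_cliques(g), function(x) sort(as.integer(x)))
}

clique_coverage <- function(graph, nodes) {
  ia <- unlist(lapply(graph$nodes[nodes], `[[`, "ia"))
  ib <- unlist(lapply(graph$nodes[nodes], `[[`, "ib"))
  length(unique(ia * 65536 + ib))
}

clique_key <- function(nodes) paste(sort(nodes), collapse = ",")

# independent perceived-segment count of a set of element spans
oracle_perceived <- function(struct, spans) {
  idx <- sort(unique(unlist(spans)))
  seg <- ldalign:::chain_segment_ids(struct)
  newrun <- c(TRUE, diff(idx) > 1L | seg[idx[-1]] != seg[idx[-length(idx)]])
  run <- cumsum(newrun)
  tot <- 0L
  for (r in unique(run)) {
    ii <- idx[run == r]
    tot <- tot + perceived_segments(
      segment_spatial_length(struct, min(ii), max(ii)))
  }
  tot
}

# brute-force enumeration of all maximal descriptor alignments satisfying
# the six validity conditions; checks every injective element assignment
# directly against the stated thresholds (independent of the search and
# pruning machinery inside compare_descriptors)
oracle_compare <- function(da, db, sa, sb) {
  ea <- da$elements; eb <- db$elements
  cmap <- ldalign:::element_exact_map(ea[[1]], eb[[1]])
  if (is.null(cmap)) return(character(0))
  np <- length(ea) - 1L; nq <- length(eb) - 1L
  cert_a <- c(TRUE, da$partner_certain)
  cert_b <- c(TRUE, db$partner_certain)

  pair_ok <- matrix(FALSE, max(np, 1), max(nq, 1))
  pair_map <- vector("list", np * max(nq, 1))
  if (np > 0 && nq > 0) {
    for (p in seq_len(np)) {
      for (q in seq_len(nq)) {
        em <- ldalign:::element_exact_map(ea[[p + 1L]], eb[[q + 1L]])
        if (is.null(em)) next
        r_el <- superpose_rmsd(sa$ca[em[, 1], , drop = FALSE],
                               sb$ca[em[, 2], , drop = FALSE])
        jm <- unique(rbind(cmap, em))
        if (!ldalign:::is_partial_bijection(jm[, 1], jm[, 2])) next
        r_j <- superpose_rmsd(sa$ca[jm[, 1], , drop = FALSE],
                              sb$ca[jm[, 2], , drop = FALSE])
        if (r_el <= 1.5 && r_j <= 2.5) {
          pair_ok[p, q] <- TRUE
          pair_map[[(p - 1L) * nq + q]] <- em
        }
      }
    }
  }

  valid_keys <- character(0)
  valid_sets <- list()
  subsets <- if (np > 0) {
    unlist(lapply(0:np, function(s) utils::combn(np, s, simplify = FALSE)),
           recursive = FALSE)
  } else list(integer(0))
  injections <- function(sel, avail) {
    if (length(sel) == 0) return(list(integer(0)))
    out <- list()
    for (q in avail) {
      for (rest in injections(sel[-1], setdiff(avail, q)))
        out[[length(out) + 1L]] <- c(q, rest)
    }
    out
  }
  for (sel in subsets) {
    for (qs in injections(sel, seq_len(nq))) {
      if (length(sel) && !all(pair_ok[cbind(sel, qs)])) next
      m <- cmap
      if (length(sel))
        for (t in seq_along(sel))
          m <- rbind(m, pair_map[[(sel[t] - 1L) * nq + qs[t]]])
      m <- unique(m)
      if (!ldalign:::is_partial_bijection(m[, 1], m[, 2])) next
      # condition 5 on both descriptors (unaligned optional disregarded)
      al_a <- oracle_perceived(sa, lapply(ea[c(1L, sel + 1L)], `[[`, "span"))
      al_b <- oracle_perceived(sb, lapply(eb[c(1L, qs + 1L)], `[[`, "span"))
      den_a <- oracle_perceived(sa, lapply(
        ea[union(c(1L, sel + 1L), which(cert_a))], `[[`, "span"))
      den_b <- oracle_perceived(sb, lapply(
        eb[union(c(1L, qs + 1L), which(cert_b))], `[[`, "span"))
      if (al_a < ceiling(den_a / 2) || al_b < ceiling(den_b / 2)) next
      if (superpose_rmsd(sa$ca[m[, 1], , drop = FALSE],
                         sb$ca[m[, 2], , drop = FALSE]) > 2.5) next
      ord <- order(m[, 1])
      valid_keys <- c(valid_keys, paste(m[ord, 1], m[ord, 2],
                                        collapse = ";"))
      valid_sets[[length(valid_sets) + 1L]] <-
        paste(m[ord, 1], m[ord, 2])
    }
  }
  if (length(valid_keys) == 0) return(character(0))
  dup <- duplicated(valid_keys)
  valid_keys <- valid_keys[!dup]
  valid_sets <- valid_sets[!dup]
  # keep inclusion-maximal pair sets
  keep <- rep(TRUE, length(valid_sets))
  for (u in seq_along(valid_sets)) {
    for (v in seq_along(valid_sets)) {
      if (u != v &&
          length(valid_sets[[u]]) < length(valid_sets[[v]]) &&
          all(valid_sets[[u]] %in% valid_sets[[v]])) {
        keep[u] <- FALSE
        break
      }
    }
  }
  sort(valid_keys[keep])
}

align_keys <- function(alns) {
  sort(vapply(alns, function(a) paste(a$ia, a$ib, collapse = ";"),
              character(1)))
}

# random small-descriptor pair (at most `max_el` non-central elements each)
# drawn from a random-walk structure and a perturbed twin
random_descriptor_pair <- function(seed, max_el = 3L) {
  fa <- fixture_structure("random-walk", n = 26, seed = seed)
  fb <- fixture_structure("random-walk", n = 26, seed = seed,
                          transform = list(type = "noise", sigma = 0.45,
                                           seed = seed + 1L))
  sa <- fa$structure; sb <- fb$structure
  ca <- find_contacts(sa); cb <- find_contacts(sb)
  deg_a <- tabulate(c(ca$i, ca$j), sa$n)
  deg_b <- tabulate(c(cb$i, cb$j), sb$n)
  ia <- which(deg_a <= max_el)
  ib <- which(deg_b <= max_el)
  set.seed(seed)
  i <- ia[sample.int(length(ia), 1)]
  j <- ib[sample.int(length(ib), 1)]
  list(da = build_descriptor(sa, i, ca), db = build_descriptor(sb, j, cb),
       sa = sa, sb = sb)
}

# independent validity check of a full structure alignment
validate_alignment <- function(aln, label = "alignment") {
  p <- aln$pairs
  expect_true(ldalign:::is_partial_bijection(p$ia, p$ib),
              info = paste(label, "must be a partial bijection"))
  keys <- p$ia * 65536 + p$ib
  memkeys <- unlist(lapply(aln$members, function(m) m$ia * 65536 + m$ib))
  expect_true(all(keys %in% memkeys),
              info = paste(label, ": every pair must come from a member"))
  for (reg in aln$regions) {
    s3 <- vapply(aln$members[reg$members],
                 function(m) m$nseg_a >= 3 && m$nseg_b >= 3, logical(1))
    expect_true(any(s3),
                info = paste(label, ": region lacks a three-segment anchor"))
  }
}
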