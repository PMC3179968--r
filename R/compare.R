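#' Test whether two elements are alignable in the context of their centrals
#'
#' Elements are aligned exactly, center to center: position `center + k` of
#' one maps to position `center + k` of the other, over the overlap of their
#' (possibly clipped) spans; at least 3 common positions are required. The
#' pair is acceptable when (a) the element-vs-element C-alpha RMSD is at
#' most 1.5 Angstrom and (b) the joint RMSD of the two elements together
#' with the residue-by-residue mapped central elements is at most 2.5
#' Angstrom, i.e. the elements sit in the same position relative to the
#' central element. The induced residue mapping must not contradict the
#' central mapping.
#'
#' @param struct_a,struct_b the two structures.
#' @param el_a,el_b element lists (`center`, `span`) from the descriptors.
#' @param cel_a,cel_b the central elements of the two descriptors.
#' @return list with `acceptable`, `rmsd_element`, `rmsd_joint`, and the
#'   element-only residue mapping `map` (two-column matrix, may be `NULL`
#'   when rejected early).
#' @export
match_element_pair <- function(struct_a, struct_b, el_a, el_b, cel_a, cel_b) {
  match_element_pair_fast(struct_a, struct_b, el_a, el_b,
                          element_exact_map(cel_a, cel_b))
}

# as match_element_pair but with the central map precomputed (hot path)
match_element_pair_fast <- function(struct_a, struct_b, el_a, el_b, cmap0) {
  bad <- list(acceptable = FALSE, rmsd_element = NA_real_,
              rmsd_joint = NA_real_, map = NULL)
  if (is.null(cmap0)) return(bad)
  emap <- element_exact_map(el_a, el_b)
  if (is.null(emap)) return(bad)
  ja <- c(cmap0[, 1], emap[, 1])
  jb <- c(cmap0[, 2], emap[, 2])
  key <- ja * 65536 + jb
  dup <- duplicated(key)
  if (anyDuplicated(ja[!dup]) || anyDuplicated(jb[!dup])) return(bad)
  r_el <- .cpp_kabsch_rmsd(struct_a$ca[emap[, 1], , drop = FALSE],
                           struct_b$ca[emap[, 2], , drop = FALSE])
  if (r_el > 1.5) {
    bad$rmsd_element <- r_el
    return(bad)
  }
  r_joint <- .cpp_kabsch_rmsd(struct_a$ca[ja[!dup], , drop = FALSE],
                              struct_b$ca[jb[!dup], , drop = FALSE])
  list(acceptable = r_joint <= 2.5, rmsd_element = r_el,
       rmsd_joint = r_joint, map = emap)
}

# exact center-to-center mapping of two (possibly clipped) element spans;
# NULL when fewer than 3 positions overlap
element_exact_map <- function(el_a, el_b, min_overlap = 3L) {
  pos_a <- el_a$span - el_a$center
  pos_b <- el_b$span - el_b$center
  common <- intersect(pos_a, pos_b)
  if (length(common) < min_overlap) return(NULL)
  common <- sort(common)
  cbind(el_a$center + common, el_b$center + common)
}

is_partial_bijection <- function(ia, ib) {
  key <- ia * 65536 + ib
  dup <- duplicated(key)
  ia <- ia[!dup]; ib <- ib[!dup]
  !anyDuplicated(ia) && !anyDuplicated(ib)
}

# do two residue mappings (two-column matrices) agree wherever they overlap?
maps_consistent <- function(m1, m2) {
  both <- rbind(m1, m2)
  is_partial_bijection(both[, 1], both[, 2])
}

#' All valid structural alignments between two descriptors
#'
#' Searches, sequence-order-independently, for every maximal alignment of
#' the two descriptors satisfying the six validity conditions: exact
#' alignment of the central residues and their elements; preservation of
#' central contacts (elements map to elements, one to one); element RMSD at
#' most 1.5 Angstrom; element-plus-central RMSD at most 2.5 Angstrom; at
#' least half of each descriptor's perceived segments aligned (unaligned
#' contacts that are optional are disregarded when counting); and a total
#' C-alpha RMSD of all aligned residues, in one joint superposition, of at
#' most 2.5 Angstrom.
#'
#' The search enumerates element pairs passing the local conditions,
#' assembles maximal mutually consistent sets of them, and reduces any
#' assembly whose total RMSD exceeds 2.5 Angstrom by removing element
#' pairs until it fits or the segment-count condition fails. Small
#' assemblies (at most `exact_max` element pairs) are reduced exactly over
#' all subsets; larger ones greedily, dropping the pair whose removal most
#' decreases the joint RMSD.
#'
#' @param desc_a,desc_b descriptors from [build_descriptor()].
#' @param struct_a,struct_b their parent structures.
#' @param exact_max assembly size up to which subset reduction is exact.
#' @return list of `ldal_desc_alignment` objects, ordered by decreasing
#'   number of aligned residues then increasing RMSD; empty when no valid
#'   alignment exists. Each has fields `central_a`, `central_b`, `ia`,
#'   `ib` (parallel index vectors of the aligned residue pairs), `rmsd`,
#'   `nseg_a`, `nseg_b` (perceived counts of the aligned portions) and
#'   `el_a`, `el_b` (aligned element centers).
#' @export
compare_descriptors <- function(desc_a, desc_b, struct_a, struct_b,
                                exact_max = 8L) {
  cel_a <- desc_a$elements[[1]]
  cel_b <- desc_b$elements[[1]]
  cmap <- element_exact_map(cel_a, cel_b)
  if (is.null(cmap)) return(list())

  els_a <- desc_a$elements[-1]
  els_b <- desc_b$elements[-1]
  cand <- list()
  for (p in seq_along(els_a)) {
    for (q in seq_along(els_b)) {
      m <- match_element_pair_fast(struct_a, struct_b, els_a[[p]],
                                   els_b[[q]], cmap)
      if (m$acceptable)
        cand[[length(cand) + 1L]] <-
          list(p = p, q = q, map = m$map, r_joint = m$rmsd_joint)
    }
  }

  assemblies <- enumerate_assemblies(cand)
  out <- list()
  seen <- character(0)
  for (asm in assemblies) {
    for (res in reduce_assembly(asm, cand, cmap, desc_a, desc_b,
                                struct_a, struct_b, exact_max)) {
      key <- paste(res$ia, res$ib, collapse = ";")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- res
      }
    }
  }
  drop_dominated(out)
}

# maximal mutually consistent sets of candidate element pairs (indices into
# `cand`); consistency = one-to-one on elements and agreeing residue maps
enumerate_assemblies <- function(cand) {
  k <- length(cand)
  if (k == 0) return(list(integer(0)))
  if (k == 1) return(list(1L))
  compat <- matrix(FALSE, k, k)
  for (u in seq_len(k - 1)) {
    for (v in (u + 1):k) {
      cu <- cand[[u]]; cv <- cand[[v]]
      if (cu$p != cv$p && cu$q != cv$q &&
          maps_consistent(cu$map, cv$map)) {
        compat[u, v] <- compat[v, u] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  cl <- igraph::max_cliques(g)
  lapply(cl, function(x) sort(as.integer(x)))
}

# enforce conditions 5 and 6 on an assembly; returns a list of alignment
# objects (possibly several maximal valid subsets, possibly none)
reduce_assembly <- function(asm, cand, cmap, desc_a, desc_b,
                            struct_a, struct_b, exact_max) {
  build <- function(sel) {
    maps <- lapply(cand[sel], `[[`, "map")
    m <- unique(do.call(rbind, c(list(cmap), maps)))
    r <- .cpp_kabsch_rmsd(struct_a$ca[m[, 1], , drop = FALSE],
                          struct_b$ca[m[, 2], , drop = FALSE])
    list(sel = sel, map = m, rmsd = r)
  }
  valid5 <- function(sel) {
    segment_condition(desc_a, desc_b, cand, sel)
  }
  finalize <- function(b) {
    segs <- aligned_segment_counts(desc_a, desc_b, cand, b$sel)
    ord <- order(b$map[, 1])
    structure(
      list(central_a = desc_a$central, central_b = desc_b$central,
           ia = b$map[ord, 1], ib = b$map[ord, 2], rmsd = b$rmsd,
           nseg_a = segs$a, nseg_b = segs$b,
           el_a = c(desc_a$central,
                    vapply(cand[b$sel], function(x)
                      desc_a$elements[-1][[x$p]]$center, integer(1))),
           el_b = c(desc_b$central,
                    vapply(cand[b$sel], function(x)
                      desc_b$elements[-1][[x$q]]$center, integer(1)))),
      class = "ldal_desc_alignment")
  }

  full <- build(asm)
  if (full$rmsd <= 2.5) {
    if (valid5(asm)) return(list(finalize(full)))
    return(list())
  }
  if (length(asm) <= exact_max) {
    # exact: all maximal valid subsets of this assembly
    found <- list()
    kept_sets <- list()
    for (size in rev(seq_len(length(asm)))) {
      combs <- utils::combn(asm, size, simplify = FALSE)
      for (sel in combs) {
        if (any(vapply(kept_sets, function(s) all(sel %in% s), logical(1))))
          next
        if (!valid5(sel)) next
        b <- build(sel)
        if (b$rmsd <= 2.5) {
          kept_sets[[length(kept_sets) + 1L]] <- sel
          found[[length(found) + 1L]] <- finalize(b)
        }
      }
      if (size == 1 && length(found) == 0 && valid5(integer(0))) {
        b <- build(integer(0))
        if (b$rmsd <= 2.5) found[[length(found) + 1L]] <- finalize(b)
      }
    }
    return(found)
  }
  # greedy: drop the element pair whose removal most decreases the RMSD
  sel <- asm
  repeat {
    if (!valid5(sel)) return(list())
    b <- build(sel)
    if (b$rmsd <= 2.5) {
      return(list(finalize(b)))
    }
    if (length(sel) == 0) return(list())
    trial <- vapply(seq_along(sel), function(k) build(sel[-k])$rmsd,
                    numeric(1))
    sel <- sel[-which.min(trial)]
  }
}

# condition 5: in each descriptor, the aligned portion must cover at least
# half of the perceived segments; unaligned optional contacts are
# disregarded before counting
segment_condition <- function(desc_a, desc_b, cand, sel) {
  counts <- aligned_segment_counts(desc_a, desc_b, cand, sel)
  denom <- denominator_segment_counts(desc_a, desc_b, cand, sel)
  counts$a >= ceiling(denom$a / 2) && counts$b >= ceiling(denom$b / 2)
}

aligned_segment_counts <- function(desc_a, desc_b, cand, sel) {
  pa <- c(1L, vapply(cand[sel], function(x) x$p + 1L, integer(1)))
  qb <- c(1L, vapply(cand[sel], function(x) x$q + 1L, integer(1)))
  list(a = perceived_count_of(desc_a, pa),
       b = perceived_count_of(desc_b, qb))
}

denominator_segment_counts <- function(desc_a, desc_b, cand, sel) {
  pa <- c(1L, vapply(cand[sel], function(x) x$p + 1L, integer(1)))
  qb <- c(1L, vapply(cand[sel], function(x) x$q + 1L, integer(1)))
  keep_a <- union(pa, which(c(TRUE, desc_a$partner_certain)))
  keep_b <- union(qb, which(c(TRUE, desc_b$partner_certain)))
  list(a = perceived_count_of(desc_a, keep_a),
       b = perceived_count_of(desc_b, keep_b))
}

# cached perceived-segment count of the sub-descriptor induced by a set of
# element indices (1 = central element)
perceived_count_of <- function(desc, el_idx) {
  el_idx <- sort(unique(el_idx))
  cache <- attr(desc, "segcache")
  key <- paste(el_idx, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  st <- attr(desc, "parent_struct")
  if (is.null(st))
    stop("descriptor lacks parent structure attribute")
  val <- sum(merge_spans(st, lapply(desc$elements[el_idx], `[[`, "span"))$N)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# drop alignments whose pair set is a strict subset of another's
drop_dominated <- function(aligns) {
  if (length(aligns) <= 1) return(order_alignments(aligns))
  keys <- lapply(aligns, function(a) paste(a$ia, a$ib))
  n <- length(aligns)
  keep <- rep(TRUE, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u != v && keep[u] &&
          length(keys[[u]]) < length(keys[[v]]) &&
          all(keys[[u]] %in% keys[[v]])) {
        keep[u] <- FALSE
        break
      }
    }
  }
  order_alignments(aligns[keep])
}

order_alignments <- function(aligns) {
  if (length(aligns) == 0) return(aligns)
  sizes <- vapply(aligns, function(a) length(a$ia), integer(1))
  rmsds <- vapply(aligns, function(a) a$rmsd, numeric(1))
  lex <- vapply(aligns, function(a) paste(a$ia, a$ib, collapse = ";"),
                character(1))
  aligns[order(-sizes, rmsds, lex)]
}

#' @export
print.ldal_desc_alignment <- function(x, ...) {
  cat("ldal_desc_alignment: centrals ", x$central_a, " -> ", x$central_b,
      ", ", length(x$ia), " residue pairs, rmsd ",
      sprintf("%.3f", x$rmsd), " A, segments ", x$nseg_a, "/", x$nseg_b,
      "\n", sep = "")
  invisible(x)
}
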