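#' Elastic tension of a structural alignment
#'
#' The average strain exerted on the two structures when superimposed as
#' elastic objects. Every pair of aligned residues that is in contact in at
#' least one of the two structures is enumerated; for each such contact the
#' C-alpha RMSD of the two five-residue backbone elements around the
#' contacting residues, jointly superposed against their counterparts in
#' the other structure, is computed. These RMSDs are averaged per residue
#' over its contacts, and then over all aligned residues; aligned residues
#' without any such contact contribute zero.
#'
#' @param pairs data frame (or list) with `ia`, `ib`: aligned residue
#'   indices in the two structures.
#' @param struct_a,struct_b the structures.
#' @param contacts_a,contacts_b contact tables from [find_contacts()]
#'   (computed if omitted).
#' @return tension in Angstrom (0 for a perfectly consistent alignment).
#' @export
tension <- function(pairs, struct_a, struct_b,
                    contacts_a = NULL, contacts_b = NULL) {
  ia <- pairs$ia; ib <- pairs$ib
  if (length(ia) == 0) stop("tension of an empty alignment is undefined")
  if (is.null(contacts_a)) contacts_a <- find_contacts(struct_a)
  if (is.null(contacts_b)) contacts_b <- find_contacts(struct_b)
  fmap <- rep(NA_integer_, struct_a$n)   # A index -> B index
  fmap[ia] <- ib
  rmap <- rep(NA_integer_, struct_b$n)
  rmap[ib] <- ia

  # contacts (as A-side index pairs) present in either structure with both
  # residues aligned
  ka <- contacts_a[!is.na(fmap[contacts_a$i]) & !is.na(fmap[contacts_a$j]),
                   c("i", "j"), drop = FALSE]
  kb <- contacts_b[!is.na(rmap[contacts_b$i]) & !is.na(rmap[contacts_b$j]),
                   c("i", "j"), drop = FALSE]
  if (nrow(kb)) {
    kb <- data.frame(i = rmap[kb$i], j = rmap[kb$j])
    sw <- kb$i > kb$j
    tmp <- kb$i[sw]; kb$i[sw] <- kb$j[sw]; kb$j[sw] <- tmp
  }
  con <- unique(rbind(ka, kb))
  if (nrow(con) == 0) return(0)

  seg_a <- chain_segment_ids(struct_a)
  seg_b <- chain_segment_ids(struct_b)
  elem_positions <- function(i, ip) {
    ks <- (-2):2
    ok <- vapply(ks, function(k) {
      ai <- i + k; bi <- ip + k
      ai >= 1 && ai <= struct_a$n && seg_a[ai] == seg_a[i] &&
        bi >= 1 && bi <= struct_b$n && seg_b[bi] == seg_b[ip]
    }, logical(1))
    ks[ok]
  }
  crmsd <- numeric(nrow(con))
  for (r in seq_len(nrow(con))) {
    i <- con$i[r]; j <- con$j[r]
    ip <- fmap[i]; jp <- fmap[j]
    k1 <- elem_positions(i, ip)
    k2 <- elem_positions(j, jp)
    pa <- struct_a$ca[c(i + k1, j + k2), , drop = FALSE]
    pb <- struct_b$ca[c(ip + k1, jp + k2), , drop = FALSE]
    crmsd[r] <- .cpp_kabsch_rmsd(pa, pb)
  }
  per_res <- vapply(ia, function(r) {
    inv <- con$i == r | con$j == r
    if (!any(inv)) 0 else mean(crmsd[inv])
  }, numeric(1))
  mean(per_res)
}

#' Alignment score
#'
#' The number of aligned residues minus the squared tension. With a finite
#' sequence-offset limit `k`, pairs with offset above `k` are removed
#' before counting; with a finite swap limit `M` the largest sub-alignment
#' with at most `M` swaps is taken first.
#'
#' @param aln an `ldal_alignment` (or any list with `n_aligned` and
#'   `tension`).
#' @return numeric score.
#' @export
alignment_score <- function(aln) {
  aln$n_aligned - aln$tension^2
}

#' Sequence offsets of aligned residue pairs
#'
#' The offset of a pair measures its departure from a direct 1:1
#' correspondence between the two chains. With `"ungapped-closest"` the
#' correspondence is the closest of the ungapped alignments of the shorter
#' chain inside the longer (offset = distance of `ib - ia` from the
#' interval `[0, nb - na]`, for `na <= nb`). With `"gaps-in-shorter"` gaps
#' may be placed anywhere in the shorter chain, and the offset is the
#' amount by which a pair violates the best such monotone correspondence
#' (`max(0, ia - ib, (na - ia) - (nb - ib))` for `na <= nb`).
#'
#' @param ia,ib aligned indices.
#' @param na,nb chain lengths.
#' @param offset_mode offset convention.
#' @return integer vector of offsets.
#' @export
pair_offsets <- function(ia, ib, na, nb,
                         offset_mode = c("ungapped-closest",
                                         "gaps-in-shorter")) {
  offset_mode <- match.arg(offset_mode)
  if (na > nb) return(pair_offsets(ib, ia, nb, na, offset_mode))
  d <- ib - ia
  if (offset_mode == "ungapped-closest") {
    pmax(0L, d - (nb - na), -d)
  } else {
    pmax(0L, ia - ib, (na - ia) - (nb - ib))
  }
}

#' Number of sequence swaps in an alignment
#'
#' The aligned pairs are decomposed into maximal blocks that are contiguous
#' and co-linear in both structures; the swap count is the number of
#' descents in the second structure's block order when blocks are sorted by
#' the first structure. A fully co-linear alignment has zero swaps; a
#' circular permutation of two blocks has one.
#'
#' @param pairs data frame/list with `ia`, `ib`.
#' @return non-negative integer.
#' @export
count_swaps <- function(pairs) {
  b <- alignment_blocks(pairs)
  if (nrow(b) <= 1) return(0L)
  sum(diff(b$ib_start) < 0)
}

# maximal runs contiguous in both structures, sorted by position in A
alignment_blocks <- function(pairs) {
  ia <- pairs$ia; ib <- pairs$ib
  if (length(ia) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      ia_start = integer(0), ib_start = integer(0),
                      size = integer(0)))
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  newblk <- c(TRUE, diff(ia) != 1L | diff(ib) != 1L)
  blk <- cumsum(newblk)
  start <- which(newblk)
  end <- c(start[-1] - 1L, length(ia))
  data.frame(start = start, end = end,
             ia_start = ia[start], ib_start = ib[start],
             size = end - start + 1L)
}

#' Largest sub-alignment with a bounded number of swaps
#'
#' Restricts an alignment to the maximum-residue subset of its co-linear
#' blocks whose induced order has at most `M` descents. Solved exactly by
#' dynamic programming over block sequences of up to `dp_max` blocks;
#' beyond that the smallest block is dropped greedily until the swap limit
#' holds.
#'
#' @param pairs data frame/list with `ia`, `ib`.
#' @param M maximal number of swaps (finite, non-negative).
#' @param dp_max block count up to which the dynamic program is used.
#' @return data frame with the retained `ia`, `ib` pairs.
#' @export
largest_subalignment <- function(pairs, M, dp_max = 64L) {
  stopifnot(is.finite(M), M >= 0)
  b <- alignment_blocks(pairs)
  ia <- pairs$ia[order(pairs$ia)]
  ib <- pairs$ib[order(pairs$ia)]
  nb <- nrow(b)
  if (nb == 0 || count_swaps(pairs) <= M)
    return(data.frame(ia = ia, ib = ib))
  if (nb <= dp_max) {
    M <- min(M, nb - 1L)
    # f[i, m+1]: best residue total of a subsequence ending at block i with
    # m descents; predecessors j < i, descent when ib_start[j] > ib_start[i]
    f <- matrix(-Inf, nb, M + 1L)
    pred <- array(0L, c(nb, M + 1L, 2L))
    f[, 1L] <- b$size
    for (i in seq_len(nb)) {
      for (m in 0:M) {
        for (j in seq_len(i - 1L)) {
          desc <- as.integer(b$ib_start[j] > b$ib_start[i])
          if (m - desc < 0) next
          cand <- f[j, m - desc + 1L] + b$size[i]
          if (cand > f[i, m + 1L]) {
            f[i, m + 1L] <- cand
            pred[i, m + 1L, ] <- c(j, m - desc)
          }
        }
      }
    }
    bestv <- max(f)
    w <- which(f == bestv, arr.ind = TRUE)[1L, ]
    sel <- integer(0)
    i <- w[1L]; m <- w[2L] - 1L
    while (i > 0L) {
      sel <- c(i, sel)
      p <- pred[i, m + 1L, ]
      i <- p[1L]; m <- p[2L]
    }
  } else {
    sel <- seq_len(nb)
    repeat {
      ibs <- b$ib_start[sel]
      if (sum(diff(ibs) < 0) <= M || length(sel) <= 1L) break
      sel <- sel[-which.min(b$size[sel])]
    }
  }
  keep <- unlist(lapply(sel, function(i) b$start[i]:b$end[i]))
  data.frame(ia = ia[keep], ib = ib[keep])
}

#' Decompose an alignment into rigid regions
#'
#' Regions are the connected components of the residue-overlap graph over
#' the alignment's descriptor-pair members: two members belong to the same
#' region when they share an aligned residue in either structure. Each
#' region is independently superposable and is reported with its own
#' optimal C-alpha superposition RMSD.
#'
#' @param members list of `ldal_desc_alignment` constituting the alignment.
#' @param pairs the final aligned pairs (`ia`, `ib`); member pairs outside
#'   it (removed by the offset/swap filters) are ignored.
#' @param struct_a,struct_b the structures.
#' @return list of regions, each with `members` (indices), `ia`, `ib`,
#'   `rmsd`, `rotation`, `translation`.
#' @export
rigid_regions <- function(members, pairs, struct_a, struct_b) {
  keys <- pairs$ia * 65536 + pairs$ib
  mp <- lapply(members, function(m) {
    keep <- (m$ia * 65536 + m$ib) %in% keys
    list(ia = m$ia[keep], ib = m$ib[keep])
  })
  nonempty <- which(vapply(mp, function(m) length(m$ia) > 0, logical(1)))
  if (length(nonempty) == 0) return(list())
  mp <- mp[nonempty]
  nm <- length(mp)
  comp <- seq_len(nm)
  find <- function(x) {
    while (comp[x] != x) x <- comp[x]
    x
  }
  if (nm > 1) {
    for (u in seq_len(nm - 1)) {
      for (v in (u + 1):nm) {
        if (any(mp[[u]]$ia %in% mp[[v]]$ia) ||
            any(mp[[u]]$ib %in% mp[[v]]$ib)) {
          ru <- find(u); rv <- find(v)
          if (ru != rv) comp[rv] <- ru
        }
      }
    }
  }
  roots <- vapply(seq_len(nm), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    mem <- which(roots == r)
    ia <- unlist(lapply(mp[mem], `[[`, "ia"))
    ib <- unlist(lapply(mp[mem], `[[`, "ib"))
    keep <- !duplicated(ia * 65536 + ib)
    ia <- ia[keep]; ib <- ib[keep]
    ord <- order(ia)
    ia <- ia[ord]; ib <- ib[ord]
    fit <- superpose_fit(struct_a$ca[ia, , drop = FALSE],
                         struct_b$ca[ib, , drop = FALSE])
    out[[length(out) + 1L]] <-
      list(members = nonempty[mem], ia = ia, ib = ib,
           rmsd = fit$rmsd, rotation = fit$rotation,
           translation = fit$translation)
  }
  out[order(-vapply(out, function(x) length(x$ia), integer(1)))]
}

#' Accuracy of a computed alignment against a curated reference
#'
#' The ratio of the number of residue pairs aligned identically in both
#' the computed and the reference alignment to the size of the reference.
#' Pairs are keyed by chain and author residue label so that alignments
#' from different tools can be compared.
#'
#' @param computed,reference data frames with columns `chain_a`, `seq_a`,
#'   `chain_b`, `seq_b`.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(computed, reference) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("reference alignment is empty")
  keyify <- function(d) paste(d$chain_a, d$seq_a, d$chain_b, d$seq_b,
                              sep = "|")
  rk <- unique(keyify(reference))
  ck <- unique(keyify(computed))
  sum(rk %in% ck) / length(rk)
}

#' Express aligned index pairs as chain/label pairs
#'
#' @param struct_a,struct_b the structures.
#' @param pairs data frame/list with `ia`, `ib` (1-based internal indices).
#' @return data frame with `chain_a`, `seq_a`, `chain_b`, `seq_b`.
#' @export
pairs_to_labels <- function(struct_a, struct_b, pairs) {
  data.frame(chain_a = struct_a$chain[pairs$ia],
             seq_a = struct_a$seq_label[pairs$ia],
             chain_b = struct_b$chain[pairs$ib],
             seq_b = struct_b$seq_label[pairs$ib],
             stringsAsFactors = FALSE)
}

# assemble the full alignment object from clique members
finalize_alignment <- function(struct_a, struct_b, members,
                               contacts_a, contacts_b,
                               k = Inf, M = Inf,
                               offset_mode = "ungapped-closest") {
  up <- unique_pairs(members)
  ia <- up$ia; ib <- up$ib
  if (is.finite(k)) {
    off <- pair_offsets(ia, ib, struct_a$n, struct_b$n, offset_mode)
    keep <- off <= k
    ia <- ia[keep]; ib <- ib[keep]
  }
  if (length(ia) == 0) return(NULL)
  prs <- data.frame(ia = ia, ib = ib)
  if (is.finite(M)) prs <- largest_subalignment(prs, M)
  if (nrow(prs) == 0) return(NULL)
  ord <- order(prs$ia)
  prs <- prs[ord, , drop = FALSE]
  tens <- tension(prs, struct_a, struct_b, contacts_a, contacts_b)
  regions <- rigid_regions(members, prs, struct_a, struct_b)
  fit_all <- superpose_fit(struct_a$ca[prs$ia, , drop = FALSE],
                           struct_b$ca[prs$ib, , drop = FALSE])
  aln <- structure(
    list(structure_ids = c(struct_a$id, struct_b$id),
         members = members,
         pairs = prs,
         n_aligned = nrow(prs),
         tension = tens,
         swaps = count_swaps(prs),
         regions = regions,
         rigid_rmsd = fit_all$rmsd),
    class = "ldal_alignment")
  aln$score <- alignment_score(aln)
  aln
}

#' @export
print.ldal_alignment <- function(x, ...) {
  cat("ldal_alignment ", x$structure_ids[1], " vs ", x$structure_ids[2],
      "\n", sep = "")
  cat(sprintf("  %d aligned residues, score %.2f, tension %.3f A\n",
              x$n_aligned, x$score, x$tension))
  cat(sprintf("  swaps %d, rigid regions %d (whole-alignment rigid RMSD %.2f A)\n",
              x$swaps, length(x$regions), x$rigid_rmsd))
  invisible(x)
}
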