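#' Residue-residue contacts with certain/optional status
#'
#' Two residues are in contact when their C-alpha distance `d_alpha` is at
#' most 6.5 Angstrom, or their side-chain-center distance `d_c` is at most
#' 8 Angstrom while `d_alpha - d_c >= 0.75` (side chains pointing towards
#' each other). A contact is *certain* when it also holds under tightened
#' thresholds (5.5 and 7 Angstrom respectively), and *optional* otherwise --
#' a rough-set device that keeps descriptor comparison robust for contacts
#' close to the cutoffs.
#'
#' Residues closer than `min_seq_sep` along the same connected chain stretch
#' are not reported: they lie inside the central element anyway and would
#' only duplicate backbone neighbours. Pairs in different chains (or across
#' a chain break) are always eligible.
#'
#' @param struct an `ldal_structure`.
#' @param d_alpha_max,d_c_max regular thresholds (Angstrom).
#' @param d_alpha_tight,d_c_tight tightened thresholds for certain status.
#' @param sep_min minimal `d_alpha - d_c` for the side-chain criterion.
#' @param min_seq_sep minimal sequence separation within a chain stretch.
#' @return data frame with columns `i`, `j` (1-based residue indices,
#'   `i < j`), `d_alpha`, `d_c`, `certain` (logical). The relation is
#'   symmetric; each unordered pair appears once.
#' @export
find_contacts <- function(struct,
                          d_alpha_max = 6.5, d_c_max = 8.0,
                          d_alpha_tight = 5.5, d_c_tight = 7.0,
                          sep_min = 0.75, min_seq_sep = 3L) {
  stopifnot(inherits(struct, "ldal_structure"), struct$n > 0)
  n <- struct$n
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0),
                      d_alpha = numeric(0), d_c = numeric(0),
                      certain = logical(0)))
  da <- as.matrix(stats::dist(struct$ca))
  dc <- as.matrix(stats::dist(struct$sc))
  seg <- chain_segment_ids(struct)
  idx <- which(upper.tri(da), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  allowed <- (j - i >= min_seq_sep) | (seg[i] != seg[j])
  dai <- da[idx]; dci <- dc[idx]
  is_contact <- allowed &
    (dai <= d_alpha_max | (dci <= d_c_max & dai - dci >= sep_min))
  certain <- dai <= d_alpha_tight |
    (dci <= d_c_tight & dai - dci >= sep_min)
  keep <- which(is_contact)
  data.frame(i = i[keep], j = j[keep],
             d_alpha = dai[keep], d_c = dci[keep],
             certain = certain[keep])
}

# indices of the <=5-residue element span around `center`, clipped at chain
# termini and chain breaks (never crosses into another connected stretch)
element_span <- function(struct, center, seg = NULL) {
  if (is.null(seg)) seg <- chain_segment_ids(struct)
  lo <- max(1L, center - 2L)
  hi <- min(struct$n, center + 2L)
  span <- lo:hi
  span[seg[span] == seg[center]]
}

#' Build the local descriptor around a residue
#'
#' The descriptor of a residue comprises the residue's own five-residue
#' element (itself plus two sequence neighbours on each side) and one such
#' element around every residue in contact with it. Overlapping or
#' index-adjacent element spans are concatenated into segments; each segment
#' carries its smoothed spatial length `L` and its perceived ("logical")
#' segment count `N = ceiling(L / 18)`, so that long hairpin-like segments
#' count as two. Elements at chain termini or breaks are clipped (3--5
#' residues) rather than dropped.
#'
#' @param struct an `ldal_structure`.
#' @param central 1-based index of the central residue.
#' @param contacts contact table from [find_contacts()]; computed on the
#'   fly when omitted.
#' @return object of class `ldal_descriptor`: list with `structure_id`,
#'   `central`, `partners` (contact residue indices), `partner_certain`,
#'   `elements` (list of `center`/`span`/`certain`), `segments` (data frame
#'   `first`, `last`, `L`, `N`) and `n_segments` (sum of perceived counts).
#' @export
build_descriptor <- function(struct, central, contacts = NULL) {
  stopifnot(inherits(struct, "ldal_structure"),
            central >= 1, central <= struct$n)
  central <- as.integer(central)
  if (is.null(contacts)) contacts <- find_contacts(struct)
  seg <- chain_segment_ids(struct)
  sel <- contacts$i == central | contacts$j == central
  partners <- ifelse(contacts$i[sel] == central,
                     contacts$j[sel], contacts$i[sel])
  certain <- contacts$certain[sel]
  ord <- order(partners)
  partners <- as.integer(partners[ord]); certain <- certain[ord]

  centers <- c(central, partners)
  status <- c(TRUE, certain)  # central element is always certain
  elements <- lapply(seq_along(centers), function(k)
    list(center = centers[k], span = element_span(struct, centers[k], seg),
         certain = status[k]))

  segs <- merge_spans(struct, lapply(elements, `[[`, "span"), seg)
  d <- structure(
    list(structure_id = struct$id, central = as.integer(central),
         partners = partners, partner_certain = certain,
         elements = elements, segments = segs,
         n_segments = sum(segs$N)),
    class = "ldal_descriptor")
  # reference to the parent structure (shared, not copied) plus a
  # memoisation cache for sub-descriptor segment counts used heavily
  # during descriptor comparison
  attr(d, "parent_struct") <- struct
  attr(d, "segcache") <- new.env(parent = emptyenv())
  d
}

# merge element spans into maximal runs of consecutive indices, never
# crossing chain breaks; returns the segment table with L and N
merge_spans <- function(struct, spans, seg = NULL) {
  if (is.null(seg)) seg <- chain_segment_ids(struct)
  idx <- sort(unique(unlist(spans)))
  if (length(idx) == 0)
    return(data.frame(first = integer(0), last = integer(0),
                      L = numeric(0), N = integer(0)))
  newrun <- c(TRUE, diff(idx) > 1L | seg[idx[-1]] != seg[idx[-length(idx)]])
  run <- cumsum(newrun)
  first <- tapply(idx, run, min)
  last <- tapply(idx, run, max)
  L <- mapply(function(f, l) segment_spatial_length(struct, f, l),
              first, last)
  data.frame(first = as.integer(first), last = as.integer(last),
             L = as.numeric(L), N = perceived_segments(as.numeric(L)),
             row.names = NULL)
}

#' Smoothed spatial length of a backbone segment
#'
#' The length of the segment running from residue `first` to `last` is the
#' sum of distances between smoothed C-alpha positions, where the smoothed
#' position of residue `i` is the mean of the C-alpha coordinates of
#' residues `i-1`, `i` and `i+1`. When either neighbour does not exist
#' (chain terminus or chain break) the raw C-alpha is used. Smoothing
#' neighbours may lie outside the segment as long as they are backbone
#' connected.
#'
#' @param struct an `ldal_structure`.
#' @param first,last 1-based inclusive residue indices, no chain break
#'   inside.
#' @return segment length in Angstrom (0 for a single residue).
#' @export
segment_spatial_length <- function(struct, first, last) {
  stopifnot(inherits(struct, "ldal_structure"))
  if (last < first || first < 1 || last > struct$n)
    stop("invalid segment range ", first, "..", last)
  seg <- chain_segment_ids(struct)
  if (length(unique(seg[first:last])) != 1)
    stop("segment ", first, "..", last, " crosses a chain break")
  if (first == last) return(0)
  sm <- t(vapply(first:last, function(i) {
    has_prev <- i > 1 && seg[i - 1] == seg[i]
    has_next <- i < struct$n && seg[i + 1] == seg[i]
    if (has_prev && has_next)
      (struct$ca[i - 1, ] + struct$ca[i, ] + struct$ca[i + 1, ]) / 3
    else struct$ca[i, ]
  }, numeric(3)))
  sum(sqrt(rowSums((sm[-1, , drop = FALSE] - sm[-nrow(sm), , drop = FALSE])^2)))
}

#' Perceived ("logical") segment count for a segment length
#'
#' A physical segment longer than 18 Angstrom is counted as several logical
#' segments connected by short loops: `max(1, ceiling(L / 18))`. This makes
#' hairpins count as two segments and is what qualifies descriptors as
#' three-segmented.
#'
#' @param L segment spatial length(s), Angstrom, non-negative.
#' @return positive integer vector.
#' @export
perceived_segments <- function(L) {
  stopifnot(all(L >= 0))
  pmax(1L, as.integer(ceiling(round(L / 18.0, 9))))
}

#' Build descriptors for every residue of a structure
#'
#' @param struct an `ldal_structure`.
#' @param contacts optional precomputed contact table.
#' @return list of `ldal_descriptor`, one per residue.
#' @export
build_descriptors <- function(struct, contacts = NULL) {
  if (is.null(contacts)) contacts <- find_contacts(struct)
  lapply(seq_len(struct$n), function(i)
    build_descriptor(struct, i, contacts))
}

#' @export
print.ldal_descriptor <- function(x, ...) {
  cat("ldal_descriptor around residue ", x$central, " of '",
      x$structure_id, "'\n", sep = "")
  cat("  contacts: ", length(x$partners), " (",
      sum(x$partner_certain), " certain)\n", sep = "")
  cat("  segments: ", nrow(x$segments), " physical, ",
      x$n_segments, " perceived\n", sep = "")
  if (nrow(x$segments)) {
    for (k in seq_len(nrow(x$segments)))
      cat(sprintf("    %d..%d  L=%.2f A  N=%d\n", x$segments$first[k],
                  x$segments$last[k], x$segments$L[k], x$segments$N[k]))
  }
  invisible(x)
}
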