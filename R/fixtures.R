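#' Generate a protein-like synthetic structure
#'
#' Builds idealised C-alpha traces (alpha helices, strand hairpins, helix
#' bundles, beta sandwiches, two-domain constructs, or random walks) with
#' realistic consecutive C-alpha spacing (3.8 Angstrom within 0.1), adds
#' N, C, O and C-beta backbone atoms by simple local geometry, writes
#' standard PDB ATOM records, and re-reads the file through the package's
#' parser so every fixture exercises the same input path as a real file.
#' Residues are alanine except every ninth, which is glycine, so both
#' side-chain-center rules are engaged.
#'
#' Available kinds: `"helix"` (single alpha helix), `"hairpin"` (two
#' antiparallel strands with a turn), `"helix-bundle"` (`n_helices` ideal
#' helices at `spacing` Angstrom axial separation, serpentine-connected so
#' inter-helix contacts yield multi-segment descriptors), `"sheet-sandwich"`
#' (two three-stranded antiparallel sheets face to face), `"two-domain"`
#' (two helix bundles joined by a linker, for hinge fixtures) and
#' `"random-walk"` (a self-avoiding 3.8-Angstrom step walk with no
#' persistent structure).
#'
#' @param kind fixture kind; see above.
#' @param n number of residues (used by `"helix"`, `"hairpin"`,
#'   `"random-walk"`; the assembled kinds derive their size from their
#'   layout parameters).
#' @param transform `NULL` or a list describing a transformation of the
#'   coordinates: `list(type = "rigid", seed =)`,
#'   `list(type = "circular_permutation", cut =)`,
#'   `list(type = "hinge", pivot =, angle =, axis =)` (angle in degrees),
#'   or `list(type = "noise", sigma =, seed =)`.
#' @param seed RNG seed for stochastic kinds (`"random-walk"`) and
#'   transforms.
#' @param n_helices,helix_len,spacing layout parameters of the bundle
#'   kinds.
#' @param id structure identifier.
#' @param file optional path to keep the generated PDB file at (a
#'   temporary file is used otherwise).
#' @return list with `structure` (`ldal_structure`), `map` (integer vector:
#'   `map[i]` is the residue of the *untransformed* trace whose coordinates
#'   residue `i` carries -- the ground-truth self correspondence), and
#'   `file` (the PDB written).
#' @export
fixture_structure <- function(kind = c("helix", "hairpin", "helix-bundle",
                                       "sheet-sandwich", "two-domain",
                                       "random-walk"),
                              n = 12L, transform = NULL, seed = 1L,
                              n_helices = 3L, helix_len = 12L,
                              spacing = 9.5, id = NULL, file = NULL) {
  kind <- match.arg(kind)
  ca <- switch(kind,
    "helix" = trace_helix(n),
    "hairpin" = trace_hairpin(n),
    "helix-bundle" = trace_bundle(n_helices, helix_len, spacing),
    "sheet-sandwich" = trace_sandwich(),
    "two-domain" = trace_two_domain(helix_len, spacing),
    "random-walk" = trace_walk(n, seed))
  nres <- nrow(ca)
  map <- seq_len(nres)
  if (!is.null(transform)) {
    tr <- apply_fixture_transform(ca, transform, seed)
    ca <- tr$ca
    map <- tr$map
  }
  if (is.null(id)) id <- paste0(kind, "_", nres)
  if (is.null(file)) file <- tempfile(fileext = ".pdb")
  write_fixture_pdb(ca, file, id)
  st <- read_structure(file, id = id)
  if (st$n != nres) stop("fixture round-trip lost residues")
  list(structure = st, map = map, file = file)
}

#' Generate a structure pair with known ground truth
#'
#' Returns a fixture structure, a transformed twin, and the exact
#' residue-level correspondence between them, for accuracy testing of the
#' whole pipeline (rigid recovery, circular permutations, hinge motions).
#'
#' @inheritParams fixture_structure
#' @param transform transformation applied to the twin (see
#'   [fixture_structure()]).
#' @param ... layout parameters passed through.
#' @return list with `a`, `b` (`ldal_structure`), `gt` (data frame `ia`,
#'   `ib`: residue `ia` of `a` corresponds to residue `ib` of `b`).
#' @export
fixture_pair <- function(kind = "helix-bundle", transform = list(type = "rigid"),
                         seed = 1L, ...) {
  fa <- fixture_structure(kind, seed = seed, ...)
  fb <- fixture_structure(kind, transform = transform, seed = seed, ...)
  # fb$map[i] = source residue of twin residue i; invert for a -> b
  gt <- data.frame(ia = fb$map, ib = seq_along(fb$map))
  gt <- gt[order(gt$ia), , drop = FALSE]
  rownames(gt) <- NULL
  list(a = fa$structure, b = fb$structure, gt = gt)
}

# ---- C-alpha trace generators -------------------------------------------

# ideal alpha helix: radius 2.3 A, rise 1.5 A per residue, 100 deg turn
trace_helix <- function(n, origin = c(0, 0, 0), axis_z = TRUE) {
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1],
        2.3 * sin(ang) + origin[2],
        1.5 * i + origin[3])
}

# antiparallel two-strand hairpin with a bulged turn
trace_hairpin <- function(n) {
  ns <- (n - 2L) %/% 2L
  s1 <- trace_strand(ns, x = 0, z0 = 0, dir = 1)
  s2 <- trace_strand(n - 2L - ns, x = 4.8,
                     z0 = s1[ns, 3], dir = -1)
  turn <- bridge_points(s1[ns, ], s2[1, ], 3L)
  rbind(s1, turn, s2)
}

# extended strand: 3.679 A rise with alternating 0.95 A pleat gives exact
# 3.8 A consecutive C-alpha steps
trace_strand <- function(n, x = 0, y = 0, z0 = 0, dir = 1) {
  i <- seq_len(n) - 1
  cbind(x + 0.95 * (i %% 2), y, z0 + dir * 3.679 * i)
}

# helix bundle: up-down-up helices at `spacing`, serpentine-connected
trace_bundle <- function(n_helices, helix_len, spacing,
                         origin = c(0, 0, 0)) {
  stopifnot(n_helices >= 2, helix_len >= 6)
  pieces <- list()
  # axial positions: zig-zag in the xy plane so all neighbours are close
  pos <- lapply(seq_len(n_helices) - 1, function(k)
    c(origin[1] + k * spacing * 0.87,
      origin[2] + (k %% 2) * spacing * 0.5, origin[3]))
  prev_end <- NULL
  for (h in seq_len(n_helices)) {
    hx <- trace_helix(helix_len, origin = pos[[h]])
    if (h %% 2 == 0) hx <- hx[rev(seq_len(helix_len)), , drop = FALSE]
    if (!is.null(prev_end)) {
      loop <- bridge_points(prev_end, hx[1, ], 3L)
      pieces[[length(pieces) + 1L]] <- loop
    }
    pieces[[length(pieces) + 1L]] <- hx
    prev_end <- hx[helix_len, ]
  }
  do.call(rbind, pieces)
}

# two three-stranded antiparallel sheets face to face
trace_sandwich <- function(strand_len = 6L, strand_sep = 4.8,
                           sheet_sep = 9.0) {
  pieces <- list()
  prev_end <- NULL
  layout <- list(c(0, 0), c(strand_sep, 0), c(2 * strand_sep, 0),
                 c(2 * strand_sep, sheet_sep), c(strand_sep, sheet_sep),
                 c(0, sheet_sep))
  ztop <- 3.679 * (strand_len - 1)
  for (s in seq_along(layout)) {
    dir <- if (s %% 2 == 1) 1 else -1
    st <- trace_strand(strand_len, x = layout[[s]][1], y = layout[[s]][2],
                       z0 = if (dir == 1) 0 else ztop, dir = dir)
    if (!is.null(prev_end)) {
      k <- max(2L, as.integer(ceiling(sqrt(sum((st[1, ] - prev_end)^2)) / 3.8)))
      pieces[[length(pieces) + 1L]] <- bridge_points(prev_end, st[1, ], k)
    }
    pieces[[length(pieces) + 1L]] <- st
    prev_end <- st[strand_len, ]
  }
  do.call(rbind, pieces)
}

# two helix bundles joined by a linker (hinge fixtures); the natural hinge
# pivot (the middle of the linker) is attached as an attribute
trace_two_domain <- function(helix_len = 10L, spacing = 9.5) {
  d1 <- trace_bundle(3L, helix_len, spacing)
  d2 <- trace_bundle(3L, helix_len, spacing,
                     origin = c(0, 34, 0))
  linker <- bridge_points(d1[nrow(d1), ], d2[1, ], 5L)
  out <- rbind(d1, linker, d2)
  attr(out, "pivot") <- nrow(d1) + nrow(linker) %/% 2 + 1L
  out
}

# self-avoiding-ish random walk with 3.8 A steps
trace_walk <- function(n, seed) {
  with_preserved_rng(seed + 77L, {
    pts <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    for (i in 2:n) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        ax <- stats::rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        ang <- runif(1, 0, 70) * pi / 180
        nd <- rotate_about(dir, ax, ang)
        cand <- pts[i - 1, ] + 3.8 * nd
        d2 <- if (i > 3) min(rowSums(sweep(pts[1:(i - 3), , drop = FALSE],
                                           2, cand)^2)) else Inf
        if (d2 > 4.2^2 || tries > 50L) break
      }
      dir <- nd
      pts[i, ] <- cand
    }
    pts
  })
}

# k equal-length chords along a circular arc from p to q; each chord is as
# close to 3.8 A as the geometry allows (never shorter than the straight
# line division, never longer than 3.9)
bridge_points <- function(p, q, k) {
  p <- as.numeric(p); q <- as.numeric(q)
  d <- sqrt(sum((q - p)^2))
  k <- max(k, as.integer(ceiling(d / 3.9)))
  target <- 3.8
  if (d >= k * target) {
    # straight division (spacing d/k <= 3.9 by choice of k)
    lam <- seq_len(k - 1) / k
    return(t(vapply(lam, function(l) p + l * (q - p), numeric(3))))
  }
  # arc: find opening angle phi with d/target = sin(k*phi/2)/sin(phi/2)
  # (the ratio decreases from k to 0 as phi grows: bisect keeping
  # f(lo) > 0 > f(hi))
  f <- function(phi) sin(k * phi / 2) / sin(phi / 2) - d / target
  lo <- 1e-6; hi <- 2 * pi / k - 1e-6
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  phi <- (lo + hi) / 2
  R <- target / (2 * sin(phi / 2))
  # arc in the plane spanned by p->q and a stable perpendicular
  u <- (q - p) / d
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  mid <- (p + q) / 2
  h <- sqrt(max(R^2 - (d / 2)^2, 0))
  ctr <- mid + h * v
  a0 <- atan2(sum((p - ctr) * v), sum((p - ctr) * u))
  a1 <- atan2(sum((q - ctr) * v), sum((q - ctr) * u))
  # the arc subtends k*phi at the center (possibly > pi); sweep in the
  # direction that lands on q
  delta <- (a1 - a0) %% (2 * pi)
  da <- if (abs(delta - k * phi) <= abs((2 * pi - delta) - k * phi))
    k * phi else -k * phi
  lam <- seq_len(k - 1) / k
  t(vapply(lam, function(l) {
    a <- a0 + l * da
    ctr + R * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

rotate_about <- function(x, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  x * cos(angle) + pracma_cross(axis, x) * sin(angle) +
    axis * sum(axis * x) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

apply_fixture_transform <- function(ca, transform, seed) {
  n <- nrow(ca)
  map <- seq_len(n)
  type <- transform$type %||% "none"
  if (type == "none") {
    # nothing
  } else if (type == "rigid") {
    s <- transform$seed %||% seed
    ca <- with_preserved_rng(s + 101L, {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 0.5, pi)
      R <- rotation_matrix(ax, ang)
      ca %*% t(R) + matrix(runif(3, -20, 20), n, 3, byrow = TRUE)
    })
  } else if (type == "circular_permutation") {
    cut <- transform$cut %||% (n %/% 2)
    src <- ((seq_len(n) - 1L + cut) %% n) + 1L
    ca <- ca[src, , drop = FALSE]
    map <- src
  } else if (type == "hinge") {
    pivot <- transform$pivot %||% attr(ca, "pivot") %||% (n %/% 2)
    angle <- (transform$angle %||% 30) * pi / 180
    axis <- transform$axis %||% c(1, 0, 0)
    axis <- axis / sqrt(sum(axis^2))
    relink <- transform$relink %||% 3L
    R <- rotation_matrix(axis, angle)
    idx <- pivot:n
    ctr <- ca[pivot, ]
    ca[idx, ] <- sweep(sweep(ca[idx, , drop = FALSE], 2, ctr) %*% t(R),
                       2, -ctr)
    # a real hinge bends through a changed linker conformation: rebuild the
    # residues around the pivot so the hinge-local backbone differs from
    # the untransformed copy while spacing and connectivity are preserved
    if (relink > 0L && abs(angle) > 1e-12) {
      lo <- max(2L, pivot - relink)
      hi <- min(n - 1L, pivot + relink)
      k <- hi - lo + 2L
      ca[lo:hi, ] <- bridge_points(ca[lo - 1L, ], ca[hi + 1L, ], k)
    }
  } else if (type == "noise") {
    s <- transform$seed %||% seed
    sigma <- transform$sigma %||% 0.1
    ca <- with_preserved_rng(s + 131L, {
      ca + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
    })
  } else {
    stop("unknown fixture transform: ", type)
  }
  list(ca = ca, map = map)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# backbone atoms (N, CA, C, O, CB) around a C-alpha trace; side-chain
# direction points away from the local backbone average, so helices get
# outward-facing and strands alternating C-betas
fixture_atoms <- function(ca) {
  n <- nrow(ca)
  aa <- ifelse(seq_len(n) %% 9L == 0L, "GLY", "ALA")
  rows <- list()
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else 2 * ca[i, ] - ca[min(i + 1, n), ]
    nxt <- if (i < n) ca[i + 1, ] else 2 * ca[i, ] - ca[max(i - 1, 1), ]
    u_prev <- prev - ca[i, ]; u_next <- nxt - ca[i, ]
    out <- ca[i, ] - (prev + ca[i, ] + nxt) / 3
    if (sqrt(sum(out^2)) < 0.15) {
      perp <- pracma_cross(u_next, c(0.3, 0.62, 0.71))
      out <- perp * (-1)^i
    }
    out <- out / sqrt(sum(out^2))
    npos <- ca[i, ] + 0.45 * u_prev + 0.35 * out
    cpos <- ca[i, ] + 0.45 * u_next + 0.35 * out
    opos <- cpos + 1.23 * out
    cb <- ca[i, ] + 1.53 * (0.6 * out - 0.28 * (u_prev + u_next) /
                              max(sqrt(sum((u_prev + u_next)^2)), 1))
    at <- rbind(N = npos, CA = ca[i, ], C = cpos, O = opos, CB = cb)
    if (aa[i] == "GLY") at <- at[rownames(at) != "CB", , drop = FALSE]
    rows[[i]] <- data.frame(elety = rownames(at), resid = aa[i],
                            resno = i, x = at[, 1], y = at[, 2],
                            z = at[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a C-alpha trace as a PDB file with ideal backbone atoms
#'
#' @param ca n x 3 C-alpha coordinate matrix.
#' @param file output path.
#' @param id header identifier.
#' @return the file path, invisibly.
#' @export
write_fixture_pdb <- function(ca, file, id = "fixture") {
  at <- fixture_atoms(ca)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("HEADER    SYNTHETIC FIXTURE %s", toupper(id)), con)
  for (r in seq_len(nrow(at))) {
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
      r, at$elety[r], at$resid[r], at$resno[r],
      at$x[r], at$y[r], at$z[r], 1.0, 0.0,
      substr(at$elety[r], 1, 1)), con)
  }
  writeLines("END", con)
  invisible(file)
}
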