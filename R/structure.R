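#' @useDynLib ldalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into the internal structure representation used by the
#' aligner: an ordered list of residues, chain-aware, with one C-alpha
#' coordinate and one side-chain geometric center per residue. Residues
#' without a C-alpha atom are dropped with a warning; HETATM records
#' (ligands, waters) are ignored. When a file holds several models
#' (e.g. NMR ensembles) a single model is used.
#'
#' Alternate locations are resolved by keeping, per atom name, the highest
#' occupancy copy (first on ties). Insertion codes are retained as part of
#' the residue label; internally residues are addressed by their 1-based
#' position in file order across all chains.
#'
#' A chain break is recorded between consecutive residues when the chain
#' identifier changes or the C-alpha--C-alpha distance exceeds
#' `break_dist` (default 4.5 Angstrom). Descriptor elements and segments
#' never span a chain break.
#'
#' @param file path to a PDB-format file.
#' @param model model number to use when several are present (default 1).
#' @param id structure identifier; defaults to the file base name.
#' @param break_dist C-alpha distance (Angstrom) above which consecutive
#'   residues are considered disconnected.
#' @return An object of class `ldal_structure`: a list with elements
#'   `id`, `n`, `chain`, `resno`, `ins`, `seq_label`, `aa`, `ca` (n x 3),
#'   `sc` (n x 3), `breaks` (indices `i` such that residues `i` and `i+1`
#'   are not backbone-connected) and `atoms` (the parsed atom table, for
#'   lossless re-serialization).
#' @export
read_structure <- function(file, model = 1, id = NULL,
                           break_dist = 4.5) {
  if (!file.exists(file)) stop("no such file: ", file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", file, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (model > 1) {
    # bio3d stores extra models only in $xyz; re-read keeping all models
    pdb <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE,
                                            rm.alt = FALSE, verbose = FALSE))
    if (nrow(pdb$xyz) < model)
      stop("model ", model, " not present in ", file)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at <- pdb$atom
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # drop hydrogens
  if ("elesy" %in% names(at)) {
    elesy <- toupper(trimws(at$elesy))
    drop_h <- !is.na(elesy) & elesy %in% c("H", "D")
    guess <- grepl("^[0-9]*[HD]", at$elety)
    at <- at[!(drop_h | (is.na(elesy) | elesy == "") & guess), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty structure: no usable ATOM records in ", file)

  at$ins[is.na(at$ins)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  rkey <- paste(at$chain, at$resno, at$ins, sep = "|")
  at$.rkey <- factor(rkey, levels = unique(rkey))

  # alternate locations: per residue+atom name keep highest occupancy
  akey <- paste(rkey, at$elety)
  keep <- rep(TRUE, nrow(at))
  dup <- akey %in% akey[duplicated(akey)]
  if (any(dup)) {
    ord <- order(at$.rkey, at$elety, -at$o, seq_len(nrow(at)))
    first <- !duplicated(akey[ord])
    keep[ord] <- first
  }
  at <- at[keep, , drop = FALSE]

  res_split <- split(seq_len(nrow(at)), at$.rkey)
  ca <- sc <- matrix(NA_real_, length(res_split), 3)
  chain <- resno <- ins <- aa <- character(length(res_split))
  ok <- logical(length(res_split))
  for (k in seq_along(res_split)) {
    rows <- res_split[[k]]
    sub <- at[rows, , drop = FALSE]
    ica <- which(sub$elety == "CA")
    if (length(ica) == 0) next
    ok[k] <- TRUE
    ca[k, ] <- c(sub$x[ica[1]], sub$y[ica[1]], sub$z[ica[1]])
    chain[k] <- sub$chain[1]
    resno[k] <- as.character(sub$resno[1])
    ins[k] <- sub$ins[1]
    aa[k] <- sub$resid[1]
    sc[k, ] <- sidechain_center(sub)
  }
  if (any(!ok))
    warning(sum(!ok), " residue(s) without a C-alpha atom dropped from ",
            file)
  if (!any(ok)) stop("empty structure: no residues with C-alpha in ", file)

  ca <- ca[ok, , drop = FALSE]
  sc <- sc[ok, , drop = FALSE]
  chain <- chain[ok]; resno <- resno[ok]; ins <- ins[ok]; aa <- aa[ok]
  n <- sum(ok)
  breaks <- integer(0)
  if (n > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    breaks <- which(chain[-1] != chain[-n] | d > break_dist)
  }
  structure(
    list(id = if (is.null(id)) sub("\\.(pdb|ent)$", "", basename(file)) else id,
         n = n, chain = chain, resno = as.integer(resno), ins = ins,
         seq_label = paste0(resno, ifelse(ins == "", "", ins)),
         aa = aa, ca = ca, sc = sc, breaks = breaks,
         atoms = at[at$.rkey %in% levels(at$.rkey)[ok], , drop = FALSE]),
    class = "ldal_structure"
  )
}

#' Side-chain geometric center of one residue
#'
#' The unweighted mean of the side-chain heavy atoms (C-beta and beyond).
#' For glycine the C-alpha is used, for alanine the C-beta; a residue whose
#' side-chain atoms are all missing falls back to its C-alpha. Hydrogens are
#' never included.
#'
#' @param residue_atoms data frame of one residue's atoms with columns
#'   `elety`, `resid`, `x`, `y`, `z` (as in `bio3d::read.pdb()$atom`).
#' @return numeric length-3 coordinate (Angstrom).
#' @export
sidechain_center <- function(residue_atoms) {
  sub <- residue_atoms
  ica <- which(sub$elety == "CA")
  if (length(ica) == 0) stop("residue has no C-alpha atom")
  ca <- c(sub$x[ica[1]], sub$y[ica[1]], sub$z[ica[1]])
  aa <- sub$resid[1]
  if (identical(aa, "GLY")) return(ca)
  if (identical(aa, "ALA")) {
    icb <- which(sub$elety == "CB")
    if (length(icb)) return(c(sub$x[icb[1]], sub$y[icb[1]], sub$z[icb[1]]))
    return(ca)
  }
  side <- sub[!(sub$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(side) == 0) return(ca)
  c(mean(side$x), mean(side$y), mean(side$z))
}

#' Minimal RMSD after optimal rigid superposition
#'
#' Least-squares RMSD over all proper rotations and translations (Kabsch
#' superposition); reflections are never used.
#'
#' @param points_a,points_b n x 3 coordinate matrices of equal length.
#' @return non-negative RMSD in Angstrom.
#' @export
superpose_rmsd <- function(points_a, points_b) {
  points_a <- as_xyz_matrix(points_a)
  points_b <- as_xyz_matrix(points_b)
  if (nrow(points_a) != nrow(points_b))
    stop("point sets differ in length")
  .cpp_kabsch_rmsd(points_a, points_b)
}

#' Optimal rigid superposition transform
#'
#' Returns the proper rotation `R` and translation `t` minimizing the RMSD of
#' `points_a %*% R + t` against `points_b`, together with that RMSD.
#'
#' @inheritParams superpose_rmsd
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
superpose_fit <- function(points_a, points_b) {
  points_a <- as_xyz_matrix(points_a)
  points_b <- as_xyz_matrix(points_b)
  if (nrow(points_a) != nrow(points_b))
    stop("point sets differ in length")
  fit <- .cpp_kabsch_fit(points_a, points_b)
  fit$translation <- as.numeric(fit$translation)
  fit
}

as_xyz_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 3)
    m <- matrix(as.numeric(m), ncol = 3, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Write a structure back to a PDB file
#'
#' Re-serializes the atom records kept at parse time, optionally after a
#' rigid transformation. Round-tripping a parsed file preserves residue
#' count, order and coordinates.
#'
#' @param struct an `ldal_structure`.
#' @param file output path.
#' @param rotation optional 3 x 3 rotation applied to all coordinates.
#' @param translation optional length-3 translation (applied after rotation).
#' @export
write_structure <- function(struct, file, rotation = NULL, translation = NULL) {
  stopifnot(inherits(struct, "ldal_structure"))
  at <- struct$atoms
  xyz <- cbind(at$x, at$y, at$z)
  if (!is.null(rotation)) xyz <- xyz %*% rotation
  if (!is.null(translation)) xyz <- sweep(xyz, 2, -as.numeric(translation))
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, ins = at$ins,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain,
                   o = at$o, b = if (all(is.na(at$b))) 0 else at$b)
  invisible(file)
}

#' @export
print.ldal_structure <- function(x, ...) {
  cat("ldal_structure '", x$id, "': ", x$n, " residues, ",
      length(unique(x$chain)), " chain(s), ", length(x$breaks),
      " chain break(s)\n", sep = "")
  invisible(x)
}

# chain-segment id per residue: residues in the same physically connected
# stretch share an id; elements/segments must not cross these boundaries
chain_segment_ids <- function(struct) {
  ids <- integer(struct$n)
  if (struct$n == 0) return(ids)
  brk <- logical(struct$n)
  brk[struct$breaks + 1L] <- TRUE
  brk[1] <- TRUE
  cumsum(brk)
}
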