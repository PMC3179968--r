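test_that("identity self-alignment has zero tension", {
  f <- fixture_structure("helix-bundle", seed = 1)
  st <- f$structure
  prs <- data.frame(ia = seq_len(st$n), ib = seq_len(st$n))
  expect_equal(tension(prs, st, st), 0, tolerance = 1e-9)
  expect_error(tension(data.frame(ia = integer(0), ib = integer(0)),
                       st, st), "empty")
})

test_that("a single aligned contact contributes its element RMSD as tension", {
  # two 5-residue pieces in contact; B displaces the second piece slightly
  ca <- rbind(cbind(3.8 * (0:4), 0, 0), cbind(3.8 * (0:4), 5.5, 0))
  sa <- mk_struct(ca)
  cb_mat <- ca
  cb_mat[6:10, 3] <- cb_mat[6:10, 3] + 1.0
  sb <- mk_struct(cb_mat)
  con_a <- find_contacts(sa)
  expect_gt(nrow(con_a), 0)
  # align only the two contacting residues 3 and 8
  prs <- data.frame(ia = c(3L, 8L), ib = c(3L, 8L))
  # independent oracle: joint RMSD of the two 5-residue elements
  r <- superpose_rmsd(sa$ca, sb$ca)
  expect_equal(tension(prs, sa, sb), r, tolerance = 1e-9)
  expect_gt(r, 0)

  # aligning all ten residues: every residue has exactly one cross-strand
  # contact, so the average stays positive and bounded by the single-pair
  # strain
  prs_all <- data.frame(ia = 1:10, ib = 1:10)
  t_all <- tension(prs_all, sa, sb)
  expect_lte(t_all, r + 1e-9)
  expect_gt(t_all, 0)
})

test_that("tension is invariant under rigid motion of either structure", {
  pr <- fixture_pair("helix-bundle", transform = list(type = "rigid"),
                     seed = 13)
  prs <- data.frame(ia = seq_len(pr$a$n), ib = seq_len(pr$b$n))
  # zero up to the 3-decimal coordinate precision of the PDB files
  expect_lt(tension(prs, pr$a, pr$b), 0.005)
})

test_that("the score is aligned residues minus squared tension", {
  expect_equal(alignment_score(list(n_aligned = 100, tension = 0)), 100)
  expect_equal(alignment_score(list(n_aligned = 100, tension = 3)), 91)
})

test_that("swap counting decomposes the mapping into co-linear blocks", {
  colinear <- data.frame(ia = 1:10, ib = 11:20)
  expect_equal(count_swaps(colinear), 0L)

  # circular permutation: two blocks in exchanged order cost one swap
  cp <- data.frame(ia = 1:10, ib = c(6:10, 1:5))
  expect_equal(count_swaps(cp), 1L)

  # three blocks in reversed order: two descents
  rev3 <- data.frame(ia = 1:9, ib = c(7:9, 4:6, 1:3))
  expect_equal(count_swaps(rev3), 2L)

  # zero swaps if and only if monotone in both structures
  gap <- data.frame(ia = c(1:3, 7:9), ib = c(2:4, 20:22))
  expect_equal(count_swaps(gap), 0L)
})

test_that("largest sub-alignment under a swap budget matches brute force", {
  # two-block swap with M = 0 keeps the larger block
  cp <- data.frame(ia = 1:10, ib = c(7:10, 1:6))
  red <- largest_subalignment(cp, 0)
  expect_equal(nrow(red), 6L)
  expect_equal(count_swaps(red), 0L)
  # an alignment already within budget is unchanged
  expect_equal(nrow(largest_subalignment(cp, 1)), 10L)

  # random block permutations vs exhaustive subset enumeration
  brute <- function(prs, M) {
    b <- ldalign:::alignment_blocks(prs)
    nb <- nrow(b)
    best <- 0L
    for (s in 0:(2^nb - 1)) {
      sel <- which(bitwAnd(s, 2^(seq_len(nb) - 1)) > 0)
      if (length(sel) == 0) next
      ibs <- b$ib_start[sel]
      if (sum(diff(ibs) < 0) <= M)
        best <- max(best, sum(b$size[sel]))
    }
    best
  }
  set.seed(31)
  for (rep in 1:12) {
    nb <- sample(3:8, 1)
    sizes <- sample(2:5, nb, replace = TRUE)
    perm <- sample(nb)
    ia <- integer(0); ib <- integer(0)
    pos_a <- 1L
    starts_b <- cumsum(c(1L, sizes[order(perm)] + 2L))
    for (k in seq_len(nb)) {
      ia <- c(ia, pos_a:(pos_a + sizes[k] - 1L))
      sb0 <- starts_b[perm[k]]
      ib <- c(ib, sb0:(sb0 + sizes[k] - 1L))
      pos_a <- pos_a + sizes[k] + 2L
    }
    prs <- data.frame(ia = ia, ib = ib)
    for (M in 0:2) {
      red <- largest_subalignment(prs, M)
      expect_lte(count_swaps(red), M)
      expect_equal(nrow(red), brute(prs, M),
                   info = sprintf("rep %d M %d", rep, M))
    }
  }
})

test_that("sequence offsets follow the two stated conventions", {
  # equal lengths: offset is |ib - ia|
  expect_equal(pair_offsets(c(1, 5), c(1, 9), 50, 50), c(0, 4))
  # ungapped-closest with unequal lengths: distance to [0, nb - na]
  expect_equal(pair_offsets(c(1, 1, 10), c(1, 6, 8), 40, 45), c(0, 0, 2))
  # gaps in the shorter chain: any monotone placement is allowed
  expect_equal(pair_offsets(5, 3, 40, 45, "gaps-in-shorter"), 2)
  expect_equal(pair_offsets(5, 8, 40, 45, "gaps-in-shorter"), 0)
  # not enough room left in the longer chain for the shorter's tail
  expect_equal(pair_offsets(5, 30, 40, 45, "gaps-in-shorter"), 20)
})

test_that("rigid regions decompose by member residue overlap", {
  mk <- function(ia, ib, nseg = 3L)
    structure(list(ia = ia, ib = ib, rmsd = 0.1, nseg_a = nseg,
                   nseg_b = nseg, central_a = ia[1], central_b = ib[1],
                   el_a = ia[1], el_b = ib[1]),
              class = "ldal_desc_alignment")
  f <- fixture_structure("helix-bundle", seed = 1)
  st <- f$structure
  # one member: one region
  m1 <- list(mk(1:8, 1:8))
  prs <- data.frame(ia = 1:8, ib = 1:8)
  regs <- rigid_regions(m1, prs, st, st)
  expect_equal(length(regs), 1L)
  expect_lt(regs[[1]]$rmsd, 1e-9)
  # two overlapping + one disjoint member: two regions
  m3 <- list(mk(1:8, 1:8), mk(6:12, 6:12), mk(25:30, 25:30))
  prs <- data.frame(ia = c(1:12, 25:30), ib = c(1:12, 25:30))
  regs <- rigid_regions(m3, prs, st, st)
  expect_equal(length(regs), 2L)
  expect_equal(sort(vapply(regs, function(r) length(r$ia), integer(1))),
               c(6L, 12L))
})

test_that("accuracy is the recovered fraction of the reference", {
  ref <- data.frame(chain_a = "A", seq_a = as.character(1:10),
                    chain_b = "B", seq_b = as.character(11:20))
  expect_equal(accuracy(ref, ref), 1.0)
  disj <- transform(ref, seq_b = as.character(31:40))
  expect_equal(accuracy(disj, ref), 0.0)
  half <- ref
  half$seq_b[6:10] <- as.character(56:60)
  expect_equal(accuracy(half, ref), 0.5)
  expect_error(accuracy(ref, ref[0, ]), "empty")
})
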