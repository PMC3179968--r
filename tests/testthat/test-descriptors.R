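# place two residues at prescribed C-alpha / side-chain-center distances,
# padded with far-away residues so the sequence separation floor is met
two_residue_struct <- function(d_alpha, d_c) {
  ca <- rbind(c(0, 0, 0), c(500, 0, 0), c(600, 0, 0), c(d_alpha, 0, 0))
  sc <- rbind(c(0, -d_c / 2 + d_alpha / 2, 0), c(500, 0, 0), c(600, 0, 0),
              c(d_alpha, d_c / 2 + d_alpha / 2 - d_alpha, 0))
  # simpler: put both side-chain centers on the y axis at distance d_c
  sc[1, ] <- c(0, 0, 0); sc[4, ] <- c(0, d_c, 0)
  mk_struct(ca, sc)
}

test_that("contact determination follows the distance thresholds", {
  ct <- find_contacts(two_residue_struct(5.0, 20))
  expect_equal(nrow(ct[ct$i == 1 & ct$j == 4, ]), 1L)
  expect_true(ct$certain[ct$i == 1 & ct$j == 4])

  ct <- find_contacts(two_residue_struct(6.0, 9.0))
  row <- ct[ct$i == 1 & ct$j == 4, ]
  expect_equal(nrow(row), 1L)
  expect_false(row$certain)

  # d_alpha - d_c = 0.7 < 0.75: no contact despite d_c below 8
  ct <- find_contacts(two_residue_struct(8.5, 7.8))
  expect_equal(nrow(ct[ct$i == 1 & ct$j == 4, ]), 0L)

  # side-chain criterion alone, above the tight d_c threshold: optional
  ct <- find_contacts(two_residue_struct(8.5, 7.5))
  row <- ct[ct$i == 1 & ct$j == 4, ]
  expect_equal(nrow(row), 1L)
  expect_false(row$certain)
})

test_that("sequence-local pairs are not contacts; the certain set is nested", {
  f <- fixture_structure("helix-bundle", seed = 2)
  ct <- find_contacts(f$structure)
  expect_true(all(abs(ct$i - ct$j) >= 3))
  # tightening thresholds shrinks the contact set monotonically
  tight <- find_contacts(f$structure, d_alpha_max = 5.5, d_c_max = 7.0)
  key <- function(d) paste(d$i, d$j)
  expect_true(all(key(tight) %in% key(ct)))
  expect_true(all(key(ct[ct$certain, ]) %in% key(tight)))
  expect_equal(key(tight), key(ct[ct$certain, ]))
})

test_that("descriptor construction is invariant under rigid motion", {
  f <- fixture_structure("helix-bundle", seed = 6)
  sa <- f$structure
  # exact in-memory rotation (file precision would jitter borderline
  # contacts by a thousandth of an Angstrom)
  R <- ldalign:::rotation_matrix(c(2, -1, 3), 1.2)
  shift <- matrix(c(8, -4, 11), sa$n, 3, byrow = TRUE)
  sb <- sa
  sb$ca <- sa$ca %*% t(R) + shift
  sb$sc <- sa$sc %*% t(R) + shift
  ca <- find_contacts(sa); cb <- find_contacts(sb)
  expect_equal(ca[c("i", "j", "certain")], cb[c("i", "j", "certain")])
  expect_equal(ca$d_alpha, cb$d_alpha, tolerance = 1e-9)
  for (i in c(5L, 20L, 33L)) {
    da <- build_descriptor(sa, i, ca)
    db <- build_descriptor(sb, i, cb)
    expect_equal(da$partners, db$partners)
    expect_equal(da$segments$first, db$segments$first)
    expect_equal(da$n_segments, db$n_segments)
  }
})

test_that("elements are clipped at termini and never cross chain breaks", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
              c(50, 0, 0), c(53.8, 0, 0))
  st <- mk_struct(ca)
  expect_equal(st$breaks, 3L)
  expect_equal(ldalign:::element_span(st, 1), 1:3)
  expect_equal(ldalign:::element_span(st, 3), 1:3)
  expect_equal(ldalign:::element_span(st, 4), 4:5)
})

test_that("adjacent contact elements merge into one segment", {
  # U-shaped chain: residues 1..12 run along +x at y = 0, residues 13..24
  # run back along -x at y = 4.5, so residue 20 faces residues 4, 5 and 6;
  # their elements (2..6, 3..7, 4..8) concatenate into one run 2..8
  ca <- rbind(cbind(3.8 * (0:11), 0, 0),
              cbind(3.8 * (11:0), 4.5, 0))
  st <- mk_struct(ca)
  expect_equal(length(st$breaks), 0L)
  ct <- find_contacts(st)
  d <- build_descriptor(st, 20, ct)
  expect_true(all(c(4L, 5L, 6L) %in% d$partners))
  seg <- d$segments
  expect_true(any(seg$first == 2 & seg$last == 8))
})

test_that("a contact-free mid-chain residue yields a one-segment descriptor", {
  ca <- cbind(3.8 * (0:19), 0, 0)  # straight chain: no contacts at all
  st <- mk_struct(ca)
  ct <- find_contacts(st)
  d <- build_descriptor(st, 10, ct)
  expect_equal(length(d$partners), 0L)
  expect_equal(nrow(d$segments), 1L)
  expect_equal(d$segments$first, 8L)
  expect_equal(d$segments$last, 12L)
  expect_equal(d$n_segments, 1L)
})

test_that("segment spatial length matches direct evaluation of the formula", {
  # single residue: empty sum
  st1 <- mk_struct(cbind(c(0, 100, 200), 0, 0))
  expect_equal(segment_spatial_length(st1, 2, 2), 0)

  # three collinear points, no flanking residues: end points unsmoothed
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  st <- mk_struct(ca)
  sm1 <- ca[1, ]
  sm2 <- (ca[1, ] + ca[2, ] + ca[3, ]) / 3
  sm3 <- ca[3, ]
  expected <- sqrt(sum((sm1 - sm2)^2)) + sqrt(sum((sm2 - sm3)^2))
  expect_equal(segment_spatial_length(st, 1, 3), expected)

  # ideal helix segment: independent re-evaluation of the smoothed sum
  f <- fixture_structure("helix", n = 20, seed = 1)
  sth <- f$structure
  sm <- t(sapply(1:20, function(i) {
    if (i > 1 && i < 20) colMeans(sth$ca[(i - 1):(i + 1), ])
    else sth$ca[i, ]
  }))
  expected <- sum(sqrt(rowSums((sm[-1, ] - sm[-20, ])^2)))
  expect_equal(segment_spatial_length(sth, 1, 20), expected)
  # smoothing follows the helix axis: well below the raw contour length
  expect_lt(segment_spatial_length(sth, 1, 20), 19 * 3.8 / 2)
})

test_that("perceived segment count is ceiling(L / 18) with a floor of one", {
  expect_equal(perceived_segments(0), 1L)
  expect_equal(perceived_segments(10), 1L)
  expect_equal(perceived_segments(18), 1L)
  expect_equal(perceived_segments(18.1), 2L)
  expect_equal(perceived_segments(c(36, 36.1)), c(2L, 3L))
})

test_that("every descriptor residue belongs to exactly one segment", {
  f <- fixture_structure("sheet-sandwich", seed = 5)
  ct <- find_contacts(f$structure)
  for (d in build_descriptors(f$structure, ct)[c(3, 12, 25, 40)]) {
    span_res <- sort(unique(unlist(lapply(d$elements, `[[`, "span"))))
    seg_res <- unlist(lapply(seq_len(nrow(d$segments)), function(k)
      d$segments$first[k]:d$segments$last[k]))
    expect_equal(sort(seg_res), span_res)
    expect_false(any(duplicated(seg_res)))
  }
})
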