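test_that("trivial graphs are searched correctly", {
  g1 <- mk_instance(1, m = 1L)
  ts <- tree_search(g1)
  expect_equal(length(ts$cliques), 1L)
  expect_equal(ts$cliques[[1]]$nodes, 1L)

  # three mutually consistent nodes form one maximal clique
  tri <- list(
    structure(list(ia = 1:3, ib = 1:3, rmsd = 0.1, nseg_a = 3L,
                   nseg_b = 3L, central_a = 1L, central_b = 1L,
                   el_a = 1L, el_b = 1L), class = "ldal_desc_alignment"),
    structure(list(ia = 4:6, ib = 4:6, rmsd = 0.2, nseg_a = 3L,
                   nseg_b = 3L, central_a = 4L, central_b = 4L,
                   el_a = 4L, el_b = 4L), class = "ldal_desc_alignment"),
    structure(list(ia = 7:9, ib = 7:9, rmsd = 0.3, nseg_a = 3L,
                   nseg_b = 3L, central_a = 7L, central_b = 7L,
                   el_a = 7L, el_b = 7L), class = "ldal_desc_alignment"))
  ts <- tree_search(build_graph(tri), enumerate_all = TRUE)
  expect_equal(length(ts$cliques), 1L)
  expect_equal(ts$cliques[[1]]$nodes, 1:3)
})

test_that("branch-and-bound enumerates exactly the maximal cliques", {
  for (seed in 1:40) {
    g <- mk_instance(seed, m = sample(c(8L, 10L, 12L), 1))
    ts <- tree_search(g, enumerate_all = TRUE)
    got <- sort(vapply(ts$cliques, function(cl) clique_key(cl$nodes),
                       character(1)))
    want <- sort(vapply(oracle_max_cliques(g), clique_key, character(1)))
    expect_equal(got, want, info = paste("graph seed", seed))
    # coverage bookkeeping agrees with an independent recount
    for (cl in ts$cliques)
      expect_equal(cl$coverage, clique_coverage(g, cl$nodes))
  }
})

test_that("the size bound preserves the top coverage values", {
  for (seed in 41:60) {
    g <- mk_instance(seed, m = 12L)
    bounded <- tree_search(g, n_best = 3L)
    all_cl <- oracle_max_cliques(g)
    covs <- sort(vapply(all_cl, function(x) clique_coverage(g, x),
                        integer(1)), decreasing = TRUE)
    got <- vapply(bounded$cliques, `[[`, integer(1), "coverage")
    expect_equal(head(got, 3), head(covs, 3),
                 info = paste("graph seed", seed))
  }
})

test_that("constrained search output is structurally connected", {
  multi <- 0L
  for (seed in c(2, 9, 17)) {
    g <- mk_instance_overlapping(seed, m = 12L)
    cts <- tree_search(g, connectivity_required = TRUE)
    multi <- multi + sum(vapply(cts$cliques,
                                function(cl) length(cl$nodes) > 1,
                                logical(1)))
    for (cl in cts$cliques) {
      mem <- g$nodes[cl$nodes]
      k <- length(mem)
      if (k == 1) next
      # residue-overlap graph over members must be connected
      adj <- matrix(FALSE, k, k)
      for (u in seq_len(k - 1)) {
        for (v in (u + 1):k) {
          adj[u, v] <- adj[v, u] <-
            any(mem[[u]]$ia %in% mem[[v]]$ia) ||
            any(mem[[u]]$ib %in% mem[[v]]$ib)
        }
      }
      reach <- 1L
      repeat {
        nxt <- unique(c(reach, which(colSums(adj[reach, , drop = FALSE]) > 0)))
        if (length(nxt) == length(reach)) break
        reach <- nxt
      }
      expect_equal(sort(reach), seq_len(k))
    }
  }
  expect_gt(multi, 0L)  # the check must exercise multi-node cliques
})

test_that("extension blocks are added only when consistent and overlapping", {
  base <- list(structure(list(ia = 1:6, ib = 1:6, rmsd = 0.1, nseg_a = 3L,
                              nseg_b = 3L, central_a = 3L, central_b = 3L,
                              el_a = 3L, el_b = 3L),
                         class = "ldal_desc_alignment"))
  s1_overlap <- structure(list(ia = 6:8, ib = 6:8, rmsd = 0.5, nseg_a = 1L,
                               nseg_b = 1L, central_a = 7L, central_b = 7L,
                               el_a = 7L, el_b = 7L),
                          class = "ldal_desc_alignment")
  s1_disjoint <- structure(list(ia = 20:22, ib = 20:22, rmsd = 0.5,
                                nseg_a = 1L, nseg_b = 1L, central_a = 21L,
                                central_b = 21L, el_a = 21L, el_b = 21L),
                           class = "ldal_desc_alignment")
  s1_conflict <- structure(list(ia = 6:8, ib = c(9L, 7L, 8L), rmsd = 0.5,
                                nseg_a = 1L, nseg_b = 1L, central_a = 7L,
                                central_b = 7L, el_a = 7L, el_b = 7L),
                           class = "ldal_desc_alignment")
  ext <- extend_with_s1(base, list(s1_overlap))
  expect_equal(ext$ia, 1:8)
  ext <- extend_with_s1(base, list(s1_disjoint))
  expect_equal(ext$ia, 1:6)
  ext <- extend_with_s1(base, list(s1_conflict))
  expect_equal(ext$ia, 1:6)
})

test_that("the Monte Carlo move generator follows its three steps", {
  # single node, empty clique
  adj1 <- matrix(FALSE, 1, 1)
  expect_equal(remc_move(integer(0), adj1), 1L)

  # d adjacent to all of C keeps every member
  adj <- matrix(TRUE, 4, 4); diag(adj) <- FALSE
  set.seed(1)
  out <- remc_move(c(1L, 2L), adj)
  expect_true(all(c(1L, 2L) %in% out))
  # complete graph: the closure forces the full vertex set
  expect_equal(out, 1:4)

  # triangle plus isolated node: picking the isolate resets the clique
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[1, 3] <- adj[3, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  # force d = 4 (the only node outside C = {1,2,3})
  out <- remc_move(c(1L, 2L, 3L), adj)
  expect_equal(out, 4L)
})

test_that("replica exchange reaches the exact optimum on solvable graphs", {
  hits <- 0L; total <- 0L
  for (seed in 1:6) {
    g <- mk_instance(seed + 100L, m = 14L)
    opt <- tree_search(g, n_best = 1L)$cliques[[1]]$coverage
    for (rs in 1:3) {
      mc <- remc_search(g, seed = rs, total_moves = 8000L)
      expect_lte(mc$coverage, opt)  # never better than the exact search
      total <- total + 1L
      if (mc$coverage == opt) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("the Monte Carlo search is deterministic given the seed", {
  g <- mk_instance(7L, m = 12L)
  a <- remc_search(g, seed = 42L, total_moves = 4000L)
  b <- remc_search(g, seed = 42L, total_moves = 4000L)
  expect_identical(a, b)
})

test_that("structures without multi-segment similarities align to nothing", {
  fh <- fixture_structure("helix", n = 14, seed = 1)
  expect_equal(length(align_structures(fh$structure, fh$structure)), 0L)
  w1 <- fixture_structure("random-walk", n = 30, seed = 21)
  w2 <- fixture_structure("random-walk", n = 30, seed = 22)
  expect_equal(length(align_structures(w1$structure, w2$structure)), 0L)
})
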