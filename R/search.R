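#' Branch-and-bound search for highest-coverage cliques (TS / CTS)
#'
#' Enumerates maximal cliques of the alignment graph by a depth-first
#' branch and bound over include/exclude decisions, with two cuts: a branch
#' is abandoned when (1) some previously rejected node could unambiguously
#' extend every clique of the branch (such cliques are found elsewhere,
#' ensuring each maximal clique is produced exactly once), or (2) enough
#' alignments have been collected and the branch's upper bound -- residues
#' aligned so far plus residues coverable by candidates not yet considered
#' -- cannot beat the current `n_best`-th best. The bound uses the raw
#' aligned-residue count, which is monotone under clique growth; the
#' tension-penalised score is applied only when ranking final alignments.
#'
#' With `connectivity_required = TRUE` (the constrained variant, CTS) a node
#' may only join the clique if it shares at least one residue, on either
#' structure, with the residues accumulated so far, so the resulting
#' alignment is one structurally continuous fragment. The constrained
#' search restarts from each of the `n_seeds` highest-coverage nodes and
#' results are de-duplicated.
#'
#' @param graph an `ldal_graph` from [build_graph()].
#' @param n_best number of top alignments the bound protects.
#' @param connectivity_required logical; `TRUE` gives the CTS variant.
#' @param enumerate_all when `TRUE` the size bound (cut 2) is disabled and
#'   every maximal clique is returned (used for exhaustive enumeration).
#' @param timeout_s wall-clock budget in seconds; on expiry the search
#'   stops and the result is flagged `timed_out` (the pipeline then falls
#'   back to the Monte Carlo search).
#' @param keep_max number of best-coverage cliques retained for final
#'   scoring.
#' @param n_seeds number of restart seeds for the constrained variant.
#' @return list with `cliques` (each a list of `nodes` -- indices into
#'   `graph$nodes` -- and `coverage`), sorted by decreasing coverage, and
#'   `timed_out`.
#' @export
tree_search <- function(graph, n_best = 5L, connectivity_required = FALSE,
                        enumerate_all = FALSE, timeout_s = Inf,
                        keep_max = 64L, n_seeds = 32L) {
  m <- length(graph$nodes)
  if (m == 0) return(list(cliques = list(), timed_out = FALSE))
  adj <- graph$adjacency
  keys <- lapply(graph$nodes, pair_keys)
  # residues (not pairs) covered by a node, as keys on each structure
  akeys <- lapply(graph$nodes, function(a) a$ia)
  bkeys <- lapply(graph$nodes, function(a) a$ib)

  st <- new.env(parent = emptyenv())
  st$found <- list()
  st$found_keys <- character(0)
  st$best_cov <- integer(0)
  st$timed_out <- FALSE
  t0 <- Sys.time()

  record <- function(C, cov) {
    key <- paste(sort(C), collapse = ",")
    if (key %in% st$found_keys) return(invisible())
    st$found_keys <- c(st$found_keys, key)
    st$found[[length(st$found) + 1L]] <- list(nodes = sort(C),
                                              coverage = cov)
    if (!enumerate_all && length(st$found) > 4L * keep_max) prune_found()
    nb <- sort(c(st$best_cov, cov), decreasing = TRUE)
    st$best_cov <- head(nb, n_best)
    invisible()
  }
  prune_found <- function() {
    covs <- vapply(st$found, `[[`, integer(1), "coverage")
    ord <- order(-covs)
    keep <- head(ord, keep_max)
    st$found <- st$found[keep]
    st$found_keys <- st$found_keys[keep]
  }

  connectable <- function(v, cov_a, cov_b) {
    any(akeys[[v]] %in% cov_a) || any(bkeys[[v]] %in% cov_b)
  }

  # recursion depth is bounded by the clique size: the include decision
  # recurses, the exclude decision iterates in place
  rec <- function(C, cov_keys, cov_a, cov_b, P, X) {
    repeat {
      if (st$timed_out) return(invisible())
      if (difftime(Sys.time(), t0, units = "secs") > timeout_s) {
        st$timed_out <- TRUE
        return(invisible())
      }
      # cut 1: a rejected node dominating every candidate closes the branch
      if (length(X)) {
        for (x in X) {
          if ((!connectivity_required ||
               length(C) == 0L || connectable(x, cov_a, cov_b)) &&
              (length(P) == 0L || all(adj[x, P]))) {
            return(invisible())
          }
        }
      }
      addable <- P
      if (connectivity_required && length(C) > 0L && length(P) > 0L) {
        ok <- vapply(P, connectable, logical(1), cov_a, cov_b)
        addable <- P[ok]
      }
      if (length(addable) == 0L) {
        if (length(C) > 0L) record(C, length(cov_keys))
        return(invisible())
      }
      # cut 2: coverage upper bound against the n_best-th best found so far
      if (!enumerate_all && length(st$best_cov) >= n_best) {
        novel <- unique(unlist(keys[addable]))
        ub <- length(cov_keys) + sum(!(novel %in% cov_keys))
        if (ub <= st$best_cov[n_best]) return(invisible())
      }
      v <- addable[1L]
      # include v
      nbr <- adj[v, ]
      rec(c(C, v), union(cov_keys, keys[[v]]),
          union(cov_a, akeys[[v]]), union(cov_b, bkeys[[v]]),
          P[nbr[P] & P != v], X[nbr[X]])
      # exclude v, continue in place
      P <- P[P != v]
      X <- c(X, v)
    }
  }

  if (!connectivity_required) {
    rec(integer(0), numeric(0), integer(0), integer(0), seq_len(m),
        integer(0))
  } else {
    seeds <- head(order(-graph$coverage), n_seeds)
    for (s in seeds) {
      if (st$timed_out) break
      nbr <- which(adj[s, ])
      rec(s, keys[[s]], akeys[[s]], bkeys[[s]], nbr[nbr != s], integer(0))
    }
  }
  covs <- vapply(st$found, `[[`, integer(1), "coverage")
  list(cliques = st$found[order(-covs)], timed_out = st$timed_out)
}

#' Extend a stage-two alignment with the small descriptor alignments
#'
#' Runs the constrained (connectivity-requiring) extension over the pool of
#' one- and two-segment descriptor alignments: an extension block is added
#' only when it is consistent with the accumulated mapping and shares at
#' least one residue with it. Blocks are added greedily in order of the
#' number of novel residues they contribute (ties broken by lower RMSD,
#' then lexicographically).
#'
#' @param members list of `ldal_desc_alignment` forming the stage-two
#'   clique.
#' @param s1_pool list of extension candidates.
#' @return list with the extended `members` and the union `ia`/`ib`
#'   mapping.
#' @export
extend_with_s1 <- function(members, s1_pool) {
  up <- unique_pairs(members)
  ia <- up$ia
  ib <- up$ib
  pool <- s1_pool
  rms <- vapply(pool, function(a) a$rmsd, numeric(1))
  lex <- vapply(pool, function(a) paste(a$ia, a$ib, collapse = ";"),
                character(1))
  while (length(pool)) {
    keys <- ia * 65536 + ib
    n_p <- length(pool)
    novel <- integer(n_p)
    ok <- logical(n_p)
    drop <- logical(n_p)
    for (kk in seq_len(n_p)) {
      cnd <- pool[[kk]]
      # a block inconsistent with the accumulated map stays inconsistent;
      # one contributing no new pairs never will: prune both permanently
      if (!is_partial_bijection(c(ia, cnd$ia), c(ib, cnd$ib))) {
        drop[kk] <- TRUE
        next
      }
      nv <- sum(!(cnd$ia * 65536 + cnd$ib) %in% keys)
      if (nv == 0L) {
        drop[kk] <- TRUE
        next
      }
      novel[kk] <- nv
      ok[kk] <- any(cnd$ia %in% ia) || any(cnd$ib %in% ib)
    }
    usable <- which(ok)
    if (length(usable) == 0L) break
    best <- usable[order(-novel[usable], rms[usable], lex[usable])][1L]
    members <- c(members, pool[best])
    add <- pool[[best]]
    newk <- !(add$ia * 65536 + add$ib) %in% keys
    ia <- c(ia, add$ia[newk]); ib <- c(ib, add$ib[newk])
    drop[best] <- TRUE
    pool <- pool[!drop]; rms <- rms[!drop]; lex <- lex[!drop]
  }
  ord <- order(ia)
  list(members = members, ia = ia[ord], ib = ib[ord])
}

unique_pairs <- function(members) {
  ia <- unlist(lapply(members, `[[`, "ia"))
  ib <- unlist(lapply(members, `[[`, "ib"))
  keep <- !duplicated(ia * 65536 + ib)
  list(ia = ia[keep], ib = ib[keep])
}

#' One Monte Carlo transition of the clique sampler
#'
#' Implements the move generator of the replica-exchange search: pick a
#' random graph node `d` outside the current clique; keep `d` together with
#' the clique members adjacent to it; then add every node that belongs to
#' all maximal cliques containing the result (operationally, every common
#' neighbour of the new clique adjacent to all other common neighbours).
#' The closure step is skipped when the common-neighbour set exceeds
#' `closure_max` nodes.
#'
#' @param clique integer vector of node indices (may be empty).
#' @param adj adjacency matrix of the alignment graph.
#' @param closure_max skip the forced-node closure above this many common
#'   neighbours.
#' @return integer vector: the new clique.
#' @export
remc_move <- function(clique, adj, closure_max = 64L) {
  m <- nrow(adj)
  outside <- setdiff(seq_len(m), clique)
  if (length(outside) == 0L) return(clique)
  d <- outside[sample.int(length(outside), 1L)]
  keep <- clique[adj[d, clique]]
  C1 <- c(d, keep)
  # forced nodes: members of every maximal clique containing C1
  if (length(C1) == 1L) {
    common <- which(adj[C1, ])
  } else {
    common <- which(colSums(adj[C1, , drop = FALSE]) == length(C1))
  }
  common <- setdiff(common, C1)
  if (length(common) > 0L && length(common) <= closure_max) {
    if (length(common) == 1L) {
      C1 <- c(C1, common)
    } else {
      sub <- adj[common, common, drop = FALSE]
      forced <- common[rowSums(sub) == length(common) - 1L]
      C1 <- c(C1, forced)
    }
  }
  sort(C1)
}

#' Replica-exchange Monte Carlo search for a high-coverage clique
#'
#' A fallback for alignment graphs too large for the exact search.
#' `n_replicas` chains sample cliques at different temperatures with the
#' move generator of [remc_move()] and Metropolis acceptance on the energy
#' `-coverage` (number of aligned residues, the same monotone quantity the
#' exact search bounds); neighbouring-temperature replicas attempt a state
#' exchange every `exchange_every` sweeps. The best clique ever visited is
#' returned. Deterministic given `seed`.
#'
#' Default temperatures span acceptance probabilities of roughly 0.1 to 0.9
#' for a one-residue coverage drop, on a geometric ladder.
#'
#' @param graph an `ldal_graph`.
#' @param n_replicas number of parallel chains.
#' @param t_min,t_max temperature ladder end points.
#' @param exchange_every sweeps between exchange attempts.
#' @param total_moves total move attempts across all replicas.
#' @param seed RNG seed.
#' @return list with `nodes` (clique indices), `coverage`, and the
#'   per-replica final coverages (`replica_coverage`).
#' @export
remc_search <- function(graph, n_replicas = 8L,
                        t_min = 1 / log(10), t_max = 1 / log(10 / 9),
                        exchange_every = 100L, total_moves = 20000L,
                        seed = 1L) {
  m <- length(graph$nodes)
  if (m == 0)
    return(list(nodes = integer(0), coverage = 0L,
                replica_coverage = integer(0)))
  adj <- graph$adjacency
  keys <- lapply(graph$nodes, pair_keys)
  coverage_of <- function(C) {
    if (length(C) == 0L) return(0L)
    length(unique(unlist(keys[C])))
  }
  temps <- exp(seq(log(t_min), log(t_max), length.out = n_replicas))
  sweeps <- max(1L, as.integer(ceiling(total_moves / n_replicas)))

  with_preserved_rng(seed, {
    state <- replicate(n_replicas, integer(0), simplify = FALSE)
    cov <- integer(n_replicas)
    best <- integer(0)
    best_cov <- 0L
    for (sw in seq_len(sweeps)) {
      for (r in seq_len(n_replicas)) {
        prop <- remc_move(state[[r]], adj)
        pcov <- coverage_of(prop)
        d_e <- -(pcov - cov[r])
        if (d_e <= 0 || runif(1) < exp(-d_e / temps[r])) {
          state[[r]] <- prop
          cov[r] <- pcov
          if (pcov > best_cov) {
            best_cov <- pcov
            best <- prop
          }
        }
      }
      if (sw %% exchange_every == 0L && n_replicas > 1L) {
        for (r in seq_len(n_replicas - 1L)) {
          # energies are -coverage
          delta <- (1 / temps[r] - 1 / temps[r + 1L]) *
            ((-cov[r + 1L]) - (-cov[r]))
          if (delta <= 0 || runif(1) < exp(-delta)) {
            tmp <- state[[r]]; state[[r]] <- state[[r + 1L]]
            state[[r + 1L]] <- tmp
            tmpc <- cov[r]; cov[r] <- cov[r + 1L]; cov[r + 1L] <- tmpc
          }
        }
      }
    }
    list(nodes = sort(best), coverage = best_cov, replica_coverage = cov)
  })
}

# run code with a private RNG stream, restoring the caller's afterwards
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Align two protein structures
#'
#' The full three-stage pipeline. Stage one compares every descriptor of
#' the first structure against every descriptor of the second and splits
#' the valid descriptor alignments into building blocks (at least three
#' perceived segments on both sides) and extension material. Stage two
#' assembles building blocks into maximal consistent sets by exact clique
#' search -- unconstrained (`"ts+cts"`) or connectivity-constrained
#' (`"cts+cts"`) -- falling back to the replica-exchange Monte Carlo
#' sampler if the exact search exceeds `timeout_s`. Stage three extends
#' each retained alignment with overlapping extension blocks. Alignments
#' are ranked by score (aligned residues minus squared tension, after the
#' optional sequence-offset and swap filters) and the top `n_best`
#' mutually distinct ones are returned; two alignments are distinct when
#' they share at most half of the pairs of the smaller one.
#'
#' @param struct_a,struct_b `ldal_structure` objects.
#' @param mode `"ts+cts"` (unconstrained stage two) or `"cts+cts"`.
#' @param k maximal accepted sequence offset (`Inf` = sequence
#'   independent).
#' @param M maximal number of sequence swaps (`Inf` = unlimited).
#' @param offset_mode convention for measuring offsets when chain lengths
#'   differ; see [pair_offsets()].
#' @param n_best maximal number of alignments returned.
#' @param timeout_s stage-two budget in seconds before the Monte Carlo
#'   fallback takes over.
#' @param seed RNG seed (used by the fallback sampler).
#' @param remc_params optional list overriding [remc_search()] defaults.
#' @param distinct_max_shared two alignments are considered the same
#'   solution when the shared fraction of the smaller exceeds this.
#' @return list of `ldal_alignment` objects (possibly empty), each with
#'   the aligned pairs, score, aligned-residue count, tension, swap count
#'   and rigid-region decomposition.
#' @export
align_structures <- function(struct_a, struct_b,
                             mode = c("ts+cts", "cts+cts"),
                             k = Inf, M = Inf,
                             offset_mode = c("ungapped-closest",
                                             "gaps-in-shorter"),
                             n_best = 5L, timeout_s = 120,
                             seed = 1L, remc_params = list(),
                             distinct_max_shared = 0.5) {
  mode <- match.arg(mode)
  offset_mode <- match.arg(offset_mode)
  stopifnot(inherits(struct_a, "ldal_structure"),
            inherits(struct_b, "ldal_structure"),
            struct_a$n > 0, struct_b$n > 0)

  contacts_a <- find_contacts(struct_a)
  contacts_b <- find_contacts(struct_b)
  descs_a <- build_descriptors(struct_a, contacts_a)
  descs_b <- build_descriptors(struct_b, contacts_b)

  nodes <- compare_all_descriptors(descs_a, descs_b, struct_a, struct_b)
  parts <- partition_s3_s1(nodes)
  if (length(parts$s3) == 0) return(list())
  graph <- build_graph(dedupe_nodes(parts$s3), dedupe_nodes(parts$s1))

  ts <- tree_search(graph, n_best = n_best,
                    connectivity_required = (mode == "cts+cts"),
                    timeout_s = timeout_s)
  cliques <- ts$cliques
  if (ts$timed_out) {
    rp <- utils::modifyList(list(graph = graph, seed = seed), remc_params)
    mc <- do.call(remc_search, rp)
    if (length(mc$nodes))
      cliques <- list(list(nodes = mc$nodes, coverage = mc$coverage))
  }
  if (length(cliques) == 0) return(list())
  # only the best-coverage cliques are worth extending and scoring: the
  # tension penalty is bounded (rmsd thresholds are 2.5 A) so low-coverage
  # cliques cannot overtake after extension
  cliques <- head(cliques, max(3L * n_best, 15L))

  out <- list()
  for (cl in cliques) {
    ext <- extend_with_s1(graph$nodes[cl$nodes], graph$s1_pool)
    aln <- finalize_alignment(struct_a, struct_b, ext$members,
                              contacts_a, contacts_b,
                              k = k, M = M, offset_mode = offset_mode)
    if (!is.null(aln)) out[[length(out) + 1L]] <- aln
  }
  if (length(out) == 0) return(list())
  scores <- vapply(out, `[[`, numeric(1), "score")
  out <- out[order(-scores)]
  distinct_top(out, n_best, distinct_max_shared)
}

#' Compare all descriptors of one structure against all of another
#'
#' @param descs_a,descs_b descriptor lists from [build_descriptors()].
#' @param struct_a,struct_b the parent structures.
#' @return flat list of `ldal_desc_alignment` over all descriptor pairs.
#' @export
compare_all_descriptors <- function(descs_a, descs_b, struct_a, struct_b) {
  out <- list()
  for (da in descs_a) {
    for (db in descs_b) {
      res <- compare_descriptors(da, db, struct_a, struct_b)
      if (length(res)) out <- c(out, res)
    }
  }
  out
}

# identical residue-pair sets from different descriptor pairs would only
# inflate the graph; keep the lowest-rmsd representative
dedupe_nodes <- function(nodes) {
  if (length(nodes) <= 1) return(nodes)
  key <- vapply(nodes, function(a) paste(a$ia, a$ib, collapse = ";"),
                character(1))
  rms <- vapply(nodes, function(a) a$rmsd, numeric(1))
  ord <- order(key, rms)
  first <- ord[!duplicated(key[ord])]
  nodes[sort(first)]
}

distinct_top <- function(alns, n_best, max_shared) {
  sel <- list()
  for (a in alns) {
    akeys <- a$pairs$ia * 65536 + a$pairs$ib
    dup <- FALSE
    for (b in sel) {
      bkeys <- b$pairs$ia * 65536 + b$pairs$ib
      shared <- sum(akeys %in% bkeys)
      if (shared / min(length(akeys), length(bkeys)) > max_shared) {
        dup <- TRUE
        break
      }
    }
    if (!dup) sel[[length(sel) + 1L]] <- a
    if (length(sel) >= n_best) break
  }
  sel
}
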