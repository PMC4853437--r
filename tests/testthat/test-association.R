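test_that("half-weight index matches its definition on corner cases", {
  expect_equal(half_weight_index(2, 1, 1, 0), 2 / 3)
  expect_equal(half_weight_index(0, 3, 2, 5), 0)
  expect_equal(half_weight_index(4, 0, 0, 0), 1)
  expect_true(is.na(half_weight_index(0, 0, 0, 0)))
})

test_that("per-scan association is pairwise with an inclusive 1-m threshold", {
  scans <- make_scans(list(
    pos(a = c(3.5, 4.5), b = c(3.5, 5.5), c = c(4.5, 5.5))
  ))
  ed <- per_scan_associations(scans)
  # a-b at 1.0 m (associated), b-c at 1.0 m, a-c at sqrt(2) (not) -- no chaining
  expect_equal(nrow(ed), 2)
  expect_true(all(paste(ed$id_a, ed$id_b) %in% c("a b", "b c")))

  lone <- make_scans(list(pos(a = c(3, 3))))
  expect_equal(nrow(per_scan_associations(lone)), 0)
})

test_that("HWI matrices equal an independent dyad-by-dyad recount", {
  set.seed(42)
  for (rep in 1:6) {
    n_ind <- sample(3:5, 1)
    ids <- letters[seq_len(n_ind)]
    positions <- lapply(1:8, function(s) {
      p <- lapply(ids, function(i) {
        if (runif(1) < 0.25) c(NA_real_, NA_real_) else runif(2, 0, 4)
      })
      names(p) <- ids
      p
    })
    scans <- make_scans(positions)
    net <- association_network(scans)
    expect_equal(net$hwi, brute_hwi(scans, ids = net$ids))
  }
})

test_that("HWI is invariant to scan order and equivariant to labels", {
  set.seed(7)
  positions <- lapply(1:6, function(s) {
    p <- lapply(letters[1:4], function(i) runif(2, 0, 3))
    names(p) <- letters[1:4]
    p
  })
  scans <- make_scans(positions)
  net <- association_network(scans)

  shuffled <- scans[sample(nrow(scans)), ]
  net2 <- association_network(shuffled)
  expect_equal(net2$hwi, net$hwi)

  relabel <- c(a = "w", b = "x", c = "y", d = "z")
  scans3 <- dplyr::mutate(scans, individual = unname(relabel[individual]))
  net3 <- association_network(scans3)
  expect_equal(unname(net3$hwi), unname(net$hwi))
})

test_that("co-occurrence pairs everyone within 5 m of the door", {
  scans <- make_scans(list(
    pos(a = c(5.5, 4.5), b = c(6.5, 3.5), c = c(5.5, 8.0), d = c(5.5, 9.1))
  ))
  # a, b, c within 5 m of (5.5, 3.5); d at 5.6 m excluded
  net <- cooccurrence_network(scans)
  td <- tidy(net)
  expect_equal(sum(td$x), 3)                       # complete graph on {a,b,c}
  expect_equal(td$x[td$id_a == "a" & td$id_b == "d"], 0)

  far <- make_scans(list(pos(a = c(25, 25), b = c(25.5, 25.5))))
  expect_equal(sum(cooccurrence_network(far)$x), 0)
})

test_that("zone exclusion removes exactly the in-zone associations", {
  at_door <- make_scans(list(pos(a = c(5.5, 4.0), b = c(5.5, 4.5))))
  ex <- association_network(at_door, exclude_zone_radius = 5)
  expect_equal(sum(ex$x), 0)

  away <- make_scans(list(pos(a = c(20, 20), b = c(20, 20.5))))
  full <- association_network(away)
  ex2 <- association_network(away, exclude_zone_radius = 5)
  expect_equal(ex2$hwi, full$hwi)

  # mixed case: brute-force recount dropping scans' in-zone pairs
  set.seed(9)
  positions <- lapply(1:10, function(s) {
    p <- lapply(letters[1:4], function(i) c(runif(1, 3, 9), runif(1, 1, 7)))
    names(p) <- letters[1:4]
    p
  })
  scans <- make_scans(positions)
  ex3 <- association_network(scans, exclude_zone_radius = 5)
  ed <- per_scan_associations(scans)
  keep <- vapply(seq_len(nrow(ed)), function(k) {
    sc <- scans[scans$scan_id == ed$scan_id[k], ]
    da <- distance_to_door(sc$x[sc$individual == ed$id_a[k]],
                           sc$y[sc$individual == ed$id_a[k]])
    db <- distance_to_door(sc$x[sc$individual == ed$id_b[k]],
                           sc$y[sc$individual == ed$id_b[k]])
    !(da <= 5 && db <= 5)
  }, logical(1))
  expect_equal(sum(ex3$x) / 2, sum(keep))
})

test_that("within-scan permutation preserves per-scan degrees and edge counts", {
  set.seed(15)
  scans <- null_scan_table(n_ind = 8, n_scans = 12, side = 5)
  net <- association_network(scans)
  edge_mat <- cbind(match(net$edges$scan_id, net$scan_ids),
                    match(net$edges$id_a, net$ids),
                    match(net$edges$id_b, net$ids))
  storage.mode(edge_mat) <- "integer"
  den_vec <- t(net$den)[lower.tri(net$den)]
  for (rep in 1:5) {
    out <- scansoc:::assoc_perm_chain(edge_mat, length(net$scan_ids),
                                      length(net$ids), den_vec,
                                      10L, 50, 0, TRUE)
    fin <- out$edges
    expect_equal(nrow(fin), nrow(edge_mat))
    # per-scan edge count and per-individual degree preserved
    for (s in unique(edge_mat[, 1])) {
      before <- edge_mat[edge_mat[, 1] == s, , drop = FALSE]
      after <- fin[fin[, 1] == s, , drop = FALSE]
      expect_equal(nrow(after), nrow(before))
      expect_equal(tabulate(c(after[, 2], after[, 3]), 8),
                   tabulate(c(before[, 2], before[, 3]), 8))
      # simple graph: no duplicated edges, no self-loops
      expect_false(any(after[, 2] == after[, 3]))
      expect_false(any(duplicated(after[, 2:3, drop = FALSE])))
    }
  }
})

test_that("the association permutation test detects planted preferences", {
  set.seed(21)
  # two fixed pairs sit together in every scan; others drift at random
  positions <- lapply(1:25, function(s) {
    base <- runif(2, 3, 18)
    p <- list(
      a = base, b = base + c(0.3, 0),
      c = base + c(10, 5), d = base + c(10.3, 5),
      e = runif(2, 0, 28), f = runif(2, 0, 28)
    )
    p
  })
  scans <- make_scans(positions)
  net <- association_network(scans)
  res <- assoc_permutation_test(net, n_perm = 199, seed = 4)
  expect_lt(res$p, 0.01)

  res2 <- assoc_permutation_test(net, n_perm = 199, seed = 4)
  expect_identical(res$p, res2$p)          # determinism under seed

  # a network with a single association has nothing to permute
  one <- make_scans(list(pos(a = c(1, 1), b = c(1, 1.5))))
  net1 <- association_network(one)
  expect_warning(r1 <- assoc_permutation_test(net1, n_perm = 19), "no permutable")
  expect_equal(r1$p, 1)
})
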