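test_that("win matrix counts only dyadic, clear-outcome records", {
  ids <- c("a", "b", "c")
  rec <- dplyr::bind_rows(
    make_agonistic(c("a>b", "a>b", "a>b")),
    make_agonistic("b>c", n_participants = 3L),
    make_agonistic("c>a", clear = FALSE)
  )
  s <- build_win_matrix(rec, ids)
  expect_equal(s["a", "b"], 3L)
  expect_equal(sum(s), 3L)
  expect_equal(attr(s, "discarded")[["polyadic"]], 1L)
  expect_equal(attr(s, "discarded")[["unclear"]], 1L)

  empty <- build_win_matrix(rec[0, ], ids)
  expect_true(all(empty == 0))
})

test_that("dyadic dominance indices shrink win proportions toward chance", {
  s <- build_win_matrix(make_agonistic(c("a>b", "a>b", "a>b")), c("a", "b"))
  d <- dyadic_dominance_index(s)
  expect_equal(d["a", "b"], 0.875)      # P = 1 shrunk by 0.5/4
  expect_equal(d["b", "a"], 0.125)

  tied <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(dyadic_dominance_index(tied)["a", "b"], 0.5)

  none <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(all(dyadic_dominance_index(none) == 0))

  set.seed(5)
  for (i in 1:20) {
    s <- random_win_matrix(sample(3:8, 1))
    d <- dyadic_dominance_index(s)
    n <- s + t(s)
    interacting <- n > 0 & upper.tri(n)
    expect_equal((d + t(d))[interacting], rep(1, sum(interacting)))
  }
})

test_that("David's scores match the hand-worked dyad and always sum to zero", {
  s <- build_win_matrix(make_agonistic(c("a>b", "a>b", "a>b")), c("a", "b"))
  ds <- david_score(dyadic_dominance_index(s))
  # w_a = 0.875, w2_a = 0.875*0.125, l_a = 0.125, l2_a = 0.125*0.875
  expect_equal(unname(ds["a"]), 0.75)
  expect_equal(unname(ds["b"]), -0.75)

  tied <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(all(david_score(dyadic_dominance_index(tied)) == 0))

  set.seed(11)
  for (i in 1:50) {
    s <- random_win_matrix(sample(3:10, 1))
    expect_equal(sum(david_score(dyadic_dominance_index(s))), 0,
                 tolerance = 1e-12)
  }
})

test_that("scores are equivariant under relabelling of individuals", {
  set.seed(3)
  s <- random_win_matrix(6)
  ds <- david_score(dyadic_dominance_index(s))
  pi <- sample(6)
  s_perm <- s[pi, pi]
  ds_perm <- david_score(dyadic_dominance_index(s_perm))
  expect_equal(ds_perm, ds[pi])
})

test_that("linearity h and h' behave on canonical matrices", {
  ids <- letters[1:4]
  lin <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  lin[upper.tri(lin)] <- 3L     # a > b > c > d, every dyad decided
  res <- linearity_h_prime(lin, n_randomizations = 500, seed = 1)
  expect_equal(res$h, 1)
  expect_equal(res$h_prime, 1)
  # ranking from MDS equals the transitive order
  mds <- david_score(dyadic_dominance_index(lin))
  expect_equal(names(sort(mds, decreasing = TRUE)), ids)

  # with 8 individuals a perfect order is vanishingly rare under the null
  ids8 <- letters[1:8]
  lin8 <- matrix(0L, 8, 8, dimnames = list(ids8, ids8))
  lin8[upper.tri(lin8)] <- 2L
  res8 <- linearity_h_prime(lin8, n_randomizations = 500, seed = 1)
  expect_equal(res8$h_prime, 1)
  expect_lt(res8$p, 0.05)

  cyc <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cyc["a", "b"] <- cyc["b", "c"] <- cyc["c", "a"] <- 2L
  expect_equal(linearity_h_prime(cyc, n_randomizations = 100, seed = 1)$h, 0)

  unknown <- matrix(0L, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  res_u <- linearity_h_prime(unknown, n_randomizations = 500, seed = 1)
  expect_gt(res_u$p, 0.1)                       # complete ignorance: not significant
  expect_equal(res_u$h_prime, 3 / (5 + 1))      # the null expectation with all unknown

  expect_error(linearity_h_prime(matrix(0, 2, 2)), "fewer than 3")
})

test_that("the linearity randomization is reproducible under a seed", {
  set.seed(8)
  s <- random_win_matrix(7, p_known = 0.6)
  a <- linearity_h_prime(s, n_randomizations = 300, seed = 42)
  b <- linearity_h_prime(s, n_randomizations = 300, seed = 42)
  expect_identical(a, b)
})

test_that("dominance_hierarchy bundles scores, linearity and filter counts", {
  rec <- dplyr::bind_rows(
    make_agonistic(c("a>b", "b>c", "a>c", "a>b")),
    make_agonistic("a>c", n_participants = 3L)
  )
  dh <- dominance_hierarchy(rec, c("a", "b", "c"), n_randomizations = 200, seed = 1)
  expect_s3_class(tidy(dh), "tbl_df")
  expect_equal(glance(dh)$n_individuals, 3)
  expect_equal(unname(dh$discarded["polyadic"]), 1L)
  expect_equal(sum(dh$scores$MDS), 0, tolerance = 1e-12)
})
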