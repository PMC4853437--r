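test_that("permutation Pearson handles perfect, reversed and degenerate input", {
  x <- 1:10
  r <- perm_pearson(x, 2 * x + 1, alternative = "greater", n_perm = 199, seed = 1)
  expect_equal(r$observed, 1)
  expect_equal(r$p, 1 / 200)                       # minimal attainable p

  wrong_tail <- perm_pearson(x, -x, alternative = "greater",
                             n_perm = 199, seed = 1)
  expect_gt(wrong_tail$p, 0.95)

  expect_error(perm_pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(perm_pearson(1:2, 2:3), "at least 3")

  x2 <- rnorm(12); y2 <- rnorm(12)
  a <- perm_pearson(x2, y2, n_perm = 99, seed = 7)
  a2 <- perm_pearson(x2, y2, n_perm = 99, seed = 7)
  expect_identical(a$p, a2$p)                      # determinism under seed
})

test_that("permutation t-test is directional on factor level order", {
  v <- c(5, 6, 7, 1, 2, 3)
  g <- factor(c("M", "M", "M", "F", "F", "F"), levels = c("M", "F"))
  res <- perm_ttest(v, g, alternative = "greater", n_perm = 999, seed = 2)
  # complete separation: exact enumeration gives 3!3!/6! = 1/20
  expect_equal(res$p, 1 / 20, tolerance = 0.35)

  same <- perm_ttest(rep(c(1, 2), 4), factor(rep(c("A", "B"), each = 4)),
                     alternative = "greater", n_perm = 199, seed = 2)
  expect_equal(same$observed, 0)
  expect_gt(same$p, 0.5)

  expect_error(perm_ttest(1:4, factor(rep("A", 4))), "two groups")
})

test_that("attribute matrices encode distances, sex and matrilineal kinship", {
  ind <- tibble::tibble(
    id = c("a", "b", "c"),
    sex = c("F", "M", "F"),
    age = c(5, 8, 20),
    matriline = c("m1", "m1", "m2"),
    MDS = c(1, -2, 4)
  )
  am <- attribute_matrices(ind)
  expect_equal(am$age_dist["a", "b"], 3)
  expect_equal(am$mds_dist["b", "c"], 6)
  expect_equal(am$sex_same["a", "c"], 1)
  expect_equal(am$sex_same["a", "b"], 0)        # F-M pair
  expect_equal(am$kinship["a", "b"], 1)
  expect_equal(am$kinship["a", "c"], 0)

  ind$matriline[2] <- NA
  expect_warning(am2 <- attribute_matrices(ind), "singleton")
  expect_equal(sum(am2$kinship), 0)
})

test_that("Mantel correlation is exact on self and symmetric under relabels", {
  set.seed(13)
  a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
  b <- matrix(runif(36), 6); b <- (b + t(b)) / 2; diag(b) <- 0
  expect_equal(mantel_perm(a, a, n_perm = 19, seed = 1)$observed, 1)
  centered <- a - mean(a[row(a) != col(a)])
  expect_equal(mantel_perm(a, -centered, n_perm = 19, seed = 1)$observed, -1)
  expect_error(mantel_perm(a, matrix(1, 6, 6)), "constant")

  r_ab <- mantel_perm(a, b, n_perm = 99, seed = 5)$observed
  pi <- sample(6)
  expect_equal(mantel_perm(a[pi, pi], b[pi, pi], n_perm = 9, seed = 5)$observed,
               r_ab)
})

test_that("Mantel r agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  a <- as.matrix(dist(matrix(rnorm(16), 8)))
  b <- as.matrix(dist(matrix(rnorm(16), 8)))
  ours <- mantel_perm(a, b, n_perm = 19, seed = 1)$observed
  theirs <- vegan::mantel(a, b, permutations = 19)$statistic
  expect_equal(ours, unname(theirs), tolerance = 1e-12)
})

test_that("MRQAP-DSP recovers planted effects and flags collinearity", {
  set.seed(61)
  sim <- simulate_dyadic(n_individuals = 25, kin_effect = 1, sex_effect = 0)
  res <- mrqap_dsp(sim$y, sim$predictors, n_perm = 199, seed = 3)
  td <- tidy(res)
  expect_lt(td$p.value[td$term == "kinship"], 0.05)
  expect_equal(td$term, c("kinship", "sex_same"))
  expect_true(all(abs(td$partial_r) <= 1))

  # duplicated predictor must be named in the error
  expect_error(
    mrqap_dsp(sim$y, list(kin = sim$predictors$kinship,
                          kin2 = sim$predictors$kinship),
              n_perm = 19),
    "kin2"
  )
})

test_that("coefficients are invariant to simultaneous relabelling", {
  set.seed(67)
  sim <- simulate_dyadic(n_individuals = 12, kin_effect = 0.7, sex_effect = 0.4)
  res <- mrqap_dsp(sim$y, sim$predictors, n_perm = 9, seed = 1)
  pi <- sample(12)
  res_p <- mrqap_dsp(sim$y[pi, pi],
                     lapply(sim$predictors, function(m) m[pi, pi]),
                     n_perm = 9, seed = 1)
  expect_equal(tidy(res_p)$estimate, tidy(res)$estimate)
  expect_equal(tidy(res_p)$statistic, tidy(res)$statistic)
})

test_that("with one predictor, DSP equals plain QAP on the same seed stream", {
  set.seed(29)
  sim <- simulate_dyadic(n_individuals = 10, kin_effect = 0.5, sex_effect = 0)
  one <- mrqap_dsp(sim$y, sim$predictors["kinship"], n_perm = 199, seed = 11)
  # plain QAP: permute the predictor matrix itself (it equals its own
  # residual when there is nothing to partial out)
  x <- sim$predictors$kinship
  off <- row(x) != col(x)
  yy <- sim$y[off]
  tstat <- function(xv) {
    f <- summary(stats::lm(yy ~ xv))
    f$coefficients[2, "t value"]
  }
  t_obs <- tstat(x[off])
  set.seed(11)
  null <- vapply(1:199, function(i) {
    pi <- sample.int(10)
    xp <- x[pi, pi]
    tstat(xp[off])
  }, numeric(1))
  p_qap <- (1 + sum(abs(null) >= abs(t_obs))) / 200
  expect_equal(tidy(one)$statistic, t_obs, tolerance = 1e-10)
  expect_equal(tidy(one)$p.value, p_qap)
})

test_that("variance partition decomposes R2 and counts df correctly", {
  set.seed(41)
  n <- 40
  cont <- rnorm(n)
  cat7 <- factor(sample(paste0("g", 1:7), n, replace = TRUE))
  y_pure <- 2 * cont + rnorm(n, 0, 1e-8)
  vp <- variance_partition(y_pure, cont, cat7, n_perm = 99, seed = 1)
  td <- tidy(vp)
  expect_equal(td$df, c(1, 6, 7))               # 7-level categorical: Df = 6
  expect_gt(td$semipartial_r2[1], 0.9)
  expect_lt(td$semipartial_r2[2], 0.05)
  expect_lt(td$p.value[1], 0.05)

  # orthogonal blocks: semipartials sum to the full R2
  cont_o <- rnorm(n)
  g <- factor(rep(c("A", "B"), each = n / 2))
  xg <- as.numeric(g == "B")
  cont_o <- residuals(lm(cont_o ~ xg))          # orthogonalise by construction
  y <- cont_o + 2 * xg + rnorm(n)
  vp2 <- variance_partition(y, cont_o, g, n_perm = 9, seed = 1)
  td2 <- tidy(vp2)
  full_r2 <- glance(vp2)$r.squared
  expect_equal(unname(td2$semipartial_r2[1] + td2$semipartial_r2[2]),
               unname(full_r2), tolerance = 1e-10)

  expect_error(variance_partition(rnorm(5), rnorm(5),
                                  factor(c("a", "b", "c", "d", "e"))),
               "too few")
})

test_that("residual-permutation mode runs and agrees on the observed table", {
  set.seed(43)
  n <- 30
  cont <- rnorm(n)
  g <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  y <- cont + rnorm(n)
  a <- variance_partition(y, cont, g, n_perm = 49, seed = 2)
  b <- variance_partition(y, cont, g, permute = "residuals",
                          n_perm = 49, seed = 2)
  expect_equal(tidy(b)$semipartial_r2, tidy(a)$semipartial_r2)
  expect_equal(tidy(b)$df, tidy(a)$df)
})

test_that("homoscedasticity report returns finite diagnostics", {
  set.seed(47)
  n <- 36
  cont <- rnorm(n)
  g <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  y <- cont + rnorm(n)
  rep_tbl <- homoscedasticity_report(y, cont, g)
  expect_equal(rep_tbl$test, c("Bartlett", "Breusch-Pagan"))
  expect_true(all(is.finite(rep_tbl$statistic)))
  expect_true(all(rep_tbl$p.value >= 0 & rep_tbl$p.value <= 1))
})
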