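test_that("the default synthetic population matches the study composition", {
  set.seed(1)
  pop <- generate_population(sim_config())
  expect_equal(nrow(pop$individuals), 39)
  expect_equal(sum(pop$individuals$sex == "M"), 21)
  expect_equal(sum(pop$individuals$sex == "F"), 18)
  expect_true(all(pop$individuals$age >= 5 & pop$individuals$age <= 26))
  expect_true(all(is.finite(pop$truth$latent_dominance)))
  expect_setequal(pop$truth$individual, pop$individuals$id)
})

test_that("tiny configurations degenerate sensibly", {
  set.seed(2)
  pop <- generate_population(sim_config(n_individuals = 3, n_males = 1,
                                        n_matrilines = 1, n_subgroups = 1))
  expect_equal(length(unique(pop$individuals$matriline)), 1)  # all kin
  am <- attribute_matrices(pop$individuals)
  expect_true(all(am$kinship[upper.tri(am$kinship)] == 1))
})

test_that("simulation is deterministic under a seed", {
  cfg <- sim_config(n_days = 2)
  a <- simulate_study(cfg, seed = 9)
  b <- simulate_study(cfg, seed = 9)
  expect_identical(a$scans, b$scans)
  expect_identical(a$agonistic, b$agonistic)
  expect_identical(a$truth, b$truth)
})

test_that("afternoon attendance exceeds morning attendance", {
  st <- simulate_study(sim_config(n_days = 6), seed = 5)
  att <- st$scans |>
    dplyr::group_by(scan_id, period) |>
    dplyr::summarise(n = sum(visible), .groups = "drop") |>
    dplyr::group_by(period) |>
    dplyr::summarise(mean_n = mean(n))
  expect_gt(att$mean_n[att$period == "pm"], att$mean_n[att$period == "am"])
})

test_that("solo positions put higher latent dominance closer to the door", {
  cfg <- sim_config(n_days = 6, subgroup_cohesion = 1)  # solo positions only
  st <- simulate_study(cfg, seed = 7)
  vis <- dplyr::filter(st$scans, visible)
  mean_d <- vis |>
    dplyr::mutate(d = distance_to_door(x, y)) |>
    dplyr::group_by(individual) |>
    dplyr::summarise(d = mean(d))
  z <- st$truth$latent_dominance[match(mean_d$individual, st$truth$individual)]
  expect_lt(cor(mean_d$d, z), -0.5)
})

test_that("generated tables are schema-valid and round-trip through disk", {
  st <- simulate_study(sim_config(n_days = 1), seed = 3)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  scans <- read_scan_table(file.path(dir, "scans.csv"),
                           individuals = read_individuals(file.path(dir, "individuals.csv")))
  ago <- read_agonistic_table(file.path(dir, "agonistic.csv"))
  expect_equal(nrow(scans), nrow(st$scans))
  expect_equal(nrow(ago), nrow(st$agonistic))
  expect_equal(sort(unique(scans$individual)), sort(st$individuals$id))
})

test_that("injected polyadic and unclear records are exactly the discarded ones", {
  st <- simulate_study(sim_config(n_days = 4), seed = 13)
  injected <- attr(st$agonistic, "injected")
  s <- build_win_matrix(st$agonistic, st$individuals$id)
  discarded <- attr(s, "discarded")
  expect_equal(unname(discarded["polyadic"]), unname(injected["polyadic"]))
  expect_equal(unname(discarded["unclear"]), unname(injected["unclear"]))
  expect_equal(sum(s), nrow(st$agonistic) - sum(injected))
})

test_that("a steep hierarchy yields near-deterministic transitive outcomes", {
  # small group so every dyad is decided within the simulated study
  cfg <- sim_config(n_individuals = 12, n_males = 6, n_matrilines = 3,
                    n_subgroups = 3, n_days = 6, hierarchy_steepness = 50)
  st <- simulate_study(cfg, seed = 17)
  s <- build_win_matrix(st$agonistic, st$individuals$id)
  # in the deterministic limit upsets are (almost) absent
  z <- st$truth$latent_dominance[match(rownames(s), st$truth$individual)]
  upsets <- sum(s[outer(z, z, "<")])
  expect_lt(upsets / sum(s), 0.02)
  h <- linearity_h_prime(s, n_randomizations = 100, seed = 1)
  expect_gt(h$h_prime, 0.9)
})

test_that("zero steepness decouples wins from the latent scale", {
  cfg <- sim_config(n_days = 4, hierarchy_steepness = 0)
  st <- simulate_study(cfg, seed = 19)
  s <- build_win_matrix(st$agonistic, st$individuals$id)
  mds <- david_score(dyadic_dominance_index(s))
  z <- st$truth$latent_dominance[match(names(mds), st$truth$individual)]
  expect_lt(abs(cor(mds, z, method = "spearman")), 0.35)
})

test_that("dyadic simulator composes planted effects symmetrically", {
  set.seed(23)
  sim <- simulate_dyadic(n_individuals = 15, kin_effect = 2, sex_effect = 1)
  expect_true(isSymmetric(sim$y))
  expect_true(all(diag(sim$y) == 0))
  off <- row(sim$y) != col(sim$y)
  kin <- sim$predictors$kinship[off] == 1
  expect_gt(mean(sim$y[off][kin]), mean(sim$y[off][!kin]))
})
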