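#' Simulation configuration
#'
#' Parameters of the synthetic scan-sampling study. Defaults emulate the
#' design the analysis assumes: 39 adults (21 males, 18 females, ages
#' 5--26 y), 26 scans per day (13 morning + 13 afternoon at 15-min
#' intervals) over 24 observation days, higher afternoon attendance, a
#' feeding-zone door whose attraction increases with latent dominance,
#' matriline- and sex-assortative 1-m associations organised into planted
#' subgroups, and agonistic outcomes driven by a latent dominance scale.
#'
#' @param n_individuals group size after juvenile exclusion.
#' @param n_males number of males (`n_individuals - n_males` females).
#' @param age_range inclusive age bounds in years (uniform draw).
#' @param n_matrilines number of maternal lines.
#' @param n_subgroups number of planted affiliative subgroups.
#' @param kin_subgroup_alignment probability that an individual joins the
#'   subgroup its matriline maps to (rather than a random one).
#' @param n_days observation days.
#' @param attendance_prob_am,attendance_prob_pm per-scan probability of
#'   being visible in the observation area (afternoon must be at least the
#'   morning value to emulate the stronger afternoon attendance).
#' @param door door centroid (metres).
#' @param grid side of the square observation area (metres).
#' @param base_door_distance mean door distance (m) of a solo, average-
#'   dominance animal.
#' @param door_attraction_slope reduction of expected door distance (m)
#'   per SD of latent dominance; 0 removes the dominance-space link.
#' @param position_sd positional spread (m) for solo, door-attracted draws.
#' @param subgroup_cohesion odds multiplier for clustering with one's
#'   subgroup; the per-scan clustering probability is
#'   `1 - 1/subgroup_cohesion` (1 = no subgroup structure).
#' @param subgroup_sd spread (m) of a subgroup cluster around its anchor;
#'   kept below the 1-m association threshold scale.
#' @param anchor_distance_range door-distance range (m) over which subgroup
#'   home anchors are spread, ordered by subgroup mean latent dominance
#'   (dominant subgroups rest nearer the feeding zone).
#' @param kin_association_boost odds multiplier tightening same-matriline
#'   pairs within a cluster (1 = no kin effect).
#' @param sex_dominance_effect,age_dominance_slope,dominance_noise_sd
#'   latent dominance model: `z = effect * (sex == M) + slope * age +
#'   N(0, noise)`.
#' @param hierarchy_steepness logistic slope of win probability on the
#'   latent dominance difference; 0 gives coin-flip outcomes.
#' @param interactions_per_day dyadic agonistic events per day.
#' @param polyadic_rate,unclear_rate injection rates of records that the
#'   hierarchy filters must discard.
#' @return named list of class `scansoc_sim_config`.
#' @export
sim_config <- function(n_individuals = 39,
                       n_males = 21,
                       age_range = c(5, 26),
                       n_matrilines = 8,
                       n_subgroups = 8,
                       kin_subgroup_alignment = 0.75,
                       n_days = 24,
                       attendance_prob_am = 0.35,
                       attendance_prob_pm = 0.60,
                       door = c(5.5, 3.5),
                       grid = 30,
                       base_door_distance = 16,
                       door_attraction_slope = 3,
                       position_sd = 4,
                       subgroup_cohesion = 3,
                       subgroup_sd = 0.45,
                       anchor_distance_range = c(6, 24),
                       kin_association_boost = 2,
                       sex_dominance_effect = 2,
                       age_dominance_slope = 0.15,
                       dominance_noise_sd = 1,
                       hierarchy_steepness = 1.5,
                       interactions_per_day = 100,
                       polyadic_rate = 0.05,
                       unclear_rate = 0.05) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_individuals >= 3,
    cfg$n_males >= 0, cfg$n_males <= cfg$n_individuals,
    cfg$attendance_prob_am >= 0, cfg$attendance_prob_pm <= 1,
    cfg$attendance_prob_am <= cfg$attendance_prob_pm,
    cfg$subgroup_cohesion >= 1, cfg$kin_association_boost >= 1,
    cfg$polyadic_rate >= 0, cfg$polyadic_rate < 1,
    cfg$unclear_rate >= 0, cfg$unclear_rate < 1
  )
  structure(cfg, class = "scansoc_sim_config")
}

#' Generate a synthetic population with latent social structure
#'
#' Draws individuals (id, sex, age, matriline), a latent dominance score
#' (`z = sex effect + age slope + noise`, so males and older animals rank
#' higher on average, as the analysis assumes), and planted subgroup
#' labels aligned with matrilines so that kin tend to share a subgroup.
#'
#' @param config a [sim_config()].
#' @return list with `individuals` (tibble `id, sex, birth_date, age,
#'   matriline`) and `truth` (tibble `individual, latent_dominance,
#'   subgroup, matriline`).
#' @export
generate_population <- function(config = sim_config()) {
  n <- config$n_individuals
  ids <- sprintf("ind%02d", seq_len(n))
  sex <- sample(c(rep("M", config$n_males), rep("F", n - config$n_males)))
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  matriline <- sprintf("mat%02d", sample.int(config$n_matrilines, n, replace = TRUE))
  z <- config$sex_dominance_effect * (sex == "M") +
    config$age_dominance_slope * age +
    stats::rnorm(n, 0, config$dominance_noise_sd)

  mat_to_sub <- sample.int(config$n_subgroups,
                           config$n_matrilines, replace = TRUE)
  sub <- ifelse(
    stats::runif(n) < config$kin_subgroup_alignment,
    mat_to_sub[as.integer(sub("mat", "", matriline))],
    sample.int(config$n_subgroups, n, replace = TRUE)
  )
  sub <- as.integer(factor(sub))  # drop empty labels

  list(
    individuals = tibble::tibble(
      id = ids, sex = sex,
      birth_date = as.Date("2012-04-01") - round(age * 365.25),
      age = age, matriline = matriline
    ),
    truth = tibble::tibble(
      individual = ids,
      latent_dominance = z,
      subgroup = sprintf("G%d", sub),
      matriline = matriline
    )
  )
}

#' Generate a synthetic scan table
#'
#' Per scheduled scan, each individual attends (is visible in the
#' observation area) with a period-dependent probability; non-attendees
#' are recorded out of sight. An attendee either clusters with its planted
#' subgroup -- all present members placed around a per-scan subgroup
#' anchor, same-matriline members drawn even closer together -- or takes a
#' solo position whose expected distance to the feeding-zone door
#' decreases with its latent dominance (positions drawn on a random
#' bearing from the door at a truncated-normal distance, clipped to the
#' observation square).
#'
#' @param population output of [generate_population()].
#' @param config a [sim_config()].
#' @return validated scan tibble (one row per scan x individual).
#' @export
generate_scans <- function(population, config = sim_config()) {
  sched <- scan_schedule()
  n <- config$n_individuals
  ids <- population$individuals$id
  z_std <- as.numeric(scale(population$truth$latent_dominance))
  sub <- population$truth$subgroup
  mat <- population$truth$matriline
  p_cluster <- 1 - 1 / config$subgroup_cohesion
  p_kin <- 1 - 1 / config$kin_association_boost
  subgroups <- sort(unique(sub))
  # Study-long home anchor per subgroup. Anchor distance to the door is
  # ranked by subgroup mean latent dominance (dominant subgroups rest
  # nearer the feeding zone, subordinate ones at the periphery), with
  # noise; bearing is drawn by rejection so the anchor stays off the walls.
  mean_z <- tapply(z_std, sub, mean)[subgroups]
  dranks <- rank(-mean_z, ties.method = "first")
  k_sub <- length(subgroups)
  target_d <- config$anchor_distance_range[1] +
    (dranks - 1) / max(1, k_sub - 1) * diff(config$anchor_distance_range) +
    stats::rnorm(k_sub, 0, 2)
  target_d <- pmax(2, target_d)
  base_anchor <- matrix(NA_real_, k_sub, 2, dimnames = list(subgroups, NULL))
  for (gi in seq_len(k_sub)) {
    repeat {
      theta <- stats::runif(1, 0, 2 * pi)
      ax <- config$door[1] + target_d[gi] * cos(theta)
      ay <- config$door[2] + target_d[gi] * sin(theta)
      if (ax >= 2 && ax <= config$grid - 2 && ay >= 2 && ay <= config$grid - 2) {
        base_anchor[gi, ] <- c(ax, ay)
        break
      }
    }
  }
  clip <- function(v) pmin(pmax(v, 0.1), config$grid - 0.1)

  rows <- vector("list", config$n_days * nrow(sched))
  scan_id <- 0L
  for (day in seq_len(config$n_days)) {
    date <- as.Date("2012-04-01") + (day - 1)
    for (k in seq_len(nrow(sched))) {
      scan_id <- scan_id + 1L
      p_att <- if (sched$period[k] == "am") config$attendance_prob_am else config$attendance_prob_pm
      here <- stats::runif(n) < p_att
      x <- rep(NA_real_, n)
      y <- rep(NA_real_, n)
      if (any(here)) {
        clustered <- here & (stats::runif(n) < p_cluster)
        solo <- here & !clustered
        if (any(clustered)) {
          anchor <- base_anchor + matrix(stats::rnorm(2 * nrow(base_anchor), 0, 2),
                                         ncol = 2)
          for (g in subgroups) {
            members <- which(clustered & sub == g)
            if (!length(members)) next
            gx <- anchor[g, 1] + stats::rnorm(length(members), 0, config$subgroup_sd)
            gy <- anchor[g, 2] + stats::rnorm(length(members), 0, config$subgroup_sd)
            # kin tightening: co-present matriline mates collapse toward
            # a shared point with the boost probability
            for (ml in unique(mat[members])) {
              kin <- members[mat[members] == ml]
              if (length(kin) >= 2 && stats::runif(1) < p_kin) {
                i <- match(kin, members)
                cx <- mean(gx[i]); cy <- mean(gy[i])
                gx[i] <- cx + stats::rnorm(length(i), 0, 0.25)
                gy[i] <- cy + stats::rnorm(length(i), 0, 0.25)
              }
            }
            x[members] <- clip(gx)
            y[members] <- clip(gy)
          }
        }
        if (any(solo)) {
          idx <- which(solo)
          mu <- config$base_door_distance - config$door_attraction_slope * z_std[idx]
          r <- pmax(0.3, stats::rnorm(length(idx), mu, config$position_sd))
          theta <- stats::runif(length(idx), 0, 2 * pi)
          x[idx] <- clip(config$door[1] + r * cos(theta))
          y[idx] <- clip(config$door[2] + r * sin(theta))
        }
      }
      rows[[scan_id]] <- tibble::tibble(
        scan_id = scan_id, date = date, time = sched$time[k],
        individual = ids, x = x, y = y, visible = here
      )
    }
  }
  validate_scan_table(dplyr::bind_rows(rows), individuals = population$individuals,
                      grid = config$grid)
}

#' Generate a synthetic agonistic log
#'
#' Samples dyads uniformly each day; the higher-latent-dominance animal
#' wins with probability `plogis(steepness * (z_i - z_j))`. Polyadic
#' (`n_participants = 3`) and unclear-outcome records are injected at the
#' configured rates to exercise the hierarchy filters.
#'
#' @inheritParams generate_scans
#' @return validated agonistic tibble; the number of injected polyadic and
#'   unclear records is attached as the `"injected"` attribute.
#' @export
generate_agonistic <- function(population, config = sim_config()) {
  n <- config$n_individuals
  ids <- population$individuals$id
  z <- population$truth$latent_dominance
  total <- config$n_days * config$interactions_per_day
  i <- sample.int(n, total, replace = TRUE)
  j <- sample.int(n - 1, total, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)                      # j != i, uniform dyads
  p_win <- stats::plogis(config$hierarchy_steepness * (z[i] - z[j]))
  i_wins <- stats::runif(total) < p_win
  actor <- ifelse(i_wins, i, j)
  receiver <- ifelse(i_wins, j, i)
  day <- rep(seq_len(config$n_days), each = config$interactions_per_day)
  hours <- sample(c(stats::runif(total, 9, 12), stats::runif(total, 15, 18)), total)
  polyadic <- stats::runif(total) < config$polyadic_rate
  unclear <- !polyadic & stats::runif(total) < config$unclear_rate
  rec <- tibble::tibble(
    timestamp = as.POSIXct(sprintf("2012-04-%02d", pmin(day, 30)),
                           tz = "UTC") + round(hours * 3600),
    actor = ids[actor],
    receiver = ids[receiver],
    behavior = sample(sprintf("B%02d", 1:13), total, replace = TRUE),
    n_participants = ifelse(polyadic, 3L, 2L),
    clear_outcome = !unclear
  )
  out <- validate_agonistic_table(rec)
  attr(out, "injected") <- c(polyadic = sum(polyadic), unclear = sum(unclear))
  out
}

#' Simulate a complete synthetic study
#'
#' Population, scan table and agonistic log in one deterministic draw.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the whole study is reproducible from it.
#' @return list with `individuals`, `scans`, `agonistic`, `truth`,
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  pop <- generate_population(config)
  scans <- generate_scans(pop, config)
  agonistic <- generate_agonistic(pop, config)
  list(individuals = pop$individuals, scans = scans, agonistic = agonistic,
       truth = pop$truth, config = config, seed = seed)
}

#' Simulate dyadic data with planted kinship and sex effects
#'
#' Small generator for checking matrix-regression methods: draws sexes and
#' matrilines for `n_individuals`, builds the binary same-sex and kinship
#' matrices, and composes a symmetric response
#' `Y = kin_effect * kinship + sex_effect * sex_same + noise` with iid
#' symmetric Gaussian noise. Effect sizes of 0 give a pure null.
#'
#' @param n_individuals group size.
#' @param kin_effect,sex_effect additive effects on the dyadic response.
#' @param noise_sd standard deviation of the dyadic noise.
#' @param n_matrilines number of maternal lines.
#' @return list with `y` (response matrix) and `predictors` (named list of
#'   `kinship`, `sex_same` matrices).
#' @export
simulate_dyadic <- function(n_individuals = 30, kin_effect = 0.5,
                            sex_effect = 0.5, noise_sd = 1,
                            n_matrilines = 6) {
  ind <- tibble::tibble(
    id = sprintf("d%02d", seq_len(n_individuals)),
    sex = sample(c("F", "M"), n_individuals, replace = TRUE),
    age = stats::runif(n_individuals, 5, 26),
    matriline = sprintf("m%d", sample.int(n_matrilines, n_individuals,
                                          replace = TRUE))
  )
  am <- attribute_matrices(ind)
  noise <- matrix(stats::rnorm(n_individuals^2, 0, noise_sd), n_individuals)
  noise <- (noise + t(noise)) / sqrt(2)
  y <- kin_effect * am$kinship + sex_effect * am$sex_same + noise
  diag(y) <- 0
  dimnames(y) <- list(ind$id, ind$id)
  list(y = y, predictors = list(kinship = am$kinship, sex_same = am$sex_same))
}

#' Write a simulated study to disk
#'
#' Emits `scans.csv`, `agonistic.csv`, `individuals.csv` (consumable
#' unchanged by the readers in this package) and `truth.json` (latent
#' state, for recovery checks).
#'
#' @param study output of [simulate_study()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_scan_table(study$scans, file.path(dir, "scans.csv"))
  readr::write_csv(study$agonistic, file.path(dir, "agonistic.csv"))
  readr::write_csv(study$individuals, file.path(dir, "individuals.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
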