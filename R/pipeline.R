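#' Pipeline configuration
#'
#' Every analysis choice is a named key with the study-design value as
#' default: buffer radii around the feeding-zone door, the 1-m association
#' threshold, the afternoon-only window for spatial frequencies, the
#' juvenile age cutoff, permutation counts and the master seed.
#'
#' @param door door centroid (metres).
#' @param r_near,r_far near/far buffer radii (m) for F10M / F20M.
#' @param assoc_threshold dyadic association distance (m).
#' @param cooccur_radius co-occurrence radius around the door (m).
#' @param spatial_period period for spatial frequencies (`"pm"`).
#' @param assoc_period scans feeding the affiliative network (`"all"`).
#' @param min_age juvenile exclusion cutoff (years, inclusive).
#' @param subadult_range inclusive subadult bounds for age imputation.
#' @param n_perm permutations for every hypothesis-level test.
#' @param n_randomizations randomizations for the h' linearity test.
#' @param assoc_n_perm,assoc_swaps_per_perm within-scan permutation test
#'   size; `NULL` swaps default to 100 x the association count.
#' @param varpart_permute `"response"` or `"residuals"`.
#' @param seed master seed; stage seeds are derived from it.
#' @return named list of class `scansoc_config`.
#' @export
pipeline_config <- function(door = c(5.5, 3.5), r_near = 10, r_far = 20,
                            assoc_threshold = 1, cooccur_radius = 5,
                            spatial_period = "pm", assoc_period = "all",
                            min_age = 5, subadult_range = c(5, 7),
                            n_perm = 10000, n_randomizations = 10000,
                            assoc_n_perm = 1000, assoc_swaps_per_perm = NULL,
                            varpart_permute = "response", seed = 1) {
  structure(as.list(environment()), class = "scansoc_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis from the three input tables:
#' age imputation and juvenile exclusion; afternoon spatial frequencies
#' around the feeding-zone door; the dominance hierarchy (MDS, h');
#' the 1-m affiliative HWI network, its within-scan permutation test and
#' subgroup partition; the 5-m co-occurrence network; and the three
#' hypothesis blocks:
#'
#' * **H1** -- one-tailed permutation Pearson correlations of SRF10M
#'   (positive alternative) and F20M (negative) with MDS.
#' * **H2** -- variance partitions of SRF10M and F20M on MDS + subgroup
#'   dummies, with semipartial r-squared per block.
#' * **H3** -- MRQAP-DSP of the co-occurrence HWI on MDS distance,
#'   kinship, age distance and sex similarity; a Mantel test of the
#'   co-occurrence network against the zone-excluded affiliative network;
#'   and the percentage of co-occurrence dyads also associated elsewhere.
#'
#' Individuals with no decided agonistic interaction have no dominance
#' score and are dropped from score-based analyses (reported in the log).
#'
#' @param scans,agonistic,individuals validated input tibbles (see
#'   [read_scan_table()], [read_agonistic_table()], [read_individuals()]).
#' @param config a [pipeline_config()].
#' @return An object of class `scansoc_report`; a list with elements
#'   `inputs` (record counts after each filter), `spatial`, `dominance`,
#'   `affiliative`, `assoc_test`, `communities`, `cooccurrence`,
#'   `preliminary`, `H1`, `H2`, `H3`, `provenance`.
#' @export
run_pipeline <- function(scans, agonistic, individuals,
                         config = pipeline_config()) {
  log <- list()
  seed <- config$seed

  # --- filters -------------------------------------------------------
  individuals <- impute_missing_ages(individuals,
                                     subadult_range = config$subadult_range)
  included <- apply_study_filters(individuals, min_age = config$min_age)
  ids <- sort(included$id)
  scans <- dplyr::filter(scans, .data$individual %in% ids)
  log$n_individuals <- length(ids)
  log$n_excluded_juveniles <- nrow(attr(included, "excluded"))
  log$n_scans <- length(unique(scans$scan_id))

  # --- spatial metrics (afternoon) -----------------------------------
  spatial <- spatial_frequencies(scans, door = config$door,
                                 r_near = config$r_near, r_far = config$r_far,
                                 period = config$spatial_period)

  # --- dominance -----------------------------------------------------
  dom <- dominance_hierarchy(agonistic, ids,
                             n_randomizations = config$n_randomizations,
                             seed = seed + 1L)
  interacting <- rowSums(dom$win_matrix + t(dom$win_matrix)) > 0
  scores <- dom$scores
  scores$MDS[!interacting[scores$individual]] <- NA_real_
  log$n_missing_mds <- sum(!interacting)
  log$discarded_agonistic <- dom$discarded

  # --- affiliative network, nonrandomness, subgroups -----------------
  affil <- association_network(scans, ids = ids,
                               threshold = config$assoc_threshold,
                               period = config$assoc_period,
                               door = config$door)
  assoc_test <- assoc_permutation_test(affil, n_perm = config$assoc_n_perm,
                                       swaps_per_perm = config$assoc_swaps_per_perm,
                                       seed = seed + 2L)
  comm <- newman_communities(affil)

  # --- co-occurrence and zone-excluded affiliative networks ----------
  cooc <- cooccurrence_network(scans, ids = ids, door = config$door,
                               radius = config$cooccur_radius, period = "pm")
  affil_nozone <- association_network(scans, ids = ids,
                                      threshold = config$assoc_threshold,
                                      period = config$assoc_period,
                                      exclude_zone_radius = config$cooccur_radius,
                                      door = config$door)

  # --- assemble the per-individual analysis frame --------------------
  frame <- included |>
    dplyr::left_join(scores, by = c(id = "individual")) |>
    dplyr::left_join(spatial, by = c(id = "individual")) |>
    dplyr::left_join(comm$assignment, by = c(id = "individual")) |>
    dplyr::arrange(.data$id)

  # --- preliminary: hierarchy structure ------------------------------
  preliminary <- list(
    mds_by_sex = perm_ttest(frame$MDS,
                            factor(frame$sex, levels = c("M", "F")),
                            alternative = "greater",
                            n_perm = config$n_perm, seed = seed + 3L),
    mds_age = perm_pearson(frame$age, frame$MDS, alternative = "greater",
                           n_perm = config$n_perm, seed = seed + 4L),
    mds_age_males = perm_pearson(frame$age[frame$sex == "M"],
                                 frame$MDS[frame$sex == "M"],
                                 alternative = "greater",
                                 n_perm = config$n_perm, seed = seed + 5L),
    mds_age_females = perm_pearson(frame$age[frame$sex == "F"],
                                   frame$MDS[frame$sex == "F"],
                                   alternative = "greater",
                                   n_perm = config$n_perm, seed = seed + 6L),
    homoscedasticity = list(
      SRF10M = homoscedasticity_report(frame$SRF10M, frame$MDS, frame$subgroup),
      F20M = homoscedasticity_report(frame$F20M, frame$MDS, frame$subgroup)
    )
  )

  # --- H1: spatial frequency ~ dominance -----------------------------
  h1 <- list(
    srf10m_mds = perm_pearson(frame$SRF10M, frame$MDS,
                              alternative = "greater",
                              n_perm = config$n_perm, seed = seed + 7L),
    f20m_mds = perm_pearson(frame$F20M, frame$MDS, alternative = "less",
                            n_perm = config$n_perm, seed = seed + 8L)
  )

  # --- H2: variance partitions (Table-1 layout) ----------------------
  h2 <- list(
    SRF10M = variance_partition(frame$SRF10M, frame$MDS, frame$subgroup,
                                permute = config$varpart_permute,
                                n_perm = config$n_perm, seed = seed + 9L),
    F20M = variance_partition(frame$F20M, frame$MDS, frame$subgroup,
                              permute = config$varpart_permute,
                              n_perm = config$n_perm, seed = seed + 10L)
  )

  # --- H3: co-occurrence ~ dominance distance ------------------------
  model_ids <- frame$id[!is.na(frame$MDS)]
  attrs <- attribute_matrices(dplyr::filter(frame, !is.na(.data$MDS)))
  h3_mrqap <- mrqap_dsp(
    zero_na(cooc$hwi)[model_ids, model_ids],
    predictors = list(
      mds_dist = attrs$mds_dist,
      kinship = attrs$kinship,
      age_dist = attrs$age_dist,
      sex_same = attrs$sex_same
    ),
    n_perm = config$n_perm, seed = seed + 11L
  )
  h3 <- list(
    mrqap = h3_mrqap,
    mantel = mantel_perm(zero_na(cooc$hwi), zero_na(affil_nozone$hwi),
                         alternative = "greater",
                         n_perm = config$n_perm, seed = seed + 12L),
    overlap = overlap_percentage(cooc, affil_nozone)
  )

  structure(
    list(
      inputs = log,
      frame = frame,
      spatial = spatial,
      dominance = dom,
      affiliative = affil,
      assoc_test = assoc_test,
      communities = comm,
      cooccurrence = cooc,
      affiliative_nozone = affil_nozone,
      preliminary = preliminary,
      H1 = h1, H2 = h2, H3 = h3,
      provenance = list(seed = seed, n_perm = config$n_perm,
                        config = unclass(config))
    ),
    class = "scansoc_report"
  )
}

# replace NA (undefined HWI / diagonal) by 0 for matrix-level statistics
zero_na <- function(m) {
  m[is.na(m)] <- 0
  m
}

#' Overlap between two binarised association networks
#'
#' Binarises both networks (`HWI > 0`) and reports the percentage of the
#' first network's dyads that are also associated in the second --- e.g.
#' how many of the dyads co-occurring at the food patch also associate in
#' the rest of the area.
#'
#' @param net_zone,net_elsewhere `scansoc_assoc` objects on the same
#'   individuals.
#' @return percentage in `[0, 100]`; `NA` (with a warning) when the first
#'   network has no dyads.
#' @export
overlap_percentage <- function(net_zone, net_elsewhere) {
  stopifnot(identical(net_zone$ids, net_elsewhere$ids))
  ut <- upper.tri(net_zone$hwi)
  a <- !is.na(net_zone$hwi[ut]) & net_zone$hwi[ut] > 0
  b <- !is.na(net_elsewhere$hwi[ut]) & net_elsewhere$hwi[ut] > 0
  if (!any(a)) {
    warning("no associated dyads in the zone network; overlap undefined")
    return(NA_real_)
  }
  100 * sum(a & b) / sum(a)
}

#' @export
print.scansoc_report <- function(x, ...) {
  cat("== Scan-sampling pipeline report ==\n")
  cat(sprintf("%d individuals (%d juveniles excluded), %d scans\n",
              x$inputs$n_individuals, x$inputs$n_excluded_juveniles,
              x$inputs$n_scans))
  d <- x$inputs$discarded_agonistic
  cat(sprintf("agonistic records discarded: %d polyadic, %d unclear\n",
              d["polyadic"], d["unclear"]))
  cat(sprintf("\nDominance: h' = %.3f, p = %.4g; %d individuals without MDS\n",
              x$dominance$linearity$h_prime, x$dominance$linearity$p,
              x$inputs$n_missing_mds))
  cat(sprintf("Association: CV = %.3f, p = %.4g (%d perms)\n",
              x$assoc_test$observed, x$assoc_test$p, x$assoc_test$n_perm))
  cat(sprintf("Subgroups: %d, Q = %.3f\n",
              x$communities$n_subgroups, x$communities$Q))
  cat(sprintf("\nH1: SRF10M ~ MDS r = %.5f, p = %.5g\n",
              x$H1$srf10m_mds$observed, x$H1$srf10m_mds$p))
  cat(sprintf("    F20M   ~ MDS r = %.5f, p = %.5g\n",
              x$H1$f20m_mds$observed, x$H1$f20m_mds$p))
  cat("\nH2 (semipartial r^2):\n")
  for (nm in names(x$H2)) {
    tb <- x$H2[[nm]]$table
    cat(sprintf("  %s: %s = %.4f (p = %.4g), %s = %.4f (p = %.4g), adj R^2 = %.4f\n",
                nm, tb$term[1], tb$semipartial_r2[1], tb$p.value[1],
                tb$term[2], tb$semipartial_r2[2], tb$p.value[2],
                tb$adj_r_squared[3]))
  }
  cat("\nH3 (MRQAP on co-occurrence HWI):\n")
  print(as.data.frame(x$H3$mrqap$coefficients[, c("term", "partial_r", "p.value")]),
        digits = 4, row.names = FALSE)
  cat(sprintf("  Mantel co-occurrence ~ zone-excluded affiliative: r = %.4f, p = %.4g\n",
              x$H3$mantel$observed, x$H3$mantel$p))
  cat(sprintf("  %.1f%% of co-occurrence dyads also associate elsewhere\n",
              x$H3$overlap))
  invisible(x)
}
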