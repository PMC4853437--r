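#' Half-weight association index
#'
#' `HWI = x / (x + yAB + (yA + yB) / 2)` where, over all sampling periods,
#' `x` counts periods with both individuals observed and associated, `yAB`
#' periods with both observed but not associated, and `yA`/`yB` periods with
#' only one of the two observed. The index corrects for unequal
#' observability of the two dyad members; it is 1 for dyads always together
#' whenever either is seen and 0 for dyads never seen associated.
#'
#' @param x,yA,yB,yAB nonnegative counts (vectorised).
#' @return values in `[0, 1]`; `NA` where all four counts are zero (the
#'   dyad was never sampled, so the index is undefined).
#' @examples
#' half_weight_index(2, 1, 1, 0)  # 2/3
#' @export
half_weight_index <- function(x, yA, yB, yAB) {
  stopifnot(all(c(x, yA, yB, yAB) >= 0))
  den <- x + yAB + (yA + yB) / 2
  ifelse(den > 0, x / den, NA_real_)
}

#' Per-scan dyadic associations
#'
#' Lists, for every scan, the dyads whose pairwise Euclidean distance is at
#' most `threshold` metres (inclusive: exactly 1.0 m apart counts as
#' associated). Association is strictly pairwise -- no chaining through
#' intermediate animals. Only visible individuals take part.
#'
#' @param scans validated scan tibble.
#' @param threshold association distance in metres.
#' @param exclude_zone_radius if non-`NULL`, associations whose two members
#'   are both within this distance of the door in that scan are dropped
#'   (used to build the feeding-zone-free affiliative network).
#' @param door door centroid, metres.
#' @return tibble `scan_id, id_a, id_b` with `id_a < id_b`.
#' @export
per_scan_associations <- function(scans, threshold = 1,
                                  exclude_zone_radius = NULL,
                                  door = c(5.5, 3.5)) {
  vis <- dplyr::filter(scans, .data$visible)
  if (nrow(vis) == 0) {
    return(tibble::tibble(scan_id = integer(), id_a = character(), id_b = character()))
  }
  per_scan <- split(vis, vis$scan_id)
  out <- purrr::map(per_scan, function(sc) {
    n <- nrow(sc)
    if (n < 2) return(NULL)
    d <- as.matrix(stats::dist(cbind(sc$x, sc$y)))
    pair <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
    if (nrow(pair) == 0) return(NULL)
    ia <- sc$individual[pair[, 1]]
    ib <- sc$individual[pair[, 2]]
    keep <- rep(TRUE, length(ia))
    if (!is.null(exclude_zone_radius)) {
      dd <- distance_to_door(sc$x, sc$y, door)
      keep <- !(dd[pair[, 1]] <= exclude_zone_radius &
                  dd[pair[, 2]] <= exclude_zone_radius)
    }
    if (!any(keep)) return(NULL)
    tibble::tibble(
      scan_id = sc$scan_id[1],
      id_a = pmin(ia[keep], ib[keep]),
      id_b = pmax(ia[keep], ib[keep])
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_edges() else out
}

empty_edges <- function() {
  tibble::tibble(scan_id = integer(), id_a = character(), id_b = character())
}

#' Affiliative association network (half-weight index)
#'
#' Builds the symmetric HWI matrix from per-scan 1-m proximity
#' associations. Presence (`observed in the scan`) enters the denominators,
#' so unequal observability is corrected dyad by dyad. By default all scans
#' (morning and afternoon) contribute.
#'
#' @inheritParams per_scan_associations
#' @param ids individuals to include (fixes matrix order); default: all ids
#'   appearing in `scans`.
#' @param period `"all"` (default), `"am"` or `"pm"`.
#' @return An object of class `scansoc_assoc`: list with `ids`, `hwi`
#'   (symmetric matrix, `NA` diagonal), count matrices `x` (associated),
#'   `n_both` (both observed), `den` (HWI denominators), `kind`, and the
#'   per-scan structure needed by [assoc_permutation_test()].
#' @export
association_network <- function(scans, ids = NULL, threshold = 1,
                                period = "all", exclude_zone_radius = NULL,
                                door = c(5.5, 3.5)) {
  stopifnot(period %in% c("am", "pm", "all"))
  if (period != "all") scans <- dplyr::filter(scans, .data$period == !!period)
  if (is.null(ids)) ids <- sort(unique(scans$individual))
  edges <- per_scan_associations(scans, threshold = threshold,
                                 exclude_zone_radius = exclude_zone_radius,
                                 door = door)
  kind <- if (is.null(exclude_zone_radius)) {
    sprintf("affiliative_%gm", threshold)
  } else {
    sprintf("affiliative_%gm_outside_%gm_zone", threshold, exclude_zone_radius)
  }
  new_assoc(scans, ids, edges, kind)
}

#' Food-patch co-occurrence network
#'
#' Within each scan (afternoon by default), every pair of individuals
#' observed within `radius` m of the feeding-zone door is counted as
#' associated (the complete graph on the co-present set); an HWI matrix is
#' then computed with presence-anywhere denominators. Co-occurrence in this
#' tight space is read as tolerance between the two animals.
#'
#' @inheritParams association_network
#' @param radius co-occurrence radius around the door, metres (inclusive).
#' @return A `scansoc_assoc` of kind `"cooccurrence_<radius>m"`.
#' @export
cooccurrence_network <- function(scans, ids = NULL, door = c(5.5, 3.5),
                                 radius = 5, period = "pm") {
  stopifnot(period %in% c("am", "pm", "all"))
  if (period != "all") scans <- dplyr::filter(scans, .data$period == !!period)
  if (is.null(ids)) ids <- sort(unique(scans$individual))
  vis <- dplyr::filter(scans, .data$visible,
                       distance_to_door(.data$x, .data$y, door) <= radius)
  edges <- if (nrow(vis)) {
    per_scan <- split(vis, vis$scan_id)
    dplyr::bind_rows(purrr::map(per_scan, function(sc) {
      if (nrow(sc) < 2) return(NULL)
      pr <- utils::combn(sort(sc$individual), 2)
      tibble::tibble(scan_id = sc$scan_id[1], id_a = pr[1, ], id_b = pr[2, ])
    }))
  } else {
    empty_edges()
  }
  if (nrow(edges) == 0) edges <- empty_edges()
  new_assoc(scans, ids, edges, sprintf("cooccurrence_%gm", radius))
}

# Shared constructor: turns per-scan presence + edge list into HWI matrices.
new_assoc <- function(scans, ids, edges, kind) {
  n <- length(ids)
  scan_ids <- sort(unique(scans$scan_id))
  vis <- dplyr::filter(scans, .data$visible, .data$individual %in% ids)
  pres <- matrix(FALSE, length(scan_ids), n,
                 dimnames = list(NULL, ids))
  pres[cbind(match(vis$scan_id, scan_ids), match(vis$individual, ids))] <- TRUE

  n_obs <- colSums(pres)
  n_both <- crossprod(pres)             # scans with both observed
  x <- matrix(0, n, n, dimnames = list(ids, ids))
  edges <- dplyr::filter(edges, .data$id_a %in% ids, .data$id_b %in% ids)
  if (nrow(edges)) {
    tab <- dplyr::count(edges, .data$id_a, .data$id_b)
    ia <- match(tab$id_a, ids); ib <- match(tab$id_b, ids)
    x[cbind(ia, ib)] <- tab$n
    x[cbind(ib, ia)] <- tab$n
  }
  only <- outer(n_obs, n_obs, "+") - 2 * n_both  # scans with exactly one observed
  den <- n_both + only / 2
  hwi <- ifelse(den > 0, x / ifelse(den > 0, den, 1), NA_real_)
  diag(hwi) <- NA_real_
  dimnames(hwi) <- dimnames(n_both) <- dimnames(den) <- list(ids, ids)

  structure(
    list(ids = ids, hwi = hwi, x = x, n_both = n_both, den = den,
         n_obs = n_obs, kind = kind,
         edges = edges, scan_ids = scan_ids),
    class = "scansoc_assoc"
  )
}

#' @export
print.scansoc_assoc <- function(x, ...) {
  up <- x$hwi[upper.tri(x$hwi)]
  cat(sprintf("Association network (%s): %d individuals, %d scans\n",
              x$kind, length(x$ids), length(x$scan_ids)))
  cat(sprintf("  nonzero dyads: %d / %d; mean HWI = %.4f\n",
              sum(up > 0, na.rm = TRUE), sum(!is.na(up)),
              mean(up, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.scansoc_assoc <- function(x, ...) {
  ut <- upper.tri(x$hwi)
  idx <- which(ut, arr.ind = TRUE)
  x_counts <- x$x[ut]
  n_both <- x$n_both[ut]
  tibble::tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    hwi = x$hwi[ut],
    x = x_counts,
    n_both = n_both
  )
}

#' @export
glance.scansoc_assoc <- function(x, ...) {
  up <- x$hwi[upper.tri(x$hwi)]
  tibble::tibble(
    kind = x$kind,
    n_individuals = length(x$ids),
    n_scans = length(x$scan_ids),
    n_associations = nrow(x$edges),
    mean_hwi = mean(up, na.rm = TRUE),
    cv_hwi = stats::sd(up, na.rm = TRUE) / mean(up, na.rm = TRUE)
  )
}

#' @export
autoplot.scansoc_assoc <- function(object, order = NULL, ...) {
  ids <- if (is.null(order)) object$ids else order
  df <- tidy(object)
  df$id_a <- factor(df$id_a, levels = ids)
  df$id_b <- factor(df$id_b, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$hwi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "HWI", title = object$kind) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export an association network as an edge list
#'
#' `source,target,weight` rows for dyads with positive HWI, for external
#' graph tools.
#'
#' @param net a `scansoc_assoc`.
#' @return tibble with columns `source`, `target`, `weight`.
#' @export
assoc_edge_list <- function(net) {
  tidy(net) |>
    dplyr::filter(!is.na(.data$hwi), .data$hwi > 0) |>
    dplyr::transmute(source = .data$id_a, target = .data$id_b, weight = .data$hwi)
}

#' Test for nonrandom association (within-scan permutation)
#'
#' Tests the null of no preferred or avoided dyadic relationships by
#' permuting associations within each scan: a long sequential chain of
#' double-edge swaps rewires each scan's association graph among the
#' individuals observed in that scan, preserving every individual's
#' within-scan number of associates and the scan's association count.
#' Because presence is untouched, each dyad's HWI denominator is fixed and
#' only the joint counts vary. The test statistic is the coefficient of
#' variation of the association indices: consistently preferred dyads
#' inflate the spread of the observed HWI relative to the rewired null, so
#' the p-value is right-tailed.
#'
#' @param net a `scansoc_assoc` from [association_network()].
#' @param n_perm number of permuted replicates.
#' @param swaps_per_perm attempted swaps between recorded replicates;
#'   default 100 x the number of associations.
#' @param burn_in attempted swaps before the first recorded replicate;
#'   default equal to `swaps_per_perm`.
#' @param seed optional integer seed.
#' @return A `scansoc_permtest` with the observed CV, null summary and p.
#' @export
assoc_permutation_test <- function(net, n_perm = 10000, swaps_per_perm = NULL,
                                   burn_in = NULL, seed = NULL) {
  stopifnot(inherits(net, "scansoc_assoc"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(net$ids)
  ut <- upper.tri(net$den)
  # upper triangle in row-major order, to match the C++ dyad indexing
  den_vec <- t(net$den)[lower.tri(net$den)]

  obs_vals <- (net$x[ut] / net$den[ut])[net$den[ut] > 0]
  observed <- stats::sd(obs_vals) / mean(obs_vals)

  m <- nrow(net$edges)
  if (m < 2 || !is.finite(observed)) {
    warning("no permutable association structure; p reported as 1")
    return(new_permtest("CV of association indices",
                        ifelse(is.finite(observed), observed, NA_real_),
                        numeric(0), 1, n_perm, "greater", seed))
  }
  if (is.null(swaps_per_perm)) swaps_per_perm <- 100 * m
  if (is.null(burn_in)) burn_in <- swaps_per_perm
  edge_mat <- cbind(match(net$edges$scan_id, net$scan_ids),
                    match(net$edges$id_a, net$ids),
                    match(net$edges$id_b, net$ids))
  storage.mode(edge_mat) <- "integer"
  res <- assoc_perm_chain(edge_mat, length(net$scan_ids), n, den_vec,
                          as.integer(n_perm), as.numeric(max(1, swaps_per_perm)),
                          as.numeric(max(0, burn_in)), FALSE)
  null_cv <- res$cv
  p <- (1 + sum(null_cv >= observed, na.rm = TRUE)) / (n_perm + 1)
  new_permtest("CV of association indices", observed, null_cv, p, n_perm,
               "greater", seed)
}
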