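#' Dyadic win matrix from agonistic records
#'
#' Counts directed wins per dyad. Only strictly dyadic events
#' (`n_participants == 2`) with a clear outcome between two included
#' individuals contribute; polyadic and unclear events are discarded and
#' reported. Each record is a single decided event (behaviour sequences are
#' reduced to their final behaviour upstream), so it contributes exactly one
#' count.
#'
#' @param records agonistic tibble (see [read_agonistic_table()]).
#' @param ids character vector of included individuals; fixes the matrix
#'   order.
#' @return Square integer matrix `s` with `s[i, j]` = wins of `i` over `j`,
#'   dimnames `ids`. Counts of discarded records are attached as the
#'   `"discarded"` attribute (`polyadic`, `unclear`, `outside`).
#' @export
build_win_matrix <- function(records, ids) {
  s <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(records) == 0) {
    attr(s, "discarded") <- c(polyadic = 0L, unclear = 0L, outside = 0L)
    return(s)
  }
  polyadic <- records$n_participants != 2L
  unclear <- !polyadic & !records$clear_outcome
  inside <- records$actor %in% ids & records$receiver %in% ids
  outside <- !polyadic & !unclear & !inside
  keep <- records[!polyadic & !unclear & inside, , drop = FALSE]
  for (k in seq_len(nrow(keep))) {
    s[keep$actor[k], keep$receiver[k]] <- s[keep$actor[k], keep$receiver[k]] + 1L
  }
  attr(s, "discarded") <- c(polyadic = sum(polyadic), unclear = sum(unclear),
                            outside = sum(outside))
  s
}

#' Chance-corrected dyadic dominance indices
#'
#' For each dyad with `n_ij = s_ij + s_ji` decided interactions, the raw win
#' proportion `P_ij = s_ij / n_ij` is shrunk toward 0.5 by
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`, so that a 1--0 record carries
#' less weight than a 10--0 record. Dyads that never interacted get
#' `D_ij = D_ji = 0`.
#'
#' @param s win matrix from [build_win_matrix()].
#' @return Matrix `D` with `D_ij + D_ji = 1` for interacting dyads.
#' @export
dyadic_dominance_index <- function(s) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  n <- s + t(s)
  p <- ifelse(n > 0, s / ifelse(n > 0, n, 1), 0)
  d <- ifelse(n > 0, p - (p - 0.5) / (n + 1), 0)
  diag(d) <- 0
  dimnames(d) <- dimnames(s)
  d
}

#' Modified David's scores
#'
#' Cardinal dominance index summing chance-corrected dyadic win proportions
#' and their second-order terms: `DS_i = w_i + w2_i - l_i - l2_i` with
#' `w_i = sum_j D_ij`, `w2_i = sum_j D_ij w_j`, `l_i = sum_j D_ji`,
#' `l2_i = sum_j D_ji l_j`. Beating individuals that themselves win a lot
#' counts for more. Scores always sum to zero; higher is more dominant.
#'
#' @param d dyadic index matrix from [dyadic_dominance_index()].
#' @return Named numeric vector of scores (one per individual).
#' @export
david_score <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  w <- rowSums(d)
  l <- colSums(d)
  w2 <- as.numeric(d %*% w)
  l2 <- as.numeric(t(d) %*% l)
  stats::setNames(w + w2 - l - l2, rownames(d))
}

#' Hierarchy linearity: Landau's h and de Vries' h'
#'
#' Landau's index `h = 12 / (N^3 - N) * sum_i (V_i - (N - 1) / 2)^2`
#' measures how close the dominance relations come to a strict linear order
#' (`h = 1`), where `V_i` is the number of individuals `i` dominates. Tied
#' dyads (equal wins both ways) and unknown dyads (no decided interaction)
#' each contribute 0.5 to both members' `V`. Because unknown relationships
#' bias `h` downward, the improved index adds a correction for the `u`
#' unknown dyads: `h' = h + 6u / (N^3 - N)`.
#'
#' Significance is assessed by randomisation: under the null of no linear
#' order, the direction of every known (including tied) dyad is resolved by
#' a fair coin while unknown dyads stay unknown, and `h'` is recomputed;
#' `p` is the right-tailed proportion of randomised values at least as large
#' as the observed one (observed arrangement included in the count).
#'
#' @param s win matrix (at least 3 individuals).
#' @param n_randomizations number of null matrices.
#' @param seed optional integer seed for reproducibility.
#' @return A list with `h`, `h_prime`, `p`, `n_unknown`, `n_tied`,
#'   `n_randomizations`.
#' @export
linearity_h_prime <- function(s, n_randomizations = 10000, seed = NULL) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  n <- nrow(s)
  if (n < 3) stop("linearity is undefined for fewer than 3 individuals")
  if (!is.null(seed)) set.seed(seed)

  tot <- s + t(s)
  upper <- upper.tri(s)
  known_dir <- (s != t(s)) & upper        # decided dyads (i beats j or vice versa)
  tied <- (tot > 0) & (s == t(s)) & upper
  unknown <- (tot == 0) & upper
  u <- sum(unknown)
  denom <- n^3 - n

  h_of_v <- function(v) 12 / denom * sum((v - (n - 1) / 2)^2)

  # V from a win matrix: 1 per dominated opponent, 0.5 per tie/unknown
  v_obs <- rowSums(s > t(s)) + 0.5 * (rowSums(tied | t(tied)) + rowSums(unknown | t(unknown)))
  h_obs <- h_of_v(v_obs)
  hp_obs <- h_obs + 6 * u / denom

  idx <- which(known_dir | tied, arr.ind = TRUE)  # dyads randomised under H0
  base_v <- 0.5 * rowSums(unknown | t(unknown))
  null_hp <- vapply(seq_len(n_randomizations), function(k) {
    v <- base_v
    if (nrow(idx)) {
      flip <- stats::runif(nrow(idx)) < 0.5
      winners <- ifelse(flip, idx[, 1], idx[, 2])
      tv <- tabulate(winners, nbins = n)
      v <- v + tv
    }
    h_of_v(v) + 6 * u / denom
  }, numeric(1))
  p <- (1 + sum(null_hp >= hp_obs)) / (n_randomizations + 1)

  list(h = h_obs, h_prime = hp_obs, p = p,
       n_unknown = u, n_tied = sum(tied),
       n_randomizations = n_randomizations)
}

#' Dominance hierarchy from agonistic records
#'
#' Convenience wrapper running [build_win_matrix()],
#' [dyadic_dominance_index()], [david_score()] and [linearity_h_prime()] in
#' one pass.
#'
#' @inheritParams build_win_matrix
#' @inheritParams linearity_h_prime
#' @return An object of class `scansoc_dominance`: list with `scores`
#'   (tibble `individual`, `MDS`), `win_matrix`, `linearity`, `discarded`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
dominance_hierarchy <- function(records, ids, n_randomizations = 10000, seed = NULL) {
  s <- build_win_matrix(records, ids)
  d <- dyadic_dominance_index(s)
  mds <- david_score(d)
  lin <- linearity_h_prime(s, n_randomizations = n_randomizations, seed = seed)
  structure(
    list(
      scores = tibble::tibble(individual = names(mds), MDS = as.numeric(mds)),
      win_matrix = s,
      dyadic_index = d,
      linearity = lin,
      discarded = attr(s, "discarded")
    ),
    class = "scansoc_dominance"
  )
}

#' @export
print.scansoc_dominance <- function(x, ...) {
  cat("Dominance hierarchy:", nrow(x$scores), "individuals\n")
  cat(sprintf("  h' = %.3f (h = %.3f), p = %.4g [%d randomizations]\n",
              x$linearity$h_prime, x$linearity$h, x$linearity$p,
              x$linearity$n_randomizations))
  cat(sprintf("  unknown dyads: %d, tied dyads: %d\n",
              x$linearity$n_unknown, x$linearity$n_tied))
  cat("  top of hierarchy:\n")
  top <- dplyr::slice_max(x$scores, .data$MDS, n = 3)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s  MDS = %.2f\n", top$individual[i], top$MDS[i]))
  }
  invisible(x)
}

#' @export
tidy.scansoc_dominance <- function(x, ...) {
  dplyr::arrange(x$scores, dplyr::desc(.data$MDS))
}

#' @export
glance.scansoc_dominance <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$scores),
    h = x$linearity$h,
    h_prime = x$linearity$h_prime,
    p_linearity = x$linearity$p,
    n_unknown_dyads = x$linearity$n_unknown,
    n_randomizations = x$linearity$n_randomizations
  )
}

#' @export
autoplot.scansoc_dominance <- function(object, ...) {
  df <- tidy(object)
  df$individual <- factor(df$individual, levels = rev(df$individual))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$MDS, y = .data$individual)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "modified David's score", y = NULL,
                  title = "Dominance hierarchy") +
    ggplot2::theme_minimal()
}
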