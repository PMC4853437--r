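#' Permutation Pearson correlation
#'
#' Ordinary Pearson `r` with a permutation p-value obtained by shuffling
#' one vector; used because the study group is not a sample from a known
#' distribution. The observed arrangement counts toward the null, so
#' `p >= 1/(n_perm + 1)`.
#'
#' @param x,y numeric vectors of equal length (n >= 3), pairwise complete.
#' @param alternative `"two.sided"`, `"greater"` (positive correlation) or
#'   `"less"`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return A `scansoc_permtest` with `observed = r`.
#' @export
perm_pearson <- function(x, y, alternative = "two.sided", n_perm = 10000,
                         seed = NULL) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  null <- vapply(seq_len(n_perm), function(i) stats::cor(x, sample(y)),
                 numeric(1))
  p <- perm_p_value(r, null, alternative)
  new_permtest("Pearson r", r, null, p, n_perm, alternative, seed)
}

#' Permutation Welch t-test
#'
#' Welch's t statistic for a two-group comparison with a permutation
#' p-value from shuffling group labels. `alternative = "greater"` tests
#' whether the first factor level's mean exceeds the second's.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) with exactly two levels, each with
#'   at least 2 observations.
#' @inheritParams perm_pearson
#' @return A `scansoc_permtest` with `observed = t` (Welch).
#' @export
perm_ttest <- function(values, groups, alternative = "two.sided",
                       n_perm = 10000, seed = NULL) {
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) != 2) stop("need exactly two groups")
  if (min(table(groups)) < 2) stop("each group needs at least 2 observations")
  if (!is.null(seed)) set.seed(seed)

  welch_t <- function(g) {
    a <- values[g == levels(groups)[1]]
    b <- values[g == levels(groups)[2]]
    (mean(a) - mean(b)) /
      sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  t_obs <- welch_t(groups)
  null <- vapply(seq_len(n_perm), function(i) welch_t(sample(groups)),
                 numeric(1))
  p <- perm_p_value(t_obs, null, alternative)
  new_permtest("Welch t", t_obs, null, p, n_perm, alternative, seed,
               extra = list(levels = levels(groups)))
}

#' Dyadic attribute matrices
#'
#' Turns per-individual attributes into the square dyadic matrices used in
#' matrix regressions: absolute (Euclidean) differences for age and
#' dominance score, a binary same-sex indicator (same sex = 1, different
#' sex = 0), and a binary matriline-kinship indicator (same matriline = 1).
#' Individuals with missing matriline are treated as singleton matrilines
#' (kin to nobody) and flagged.
#'
#' @param individuals tibble with `id`, `sex`, `age`, `matriline` and
#'   optionally `MDS`.
#' @return named list of labelled matrices: `age_dist`, `sex_same`,
#'   `kinship`, and `mds_dist` when `MDS` is present. Diagonals are 0.
#' @export
attribute_matrices <- function(individuals) {
  ids <- individuals$id
  out <- list()
  abs_diff <- function(v) {
    m <- abs(outer(v, v, "-"))
    dimnames(m) <- list(ids, ids)
    m
  }
  out$age_dist <- abs_diff(individuals$age)
  sex <- as.character(individuals$sex)
  out$sex_same <- outer(sex, sex, "==") * 1
  mat <- as.character(individuals$matriline)
  if (anyNA(mat)) {
    warning(sum(is.na(mat)), " individual(s) with missing matriline treated as singletons")
    mat[is.na(mat)] <- paste0(".singleton", seq_len(sum(is.na(mat))))
  }
  out$kinship <- outer(mat, mat, "==") * 1
  diag(out$sex_same) <- 0
  diag(out$kinship) <- 0
  dimnames(out$sex_same) <- dimnames(out$kinship) <- list(ids, ids)
  if ("MDS" %in% names(individuals)) out$mds_dist <- abs_diff(individuals$MDS)
  out
}

#' Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two conformable
#' symmetric matrices, with significance from simultaneous row-and-column
#' permutation of one matrix (the only permutation that respects the
#' dyadic dependence structure).
#'
#' @param a,b symmetric matrices over the same individuals.
#' @inheritParams perm_pearson
#' @return A `scansoc_permtest` with `observed = r` (matrix correlation).
#' @export
mantel_perm <- function(a, b, alternative = "two.sided", n_perm = 10000,
                        seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)), nrow(a) == ncol(a))
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    stopifnot(identical(rownames(a), rownames(b)))
  }
  off <- row(a) != col(a)
  va <- a[off]
  if (stats::sd(va, na.rm = TRUE) == 0 || stats::sd(b[off], na.rm = TRUE) == 0) {
    stop("Mantel correlation undefined: constant matrix")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  r_with <- function(bb) stats::cor(va, bb[off], use = "complete.obs")
  r <- r_with(b)
  null <- vapply(seq_len(n_perm), function(i) {
    pi <- sample.int(n)
    r_with(b[pi, pi])
  }, numeric(1))
  p <- perm_p_value(r, null, alternative)
  new_permtest("Mantel r", r, null, p, n_perm, alternative, seed)
}

#' MRQAP with double-semi-partialing
#'
#' Multiple regression of a dyadic response matrix on dyadic predictor
#' matrices, with permutation p-values that are robust to network
#' autocorrelation and to correlation among predictors. For each predictor
#' `X_k`, its residual matrix after regressing out the remaining predictors
#' is row-and-column permuted (quadratic assignment), the model is refit,
#' and the permuted t statistics form that predictor's null (Dekker's
#' double-semi-partialing). With one predictor this reduces to plain QAP
#' regression.
#'
#' All off-diagonal cells enter the regression. Reported per predictor:
#' the raw coefficient, standardised coefficient, partial correlation
#' (`t / sqrt(t^2 + df)`), t, and permutation p.
#'
#' @param y response matrix.
#' @param predictors named list of predictor matrices.
#' @inheritParams perm_pearson
#' @return object of class `scansoc_mrqap`; see [tidy()] and [glance()].
#' @export
mrqap_dsp <- function(y, predictors, alternative = "two.sided",
                      n_perm = 10000, seed = NULL) {
  y <- as.matrix(y)
  stopifnot(length(predictors) >= 1)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  n <- nrow(y)
  for (nm in names(predictors)) {
    stopifnot(identical(dim(predictors[[nm]]), dim(y)))
  }
  if (!is.null(seed)) set.seed(seed)

  off <- row(y) != col(y)
  yy <- y[off]
  if (anyNA(yy)) stop("missing values in the response matrix")
  xmat <- vapply(predictors, function(m) as.matrix(m)[off], numeric(sum(off)))
  design <- cbind(`(Intercept)` = 1, xmat)
  qr_full <- qr(design)
  if (qr_full$rank < ncol(design)) {
    bad <- colnames(design)[qr_full$pivot[(qr_full$rank + 1):ncol(design)]]
    stop("collinear predictor set; offending matrix: ",
         paste(bad, collapse = ", "))
  }
  nobs <- length(yy)
  k <- length(predictors)
  df <- nobs - (k + 1)
  fit <- stats::lm.fit(design, yy)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((yy - mean(yy))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (nobs - 1) / df

  # t statistic of a focal vector after projecting out `others`
  # (Frisch-Waugh): identical to its t in the full model.
  t_of <- function(ex, ey, dfree) {
    sxx <- sum(ex^2)
    beta <- sum(ex * ey) / sxx
    resid2 <- sum(ey^2) - beta^2 * sxx
    se <- sqrt(resid2 / dfree / sxx)
    beta / se
  }

  per_pred <- purrr::map(seq_len(k), function(j) {
    others <- design[, -(j + 1), drop = FALSE]
    qo <- qr(others)
    ex <- qr.resid(qo, xmat[, j])
    ey <- qr.resid(qo, yy)
    t_obs <- t_of(ex, ey, df)
    # residual matrix of X_j given the other predictors, in dyad layout
    emat <- matrix(0, n, n)
    emat[off] <- ex
    null_t <- vapply(seq_len(n_perm), function(b) {
      pi <- sample.int(n)
      ep <- emat[pi, pi][off]
      ep <- ep - qr.fitted(qo, ep)   # re-orthogonalise after permutation
      t_of(ep, ey, df)
    }, numeric(1))
    p <- perm_p_value(t_obs, null_t, alternative)
    sx <- stats::sd(xmat[, j])
    tibble::tibble(
      term = names(predictors)[j],
      estimate = coefs[j + 1],
      std_estimate = coefs[j + 1] * sx / stats::sd(yy),
      partial_r = t_obs / sqrt(t_obs^2 + df),
      statistic = t_obs,
      p.value = p
    )
  })

  structure(
    list(
      coefficients = dplyr::bind_rows(per_pred),
      intercept = coefs[1],
      r_squared = r2,
      adj_r_squared = adj_r2,
      n_dyads = nobs,
      df_residual = df,
      n_perm = n_perm,
      alternative = alternative,
      seed = seed
    ),
    class = "scansoc_mrqap"
  )
}

#' @export
print.scansoc_mrqap <- function(x, ...) {
  cat(sprintf("MRQAP (double-semi-partialing), %d dyads, %d permutations\n",
              x$n_dyads, x$n_perm))
  cat(sprintf("  R^2 = %.4f (adjusted %.4f)\n", x$r_squared, x$adj_r_squared))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.scansoc_mrqap <- function(x, ...) {
  x$coefficients
}

#' @export
glance.scansoc_mrqap <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    n_dyads = x$n_dyads,
    df.residual = x$df_residual,
    n_perm = x$n_perm
  )
}

#' Variance partitioning with semipartial r-squared
#'
#' Partial regression of a per-individual response on a continuous block
#' (dominance score) and a categorical block (subgroup membership,
#' dummy-coded with levels - 1 columns). Each block's unique contribution
#' is the semipartial `r^2 = R^2(full) - R^2(without block)`. Permutation
#' p-values (right-tailed on each block's semipartial r^2, and on the full
#' model's R^2) come from permuting the response by default; set
#' `permute = "residuals"` for Freedman-Lane permutation of reduced-model
#' residuals.
#'
#' @param y numeric response per individual.
#' @param continuous numeric vector (or single-column matrix), e.g. MDS.
#' @param categorical factor of subgroup labels.
#' @param continuous_name,categorical_name labels for the output table.
#' @param permute `"response"` or `"residuals"`.
#' @inheritParams perm_pearson
#' @return object of class `scansoc_varpart`; `tidy()` gives the
#'   Df / semipartial r^2 / p table, `glance()` the full-model summary.
#' @export
variance_partition <- function(y, continuous, categorical,
                               continuous_name = "MDS",
                               categorical_name = "Subgroups",
                               permute = c("response", "residuals"),
                               n_perm = 10000, seed = NULL) {
  permute <- match.arg(permute)
  keep <- stats::complete.cases(y, continuous, categorical)
  y <- y[keep]
  continuous <- continuous[keep]
  categorical <- droplevels(factor(categorical[keep]))
  n <- length(y)
  xc <- cbind(continuous)
  xg <- stats::model.matrix(~categorical)[, -1, drop = FALSE]
  df_cont <- ncol(xc)
  df_cat <- ncol(xg)
  if (n <= 1 + df_cont + df_cat) stop("too few individuals for the model")
  singletons <- names(which(table(categorical) == 1))
  if (length(singletons)) {
    message("subgroup level(s) with a single member retained: ",
            paste(singletons, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  r2_of <- function(yy, x) {
    f <- stats::lm.fit(cbind(1, x), yy)
    1 - sum(f$residuals^2) / sum((yy - mean(yy))^2)
  }
  stats_of <- function(yy) {
    full <- r2_of(yy, cbind(xc, xg))
    c(full = full,
      sp_cont = full - r2_of(yy, xg),
      sp_cat = full - r2_of(yy, xc))
  }
  obs <- stats_of(y)
  p_full <- ncol(xc) + ncol(xg)
  adj_r2 <- 1 - (1 - obs["full"]) * (n - 1) / (n - p_full - 1)

  if (permute == "response") {
    null <- vapply(seq_len(n_perm), function(b) stats_of(sample(y)),
                   numeric(3))
  } else {
    # Freedman-Lane: permute residuals of the reduced model for each block
    red_cont <- stats::lm.fit(cbind(1, xg), y)   # reduced w.r.t. continuous
    red_cat <- stats::lm.fit(cbind(1, xc), y)    # reduced w.r.t. categorical
    null <- vapply(seq_len(n_perm), function(b) {
      pi <- sample.int(n)
      y_c <- red_cont$fitted.values + red_cont$residuals[pi]
      y_g <- red_cat$fitted.values + red_cat$residuals[pi]
      y_f <- mean(y) + (y - mean(y))[pi]
      c(full = r2_of(y_f, cbind(xc, xg)),
        sp_cont = r2_of(y_c, cbind(xc, xg)) - r2_of(y_c, xg),
        sp_cat = r2_of(y_g, cbind(xc, xg)) - r2_of(y_g, xc))
    }, numeric(3))
  }
  p_of <- function(stat) (1 + sum(null[stat, ] >= obs[stat])) / (n_perm + 1)

  structure(
    list(
      table = tibble::tibble(
        term = c(continuous_name, categorical_name,
                 paste(continuous_name, "+", categorical_name)),
        df = c(df_cont, df_cat, p_full),
        semipartial_r2 = c(obs["sp_cont"], obs["sp_cat"], NA_real_),
        adj_r_squared = c(NA_real_, NA_real_, unname(adj_r2)),
        p.value = c(p_of("sp_cont"), p_of("sp_cat"), p_of("full"))
      ),
      r_squared = unname(obs["full"]),
      adj_r_squared = unname(adj_r2),
      n = n,
      n_perm = n_perm,
      permute = permute,
      seed = seed
    ),
    class = "scansoc_varpart"
  )
}

#' @export
print.scansoc_varpart <- function(x, ...) {
  cat(sprintf("Variance partition (%d individuals, %d permutations, %s permuted)\n",
              x$n, x$n_perm, x$permute))
  print(as.data.frame(x$table), digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.scansoc_varpart <- function(x, ...) {
  x$table
}

#' @export
glance.scansoc_varpart <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    n = x$n,
    n_perm = x$n_perm,
    p.value = x$table$p.value[3]
  )
}

#' Homoscedasticity pre-flight report
#'
#' Numeric diagnostics run before the variance partitions: Bartlett's test
#' of equal response variance across subgroups and the Breusch-Pagan test
#' on the full linear model. Reported, never used as a gate; the
#' square-root transform of F10M is applied unconditionally upstream.
#'
#' @inheritParams variance_partition
#' @return tibble with one row per diagnostic (`test`, `statistic`, `df`,
#'   `p.value`).
#' @export
homoscedasticity_report <- function(y, continuous, categorical) {
  keep <- stats::complete.cases(y, continuous, categorical)
  y <- y[keep]; continuous <- continuous[keep]
  categorical <- droplevels(factor(categorical[keep]))
  multi <- names(which(table(categorical) >= 2))
  bt <- stats::bartlett.test(y[categorical %in% multi],
                             droplevels(categorical[categorical %in% multi]))
  fit <- stats::lm(y ~ continuous + categorical)
  # Breusch-Pagan (studentised, Koenker): n * R^2 of squared residuals on
  # the model's own regressors
  u2 <- stats::residuals(fit)^2
  aux <- stats::lm(u2 ~ continuous + categorical)
  n <- length(y)
  bp_stat <- n * summary(aux)$r.squared
  bp_df <- length(stats::coefficients(aux)) - 1
  tibble::tibble(
    test = c("Bartlett", "Breusch-Pagan"),
    statistic = c(unname(bt$statistic), bp_stat),
    df = c(unname(bt$parameter), bp_df),
    p.value = c(bt$p.value, stats::pchisq(bp_stat, bp_df, lower.tail = FALSE))
  )
}
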