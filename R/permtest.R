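# Common container for permutation tests (correlation, t, Mantel, CV of
# association indices). The observed arrangement is always counted in the
# null (p >= 1/(n_perm + 1)).
new_permtest <- function(statistic_name, observed, null, p, n_perm,
                         alternative, seed, extra = list()) {
  structure(
    c(list(statistic_name = statistic_name, observed = observed,
           null = null, p = p, n_perm = n_perm,
           alternative = alternative, seed = seed), extra),
    class = "scansoc_permtest"
  )
}

perm_p_value <- function(observed, null, alternative) {
  n_perm <- length(null)
  count <- switch(
    alternative,
    greater = sum(null >= observed, na.rm = TRUE),
    less = sum(null <= observed, na.rm = TRUE),
    two.sided = sum(abs(null) >= abs(observed), na.rm = TRUE),
    stop("unknown alternative: ", alternative)
  )
  (1 + count) / (n_perm + 1)
}

#' @export
print.scansoc_permtest <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.5f, p(perm) = %.5g (%s, %d permutations)\n",
              x$observed, x$p, x$alternative, x$n_perm))
  if (length(x$null)) {
    cat(sprintf("  null: mean = %.5f, sd = %.5f\n",
                mean(x$null, na.rm = TRUE), stats::sd(x$null, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
tidy.scansoc_permtest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name,
    estimate = x$observed,
    p.value = x$p,
    alternative = x$alternative,
    n_perm = x$n_perm
  )
}

#' @export
glance.scansoc_permtest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name,
    estimate = x$observed,
    null_mean = if (length(x$null)) mean(x$null, na.rm = TRUE) else NA_real_,
    null_sd = if (length(x$null)) stats::sd(x$null, na.rm = TRUE) else NA_real_,
    p.value = x$p,
    n_perm = x$n_perm,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @export
autoplot.scansoc_permtest <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic_name, y = "permutations",
      title = sprintf("%s: observed vs permutation null", object$statistic_name),
      subtitle = sprintf("p(perm) = %.4g, %d permutations", object$p, object$n_perm)
    ) +
    ggplot2::theme_minimal()
}
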