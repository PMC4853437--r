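# In-code fixtures and independent brute-force oracles used across tests.

# A minimal valid scan tibble from position triples: list of per-scan
# named vectors id -> c(x, y); NA position means out of sight.
make_scans <- function(positions, times = NULL) {
  rows <- purrr::imap(positions, function(p, s) {
    tibble::tibble(
      scan_id = as.integer(s),
      date = as.Date("2012-04-01"),
      time = if (is.null(times)) "15:00" else times[[as.integer(s)]],
      individual = names(p),
      x = vapply(p, `[`, numeric(1), 1),
      y = vapply(p, `[`, numeric(1), 2),
      visible = !vapply(p, function(v) anyNA(v), logical(1))
    )
  })
  validate_scan_table(dplyr::bind_rows(rows))
}

pos <- function(...) {
  v <- list(...)
  lapply(v, function(p) c(p[1], p[2]))
}

# agonistic record builder: each row "actor>receiver" strings
make_agonistic <- function(pairs, n_participants = 2L, clear = TRUE) {
  parts <- strsplit(pairs, ">", fixed = TRUE)
  tibble::tibble(
    timestamp = as.POSIXct("2012-04-01 10:00:00", tz = "UTC") + seq_along(pairs),
    actor = vapply(parts, `[`, character(1), 1),
    receiver = vapply(parts, `[`, character(1), 2),
    behavior = "B01",
    n_participants = rep_len(n_participants, length(pairs)),
    clear_outcome = rep_len(clear, length(pairs))
  )
}

# independent per-record recount of spatial frequencies (oracle)
brute_spatial <- function(scans, door = c(5.5, 3.5), r_near = 10, r_far = 20) {
  pm <- scans[scans$period == "pm", ]
  ids <- sort(unique(pm$individual))
  out <- lapply(ids, function(i) {
    ri <- pm[pm$individual == i, ]
    n_obs <- 0L; near <- 0L; far <- 0L; unseen <- 0L
    for (k in seq_len(nrow(ri))) {
      if (!ri$visible[k]) { unseen <- unseen + 1L; next }
      n_obs <- n_obs + 1L
      d <- sqrt((ri$x[k] - door[1])^2 + (ri$y[k] - door[2])^2)
      if (d <= r_near) near <- near + 1L
      if (d > r_far) far <- far + 1L
    }
    data.frame(individual = i, n_scans_observed = n_obs,
               F10M = if (n_obs > 0) near / n_obs else NA_real_,
               F20M = far + unseen)
  })
  do.call(rbind, out)
}

# independent dyad-by-dyad HWI recount (oracle)
brute_hwi <- function(scans, threshold = 1, ids = NULL) {
  vis <- scans[scans$visible, ]
  if (is.null(ids)) ids <- sort(unique(scans$individual))
  scan_ids <- sort(unique(scans$scan_id))
  n <- length(ids)
  hwi <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- yA <- yB <- yAB <- 0L
      for (s in scan_ids) {
        sc <- vis[vis$scan_id == s, ]
        a <- match(ids[i], sc$individual)
        b <- match(ids[j], sc$individual)
        if (!is.na(a) && !is.na(b)) {
          d <- sqrt((sc$x[a] - sc$x[b])^2 + (sc$y[a] - sc$y[b])^2)
          if (d <= threshold) x <- x + 1L else yAB <- yAB + 1L
        } else if (!is.na(a)) {
          yA <- yA + 1L
        } else if (!is.na(b)) {
          yB <- yB + 1L
        }
      }
      den <- x + yAB + (yA + yB) / 2
      v <- if (den > 0) x / den else NA_real_
      hwi[i, j] <- hwi[j, i] <- v
    }
  }
  hwi
}

# all permutations of 1..n (for enumeration oracles, n <= 6)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive best modularity over partitions into at most k groups (oracle)
brute_best_modularity <- function(w, k = 3) {
  n <- nrow(w)
  best <- -Inf
  grid <- rep(list(seq_len(k)), n)
  assign_next <- function(memb, i) {
    if (i > n) {
      q <- modularity_q(w, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    top <- min(k, max(memb[seq_len(i - 1)], 0) + 1)
    for (g in seq_len(top)) {   # canonical labelling avoids duplicates
      memb[i] <- g
      assign_next(memb, i + 1)
    }
  }
  assign_next(integer(n), 1L)
  best
}

# random win matrix with given density of decided dyads
random_win_matrix <- function(n, max_wins = 5, p_known = 0.8) {
  s <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_known) {
        s[i, j] <- stats::rpois(1, 1.5)
        s[j, i] <- stats::rpois(1, 1.5)
        if (s[i, j] == 0 && s[j, i] == 0) s[i, j] <- 1L
      }
    }
  }
  s
}

# iid-uniform-position scan table: the exchangeable null for the
# within-scan association permutation test
null_scan_table <- function(n_ind = 10, n_scans = 20, side = 6) {
  sc <- do.call(rbind, lapply(seq_len(n_scans), function(s) {
    data.frame(scan_id = s, date = as.Date("2012-04-01"), time = "15:00",
               individual = sprintf("i%02d", seq_len(n_ind)),
               x = stats::runif(n_ind, 0, side),
               y = stats::runif(n_ind, 0, side), visible = TRUE)
  }))
  validate_scan_table(sc)
}
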