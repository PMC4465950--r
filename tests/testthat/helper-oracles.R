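# Independent brute-force oracles: naive per-event-time risk tables
# and all-pairs enumerations, deliberately written without reusing any
# package internals.

# Standardized log-rank via explicit risk-table tabulation at every
# distinct event time.
oracle_logrank <- function(time, status, membership) {
  membership <- as.logical(membership)
  ev_times <- sort(unique(time[status == 1]))
  oe <- 0
  v <- 0
  for (u in ev_times) {
    at_risk <- time >= u
    Y <- sum(at_risk)
    Y1 <- sum(at_risk & membership)
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & membership)
    oe <- oe + d1 - d * Y1 / Y
    if (Y > 1) v <- v + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (v <= 1e-12) return(NA_real_)
  oe / sqrt(v)
}

# Best split by trying every (variable, midpoint) pair through the
# oracle statistic.
oracle_best_split <- function(time, status, x, min_node_size) {
  best <- list(var = NA_integer_, thresh = NA_real_, stat = -Inf)
  for (v in seq_len(ncol(x))) {
    vals <- sort(unique(x[, v]))
    if (length(vals) < 2) next
    mids <- (vals[-1] + vals[-length(vals)]) / 2
    for (thr in mids) {
      left <- x[, v] <= thr
      if (sum(left) < min_node_size || sum(!left) < min_node_size) next
      s <- oracle_logrank(time, status, left)
      if (!is.na(s) && abs(s) > best$stat) {
        best <- list(var = v, thresh = thr, stat = abs(s))
      }
    }
  }
  if (!is.finite(best$stat)) NULL else best
}

# Nelson-Aalen by direct risk-table accumulation.
oracle_nelson_aalen <- function(time, status, grid) {
  vapply(grid, function(g) {
    ev <- sort(unique(time[status == 1 & time <= g]))
    sum(vapply(ev, function(u) {
      sum(time == u & status == 1) / sum(time >= u)
    }, numeric(1)))
  }, numeric(1))
}

# Harrell C by explicit enumeration of all subject pairs, applying the
# permissible-pair and tie rules case by case.
oracle_cindex <- function(time, status, risk) {
  n <- length(time)
  conc <- 0
  perm <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] != time[j]) {
        s <- if (time[i] < time[j]) i else j
        l <- if (time[i] < time[j]) j else i
        if (status[s] == 0) next
        perm <- perm + 1
        conc <- conc +
          if (risk[s] > risk[l]) 1 else if (risk[s] == risk[l]) 0.5 else 0
      } else if (status[i] == 1 && status[j] == 1) {
        perm <- perm + 1
        conc <- conc + if (risk[i] == risk[j]) 1 else 0.5
      } else if (status[i] + status[j] == 1) {
        e <- if (status[i] == 1) i else j
        o <- if (status[i] == 1) j else i
        perm <- perm + 1
        conc <- conc + if (risk[e] > risk[o]) 1 else 0.5
      }
    }
  }
  if (perm == 0) NA_real_ else conc / perm
}

# Friedman statistic straight off the printed formula.
oracle_friedman <- function(ranks) {
  n <- nrow(ranks); m <- ncol(ranks)
  12 / (n * m * (m + 1)) * sum(colSums(ranks)^2) - 3 * n * (m + 1)
}

# Small random censored dataset for property sweeps.
random_surv_fixture <- function(n, p = 2, tie_prob = 0.3, cens_prob = 0.3) {
  repeat {
    time <- if (stats::runif(1) < tie_prob) {
      sample(1:4, n, replace = TRUE)  # heavy ties
    } else {
      round(stats::rexp(n), 2) + 0.01
    }
    status <- stats::rbinom(n, 1, 1 - cens_prob)
    if (sum(status) >= 1) break
  }
  surv_data(time, status, matrix(stats::rnorm(n * p), n, p))
}
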