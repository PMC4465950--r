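#' Harrell's concordance index
#'
#' Fraction of permissible subject pairs in which the subject with the
#' shorter survival carries the higher predicted risk; 0.5 is chance,
#' 1 perfect ranking. The permissible-pair and tie rules follow
#' Harrell's convention as used throughout the survival-ensemble
#' literature:
#' \itemize{
#'   \item pairs with unequal times are permissible when the shorter
#'     time is an event; concordance 1 if the shorter-lived subject
#'     has strictly higher risk, 0.5 on tied risks, else 0;
#'   \item tied times, both events: permissible; 1 on tied risks,
#'     0.5 otherwise;
#'   \item tied times, exactly one event: permissible; 1 when the
#'     event subject has the higher risk, 0.5 otherwise;
#'   \item tied times, both censored (or shorter time censored):
#'     not permissible.
#' }
#'
#' @param time positive follow-up times.
#' @param status 0/1 event indicators.
#' @param risk predicted risk scores (higher = shorter survival).
#' @return C-index in `[0, 1]`, or `NA` when no pair is permissible.
#' @examples
#' harrell_cindex(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 2, 1))  # 1
#' @export
harrell_cindex <- function(time, status, risk) {
  n <- length(time)
  stopifnot(length(status) == n, length(risk) == n)
  if (n < 2L) return(NA_real_)
  conc <- 0
  perm <- 0
  for (i in seq_len(n - 1L)) {
    ti <- time[i]; tj <- time[(i + 1L):n]
    di <- status[i]; dj <- status[(i + 1L):n]
    ri <- risk[i]; rj <- risk[(i + 1L):n]

    neq <- ti != tj
    short_i <- neq & ti < tj & di == 1
    short_j <- neq & tj < ti & dj == 1
    perm <- perm + sum(short_i) + sum(short_j)
    conc <- conc + sum(short_i * ((ri > rj) + 0.5 * (ri == rj))) +
      sum(short_j * ((rj > ri) + 0.5 * (ri == rj)))

    tie_both <- !neq & di == 1 & dj == 1
    perm <- perm + sum(tie_both)
    conc <- conc + sum(tie_both * ifelse(ri == rj, 1, 0.5))

    tie_i <- !neq & di == 1 & dj == 0
    tie_j <- !neq & di == 0 & dj == 1
    perm <- perm + sum(tie_i) + sum(tie_j)
    conc <- conc + sum(tie_i * ifelse(ri > rj, 1, 0.5)) +
      sum(tie_j * ifelse(rj > ri, 1, 0.5))
  }
  if (perm == 0) return(NA_real_)
  conc / perm
}

#' Rank matrix of model scores over repeated runs
#'
#' Converts a runs-by-models score matrix (higher score = better) to
#' within-run ranks, with average ranks on ties; the best model in a
#' run receives rank `m`. Each row's ranks sum to `m (m + 1) / 2`.
#'
#' @param scores numeric matrix, runs in rows, models in columns.
#' @return Matrix of ranks with the input's dimnames.
#' @export
rank_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L || ncol(scores) < 2L) {
    stop("need at least one run and two models", call. = FALSE)
  }
  t(apply(scores, 1L, rank))
}

#' Friedman rank-sum test statistic
#'
#' Omnibus statistic for whether `m` models perform identically over
#' `n` repeated runs, computed from the within-run ranks:
#' `FT = 12 / (n m (m + 1)) * sum_j (sum_i r_ij)^2 - 3 n (m + 1)`.
#' Under the null it is approximately chi-squared with `m - 1`
#' degrees of freedom; with ties handled by average ranks, full ties
#' give exactly 0.
#'
#' @param ranks a rank matrix as produced by [rank_matrix()].
#' @return The statistic `FT`.
#' @examples
#' friedman_statistic(rank_matrix(cbind(a = c(1, 2, 3), b = c(4, 5, 6))))
#' @export
friedman_statistic <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks); m <- ncol(ranks)
  if (n < 2L || m < 2L) stop("need n >= 2 runs and m >= 2 models",
                             call. = FALSE)
  if (any(abs(rowSums(ranks) - m * (m + 1) / 2) > 1e-8)) {
    stop("each row's ranks must sum to m(m+1)/2", call. = FALSE)
  }
  12 / (n * m * (m + 1)) * sum(colSums(ranks)^2) - 3 * n * (m + 1)
}

#' Nemenyi post-hoc statistic
#'
#' Pairwise follow-up to a significant Friedman test:
#' `z = (R1 - R2) / sqrt(m (m + 1) / (6 n))` where `R1`, `R2` are two
#' models' mean ranks over the `n` runs and `m` the number of models
#' compared. Antisymmetric in its two rank arguments; compared against
#' a studentized-range-based critical value (see
#' [nemenyi_critical_value()]).
#'
#' @param mean_rank_1,mean_rank_2 the two models' mean ranks.
#' @param n number of runs.
#' @param m number of models.
#' @return The `z` statistic.
#' @examples
#' nemenyi_z(3.0, 2.5, n = 1000, m = 4)
#' @export
nemenyi_z <- function(mean_rank_1, mean_rank_2, n, m) {
  (mean_rank_1 - mean_rank_2) / sqrt(m * (m + 1) / (6 * n))
}

#' Reference critical value for the Nemenyi test
#'
#' The conventional threshold `q_alpha / sqrt(2)`, with `q_alpha` the
#' upper-`alpha` quantile of the studentized range of `m` means with
#' infinite degrees of freedom. Provided as a reference; comparison
#' functions accept any user-supplied threshold.
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of models.
#' @return The critical value.
#' @export
nemenyi_critical_value <- function(alpha = 0.05, m) {
  stats::qtukey(1 - alpha, nmeans = m, df = Inf) / sqrt(2)
}

#' Compare survival models over repeated runs
#'
#' Full rank-based comparison of a runs-by-models score matrix
#' (e.g. per-run C-index values): within-run ranks, the Friedman
#' omnibus statistic with its chi-squared p-value, all pairwise
#' Nemenyi z statistics, and paired two-sided Wilcoxon signed-rank
#' p-values for each model pair. Models are additionally labelled
#' A, B, C, ... in column order for compact grid reporting.
#'
#' @param scores numeric matrix, runs x models, higher = better;
#'   column names are used as model names when present.
#' @param alpha significance level for the reference Nemenyi critical
#'   value.
#' @param critical critical value used to flag significant pairs;
#'   defaults to [nemenyi_critical_value()] at `alpha`.
#' @return An object of class `rotsf_comparison`: `mean_ranks`,
#'   `friedman` (statistic, df, p), `z` (antisymmetric m x m matrix),
#'   `wilcoxon_p` (m x m, `NA` on degenerate pairs), `significant`
#'   (`|z| > critical`), `critical`, `labels`.
#' @export
compare_models <- function(scores, alpha = 0.05, critical = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("need at least 2 runs and 2 models", call. = FALSE)
  }
  m <- ncol(scores)
  n <- nrow(scores)
  models <- colnames(scores)
  if (is.null(models)) models <- paste0("model", seq_len(m))
  labels <- LETTERS[seq_len(m)]
  ranks <- rank_matrix(scores)
  mean_ranks <- colMeans(ranks)
  ft <- friedman_statistic(ranks)
  if (is.null(critical)) critical <- nemenyi_critical_value(alpha, m)

  z <- outer(mean_ranks, mean_ranks,
             function(a, b) nemenyi_z(a, b, n = n, m = m))
  wil <- matrix(NA_real_, m, m, dimnames = list(models, models))
  for (j1 in seq_len(m - 1L)) {
    for (j2 in (j1 + 1L):m) {
      d <- scores[, j1] - scores[, j2]
      if (all(d == 0)) next  # degenerate pair: identical scores
      p <- stats::wilcox.test(scores[, j1], scores[, j2], paired = TRUE,
                              exact = FALSE)$p.value
      wil[j1, j2] <- wil[j2, j1] <- p
    }
  }
  dimnames(z) <- list(models, models)
  structure(list(
    models = models, labels = stats::setNames(labels, models),
    n = n, mean_ranks = mean_ranks,
    friedman = list(statistic = ft, df = m - 1L,
                    p = stats::pchisq(ft, m - 1L, lower.tail = FALSE)),
    z = z, wilcoxon_p = wil,
    significant = abs(z) > critical, critical = critical
  ), class = "rotsf_comparison")
}

#' @export
print.rotsf_comparison <- function(x, ...) {
  m <- length(x$models)
  cat(sprintf("Model comparison over %d runs\n", x$n))
  for (j in seq_len(m)) {
    cat(sprintf("  %s = %-10s mean rank %.4f\n",
                x$labels[j], x$models[j], x$mean_ranks[j]))
  }
  cat(sprintf("Friedman FT = %.4f (df = %d, p = %.4g)\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p))
  cat(sprintf("Nemenyi z (row - column), critical value %.4f:\n",
              x$critical))
  zz <- x$z
  dimnames(zz) <- list(x$labels, x$labels)
  print(round(zz, 4))
  cat("Wilcoxon signed-rank p (paired):\n")
  ww <- x$wilcoxon_p
  dimnames(ww) <- list(x$labels, x$labels)
  print(signif(ww, 4))
  invisible(x)
}
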