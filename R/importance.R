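#' Permutation variable importance: mean C-index decrease
#'
#' For each ensemble member, Harrell's C-index of the member's risk
#' predictions is computed on its own out-of-bag subjects before and
#' after permuting one covariate's values among those subjects, and
#' the importance of the covariate is the average drop across
#' members, scaled by 100:
#' `VI = (100 / L) * sum_j (C_j - C_j_permuted)`.
#'
#' Permutation happens in the original covariate space, before each
#' member's rotation is applied, so importance is attributed to the
#' named covariates rather than to rotated features; in-bag rows are
#' never touched. A member for which the covariate fell into the
#' remainder set contributes exactly zero (its rotation row is zero,
#' so the permutation is invisible). Members whose OOB set admits no
#' permissible pairs (undefined C-index) are skipped and the divisor
#' reduced accordingly.
#'
#' @param model a fitted [rotsf].
#' @param data the training [surv_data].
#' @param vars covariate indices or names to score (default: all).
#' @param n_perm permutation replicates per member per covariate,
#'   averaged (default 1, matching the one-shuffle-per-member
#'   definition).
#' @param seed optional seed for the permutation draws.
#' @param .permute permutation generator, `function(k)` returning an
#'   ordering of `1:k`; the default draws a uniform shuffle.
#'   Substituting `seq_len` yields the identity permutation, under
#'   which every importance is exactly zero.
#' @return Named numeric vector of importances on the x100 percent
#'   scale (positive = predictive signal).
#' @examples
#' d <- generate_ph_data(sim_spec(n = 150, p = 4,
#'                                beta = c(1.5, 0, 0, 0), seed = 3))
#' fit <- rotsf(d, trees = 30, seed = 3)
#' mean_cindex_decrease(fit, d, seed = 3)
#' @export
mean_cindex_decrease <- function(model, data, vars = NULL, n_perm = 1L,
                                 seed = NULL, .permute = NULL) {
  stopifnot(inherits(model, "rotsf"), inherits(data, "surv_data"))
  x <- as_covmatrix(data, model$p)
  vars <- resolve_vars(vars, model$names)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(.permute)) .permute <- function(k) sample.int(k)

  vi_sum <- numeric(length(vars))
  used <- integer(length(vars))
  for (i in seq_along(model$members)) {
    oob <- which(model$inbag[i, ] == 0L)
    if (length(oob) < 2L) next
    xo <- x[oob, , drop = FALSE]
    c0 <- harrell_cindex(data$time[oob], data$status[oob],
                         member_risk(model, i, xo))
    if (is.na(c0)) next
    rem <- model$members[[i]]$partition$remainder
    for (k in seq_along(vars)) {
      v <- vars[k]
      used[k] <- used[k] + 1L
      if (v %in% rem) next  # zero loading row: drop is identically 0
      drop_sum <- 0
      for (r in seq_len(n_perm)) {
        xp <- xo
        xp[, v] <- xp[.permute(nrow(xp)), v]
        cp <- harrell_cindex(data$time[oob], data$status[oob],
                             member_risk(model, i, xp))
        drop_sum <- drop_sum + (c0 - cp)
      }
      vi_sum[k] <- vi_sum[k] + drop_sum / n_perm
    }
  }
  if (any(used == 0L)) {
    warning("no member had a usable OOB C-index", call. = FALSE)
  }
  vi <- 100 * vi_sum / pmax(used, 1L)
  vi[used == 0L] <- NA_real_
  stats::setNames(vi, model$names[vars])
}

resolve_vars <- function(vars, names) {
  p <- length(names)
  if (is.null(vars)) return(seq_len(p))
  if (is.character(vars)) {
    idx <- match(vars, names)
    if (anyNA(idx)) {
      stop("unknown covariate(s): ",
           paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  vars <- as.integer(vars)
  if (any(vars < 1L | vars > p)) stop("covariate index out of range",
                                      call. = FALSE)
  vars
}

#' Rank covariates by importance
#'
#' Sorts covariates by decreasing mean C-index decrease; ties resolve
#' to the original column order. Larger values mark covariates whose
#' shuffling costs the most ranking accuracy.
#'
#' @inheritParams mean_cindex_decrease
#' @param top_k how many covariates to keep (default: all).
#' @param ... passed to [mean_cindex_decrease()].
#' @return Data frame with columns `variable`, `vi`, `rank`.
#' @export
rank_importances <- function(model, data, top_k = NULL, ...) {
  vi <- mean_cindex_decrease(model, data, ...)
  ord <- order(-vi, seq_along(vi))
  out <- data.frame(variable = names(vi)[ord], vi = unname(vi[ord]),
                    rank = seq_along(vi))
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  rownames(out) <- NULL
  out
}
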