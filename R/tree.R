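#' Standardized two-group log-rank statistic
#'
#' The split criterion of the survival trees: observed-minus-expected
#' events in group 1, divided by the square root of the summed
#' hypergeometric variance, accumulated over the distinct event times.
#' Censored subjects tied with an event time remain at risk at that
#' time. The statistic is antisymmetric under swapping the group
#' labels; split search uses its absolute value.
#'
#' @param time positive follow-up times.
#' @param status 0/1 event indicators.
#' @param membership logical or 0/1 vector; TRUE/1 marks group 1. Both
#'   groups must be non-empty.
#' @return The standardized log-rank statistic, or `NA` when the
#'   variance is zero (the "no information" sentinel — e.g. all events
#'   concentrated where the risk sets contain a single group).
#' @examples
#' logrank_split_stat(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
#' @export
logrank_split_stat <- function(time, status, membership) {
  membership <- as.integer(as.logical(membership))
  if (length(unique(membership)) != 2L) {
    stop("membership must split subjects into two non-empty groups",
         call. = FALSE)
  }
  if (sum(status) < 1) stop("need at least one event", call. = FALSE)
  cpp_logrank_split_stat(as.numeric(time), as.numeric(status), membership)
}

#' Nelson-Aalen cumulative hazard on a grid
#'
#' Step-function estimate of the cumulative hazard,
#' `CHF(t) = sum over event times u <= t of d(u) / Y(u)`,
#' with `d(u)` events and `Y(u)` subjects at risk at `u`; evaluated at
#' the supplied grid points (right-continuous, zero before the first
#' event time). With no events the estimate is identically zero.
#'
#' @inheritParams logrank_split_stat
#' @param grid sorted ascending evaluation times.
#' @return Numeric vector of CHF values, one per grid point;
#'   non-negative and non-decreasing.
#' @examples
#' nelson_aalen_chf(c(1, 2, 3), c(1, 1, 1), grid = c(1, 2, 3))  # 1/3, 5/6, 11/6
#' @export
nelson_aalen_chf <- function(time, status, grid) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending", call. = FALSE)
  cpp_nelson_aalen(as.numeric(time), as.numeric(status), as.numeric(grid))
}

#' Best log-rank split of a node
#'
#' Exhaustively scans every covariate and every candidate threshold
#' (midpoints of consecutive distinct observed values) and returns the
#' split maximizing the absolute log-rank statistic, subject to both
#' children containing at least `min_node_size` subjects. The
#' convention `x <= thresh` goes left; ties in the criterion resolve
#' to the earliest covariate and smallest threshold.
#'
#' @param data a [surv_data] object (the node's subjects).
#' @param min_node_size minimum child size.
#' @return A list with `var` (column index), `thresh` and `stat`
#'   (absolute log-rank value), or `NULL` when no admissible split
#'   exists (constant covariates, size limits, or all-sentinel
#'   statistics).
#' @export
best_split <- function(data, min_node_size = 6L) {
  stopifnot(inherits(data, "surv_data"))
  res <- cpp_best_split(data$x, data$time, data$status,
                        as.integer(min_node_size))
  if (res$var < 1) return(NULL)
  res
}

#' Grow a survival CART
#'
#' Recursive greedy partition by [best_split] until no admissible
#' split remains (fewer than `2 * min_node_size` subjects, no events,
#' or only sentinel statistics). Each leaf stores the Nelson-Aalen
#' cumulative hazard of its training subjects evaluated on the tree
#' grid — the sorted distinct event times of the tree's training data.
#'
#' @param data a [surv_data] object.
#' @param min_node_size minimum subjects per leaf (default 6).
#' @return An object of class `rotsf_tree`: node table (`var`,
#'   `thresh`, `left`, `right`, `size`), per-leaf `chf` list, `grid`,
#'   `leaf_of` (training-row leaf assignment) and `p`.
#' @examples
#' d <- sim_spec(n = 80, p = 3, beta = c(1.5, 0, 0), seed = 1) |>
#'   generate_ph_data()
#' tr <- grow_tree(d)
#' length(tr$grid)
#' @export
grow_tree <- function(data, min_node_size = 6L) {
  stopifnot(inherits(data, "surv_data"))
  fit <- cpp_grow_tree(data$x, data$time, data$status,
                       as.integer(min_node_size))
  fit$min_node_size <- as.integer(min_node_size)
  fit$p <- ncol(data$x)
  class(fit) <- "rotsf_tree"
  fit
}

#' @export
print.rotsf_tree <- function(x, ...) {
  cat(sprintf("<rotsf_tree> %d nodes (%d leaves), grid of %d event times\n",
              length(x$var), sum(x$var < 0), length(x$grid)))
  invisible(x)
}

#' Predict per-subject cumulative hazard from a single tree
#'
#' Routes each covariate row through the splits (`x <= thresh` goes
#' left) and returns the reached leaf's cumulative hazard function on
#' the tree grid.
#'
#' @param tree a `rotsf_tree`.
#' @param x numeric matrix (or single vector) with as many columns as
#'   the tree's training data.
#' @return A list with `grid` and `chf`, an `nrow(x)` by
#'   `length(grid)` matrix of step-function values.
#' @export
predict_tree_chf <- function(tree, x) {
  stopifnot(inherits(tree, "rotsf_tree"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != tree$p) {
    stop(sprintf("tree expects %d covariates, got %d", tree$p, ncol(x)),
         call. = FALSE)
  }
  leaves <- tree_leaf_of(tree, x)
  G <- length(tree$grid)
  if (G == 0L) {
    chf <- matrix(0, nrow(x), 0L)
  } else {
    chf <- t(vapply(tree$chf[leaves + 1L], identity, numeric(G)))
  }
  list(grid = tree$grid, chf = chf)
}

# 0-based leaf node index per row of x
tree_leaf_of <- function(tree, x) {
  cpp_predict_leaf(tree$var, tree$thresh, tree$left, tree$right, x)
}
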