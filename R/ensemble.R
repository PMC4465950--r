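#' Fit a rotation survival forest
#'
#' Trains an ensemble of `trees` survival CARTs, each on its own
#' rotated view of a bootstrap sample. For member `i`: (1) draw an
#' outer bootstrap `D'` of size `n` from the data; (2) randomly
#' partition the `p` covariates into `floor(p / M)` disjoint subsets
#' of size `M` (the `p %% M` leftovers form that member's remainder
#' set); (3) for each subset, draw an inner bootstrap `D''` of size
#' `n` from `D'` and take the PCA loadings of the subset's columns of
#' `D''`; (4) assemble the block rotation matrix with zero rows for
#' the remainder covariates; (5) grow a log-rank survival tree on the
#' rotated outer sample. The inner bootstrap only shapes the loadings
#' ("double bagging"); with `double_bagging = FALSE` the loadings are
#' computed on `D'` itself (single bagging).
#'
#' Member construction is a pure function of the data and the member's
#' own seed: the `i`-th member is identical whatever the ensemble
#' size, and refitting with the same seed reproduces the model.
#'
#' @param data a [surv_data] object.
#' @param trees ensemble size `L` (default 1000).
#' @param M variable-subset size (default 2, the conventional rotation
#'   forest setting).
#' @param min_node_size minimum subjects per leaf (default 6).
#' @param double_bagging use the inner bootstrap for the loadings
#'   (TRUE, the default) or compute them on the outer sample (FALSE).
#' @param scale. scale covariate blocks to unit variance before PCA
#'   (default FALSE: centering only).
#' @param seed integer master seed; every source of randomness in the
#'   fit flows from it.
#' @return An object of class `rotsf`: `members` (list of rotation +
#'   tree pairs), `inbag` (`L x n` outer-bootstrap draw counts),
#'   `grid` (pooled sorted distinct training event times), `config`,
#'   `names`.
#' @examples
#' d <- generate_ph_data(sim_spec(n = 120, p = 4,
#'                                beta = c(1, 0, 0, 0), seed = 7))
#' fit <- rotsf(d, trees = 25, seed = 7)
#' fit
#' @seealso [predict.rotsf()], [oob_cindex()], [mean_cindex_decrease()]
#' @export
rotsf <- function(data, trees = 1000L, M = 2L, min_node_size = 6L,
                  double_bagging = TRUE, scale. = FALSE, seed = NULL) {
  stopifnot(inherits(data, "surv_data"))
  trees <- as.integer(trees)
  M <- as.integer(M)
  n <- length(data$time)
  p <- ncol(data$x)
  if (trees < 1L) stop("need at least one tree", call. = FALSE)
  if (M < 1L || M > p) stop("need 1 <= M <= p", call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, trees)

  members <- vector("list", trees)
  inbag <- matrix(0L, nrow = trees, ncol = n)
  for (i in seq_len(trees)) {
    m <- fit_member(data, member_seeds[i], M, min_node_size,
                    double_bagging, scale.)
    members[[i]] <- m
    inbag[i, ] <- m$inbag
    members[[i]]$inbag <- NULL
  }

  structure(list(
    members = members,
    inbag = inbag,
    grid = sort(unique(data$time[data$status == 1])),
    config = list(trees = trees, M = M, min_node_size = min_node_size,
                  double_bagging = double_bagging, scale. = scale.,
                  seed = seed),
    names = data$names,
    n = n, p = p
  ), class = "rotsf")
}

# One ensemble member, a pure function of (data, member seed).
fit_member <- function(data, member_seed, M, min_node_size,
                       double_bagging, scale.) {
  set.seed(member_seed)
  n <- length(data$time)
  rows <- sample.int(n, n, replace = TRUE)
  spec <- build_rotation_spec(data, rows, M, double_bagging, scale.)
  rotated <- surv_data(data$time[rows], data$status[rows],
                       rotate(data$x[rows, , drop = FALSE], spec$rotation))
  tree <- grow_tree(rotated, min_node_size)
  list(partition = spec$partition, loadings = spec$loadings,
       rotation = spec$rotation, tree = tree, seed = member_seed,
       inbag = tabulate(rows, nbins = n))
}

#' @export
print.rotsf <- function(x, ...) {
  cat(sprintf(
    "<rotsf> %d trees (%s bagging), M = %d, %d subjects x %d covariates\n",
    x$config$trees, if (x$config$double_bagging) "double" else "single",
    x$config$M, x$n, x$p
  ))
  invisible(x)
}

# Member i's CHF for rows of x (original covariate space), carried
# onto the model grid by right-continuous step interpolation: 0 before
# the member's first event time, last value after its last.
member_chf <- function(model, i, x) {
  m <- model$members[[i]]
  pred <- predict_tree_chf(m$tree, rotate(x, m$rotation))
  step_interp(pred$grid, pred$chf, model$grid)
}

member_risk <- function(model, i, x) {
  rowSums(member_chf(model, i, x))
}

# chf: n x length(from) step values on grid `from`; re-evaluated at `to`
step_interp <- function(from, chf, to) {
  idx <- findInterval(to, from)
  cbind(0, chf)[, idx + 1L, drop = FALSE]
}

#' Predict ensemble cumulative hazard and risk
#'
#' Each member rotates the new covariates with its own rotation
#' matrix, routes them through its tree and contributes its leaf
#' Nelson-Aalen CHF (re-evaluated on the pooled model grid); the
#' ensemble CHF is the unweighted mean over members. The scalar risk
#' score is the sum of the ensemble CHF over all grid times — a
#' mortality-style score: higher values mean shorter expected
#' survival, and it preserves the ordering of non-crossing CHF curves.
#'
#' @param object a fitted [rotsf] model.
#' @param newdata numeric matrix (or `surv_data`) with `p` columns.
#' @param type `"risk"` (default) for the scalar score per subject, or
#'   `"chf"` for the full list with `grid` and the `n x grid` CHF
#'   matrix.
#' @param ... unused.
#' @return Numeric risk vector, or a list `(grid, chf)`.
#' @export
predict.rotsf <- function(object, newdata, type = c("risk", "chf"), ...) {
  type <- match.arg(type)
  x <- as_covmatrix(newdata, object$p)
  acc <- matrix(0, nrow(x), length(object$grid))
  for (i in seq_along(object$members)) {
    acc <- acc + member_chf(object, i, x)
  }
  chf <- acc / length(object$members)
  if (type == "chf") list(grid = object$grid, chf = chf) else rowSums(chf)
}

as_covmatrix <- function(newdata, p) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else newdata
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != p) {
    stop(sprintf("model expects %d covariates, got %d", p, ncol(x)),
         call. = FALSE)
  }
  x
}

#' Out-of-bag risk predictions
#'
#' For each training subject, averages the risk predictions of only
#' those members whose outer bootstrap excluded the subject. Subjects
#' that every member drew in-bag get `NA` (flagged, never imputed);
#' with more than a handful of trees this is vanishingly rare.
#'
#' @param model a fitted [rotsf].
#' @param data the training [surv_data].
#' @return Numeric vector of length `n` with `NA` for uncovered
#'   subjects.
#' @export
oob_risk <- function(model, data) {
  stopifnot(inherits(model, "rotsf"))
  x <- as_covmatrix(data, model$p)
  n <- nrow(x)
  risk_sum <- numeric(n)
  cover <- integer(n)
  for (i in seq_along(model$members)) {
    oob <- which(model$inbag[i, ] == 0L)
    if (!length(oob)) next
    risk_sum[oob] <- risk_sum[oob] +
      member_risk(model, i, x[oob, , drop = FALSE])
    cover[oob] <- cover[oob] + 1L
  }
  out <- risk_sum / cover
  out[cover == 0L] <- NA_real_
  out
}

#' Out-of-bag concordance index
#'
#' Harrell's C-index of the out-of-bag risk predictions against the
#' training outcomes; the honest (refit-free) estimate of the model's
#' ranking accuracy. Subjects without OOB coverage are dropped.
#'
#' @inheritParams oob_risk
#' @return C-index in `[0, 1]`, or `NA` if no permissible pairs.
#' @export
oob_cindex <- function(model, data) {
  r <- oob_risk(model, data)
  ok <- !is.na(r)
  harrell_cindex(data$time[ok], data$status[ok], r[ok])
}

#' Serialize / restore a fitted model
#'
#' Writes the complete fitted ensemble — configuration, per-member
#' variable partitions, PCA loadings, tree node tables and leaf
#' CHFs, in-bag counts and the time grid — to a JSON container, so a
#' model can be reloaded and used for prediction without refitting.
#'
#' @param model a fitted [rotsf].
#' @param path file path for the JSON container.
#' @return `write_rotsf` invisibly returns `path`; `read_rotsf`
#'   returns the restored `rotsf` object.
#' @export
write_rotsf <- function(model, path) {
  stopifnot(inherits(model, "rotsf"))
  payload <- list(
    format = "rotsf-model-1",
    config = model$config,
    names = model$names,
    n = model$n, p = model$p,
    grid = model$grid,
    inbag = model$inbag,
    members = lapply(model$members, function(m) {
      list(
        subsets = m$partition$subsets,
        remainder = m$partition$remainder,
        loadings = m$loadings,
        seed = m$seed,
        tree = list(
          var = m$tree$var, thresh = m$tree$thresh,
          left = m$tree$left, right = m$tree$right,
          size = m$tree$size, chf = m$tree$chf,
          grid = m$tree$grid, min_node_size = m$tree$min_node_size,
          p = m$tree$p
        )
      )
    })
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              na = "null", null = "null"),
             path)
  invisible(path)
}

#' @rdname write_rotsf
#' @export
read_rotsf <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(j$format, "rotsf-model-1")) {
    stop("not a rotsf model container", call. = FALSE)
  }
  p <- as.integer(j$p)
  num <- function(v) as.numeric(unlist(v))
  members <- lapply(j$members, function(m) {
    subsets <- lapply(m$subsets, function(s) as.integer(unlist(s)))
    loadings <- lapply(m$loadings, function(l) {
      do.call(rbind, lapply(l, num))  # rows round-trip as inner arrays
    })
    partition <- list(subsets = subsets,
                      remainder = as.integer(unlist(m$remainder)))
    tree <- list(
      var = as.integer(unlist(m$tree$var)),
      thresh = num(m$tree$thresh),
      left = as.integer(unlist(m$tree$left)),
      right = as.integer(unlist(m$tree$right)),
      size = as.integer(unlist(m$tree$size)),
      chf = lapply(m$tree$chf, num),
      grid = num(m$tree$grid),
      min_node_size = as.integer(m$tree$min_node_size),
      p = as.integer(m$tree$p)
    )
    # a single-node tree's scalar fields lose their array wrapper
    if (!is.list(m$tree$chf)) tree$chf <- list(num(m$tree$chf))
    class(tree) <- "rotsf_tree"
    list(partition = partition, loadings = loadings,
         rotation = assemble_rotation(partition, loadings, p),
         tree = tree, seed = m$seed)
  })
  structure(list(
    members = members,
    inbag = matrix(as.integer(unlist(j$inbag)), nrow = length(members),
                   byrow = TRUE),
    grid = num(j$grid),
    config = j$config,
    names = as.character(unlist(j$names)),
    n = as.integer(j$n), p = p
  ), class = "rotsf")
}
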