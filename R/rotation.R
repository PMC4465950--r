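#' Random partition of covariates into equal-size subsets
#'
#' Chops a uniformly random permutation of `1:p` into
#' `k = floor(p / M)` disjoint subsets of size `M`; when `p` is not
#' divisible by `M` the trailing `p %% M` indices form the remainder
#' set, which receives zero loadings in the assembled rotation (those
#' covariates do not influence that ensemble member).
#'
#' @param p number of covariates.
#' @param M subset size, `1 <= M <= p`.
#' @return A list with `subsets` (list of `k` integer vectors of
#'   length `M`) and `remainder` (integer vector of length `p %% M`).
#' @examples
#' set.seed(1)
#' partition_variables(5, 2)  # 2 subsets, 1 remainder variable
#' @export
partition_variables <- function(p, M) {
  p <- as.integer(p); M <- as.integer(M)
  if (M < 1L || M > p) stop("need 1 <= M <= p", call. = FALSE)
  perm <- sample.int(p)
  k <- p %/% M
  subsets <- lapply(seq_len(k), function(j) perm[((j - 1L) * M + 1L):(j * M)])
  remainder <- if (p %% M) perm[(k * M + 1L):p] else integer(0)
  list(subsets = subsets, remainder = remainder)
}

#' PCA loadings of a covariate block
#'
#' Principal-axis loading vectors of a column-centered (by default
#' unscaled) data block: the orthonormal eigenvectors of the sample
#' covariance, ordered by decreasing explained variance, all `M`
#' components retained. The sign of each column is fixed by making its
#' largest-magnitude entry positive, removing the sign ambiguity of
#' PCA. Rank-deficient blocks (constant columns, duplicated rows from
#' an inner bootstrap) are completed to a full orthonormal basis via
#' the eigendecomposition rather than failing.
#'
#' @param x_block numeric matrix, `n >= 2` rows and `M` columns.
#' @param scale. also scale columns to unit variance before the
#'   decomposition (default FALSE: centering only).
#' @return `M x M` matrix with orthonormal columns.
#' @examples
#' b <- cbind(c(2, -2, 0, 0), c(0, 0, 1, -1))  # cov = diag(4/3, 2/3)
#' block_pca_loadings(b)
#' @export
block_pca_loadings <- function(x_block, scale. = FALSE) {
  x_block <- as.matrix(x_block)
  if (nrow(x_block) < 2L) stop("need at least 2 rows for PCA", call. = FALSE)
  if (scale.) {
    s <- apply(x_block, 2L, stats::sd)
    x_block <- sweep(x_block, 2L, ifelse(s > 0, s, 1), "/")
  }
  ev <- eigen(stats::cov(x_block), symmetric = TRUE)
  fix_signs(ev$vectors)
}

# largest-magnitude entry of each column made positive (first on ties)
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Assemble the rearranged rotation matrix
#'
#' Places each subset's loading block on the block diagonal, with rows
#' indexed by the original covariates: the row for covariate `v` in
#' subset `j` carries `v`'s row of that subset's loadings in column
#' block `j`; rows for remainder covariates are identically zero.
#' Column blocks are ordered by subset index, so the result is a
#' `p x (k * M)` matrix mapping original covariates to rotated
#' features.
#'
#' @param partition as returned by [partition_variables].
#' @param loadings list of `k` loading matrices from
#'   [block_pca_loadings], one per subset.
#' @param p total number of covariates.
#' @return The rotation matrix, with column names `s<j>.pc<c>` naming
#'   subset and component.
#' @export
assemble_rotation <- function(partition, loadings, p) {
  subsets <- partition$subsets
  k <- length(subsets)
  if (length(loadings) != k) stop("one loading block per subset", call. = FALSE)
  idx <- unlist(subsets)
  if (anyDuplicated(c(idx, partition$remainder)) ||
      !setequal(c(idx, partition$remainder), seq_len(p))) {
    stop("subsets plus remainder must partition 1:p", call. = FALSE)
  }
  M <- length(subsets[[1L]])
  R <- matrix(0, nrow = p, ncol = k * M)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * M + 1L):(j * M)
    R[subsets[[j]], cols] <- loadings[[j]]
  }
  colnames(R) <- unlist(lapply(seq_len(k), function(j) {
    paste0("s", j, ".pc", seq_len(M))
  }))
  R
}

#' Rotate a covariate matrix
#'
#' The matrix product `x %*% rotation`: re-expresses the original
#' covariates as per-subset principal components. Remainder covariates
#' have all-zero rows in the rotation, so their values cannot affect
#' the result.
#'
#' @param x numeric matrix with `p` columns.
#' @param rotation a `p x (k * M)` matrix from [assemble_rotation].
#' @return `n x (k * M)` rotated matrix.
#' @export
rotate <- function(x, rotation) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(rotation)) {
    stop(sprintf("x has %d columns but rotation expects %d",
                 ncol(x), nrow(rotation)), call. = FALSE)
  }
  x %*% rotation
}

# Draws one member's complete rotation: partition, per-subset loadings
# (each on its own inner bootstrap when double_bagging), assembled R.
# rows: the member's outer-bootstrap row indices into data$x.
build_rotation_spec <- function(data, rows, M, double_bagging = TRUE,
                                scale. = FALSE) {
  p <- ncol(data$x)
  n <- length(rows)
  partition <- partition_variables(p, M)
  loadings <- lapply(partition$subsets, function(vs) {
    inner <- if (double_bagging) rows[sample.int(n, n, replace = TRUE)] else rows
    block_pca_loadings(data$x[inner, vs, drop = FALSE], scale. = scale.)
  })
  list(partition = partition, loadings = loadings,
       rotation = assemble_rotation(partition, loadings, p))
}
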