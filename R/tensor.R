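#' Vectorize a symmetric matrix, preserving the Frobenius inner product
#'
#' Diagonal elements are copied in trait order; each off-diagonal element is
#' included once, scaled by sqrt(2), in row-major upper-triangle order
#' ((1,2), (1,3), ..., (1,n), (2,3), ...). With this scaling the Euclidean
#' inner product of two vectorized matrices equals the Frobenius inner
#' product of the matrices, which is what makes the covariance-of-matrices
#' construction an honest covariance.
#'
#' @param G symmetric n x n matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `n(n+1)/2`.
#' @export
vec_sym <- function(G, tol = 1e-10) {
  G <- as.matrix(G)
  if (!isSymmetric(unname(G), tol = tol)) stop("matrix must be symmetric")
  n <- nrow(G)
  idx <- upper_pairs(n)
  c(diag(G), sqrt(2) * G[idx])
}

#' @rdname vec_sym
#' @param v vector of length `n(n+1)/2` produced by [vec_sym()].
#' @param n matrix dimension.
#' @export
unvec_sym <- function(v, n) {
  if (length(v) != n * (n + 1) / 2) stop("length(v) != n(n+1)/2")
  G <- diag(v[seq_len(n)], n)
  idx <- upper_pairs(n)
  off <- v[-seq_len(n)] / sqrt(2)
  G[idx] <- off
  G[idx[, 2:1, drop = FALSE]] <- off
  G
}

upper_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(seq_len(n - 1), function(i)
    cbind(i, seq.int(i + 1, n))))
}

#' Covariance matrix of matrix elements across a set of matrices
#'
#' The s x s matrix `S` (s = n(n+1)/2) is the sample covariance (divisor
#' m - 1) of the vectorized matrices; its eigenstructure describes how the
#' matrices in the set differ from one another.
#'
#' @param mats list of m >= 2 symmetric matrices of common dimension.
#' @return s x s symmetric PSD matrix.
#' @export
build_s_matrix <- function(mats) {
  if (length(mats) < 2) stop("need at least 2 matrices")
  s <- length(vec_sym(mats[[1]]))
  V <- matrix(vapply(mats, vec_sym, numeric(s)), ncol = s, byrow = TRUE)
  S <- cov(V)
  (S + t(S)) / 2
}

#' Eigentensor decomposition of a matrix set
#'
#' Eigen-decomposes the element-covariance matrix `S`; each eigenvector is
#' mapped back to a symmetric n x n matrix (an eigentensor, unit Frobenius
#' norm). At most m - 1 eigenvalues are nonzero for a set of m matrices.
#' Each eigentensor is further spectrally decomposed into its own
#' eigenvectors, ordered by decreasing absolute eigenvalue, so that `e11` —
#' the first eigenvector of the first eigentensor — is the phenotypic
#' direction carrying most of the differentiation among the matrices.
#'
#' @param S output of [build_s_matrix()] (or any symmetric PSD matrix of
#'   valid dimension).
#' @param tol tolerance for the PSD check, relative to the largest eigenvalue.
#' @return a `tensor_decomposition` list: `S`, `alpha` (descending
#'   eigenvalues), `alpha_prop` (proportions of their sum), `eigentensors`
#'   (list of symmetric matrices), `tensor_eigen` (per-eigentensor
#'   eigendecompositions: `values` ordered by |value|, `vectors`), `n`.
#' @export
eigentensor_decomposition <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  s <- nrow(S)
  n <- (sqrt(8 * s + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) stop("S dimension is not n(n+1)/2")
  n <- as.integer(round(n))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(tol, max(abs(e$values))))
    stop("S is not positive semi-definite within tolerance")
  alpha <- pmax(e$values, 0)
  ets <- lapply(seq_len(s), function(j) unvec_sym(e$vectors[, j], n))
  tensor_eigen <- lapply(ets, function(E) {
    ee <- eigen(E, symmetric = TRUE)
    o <- order(abs(ee$values), decreasing = TRUE)
    V <- ee$vectors[, o, drop = FALSE]
    for (j in seq_len(ncol(V))) {
      k <- which.max(abs(V[, j]))
      if (V[k, j] < 0) V[, j] <- -V[, j]
    }
    list(values = ee$values[o], vectors = V)
  })
  structure(list(S = S, alpha = alpha,
                 alpha_prop = if (sum(alpha) > 0) alpha / sum(alpha) else alpha,
                 eigentensors = ets, tensor_eigen = tensor_eigen, n = n),
            class = "tensor_decomposition")
}

#' Coordinates of each matrix in the eigentensor basis
#'
#' The coordinate of matrix `G_j` in eigentensor `E_i` is the Frobenius inner
#' product `<G_j, E_i>`. Across the set, the sample variance of the
#' coordinates in `E_i` equals the eigenvalue `alpha_i`.
#'
#' @param mats list of symmetric matrices (same set, or posterior draws of
#'   it, as the decomposition was built from).
#' @param decomposition a `tensor_decomposition`.
#' @param k number of leading eigentensors to project on (default: all).
#' @return m x k matrix of coordinates.
#' @export
tensor_coordinates <- function(mats, decomposition, k = NULL) {
  stopifnot(inherits(decomposition, "tensor_decomposition"))
  n <- decomposition$n
  if (nrow(mats[[1]]) != n) stop("matrix dimension mismatch")
  if (is.null(k)) k <- length(decomposition$eigentensors)
  out <- matrix(NA_real_, length(mats), k)
  for (j in seq_along(mats)) for (i in seq_len(k))
    out[j, i] <- sum(as.matrix(mats[[j]]) * decomposition$eigentensors[[i]])
  rownames(out) <- names(mats)
  colnames(out) <- paste0("E", seq_len(k))
  out
}

#' Null distribution of eigentensor eigenvalues
#'
#' Runs the full tensor analysis on each randomized matrix set (e.g. sets of
#' permutation-null posterior-mean matrices) and returns the per-eigenvalue
#' null bands the observed `alpha` are compared against.
#'
#' @param null_sets list of matrix sets; each set is a list of matrices with
#'   the same shape as the observed set.
#' @param observed the observed `tensor_decomposition`.
#' @param level credible level of the bands.
#' @return list with `samples` (replicates x s matrix of null alphas) and
#'   `bands` (s x 2).
#' @export
tensor_null <- function(null_sets, observed, level = 0.95) {
  stopifnot(inherits(observed, "tensor_decomposition"))
  s <- length(observed$alpha)
  samples <- t(vapply(null_sets, function(set) {
    td <- eigentensor_decomposition(build_s_matrix(set))
    if (length(td$alpha) != s) stop("null set shape mismatch")
    td$alpha
  }, numeric(s)))
  bands <- t(apply(samples, 2, interval_or_point, level = level))
  colnames(bands) <- c("lower", "upper")
  list(samples = samples, bands = bands)
}

#' Posterior uncertainty of eigentensor coordinates and eigenvalues
#'
#' Eigentensors stay fixed at the point-estimate decomposition; each
#' posterior draw of the matrix set is projected onto them, giving draws of
#' the coordinates and, via the across-set variance of coordinates per
#' eigentensor, draws of an alpha analog.
#'
#' @param posteriors list (one element per matrix in the set) of d x d x n
#'   arrays of posterior draws; draw counts may differ, the minimum is used.
#' @param decomposition the point-estimate `tensor_decomposition`.
#' @param k number of leading eigentensors to track.
#' @param levels credible levels.
#' @return list with `coordinates` (array m x k x draws),
#'   `alpha_samples` (draws x k), and equal-tailed `intervals` for both.
#' @export
tensor_posterior <- function(posteriors, decomposition, k = 2,
                             levels = c(0.83, 0.95)) {
  stopifnot(inherits(decomposition, "tensor_decomposition"))
  if (length(posteriors) < 2) stop("need posterior draws for >= 2 matrices")
  arrs <- lapply(posteriors, posterior_array)
  n_draws <- min(vapply(arrs, function(a) dim(a)[3], integer(1)))
  if (n_draws < 2) stop("need at least 2 posterior draws per matrix")
  m <- length(arrs)
  coords <- array(NA_real_, c(m, k, n_draws),
                  dimnames = list(names(posteriors),
                                  paste0("E", seq_len(k)), NULL))
  for (s in seq_len(n_draws)) {
    mats <- lapply(arrs, function(a) a[, , s])
    coords[, , s] <- tensor_coordinates(mats, decomposition, k = k)
  }
  alpha_samples <- t(apply(coords, 3, function(cm)
    apply(matrix(cm, m, k), 2, var)))
  colnames(alpha_samples) <- paste0("E", seq_len(k))
  ivs <- function(x) {
    out <- t(vapply(levels, function(lv) interval_or_point(x, lv), numeric(2)))
    rownames(out) <- paste0(levels * 100, "%")
    out
  }
  coord_int <- lapply(seq_len(m), function(j)
    lapply(seq_len(k), function(i) ivs(coords[j, i, ])))
  names(coord_int) <- names(posteriors)
  list(coordinates = coords, alpha_samples = alpha_samples,
       intervals = list(coordinates = coord_int,
                        alpha = lapply(seq_len(k), function(i)
                          ivs(alpha_samples[, i]))))
}
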