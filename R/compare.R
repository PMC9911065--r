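#' Eigendecomposition summary of a symmetric (co)variance matrix
#'
#' Eigenvalues are returned in descending order; each eigenvector's sign is
#' fixed by making its largest-magnitude coordinate positive, so the leading
#' axis (`mmax` for an M matrix, `gmax` for a G matrix) is reported
#' reproducibly. When the top two eigenvalues are separated by less than
#' `tie_tol` the leading axis is ill-defined and the summary is flagged.
#'
#' @param M symmetric matrix (asymmetry beyond `tol` is an error).
#' @param tol symmetry tolerance.
#' @param tie_tol gap below which the leading eigenvalue is flagged as tied.
#' @return an `eigen_summary` list: `values`, `vectors` (columns, orthonormal),
#'   `mmax` (first eigenvector), `tied_leading` flag.
#' @export
eigen_summary <- function(M, tol = 1e-10, tie_tol = 1e-8) {
  M <- as.matrix(M)
  if (!isSymmetric(unname(M), tol = tol))
    stop("matrix must be symmetric within ", tol)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(M)
  structure(list(values = e$values, vectors = V, mmax = V[, 1],
                 tied_leading = (e$values[1] - e$values[2]) < tie_tol),
            class = "eigen_summary")
}

#' Folded angle between two directions, in degrees
#'
#' The angle between leading eigenvectors is only defined up to sign
#' (`v` and `-v` span the same axis), so angles above 90 degrees are folded
#' back: `theta' = 180 - theta`. The result always lies in \[0, 90\].
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return angle in degrees in \[0, 90\].
#' @export
vector_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  ct <- sum(v1 * v2) / (n1 * n2)
  ct <- min(1, max(-1, ct))
  theta <- acos(ct) * 180 / pi
  if (theta > 90) theta <- 180 - theta
  theta
}

#' Monte Carlo null distribution of the folded angle
#'
#' Samples pairs of vectors with coordinates uniform on (-1, 1) and returns
#' their folded angles. In dimension two the expected folded angle is exactly
#' 45 degrees; in higher dimensions it is larger, approaching 90 as the
#' dimension grows.
#'
#' @param dim dimension of the vectors (>= 2).
#' @param n_pairs number of pairs.
#' @param levels credible levels for the returned equal-tailed intervals.
#' @return list with `samples`, `mean`, `se` (Monte Carlo standard error) and
#'   `intervals` (one row per level).
#' @export
null_angle_samples <- function(dim, n_pairs, levels = c(0.83, 0.95)) {
  if (dim < 2) stop("`dim` must be >= 2")
  if (n_pairs < 1) stop("`n_pairs` must be >= 1")
  A <- matrix(runif(n_pairs * dim, -1, 1), n_pairs, dim)
  B <- matrix(runif(n_pairs * dim, -1, 1), n_pairs, dim)
  ct <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  ct <- pmin(1, pmax(-1, ct))
  theta <- acos(ct) * 180 / pi
  theta <- ifelse(theta > 90, 180 - theta, theta)
  ivs <- t(vapply(levels, function(lv) credible_interval(theta, lv),
                  numeric(2)))
  rownames(ivs) <- paste0(levels * 100, "%")
  list(samples = theta, mean = mean(theta),
       se = sd(theta) / sqrt(n_pairs), intervals = ivs)
}

#' Equal-tailed credible interval from posterior / Monte Carlo samples
#' @param x numeric samples (>= 2 values).
#' @param level interval mass, e.g. 0.83 or 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
credible_interval <- function(x, level = 0.95) {
  if (length(x) < 2) stop("need at least 2 samples")
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}

#' Genetic variance of a matrix along a direction
#'
#' The Rayleigh quotient `v' M v / ||v||^2`: the variance of `M` projected on
#' the axis `v` (e.g. the other genotype's `mmax`).
#'
#' @param M symmetric PSD matrix.
#' @param v nonzero direction vector.
#' @return scalar variance.
#' @export
project_variance <- function(M, v) {
  nv <- sum(v^2)
  if (nv == 0) stop("zero vector has no direction")
  drop(crossprod(v, as.matrix(M) %*% v)) / nv
}

#' Alignment statistic: projected variance relative to the leading eigenvalue
#'
#' `Pi = e / lambda_max(Mx)` where `e` is the variance of `Mx` along the
#' other matrix's leading axis. Ranges from 0 (no variance along that axis)
#' to 1 (the two leading axes are aligned).
#'
#' @param Mx symmetric PSD matrix being projected.
#' @param y_mmax leading axis of the other matrix.
#' @return scalar in \[0, 1\].
#' @export
pi_statistic <- function(Mx, y_mmax) {
  lmax <- eigen(as.matrix(Mx), symmetric = TRUE, only.values = TRUE)$values[1]
  if (lmax <= 0) stop("degenerate matrix: leading eigenvalue is not positive")
  project_variance(Mx, y_mmax) / lmax
}

#' Null expectation of the alignment statistic
#'
#' For a random direction the expected projected variance is the mean
#' eigenvalue, so `Pi0 = mean(lambda) / lambda_max = (trace/d) / lambda_max`.
#'
#' @param Mx symmetric PSD matrix.
#' @return scalar in (0, 1].
#' @export
pi_null <- function(Mx) {
  Mx <- as.matrix(Mx)
  lmax <- eigen(Mx, symmetric = TRUE, only.values = TRUE)$values[1]
  if (lmax <= 0) stop("degenerate matrix: leading eigenvalue is not positive")
  (sum(diag(Mx)) / nrow(Mx)) / lmax
}

#' Posterior distributions of Pi and Pi0
#'
#' Applies [pi_statistic()] and [pi_null()] to draws from the posterior of a
#' covariance matrix, giving equal-tailed credible intervals for both.
#'
#' @param samples 3-d array (d x d x draws) of posterior matrix draws, or a
#'   `m_posterior` object.
#' @param y_mmax direction to project along.
#' @param n_draws number of posterior draws to use (default: all; draws are
#'   subsampled evenly when fewer are requested).
#' @param levels credible levels.
#' @return list with `pi`, `pi0` sample vectors and `intervals` (list of two
#'   matrices, one row per level).
#' @export
pi_posterior <- function(samples, y_mmax, n_draws = NULL,
                         levels = c(0.83, 0.95)) {
  arr <- posterior_array(samples)
  S <- dim(arr)[3]
  if (S < 2) stop("need at least 2 posterior samples")
  idx <- seq_len(S)
  if (!is.null(n_draws) && n_draws < S)
    idx <- round(seq(1, S, length.out = n_draws))
  pis <- vapply(idx, function(s) pi_statistic(arr[, , s], y_mmax), numeric(1))
  pi0s <- vapply(idx, function(s) pi_null(arr[, , s]), numeric(1))
  iv <- function(x) {
    out <- t(vapply(levels, function(lv) interval_or_point(x, lv), numeric(2)))
    rownames(out) <- paste0(levels * 100, "%")
    out
  }
  list(pi = pis, pi0 = pi0s,
       intervals = list(pi = iv(pis), pi0 = iv(pi0s)))
}

interval_or_point <- function(x, level) {
  if (length(unique(x)) == 1) c(x[1], x[1]) else credible_interval(x, level)
}

#' Rotate null matrices onto the observed eigentraits
#'
#' For each randomized null matrix `N` and each observed eigenvector `v_k`,
#' computes the null variance `v_k' N v_k`. The resulting per-eigentrait null
#' distributions are what the observed eigenvalues are compared against.
#'
#' @param null_mats list of matrices, or a 3-d array (d x d x n).
#' @param observed an `eigen_summary` of the observed matrix.
#' @param level credible level of the returned null bands.
#' @return list with `samples` (n x d matrix, one column per eigentrait) and
#'   `bands` (d x 2 matrix of equal-tailed interval bounds).
#' @export
rotate_null_eigenvalues <- function(null_mats, observed, level = 0.95) {
  stopifnot(inherits(observed, "eigen_summary"))
  arr <- posterior_array(null_mats)
  d <- ncol(observed$vectors)
  if (dim(arr)[1] != d) stop("dimension mismatch between nulls and observed")
  n <- dim(arr)[3]
  samples <- matrix(NA_real_, n, d)
  for (k in seq_len(d)) {
    v <- observed$vectors[, k]
    samples[, k] <- vapply(seq_len(n),
                           function(s) project_variance(arr[, , s], v),
                           numeric(1))
  }
  colnames(samples) <- paste0("eigentrait_", seq_len(d))
  bands <- t(apply(samples, 2, interval_or_point, level = level))
  colnames(bands) <- c("lower", "upper")
  list(samples = samples, bands = bands)
}

#' Credible-interval overlap comparison between two sample sets
#'
#' Two posterior distributions are declared different when their equal-tailed
#' credible intervals at the chosen level do not overlap. Under variance
#' homogeneity the 83% level gives an approximate 5% pairwise test.
#'
#' @param samples_a,samples_b numeric sample vectors (>= 2 each).
#' @param level 0.83 or 0.95.
#' @return list with `different` (logical), `interval_a`, `interval_b`, `level`.
#' @export
ci_compare <- function(samples_a, samples_b, level = 0.83) {
  if (!level %in% c(0.83, 0.95))
    stop("`level` must be 0.83 or 0.95")
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("need at least 2 samples per distribution")
  ia <- interval_or_point(samples_a, level)
  ib <- interval_or_point(samples_b, level)
  different <- ia[2] < ib[1] || ib[2] < ia[1]
  list(different = different, interval_a = ia, interval_b = ib, level = level)
}

# normalize list-of-matrices / array / posterior objects to a d x d x n array
posterior_array <- function(x) {
  if (inherits(x, "m_posterior")) return(x$samples)
  if (inherits(x, "matrix_posterior")) return(x$line)
  if (is.list(x)) {
    d <- nrow(x[[1]])
    arr <- array(unlist(x), dim = c(d, d, length(x)))
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("cannot interpret input as a set of matrices")
}
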