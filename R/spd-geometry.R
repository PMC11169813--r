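#' Matrix logarithm of an SPD matrix
#'
#' Via symmetric eigendecomposition: `U diag(log lambda_i) U'`. Under the
#' log-Euclidean metric this maps the SPD manifold isometrically onto the
#' Euclidean space of symmetric matrices, where means, dispersions and
#' distances reduce to ordinary linear algebra.
#'
#' @param X SPD matrix.
#' @param regularize,epsilon see [spd_eigen()].
#' @return symmetric matrix `log(X)`.
#' @export
sym_logm <- function(X, regularize = FALSE, epsilon = NULL) {
  e <- spd_eigen(X, regularize = regularize, epsilon = epsilon)
  sym_part(e$vectors %*% (log(e$values) * t(e$vectors)))
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [sym_logm()]; always returns an SPD matrix.
#'
#' @param S symmetric matrix.
#' @return SPD matrix `exp(S)`.
#' @export
sym_expm <- function(S) {
  assert_symmetric(S, "symmetric input")
  e <- eigen(sym_part(S), symmetric = TRUE)
  sym_part(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

#' Matrix power of an SPD matrix
#'
#' `U diag(lambda_i^s) U'`. Satisfies `log(X^s) = s log(X)`; `s = -1` is the
#' inverse, `s = 0` the identity. Powers move a matrix along the geodesic
#' that joins the identity to `X`, which is how the stretching step of
#' Riemannian Procrustes analysis rescales a dataset's dispersion.
#'
#' @param X SPD matrix.
#' @param s real exponent.
#' @return SPD matrix `X^s`.
#' @export
spd_power <- function(X, s) {
  e <- spd_eigen(X)
  sym_part(e$vectors %*% (e$values^s * t(e$vectors)))
}

#' @rdname spd_power
#' @details `spd_invsqrt(X)` is the congruence factor `X^{-1/2}` used to
#'   re-center a dataset at the identity.
#' @export
spd_invsqrt <- function(X) spd_power(X, -0.5)

#' Log-Euclidean distance between two SPD matrices
#'
#' `sqrt(Tr[(log X2 - log X1)^2])`, the Frobenius norm of the log
#' difference: a Euclidean distance in the logarithmic domain. Invariant
#' under matrix inversion and orthogonal congruence.
#'
#' @param X1,X2 SPD matrices of equal dimension.
#' @return non-negative scalar.
#' @export
lem_distance <- function(X1, X2) {
  if (!identical(dim(X1), dim(X2)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  D <- sym_logm(X2) - sym_logm(X1)
  sqrt(sum(D * D))
}

#' Affine-invariant Riemannian distance between two SPD matrices
#'
#' `sqrt(sum(log(lambda_k)^2))` over the eigenvalues `lambda_k` of
#' `X1^{-1} X2`, computed through the symmetric congruence
#' `X1^{-1/2} X2 X1^{-1/2}` for numerical stability. Invariant under any
#' congruence `X -> A X A'` with invertible `A` -- the property that makes
#' the AIRM re-centering step exact.
#'
#' @param X1,X2 SPD matrices of equal dimension.
#' @return non-negative scalar.
#' @export
airm_distance <- function(X1, X2) {
  if (!identical(dim(X1), dim(X2)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  P <- spd_invsqrt(X1)
  lam <- spd_eigen(sym_part(P %*% X2 %*% P))$values
  sqrt(sum(log(lam)^2))
}

#' Log-Euclidean (Frechet) mean of an SPD dataset
#'
#' Closed form `exp(mean_i log X_i)`: the minimizer of the sum of squared
#' log-Euclidean distances. No iteration is required, which is the source of
#' the LEM methods' computational advantage over AIRM.
#'
#' @param dataset `spd_dataset` or list of SPD matrices.
#' @return SPD matrix.
#' @export
lem_mean <- function(dataset) {
  mats <- as_matrix_list(dataset)
  if (length(mats) == 0)
    ra_stop("empty dataset", "riemalign_error_invalid_input")
  sym_expm(mean_logm(mats))
}

mean_logm <- function(mats) {
  S <- sym_logm(mats[[1]])
  if (length(mats) > 1)
    for (i in 2:length(mats)) S <- S + sym_logm(mats[[i]])
  S / length(mats)
}

#' AIRM (Karcher) mean of an SPD dataset
#'
#' Deterministic full-batch fixed-point iteration
#' `M <- M^{1/2} exp(mean_i log(M^{-1/2} X_i M^{-1/2})) M^{1/2}`
#' until the Frobenius norm of the mean log term falls below `tol`.
#' Initialized at the log-Euclidean mean. The number of iterations is
#' attached as attribute `"iterations"` and the final residual as
#' `"residual"`.
#'
#' @param dataset `spd_dataset` or list of SPD matrices.
#' @param tol convergence tolerance on the gradient norm, default `1e-8`.
#' @param max_iter maximum iterations, default 100.
#' @return SPD matrix with attributes `iterations` and `residual`.
#' @export
airm_mean <- function(dataset, tol = 1e-8, max_iter = 100) {
  mats <- as_matrix_list(dataset)
  if (length(mats) == 0)
    ra_stop("empty dataset", "riemalign_error_invalid_input")
  if (length(mats) == 1) {
    M <- sym_part(mats[[1]])
    attr(M, "iterations") <- 1L
    attr(M, "residual") <- 0
    return(M)
  }
  M <- lem_mean(mats)
  resid <- Inf
  for (k in seq_len(max_iter)) {
    e <- spd_eigen(M)
    Mh <- sym_part(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
    Mih <- sym_part(e$vectors %*% (1 / sqrt(e$values) * t(e$vectors)))
    S <- matrix(0, nrow(M), ncol(M))
    for (X in mats) S <- S + sym_logm(sym_part(Mih %*% X %*% Mih))
    S <- S / length(mats)
    resid <- sqrt(sum(S * S))
    M <- sym_part(Mh %*% sym_expm(S) %*% Mh)
    if (resid <= tol) {
      attr(M, "iterations") <- k
      attr(M, "residual") <- resid
      return(M)
    }
  }
  ra_stop(sprintf("Karcher mean did not converge in %d iterations (residual %.3e)",
                  max_iter, resid),
          "riemalign_error_convergence", residual = resid)
}

#' Dispersion of an SPD dataset around a center
#'
#' Sum (or mean) of squared geodesic distances from `center` to each matrix
#' -- the manifold analogue of a variance. Both normalizations are exposed
#' because the alignment methods use the sum when forming the stretching
#' exponent and the mean when standardizing to unit variance.
#'
#' @param dataset `spd_dataset` or list of SPD matrices.
#' @param center SPD matrix.
#' @param metric `"lem"` or `"airm"`.
#' @param normalize `"sum"` or `"mean"`.
#' @return non-negative scalar.
#' @export
spd_dispersion <- function(dataset, center, metric = c("lem", "airm"),
                           normalize = c("sum", "mean")) {
  metric <- match.arg(metric)
  normalize <- match.arg(normalize)
  mats <- as_matrix_list(dataset)
  if (length(mats) == 0)
    ra_stop("empty dataset", "riemalign_error_invalid_input")
  if (!identical(dim(mats[[1]]), dim(center)))
    ra_stop("dimension mismatch between dataset and center",
            "riemalign_error_invalid_input")
  d2 <- if (metric == "lem") {
    logC <- sym_logm(center)
    vapply(mats, function(X) {
      D <- sym_logm(X) - logC
      sum(D * D)
    }, numeric(1))
  } else {
    vapply(mats, function(X) airm_distance(center, X)^2, numeric(1))
  }
  if (normalize == "mean") mean(d2) else sum(d2)
}

#' Log-Euclidean geodesic between two SPD matrices
#'
#' `exp((1 - t) log X1 + t log X2)`: the straight line in the log-domain.
#'
#' @param X1,X2 SPD matrices of equal dimension.
#' @param t position along the geodesic; 0 gives `X1`, 1 gives `X2`.
#' @return SPD matrix.
#' @export
lem_geodesic <- function(X1, X2, t) {
  if (!identical(dim(X1), dim(X2)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  if (t == 0) return(sym_part(X1))
  if (t == 1) return(sym_part(X2))
  sym_expm((1 - t) * sym_logm(X1) + t * sym_logm(X2))
}

#' Riemannian exponential map under the log-Euclidean metric
#'
#' `Exp_X(V) = exp(log X + X^{-1} V)` for a tangent vector `V` at `X`.
#' The formula carries the asymmetric term `X^{-1} V`; the argument of the
#' matrix exponential is symmetrized before decomposition (it is exactly
#' symmetric whenever `V` lies in the image of [lem_log_map()]).
#'
#' @param X base SPD matrix.
#' @param V tangent matrix at `X`.
#' @return SPD matrix.
#' @export
lem_exp_map <- function(X, V) {
  if (!identical(dim(X), dim(V)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  sym_expm(sym_part(sym_logm(X) + solve(X, V)))
}

#' Riemannian logarithmic map under the log-Euclidean metric
#'
#' `Log_X1(X2) = X1 (log X2 - log X1)`: the initial velocity of the
#' geodesic from `X1` to `X2`. Inverse of [lem_exp_map()].
#'
#' @param X1 base SPD matrix.
#' @param X2 SPD matrix of the same dimension.
#' @return tangent matrix at `X1` (not symmetric in general).
#' @export
lem_log_map <- function(X1, X2) {
  if (!identical(dim(X1), dim(X2)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  X1 %*% (sym_logm(X2) - sym_logm(X1))
}

#' Log-Euclidean group operation
#'
#' `X (.) Y = exp(log X + log Y)`: the commutative Lie-group product under
#' which the SPD manifold becomes a vector space in the log-domain. The
#' LEM mean of two matrices is the square root of their product:
#' `lem_mean({X, Y}) = (X (.) Y)^{1/2}`.
#'
#' @param X,Y SPD matrices of equal dimension.
#' @return SPD matrix.
#' @export
lem_group_op <- function(X, Y) {
  if (!identical(dim(X), dim(Y)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  sym_expm(sym_logm(X) + sym_logm(Y))
}
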