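#' @keywords internal
ra_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "riemalign_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Test a matrix for symmetry at the package tolerance
#'
#' Symmetry is judged relative to the largest absolute entry:
#' `max |X - t(X)| <= tol * max |X|` (absolute `tol` for the zero matrix).
#'
#' @param X square numeric matrix.
#' @param tol relative tolerance, default `1e-10`.
#' @return `TRUE` or `FALSE`.
#' @export
is_symmetric_matrix <- function(X, tol = 1e-10) {
  if (!is.matrix(X) || !is.numeric(X) || nrow(X) != ncol(X)) return(FALSE)
  scale <- max(abs(X))
  if (scale == 0) return(TRUE)
  max(abs(X - t(X))) <= tol * scale
}

assert_symmetric <- function(X, what = "matrix") {
  if (!is.matrix(X) || !is.numeric(X) || nrow(X) != ncol(X))
    ra_stop(sprintf("%s must be a square numeric matrix", what),
            "riemalign_error_invalid_input")
  if (!all(is.finite(X)))
    ra_stop(sprintf("%s contains non-finite values", what),
            "riemalign_error_invalid_input")
  if (!is_symmetric_matrix(X))
    ra_stop(sprintf("%s is not symmetric (tolerance 1e-10 relative)", what),
            "riemalign_error_invalid_input")
  invisible(X)
}

sym_part <- function(X) (X + t(X)) / 2

#' Eigendecomposition of an SPD matrix with an eigenvalue floor
#'
#' All matrix functions in the package go through this decomposition. The
#' input is symmetrized as `(X + t(X))/2` before `eigen()`. Eigenvalues below
#' `1e-12 * max(eigenvalue)` raise a singular-matrix error naming the
#' offending eigenvalue; with `regularize = TRUE`, `epsilon * I` is added
#' first (default `epsilon = 1e-10 * trace/n`) instead of failing silently.
#'
#' @param X square symmetric numeric matrix, expected positive definite.
#' @param regularize add `epsilon * I` before decomposing.
#' @param epsilon ridge size; default `1e-10 * mean(diag(X))`.
#' @return list with `values` and `vectors` as from [eigen()].
#' @export
spd_eigen <- function(X, regularize = FALSE, epsilon = NULL) {
  assert_symmetric(X, "SPD input")
  if (regularize) {
    if (is.null(epsilon)) epsilon <- 1e-10 * mean(diag(X))
    X <- X + diag(epsilon, nrow(X))
  }
  e <- eigen(sym_part(X), symmetric = TRUE)
  floor_val <- 1e-12 * max(e$values)
  if (any(e$values <= max(floor_val, 0))) {
    bad <- min(e$values)
    ra_stop(sprintf(
      "matrix is singular or not positive definite: eigenvalue %.6e below floor %.6e",
      bad, floor_val), "riemalign_error_singular")
  }
  e
}

#' Labeled stack of SPD matrices from one recording domain
#'
#' The manifold-valued sample: `N` symmetric positive definite matrices of a
#' shared dimension `n`, optionally labeled with class indices `1..C`, and
#' tagged with a free-form domain identifier (session or subject).
#'
#' @param matrices list of `n x n` SPD matrices.
#' @param labels optional integer class labels, one per matrix, covering a
#'   contiguous set `1..C`.
#' @param domain_id free-form tag, e.g. `"subject1/session2"`.
#' @param validate check symmetry and positive definiteness of every matrix.
#' @return object of class `spd_dataset` with fields `matrices`, `labels`,
#'   `domain_id`, `n`, `N`.
#' @export
spd_dataset <- function(matrices, labels = NULL, domain_id = "domain",
                        validate = TRUE) {
  if (!is.list(matrices) || length(matrices) == 0)
    ra_stop("matrices must be a non-empty list", "riemalign_error_invalid_input")
  n <- nrow(matrices[[1]])
  dims_ok <- vapply(matrices, function(m)
    is.matrix(m) && nrow(m) == n && ncol(m) == n, logical(1))
  if (!all(dims_ok))
    ra_stop("all matrices must share the same square dimension",
            "riemalign_error_invalid_input")
  if (validate) for (i in seq_along(matrices)) {
    assert_symmetric(matrices[[i]], sprintf("matrix %d", i))
    spd_eigen(matrices[[i]])
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(matrices))
      ra_stop("labels must match the number of matrices",
              "riemalign_error_invalid_input")
    C <- max(labels)
    if (min(labels) < 1L || !all(seq_len(C) %in% labels))
      ra_stop("labels must cover a contiguous index set 1..C",
              "riemalign_error_invalid_input")
  }
  structure(list(matrices = matrices, labels = labels,
                 domain_id = domain_id, n = n, N = length(matrices)),
            class = "spd_dataset")
}

#' @export
print.spd_dataset <- function(x, ...) {
  cat(sprintf("<spd_dataset> %d matrices of dimension %dx%d, domain '%s'\n",
              x$N, x$n, x$n, x$domain_id))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n")
  } else cat("  unlabeled\n")
  invisible(x)
}

#' @export
length.spd_dataset <- function(x) x$N

#' Subset an SPD dataset by index
#'
#' @param x `spd_dataset`.
#' @param i integer or logical index vector over trials.
#' @param ... unused.
#' @return `spd_dataset` with the selected matrices (labels subset in step).
#' @export
`[.spd_dataset` <- function(x, i, ...) {
  spd_dataset(x$matrices[i],
              labels = if (!is.null(x$labels)) x$labels[i] else NULL,
              domain_id = x$domain_id, validate = FALSE)
}

as_matrix_list <- function(x) {
  if (inherits(x, "spd_dataset")) x$matrices
  else if (is.list(x)) x
  else ra_stop("expected an spd_dataset or a list of matrices",
               "riemalign_error_invalid_input")
}
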