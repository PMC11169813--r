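#' Geometric summary statistics of one recording domain
#'
#' A domain (one session or subject) is summarized by its geometric mean,
#' optional per-class geometric means, and the dispersion of the sample
#' around the global mean -- everything the unsupervised alignment methods
#' need. Class means are computed when labels are present; they are carried
#' for completeness (they would feed a rotation step, which this package
#' deliberately omits) but no implemented transform uses them.
#'
#' @param dataset `spd_dataset`.
#' @param metric `"lem"` (closed-form mean) or `"airm"` (Karcher iteration).
#' @param normalize dispersion normalization, `"sum"` or `"mean"`.
#' @param tol,max_iter Karcher-mean controls (AIRM only).
#' @return object of class `domain_statistics` with fields `global_mean`,
#'   `class_means` (named list or `NULL`), `dispersion`, `metric`,
#'   `normalize`, `n_items`.
#' @export
compute_domain_statistics <- function(dataset, metric = c("lem", "airm"),
                                      normalize = c("sum", "mean"),
                                      tol = 1e-8, max_iter = 100) {
  metric <- match.arg(metric)
  normalize <- match.arg(normalize)
  if (!inherits(dataset, "spd_dataset") || dataset$N == 0)
    ra_stop("non-empty spd_dataset required", "riemalign_error_invalid_input")
  mean_fun <- function(mats) {
    if (metric == "lem") lem_mean(mats) else airm_mean(mats, tol, max_iter)
  }
  M <- mean_fun(dataset$matrices)
  class_means <- NULL
  if (!is.null(dataset$labels)) {
    C <- max(dataset$labels)
    class_means <- vector("list", C)
    for (k in seq_len(C)) {
      idx <- which(dataset$labels == k)
      if (length(idx) == 0)
        ra_stop(sprintf("class %d is empty", k), "riemalign_error_invalid_input")
      class_means[[k]] <- mean_fun(dataset$matrices[idx])
    }
    names(class_means) <- as.character(seq_len(C))
  }
  structure(list(global_mean = M, class_means = class_means,
                 dispersion = spd_dispersion(dataset, M, metric, normalize),
                 metric = metric, normalize = normalize,
                 n_items = dataset$N),
            class = "domain_statistics")
}

new_alignment_transform <- function(method, log_center = NULL,
                                    recenter_matrix = NULL,
                                    stretch_exponent = 1,
                                    scale_divisor = 1, fitted_on = NULL) {
  if (stretch_exponent <= 0 || scale_divisor <= 0)
    ra_stop("stretch exponent and scale divisor must be positive",
            "riemalign_error_invalid_input")
  structure(list(method = method, log_center = log_center,
                 recenter_matrix = recenter_matrix,
                 stretch_exponent = stretch_exponent,
                 scale_divisor = scale_divisor, fitted_on = fitted_on),
            class = "alignment_transform")
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("<alignment_transform> method = %s", x$method))
  if (x$method == "pa_lem")
    cat(sprintf(", divisor = %.4g, ||log center||_F = %.4g",
                x$scale_divisor, sqrt(sum(x$log_center^2))))
  else
    cat(sprintf(", stretch s = %.4g", x$stretch_exponent))
  cat("\n")
  invisible(x)
}

pa_lem_one_domain <- function(dataset) {
  logs <- lapply(dataset$matrices, sym_logm)
  logM <- Reduce(`+`, logs) / length(logs)
  d2 <- vapply(logs, function(L) sum((L - logM)^2), numeric(1))
  dprime <- mean(d2)
  if (dprime <= 0)
    ra_stop("degenerate dispersion: all matrices identical, cannot standardize",
            "riemalign_error_degenerate")
  new_alignment_transform("pa_lem", log_center = logM,
                          scale_divisor = sqrt(dprime),
                          fitted_on = compute_domain_statistics(
                            strip_labels(dataset), "lem", "mean"))
}

strip_labels <- function(dataset) {
  dataset$labels <- NULL
  dataset
}

#' Procrustes alignment in the log-domain (PA-LEM)
#'
#' Each domain is mapped to the log-domain, centered at its own log-mean and
#' standardized to unit mean dispersion; no cross-domain information is
#' mixed and no labels are used. The divisor is the square root of the mean
#' squared log-deviation, which is the unique choice that leaves both
#' domains at exactly unit variance (see the methods vignette). Rotation is
#' omitted by design.
#'
#' @param source,target `spd_dataset` objects of equal matrix dimension.
#' @return list with elements `source` and `target`, each an
#'   `alignment_transform` with method `"pa_lem"`.
#' @export
fit_pa_lem <- function(source, target) {
  check_domain_pair(source, target)
  list(source = pa_lem_one_domain(source), target = pa_lem_one_domain(target))
}

check_domain_pair <- function(source, target) {
  if (!inherits(source, "spd_dataset") || !inherits(target, "spd_dataset"))
    ra_stop("source and target must be spd_dataset objects",
            "riemalign_error_invalid_input")
  if (source$n != target$n)
    ra_stop("source and target matrix dimensions differ",
            "riemalign_error_invalid_input")
}

#' Riemannian Procrustes alignment under the log-Euclidean metric (RPA-LEM)
#'
#' Re-centering plus stretching, unsupervised. Each domain is re-centered at
#' the identity by the congruence `X -> M^{-1/2} X M^{-1/2}` with `M` the
#' domain's closed-form LEM mean; the target is then stretched along
#' geodesics through the identity, `X -> X^s` with `s^2 = d / d~` the ratio
#' of source to target dispersion, so that the two dispersions match. By
#' default dispersions are measured on the re-centered sets around the
#' identity (`dispersion_order = "post"`), which makes the dispersion-match
#' post-condition exact under LEM; `"pre"` measures them around the domain
#' means before re-centering (the two coincide under AIRM but differ
#' slightly under LEM).
#'
#' @param source,target `spd_dataset` objects of equal matrix dimension.
#' @param normalize dispersion normalization entering `s`; the ratio is
#'   unaffected when both domains have the same size.
#' @param dispersion_order `"post"` (around identity, after re-centering;
#'   default) or `"pre"` (around the domain mean, before).
#' @return list with elements `source` and `target`
#'   (`alignment_transform`s with method `"rpa_lem"`).
#' @export
fit_rpa_lem <- function(source, target, normalize = c("sum", "mean"),
                        dispersion_order = c("post", "pre")) {
  normalize <- match.arg(normalize)
  dispersion_order <- match.arg(dispersion_order)
  check_domain_pair(source, target)
  fit_rpa(source, target, metric = "lem", normalize = normalize,
          dispersion_order = dispersion_order)
}

#' Riemannian Procrustes alignment under AIRM (baseline RPA)
#'
#' Same re-center + stretch scheme as [fit_rpa_lem()] but with means from
#' the iterative Karcher algorithm and dispersions under the
#' affine-invariant metric. AIRM congruence invariance makes the Karcher
#' mean of each re-centered set exactly the identity, and
#' `delta(X^s, I) = s * delta(X, I)` makes the stretch exact; the method is
#' the accuracy reference the LEM variants are measured against, at a much
#' higher computational cost.
#'
#' @inheritParams fit_rpa_lem
#' @param tol,max_iter Karcher-mean controls.
#' @return list with elements `source` and `target`
#'   (`alignment_transform`s with method `"rpa_airm"`).
#' @export
fit_rpa_airm <- function(source, target, normalize = c("sum", "mean"),
                         tol = 1e-8, max_iter = 100) {
  normalize <- match.arg(normalize)
  check_domain_pair(source, target)
  fit_rpa(source, target, metric = "airm", normalize = normalize,
          dispersion_order = "post", tol = tol, max_iter = max_iter)
}

fit_rpa <- function(source, target, metric, normalize, dispersion_order,
                    tol = 1e-8, max_iter = 100) {
  method <- if (metric == "lem") "rpa_lem" else "rpa_airm"
  stats_s <- compute_domain_statistics(strip_labels(source), metric, normalize,
                                       tol, max_iter)
  stats_t <- compute_domain_statistics(strip_labels(target), metric, normalize,
                                       tol, max_iter)
  Ps <- spd_invsqrt(stats_s$global_mean)
  Pt <- spd_invsqrt(stats_t$global_mean)
  I_n <- diag(source$n)
  if (dispersion_order == "post") {
    rct <- function(P, dataset) lapply(dataset$matrices, function(X)
      sym_part(P %*% X %*% P))
    d_s <- spd_dispersion(rct(Ps, source), I_n, metric, normalize)
    d_t <- spd_dispersion(rct(Pt, target), I_n, metric, normalize)
  } else {
    d_s <- stats_s$dispersion
    d_t <- stats_t$dispersion
  }
  # all-equal targets leave only floating-point dust in the dispersion
  if (d_t <= 1e-20 * max(1, d_s))
    ra_stop("degenerate target dispersion: all target matrices identical",
            "riemalign_error_degenerate")
  s <- sqrt(d_s / d_t)
  list(source = new_alignment_transform(method, recenter_matrix = Ps,
                                        stretch_exponent = 1,
                                        fitted_on = stats_s),
       target = new_alignment_transform(method, recenter_matrix = Pt,
                                        stretch_exponent = s,
                                        fitted_on = stats_t))
}

#' Apply a fitted alignment transform to an SPD dataset
#'
#' PA-LEM returns `exp((log X - log M) / divisor)` so downstream consumers
#' stay on the manifold (set `log_domain = TRUE` for the raw log-domain
#' points); the RPA variants return `(M^{-1/2} X M^{-1/2})^s`. Labels and
#' trial order are passed through untouched.
#'
#' @param transform fitted `alignment_transform`.
#' @param dataset `spd_dataset` of matching dimension.
#' @param log_domain PA-LEM only: return symmetric log-domain matrices
#'   instead of mapping back to the manifold.
#' @return `spd_dataset` (or a list of symmetric matrices when
#'   `log_domain = TRUE`).
#' @export
apply_transform <- function(transform, dataset, log_domain = FALSE) {
  if (!inherits(transform, "alignment_transform"))
    ra_stop("unfitted or invalid transform", "riemalign_error_invalid_input")
  if (!inherits(dataset, "spd_dataset"))
    ra_stop("spd_dataset required", "riemalign_error_invalid_input")
  out <- lapply(dataset$matrices, transform_one,
                transform = transform, log_domain = log_domain)
  if (log_domain) return(out)
  spd_dataset(out, labels = dataset$labels, domain_id = dataset$domain_id,
              validate = FALSE)
}

transform_one <- function(X, transform, log_domain = FALSE) {
  if (transform$method == "pa_lem") {
    if (!identical(dim(X), dim(transform$log_center)))
      ra_stop("dimension mismatch with fitted transform",
              "riemalign_error_invalid_input")
    L <- (sym_logm(X) - transform$log_center) / transform$scale_divisor
    if (log_domain) L else sym_expm(L)
  } else {
    P <- transform$recenter_matrix
    if (!identical(dim(X), dim(P)))
      ra_stop("dimension mismatch with fitted transform",
              "riemalign_error_invalid_input")
    Y <- sym_part(P %*% X %*% P)
    if (transform$stretch_exponent != 1) Y <- spd_power(Y, transform$stretch_exponent)
    if (log_domain) sym_logm(Y) else Y
  }
}

#' Apply a fitted alignment transform to a single new SPD matrix
#'
#' Single-sample version of [apply_transform()] with identical numerics,
#' for online / test-time use on later-arriving trials.
#'
#' @param transform fitted `alignment_transform`.
#' @param X SPD matrix.
#' @return SPD matrix.
#' @export
apply_to_new_sample <- function(transform, X) {
  if (!inherits(transform, "alignment_transform"))
    ra_stop("unfitted or invalid transform", "riemalign_error_invalid_input")
  transform_one(X, transform)
}
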