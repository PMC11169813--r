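#' Annealing learning-rate schedule for PLVQ-LEML
#'
#' Prototype rate `alpha(t) = (n * xi / 100) * 0.01^(t / T)` and metric rate
#' `eta(t) = (n * xi / 10000) * 0.01^((t - t0) / (T - t0))`, where `n` is
#' the matrix dimension, `xi` the number of prototypes per class, `T` the
#' total number of epochs and `t0` the epoch at which metric learning
#' starts. `eta(t)` stays two orders of magnitude below `alpha(t)`, which
#' stabilizes joint prototype / metric training.
#'
#' @param T total training epochs (default 100).
#' @param t0 metric-learning start epoch (default 1).
#' @param n matrix dimension.
#' @param xi prototypes per class.
#' @return object of class `learning_schedule`: list with `T`, `t0` and
#'   functions `alpha(t)`, `eta(t)`.
#' @export
learning_schedule <- function(T = 100, t0 = 1, n, xi) {
  if (T < 1 || t0 < 1 || t0 > T)
    ra_stop("need 1 <= t0 <= T", "riemalign_error_invalid_input")
  denom <- max(T - t0, 1)
  structure(list(
    T = T, t0 = t0,
    alpha = function(t) (n * xi / 100) * 0.01^(t / T),
    eta = function(t) (n * xi / 10000) * 0.01^((t - t0) / denom)
  ), class = "learning_schedule")
}

new_plvq_model <- function(log_prototypes, proto_labels, omega, sigma2,
                           priors, n_per_class) {
  if (sigma2 <= 0)
    ra_stop("sigma2 must be positive", "riemalign_error_invalid_input")
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-12)
    ra_stop("priors must be non-negative and sum to 1",
            "riemalign_error_invalid_input")
  structure(list(log_prototypes = log_prototypes,
                 proto_labels = as.integer(proto_labels),
                 omega = omega, sigma2 = sigma2, priors = priors,
                 n_per_class = as.integer(n_per_class),
                 n = nrow(omega), C = max(proto_labels)),
            class = "plvq_model")
}

#' @export
print.plvq_model <- function(x, ...) {
  cat(sprintf("<plvq_model> %d prototypes (%d per class, %d classes), n = %d, sigma2 = %g\n",
              length(x$log_prototypes), x$n_per_class, x$C, x$n, x$sigma2))
  invisible(x)
}

#' Metric tensor of a PLVQ model
#'
#' `Q = Omega Omega'`, the learned positive semi-definite tensor weighting
#' the log-domain distance.
#'
#' @param model `plvq_model`.
#' @return symmetric PSD matrix.
#' @export
plvq_Q <- function(model) sym_part(tcrossprod(model$omega))

# squared log-domain distance Tr[Q (logX - logW)^2]; both args are logs
plvq_delta_log <- function(logX, logW, Q) {
  D <- logX - logW
  sum(Q * (D %*% D))
}

#' Metric-weighted squared log-domain distance
#'
#' `delta(X, W, Q) = Tr[Q (log X - log W)(log X - log W)]`. With `Q = I`
#' this is the squared log-Euclidean distance; a learned `Q` re-weights
#' directions of the log-domain, suppressing uninformative components.
#'
#' @param X,W SPD matrices of equal dimension.
#' @param Q symmetric positive semi-definite matrix.
#' @return non-negative scalar.
#' @export
plvq_distance <- function(X, W, Q) {
  if (!identical(dim(X), dim(W)) || !identical(dim(X), dim(Q)))
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  plvq_delta_log(sym_logm(X), sym_logm(W), sym_part(Q))
}

# f_j = -delta_j / (2 sigma^2) for every prototype; logX precomputed
plvq_f_values <- function(logX, model, Q = plvq_Q(model)) {
  vapply(model$log_prototypes, function(logW)
    -plvq_delta_log(logX, logW, Q) / (2 * model$sigma2), numeric(1))
}

softmax_log <- function(lp) {
  m <- max(lp)
  w <- exp(lp - m)
  w / sum(w)
}

#' Class posteriors of a PLVQ model at one point
#'
#' `p(y | X) = sum_{j: c_j = y} P(j) exp(f_j) / sum_i P(i) exp(f_i)` with
#' `f_j = -delta(X, W_j, Q) / (2 sigma^2)`, evaluated with log-sum-exp
#' stabilization.
#'
#' @param X SPD matrix.
#' @param model `plvq_model`.
#' @return list with `class_posterior` (length `C`, sums to 1),
#'   `prototype_posterior` (length `M`), and the raw `f` values.
#' @export
plvq_posteriors <- function(X, model) {
  logX <- sym_logm(X)
  f <- plvq_f_values(logX, model)
  pj <- softmax_log(log(model$priors) + f)
  py <- as.numeric(rowsum(pj, model$proto_labels))
  list(class_posterior = py, prototype_posterior = pj, f = f)
}

#' Negative log-likelihood cost of a PLVQ model
#'
#' `E = sum_i [ -log sum_{j: c_j = y_i} P(j) e^{f_j}
#'              + log sum_j P(j) e^{f_j} ]`, always non-negative and zero
#' only when every sample has correct-class posterior 1.
#'
#' @param model `plvq_model`.
#' @param dataset labeled `spd_dataset`.
#' @return scalar cost.
#' @export
plvq_cost <- function(model, dataset) {
  if (is.null(dataset$labels))
    ra_stop("labeled dataset required", "riemalign_error_invalid_input")
  Q <- plvq_Q(model)
  lprior <- log(model$priors)
  total <- 0
  for (i in seq_len(dataset$N)) {
    lp <- lprior + plvq_f_values(sym_logm(dataset$matrices[[i]]), model, Q)
    idx <- model$proto_labels == dataset$labels[i]
    total <- total + (logsumexp(lp) - logsumexp(lp[idx]))
  }
  total
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Analytic gradients of the per-sample PLVQ cost
#'
#' Gradients of the single-sample negative log-likelihood with respect to
#' each log-prototype and to `Omega`, evaluated at the current model. The
#' prototype gradient is the symmetrized `coef * (Q D + D Q) / (2 sigma^2)`
#' with `D = log X - log W_l` and `coef = P(l|X) - P_y(l|X)` for prototypes
#' of the correct class, `P(l|X)` otherwise -- the restriction of the
#' unconstrained gradient to the symmetric subspace the prototypes live in.
#' Exposed so the update rules can be validated against finite differences.
#'
#' @param model `plvq_model`.
#' @param X SPD matrix.
#' @param y class label of `X`.
#' @return list with `proto_grads` (list of symmetric matrices) and
#'   `omega_grad` (matrix).
#' @export
plvq_gradients <- function(model, X, y) {
  y <- as.integer(y)
  if (y < 1 || y > model$C)
    ra_stop("invalid label", "riemalign_error_invalid_input")
  logX <- sym_logm(X)
  Q <- plvq_Q(model)
  f <- plvq_f_values(logX, model, Q)
  lp <- log(model$priors) + f
  P <- softmax_log(lp)
  correct <- model$proto_labels == y
  Py <- numeric(length(P))
  Py[correct] <- softmax_log(lp[correct])
  s2 <- model$sigma2
  proto_grads <- vector("list", length(P))
  omega_grad <- matrix(0, model$n, model$n)
  for (l in seq_along(P)) {
    D <- logX - model$log_prototypes[[l]]
    coef <- if (correct[l]) P[l] - Py[l] else P[l]
    QD <- Q %*% D
    proto_grads[[l]] <- coef * (QD + t(QD)) / (2 * s2)
    # dE/dOmega accumulates -coef * D^2 Omega / sigma^2
    omega_grad <- omega_grad - (coef / s2) * (D %*% D)
  }
  list(proto_grads = proto_grads,
       omega_grad = omega_grad %*% model$omega)
}

#' One stochastic update of a PLVQ model
#'
#' Applies the per-sample prototype rule
#' `logW_l <- logW_l - (alpha / sigma^2) * coef_l * sym(Q (logX - logW_l))`
#' and, when `learn_metric`, the metric rule
#' `Omega <- Omega - (eta / sigma^2) [ sum_{c_j = y} P_y(j|X) D_j^2
#'   - sum_j P(j|X) D_j^2 ] Omega`, followed by `Q <- Omega Omega'`
#' re-normalized to `Tr(Q) = n` (set `renormalize = FALSE` to keep the raw
#' gradient step, e.g. for finite-difference checks). Both gradients are
#' evaluated at the incoming model before either is applied.
#'
#' @param model `plvq_model`.
#' @param X SPD training matrix.
#' @param y its class label.
#' @param alpha prototype learning rate.
#' @param eta metric learning rate.
#' @param learn_metric update `Omega` as well.
#' @param renormalize rescale `Omega` so `Tr(Q) = n` after a metric step.
#' @return updated `plvq_model`.
#' @export
plvq_update_step <- function(model, X, y, alpha, eta, learn_metric = TRUE,
                             renormalize = TRUE) {
  g <- plvq_gradients(model, X, y)
  for (l in seq_along(model$log_prototypes))
    model$log_prototypes[[l]] <- model$log_prototypes[[l]] - alpha * g$proto_grads[[l]]
  if (learn_metric) {
    omega <- model$omega - eta * g$omega_grad
    if (renormalize) {
      trQ <- sum(omega * omega)   # Tr(Omega Omega') = ||Omega||_F^2
      omega <- omega * sqrt(model$n / trQ)
    }
    model$omega <- omega
  }
  model
}

plvq_init <- function(train, n_per_class, sigma2, seed) {
  C <- max(train$labels)
  n <- train$n
  counts <- tabulate(train$labels, C)
  if (any(counts < n_per_class))
    ra_stop(sprintf(
      "class %d has %d samples, fewer than %d prototypes requested",
      which.min(counts), min(counts), n_per_class),
      "riemalign_error_invalid_input")
  log_prototypes <- list()
  proto_labels <- integer(0)
  set.seed(seed)
  basis_dim <- n * (n + 1) / 2
  for (k in seq_len(C)) {
    logMk <- mean_logm(train$matrices[train$labels == k])
    for (j in seq_len(n_per_class)) {
      W <- logMk
      if (n_per_class > 1) {
        jit <- coords_to_sym(stats::rnorm(basis_dim), n)
        W <- W + 0.01 * jit / sqrt(sum(jit^2))
      }
      log_prototypes <- c(log_prototypes, list(W))
      proto_labels <- c(proto_labels, k)
    }
  }
  M <- length(log_prototypes)
  new_plvq_model(log_prototypes, proto_labels, diag(n), sigma2,
                 rep(1 / M, M), n_per_class)
}

#' Train a PLVQ-LEML classifier
#'
#' Prototypes are initialized at the class-conditional log-Euclidean means
#' (plus a small seeded symmetric jitter when several prototypes share a
#' class), `Omega` at the identity (`Tr(Q) = n`), and priors fixed uniform.
#' Each epoch visits the training samples in a seeded shuffled order and
#' applies [plvq_update_step()] with the annealing rates of `schedule`;
#' metric learning starts at epoch `t0`. The per-epoch cost trace is
#' attached as attribute `"cost_trace"`.
#'
#' @param train labeled `spd_dataset`.
#' @param n_per_class prototypes per class (default 1).
#' @param sigma2 Gaussian width of the posterior (default 1).
#' @param schedule `learning_schedule`; default
#'   `learning_schedule(100, 1, n, n_per_class)`.
#' @param seed RNG seed for initialization jitter and epoch shuffles.
#' @param learn_metric train the metric tensor (default `TRUE`).
#' @param trace record the cost after every epoch (adds one full cost
#'   evaluation per epoch; default `FALSE`).
#' @return fitted `plvq_model` (attribute `cost_trace` when `trace`).
#' @export
plvq_fit <- function(train, n_per_class = 1, sigma2 = 1, schedule = NULL,
                     seed = 1, learn_metric = TRUE, trace = FALSE) {
  if (is.null(train$labels))
    ra_stop("labeled training data required", "riemalign_error_invalid_input")
  if (is.null(schedule))
    schedule <- learning_schedule(100, 1, train$n, n_per_class)
  model <- plvq_init(train, n_per_class, sigma2, seed)
  logs <- lapply(train$matrices, sym_logm)
  costs <- numeric(0)
  set.seed(seed + 1L)
  for (t in seq_len(schedule$T)) {
    a_t <- schedule$alpha(t)
    e_t <- schedule$eta(t)
    lm <- learn_metric && t >= schedule$t0
    for (i in sample.int(train$N)) {
      model <- plvq_update_step_log(model, logs[[i]], train$labels[i],
                                    a_t, e_t, lm)
    }
    if (trace) costs <- c(costs, plvq_cost(model, train))
  }
  if (trace) attr(model, "cost_trace") <- costs
  model
}

# update with a precomputed log-domain sample (hot loop of plvq_fit)
plvq_update_step_log <- function(model, logX, y, alpha, eta, learn_metric) {
  Q <- sym_part(tcrossprod(model$omega))
  f <- plvq_f_values_from_Q(logX, model, Q)
  lp <- log(model$priors) + f
  P <- softmax_log(lp)
  correct <- model$proto_labels == y
  Py <- numeric(length(P))
  Py[correct] <- softmax_log(lp[correct])
  s2 <- model$sigma2
  acc <- if (learn_metric) matrix(0, model$n, model$n) else NULL
  for (l in seq_along(P)) {
    D <- logX - model$log_prototypes[[l]]
    coef <- if (correct[l]) P[l] - Py[l] else P[l]
    QD <- Q %*% D
    model$log_prototypes[[l]] <- model$log_prototypes[[l]] -
      (alpha / s2) * coef * (QD + t(QD)) / 2
    if (learn_metric && coef != 0) acc <- acc - coef * (D %*% D)
  }
  if (learn_metric) {
    omega <- model$omega - (eta / s2) * (acc %*% model$omega)
    model$omega <- omega * sqrt(model$n / sum(omega * omega))
  }
  model
}

plvq_f_values_from_Q <- function(logX, model, Q) {
  vapply(model$log_prototypes, function(logW) {
    D <- logX - logW
    -sum(Q * (D %*% D)) / (2 * model$sigma2)
  }, numeric(1))
}

#' Predict class labels with a PLVQ model
#'
#' Argmax of the class posterior, breaking ties toward the lowest class
#' index.
#'
#' @param model fitted `plvq_model`.
#' @param dataset `spd_dataset`.
#' @return integer label vector.
#' @export
plvq_predict <- function(model, dataset) {
  if (dataset$n != model$n)
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  vapply(dataset$matrices, function(X)
    which.max(plvq_posteriors(X, model)$class_posterior), integer(1))
}

#' Minimum distance to Riemannian mean (MDRM) classifier
#'
#' Per-class geometric means under the chosen metric; a trial is assigned
#' to the class of the nearest mean (ties to the lowest class index).
#'
#' @param train labeled `spd_dataset`.
#' @param metric `"lem"` or `"airm"`.
#' @param tol,max_iter Karcher-mean controls (AIRM only).
#' @return object of class `mdrm_model`.
#' @export
mdrm_fit <- function(train, metric = c("lem", "airm"),
                     tol = 1e-8, max_iter = 100) {
  metric <- match.arg(metric)
  if (is.null(train$labels))
    ra_stop("labeled training data required", "riemalign_error_invalid_input")
  C <- max(train$labels)
  means <- vector("list", C)
  for (k in seq_len(C)) {
    mats <- train$matrices[train$labels == k]
    if (length(mats) == 0)
      ra_stop(sprintf("class %d is empty", k), "riemalign_error_invalid_input")
    means[[k]] <- if (metric == "lem") lem_mean(mats)
                  else airm_mean(mats, tol, max_iter)
  }
  structure(list(class_means = means, metric = metric, n = train$n, C = C),
            class = "mdrm_model")
}

#' @rdname mdrm_fit
#' @param model fitted `mdrm_model`.
#' @param dataset `spd_dataset` to classify.
#' @return integer label vector.
#' @export
mdrm_predict <- function(model, dataset) {
  if (dataset$n != model$n)
    ra_stop("dimension mismatch", "riemalign_error_invalid_input")
  dist_fun <- if (model$metric == "lem") lem_distance else airm_distance
  vapply(dataset$matrices, function(X)
    which.min(vapply(model$class_means, dist_fun, numeric(1), X2 = X)),
    integer(1))
}

#' Grid search over PLVQ hyper-parameters by stratified cross-validation
#'
#' Stratified `folds`-fold cross-validation over the cartesian grid of
#' prototypes-per-class and `sigma2`, selecting the configuration with the
#' highest mean validation kappa; ties break toward smaller `n_per_class`,
#' then smaller `sigma2`. Deterministic given `seed`.
#'
#' @param train labeled `spd_dataset`.
#' @param grid_n candidate prototypes per class (default `1:8`).
#' @param grid_sigma2 candidate `sigma2` values (default `seq(0.5, 4, 0.5)`).
#' @param folds number of folds (default 5).
#' @param seed RNG seed controlling folds and training.
#' @param ... further arguments to [plvq_fit()] (e.g. `schedule`).
#' @return list with `n_per_class`, `sigma2`, and the full `cv_table`
#'   (data.frame of mean kappa per grid point).
#' @export
grid_search_cv <- function(train, grid_n = 1:8,
                           grid_sigma2 = seq(0.5, 4, by = 0.5),
                           folds = 5, seed = 1, ...) {
  if (is.null(train$labels))
    ra_stop("labeled training data required", "riemalign_error_invalid_input")
  C <- max(train$labels)
  if (any(tabulate(train$labels, C) < folds))
    ra_stop("need at least `folds` samples per class",
            "riemalign_error_invalid_input")
  set.seed(seed)
  fold_id <- integer(train$N)
  for (k in seq_len(C)) {
    idx <- sample(which(train$labels == k))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  grid <- expand.grid(n_per_class = grid_n, sigma2 = grid_sigma2)
  grid$kappa <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ks <- numeric(folds)
    ok <- TRUE
    for (fd in seq_len(folds)) {
      tr <- train[fold_id != fd]
      va <- train[fold_id == fd]
      fit <- tryCatch(
        plvq_fit(tr, n_per_class = grid$n_per_class[g],
                 sigma2 = grid$sigma2[g], seed = seed, ...),
        riemalign_error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      ks[fd] <- kappa_score(va$labels, plvq_predict(fit, va), C)
    }
    if (ok) grid$kappa[g] <- mean(ks)
  }
  if (all(is.na(grid$kappa)))
    ra_stop("no grid configuration could be trained",
            "riemalign_error_invalid_input")
  # ties: smaller n_per_class, then smaller sigma2
  ord <- order(-grid$kappa, grid$n_per_class, grid$sigma2)
  best <- grid[ord[1], ]
  list(n_per_class = best$n_per_class, sigma2 = best$sigma2, cv_table = grid)
}
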