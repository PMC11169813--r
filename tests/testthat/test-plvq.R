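test_that("plvq_distance: zero at the prototype, LEM reduction, hand case", {
  set.seed(51)
  X <- rand_spd(3)
  Q <- crossprod(matrix(rnorm(9), 3))
  expect_equal(plvq_distance(X, X, Q), 0, tolerance = 1e-14)
  Y <- rand_spd(3)
  expect_equal(plvq_distance(X, Y, diag(3)), lem_distance(X, Y)^2,
               tolerance = 1e-12)
  # logX - logW = diag(1, 2), Q = diag(2, 1) -> Tr[diag(2, 4)] = 6
  W <- diag(c(1, 1))
  X2 <- diag(c(exp(1), exp(2)))
  expect_equal(plvq_distance(X2, W, diag(c(2, 1))), 6, tolerance = 1e-12)
})

two_class_model <- function(n = 3, n_per_class = 2, sigma2 = 1.5, seed = 52,
                            perturb_omega = TRUE) {
  set.seed(seed)
  means <- make_class_means(n, 2, 2)
  train <- riemalign:::sample_mixture(lapply(means, sym_logm), 0.3, 8, "d")
  model <- riemalign:::plvq_init(train, n_per_class, sigma2, seed = seed)
  if (perturb_omega) model$omega <- model$omega + 0.1 * matrix(rnorm(n * n), n)
  list(model = model, train = train)
}

test_that("posteriors: uniform when equidistant, sharp at a prototype, naive-formula oracle", {
  # all prototypes identical => all f equal => uniform class posterior
  W <- rand_spd(3)
  model <- riemalign:::new_plvq_model(rep(list(sym_logm(W)), 4), 1:4,
                                      diag(3), 1, rep(0.25, 4), 1L)
  p <- plvq_posteriors(rand_spd(3), model)
  expect_equal(p$class_posterior, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(p$class_posterior), 1, tolerance = 1e-12)
  # X at class-1 prototype with small sigma2 and separated prototypes
  set.seed(53)
  means <- make_class_means(3, 2, 2)
  model <- riemalign:::new_plvq_model(lapply(means, sym_logm), 1:2, diag(3),
                                      0.01, c(0.5, 0.5), 1L)
  p <- plvq_posteriors(means[[1]], model)
  expect_gte(p$class_posterior[1], 0.999)
  # matches the unstabilized printed formula on a well-conditioned instance
  tc <- two_class_model()
  X <- tc$train$matrices[[3]]
  Q <- plvq_Q(tc$model)
  f <- vapply(tc$model$log_prototypes, function(logW)
    -plvq_distance(X, sym_expm(logW), Q) / (2 * tc$model$sigma2), numeric(1))
  naive <- vapply(1:2, function(y) {
    idx <- tc$model$proto_labels == y
    sum(tc$model$priors[idx] * exp(f[idx])) / sum(tc$model$priors * exp(f))
  }, numeric(1))
  expect_equal(plvq_posteriors(X, tc$model)$class_posterior, naive,
               tolerance = 1e-12)
})

test_that("cost: zero at perfect posteriors, log C at uniform, decomposition oracle", {
  set.seed(54)
  means <- make_class_means(3, 2, 3)
  model <- riemalign:::new_plvq_model(lapply(means, sym_logm), 1:2, diag(3),
                                      0.01, c(0.5, 0.5), 1L)
  ds <- spd_dataset(means, labels = 1:2, validate = FALSE)
  expect_lt(plvq_cost(model, ds), 1e-6)
  # single sample, uniform posterior over 4 classes -> log 4
  W <- rand_spd(3)
  model4 <- riemalign:::new_plvq_model(rep(list(sym_logm(W)), 4), 1:4,
                                       diag(3), 1, rep(0.25, 4), 1L)
  one <- spd_dataset(list(rand_spd(3)), labels = NULL, validate = FALSE)
  one$labels <- 2L
  expect_equal(plvq_cost(model4, one), log(4), tolerance = 1e-12)
  # decomposition: cost = sum of -log correct-class posteriors
  tc <- two_class_model()
  per_sample <- vapply(seq_len(tc$train$N), function(i)
    -log(plvq_posteriors(tc$train$matrices[[i]],
                         tc$model)$class_posterior[tc$train$labels[i]]),
    numeric(1))
  expect_equal(plvq_cost(tc$model, tc$train), sum(per_sample),
               tolerance = 1e-12)
})

test_that("update rules match finite-difference gradients of the cost", {
  tc <- two_class_model()
  model <- tc$model
  X <- tc$train$matrices[[4]]
  y <- tc$train$labels[4]
  one <- spd_dataset(list(X), validate = FALSE)
  one$labels <- y
  g <- plvq_gradients(model, X, y)
  h <- 1e-6
  for (l in c(1, 3)) {   # one correct-class, one wrong-class prototype
    fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      mp <- model; mm <- model
      mp$log_prototypes[[l]][i, j] <- mp$log_prototypes[[l]][i, j] + h
      mm$log_prototypes[[l]][i, j] <- mm$log_prototypes[[l]][i, j] - h
      fd[i, j] <- (plvq_cost(mp, one) - plvq_cost(mm, one)) / (2 * h)
    }
    expect_lt(max_abs(fd, g$proto_grads[[l]]) / max(abs(fd)), 1e-4)
  }
  fdo <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    mp <- model; mm <- model
    mp$omega[i, j] <- mp$omega[i, j] + h
    mm$omega[i, j] <- mm$omega[i, j] - h
    fdo[i, j] <- (plvq_cost(mp, one) - plvq_cost(mm, one)) / (2 * h)
  }
  expect_lt(max_abs(fdo, g$omega_grad) / max(abs(fdo)), 1e-4)
})

test_that("update step: zero-coefficient fixed point, attraction, Q stays PSD", {
  # single class: P = P_y identically, prototypes must not move
  set.seed(55)
  W <- rand_spd(3)
  model <- riemalign:::new_plvq_model(list(sym_logm(W)), 1L, diag(3), 1,
                                      1, 1L)
  up <- plvq_update_step(model, W, 1L, alpha = 0.1, eta = 0.01)
  expect_equal(up$log_prototypes[[1]], model$log_prototypes[[1]],
               tolerance = 1e-14)
  # correct-class prototype moves toward the sample
  tc <- two_class_model(perturb_omega = FALSE)
  X <- tc$train$matrices[[2]]
  y <- tc$train$labels[2]
  l <- which(tc$model$proto_labels == y)[1]
  up <- plvq_update_step(tc$model, X, y, alpha = 0.05, eta = 0)
  expect_lt(sqrt(sum((up$log_prototypes[[l]] - sym_logm(X))^2)),
            sqrt(sum((tc$model$log_prototypes[[l]] - sym_logm(X))^2)))
  # Q remains PSD through a run of updates
  model <- tc$model
  for (i in seq_len(tc$train$N)) {
    model <- plvq_update_step(model, tc$train$matrices[[i]],
                              tc$train$labels[i], 0.05, 0.01)
    ev <- eigen(plvq_Q(model), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("plvq_fit: separable benchmark, descending cost, frozen at zero rates", {
  set.seed(56)
  means <- make_class_means(3, 2, 3)   # separation 10x the dispersion
  train <- riemalign:::sample_mixture(lapply(means, sym_logm), 0.3, 25, "d")
  sched <- learning_schedule(50, 1, 3, 1)
  fit <- plvq_fit(train, 1, sigma2 = 1, schedule = sched, seed = 1,
                  trace = TRUE)
  expect_equal(mean(plvq_predict(fit, train) == train$labels), 1.0)
  ct <- attr(fit, "cost_trace")
  expect_lte(ct[10], ct[1] + 1e-10)
  # zero learning rates: model identical to its initialization
  zero <- structure(list(T = 5, t0 = 1, alpha = function(t) 0,
                         eta = function(t) 0), class = "learning_schedule")
  frozen <- plvq_fit(train, 1, sigma2 = 1, schedule = zero, seed = 1)
  init <- riemalign:::plvq_init(train, 1, 1, seed = 1)
  expect_identical(frozen$log_prototypes, init$log_prototypes)
  expect_identical(frozen$omega, init$omega)
})

test_that("plvq_predict: prototype class, brute-force agreement, prototype-order invariance", {
  set.seed(57)
  means <- make_class_means(3, 3, 2)
  model <- riemalign:::new_plvq_model(lapply(means, sym_logm), 1:3, diag(3),
                                      0.01, rep(1 / 3, 3), 1L)
  expect_equal(plvq_predict(model, spd_dataset(means, validate = FALSE)),
               1:3)
  samples <- spd_dataset(lapply(1:100, function(i) rand_spd(3)),
                         validate = FALSE)
  brute <- vapply(samples$matrices, function(X)
    which.max(plvq_posteriors(X, model)$class_posterior), integer(1))
  expect_identical(plvq_predict(model, samples), brute)
  perm <- c(3, 1, 2)
  pmodel <- model
  pmodel$log_prototypes <- model$log_prototypes[perm]
  pmodel$proto_labels <- model$proto_labels[perm]
  expect_identical(plvq_predict(pmodel, samples),
                   plvq_predict(model, samples))
})

test_that("learning schedule follows the annealing formulas and eta < alpha", {
  sch <- learning_schedule(100, 1, n = 22, xi = 2)
  expect_equal(sch$alpha(50), (22 * 2 / 100) * 0.01^(50 / 100))
  expect_equal(sch$eta(50), (22 * 2 / 10000) * 0.01^((50 - 1) / 99))
  ts <- 1:100
  expect_true(all(sch$eta(ts) < sch$alpha(ts)))
})

test_that("mdrm: trivial assignment, brute-force oracle, commuting-metric agreement", {
  set.seed(58)
  means <- make_class_means(3, 3, 2)
  train <- riemalign:::sample_mixture(lapply(means, sym_logm), 0.2, 10, "d")
  model <- mdrm_fit(train, "lem")
  expect_equal(mdrm_predict(model, spd_dataset(model$class_means,
                                               validate = FALSE)), 1:3)
  test <- spd_dataset(lapply(1:50, function(i) rand_spd(3)),
                      validate = FALSE)
  brute <- vapply(test$matrices, function(X)
    which.min(vapply(model$class_means, lem_distance, numeric(1), X2 = X)),
    integer(1))
  expect_identical(mdrm_predict(model, test), brute)
  # diagonal data: lem and airm agree end to end
  set.seed(59)
  diag_train <- spd_dataset(commuting_family(3, 20),
                            labels = rep(1:2, 10), validate = FALSE)
  diag_test <- spd_dataset(commuting_family(3, 15), validate = FALSE)
  expect_identical(mdrm_predict(mdrm_fit(diag_train, "lem"), diag_test),
                   mdrm_predict(mdrm_fit(diag_train, "airm"), diag_test))
})

test_that("grid_search_cv: single point, separable winner, determinism", {
  set.seed(60)
  means <- make_class_means(3, 2, 3)
  train <- riemalign:::sample_mixture(lapply(means, sym_logm), 0.3, 15, "d")
  sched <- learning_schedule(15, 1, 3, 1)
  single <- grid_search_cv(train, grid_n = 2, grid_sigma2 = 1.5, folds = 3,
                           seed = 4, schedule = sched)
  expect_equal(single$n_per_class, 2)
  expect_equal(single$sigma2, 1.5)
  sel <- grid_search_cv(train, grid_n = 1, grid_sigma2 = c(0.5, 1),
                        folds = 3, seed = 4, schedule = sched)
  expect_equal(max(sel$cv_table$kappa), 1.0)   # separable: some config is perfect
  expect_equal(sel$cv_table$kappa[sel$cv_table$sigma2 == sel$sigma2], 1.0)
  sel2 <- grid_search_cv(train, grid_n = 1, grid_sigma2 = c(0.5, 1),
                         folds = 3, seed = 4, schedule = sched)
  expect_identical(sel, sel2)
})

test_that("fitted prototypes recover true class means at matched sigma2", {
  means <- make_class_means(4, 3, 1.2, seed = 9)
  train <- local({
    set.seed(9)
    riemalign:::sample_mixture(lapply(means, sym_logm), 0.1, 200, "d")
  })
  fit <- plvq_fit(train, 1, sigma2 = 0.1, seed = 2)
  for (k in 1:3)
    expect_lt(lem_distance(sym_expm(fit$log_prototypes[[k]]), means[[k]]),
              0.2)
})

test_that("PLVQ models serialize to JSON and predict identically after reload", {
  set.seed(61)
  means <- make_class_means(3, 2, 2)
  train <- riemalign:::sample_mixture(lapply(means, sym_logm), 0.3, 10, "d")
  fit <- plvq_fit(train, 2, sigma2 = 1,
                  schedule = learning_schedule(10, 1, 3, 2), seed = 1)
  back <- plvq_from_json(plvq_to_json(fit))
  expect_identical(plvq_predict(back, train), plvq_predict(fit, train))
  expect_equal(back$omega, fit$omega, tolerance = 1e-15)
  p <- tempfile(fileext = ".json")
  plvq_to_json(fit, p)
  expect_identical(plvq_predict(plvq_from_json(p), train),
                   plvq_predict(fit, train))
  unlink(p)
})
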