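#' Balanced-class Cohen kappa
#'
#' `kappa = (D - 1/C) / (1 - 1/C)` with `D` the classification accuracy and
#' `C` the number of equiprobable classes: 1 for perfect prediction, 0 at
#' chance level `1/C`. This is the chance-corrected accuracy conventionally
#' reported for balanced motor-imagery benchmarks. (Some print runs of the
#' formula show `D - C` in the numerator, which would be negative for any
#' accuracy; the balanced-class form is the only one consistent with
#' reported kappa ranges and is what this function implements.)
#'
#' @param y_true,y_pred integer label vectors of equal length, values in
#'   `1..C`.
#' @param C number of classes (default `max(y_true)`).
#' @return scalar kappa.
#' @export
kappa_score <- function(y_true, y_pred, C = max(y_true)) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    ra_stop("label vectors must be non-empty and of equal length",
            "riemalign_error_invalid_input")
  D <- mean(y_true == y_pred)
  (D - 1 / C) / (1 - 1 / C)
}

#' Confusion matrix with fixed class set
#'
#' @inheritParams kappa_score
#' @return `C x C` count matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(y_true, y_pred, C = max(y_true)) {
  tab <- matrix(0L, C, C, dimnames = list(true = seq_len(C),
                                          pred = seq_len(C)))
  for (i in seq_along(y_true))
    tab[y_true[i], y_pred[i]] <- tab[y_true[i], y_pred[i]] + 1L
  tab
}

cpu_seconds <- function(expr) {
  t0 <- proc.time()
  value <- force(expr)
  dt <- proc.time() - t0
  list(value = value, seconds = unname(dt["user.self"] + dt["sys.self"]))
}

# polynomial rolling hash of a config list, for provenance stamps
# (kept in doubles below 2^31 to stay clear of R's integer range)
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

new_evaluation_result <- function(kappa, accuracy, confusion, cpu_time,
                                  config, seed) {
  structure(list(kappa = kappa, accuracy = accuracy, confusion = confusion,
                 cpu_time = cpu_time, config_hash = config_hash(config),
                 seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> kappa = %.4f, accuracy = %.4f (seed %d, config %s)\n",
              x$kappa, x$accuracy, x$seed, x$config_hash))
  cat("  cpu seconds:", paste(sprintf("%s %.3f", names(x$cpu_time),
                                      x$cpu_time), collapse = ", "), "\n")
  invisible(x)
}

fit_alignment <- function(method, source, target, align_args = list()) {
  switch(method,
    none = NULL,
    pa_lem = do.call(fit_pa_lem, c(list(source, target), align_args)),
    rpa_lem = do.call(fit_rpa_lem, c(list(source, target), align_args)),
    rpa_airm = do.call(fit_rpa_airm, c(list(source, target), align_args)),
    ra_stop(sprintf("unknown alignment method '%s'", method),
            "riemalign_error_invalid_input"))
}

train_classifier <- function(classifier, train, args = list(), seed = 1) {
  switch(classifier,
    mdrm = do.call(mdrm_fit, c(list(train), args)),
    plvq = do.call(plvq_fit, c(list(train), args, list(seed = seed))),
    ra_stop(sprintf("unknown classifier '%s'", classifier),
            "riemalign_error_invalid_input"))
}

predict_classifier <- function(model, dataset) {
  if (inherits(model, "mdrm_model")) mdrm_predict(model, dataset)
  else plvq_predict(model, dataset)
}

#' Cross-session transfer evaluation
#'
#' Fits the alignment unsupervised on (source, target) -- target labels are
#' never seen by the fit -- trains the classifier on the aligned source,
#' and scores predictions on the aligned target against the target labels.
#' `method = "none"` skips alignment. CPU time is recorded separately for
#' alignment, training and prediction.
#'
#' @param source labeled `spd_dataset` (training session).
#' @param target labeled `spd_dataset` (testing session; labels used for
#'   scoring only).
#' @param method `"none"`, `"pa_lem"`, `"rpa_lem"`, or `"rpa_airm"`.
#' @param classifier `"mdrm"` or `"plvq"`.
#' @param config list with optional elements `align` and `classifier`,
#'   extra arguments for the respective fits.
#' @param seed RNG seed (classifier training).
#' @return `evaluation_result`.
#' @export
run_cross_session <- function(source, target,
                              method = c("none", "pa_lem", "rpa_lem",
                                         "rpa_airm"),
                              classifier = c("mdrm", "plvq"),
                              config = list(), seed = 1) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  if (is.null(source$labels) || is.null(target$labels))
    ra_stop("both domains must be labeled (target labels are used for scoring only)",
            "riemalign_error_invalid_input")
  ta <- cpu_seconds({
    tf <- fit_alignment(method, source, target,
                        config$align %||% list())
    if (is.null(tf)) list(src = source, tgt = target)
    else list(src = apply_transform(tf$source, source),
              tgt = apply_transform(tf$target, target))
  })
  tt <- cpu_seconds(train_classifier(classifier, ta$value$src,
                                     config$classifier %||% list(), seed))
  tp <- cpu_seconds(predict_classifier(tt$value, ta$value$tgt))
  C <- max(source$labels, target$labels)
  pred <- tp$value
  new_evaluation_result(
    kappa = kappa_score(target$labels, pred, C),
    accuracy = mean(target$labels == pred),
    confusion = confusion_matrix(target$labels, pred, C),
    cpu_time = c(alignment = ta$seconds, training = tt$seconds,
                 prediction = tp$seconds),
    config = c(list(method = method, classifier = classifier), config),
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-subject transfer evaluation over all directed pairs
#'
#' Every subject serves as test subject once per remaining training
#' subject (full directed pairing). Results are averaged per test subject
#' with standard deviation, mirroring the usual cross-subject reporting
#' shape.
#'
#' @param datasets named list of labeled `spd_dataset`s, one per subject
#'   (at least 2).
#' @param method,classifier,config,seed as in [run_cross_session()].
#' @return list with `results` (one row per directed pair: train, test,
#'   kappa, accuracy) and `summary` (per test subject: mean_kappa,
#'   sd_kappa, n_pairs).
#' @export
run_cross_subject <- function(datasets, method = "rpa_lem",
                              classifier = "mdrm", config = list(),
                              seed = 1) {
  if (length(datasets) < 2)
    ra_stop("need at least 2 subjects", "riemalign_error_invalid_input")
  subs <- names(datasets)
  if (is.null(subs)) subs <- as.character(seq_along(datasets))
  rows <- list()
  for (te in seq_along(datasets)) for (tr in seq_along(datasets)) {
    if (tr == te) next
    res <- run_cross_session(datasets[[tr]], datasets[[te]], method,
                             classifier, config, seed)
    rows[[length(rows) + 1]] <- data.frame(
      train_subject = subs[tr], test_subject = subs[te],
      kappa = res$kappa, accuracy = res$accuracy,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  agg <- split(results$kappa, results$test_subject)
  summary <- data.frame(
    test_subject = names(agg),
    mean_kappa = vapply(agg, mean, numeric(1)),
    sd_kappa = vapply(agg, stats::sd, numeric(1)),
    n_pairs = vapply(agg, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}

#' Repeat a seeded experiment and aggregate
#'
#' Runs `experiment(seed)` for seeds `base_seed .. base_seed + n_runs - 1`
#' and reports the per-run kappa values with their mean and standard
#' deviation (the customary "mean (sd)" table cell).
#'
#' @param experiment function of a single integer seed returning either a
#'   numeric scalar or an `evaluation_result`.
#' @param n_runs number of repetitions (default 10).
#' @param base_seed first seed (default 0).
#' @return list with `values`, `mean`, `sd`, `seeds`.
#' @export
run_repeated <- function(experiment, n_runs = 10, base_seed = 0) {
  if (n_runs < 1)
    ra_stop("n_runs must be >= 1", "riemalign_error_invalid_input")
  seeds <- base_seed + seq_len(n_runs) - 1
  values <- vapply(seeds, function(s) {
    r <- experiment(s)
    if (inherits(r, "evaluation_result")) r$kappa else as.numeric(r)
  }, numeric(1))
  list(values = values, mean = mean(values),
       sd = if (n_runs > 1) stats::sd(values) else 0,
       seeds = seeds)
}

#' CPU-time comparison of alignment methods
#'
#' Fits each method on the same (source, target) pair `repeats` times and
#' reports the mean process-CPU seconds per method plus the ratio of the
#' first to the second method. The closed-form LEM mean makes `rpa_lem`
#' fitting O(N n^2)-ish per pass versus the iterated Karcher mean inside
#' `rpa_airm`.
#'
#' @param source,target unlabeled or labeled `spd_dataset`s.
#' @param methods character vector of alignment methods (default
#'   `c("rpa_airm", "rpa_lem")`).
#' @param repeats averaging repeats (default 10).
#' @return list with `mean_seconds` (named), `ratio`
#'   (`first / second`), and the raw `seconds` matrix.
#' @export
timing_comparison <- function(source, target,
                              methods = c("rpa_airm", "rpa_lem"),
                              repeats = 10) {
  secs <- matrix(NA_real_, nrow = repeats, ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (m in methods) for (r in seq_len(repeats))
    secs[r, m] <- cpu_seconds(fit_alignment(m, source, target))$seconds
  mean_seconds <- colMeans(secs)
  ratio <- if (length(methods) >= 2)
    mean_seconds[[1]] / max(mean_seconds[[2]], .Machine$double.eps)
  else NA_real_
  list(mean_seconds = mean_seconds, ratio = ratio, seconds = secs)
}
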