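matrix_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) M[i, ])

rows_to_matrix <- function(rows) do.call(rbind, lapply(rows, unlist))

#' Serialize an SPD dataset to JSON
#'
#' Matrices as nested row lists plus labels and domain tag, full double
#' precision. [read_spd_dataset()] restores the object.
#'
#' @param dataset `spd_dataset`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_spd_dataset <- function(dataset, path) {
  obj <- list(format = "riemalign_spd_dataset", n = dataset$n,
              domain_id = dataset$domain_id,
              labels = dataset$labels,
              matrices = lapply(dataset$matrices, matrix_to_rows))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_spd_dataset
#' @export
read_spd_dataset <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "riemalign_spd_dataset"))
    ra_stop("not a riemalign SPD dataset file", "riemalign_error_invalid_input")
  mats <- lapply(obj$matrices, rows_to_matrix)
  spd_dataset(lapply(mats, sym_part),
              labels = if (length(obj$labels)) unlist(obj$labels) else NULL,
              domain_id = obj$domain_id, validate = FALSE)
}

#' Serialize epoched EEG to JSON
#'
#' Plain-text archive with keys `data` (trials x channels x samples,
#' nested), `fs`, `labels`, `tmin`. Suited to the small fixtures this
#' package works with; large recordings should be regenerated from code.
#'
#' @param epochs `epoched_eeg`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  obj <- list(format = "riemalign_epochs", fs = epochs$fs,
              tmin = epochs$tmin, dim = d, labels = epochs$labels,
              data = as.numeric(epochs$data))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "riemalign_epochs"))
    ra_stop("not a riemalign epochs file", "riemalign_error_invalid_input")
  epoched_eeg(array(obj$data, dim = obj$dim), obj$fs,
              labels = if (length(obj$labels)) obj$labels else NULL,
              tmin = obj$tmin)
}

#' Read a CSV event table (trial index, class label)
#'
#' Accepts a two-column CSV with headers `trial` and `label`; returns the
#' label vector ordered by trial index.
#'
#' @param path CSV file.
#' @return integer label vector.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial", "label") %in% names(df)))
    ra_stop("event table needs columns 'trial' and 'label'",
            "riemalign_error_invalid_input")
  as.integer(df$label[order(df$trial)])
}

#' Serialize an alignment transform to JSON
#'
#' Method tag, matrices as nested lists, scalars at full double precision;
#' the round trip through [transform_from_json()] is lossless to 1e-15.
#'
#' @param transform `alignment_transform`.
#' @param path optional output file; omitted, the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
transform_to_json <- function(transform, path = NULL) {
  obj <- list(format = "riemalign_transform", method = transform$method,
              log_center = if (!is.null(transform$log_center))
                matrix_to_rows(transform$log_center),
              recenter_matrix = if (!is.null(transform$recenter_matrix))
                matrix_to_rows(transform$recenter_matrix),
              stretch_exponent = transform$stretch_exponent,
              scale_divisor = transform$scale_divisor)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname transform_to_json
#' @param json JSON string or path to a JSON file.
#' @export
transform_from_json <- function(json) {
  obj <- if (file.exists(json[1]) && !grepl("^\\s*\\{", json[1]))
    jsonlite::read_json(json) else jsonlite::fromJSON(json,
                                                      simplifyVector = FALSE)
  if (!identical(obj$format, "riemalign_transform"))
    ra_stop("not a riemalign transform document",
            "riemalign_error_invalid_input")
  new_alignment_transform(
    method = obj$method,
    log_center = if (!is.null(obj$log_center)) rows_to_matrix(obj$log_center),
    recenter_matrix = if (!is.null(obj$recenter_matrix))
      rows_to_matrix(obj$recenter_matrix),
    stretch_exponent = obj$stretch_exponent,
    scale_divisor = obj$scale_divisor)
}

#' Serialize a PLVQ model to JSON
#'
#' Log-prototypes, `Omega`, `sigma2` and priors, losslessly restorable with
#' [plvq_from_json()].
#'
#' @param model `plvq_model`.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
plvq_to_json <- function(model, path = NULL) {
  obj <- list(format = "riemalign_plvq", n = model$n,
              n_per_class = model$n_per_class,
              proto_labels = model$proto_labels,
              log_prototypes = lapply(model$log_prototypes, matrix_to_rows),
              omega = matrix_to_rows(model$omega),
              sigma2 = model$sigma2, priors = model$priors)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname plvq_to_json
#' @param json JSON string or path to a JSON file.
#' @export
plvq_from_json <- function(json) {
  obj <- if (file.exists(json[1]) && !grepl("^\\s*\\{", json[1]))
    jsonlite::read_json(json) else jsonlite::fromJSON(json,
                                                      simplifyVector = FALSE)
  if (!identical(obj$format, "riemalign_plvq"))
    ra_stop("not a riemalign PLVQ document", "riemalign_error_invalid_input")
  new_plvq_model(lapply(obj$log_prototypes, rows_to_matrix),
                 unlist(obj$proto_labels), rows_to_matrix(obj$omega),
                 obj$sigma2, unlist(obj$priors), obj$n_per_class)
}

#' Write / read an evaluation results table as CSV
#'
#' Numeric columns are written with 17 significant digits so the round trip
#' is lossless well below 1e-12.
#'
#' @param df data.frame of results (one row per subject/method/run).
#' @param path CSV file.
#' @return invisibly, the path (write) / the data.frame (read).
#' @export
write_results_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
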