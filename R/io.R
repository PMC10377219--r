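# Cohort CSV and model checkpoint I/O. Cohort files carry the 12-column
# schema with categorical columns encoded as strings; checkpoints are a
# single JSON document (full-precision numeric arrays plus the scaler,
# feature order and shape metadata) so a loaded model reproduces forward
# outputs of the saved one.

#' Write a cohort to CSV
#'
#' Header row with the 12 schema column names, one record per row;
#' categorical columns encoded as `man`/`woman`, `no`/`yes` and
#' `low`/`high` strings.
#'
#' @param cohort Cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (v in c(binary_vars(), "stress")) df[[v]] <- as.character(df[[v]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the 12-column schema and coerces types; rows with missing or
#' unparseable values (non-numeric measurements, unknown category strings)
#' are dropped with a message reporting the count, mirroring the exclusion
#' of non-respondent records in survey pre-processing.
#'
#' @param path CSV file written by [write_cohort()] or of identical layout.
#' @return Cohort tibble with typed columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(cohort_schema(), "stress")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(df)) stop("cohort file has no records", call. = FALSE)
  df <- df[, need]
  n0 <- nrow(df)
  for (v in continuous_vars())
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  lv <- c(binary_levels(), list(stress = c("low", "high")))
  for (v in names(lv)) {
    bad <- !(df[[v]] %in% lv[[v]])
    df[[v]][bad] <- NA
    df[[v]] <- factor(df[[v]], levels = lv[[v]])
  }
  keep <- stats::complete.cases(df)
  if (any(!keep))
    message("read_cohort: dropped ", sum(!keep),
            " record(s) with missing or unparseable values")
  tibble::as_tibble(df[keep, , drop = FALSE])
}

leaf_to_json <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
  else list(dim = length(x), data = as.numeric(x))
}

params_to_json <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, params_to_json)
    names(out) <- names(p)
    return(out)
  }
  if (is.numeric(p)) leaf_to_json(p) else list(flag = p)
}

params_from_json <- function(j) {
  if (!is.null(j$flag)) return(as.logical(j$flag))
  if (!is.null(j$data)) {
    x <- as.numeric(j$data)
    if (length(j$dim) == 2L) dim(x) <- as.integer(j$dim)
    return(x)
  }
  out <- lapply(j, params_from_json)
  names(out) <- names(j)
  out
}

#' Save a fitted model checkpoint
#'
#' Writes one JSON document holding every trainable array at full numeric
#' precision together with the scaler statistics, feature order, threshold
#' and shape metadata; [load_elstm()] reconstructs a model with identical
#' forward behavior.
#'
#' @param model An [fit_elstm()] model.
#' @param path Output file (JSON).
#' @return `path`, invisibly.
#' @export
save_elstm <- function(model, path) {
  d <- elstm_dims(model$params)
  doc <- list(
    format = "elstm-checkpoint-1",
    n = d$n, T = d$T, m = d$m, seed = model$seed,
    features = model$features,
    scaler = list(center = as.numeric(model$scaler$center),
                  scale = as.numeric(model$scaler$scale),
                  features = model$scaler$features),
    config = unclass(model$config),
    params = params_to_json(unclass(model$params)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_elstm()].
#' @return An `elstm_model` (without training history).
#' @export
load_elstm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "elstm-checkpoint-1"))
    stop("not an elstm checkpoint: ", path, call. = FALSE)
  params <- structure(params_from_json(doc$params), class = "elstm_params",
                      n = as.integer(doc$n), T = as.integer(doc$T),
                      m = as.integer(doc$m))
  scaler <- list(center = doc$scaler$center, scale = doc$scaler$scale,
                 features = doc$scaler$features)
  names(scaler$center) <- names(scaler$scale) <- scaler$features
  cfg <- doc$config
  config <- training_config(
    preset = cfg$preset, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, epochs = cfg$epochs,
    dropout_rate = cfg$dropout_rate, momentum = cfg$momentum,
    beta1 = cfg$beta1, beta2 = cfg$beta2, adam_eps = cfg$adam_eps,
    lambda = cfg$lambda, threshold = cfg$threshold,
    n_hidden = cfg$n_hidden, steps = cfg$steps, optimizer = cfg$optimizer,
    val_fraction = cfg$val_fraction)
  structure(list(params = params, scaler = scaler, features = doc$features,
                 config = config, history = NULL, split = NULL,
                 seed = doc$seed),
            class = "elstm_model")
}
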