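#' Read a numeric regression dataset from CSV
#'
#' The expected dialect is strict: comma separator, `.` decimal, UTF-8, a
#' header row, all cells numeric and finite. The loader rejects anything
#' else, naming the offending row and column.
#'
#' @param path CSV file path.
#' @param target_column Name of the target column, or `NULL` for
#'   predict-only data with features exclusively.
#' @return A [dataset()].
#' @export
read_csv_dataset <- function(path, target_column = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) == 0L) stop("CSV contains no data rows", call. = FALSE)
  if (anyDuplicated(names(df))) stop("CSV has duplicated column names", call. = FALSE)
  for (cn in names(df)) {
    col <- df[[cn]]
    if (is.logical(col) && all(is.na(col))) col <- as.numeric(col)
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed))[1L]
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   col[bad], bad, cn), call. = FALSE)
    }
    if (!all(is.finite(col))) {
      bad <- which(!is.finite(col))[1L]
      stop(sprintf("non-finite value at data row %d, column '%s'", bad, cn),
           call. = FALSE)
    }
  }
  if (is.null(target_column)) {
    return(dataset(as.matrix(df), feature_names = names(df)))
  }
  if (!target_column %in% names(df)) {
    stop(sprintf("target column '%s' not found in %s", target_column, path),
         call. = FALSE)
  }
  feats <- setdiff(names(df), target_column)
  if (length(feats) == 0L) stop("no feature columns besides the target", call. = FALSE)
  dataset(as.matrix(df[feats]), df[[target_column]],
          feature_names = feats, target_name = target_column)
}

#' Write a dataset to CSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every double exactly.
#'
#' @param data A [dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(data, path) {
  stopifnot(inherits(data, "dataset"))
  cols <- c(
    stats::setNames(lapply(seq_len(ncol(data$x)),
                           function(j) sprintf("%.17g", data$x[, j])),
                    data$feature_names),
    if (!is.null(data$y)) stats::setNames(list(sprintf("%.17g", data$y)),
                                          data$target_name)
  )
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

ARCHIVE_FORMAT_VERSION <- "1.0"

mat_pack <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
mat_unpack <- function(x) {
  matrix(as.numeric(x$data), nrow = x$dim[[1L]], ncol = x$dim[[2L]], byrow = TRUE)
}

#' Save a fitted cascade model to a JSON archive
#'
#' The archive is a complete, self-describing, human-readable JSON document
#' (configuration, per-level scaler scales, monomial bases and SGTM steps —
#' base directions, alpha coefficients, centring means) written at full
#' double precision, in keeping with the interpretability goals of the
#' method: a saved model can be audited with a text editor.
#'
#' @param model A fitted [cascade_fit()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sgtm_cascade"))
  archive <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    model_class = "sgtm_cascade",
    config = model$config,
    feature_names = as.list(model$feature_names),
    target_name = model$target_name,
    levels = lapply(model$levels, function(lvl) list(
      basis = list(variable_names = as.list(lvl$basis$variable_names),
                   degree = lvl$basis$degree,
                   exponents = mat_pack(lvl$basis$exponents)),
      scaler = list(scale = as.numeric(lvl$scaler$scale)),
      sgtm = list(directions = mat_pack(lvl$sgtm$directions),
                  alphas = as.numeric(lvl$sgtm$alphas),
                  base_row_indices = as.integer(lvl$sgtm$base_row_indices),
                  base_norms = as.numeric(lvl$sgtm$base_norms),
                  input_means = as.numeric(lvl$sgtm$input_means),
                  output_means = as.numeric(lvl$sgtm$output_means),
                  p = lvl$sgtm$p, q = lvl$sgtm$q, m = lvl$sgtm$m,
                  rank_tol = lvl$sgtm$rank_tol,
                  gains = as.numeric(lvl$sgtm$gains),
                  app_weights = mat_pack(lvl$sgtm$app_weights))
    ))
  )
  jsonlite::write_json(archive, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a cascade model from a JSON archive
#'
#' Refuses archives whose `format_version` is unknown. A save/load round
#' trip preserves predictions to better than 1e-12.
#'
#' @param path Archive path written by [save_model()].
#' @return A fitted `"sgtm_cascade"` model.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  archive <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                       simplifyDataFrame = FALSE),
    error = function(e) stop(sprintf("cannot parse model archive: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  if (!identical(archive$format_version, ARCHIVE_FORMAT_VERSION)) {
    stop(sprintf("unsupported model archive format_version '%s' (expected '%s')",
                 as.character(archive$format_version), ARCHIVE_FORMAT_VERSION),
         call. = FALSE)
  }
  cfg <- archive$config
  hn <- cfg$hidden_neurons
  if (!identical(hn, "full")) hn <- as.integer(hn)
  model <- structure(
    list(
      config = list(levels = as.integer(cfg$levels), degree = as.integer(cfg$degree),
                    hidden_neurons = hn, seed = as.integer(cfg$seed),
                    shuffled_partition = isTRUE(cfg$shuffled_partition)),
      feature_names = as.character(unlist(archive$feature_names)),
      target_name = archive$target_name,
      levels = lapply(archive$levels, function(lvl) {
        expo <- mat_unpack(lvl$basis$exponents)
        storage.mode(expo) <- "integer"
        basis <- structure(
          list(variable_names = as.character(unlist(lvl$basis$variable_names)),
               degree = as.integer(lvl$basis$degree), exponents = expo),
          class = "kg_basis")
        scaler <- structure(list(scale = as.numeric(lvl$scaler$scale),
                                 n_cols = length(lvl$scaler$scale)),
                            class = "maxabs_scaler")
        s <- lvl$sgtm
        sgtm <- structure(
          list(directions = mat_unpack(s$directions),
               alphas = as.numeric(s$alphas),
               base_row_indices = as.integer(s$base_row_indices),
               base_norms = as.numeric(s$base_norms),
               input_means = as.numeric(s$input_means),
               output_means = as.numeric(s$output_means),
               p = as.integer(s$p), q = as.integer(s$q), m = as.integer(s$m),
               supervised = TRUE, rank_tol = as.numeric(s$rank_tol),
               gains = as.numeric(s$gains),
               app_weights = mat_unpack(s$app_weights)),
          class = "sgtm")
        list(basis = basis, scaler = scaler, sgtm = sgtm)
      })
    ),
    class = "sgtm_cascade"
  )
  model
}
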