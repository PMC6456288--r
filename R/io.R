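#' Read a feature table from CSV or ARFF
#'
#' Loads an instances-by-features table with one categorical class column.
#' CSV files must have a header row, comma separators, `.` decimals and
#' UTF-8 encoding; ARFF files are read with their declared attribute types.
#' Feature columns are coerced to numeric; the class column is extracted as
#' a factor. Missing values, non-numeric feature cells and duplicate
#' feature names are rejected.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"arff"`.
#' @param label_column Name of the class column, or `"last"` to take the
#'   final column.
#' @return A tibble of numeric feature columns plus a factor column named as
#'   in the file (reported in attribute `class_col`), with at least two
#'   distinct class labels.
#' @export
read_feature_table <- function(path, format = c("auto", "csv", "arff"),
                               label_column = "last") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  raw <- switch(format,
    csv = as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE,
                                        name_repair = "minimal")),
    arff = foreign::read.arff(path)
  )
  if (ncol(raw) < 2L) stop("table needs at least one feature and a class column")
  if (anyDuplicated(names(raw))) {
    stop("duplicate feature ids: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  class_col <- if (identical(label_column, "last")) {
    names(raw)[ncol(raw)]
  } else {
    if (!label_column %in% names(raw)) {
      stop("label column '", label_column, "' not found")
    }
    label_column
  }
  if (anyNA(raw)) {
    bad <- which(is.na(raw), arr.ind = TRUE)
    stop("missing values at ",
         paste(sprintf("row %d col %s", bad[, 1], names(raw)[bad[, 2]]),
               collapse = "; "))
  }
  feats <- setdiff(names(raw), class_col)
  for (f in feats) {
    if (!is.numeric(raw[[f]])) {
      coerced <- suppressWarnings(as.numeric(as.character(raw[[f]])))
      if (anyNA(coerced)) {
        stop("non-numeric value in feature column '", f, "'")
      }
      raw[[f]] <- coerced
    }
  }
  raw[[class_col]] <- factor(raw[[class_col]])
  if (nlevels(raw[[class_col]]) < 2L) {
    stop("class column must have >= 2 distinct class labels")
  }
  out <- tibble::as_tibble(raw)
  attr(out, "class_col") <- class_col
  out
}

#' Write a feature table to CSV (with optional ground-truth sidecar)
#'
#' Writes the table with a header row and the class column last. If the
#' table carries planted ground truth (from [synth_table()]) it is written
#' alongside as `<path>.truth.json`.
#'
#' @param data Feature table (tibble or data frame).
#' @param path Output CSV path.
#' @param class_col Name of the class column (moved to the last position).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, class_col = "class") {
  df <- as.data.frame(data)
  if (!class_col %in% names(df)) stop("class column '", class_col, "' not found")
  df <- df[c(setdiff(names(df), class_col), class_col)]
  readr::write_csv(df, path, progress = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Serialize an FSBRR selection result
#'
#' Writes the selection as JSON (selected features with scores, the removal
#' log, the pairwise-evaluation count and the configuration) and, when
#' `list_path` is given, as a plain-text one-feature-per-line list.
#'
#' @param x An object returned by [fsbrr()].
#' @param json_path Output JSON path.
#' @param list_path Optional output path for the plain-text feature list.
#' @return `json_path`, invisibly.
#' @export
write_selection <- function(x, json_path, list_path = NULL) {
  if (!inherits(x, "fsbrr")) stop("x must be an fsbrr result")
  payload <- list(
    selected = x$selected,
    removal_log = x$removal_log,
    pair_evaluations = x$pair_evaluations,
    r_max = x$r_max,
    r_bar = x$r_bar,
    config = x$config
  )
  jsonlite::write_json(payload, json_path, dataframe = "rows",
                       auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(list_path)) {
    writeLines(x$selected$feature, list_path)
  }
  invisible(json_path)
}
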