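# Delimited-text dataset I/O.

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited-text dataset
#'
#' Parses a CSV (default) or TSV file with a header row into a
#' [gatan_dataset()]. Rows with a missing value in any target column are
#' dropped with a message reporting the count. Categorical targets are
#' one-hot encoded with the level order of first occurrence.
#'
#' @param path File path.
#' @param primary Name of the primary target column.
#' @param aux Character vector of auxiliary target column names.
#' @param primary_type,aux_types Optional explicit task types.
#' @param delim Field delimiter; guessed from the first line when NULL.
#' @return A [gatan_dataset()] (with `encoding` attribute, see
#'   [as_gatan_dataset()]).
#' @export
read_dataset <- function(path, primary, aux = character(),
                         primary_type = NULL, aux_types = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% guess_delim(path)
  df <- as.data.frame(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE))
  missing_cols <- setdiff(c(primary, aux), names(df))
  if (length(missing_cols)) {
    stop("read_dataset: column(s) not in header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(df[c(primary, aux)])
  if (any(!keep)) {
    message("read_dataset: dropped ", sum(!keep),
            " row(s) with missing target values")
    df <- df[keep, , drop = FALSE]
  }
  features <- setdiff(names(df), c(primary, aux))
  for (f in features) {
    if (!is.numeric(df[[f]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[f]]))) |
                       !grepl("^\\s*[-+0-9.eE]+\\s*$", as.character(df[[f]])))[1L]
      stop("read_dataset: non-numeric value in feature column '", f,
           "', row ", bad_row %||% 1L, call. = FALSE)
    }
  }
  as_gatan_dataset(df, primary, aux, primary_type, aux_types,
                   features = features)
}

#' Write a data frame as delimited text
#'
#' Values are written at full double precision so a read-back reproduces
#' them exactly.
#'
#' @param data Data frame or tibble.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}
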