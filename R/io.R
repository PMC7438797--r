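#' Read a binary dataset from CSV or Mplus-style .dat
#'
#' CSV files are expected to carry a header row; `.dat` files are
#' whitespace-delimited without header (the Mplus convention).  Every entry
#' must be 0 or 1; missing-value codes (blanks, ".", "*", "-99", NA) are
#' rejected explicitly since the model has no missing-data mechanism.
#'
#' @param path file path.
#' @param format `"csv"` or `"dat"`; guessed from the file extension by
#'   default.
#' @return a `flexlca_data`.
#' @export
read_binary_data <- function(path, format = c("auto", "csv", "dat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "dat"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("file is empty: ", path)
  header <- NULL
  if (format == "csv") {
    header <- strsplit(lines[1], ",")[[1]]
    lines <- lines[-1]
    if (!length(lines)) stop("CSV has a header but no data rows: ", path)
    tokens <- strsplit(lines, ",")
  } else {
    tokens <- strsplit(trimws(lines), "[[:space:]]+")
  }
  J <- length(tokens[[1]])
  missing_codes <- c("", ".", "*", "-99", "NA", "na")
  Y <- matrix(0L, length(tokens), J)
  for (i in seq_along(tokens)) {
    row <- trimws(tokens[[i]])
    if (length(row) != J) {
      stop("ragged file: row ", i + (format == "csv"), " has ", length(row),
           " fields, expected ", J)
    }
    for (j in seq_len(J)) {
      v <- row[j]
      if (v %in% missing_codes || is.na(suppressWarnings(as.numeric(v)))) {
        stop("missing or non-numeric value '", v, "' at row ",
             i + (format == "csv"), ", column ", j,
             ": missing data are not supported")
      }
      num <- as.numeric(v)
      if (!num %in% c(0, 1)) {
        stop("non-binary value '", v, "' at row ", i + (format == "csv"),
             ", column ", j, ": entries must be 0 or 1")
      }
      Y[i, j] <- as.integer(num)
    }
  }
  colnames(Y) <- if (!is.null(header) && length(header) == J) {
    trimws(header)
  } else paste0("item", seq_len(J))
  out <- as_flexlca_data(Y)
  out$meta$path <- path
  out
}

#' Write a binary dataset to CSV and/or Mplus-style .dat
#'
#' Writes a headered CSV of 0/1 integers, a whitespace-delimited headerless
#' `.dat` twin, and a sidecar JSON recording the generation metadata.
#'
#' @param data a `flexlca_data`.
#' @param path_csv,path_dat,path_json output paths; `NULL` skips that file.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(data, path_csv = NULL, path_dat = NULL,
                          path_json = NULL) {
  stopifnot(inherits(data, "flexlca_data"))
  written <- character(0)
  if (!is.null(path_csv)) {
    utils::write.csv(as.data.frame(data$responses), path_csv, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, csv = path_csv)
  }
  if (!is.null(path_dat)) {
    utils::write.table(data$responses, path_dat, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    written <- c(written, dat = path_dat)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(c(data$meta, list(n = nrow(data$responses),
                                           n_items = ncol(data$responses))),
                         path_json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json = path_json)
  }
  invisible(written)
}

# manifest for artifact-producing commands: config + seed + file hashes
write_manifest <- function(dir, config, files) {
  files <- files[file.exists(files)]
  manifest <- list(config = config,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
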