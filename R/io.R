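# Readers and writers: signals as one-column CSV plus a JSON metadata
# sidecar, feature matrices as TSV with a header row. Plain-text on purpose:
# fixtures stay human-inspectable and diffable.

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a signal record
#'
#' Emits a headerless one-column CSV of sample values (full double
#' precision) and a JSON sidecar `<stem>.json` carrying `fs`, `label` (if
#' any) and `source_id`.
#'
#' @param record A [signal_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path) {
  if (!inherits(record, "signal_record")) {
    stop("`record` must be a signal_record", call. = FALSE)
  }
  writeLines(sprintf("%.17g", record$samples), path)
  meta <- list(fs = record$fs, source_id = record$source_id)
  if (!is.null(record$label)) meta$label <- record$label
  jsonlite::write_json(meta, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal record
#'
#' Inverse of [write_signal()]. Malformed sample rows and invalid sidecars
#' are rejected with an error naming the file and line.
#'
#' @param path CSV path; the sidecar `<stem>.json` must exist.
#' @return A [signal_record()].
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("%s: no such file", path), call. = FALSE)
  }
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("%s: missing JSON sidecar %s", path, sc), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("%s: line %d: not a number: '%s'", path, bad, lines[bad]),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
    stop(sprintf("%s: sidecar `fs` must be a positive number", sc),
         call. = FALSE)
  }
  signal_record(vals, fs = meta$fs, label = meta$label,
                source_id = if (is.null(meta$source_id)) "" else meta$source_id)
}

#' Write/read a whole dataset directory
#'
#' One CSV + sidecar per record, named `rec-0001.csv`, ... in list order.
#'
#' @param records List of [signal_record()]s.
#' @param dir Directory (created if needed).
#' @return For `write_dataset`, the vector of CSV paths, invisibly; for
#'   `read_dataset`, a list of records in filename order.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("rec-%04d.csv", seq_along(records)))
  for (i in seq_along(records)) write_signal(records[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(paths, read_signal)
}

#' Fixed feature column order
#'
#' Subband-major: `d1_E, d1_K, d1_PV, d1_NV, d2_..., d3_..., a3_...`.
#'
#' @return Character vector of the 16 feature column names.
#' @export
feature_names <- function() {
  paste(rep(c("d1", "d2", "d3", "a3"), each = 4),
        rep(c("E", "K", "PV", "NV"), times = 4), sep = "_")
}

#' Write/read a feature matrix
#'
#' TSV with a header row of the 16 feature names plus `"label"`; reading
#' inverts writing. Column-count or name mismatches on read raise a format
#' error.
#'
#' @param fm A feature matrix as returned by [build_feature_matrix()]: a
#'   data frame of the 16 numeric feature columns plus a `label` column.
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, the feature
#'   matrix data frame.
#' @export
write_feature_matrix <- function(fm, path) {
  .check_feature_matrix(fm)
  out <- fm
  for (nm in feature_names()) out[[nm]] <- sprintf("%.17g", fm[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, c(feature_names(), "label"))) {
    stop(sprintf("%s: expected 17 columns (the 16 feature names plus label), found %d",
                 path, length(header)), call. = FALSE)
  }
  fm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(rep("numeric", 16), "character"),
                          check.names = FALSE)
  .check_feature_matrix(fm)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

.check_feature_matrix <- function(fm) {
  if (!is.data.frame(fm) ||
      !identical(names(fm), c(feature_names(), "label"))) {
    stop("feature matrix must have the 16 feature columns plus `label`",
         call. = FALSE)
  }
  num <- as.matrix(fm[, feature_names(), drop = FALSE])
  if (nrow(fm) > 0 && any(!is.finite(num))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  invisible(fm)
}
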