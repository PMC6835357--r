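#' Read a feature table from delimited files
#'
#' The response matrix is stored as CSV with one feature per row
#' (`feature_id` in the first column) and one sample per column; empty
#' cells are missing values.  Feature and sample metadata live in sidecar
#' CSVs keyed by `feature_id` / `sample_id`.  Parsing is
#' locale-independent (decimal point only).
#'
#' @param path CSV file with the response matrix.
#' @param samples_path CSV file with sample metadata.
#' @param features_path CSV file with feature metadata; if `NULL`, minimal
#'   metadata holding only the feature ids is constructed.
#' @param zeros_as_missing treat zero responses as missing on import.  Off
#'   by default: zero is a legal measured value distinct from missing, but
#'   upstream exports that encode below-detection-limit values as zero can
#'   be imported with this switch.
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(path, samples_path, features_path = NULL,
                               zeros_as_missing = FALSE) {
  for (p in c(path, samples_path, features_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = NA)
  if (ncol(raw) < 1 || names(raw)[1] != "feature_id")
    stop("response matrix must have 'feature_id' as its first column",
         call. = FALSE)
  feature_ids <- as.character(raw$feature_id)
  resp <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(resp) <- "double")
  samples <- utils::read.csv(samples_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!("sample_id" %in% names(samples)))
    stop("sample metadata must contain a 'sample_id' column", call. = FALSE)
  missing_cols <- setdiff(samples$sample_id, colnames(resp))
  if (length(missing_cols) > 0)
    stop("sample(s) listed in metadata but absent from response matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra_cols <- setdiff(colnames(resp), samples$sample_id)
  if (length(extra_cols) > 0)
    stop("response matrix column(s) without sample metadata: ",
         paste(extra_cols, collapse = ", "), call. = FALSE)
  resp <- resp[, samples$sample_id, drop = FALSE]
  if ("is_qc" %in% names(samples)) samples$is_qc <- as.logical(samples$is_qc)
  if (is.null(features_path)) {
    features <- data.frame(feature_id = feature_ids, stringsAsFactors = FALSE)
  } else {
    features <- utils::read.csv(features_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
    if (!("feature_id" %in% names(features)))
      stop("feature metadata must contain a 'feature_id' column", call. = FALSE)
    missing_feat <- setdiff(feature_ids, features$feature_id)
    if (length(missing_feat) > 0)
      stop("feature(s) in response matrix without metadata: ",
           paste(missing_feat, collapse = ", "), call. = FALSE)
    features <- features[match(feature_ids, features$feature_id), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (zeros_as_missing) resp[!is.na(resp) & resp == 0] <- NA_real_
  feature_table(resp, features, samples)
}

#' Write a feature table to delimited files
#'
#' Inverse of [read_feature_table()]: numeric values are serialized with 17
#' significant digits so a round-trip reproduces the doubles exactly;
#' missing values become empty cells.
#'
#' @param ft a `feature_table`.
#' @param path output CSV for the response matrix.
#' @param samples_path output CSV for sample metadata.
#' @param features_path output CSV for feature metadata (optional).
#' @return invisibly, the vector of paths written.
#' @export
write_feature_table <- function(ft, path, samples_path, features_path = NULL) {
  validate_feature_table(ft)
  resp <- ft$responses
  chr <- matrix("", nrow = nrow(resp), ncol = ncol(resp))
  ok <- !is.na(resp)
  chr[ok] <- formatC(resp[ok], digits = 17, format = "g")
  out <- data.frame(feature_id = ft$features$feature_id, chr,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("feature_id", ft$samples$sample_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(ft$samples, samples_path, row.names = FALSE, na = "")
  if (!is.null(features_path))
    utils::write.csv(ft$features, features_path, row.names = FALSE, na = "")
  invisible(c(path, samples_path, features_path))
}

#' Read per-participant nutrient records
#'
#' Long-ish layout: one row per (participant, period), one column per
#' nutrient category plus the five absolute-unit fields used by the diet
#' quality score.
#'
#' @param path CSV file.
#' @return data.frame with columns `participant_id`, `period`
#'   (`"baseline"`/`"intervention"`), and numeric intake columns.
#' @export
read_nutrient_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant_id", "period")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("nutrient records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(rec$period), c("baseline", "intervention"))
  if (length(bad) > 0)
    stop("unknown period value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rec
}

#' Write nutrient records
#' @param records data.frame as returned by [read_nutrient_records()].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_nutrient_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
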