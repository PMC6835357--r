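#' Feature-response table with sample and feature metadata
#'
#' The central container of the pipeline: a nonnegative response matrix
#' (features in rows, samples in columns) together with a feature metadata
#' data frame and a sample metadata data frame.  Missing responses are held
#' as `NA`; zero is a legal measured value distinct from missing.
#'
#' @param responses numeric matrix, features x samples, values `>= 0` or `NA`.
#' @param features data.frame with at least a `feature_id` column (unique);
#'   conventional columns are `name`, `mz`, `rmt`, `ion_mode`
#'   (`"+"`/`"-"`), `platform`, `id_level` (1-4).
#' @param samples data.frame with at least a `sample_id` column (unique);
#'   conventional columns are `participant_id`, `arm` (`"W-P"`/`"P-W"`),
#'   `timepoint` (`"baseline"`/`"week2"`), `matrix` (`"plasma"`/`"urine"`),
#'   `age`, `sex` (`"F"`/`"M"`), `bmi`, `run_id`, `injection_position`,
#'   `is_qc` (logical).
#'
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(responses, features, samples) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(responses) != nrow(features))
    stop(sprintf("response matrix has %d rows but feature metadata lists %d features",
                 nrow(responses), nrow(features)), call. = FALSE)
  if (ncol(responses) != nrow(samples))
    stop(sprintf("response matrix has %d columns but sample metadata lists %d samples",
                 ncol(responses), nrow(samples)), call. = FALSE)
  rownames(responses) <- features$feature_id
  colnames(responses) <- samples$sample_id
  ft <- structure(
    list(responses = responses, features = features, samples = samples),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate a feature table's structural invariants
#'
#' Checks dimension consistency, id uniqueness, nonnegativity of responses,
#' and metadata constraints (QC samples carry no participant id; non-QC
#' samples have arm and timepoint set; each participant appears at most
#' once per timepoint within the table's matrix).
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  resp <- ft$responses
  if (!("feature_id" %in% names(ft$features)))
    stop("feature metadata must contain a 'feature_id' column", call. = FALSE)
  if (!("sample_id" %in% names(ft$samples)))
    stop("sample metadata must contain a 'sample_id' column", call. = FALSE)
  if (nrow(resp) != nrow(ft$features))
    stop(sprintf("response matrix has %d rows but feature metadata lists %d features",
                 nrow(resp), nrow(ft$features)), call. = FALSE)
  if (ncol(resp) != nrow(ft$samples))
    stop(sprintf("response matrix has %d columns but sample metadata lists %d samples",
                 ncol(resp), nrow(ft$samples)), call. = FALSE)
  if (anyDuplicated(ft$features$feature_id))
    stop("duplicated feature_id: ",
         paste(unique(ft$features$feature_id[duplicated(ft$features$feature_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(ft$samples$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(ft$samples$sample_id[duplicated(ft$samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  neg <- which(!is.na(resp) & resp < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative response for feature '%s' in sample '%s'",
                 rownames(resp)[neg[1, 1]], colnames(resp)[neg[1, 2]]),
         call. = FALSE)
  if ("id_level" %in% names(ft$features)) {
    bad <- ft$features$id_level[!is.na(ft$features$id_level)]
    if (any(!bad %in% 1:4))
      stop("id_level must be in 1..4", call. = FALSE)
  }
  sm <- ft$samples
  if ("is_qc" %in% names(sm)) {
    qc <- isTRUE_vec(sm$is_qc)
    if ("participant_id" %in% names(sm)) {
      bad <- qc & !is.na(sm$participant_id) & nzchar(sm$participant_id)
      if (any(bad))
        stop("QC samples must not carry a participant_id: ",
             paste(sm$sample_id[bad], collapse = ", "), call. = FALSE)
    }
    if (all(c("arm", "timepoint") %in% names(sm))) {
      bad <- !qc & (is.na(sm$arm) | is.na(sm$timepoint))
      if (any(bad))
        stop("non-QC samples must have arm and timepoint set: ",
             paste(sm$sample_id[bad], collapse = ", "), call. = FALSE)
    }
    if (all(c("participant_id", "timepoint") %in% names(sm))) {
      key <- paste(sm$participant_id[!qc], sm$timepoint[!qc])
      if (anyDuplicated(key))
        stop("participant appears more than once per timepoint: ",
             paste(unique(key[duplicated(key)]), collapse = ", "),
             call. = FALSE)
    }
  }
  invisible(ft)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.feature_table <- function(x, ...) {
  n_qc <- if ("is_qc" %in% names(x$samples)) sum(isTRUE_vec(x$samples$is_qc)) else 0L
  cat(sprintf("feature_table: %d features x %d samples (%d QC)\n",
              nrow(x$responses), ncol(x$responses), n_qc))
  if ("matrix" %in% names(x$samples)) {
    mats <- unique(stats::na.omit(x$samples$matrix))
    cat("  matrix:", paste(mats, collapse = ", "), "\n")
  }
  cat(sprintf("  missing: %d of %d cells\n",
              sum(is.na(x$responses)), length(x$responses)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$responses)

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param i feature index (integer, logical, or feature_id character).
#' @param j sample index (integer, logical, or sample_id character).
#' @param ... unused.
#' @return the subsetted `feature_table`.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$responses))
  if (missing(j)) j <- seq_len(ncol(x$responses))
  if (is.character(i)) i <- match(i, x$features$feature_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  structure(
    list(responses = x$responses[i, j, drop = FALSE],
         features = x$features[i, , drop = FALSE],
         samples = x$samples[j, , drop = FALSE]),
    class = "feature_table"
  )
}

#' Logical mask of QC samples
#' @param ft a `feature_table`.
#' @return logical vector over samples.
#' @export
qc_mask <- function(ft) {
  if (!("is_qc" %in% names(ft$samples))) return(rep(FALSE, nrow(ft$samples)))
  isTRUE_vec(ft$samples$is_qc)
}

#' Drop features by id
#' @param ft a `feature_table`.
#' @param ids feature ids to remove.
#' @return the reduced `feature_table`.
#' @export
drop_features <- function(ft, ids) {
  keep <- !(ft$features$feature_id %in% ids)
  ft[keep, ]
}

#' Replace the response matrix, keeping metadata
#' @keywords internal
set_responses <- function(ft, responses) {
  stopifnot(all(dim(responses) == dim(ft$responses)))
  ft$responses <- responses
  rownames(ft$responses) <- ft$features$feature_id
  colnames(ft$responses) <- ft$samples$sample_id
  ft
}
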