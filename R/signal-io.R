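# Reading and writing EEG matrices as delimited text with JSON sidecars.
# Native acquisition formats (BCI2000 .dat, EDF, ...) are out of scope; the
# exchange format is a plain numeric matrix (rows = time samples, columns =
# channels) plus a JSON metadata sidecar.

DEFAULT_EXCLUDED_CHANNELS <- "O2"

#' Construct an EEGRecord
#'
#' Low-level constructor validating the container invariants. Most users
#' will use [readSignal()] or [simulateSubject()] instead.
#'
#' @param data numeric matrix, samples x channels.
#' @param subjectId subject identifier.
#' @param classLabel `"ASD"` or `"NORMAL"`.
#' @param fs sampling rate, Hz.
#' @param channelLabels channel names, one per column.
#' @return an [EEGRecord-class].
#' @export
#' @examples
#' eegRecord(matrix(rnorm(8), 4, 2), "s01", "NORMAL", 256, c("FP1", "F3"))
eegRecord <- function(data, subjectId, classLabel, fs = 256,
                      channelLabels = colnames(data)) {
  if (is.null(channelLabels))
    stop("channelLabels are required (no column names found)")
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  colnames(data) <- channelLabels
  new("EEGRecord", subjectId = as.character(subjectId),
      classLabel = as.character(classLabel), fs = as.numeric(fs),
      channelLabels = as.character(channelLabels), data = data)
}

#' Read an EEG matrix and its metadata
#'
#' Reads a delimited numeric matrix (CSV/TSV, no header by default) plus
#' metadata, either from an explicit `meta` list or from a JSON sidecar file
#' (`<path>.json` by default) with fields `subject_id`, `class_label`, `fs`
#' and `channel_labels`. Non-numeric cells raise a parse error naming the
#' offending row and column; a label/column count mismatch raises a shape
#' error.
#'
#' @param path path to the delimited matrix file.
#' @param meta optional list with entries `subject_id`, `class_label`, `fs`,
#'   `channel_labels`; read from `sidecar` when omitted.
#' @param sidecar path to the JSON sidecar (default `paste0(path, ".json")`).
#' @param sep field separator; `","` for `.csv`, `"\t"` otherwise.
#' @param exclude channels dropped after reading (default none; the
#'   conventional grounding-channel exclusion is `"O2"`, see
#'   [dropChannels()]).
#' @param transpose set `TRUE` if the file stores channels x samples.
#' @return an [EEGRecord-class].
#' @seealso [writeSignal()], [dropChannels()]
#' @export
readSignal <- function(path, meta = NULL, sidecar = paste0(path, ".json"),
                       sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                       exclude = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(meta)) {
    if (!file.exists(sidecar))
      stop("metadata sidecar not found: ", sidecar)
    meta <- jsonlite::fromJSON(sidecar)
  }
  for (f in c("subject_id", "class_label", "fs", "channel_labels"))
    if (is.null(meta[[f]])) stop("metadata field missing: ", f)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  M <- suppressWarnings(matrix(as.numeric(as.matrix(raw)),
                               nrow(raw), ncol(raw)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  if (transpose) M <- t(M)
  labels <- as.character(meta$channel_labels)
  if (ncol(M) != length(labels))
    stop(sprintf(
      "shape error: %d channel labels but %d data columns in %s",
      length(labels), ncol(M), path))
  rec <- eegRecord(M, meta$subject_id, meta$class_label, meta$fs, labels)
  if (!is.null(exclude) && length(exclude)) rec <- dropChannels(rec, exclude)
  rec
}

#' Write an EEG record as delimited text plus a JSON sidecar
#'
#' Values are written at full double precision (round-trip safe through
#' [readSignal()] to ~1e-15 relative). The sidecar carries a
#' `format_version` field.
#'
#' @param rec an [EEGRecord-class].
#' @param path output matrix path (CSV).
#' @param sidecar output sidecar path.
#' @return `path`, invisibly.
#' @export
writeSignal <- function(rec, path, sidecar = paste0(path, ".json")) {
  stopifnot(is(rec, "EEGRecord"))
  utils::write.table(format(rec@data, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(format_version = FORMAT_VERSION,
               subject_id = rec@subjectId,
               class_label = rec@classLabel,
               fs = rec@fs,
               channel_labels = rec@channelLabels)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Drop channels from a record
#'
#' Removes the columns named in `exclude`, preserving the original order of
#' the remaining channels. Unknown labels are ignored with a warning;
#' excluding every channel is an error. The conventional default exclusion
#' in this pipeline is the grounding channel `"O2"`.
#'
#' @param rec an [EEGRecord-class].
#' @param exclude character vector of channel labels to remove.
#' @return the filtered [EEGRecord-class].
#' @export
dropChannels <- function(rec, exclude = DEFAULT_EXCLUDED_CHANNELS) {
  stopifnot(is(rec, "EEGRecord"))
  exclude <- as.character(exclude)
  if (!length(exclude)) return(rec)
  unknown <- setdiff(exclude, rec@channelLabels)
  if (length(unknown))
    warning("ignoring channels not present in record: ",
            paste(unknown, collapse = ", "))
  keep <- !(rec@channelLabels %in% exclude)
  if (!any(keep))
    stop("excluding all channels would leave an empty record")
  if (all(keep)) return(rec)
  eegRecord(rec@data[, keep, drop = FALSE], rec@subjectId, rec@classLabel,
            rec@fs, rec@channelLabels[keep])
}

#' Write a cohort of records to a directory
#'
#' Emits one CSV + JSON sidecar per record and a `manifest.json` listing
#' file paths, subject identifiers, class labels and per-class counts.
#'
#' @param records list of [EEGRecord-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(records, subjectId, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  entries <- lapply(records, function(r) {
    f <- paste0(subjectId(r), ".csv")
    writeSignal(r, file.path(dir, f))
    list(path = f, subject_id = subjectId(r), class_label = classLabel(r))
  })
  counts <- table(vapply(records, classLabel, character(1)))
  manifest <- list(format_version = FORMAT_VERSION,
                   records = entries,
                   class_counts = as.list(counts))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cohort directory or manifest
#'
#' @param path a cohort directory containing `manifest.json`, or the
#'   manifest path itself.
#' @return list of [EEGRecord-class] objects.
#' @export
readCohort <- function(path) {
  mp <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mp)) stop("manifest not found: ", mp)
  man <- jsonlite::fromJSON(mp, simplifyDataFrame = FALSE)
  base <- dirname(mp)
  recs <- lapply(man$records, function(e) {
    f <- file.path(base, e$path)
    if (!file.exists(f)) stop("manifest references missing file: ", f)
    readSignal(f)
  })
  ids <- vapply(recs, subjectId, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in manifest")
  recs
}
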