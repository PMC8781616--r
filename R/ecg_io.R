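#' Construct an ECG record
#'
#' @param samples Numeric vector of voltages (mV), finite.
#' @param fs Sampling rate in Hz (default 360).
#' @param record_id Identifier string.
#' @param annotations Optional data frame with columns `time_s` (seconds,
#'   within the record) and `label` (symptom ID 1--5).
#' @return An object of class `"ecg_record"`.
#' @export
ecg_record <- function(samples, fs = 360, record_id = "", annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty record")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  dur <- length(samples) / fs
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!all(c("time_s", "label") %in% names(annotations)))
      stop("annotations need columns time_s and label")
    annotations$time_s <- as.numeric(annotations$time_s)
    annotations$label <- as.integer(annotations$label)
    check_labels(annotations$label)
    if (any(annotations$time_s < 0 | annotations$time_s > dur))
      stop("annotation times outside [0, duration]")
    annotations <- annotations[order(annotations$time_s), c("time_s", "label"),
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(samples = samples, fs = fs, record_id = as.character(record_id),
                 annotations = annotations),
            class = "ecg_record")
}

check_labels <- function(label) {
  if (any(is.na(label)) || !all(label %in% 1:5))
    stop("symptom labels must be integers in 1..5")
  invisible(label)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples @ %g Hz (%.2f s), %d annotation(s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

record_duration <- function(rec) length(rec$samples) / rec$fs

#' Read an ECG record from disk
#'
#' Reads a plain-text voltage series.  CSV files carry either one column
#' (mV) or two (`time_s,mV`); a header line is detected automatically.
#' `"wfdb-text"` reads whitespace-separated dumps (e.g. `rdsamp -p` output)
#' and takes the second column as the voltage.  If a sidecar annotation
#' file `<stem>.ann.csv` (columns `time_s,label`) exists next to the
#' record, it is loaded automatically.
#'
#' @param path Path to the record file.
#' @param fs Sampling rate in Hz (default 360).
#' @param format `"csv"` or `"wfdb-text"`.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, fs = 360, format = c("csv", "wfdb-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty record")
    toks <- strsplit(first, ",", fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(toks))))
    tab <- utils::read.csv(path, header = header,
                           colClasses = "character", strip.white = TRUE)
    if (nrow(tab) == 0L) stop("empty record")
    num <- suppressWarnings(vapply(tab, as.numeric,
                                   numeric(nrow(tab))))
    num <- matrix(num, nrow = nrow(tab))
    if (any(is.na(num))) stop("non-numeric rows in record ", path)
    mv <- if (ncol(num) >= 2L) num[, 2L] else num[, 1L]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0L) stop("empty record")
    parts <- strsplit(trimws(lines), "\\s+")
    mv <- vapply(parts, function(p) {
      suppressWarnings(as.numeric(p[min(2L, length(p))]))
    }, numeric(1))
    if (any(is.na(mv))) stop("non-numeric rows in record ", path)
  }
  ann <- NULL
  ann_path <- paste0(sub("\\.[^./]*$", "", path), ".ann.csv")
  if (file.exists(ann_path)) ann <- read_annotations(ann_path)
  ecg_record(mv, fs = fs,
             record_id = sub("\\.[^./]*$", "", basename(path)),
             annotations = ann)
}

#' Read an annotation sidecar (time_s,label CSV)
#' @param path Path to a CSV with columns `time_s,label`.
#' @return Data frame with columns `time_s`, `label`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "label") %in% names(tab)))
    stop("annotation file needs columns time_s,label: ", path)
  tab$label <- as.integer(tab$label)
  check_labels(tab$label)
  tab[order(tab$time_s), c("time_s", "label"), drop = FALSE]
}

#' Write an annotation sidecar
#' @param annotations Data frame with `time_s`, `label`.
#' @param path Output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  check_labels(as.integer(annotations$label))
  utils::write.csv(annotations[, c("time_s", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a WFDB-style text annotation dump
#'
#' Maps standard beat/rhythm codes to symptom IDs: beat codes `N` -> 1,
#' `A` -> 2, `V` -> 4; rhythm change markers (`+` with aux `(AFIB` or
#' `(VT`) -> 3 and 5.  Unrecognised codes are dropped.  Expects the usual
#' `rdann -p` column layout: elapsed time, sample number, code, then
#' subtype/chan/num and optional aux.
#'
#' @param path Path to the text dump.
#' @return Data frame with columns `time_s`, `label`.
#' @export
read_wfdb_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(strsplit(trimws(lines), "\\s+"), function(p) {
    if (length(p) < 3L) return(NULL)
    t <- wfdb_time(p[[1]])
    code <- p[[3]]
    lab <- switch(code, N = 1L, A = 2L, V = 4L, `+` = {
      aux <- if (length(p) >= 7L) p[[7]] else ""
      if (grepl("^\\(AFIB", aux)) 3L
      else if (grepl("^\\(VT", aux)) 5L
      else NA_integer_
    }, NA_integer_)
    if (is.na(t) || is.na(lab)) NULL else data.frame(time_s = t, label = lab)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(time_s = numeric(), label = integer())
  else out[order(out$time_s), , drop = FALSE]
}

wfdb_time <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  parts <- suppressWarnings(as.numeric(parts))
  if (any(is.na(parts))) return(NA_real_)
  sum(parts * rev(60 ^ (seq_along(parts) - 1)))
}

#' Construct an analysis frame
#' @param samples Numeric voltages (mV).
#' @param fs Sampling rate (Hz).
#' @param start_s Frame start within the parent record (s).
#' @param label Optional symptom ID 1--5.
#' @return Object of class `"ecg_frame"`.
#' @export
ecg_frame <- function(samples, fs, start_s = 0, label = NA_integer_) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_s = start_s,
                 duration_s = length(samples) / fs,
                 label = as.integer(label)),
            class = "ecg_frame")
}

#' Cut one fixed-length frame around an annotation timestamp
#'
#' The frame is centred on `time_s` and shifted inward (never truncated)
#' when the centre sits within half a frame of a record edge, so the
#' complete symptom waveform stays inside the frame.  Windows are
#' half-open `[start, end)` in seconds.
#'
#' @param rec An [ecg_record()].
#' @param time_s Annotation timestamp (s).
#' @param duration_s Frame length in seconds (default 3).
#' @return An [ecg_frame()]; `label` is copied from a record annotation at
#'   `time_s` when one exists.
#' @export
frame_at_annotation <- function(rec, time_s, duration_s = 3) {
  n <- round(duration_s * rec$fs)
  if (abs(n - duration_s * rec$fs) > 1e-9)
    stop("duration_s * fs must be a whole number of samples")
  if (length(rec$samples) < n)
    stop("record shorter than the requested frame")
  dur <- record_duration(rec)
  start <- min(max(time_s - duration_s / 2, 0), dur - duration_s)
  i0 <- round(start * rec$fs)           # 0-based sample offset
  i0 <- min(max(i0, 0L), length(rec$samples) - n)
  lab <- NA_integer_
  if (!is.null(rec$annotations)) {
    hit <- which(abs(rec$annotations$time_s - time_s) < 0.5 / rec$fs)
    if (length(hit)) lab <- rec$annotations$label[hit[1]]
  }
  ecg_frame(rec$samples[(i0 + 1):(i0 + n)], rec$fs,
            start_s = i0 / rec$fs, label = lab)
}

#' Cut sliding analysis frames over a whole record
#'
#' Frames of `duration_s` seconds start at 0 and advance by
#' `duration_s - overlap_s`; the last frame lies fully inside the record,
#' giving `floor((T - duration) / step) + 1` frames.
#'
#' @inheritParams frame_at_annotation
#' @param overlap_s Overlap between consecutive frames in seconds
#'   (default 1).
#' @return List of [ecg_frame()]s.
#' @export
sliding_frames <- function(rec, duration_s = 3, overlap_s = 1) {
  if (overlap_s < 0 || overlap_s >= duration_s)
    stop("overlap_s must satisfy 0 <= overlap < duration")
  n <- round(duration_s * rec$fs)
  if (length(rec$samples) < n) stop("record shorter than the frame length")
  step <- duration_s - overlap_s
  total <- record_duration(rec)
  count <- floor((total - duration_s) / step + 1e-9) + 1
  lapply(seq_len(count), function(k) {
    start <- (k - 1) * step
    i0 <- round(start * rec$fs)
    ecg_frame(rec$samples[(i0 + 1):(i0 + n)], rec$fs, start_s = i0 / rec$fs)
  })
}

feature_cols <- c("f1_freq", "f1_pow", "f2_freq", "f2_pow",
                  "f3_freq", "f3_pow")

#' Assemble a feature table
#'
#' @param x Matrix or data frame with the six centroid columns
#'   `f1_freq,f1_pow,f2_freq,f2_pow,f3_freq,f3_pow`.
#' @param label Integer symptom IDs (1--5), or NA for unlabeled rows.
#' @return Data frame with the six feature columns and `label`.
#' @export
feature_table <- function(x, label = NA_integer_) {
  x <- as.data.frame(x)
  if (!all(feature_cols %in% names(x))) names(x) <- feature_cols
  x <- x[, feature_cols, drop = FALSE]
  x$label <- as.integer(label)
  ok <- is.na(x$label) | x$label %in% 1:5
  if (!all(ok)) stop("symptom labels must be integers in 1..5")
  x
}

#' Write / read feature tables
#'
#' Features travel as plain CSV with the fixed column set
#' `f1_freq,f1_pow,f2_freq,f2_pow,f3_freq,f3_pow,label`; `read_features`
#' validates the layout and the label range so that write-then-read is an
#' identity up to float-text precision.
#'
#' @param features A feature table (see [feature_table()]).
#' @param path CSV path.
#' @return `read_features` returns the feature table.
#' @export
write_features <- function(features, path) {
  features <- feature_table(features[, feature_cols, drop = FALSE],
                            features$label)
  utils::write.csv(format(features, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path)
  if (!identical(names(tab), c(feature_cols, "label")))
    stop("malformed feature file (expected columns ",
         paste(c(feature_cols, "label"), collapse = ","), "): ", path)
  if (nrow(tab) == 0L)
    return(feature_table(as.data.frame(matrix(numeric(), 0, 6,
             dimnames = list(NULL, feature_cols))), integer()))
  if (any(vapply(tab[feature_cols], function(v) any(is.na(v)), logical(1))))
    stop("non-numeric feature rows in ", path)
  feature_table(tab[feature_cols], tab$label)
}
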