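#' Extract the 6-dimensional centroid feature vector of one frame
#'
#' Runs the full featuring pipeline on one analysis frame: low-pass
#' filter, EMD, Hilbert spectral analysis, marginal Hilbert spectrum of
#' IMF1--IMF3, and the area centroid (frequency, power) of each.  When the
#' decomposition yields fewer than three IMFs the missing centroids are
#' reported as (0, 0) and the result carries attribute
#' `"warn_low_imfs" = TRUE`.  The computation is deterministic.
#'
#' @param frame An [ecg_frame()].
#' @param cfg An [hht_config()].
#' @return One-row [feature_table()] (label copied from the frame).
#' @export
extract_features_frame <- function(frame, cfg = hht_config()) {
  if (stats::sd(frame$samples) == 0) {          # flat line: nothing to analyse
    out <- feature_table(as.data.frame(as.list(stats::setNames(numeric(6),
                                                               feature_cols))),
                         frame$label)
    attr(out, "warn_low_imfs") <- TRUE
    return(out)
  }
  filt <- lowpass_filter(frame, order = cfg$filter_order,
                         cutoff_hz = cfg$cutoff_hz)
  dec <- emd(filt, stop_sd = cfg$stop_sd, max_imfs = cfg$max_imfs,
             max_sifts = cfg$max_sifts)
  vals <- numeric(6)
  warn <- length(dec$imfs) < 3L
  if (length(dec$imfs) > 0L) {
    hs <- hilbert_analysis(dec)
    for (j in seq_len(min(3L, length(dec$imfs)))) {
      ct <- mhs_centroid(marginal_spectrum(hs, j, bin_hz = cfg$bin_hz,
                                           fmax_hz = cfg$fmax_hz,
                                           energy = cfg$energy))
      vals[2 * j - 1] <- ct$freq_hz
      vals[2 * j] <- ct$power
    }
  }
  out <- feature_table(as.data.frame(as.list(stats::setNames(vals,
                                                             feature_cols))),
                       frame$label)
  attr(out, "warn_low_imfs") <- warn
  out
}

#' Extract features for a set of frames
#' @param frames List of [ecg_frame()]s.
#' @param cfg An [hht_config()].
#' @return [feature_table()] with one row per frame; attribute
#'   `"warn_low_imfs"` is a logical vector.
#' @export
extract_features <- function(frames, cfg = hht_config()) {
  rows <- lapply(frames, extract_features_frame, cfg = cfg)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "warn_low_imfs") <-
    vapply(rows, function(r) isTRUE(attr(r, "warn_low_imfs")), logical(1))
  out
}

#' Scan a record with sliding frames and a trained model
#'
#' Cuts 3 s frames with 1 s overlap (by default) over the whole record,
#' extracts the centroid features of each frame and predicts its symptom
#' label, yielding a traceable annotation track.  Frames are labelled
#' independently; an optional majority-vote smoother over each frame and
#' its neighbours can be enabled with `smooth = TRUE`.
#'
#' @param rec An [ecg_record()] of at least `duration_s` seconds.
#' @param model A trained [train_model()] result.
#' @param cfg An [hht_config()].
#' @param duration_s,overlap_s Frame length and overlap in seconds
#'   (defaults 3 and 1).
#' @param smooth Apply the majority-vote smoother (default `FALSE`).
#' @return Object of class `"scan_result"`: list with `record_id`, `track`
#'   (data frame `start_s,end_s,label,model`), `scores` (per-frame class
#'   scores), `model_name`, `config` (snapshot of `cfg` and framing) and
#'   `record`.
#' @export
scan_record <- function(rec, model, cfg = hht_config(),
                        duration_s = 3, overlap_s = 1, smooth = FALSE) {
  if (!inherits(model, "pattern_model")) stop("model must be a pattern_model")
  frames <- sliding_frames(rec, duration_s, overlap_s)
  feats <- extract_features(frames, cfg)
  preds <- predict(model, feats)
  lab <- preds$label
  if (smooth && length(lab) > 2L) {
    lab <- vapply(seq_along(lab), function(i) {
      win <- lab[max(1, i - 1):min(length(lab), i + 1)]
      as.integer(names(which.max(table(win))))
    }, integer(1))
  }
  track <- data.frame(
    start_s = vapply(frames, function(f) f$start_s, numeric(1)),
    end_s = vapply(frames, function(f) f$start_s + f$duration_s, numeric(1)),
    label = lab, model = model$config$method)
  structure(list(record_id = rec$record_id, track = track,
                 scores = preds[, -1, drop = FALSE],
                 model_name = model$config$method,
                 config = list(hht = unclass(cfg), duration_s = duration_s,
                               overlap_s = overlap_s, smooth = smooth,
                               model_seed = model$config$seed),
                 record = rec),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan of '%s' by %s: %d frames\n", x$record_id, x$model_name,
              nrow(x$track)))
  print(table(factor(symptom_names[x$track$label],
                     levels = symptom_names)))
  invisible(x)
}

#' Export a traceable annotation track
#'
#' Writes the per-frame track as CSV (`start_s,end_s,label,model`), and
#' optionally a trace plot of the signal with coloured per-frame label
#' bands.
#'
#' @param result A [scan_record()] result.
#' @param path Output CSV path.
#' @param plot Also write a PNG trace plot (default `FALSE`).
#' @param plot_path PNG path (default: `path` with a `.png` extension).
#' @return Invisibly, the CSV path.
#' @export
export_trace <- function(result, path, plot = FALSE, plot_path = NULL) {
  stopifnot(inherits(result, "scan_result"))
  if (nrow(result$track) == 0L) stop("empty scan result")
  utils::write.csv(result$track, path, row.names = FALSE, quote = FALSE)
  if (plot) {
    if (is.null(plot_path)) plot_path <- paste0(sub("\\.[^./]*$", "", path),
                                                ".png")
    grDevices::png(plot_path, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
    rec <- result$record
    tt <- (seq_along(rec$samples) - 1) / rec$fs
    graphics::plot(tt, rec$samples, type = "l", xlab = "time (s)",
                   ylab = "mV", main = paste(result$record_id, "-",
                                             result$model_name))
    cols <- grDevices::adjustcolor(
      c("grey", "orange", "red", "purple", "blue"), alpha.f = 0.25)
    tr <- result$track
    for (i in seq_len(nrow(tr)))
      graphics::rect(tr$start_s[i], min(rec$samples), tr$end_s[i],
                     max(rec$samples), col = cols[tr$label[i]], border = NA)
  }
  invisible(path)
}

#' Re-read an exported annotation track
#' @param path CSV written by [export_trace()].
#' @return Data frame `start_s,end_s,label,model`.
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path)
  if (!identical(names(tab), c("start_s", "end_s", "label", "model")))
    stop("malformed trace file: ", path)
  check_labels(as.integer(tab$label))
  if (any(tab$end_s <= tab$start_s)) stop("malformed trace: end <= start")
  tab[order(tab$start_s), , drop = FALSE]
}
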