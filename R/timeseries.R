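#' ROI time-series container
#'
#' Bundles a frames-by-ROI signal matrix with its repetition time, subject /
#' session labels and (optionally) the paired six-parameter motion trace.
#'
#' @param signal numeric matrix, frames in rows, ROIs in columns; column
#'   names are ROI ids (generated if absent).
#' @param tr repetition time in seconds.
#' @param subject,session labels carried through the pipeline.
#' @param motion optional frames x 6 motion-parameter matrix: three
#'   translations (mm) then three rotations (radians by convention; see
#'   [compute_fd()] for the degrees switch).
#' @return an object of class `fc_timeseries`.
#' @export
fc_timeseries <- function(signal, tr = 2, subject = "sub-01",
                          session = "ses-1", motion = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stopf("signal must be a finite numeric matrix")
  if (is.null(colnames(signal)))
    colnames(signal) <- sprintf("ROI%03d", seq_len(ncol(signal)))
  if (!is_number(tr) || tr <= 0) stopf("tr must be a positive scalar (seconds)")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L)
      stopf("motion trace must have 6 columns (3 translations, 3 rotations)")
    if (nrow(motion) != nrow(signal))
      stopf("frame-mismatch: motion trace has %d frames, signal has %d (%s %s)",
            nrow(motion), nrow(signal), subject, session)
    if (any(!is.finite(motion))) stopf("motion trace must be finite")
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
  }
  structure(list(signal = signal, tr = tr, subject = subject,
                 session = session, motion = motion),
            class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf("<fc_timeseries> %s %s: %d frames x %d ROIs, TR = %gs%s\n",
              x$subject, x$session, nrow(x$signal), ncol(x$signal), x$tr,
              if (is.null(x$motion)) "" else ", motion trace attached"))
  invisible(x)
}

#' @export
dim.fc_timeseries <- function(x) dim(x$signal)

n_frames <- function(ts) nrow(ts$signal)

#' Read / write ROI time series and motion traces
#'
#' ROI signal files are tab-separated with a header row of ROI ids, one row
#' per frame. Motion files are whitespace-delimited, six columns per frame
#' (translations in mm, then rotations in rad), no header.
#'
#' @param path file path.
#' @param tr,subject,session metadata attached to the returned object.
#' @param motion_path optional motion file read alongside the signal.
#' @return `read_roi_timeseries`: an `fc_timeseries`.
#' @export
read_roi_timeseries <- function(path, tr = 2, subject = "sub-01",
                                session = "ses-1", motion_path = NULL) {
  sig <- as.matrix(utils::read.delim(path, check.names = FALSE))
  motion <- if (!is.null(motion_path)) read_motion(motion_path) else NULL
  fc_timeseries(sig, tr = tr, subject = subject, session = session,
                motion = motion)
}

#' @rdname read_roi_timeseries
#' @param ts an `fc_timeseries`.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.table(ts$signal, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_roi_timeseries
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L)
    stopf("motion file %s has %d columns, expected 6", path, ncol(m))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_roi_timeseries
#' @param motion frames x 6 motion matrix.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# replace the signal (and optionally motion) keeping metadata
ts_replace <- function(ts, signal = ts$signal, motion = ts$motion) {
  fc_timeseries(signal, tr = ts$tr, subject = ts$subject,
                session = ts$session, motion = motion)
}
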