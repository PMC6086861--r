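#' Discard initial volumes
#'
#' Removes the first `n_discard` frames of each acquisition run from the
#' signal and the paired motion trace. Resting-state sessions acquired as
#' several concatenated runs discard the leading frames of every run (the
#' scanner's approach to steady-state magnetization).
#'
#' @param ts an `fc_timeseries`.
#' @param n_discard frames dropped per run (default 5).
#' @param n_runs number of equal-length concatenated runs (default 1).
#' @return the trimmed `fc_timeseries`.
#' @examples
#' ts <- fc_timeseries(matrix(rnorm(246 * 4), 246, 4))
#' nrow(discard_initial_volumes(ts, 5, n_runs = 2)$signal)  # 236
#' @export
discard_initial_volumes <- function(ts, n_discard = 5L, n_runs = 1L) {
  stopifnot(inherits(ts, "fc_timeseries"))
  n <- n_frames(ts)
  if (!is_count(n_discard) || !is_count(n_runs, 1L))
    stopf("n_discard and n_runs must be non-negative integers")
  if (n %% n_runs != 0L)
    stopf("%d frames cannot be split into %d equal runs", n, n_runs)
  per_run <- n %/% n_runs
  if (n_discard >= per_run)
    stopf("cannot discard %d frames from runs of %d", n_discard, per_run)
  if (n_discard == 0L) return(ts)
  drop <- as.vector(outer(seq_len(n_discard), (seq_len(n_runs) - 1L) * per_run, "+"))
  keep <- setdiff(seq_len(n), drop)
  ts_replace(ts, signal = ts$signal[keep, , drop = FALSE],
             motion = if (is.null(ts$motion)) NULL
                      else ts$motion[keep, , drop = FALSE])
}

#' Polynomial detrending and zero-phase band-pass filtering
#'
#' First removes per-ROI polynomial trends of order one and two (including
#' the mean), then applies a zero-phase band-pass. The default filter is an
#' FFT frequency mask (sharp band edges, exactly zero phase); a 4th-order
#' Butterworth applied forward-backward is available via `method`.
#'
#' @param ts an `fc_timeseries` (its `tr` sets the sampling rate).
#' @param low_hz,high_hz pass-band edges in Hz; defaults 0.009 and 0.1,
#'   the conventional resting-state band. Must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param method `"fft"` (default) or `"butterworth"`.
#' @return the filtered `fc_timeseries` (same length as input).
#' @export
bandpass_detrend <- function(ts, low_hz = 0.009, high_hz = 0.1,
                             method = c("fft", "butterworth")) {
  stopifnot(inherits(ts, "fc_timeseries"))
  method <- match.arg(method)
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
          low_hz, high_hz, nyq)
  x <- ts$signal
  n <- nrow(x)
  t <- seq_len(n)
  X <- cbind(1, t, t^2)
  x <- x - X %*% qr.coef(qr(X), x)
  if (method == "fft") {
    freqs <- seq_len(n) - 1L
    freqs <- pmin(freqs, n - freqs) / (n * ts$tr)
    mask <- as.numeric(freqs >= low_hz & freqs <= high_hz)
    x <- Re(stats::mvfft(stats::mvfft(x) * mask, inverse = TRUE)) / n
  } else {
    # 4th-order Butterworth magnitude response applied in the frequency
    # domain, squared (forward-backward equivalent), so the phase is zero
    freqs <- seq_len(n) - 1L
    freqs <- pmin(freqs, n - freqs) / (n * ts$tr)
    hp <- 1 / (1 + (low_hz / pmax(freqs, 1e-12))^8)
    lp <- 1 / (1 + (freqs / high_hz)^8)
    x <- Re(stats::mvfft(stats::mvfft(x) * (hp * lp), inverse = TRUE)) / n
  }
  ts_replace(ts, signal = x)
}

#' Framewise displacement
#'
#' `FD(t) = sum(|delta translations|) + r * sum(|delta rotations|)` with
#' rotations converted to millimetres of arc on a sphere of radius `r`
#' (default 50 mm). `FD(1) = 0` by definition.
#'
#' @param motion frames x 6 matrix (translations mm, then rotations).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @param rotations `"radians"` (default) or `"degrees"`, the unit of the
#'   rotation columns.
#' @return numeric vector of per-frame FD in mm.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.2; m[3, 4] <- 0.004
#' compute_fd(m)[3]  # 0.2 + 50 * 0.004 = 0.4
#' @export
compute_fd <- function(motion, head_radius_mm = 50,
                       rotations = c("radians", "degrees")) {
  motion <- as.matrix(motion)
  rotations <- match.arg(rotations)
  if (nrow(motion) < 2L) stopf("need at least 2 frames")
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotations == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(motion[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot))
  c(0, rowSums(d_trans) + head_radius_mm * rowSums(d_rot))
}

#' DVARS: framewise rate of whole-brain signal change
#'
#' `DVARS(t)` is the root-mean-square over ROIs of the frame-to-frame signal
#' difference, divided by the series' grand mean so that the value is a
#' fractional change (a 0.05 threshold means a 5% whole-brain jump).
#' `DVARS(1) = 0`. Intended for series with a positive baseline (raw or
#' grand-mean-scaled data); for demeaned/filtered data supply `divisor`
#' explicitly.
#'
#' @param ts an `fc_timeseries` or a frames x ROI matrix.
#' @param divisor normalization constant; default the grand mean of the
#'   series, with an error if that is not positive.
#' @return numeric vector of per-frame fractional DVARS.
#' @export
compute_dvars <- function(ts, divisor = NULL) {
  x <- if (inherits(ts, "fc_timeseries")) ts$signal else as.matrix(ts)
  if (nrow(x) < 2L) stopf("need at least 2 frames")
  if (is.null(divisor)) divisor <- mean(x)
  if (!is_number(divisor) || divisor <= 0)
    stopf(paste("grand mean of the series is not positive; DVARS needs",
                "mean-scaled positive signal or an explicit divisor"))
  c(0, sqrt(rowMeans(diff(x)^2))) / divisor
}

#' Motion and signal quality-control report
#'
#' Computes per-frame FD and fractional DVARS, the keep mask at the given
#' thresholds, and summary motion statistics (mean and max absolute
#' displacement, the Euclidean norm of the translation parameters).
#'
#' @param ts an `fc_timeseries` with a motion trace attached.
#' @param fd_thresh,dvars_thresh censoring thresholds (defaults 0.8 mm and
#'   0.05); a frame is flagged when either is exceeded (flag-union).
#' @param head_radius_mm,rotations passed to [compute_fd()].
#' @param dvars_divisor passed to [compute_dvars()].
#' @return an object of class `qc_report`: `fd`, `dvars`, `keep`, `n_kept`,
#'   `mean_abs_disp`, `max_abs_disp`, thresholds, `exclude` flag.
#' @export
compute_qc <- function(ts, fd_thresh = 0.8, dvars_thresh = 0.05,
                       head_radius_mm = 50, rotations = "radians",
                       dvars_divisor = NULL) {
  stopifnot(inherits(ts, "fc_timeseries"))
  if (is.null(ts$motion)) stopf("time series has no motion trace")
  fd <- compute_fd(ts$motion, head_radius_mm, rotations)
  dvars <- compute_dvars(ts, divisor = dvars_divisor)
  keep <- !(fd > fd_thresh | dvars > dvars_thresh)
  disp <- sqrt(rowSums(ts$motion[, 1:3, drop = FALSE]^2))
  structure(list(fd = fd, dvars = dvars, keep = keep,
                 n_kept = sum(keep),
                 mean_abs_disp = mean(disp), max_abs_disp = max(disp),
                 fd_thresh = fd_thresh, dvars_thresh = dvars_thresh,
                 exclude = FALSE, subject = ts$subject, session = ts$session),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %s %s: %d/%d frames kept ",
                     "(FD > %g | DVARS > %g), mean disp %.2f mm%s\n"),
              x$subject, x$session, x$n_kept, length(x$keep),
              x$fd_thresh, x$dvars_thresh, x$mean_abs_disp,
              if (x$exclude) " [FLAGGED FOR EXCLUSION]" else ""))
  invisible(x)
}

#' Interpolate over censored frames
#'
#' Replaces flagged frames by linear interpolation between the nearest
#' surviving frames (constant extension at the series ends), per ROI. Used
#' before temporal filtering so transient motion artifacts cannot ring
#' through the filter into neighbouring frames; the flagged frames are
#' still removed after filtering.
#'
#' @param ts an `fc_timeseries`.
#' @param bad_frames integer indices of flagged frames.
#' @return the `fc_timeseries` with interpolated signal.
#' @export
interpolate_censored <- function(ts, bad_frames) {
  stopifnot(inherits(ts, "fc_timeseries"))
  if (!length(bad_frames)) return(ts)
  n <- n_frames(ts)
  good <- setdiff(seq_len(n), bad_frames)
  if (length(good) < 2L) stopf("fewer than 2 surviving frames to interpolate from")
  sig <- apply(ts$signal, 2L, function(col)
    stats::approx(good, col[good], xout = seq_len(n), rule = 2)$y)
  ts_replace(ts, signal = sig)
}

#' Motion scrubbing
#'
#' Censors every frame whose FD or fractional DVARS exceeds its threshold
#' (flag-union; switch to requiring both via `rule = "intersection"`).
#' Optionally also censors frames adjacent to flagged ones. The returned
#' QC report carries the retained frames' original FD/DVARS values, all of
#' which are below threshold, so scrubbing is idempotent. If fewer than
#' `min_frames` frames survive, the report's `exclude` flag is set and a
#' condition of class `rsfcnet_low_frames` is signalled as a warning —
#' distinct from a hard error, so cohort drivers can drop the subject.
#'
#' @param ts an `fc_timeseries`.
#' @param qc its `qc_report` (recomputed via [compute_qc()] if `NULL`).
#' @param fd_thresh,dvars_thresh censoring thresholds.
#' @param rule `"union"` (either exceeds, default) or `"intersection"`.
#' @param augment if `TRUE`, also censor 1 frame back and 2 forward of each
#'   flagged frame (off by default).
#' @param min_frames minimum surviving frames before the subject is flagged
#'   for exclusion (default 100).
#' @return list with elements `ts` (censored series) and `qc` (updated
#'   report, `n_kept` matching the returned series).
#' @export
scrub <- function(ts, qc = NULL, fd_thresh = 0.8, dvars_thresh = 0.05,
                  rule = c("union", "intersection"), augment = FALSE,
                  min_frames = 100L) {
  stopifnot(inherits(ts, "fc_timeseries"))
  rule <- match.arg(rule)
  if (is.null(qc)) qc <- compute_qc(ts, fd_thresh, dvars_thresh)
  fd_bad <- qc$fd > fd_thresh
  dv_bad <- qc$dvars > dvars_thresh
  bad <- if (rule == "union") fd_bad | dv_bad else fd_bad & dv_bad
  if (augment && any(bad)) {
    idx <- which(bad)
    idx <- unique(pmin(pmax(c(idx - 1L, idx, idx + 1L, idx + 2L), 1L),
                       length(bad)))
    bad[idx] <- TRUE
  }
  keep <- which(!bad)
  out <- ts_replace(ts, signal = ts$signal[keep, , drop = FALSE],
                    motion = if (is.null(ts$motion)) NULL
                             else ts$motion[keep, , drop = FALSE])
  qc2 <- qc
  qc2$fd <- qc$fd[keep]
  qc2$dvars <- qc$dvars[keep]
  qc2$keep <- rep(TRUE, length(keep))
  qc2$n_kept <- length(keep)
  if (length(keep) < min_frames) {
    qc2$exclude <- TRUE
    warning(structure(class = c("rsfcnet_low_frames", "warning", "condition"),
                      list(message = sprintf(
                        "%s %s: only %d frames survive scrubbing (min %d); flagged for exclusion",
                        ts$subject, ts$session, length(keep), min_frames),
                        call = NULL)))
  }
  list(ts = out, qc = qc2)
}

#' Write a QC report
#'
#' Per-frame table as TSV plus a JSON summary.
#' @param qc a `qc_report`.
#' @param stem output path stem (writes `<stem>_qc.tsv`, `<stem>_qc.json`).
#' @return `stem`, invisibly.
#' @export
write_qc_report <- function(qc, stem) {
  utils::write.table(
    data.frame(frame = seq_along(qc$fd), fd = qc$fd, dvars = qc$dvars,
               keep = qc$keep),
    paste0(stem, "_qc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subject = qc$subject, session = qc$session, n_kept = qc$n_kept,
         n_frames = length(qc$keep), mean_abs_disp = qc$mean_abs_disp,
         max_abs_disp = qc$max_abs_disp, fd_thresh = qc$fd_thresh,
         dvars_thresh = qc$dvars_thresh, exclude = qc$exclude),
    paste0(stem, "_qc.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
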