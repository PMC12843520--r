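#' Construct a continuous multichannel EEG recording
#'
#' The unit the generator emits and the preprocessing stage consumes: one
#' subject's continuous voltage matrix plus video-onset events.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param channels Character vector of unique channel labels (10-20 names
#'   plus optionally "EOG").
#' @param fs Sampling rate in Hz (> 0).
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param events Data frame with columns `video_id`, `onset_sample`
#'   (0-based sample index of the video onset) and `duration` (seconds).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, channels, fs, data, events) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  data <- as.matrix(data)
  if (nrow(data) != length(channels)) {
    stop("data must have one row per channel", call. = FALSE)
  }
  rownames(data) <- channels
  events <- as.data.frame(events)
  stopifnot(all(c("video_id", "onset_sample", "duration") %in% names(events)))
  n <- ncol(data)
  if (nrow(events)) {
    end_sample <- events$onset_sample + round(events$duration * fs)
    end_sample[is.na(end_sample)] <- 0
    if (any(end_sample > n)) {
      stop("event extends past end of recording: video ",
           events$video_id[which.max(end_sample)], call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), channels = channels,
                 fs = fs, data = data, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples (%.1f s at %g Hz), %d events\n",
              x$subject_id, length(x$channels), ncol(x$data),
              ncol(x$data) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

#' Construct a single subject-by-video epoch
#'
#' Time 0 is the video onset; the epoch spans `[-baseline, duration)` in
#' half-open sample convention, so the onset sample belongs to the epoch
#' and not to the baseline.
#'
#' @param subject_id,video_id Identifiers.
#' @param fs Sampling rate, Hz.
#' @param data Channels x samples matrix (microvolts) including the
#'   pre-stimulus baseline.
#' @param channels Channel labels (rows of `data`).
#' @param baseline Pre-stimulus span in seconds (>= 0.2 by convention).
#' @param bad_channels Labels flagged as bad (subset of `channels`).
#' @param cleaned Logical: has artifact cleanup been applied?
#'
#' @return An object of class `video_epoch`. Sample `i` (0-based) is at
#'   time `i / fs - baseline` seconds.
#' @export
video_epoch <- function(subject_id, video_id, fs, data, channels,
                        baseline = 0.2, bad_channels = character(),
                        cleaned = FALSE) {
  data <- as.matrix(data)
  if (nrow(data) != length(channels)) {
    stop("data must have one row per channel", call. = FALSE)
  }
  if (!all(bad_channels %in% channels)) {
    stop("bad_channels must be a subset of channels", call. = FALSE)
  }
  rownames(data) <- channels
  structure(list(subject_id = as.character(subject_id),
                 video_id = as.character(video_id), fs = fs, data = data,
                 channels = channels, baseline = baseline,
                 bad_channels = bad_channels, cleaned = cleaned),
            class = "video_epoch")
}

#' @export
print.video_epoch <- function(x, ...) {
  cat(sprintf("<video_epoch> subject %s, video %s: %d ch x %d samples, baseline %.2g s%s%s\n",
              x$subject_id, x$video_id, length(x$channels), ncol(x$data),
              x$baseline, if (x$cleaned) ", cleaned" else "",
              if (length(x$bad_channels)) {
                paste0(", bads: ", paste(x$bad_channels, collapse = ","))
              } else ""))
  invisible(x)
}

#' Time axis of an epoch
#'
#' Sample times in seconds relative to video onset (negative during the
#' pre-stimulus baseline).
#'
#' @param epoch A [video_epoch()].
#' @return Numeric vector, one time per sample.
#' @export
epoch_times <- function(epoch) {
  (seq_len(ncol(epoch$data)) - 1) / epoch$fs - epoch$baseline
}

# Duration of the post-onset part of an epoch, seconds.
epoch_duration <- function(epoch) {
  ncol(epoch$data) / epoch$fs - epoch$baseline
}
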