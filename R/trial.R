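#' Validate a source trial against an atlas
#'
#' Checks array shape (ROIs x 3 x samples), ROI labels against the atlas,
#' finiteness of every sample, and a minimum duration of 10 s.  Returns the
#' trial unchanged when all checks pass.
#'
#' @param trial A `source_trial`.
#' @param atlas Atlas for one brain (26 rows by default).
#' @return The validated trial.
#' @export
validate_trial <- function(trial, atlas = roi_atlas("J1")) {
  stopifnot(inherits(trial, "source_trial"))
  d <- dim(trial$data)
  if (length(d) != 3 || d[2] != 3)
    stop("trial data must be an ROI x 3 x samples array")
  if (d[1] != nrow(atlas))
    stop(sprintf("trial has %d ROIs but the atlas defines %d", d[1],
                 nrow(atlas)))
  if (!is.null(trial$roi_labels) && all(grepl("_", trial$roi_labels))) {
    want <- sub("^J[12]_", "", atlas$node)
    have <- sub("^J[12]_", "", trial$roi_labels)
    if (!identical(want, have))
      stop("trial ROI labels do not match the atlas")
  }
  if (!all(is.finite(trial$data)))
    stop("trial contains non-finite samples")
  if (d[3] / trial$sampling_rate < 10 - 1e-9)
    stop("trial shorter than 10 s (unsuccessful trial)")
  trial
}

#' Trim a trial to its central interval
#'
#' Retains the central `target_duration` seconds, dropping equal amounts
#' from both ends (a 20 s trial loses its first and last 5 s, so the first
#' retained sample is index 5121 with 1-based indexing at 1024 Hz).
#' Trimming is idempotent: a trial already at the target length is returned
#' unchanged.
#'
#' @param trial A `source_trial`.
#' @param target_duration Seconds to keep (default 10).
#' @return The trimmed trial.
#' @export
trim_trial <- function(trial, target_duration = 10) {
  stopifnot(inherits(trial, "source_trial"))
  fs <- trial$sampling_rate
  n <- dim(trial$data)[3]
  keep <- round(target_duration * fs)
  if (n < keep)
    stop("trial shorter than the target duration; exclude it")
  if (n == keep) return(trial)
  start <- floor((n - keep) / 2) + 1L
  trial$data <- trial$data[, , start:(start + keep - 1L), drop = FALSE]
  trial
}

#' Segment a trimmed trial into analysis windows
#'
#' Cuts the trial into the maximal set of equal-length windows of
#' `window` seconds starting at multiples of `step` seconds from the trial
#' start: `floor((D - w) / s) + 1` windows.  With the defaults (2 s windows,
#' 1 s step) a 10 s trial yields exactly 9 windows covering the full trial.
#'
#' @param trial A `source_trial` (already trimmed).
#' @param window Window length in seconds; must be a whole number of
#'   samples.
#' @param step Step between window starts in seconds; must be positive and
#'   a whole number of samples.
#' @return A `segment_set`: list with `windows` (list of ROI x 3 x w
#'   arrays), `window`, `step`, `sampling_rate`.
#' @export
segment_trial <- function(trial, window = 2, step = 1) {
  stopifnot(inherits(trial, "source_trial"))
  fs <- trial$sampling_rate
  if (step <= 0) stop("step must be positive")
  w <- window * fs
  s <- step * fs
  if (abs(w - round(w)) > 1e-9)
    stop("window is not a whole number of samples")
  if (abs(s - round(s)) > 1e-9)
    stop("step is not a whole number of samples")
  w <- as.integer(round(w)); s <- as.integer(round(s))
  n <- dim(trial$data)[3]
  if (w > n) stop("window longer than the trial")
  starts <- seq(1L, n - w + 1L, by = s)
  windows <- lapply(starts, function(i)
    trial$data[, , i:(i + w - 1L), drop = FALSE])
  structure(list(windows = windows, window = window, step = step,
                 sampling_rate = fs, roi_labels = trial$roi_labels),
            class = "segment_set")
}
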