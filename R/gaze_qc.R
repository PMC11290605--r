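# Eye-tracking quality control: velocity-based fixation detection and the
# Fujii 2/4 fixation-stability grading used to exclude participants who
# failed to hold central fixation during encoding.

#' Detect fixations in a gaze stream by velocity thresholding
#'
#' Velocities are estimated per axis with symmetric differences
#' (`(p[i+1] - p[i-1]) / (t[i+1] - t[i-1])`), and a sample counts as
#' saccadic when its velocity exceeds an elliptic threshold
#' `(vx/(lambda*sx))^2 + (vy/(lambda*sy))^2 > 1`, where `sx`, `sy` are
#' median-based robust dispersion estimates
#' `sqrt(median(v^2) - median(v)^2)` — the classic velocity-threshold
#' (micro)saccade detector. Maximal runs of non-saccadic samples become
#' fixations with centroid coordinates; fixations shorter than `min_dur`
#' (100 ms by default) are discarded.
#'
#' @param stream `data.frame` with columns `t_ms` (strictly increasing
#'   milliseconds), `x_deg`, `y_deg` (degrees of visual angle).
#' @param lambda velocity-threshold multiplier (default 6).
#' @param min_dur minimum fixation duration in ms (default 100).
#' @return A `data.frame` of fixations: `onset`, `offset`, `cx`, `cy`,
#'   `duration` (ms). Zero rows when the stream is all saccade.
#' @export
detect_fixations <- function(stream, lambda = 6, min_dur = 100) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg") %in% names(stream)))
  n <- nrow(stream)
  if (n < 3L) stop("need at least 3 gaze samples")
  t <- stream$t_ms
  if (any(diff(t) <= 0)) stop("gaze timestamps must be strictly increasing")
  x <- stream$x_deg; y <- stream$y_deg

  idx <- 2:(n - 1L)
  dt <- t[idx + 1L] - t[idx - 1L]
  vx <- (x[idx + 1L] - x[idx - 1L]) / dt
  vy <- (y[idx + 1L] - y[idx - 1L]) / dt
  robust_sd <- function(v) {
    s <- sqrt(stats::median(v^2) - stats::median(v)^2)
    if (!is.finite(s) || s < 1e-9) s <- 1e-9
    s
  }
  sx <- robust_sd(vx); sy <- robust_sd(vy)
  saccadic <- (vx / (lambda * sx))^2 + (vy / (lambda * sy))^2 > 1
  # endpoints inherit the state of their neighbor
  saccadic <- c(saccadic[1L], saccadic, saccadic[length(saccadic)])

  runs <- rle(!saccadic)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fix <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r]
    if (i1 <= i0) next
    dur <- t[i1] - t[i0]
    if (dur < min_dur) next
    fix[[length(fix) + 1L]] <- data.frame(
      onset = t[i0], offset = t[i1],
      cx = mean(x[i0:i1]), cy = mean(y[i0:i1]), duration = dur)
  }
  if (length(fix) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      cx = numeric(0), cy = numeric(0),
                      duration = numeric(0)))
  }
  do.call(rbind, fix)
}

#' Fujii 2/4 fixation-stability classification
#'
#' Grades fixation stability from the percentage of fixation centroids
#' within 2 and 4 degrees of the fixation target: `stable` when >= 75% lie
#' within 2 degrees; `relatively_unstable` when not, but >= 75% lie within
#' 4 degrees; `unstable` when fewer than 75% lie within 4 degrees.
#' Participants grading `unstable` are excluded — the exclusion decision
#' depends only on the 4-degree percentage. Distances exactly equal to the
#' radius count as inside, and exactly 75% counts as meeting the criterion
#' ("less than 75%" excludes strictly below).
#'
#' @param fixations a `data.frame` from [detect_fixations()] (columns `cx`,
#'   `cy`); >= 1 fixation required.
#' @param center fixation-target coordinates in degrees, default `c(0, 0)`.
#' @return A list of class `stability_report`: `pct_within_2deg`,
#'   `pct_within_4deg`, `category`, `excluded`, `n_fixations`.
#' @export
fujii_classify <- function(fixations, center = c(0, 0)) {
  if (nrow(fixations) == 0L) stop("cannot assess stability without fixations")
  d <- sqrt((fixations$cx - center[1L])^2 + (fixations$cy - center[2L])^2)
  pct2 <- 100 * mean(d <= 2)
  pct4 <- 100 * mean(d <= 4)
  category <- if (pct2 >= 75) "stable"
  else if (pct4 >= 75) "relatively_unstable"
  else "unstable"
  structure(list(pct_within_2deg = pct2, pct_within_4deg = pct4,
                 category = category, excluded = pct4 < 75,
                 n_fixations = nrow(fixations)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Fixation stability: %s (%.1f%% within 2 deg, %.1f%% within 4 deg)%s\n",
              x$category, x$pct_within_2deg, x$pct_within_4deg,
              if (x$excluded) " -> EXCLUDED" else ""))
  invisible(x)
}

#' Read a gaze-sample CSV
#'
#' Columns: `participant_id, block, t_ms, x_deg, y_deg`.
#'
#' @param path path to the gaze CSV.
#' @return A `data.frame` of gaze samples.
#' @export
read_gaze <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("participant_id", "block", "t_ms", "x_deg", "y_deg")
  if (!identical(names(df), expected)) {
    stop("unexpected gaze CSV header: ", paste(names(df), collapse = ","))
  }
  df
}

#' Per-participant gaze QC over a multi-participant gaze log
#'
#' Detects fixations per participant per block, pools centroids across
#' blocks (stability is assessed over all encoding phases), and applies the
#' Fujii classification.
#'
#' @param gaze gaze samples (as from [read_gaze()]).
#' @param center fixation-target coordinates.
#' @param lambda,min_dur passed to [detect_fixations()].
#' @return A `data.frame`: participant_id, n_fixations, pct_2deg, pct_4deg,
#'   category, excluded.
#' @export
gaze_qc_report <- function(gaze, center = c(0, 0), lambda = 6, min_dur = 100) {
  ids <- unique(gaze$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- gaze[gaze$participant_id == id, , drop = FALSE]
    fixations <- do.call(rbind, lapply(unique(sub$block), function(b) {
      detect_fixations(sub[sub$block == b, , drop = FALSE],
                       lambda = lambda, min_dur = min_dur)
    }))
    rep <- fujii_classify(fixations, center = center)
    data.frame(participant_id = id, n_fixations = rep$n_fixations,
               pct_2deg = rep$pct_within_2deg, pct_4deg = rep$pct_within_4deg,
               category = rep$category, excluded = rep$excluded)
  })
  do.call(rbind, rows)
}
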