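#' Define a chamber line for kymograph analysis
#'
#' Cardiac-function readouts are semi-automatic: the user places a line
#' across the atrium or the ventricle and all metrics derive from the
#' kymograph sampled along it.
#'
#' @param p1,p2 numeric(2) endpoints `(x, y)` in pixels.
#' @param chamber `"ventricle"` or `"atrium"`.
#' @return an object of class `chamber_line`.
#' @export
chamber_line <- function(p1, p2, chamber = c("ventricle", "atrium")) {
  chamber <- match.arg(chamber)
  stopifnot(length(p1) == 2, length(p2) == 2)
  len <- sqrt(sum((p2 - p1)^2))
  if (len < 8) stop("chamber line must be at least 8 px long")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 chamber = chamber, length = len),
            class = "chamber_line")
}

#' Build a space x time kymograph along a chamber line
#'
#' Samples every video frame along the line by bilinear interpolation at
#' (approximately) unit-pixel spacing: `S = ceiling(L) + 1` samples for a
#' line of length `L`. Column `t` of the matrix is frame `t`; wall motion
#' appears as oscillating band edges.
#'
#' @param video a [video_stack()] (or a bare `Y x X x T` array with
#'   `frame_rate_fps`/`pixel_size_um` attributes supplied by the caller).
#' @param line a [chamber_line()]; must lie inside the frame bounds.
#' @return object of class `kymograph`: list with `matrix` (S x T),
#'   `sample_spacing_px`, `frame_interval_s`, `pixel_size_um`, `chamber`.
#' @export
build_kymograph <- function(video, line) {
  stopifnot(inherits(video, "video_stack"), inherits(line, "chamber_line"))
  frames <- video$frames
  d <- dim(frames)
  if (d[3] < 2) stop("kymograph needs at least 2 frames")
  S <- ceiling(line$length) + 1
  tt <- seq(0, 1, length.out = S)
  xs <- line$p1[1] + tt * (line$p2[1] - line$p1[1])
  ys <- line$p1[2] + tt * (line$p2[2] - line$p1[2])
  if (any(xs < 1) || any(xs > d[2]) || any(ys < 1) || any(ys > d[1]))
    stop("chamber line exits the frame bounds")
  x0 <- pmin(floor(xs), d[2] - 1); y0 <- pmin(floor(ys), d[1] - 1)
  fx <- xs - x0; fy <- ys - y0
  # linear indices of the 4 neighbours for all samples at once
  i00 <- (x0 - 1) * d[1] + y0
  i01 <- i00 + d[1]       # x0+1
  i10 <- i00 + 1          # y0+1
  i11 <- i01 + 1
  w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
  w10 <- (1 - fx) * fy;       w11 <- fx * fy
  per_frame <- prod(d[1:2])
  fmat <- matrix(frames, per_frame, d[3])
  kymo <- w00 * fmat[i00, , drop = FALSE] + w01 * fmat[i01, , drop = FALSE] +
    w10 * fmat[i10, , drop = FALSE] + w11 * fmat[i11, , drop = FALSE]
  structure(list(matrix = kymo,
                 sample_spacing_px = line$length / (S - 1),
                 frame_interval_s = 1 / video$frame_rate_fps,
                 pixel_size_um = video$pixel_size_um,
                 chamber = line$chamber),
            class = "kymograph")
}

#' Chamber diameter trace from a kymograph
#'
#' Wall detection by outermost above-threshold extent: per frame (column),
#' the diameter is the distance between the first and last sample above the
#' threshold (the edges of the fluorescent myocardium), 0 when no sample
#' exceeds it. A 3-frame running median suppresses single-frame dropouts.
#'
#' @param kymo a [build_kymograph()] result.
#' @param threshold intensity threshold (> background) in the kymograph's
#'   intensity units.
#' @return numeric vector of per-frame diameters in px.
#' @export
extract_diameter_trace <- function(kymo, threshold) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  diam <- vapply(seq_len(ncol(m)), function(j) {
    above <- which(m[, j] > threshold)
    if (length(above) < 2) return(0)
    (max(above) - min(above)) * kymo$sample_spacing_px
  }, numeric(1))
  if (length(diam) >= 3) as.numeric(runmed(diam, 3)) else diam
}

# topographic prominence of local maxima: height above the higher of the two
# lowest saddles separating the peak from higher ground
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) {
      if (max(higher_l) + 1 <= p - 1) min(left[(max(higher_l) + 1):(p - 1)])
      else h
    } else min(c(left, h))
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) {
      if (min(higher_r) > 1) min(right[seq_len(min(higher_r) - 1)]) else h
    } else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect heart beats in a diameter trace
#'
#' Beats are the diastolic peaks of the (mean-subtracted) diameter trace.
#' The dominant beat period is estimated from the first off-zero maximum of
#' the autocorrelation; peaks must have topographic prominence of at least
#' 25% of the trace amplitude and be separated by at least 0.4 of that
#' period, which tolerates mild arrhythmia. With `n` beats the rate is
#' `60 * (n - 1) / (time between first and last peak)`; fewer than 2 beats
#' give `bpm = NA`.
#'
#' @param trace per-frame diameter (or any periodic cardiac signal).
#' @param frame_rate_fps sampling rate, frames/s.
#' @return list with `peak_times_s`, `n_beats`, `bpm`.
#' @export
detect_beats <- function(trace, frame_rate_fps) {
  stopifnot(length(trace) >= 2, frame_rate_fps > 0)
  amp <- diff(range(trace))
  if (amp == 0)
    return(list(peak_times_s = numeric(0), n_beats = 0L, bpm = NA_real_))
  x <- trace - mean(trace)
  ac <- as.numeric(acf(x, lag.max = length(x) - 2, plot = FALSE,
                       demean = FALSE)$acf)
  period <- NA_real_
  if (length(ac) >= 3) {
    inner <- 2:(length(ac) - 1)
    lmax <- inner[ac[inner] > ac[inner - 1] & ac[inner] >= ac[inner + 1]]
    if (length(lmax)) period <- lmax[1] - 1
  }
  if (is.na(period)) period <- length(x) / 3
  min_sep <- max(1, round(0.4 * period))
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0)
    return(list(peak_times_s = numeric(0), n_beats = 0L, bpm = NA_real_))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= 0.25 * amp]
  if (length(cand) == 0)
    return(list(peak_times_s = numeric(0), n_beats = 0L, bpm = NA_real_))
  # greedy selection by height, enforcing the minimum separation
  kept <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(p - kept) >= min_sep)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  times <- (kept - 1) / frame_rate_fps
  bpm <- if (length(kept) >= 2)
    60 * (length(kept) - 1) / (times[length(times)] - times[1]) else NA_real_
  list(peak_times_s = times, n_beats = length(kept), bpm = bpm)
}

#' Cardiac-function metrics from a diameter trace
#'
#' Derives the standard readout set from a chamber diameter trace and its
#' detected beats: maximal/minimal diameter (robust 98th/2nd percentiles,
#' converted to um), ejection fraction from the squared diameter ratio
#' `EF = (dmax^2 - dmin^2) / dmax^2` (a single-plane approximation),
#' individual beat lengths, and the contraction interval ("QT phase"): the
#' per-beat time from contraction onset (trace falls below 90% of the local
#' diastolic diameter) to relaxation end (returns above 90%), with a linear
#' rate correction `qtc = qt + slope * (1 - RR)` (Framingham-style,
#' default slope 0.154, RR in seconds).
#'
#' @param trace per-frame diameter, px.
#' @param beats result of [detect_beats()] on the same trace.
#' @param frame_rate_fps sampling rate, frames/s.
#' @param pixel_size_um pixel size for diameter conversion.
#' @param qtc_slope slope of the linear rate correction.
#' @return object of class `cardiac_metrics`: list with `bpm`, `d_max_um`,
#'   `d_min_um`, `ejection_fraction`, `beat_lengths_s`,
#'   `mean_beat_length_s`, `qt_s`, `qtc_s`. Interval fields are `NA` with
#'   fewer than 2 beats; diameters are always reported.
#' @export
beat_metrics <- function(trace, beats, frame_rate_fps, pixel_size_um = 1,
                         qtc_slope = 0.154) {
  d_max <- as.numeric(quantile(trace, 0.98)) * pixel_size_um
  d_min <- as.numeric(quantile(trace, 0.02)) * pixel_size_um
  ef <- if (d_max > 0) (d_max^2 - d_min^2) / d_max^2 else 0
  res <- list(bpm = beats$bpm, d_max_um = d_max, d_min_um = d_min,
              ejection_fraction = ef, beat_lengths_s = NA_real_,
              mean_beat_length_s = NA_real_, qt_s = NA_real_,
              qtc_s = NA_real_)
  peaks <- round(beats$peak_times_s * frame_rate_fps) + 1L
  if (length(peaks) >= 2) {
    res$beat_lengths_s <- diff(beats$peak_times_s)
    res$mean_beat_length_s <- mean(res$beat_lengths_s)
    qts <- numeric(0)
    for (i in seq_len(length(peaks) - 1)) {
      seg <- trace[peaks[i]:peaks[i + 1]]
      ref <- 0.9 * trace[peaks[i]]
      onset <- which(seg < ref)[1]
      if (is.na(onset)) next
      back <- which(seg[-seq_len(onset)] >= ref)[1]
      if (is.na(back)) next
      qts <- c(qts, back / frame_rate_fps)
    }
    if (length(qts)) {
      res$qt_s <- mean(qts)
      res$qtc_s <- res$qt_s + qtc_slope * (1 - res$mean_beat_length_s)
    }
  }
  structure(res, class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat(sprintf("<cardiac_metrics> bpm %.1f, EF %.3f, d %.1f-%.1f um, beat %.3f s, QTc %.3f s\n",
              x$bpm, x$ejection_fraction, x$d_min_um, x$d_max_um,
              x$mean_beat_length_s, x$qtc_s))
  invisible(x)
}

#' Full cardiac-function analysis of one video
#'
#' Rescales the video to the 8-bit-equivalent range, builds a kymograph per
#' chamber line, extracts the diameter trace (threshold defaulting to an
#' Otsu split of the kymograph itself), detects beats and computes
#' [beat_metrics()]. Chambers are analyzed independently.
#'
#' @param video a [video_stack()].
#' @param lines list of [chamber_line()]s.
#' @param threshold intensity threshold on the 8-bit-equivalent scale;
#'   `NULL` for an automatic per-kymograph Otsu split.
#' @return data.frame with one row per chamber: `chamber, bpm,
#'   ejection_fraction, mean_beat_length_s, qt_s, qtc_s, d_max_um, d_min_um,
#'   n_beats`.
#' @export
analyze_cardiac_function <- function(video, lines, threshold = NULL) {
  stopifnot(inherits(video, "video_stack"))
  if (inherits(lines, "chamber_line")) lines <- list(lines)
  v8 <- video
  v8$frames <- rescale_to_8bit(video$frames)
  rows <- lapply(lines, function(ln) {
    kymo <- build_kymograph(v8, ln)
    thr <- threshold
    if (is.null(thr)) thr <- otsu_split(kymo$matrix)
    trace <- extract_diameter_trace(kymo, thr)
    beats <- detect_beats(trace, video$frame_rate_fps)
    m <- beat_metrics(trace, beats, video$frame_rate_fps,
                      video$pixel_size_um)
    data.frame(chamber = ln$chamber, bpm = m$bpm,
               ejection_fraction = m$ejection_fraction,
               mean_beat_length_s = m$mean_beat_length_s,
               qt_s = m$qt_s, qtc_s = m$qtc_s,
               d_max_um = m$d_max_um, d_min_um = m$d_min_um,
               n_beats = beats$n_beats, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
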