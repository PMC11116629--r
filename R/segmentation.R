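#' @title Ventricle segmentation at systole
#' @description Implements the measurement protocol: duplicate the systole
#'   frame, convert to an 8-bit-equivalent scale, smooth with a Gaussian
#'   (sigma = 2 px), threshold at a value calibrated on negative-control
#'   larvae, keep only the ventricular connected component (discarding bulbus
#'   arteriosus signal and autofluorescent distractors) and report the area
#'   in px and um^2.
#' @name segmentation
NULL

# min-max rescale of a whole video to the 8-bit-equivalent range [0, 255];
# constant input maps to all zeros (callers decide whether that is an error)
rescale_to_8bit <- function(frames) {
  lo <- min(frames); hi <- max(frames)
  if (hi == lo) return(array(0, dim(frames)))
  round(255 * (frames - lo) / (hi - lo))
}

# separable truncated-Gaussian smoothing via banded matrix multiply; the
# kernel is renormalized at the borders. Works on a matrix or a Y x X x T
# stack (each frame smoothed independently).
smooth_gaussian <- function(x, sigma = 2) {
  if (sigma <= 0) return(x)
  band <- function(n) {
    r <- seq_len(n)
    K <- outer(r, r, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
    K / rowSums(K)
  }
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  Ky <- band(d[1]); Kx <- band(d[2])
  y <- Ky %*% matrix(x, d[1], d[2] * d[3])
  dim(y) <- d
  y <- aperm(y, c(2, 1, 3))
  y <- Kx %*% matrix(y, d[2], d[1] * d[3])
  dim(y) <- c(d[2], d[1], d[3])
  y <- aperm(y, c(2, 1, 3))
  if (d[3] == 1L) y[, , 1] else y
}

# exhaustive two-class histogram split maximizing between-class variance
# (Otsu's criterion) on the 8-bit scale; returns the threshold t such that
# foreground is `values > t`
otsu_split <- function(values) {
  h <- tabulate(pmin(pmax(round(values), 0), 255) + 1, nbins = 256)
  p <- h / sum(h)
  lv <- 0:255
  mu_total <- sum(lv * p)
  w0 <- cumsum(p)
  mu0 <- cumsum(lv * p)
  between <- (mu_total * w0 - mu0)^2 / (w0 * (1 - w0))
  between[w0 == 0 | w0 >= 1] <- -Inf
  lv[which.max(between)]
}

# per-frame size of the largest connected component of `bin` (Y x X x T)
largest_component_trace <- function(bin) {
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  if (length(dim(labels)) == 2L) labels <- array(labels, c(dim(labels), 1L))
  vapply(seq_len(dim(labels)[3]), function(k) {
    tb <- tabulate(as.integer(labels[, , k]))
    if (length(tb)) max(tb) else 0L
  }, integer(1))
}

#' Calibrate a segmentation threshold from negative-control videos
#'
#' Thresholds are determined from the fluorescence levels of control larvae
#' at each timepoint and then applied to every video of that timepoint and
#' channel. The automated rule pools the sigma-smoothed provisional systole
#' frame (the frame of minimum total intensity) of each control video on the
#' 8-bit-equivalent scale and maximizes between-class variance over the
#' intensity histogram (Otsu's criterion), yielding one scalar per
#' (timepoint, channel). A manual override can be passed downstream instead.
#'
#' After calibration the threshold is checked against each control: the
#' resulting mask should cover at least 95% of that control's
#' above-half-maximum region and the ventricle should be the largest
#' connected component; violations raise warnings.
#'
#' @param control_videos list of [video_stack()]s from control larvae of one
#'   timepoint and channel.
#' @param sigma Gaussian smoothing scale, px.
#' @return scalar threshold on the 8-bit-equivalent scale `[0, 255]`.
#' @export
calibrate_threshold <- function(control_videos, sigma = 2) {
  if (inherits(control_videos, "video_stack"))
    control_videos <- list(control_videos)
  if (length(control_videos) == 0) stop("empty control set")
  frames <- lapply(control_videos, function(v) {
    stopifnot(inherits(v, "video_stack"))
    if (diff(range(v$frames)) == 0)
      stop("constant-intensity control video: no threshold split exists")
    v8 <- rescale_to_8bit(v$frames)
    totals <- colSums(matrix(v8, prod(dim(v8)[1:2]), dim(v8)[3]))
    smooth_gaussian(v8[, , which.min(totals)], sigma)
  })
  pooled <- do.call(cbind, frames)
  if (diff(range(pooled)) == 0)
    stop("constant-intensity control frames: no threshold split exists")
  thr <- otsu_split(pooled)
  for (i in seq_along(frames)) {
    sm <- frames[[i]]
    halfmax <- sm >= max(sm) / 2
    mask <- sm > thr
    if (mean(mask[halfmax]) < 0.95)
      warning("calibrated threshold covers < 95% of the bright ventricular ",
              "region in control ", i)
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
    if (max(labels) > 0) {
      biggest <- which.max(tabulate(as.integer(labels)))
      if (labels[which.max(sm)] != biggest)
        warning("largest component of control ", i,
                " does not contain the intensity maximum; distractors may ",
                "exceed the calibrated threshold")
    }
  }
  thr
}

#' Select the systole (minimum-area) frame of a video
#'
#' The systolic minimum is the measurement frame: for every frame the video
#' is rescaled to the 8-bit-equivalent range, smoothed (sigma px), thresholded,
#' and the pixel count of the largest connected component recorded. The frame
#' minimizing that count is returned (earliest frame on ties). Frame indices
#' are 1-based.
#'
#' @param video a [video_stack()].
#' @param threshold threshold from [calibrate_threshold()] (8-bit scale) or a
#'   manual override.
#' @param sigma Gaussian smoothing scale, px.
#' @return integer frame index in `[1, T]`, with the per-frame area trace
#'   attached as attribute `"area_trace"`.
#' @export
select_systole_frame <- function(video, threshold, sigma = 2) {
  stopifnot(inherits(video, "video_stack"))
  sm <- smooth_gaussian(rescale_to_8bit(video$frames), sigma)
  if (length(dim(sm)) == 2L) sm <- array(sm, c(dim(sm), 1L))
  trace <- largest_component_trace(sm > threshold)
  if (all(trace == 0))
    stop("all frames lie entirely below the threshold")
  structure(which.min(trace), area_trace = trace)
}

#' Keep only the ventricular component of a labelled mask
#'
#' BFP signal in the bulbus arteriosus (and any residual distractor signal)
#' is discarded: after optional subtraction of a user-supplied exclusion
#' polygon, only the largest-area connected component is retained.
#'
#' @param labels integer label matrix (e.g. from connected-component
#'   labelling) or a logical mask (labelled internally).
#' @param exclude_poly optional polygon as a two-column matrix of `(x, y)`
#'   vertices; pixels inside it are removed before the largest-component
#'   rule.
#' @return logical mask of the retained component (all `FALSE` when the
#'   input has no foreground).
#' @export
exclude_bulbus <- function(labels, exclude_poly = NULL) {
  if (is.logical(labels))
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(labels)))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!is.null(exclude_poly)) {
    X <- matrix(rep(seq_len(ncol(labels)), each = nrow(labels)), nrow(labels))
    Y <- matrix(rep(seq_len(nrow(labels)), ncol(labels)), nrow(labels))
    inside <- pracma::inpolygon(as.vector(X), as.vector(Y),
                                exclude_poly[, 1], exclude_poly[, 2],
                                boundary = TRUE)
    labels[matrix(inside, nrow(labels))] <- 0L
  }
  tb <- tabulate(labels[labels > 0])
  if (length(tb) == 0) return(matrix(FALSE, nrow(labels), ncol(labels)))
  labels == which.max(tb)
}

#' Segment the ventricle at the systole frame
#'
#' Full measurement chain on one video: 8-bit-equivalent rescale, Gaussian
#' smoothing (sigma = 2 px by default), binarization at the calibrated
#' threshold, connected-component labelling and exclusion of non-ventricular
#' components ([exclude_bulbus()]). An empty mask is reported as area 0 with
#' `flag = "empty"` rather than an error: an ablated mCherry channel
#' legitimately carries almost no signal.
#'
#' @inheritParams select_systole_frame
#' @param frame_index systole frame (1-based); selected automatically via
#'   [select_systole_frame()] when `NULL`.
#' @param exclude_poly optional exclusion polygon, see [exclude_bulbus()].
#' @return an object of class `segmentation_result`: list with
#'   `systole_frame`, `threshold`, `sigma`, `mask`, `area_px`, `area_um2`,
#'   `flag` (`""` or `"empty"`).
#' @export
segment_ventricle <- function(video, threshold, frame_index = NULL,
                              sigma = 2, exclude_poly = NULL) {
  stopifnot(inherits(video, "video_stack"))
  v8 <- rescale_to_8bit(video$frames)
  if (is.null(frame_index)) {
    sm_all <- smooth_gaussian(v8, sigma)
    if (length(dim(sm_all)) == 2L) sm_all <- array(sm_all, c(dim(sm_all), 1L))
    trace <- largest_component_trace(sm_all > threshold)
    frame_index <- if (all(trace == 0)) 1L else which.min(trace)
    sm <- sm_all[, , frame_index]
  } else {
    if (frame_index < 1 || frame_index > n_frames(video))
      stop("frame_index out of range")
    sm <- smooth_gaussian(v8[, , frame_index], sigma)
  }
  mask <- exclude_bulbus(sm > threshold, exclude_poly)
  area_px <- sum(mask)
  structure(list(systole_frame = as.integer(frame_index),
                 threshold = threshold, sigma = sigma, mask = mask,
                 area_px = area_px,
                 area_um2 = area_px * video$pixel_size_um^2,
                 flag = if (area_px == 0) "empty" else ""),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> frame %d, threshold %.1f, area %d px (%.1f um^2)%s\n",
              x$systole_frame, x$threshold, x$area_px, x$area_um2,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Calibrate per-timepoint thresholds from a plate
#'
#' Convenience driver: for each timepoint, reads the control-group videos of
#' the requested channel and runs [calibrate_threshold()]. For the BFP
#' channel the negative-control group is the usual reference; mCherry signal
#' is calibrated on not-ablated control larvae.
#'
#' @param plate a plate table from [load_plate()].
#' @param channel channel to calibrate.
#' @param control_group group used as calibration reference.
#' @param sigma smoothing scale, px.
#' @return named numeric vector of thresholds, one per timepoint.
#' @export
calibrate_plate <- function(plate, channel, control_group = "negative_control",
                            sigma = 2) {
  path_col <- paste0("path_", channel)
  if (!path_col %in% names(plate)) stop("plate lacks channel: ", channel)
  tps <- sort(unique(plate$timepoint))
  vapply(tps, function(tp) {
    sub <- plate[plate$timepoint == tp & plate$group == control_group, ]
    if (nrow(sub) == 0)
      stop("no ", control_group, " larvae at timepoint ", tp)
    vids <- lapply(seq_len(nrow(sub)), function(i)
      read_video(sub[[path_col]][i], sub$pixel_size_um[i],
                 sub$frame_rate_fps[i], channel))
    calibrate_threshold(vids, sigma)
  }, numeric(1))
}

#' Segment every larva of a plate in one channel
#'
#' @inheritParams calibrate_plate
#' @param thresholds named per-timepoint thresholds (from
#'   [calibrate_plate()]) or a single scalar manual override.
#' @return data.frame with one row per `(well, timepoint)`:
#'   `well, group, timepoint, channel, systole_frame, threshold, area_px,
#'   area_um2, flag`.
#' @export
segment_plate <- function(plate, channel, thresholds, sigma = 2) {
  path_col <- paste0("path_", channel)
  if (!path_col %in% names(plate)) stop("plate lacks channel: ", channel)
  res <- lapply(seq_len(nrow(plate)), function(i) {
    tp <- plate$timepoint[i]
    thr <- if (length(thresholds) == 1L && is.null(names(thresholds)))
      thresholds else thresholds[[tp]]
    if (is.null(thr) || is.na(thr))
      stop("no threshold for timepoint ", tp)
    vid <- read_video(plate[[path_col]][i], plate$pixel_size_um[i],
                      plate$frame_rate_fps[i], channel)
    seg <- segment_ventricle(vid, thr, sigma = sigma)
    data.frame(well = plate$well[i], group = plate$group[i], timepoint = tp,
               channel = channel, systole_frame = seg$systole_frame,
               threshold = thr, area_px = seg$area_px,
               area_um2 = seg$area_um2, flag = seg$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
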