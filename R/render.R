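#' Noise and distractor parameters for the synthetic renderer
#'
#' Background offset, per-pixel Gaussian read noise and autofluorescent
#' distractor structures (yolk, pigment and similar off-target signal seen in
#' real larvae, rendered in both channels). The default noise SD is 5% of the
#' compartment fluorophore intensity; distractor intensity sits below typical
#' control-calibrated thresholds, mimicking structures that correct
#' thresholding must exclude.
#'
#' @param background_level constant background offset, intensity units.
#' @param gaussian_sd SD of additive Gaussian noise, intensity units.
#' @param n_distractors number of distractor discs.
#' @param distractor_intensity distractor intensity, units.
#' @param distractor_radius distractor disc radius, px.
#' @param distractor_xy optional `n x 2` matrix of distractor centers (x, y);
#'   when `NULL`, deterministic default positions on a ring outside the
#'   ventricle are used.
#' @return a list of class `noise_params`.
#' @export
noise_params <- function(background_level = 400, gaussian_sd = 200,
                         n_distractors = 3, distractor_intensity = 1800,
                         distractor_radius = 4, distractor_xy = NULL) {
  stopifnot(background_level >= 0, gaussian_sd >= 0, n_distractors >= 0)
  structure(list(background_level = background_level,
                 gaussian_sd = gaussian_sd,
                 n_distractors = n_distractors,
                 distractor_intensity = distractor_intensity,
                 distractor_radius = distractor_radius,
                 distractor_xy = distractor_xy),
            class = "noise_params")
}

# default distractor centers: frame corners (inset 14 px), guaranteed clear
# of a centered heart and its bulbus; ring positions for n > 4
default_distractor_xy <- function(n, frame_shape, center_xy) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  ins <- 14
  corners <- rbind(c(frame_shape[2] - ins, frame_shape[1] - ins),
                   c(ins, frame_shape[1] - ins),
                   c(frame_shape[2] - ins, ins),
                   c(ins, ins))
  if (n <= 4) return(corners[seq_len(n), , drop = FALSE])
  r <- min(frame_shape) / 2 - 10
  ang <- (75 + (seq_len(n - 4) - 1) * 360 / (n - 4)) * pi / 180
  rbind(corners,
        cbind(center_xy[1] + r * cos(ang), center_xy[2] + r * sin(ang)))
}

# static (time-independent) scene: background + distractors (+ bulbus in BFP)
render_static <- function(model, channel, frame_shape, noise) {
  ny <- frame_shape[1]; nx <- frame_shape[2]
  img <- matrix(noise$background_level, ny, nx)
  dxy <- noise$distractor_xy
  if (is.null(dxy))
    dxy <- default_distractor_xy(noise$n_distractors, frame_shape,
                                 model$center_xy)
  if (nrow(dxy) > 0) {
    X <- matrix(rep(seq_len(nx), each = ny), ny)
    Y <- matrix(rep(seq_len(ny), nx), ny)
    for (k in seq_len(nrow(dxy))) {
      d <- (X - dxy[k, 1])^2 + (Y - dxy[k, 2])^2 <= noise$distractor_radius^2
      img[d] <- img[d] + noise$distractor_intensity
    }
  }
  if (channel == "BFP" && model$intensity$bulbus > 0) {
    bx <- model$center_xy[1] + model$bulbus_offset_xy[1]
    by <- model$center_xy[2] + model$bulbus_offset_xy[2]
    X <- matrix(rep(seq_len(nx), each = ny), ny)
    Y <- matrix(rep(seq_len(ny), nx), ny)
    bd <- (X - bx)^2 + (Y - by)^2 <= model$bulbus_radius^2
    img[bd] <- img[bd] + model$intensity$bulbus
  }
  img
}

# paint the time-dependent compartments into `img` (no noise). Returns img.
render_compartments <- function(img, model, t, channel) {
  ny <- nrow(img); nx <- ncol(img)
  ab <- heart_geometry_at(model, t)
  cx <- model$center_xy[1]; cy <- model$center_xy[2]
  a0 <- model$diastolic_semi_axes[1]; b0 <- model$diastolic_semi_axes[2]
  # bounding box of the diastolic ellipse (+ residual patch margin)
  x0 <- max(1L, floor(cx - a0 - 2)); x1 <- min(nx, ceiling(cx + a0 + 2))
  y0 <- max(1L, floor(cy - b0 - 2)); y1 <- min(ny, ceiling(cy + b0 + 2))
  xs <- x0:x1; ys <- y0:y1
  U <- matrix(rep((xs - cx) / ab["a"], each = length(ys)), length(ys))
  V <- matrix(rep((ys - cy) / ab["b"], length(xs)), length(ys))
  inside <- U * U + V * V <= 1
  sub <- img[ys, xs, drop = FALSE]
  if (is.null(model$mcherry_residual_area)) {
    f <- model$fhf_area_fraction
    if (channel == "BFP") {
      comp <- if (f == 0) inside else inside & (U > fhf_chord_offset(f))
      sub[comp] <- sub[comp] + model$intensity$bfp
    } else if (f > 0) {
      comp <- if (f == 1) inside else inside & (U <= fhf_chord_offset(f))
      sub[comp] <- sub[comp] + model$intensity$mcherry
    }
  } else {
    if (channel == "BFP") {
      sub[inside] <- sub[inside] + model$intensity$bfp
    } else if (model$mcherry_residual_area > 0) {
      # surviving mCherry+ cells: compact patch contracting with the heart
      area_t <- model$mcherry_residual_area * (ab["a"] * ab["b"]) / (a0 * b0)
      r <- sqrt(area_t / pi)
      px <- cx + 0.45 * ab["a"]
      Xs <- matrix(rep(xs, each = length(ys)), length(ys))
      Ys <- matrix(rep(ys, length(xs)), length(ys))
      patch <- (Xs - px)^2 + (Ys - cy)^2 <= r^2
      sub[patch] <- sub[patch] + model$intensity$mcherry
    }
  }
  img[ys, xs] <- sub
  img
}

#' Render one synthetic fluorescence frame
#'
#' Draws the heart model at time `t` in the requested channel: the BFP channel
#' shows the SHF compartment (plus weak BFP in the bulbus arteriosus disc),
#' the mCherry channel the FHF sector (or, for ablated hearts, the surviving
#' mCherry+ patch). Distractor discs and Gaussian noise are added and
#' intensities clipped to the 16-bit range. Pixel values are integers in
#' `[0, 65535]`.
#'
#' Adding Gaussian noise consumes random numbers from the R session stream;
#' seed the session for reproducible frames.
#'
#' @param model a [heart_model()].
#' @param t time in seconds.
#' @param channel `"BFP"` or `"mCherry"`.
#' @param frame_shape integer(2), frame size (rows, cols); must be positive
#'   and large enough to contain the heart.
#' @param noise a [noise_params()] list.
#' @return numeric matrix `frame_shape[1] x frame_shape[2]`.
#' @export
render_frame <- function(model, t, channel = c("BFP", "mCherry"),
                         frame_shape = c(128, 128), noise = noise_params()) {
  channel <- match.arg(channel)
  if (any(frame_shape <= 0)) stop("frame dimensions must be positive")
  check_heart_fits(model, frame_shape)
  img <- render_static(model, channel, frame_shape, noise)
  img <- render_compartments(img, model, t, channel)
  if (noise$gaussian_sd > 0)
    img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  matrix(pmin(pmax(round(img), 0), 65535), nrow(img), ncol(img))
}

check_heart_fits <- function(model, frame_shape) {
  cx <- model$center_xy[1]; cy <- model$center_xy[2]
  a0 <- model$diastolic_semi_axes[1]; b0 <- model$diastolic_semi_axes[2]
  if (cx - a0 < 1 || cx + a0 > frame_shape[2] ||
      cy - b0 < 1 || cy + b0 > frame_shape[1])
    stop("frame_shape too small to contain the diastolic ventricle")
  invisible(TRUE)
}

#' Render a synthetic single-channel beating-heart video
#'
#' Renders `floor(duration_s * frame_rate_fps)` frames of the model. Defaults
#' mirror a standard acquisition: 2.8 s at 96.8 fps with an effective pixel
#' size of 1.3 um (2x2 binning), during which the default-rate heart beats
#' exactly 10 times.
#'
#' @inheritParams render_frame
#' @param duration_s acquisition duration, seconds.
#' @param frame_rate_fps frame rate, frames/second.
#' @param pixel_size_um pixel size, micrometres.
#' @return a [video_stack()].
#' @export
render_video <- function(model, duration_s = 2.8, frame_rate_fps = 96.8,
                         channel = c("BFP", "mCherry"),
                         frame_shape = c(128, 128), noise = noise_params(),
                         pixel_size_um = 1.3) {
  channel <- match.arg(channel)
  n_frames <- floor(duration_s * frame_rate_fps)
  if (n_frames < 1) stop("duration_s * frame_rate_fps must be >= 1 frame")
  if (any(frame_shape <= 0)) stop("frame dimensions must be positive")
  check_heart_fits(model, frame_shape)
  static <- render_static(model, channel, frame_shape, noise)
  frames <- array(0, c(frame_shape[1], frame_shape[2], n_frames))
  for (k in seq_len(n_frames)) {
    frames[, , k] <- render_compartments(static, model,
                                         (k - 1) / frame_rate_fps, channel)
  }
  if (noise$gaussian_sd > 0)
    frames <- frames + rnorm(length(frames), 0, noise$gaussian_sd)
  frames <- array(pmin(pmax(round(frames), 0), 65535), dim(frames))
  video_stack(frames, pixel_size_um = pixel_size_um,
              frame_rate_fps = frame_rate_fps, channel = channel)
}
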