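#' In-memory fluorescence video stack
#'
#' The uniform representation every pipeline stage consumes: a `Y x X x T`
#' array of non-negative intensities plus physical metadata. Pixel
#' coordinates are 1-based `(x = column, y = row)`; areas are pixel counts,
#' converted to um^2 only at reporting time via `pixel_size_um^2`.
#'
#' @param frames numeric array `Y x X x T` (a single matrix is promoted to
#'   `T = 1`).
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param frame_rate_fps frame rate in frames/second (> 0).
#' @param channel channel label (e.g. `"BFP"`, `"mCherry"`), or `NA`.
#' @return an object of class `video_stack` with elements `frames`,
#'   `pixel_size_um`, `frame_rate_fps`, `channel`.
#' @export
video_stack <- function(frames, pixel_size_um, frame_rate_fps, channel = NA) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a Y x X x T array or a single matrix")
  if (dim(frames)[3] < 1L) stop("video must contain at least one frame")
  if (any(frames < 0)) stop("frame intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.numeric(frame_rate_fps) || frame_rate_fps <= 0)
    stop("frame_rate_fps must be > 0")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_fps = frame_rate_fps, channel = channel),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d x %d px, %d frames (%.2f s @ %.1f fps), %.2f um/px, channel %s\n",
              d[1], d[2], d[3], n_frames(x) / x$frame_rate_fps,
              x$frame_rate_fps, x$pixel_size_um, x$channel))
  invisible(x)
}

#' @rdname video_stack
#' @param video a `video_stack`.
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' @rdname video_stack
#' @export
video_duration <- function(video) n_frames(video) / video$frame_rate_fps

#' Read a multi-page TIFF video
#'
#' Loads all pages of a grayscale multi-page TIFF into a [video_stack()].
#' Physical metadata (pixel size, frame rate) is not reliably carried by plain
#' TIFF, so it is supplied by the caller (normally from the plate metadata
#' CSV); supplied arguments always win over any embedded tags.
#'
#' @param path path to a multi-page TIFF.
#' @param pixel_size_um pixel size, um/px.
#' @param frame_rate_fps frame rate, frames/s.
#' @param channel channel label to attach.
#' @return a [video_stack()]; 16-bit pages come back as integer intensities
#'   in `[0, 65535]`.
#' @export
read_video <- function(path, pixel_size_um, frame_rate_fps, channel = NA) {
  if (!file.exists(path)) stop("video file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  if (any(!vapply(pages, function(p) is.matrix(p), logical(1))))
    stop("TIFF pages must be 2-D grayscale images: ", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages differ in shape: ", path)
  frames <- array(unlist(pages, use.names = FALSE),
                  c(dims[1, 1], dims[2, 1], length(pages)))
  video_stack(frames, pixel_size_um, frame_rate_fps, channel)
}

#' Write a video stack to a 16-bit multi-page TIFF
#'
#' Lossless for integer intensities in `[0, 65535]`; a write-then-read
#' round-trip is the identity on pixel values and shape.
#'
#' @param video a [video_stack()] or a `Y x X x T` array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (any(frames < 0) || any(frames > 65535))
    stop("intensities must lie in [0, 65535] for 16-bit TIFF")
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(k) frames[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Load and validate a plate metadata table
#'
#' Reads the long-format plate CSV (one row per well, timepoint and channel)
#' and merges channels into one record per larva and timepoint. Wells map to
#' the same larva across timepoints: the imaging platform redispenses each
#' larva into its original well, which is what makes longitudinal tracking
#' possible.
#'
#' @param metadata_csv CSV with columns `well, group, timepoint, channel,
#'   path, pixel_size_um, frame_rate_fps`.
#' @param check_paths verify that every referenced video file exists.
#' @return a data.frame with one row per `(well, timepoint)` and one
#'   `path_<channel>` column per channel, plus a `channels` attribute.
#' @export
load_plate <- function(metadata_csv, check_paths = TRUE) {
  if (!file.exists(metadata_csv)) stop("metadata file not found: ", metadata_csv)
  md <- read.csv(metadata_csv, stringsAsFactors = FALSE)
  required <- c("well", "group", "timepoint", "channel", "path",
                "pixel_size_um", "frame_rate_fps")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(md$well, md$timepoint, md$channel, sep = "/")
  if (anyDuplicated(key))
    stop("duplicated (well, timepoint, channel) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (check_paths) {
    gone <- !file.exists(md$path)
    if (any(gone))
      stop("missing video file(s):\n  ", paste(md$path[gone], collapse = "\n  "))
  }
  channels <- sort(unique(md$channel))
  base <- unique(md[, c("well", "group", "timepoint",
                        "pixel_size_um", "frame_rate_fps")])
  dup <- duplicated(paste(base$well, base$timepoint))
  if (any(dup))
    stop("inconsistent group/metadata for well-timepoint: ",
         paste(base$well[dup], base$timepoint[dup], collapse = ", "))
  for (ch in channels) {
    sub <- md[md$channel == ch, c("well", "timepoint", "path")]
    names(sub)[3] <- paste0("path_", ch)
    base <- merge(base, sub, by = c("well", "timepoint"), all.x = TRUE)
  }
  # a record silently missing one channel would corrupt downstream ratios
  for (ch in channels) {
    col <- paste0("path_", ch)
    if (anyNA(base[[col]]))
      warning(sum(is.na(base[[col]])), " record(s) lack the ", ch, " channel")
  }
  base <- base[order(base$timepoint, base$well), ]
  rownames(base) <- NULL
  attr(base, "channels") <- channels
  base
}
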