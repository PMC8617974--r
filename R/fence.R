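#' Define a rectangular measurement fence
#'
#' A fence is the axis-aligned rectangular region of the video frame inside
#' which rider movement is analyzed. Riders are expected to traverse it in a
#' consistent direction (`travel_axis`). The rectangle is half-open,
#' `[xmin, xmax) x [ymin, ymax)`, so a point on the shared edge of two
#' adjacent fences belongs to exactly one of them. Pixel coordinates use the
#' image convention: origin top-left, x rightward, y downward.
#'
#' @param xmin,ymin,xmax,ymax Fence rectangle in pixels; `xmin < xmax`,
#'   `ymin < ymax`.
#' @param travel_axis One of `"left_to_right"`, `"right_to_left"`,
#'   `"top_to_bottom"`, `"bottom_to_top"`: the direction riders travel
#'   through the fence.
#' @param fps Frame rate of the source video in frames per second.
#' @param frame_stride Analyze every `frame_stride`-th video frame
#'   (integer >= 1). Frame indices are kept in original video numbering, so
#'   timing always uses `fps` directly.
#' @return An object of class `"fence"`.
#' @examples
#' f <- fence(0, 0, 600, 400, "left_to_right", fps = 30)
#' fence_diagonal(f)
#' @export
fence <- function(xmin, ymin, xmax, ymax,
                  travel_axis = c("left_to_right", "right_to_left",
                                  "top_to_bottom", "bottom_to_top"),
                  fps = 30, frame_stride = 3L) {
  travel_axis <- match.arg(travel_axis)
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax),
            is.numeric(ymax), length(xmin) == 1L, length(ymin) == 1L,
            length(xmax) == 1L, length(ymax) == 1L)
  if (!all(is.finite(c(xmin, ymin, xmax, ymax))))
    stop("fence coordinates must be finite")
  if (xmin >= xmax) stop("invalid fence: xmin must be < xmax")
  if (ymin >= ymax) stop("invalid fence: ymin must be < ymax")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive number")
  frame_stride <- as.integer(frame_stride)
  if (is.na(frame_stride) || frame_stride < 1L)
    stop("frame_stride must be an integer >= 1")
  structure(
    list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax),
         travel_axis = travel_axis, fps = as.numeric(fps),
         frame_stride = frame_stride),
    class = "fence"
  )
}

#' @export
print.fence <- function(x, ...) {
  cat(sprintf("<fence> [%g, %g) x [%g, %g) px, travel %s, %g fps, stride %d\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$travel_axis, x$fps,
              x$frame_stride))
  invisible(x)
}

#' Diagonal length of the fence rectangle in pixels
#'
#' Used as the scale for the fragment-merge threshold (a fraction of the
#' fence diagonal by default).
#'
#' @param fence A [fence()] object.
#' @return Numeric scalar, pixels.
#' @export
fence_diagonal <- function(fence) {
  stopifnot(inherits(fence, "fence"))
  sqrt((fence$xmax - fence$xmin)^2 + (fence$ymax - fence$ymin)^2)
}

#' Fence membership test
#'
#' A detection is inside the fence iff the center of its keypoint bounding
#' box lies in the half-open fence rectangle. Vectorized over points.
#'
#' @param cx,cy Point coordinates in pixels (equal-length vectors), typically
#'   bounding-box centers of pose detections.
#' @param fence A [fence()] object.
#' @return Logical vector.
#' @examples
#' f <- fence(0, 0, 100, 100, "left_to_right")
#' in_fence(c(50, 100), c(50, 50), f)  # TRUE, FALSE (half-open right edge)
#' @export
in_fence <- function(cx, cy, fence) {
  stopifnot(inherits(fence, "fence"), length(cx) == length(cy))
  cx >= fence$xmin & cx < fence$xmax & cy >= fence$ymin & cy < fence$ymax
}

#' Frame indices to analyze given a sampling stride
#'
#' Periodically skipping frames trades detection density for processing
#' speed; a stride of 3 on 30 fps footage retains 10 analyzed frames per
#' second. Indices are 0-based in original video numbering.
#'
#' @param total_frames Number of frames in the video (>= 0).
#' @param frame_stride Keep every `frame_stride`-th frame (integer >= 1).
#' @return Integer vector `0, frame_stride, 2*frame_stride, ... <
#'   total_frames` (empty when `total_frames == 0`).
#' @examples
#' sample_frames(10, 3)  # 0 3 6 9
#' @export
sample_frames <- function(total_frames, frame_stride) {
  total_frames <- as.integer(total_frames)
  frame_stride <- as.integer(frame_stride)
  if (is.na(total_frames) || total_frames < 0L)
    stop("total_frames must be a non-negative integer")
  if (is.na(frame_stride) || frame_stride < 1L)
    stop("frame_stride must be an integer >= 1")
  if (total_frames == 0L) return(integer(0))
  seq.int(0L, total_frames - 1L, by = frame_stride)
}
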