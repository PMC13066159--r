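#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius (the classic
#' rolling-ball idea: features narrower than the ball survive, the broad
#' background does not) and subtracts it. The output is clipped at zero and is
#' pointwise less than or equal to the input.
#'
#' @param frame a [calibrated_frame()].
#' @param ball_radius_px ball (disc) radius in pixels; default 50, the common
#'   default of the background-subtraction command in imaging tools.
#' @return A background-subtracted [calibrated_frame()].
#' @export
subtract_background <- function(frame, ball_radius_px = 50L) {
  stopifnot(inherits(frame, "calibrated_frame"))
  r <- as.integer(ball_radius_px)
  if (r < 1L) stop("ball_radius_px must be >= 1")
  if (r >= min(dim(frame$intensities)))
    stop("ball_radius_px must be smaller than the smallest image dimension")
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  # grayscale morphology is equivariant under positive scaling; work in
  # [0, 1] (the range EBImage assumes) and scale back
  m <- max(frame$intensities)
  if (m == 0) return(frame)
  bg <- EBImage::opening(frame$intensities / m, brush) * m
  out <- pmax(frame$intensities - bg, 0)
  calibrated_frame(out, frame$pixel_size, t = frame$t,
                   source_id = frame$source_id)
}

#' Triangle (Zack) histogram threshold
#'
#' Builds a histogram of the intensities (default 256 equal-width bins over
#' the observed min-max range), draws the line from the histogram peak to the
#' far tail end — the last non-empty bin on the side of the peak with the
#' longer tail; if the peak sits at an extreme bin the construction runs
#' toward the other extreme — and returns the intensity at the bin whose
#' histogram point is farthest (perpendicular distance) from that line. Ties
#' in maximal distance break toward the peak, i.e. toward the lower threshold
#' for the usual dark-background histogram, keeping faint objects.
#'
#' @param frame a [calibrated_frame()] or a numeric matrix/vector.
#' @param n_bins number of histogram bins.
#' @return Threshold in intensity units (the upper edge of the selected bin),
#'   with attributes `bin` (selected bin index), `peak_bin` and `tail_bin`.
#' @export
triangle_threshold <- function(frame, n_bins = 256L) {
  x <- if (inherits(frame, "calibrated_frame")) frame$intensities else frame
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (!(hi > lo))
    stop("no threshold definable: image is constant")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  sel <- triangle_select_bin(h)
  structure(breaks[sel$bin + 1L], bin = sel$bin,
            peak_bin = sel$peak, tail_bin = sel$tail)
}

# Core triangle construction on a histogram of counts; shared with the tests'
# brute-force oracle only through the histogram, not through this code.
triangle_select_bin <- function(h) {
  n <- length(h)
  peak <- which.max(h)
  nz <- which(h > 0L)
  first <- nz[1]; last <- nz[length(nz)]
  # side with the longer stretch of data from the peak; peak at an extreme
  # bin automatically sends the construction toward the other extreme
  tail_bin <- if ((peak - first) > (last - peak)) first else last
  if (tail_bin == peak)                     # single occupied bin
    stop("no threshold definable: degenerate histogram")
  rng <- if (tail_bin > peak) (peak + 1L):(tail_bin - 1L) else (tail_bin + 1L):(peak - 1L)
  if (tail_bin == peak + 1L || tail_bin == peak - 1L) {
    b <- peak                               # adjacent: nothing strictly between
  } else {
    # perpendicular distance of (b, h[b]) from the line peak -> tail
    dxl <- tail_bin - peak; dyl <- h[tail_bin] - h[peak]
    d <- abs(dxl * (h[peak] - h[rng]) - (peak - rng) * dyl)
    cand <- rng[d >= max(d) - 1e-9]
    b <- cand[which.min(abs(cand - peak))]  # tie toward the peak
  }
  list(bin = b, peak = peak, tail = tail_bin)
}

#' Binarize a frame with the Triangle threshold
#'
#' Foreground is strictly above the threshold: `mask = intensity > threshold`.
#'
#' @inheritParams triangle_threshold
#' @return An object of class `binary_mask` with the logical `mask`, the
#'   `threshold_used` and the frame's pixel size.
#' @export
binarize <- function(frame, n_bins = 256L) {
  stopifnot(inherits(frame, "calibrated_frame"))
  thr <- triangle_threshold(frame, n_bins = n_bins)
  structure(list(mask = frame$intensities > as.numeric(thr),
                 threshold_used = as.numeric(thr),
                 pixel_size = frame$pixel_size),
            class = "binary_mask")
}
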