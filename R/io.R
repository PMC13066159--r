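#' Calibrated fluorescence frame
#'
#' A single 2D grayscale intensity grid together with its physical pixel size
#' and acquisition time. All downstream geometry takes the calibration from the
#' frame (or the boundary built from it); nothing re-declares the pixel size.
#'
#' Coordinate convention (used throughout the package): pixel centers sit at
#' integer `(x, y)` with `x` = column, `y` = row and the origin at the top-left
#' pixel, i.e. the 0-based convention of common imaging tools. A matrix element
#' `[i, j]` is the pixel at `x = j - 1`, `y = i - 1`.
#'
#' @param intensities numeric matrix of non-negative intensities (camera counts).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param t acquisition time in minutes.
#' @param source_id free-form identifier (file name, scene id, ...).
#' @return An object of class `calibrated_frame`.
#' @export
calibrated_frame <- function(intensities, pixel_size, t = 0, source_id = "") {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  structure(
    list(intensities = intensities, pixel_size = pixel_size,
         t = t, source_id = source_id),
    class = "calibrated_frame")
}

#' @export
print.calibrated_frame <- function(x, ...) {
  cat(sprintf("<calibrated_frame> %d x %d px, %.4g um/px, t = %g min\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size, x$t))
  invisible(x)
}

#' Time-lapse image stack
#'
#' @param frames list of [calibrated_frame()] objects with strictly increasing
#'   times, identical shape and identical pixel size.
#' @param frame_interval nominal frame spacing in minutes.
#' @return An object of class `timelapse`.
#' @export
timelapse <- function(frames, frame_interval) {
  if (length(frames) < 1L) stop("a timelapse needs at least one frame")
  stopifnot(all(vapply(frames, inherits, logical(1), "calibrated_frame")))
  tt <- vapply(frames, `[[`, numeric(1), "t")
  if (length(tt) > 1L && any(diff(tt) <= 0))
    stop("frame times must be strictly increasing")
  dims <- vapply(frames, function(f) dim(f$intensities), integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share the same shape")
  ps <- vapply(frames, `[[`, numeric(1), "pixel_size")
  if (any(ps != ps[1])) stop("all frames must share the same pixel size")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("<timelapse> %d frame(s), %d x %d px, %.4g um/px, t = %g..%g min\n",
              length(x$frames), nrow(f1$intensities), ncol(f1$intensities),
              f1$pixel_size, x$frames[[1]]$t, x$frames[[length(x$frames)]]$t))
  invisible(x)
}

#' Droplet boundary annotation
#'
#' An ordered polygon of at least three vertices, drawn on one frame of a
#' time-lapse (by convention the frame at T = 0 min). Coordinates are pixels in
#' the 0-based convention; the polygon is closed implicitly (last vertex
#' connects back to the first) and must be simple (non-self-intersecting).
#'
#' @param vertices two-column numeric matrix (or data frame) of `(x_px, y_px)`.
#' @param frame_ref index of the frame the annotation was drawn on.
#' @return An object of class `boundary_annotation`.
#' @export
boundary_annotation <- function(vertices, frame_ref = 1L) {
  v <- as.matrix(vertices)
  if (ncol(v) < 2L) stop("vertices must have two columns (x_px, y_px)")
  v <- matrix(as.numeric(v[, 1:2]), ncol = 2,
              dimnames = list(NULL, c("x_px", "y_px")))
  if (nrow(v) < 3L) stop("a boundary annotation needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertex coordinates must be finite")
  bad <- polygon_self_intersection(v)
  if (!is.null(bad))
    stop(sprintf("polygon is self-intersecting: segment %d-%d crosses segment %d-%d",
                 bad[1], bad[1] %% nrow(v) + 1L, bad[2], bad[2] %% nrow(v) + 1L))
  structure(list(vertices = v, frame_ref = frame_ref),
            class = "boundary_annotation")
}

# Returns c(i, j) for the first pair of properly crossing polygon edges,
# or NULL for a simple polygon. Edges sharing a vertex are skipped.
polygon_self_intersection <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  p1 <- v; p2 <- v[nxt, , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]            # edges adjacent to edge i
    if (!length(js)) next
    a1 <- p1[i, ]; a2 <- p2[i, ]
    d1 <- cross2(a2[1] - a1[1], a2[2] - a1[2],
                 p1[js, 1] - a1[1], p1[js, 2] - a1[2])
    d2 <- cross2(a2[1] - a1[1], a2[2] - a1[2],
                 p2[js, 1] - a1[1], p2[js, 2] - a1[2])
    d3 <- cross2(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                 a1[1] - p1[js, 1], a1[2] - p1[js, 2])
    d4 <- cross2(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                 a2[1] - p1[js, 1], a2[2] - p1[js, 2])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(c(i, js[which(hit)[1]]))
  }
  NULL
}

#' Read a multi-page grayscale TIFF stack as a time-lapse
#'
#' Pages are ordered by index; frame `k` (1-based) gets time
#' `t = (k - 1) * frame_interval`. If the file carries a JSON metadata block in
#' its description tag (as written by [write_timelapse()]), the stored
#' `pixel_size` / `frame_interval` override the arguments with a warning on
#' conflict.
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param channel for multi-channel pages, which channel to keep (default:
#'   error on multi-channel input).
#' @param t_start time of the first frame, minutes.
#' @return A [timelapse()].
#' @export
read_timelapse <- function(path, pixel_size = NULL, frame_interval = NULL,
                           channel = NULL, t_start = 0) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) == 0L) stop("TIFF stack has zero pages: ", path)
  meta <- read_stack_metadata(path, attr(pages[[1]], "description"))
  if (!is.null(meta$pixel_size)) {
    if (!is.null(pixel_size) && !isTRUE(all.equal(meta$pixel_size, pixel_size)))
      warning(sprintf("pixel_size metadata (%g) overrides argument (%g)",
                      meta$pixel_size, pixel_size))
    pixel_size <- meta$pixel_size
  }
  if (is.null(pixel_size))
    stop("pixel_size is required (not present in file metadata)")
  if (!is.null(meta$frame_interval)) {
    if (!is.null(frame_interval) &&
        !isTRUE(all.equal(meta$frame_interval, frame_interval)))
      warning(sprintf("frame_interval metadata (%g) overrides argument (%g)",
                      meta$frame_interval, frame_interval))
    frame_interval <- meta$frame_interval
  }
  if (is.null(frame_interval))
    stop("frame_interval is required (not present in file metadata)")
  if (!is.null(meta$t_start)) t_start <- meta$t_start
  frames <- lapply(seq_along(pages), function(k) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) {
      if (is.null(channel))
        stop("multi-channel TIFF: pass `channel` to select one channel")
      pg <- pg[, , channel]
    }
    pg <- matrix(as.numeric(pg), nrow(pg), ncol(pg))  # drop TIFF tag attributes
    calibrated_frame(pg, pixel_size, t = t_start + (k - 1) * frame_interval,
                     source_id = basename(path))
  })
  timelapse(frames, frame_interval)
}

# Calibration metadata travels in a JSON sidecar `<stack>.meta.json`
# (preferred) or, when present, a JSON image-description tag.
read_stack_metadata <- function(path, desc = NULL) {
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    return(tryCatch(jsonlite::fromJSON(sidecar), error = function(e) list()))
  if (is.null(desc) || !nzchar(desc)) return(list())
  out <- tryCatch(jsonlite::fromJSON(desc), error = function(e) list())
  if (!is.list(out)) list() else out
}

#' Write a time-lapse as a 16-bit multi-page TIFF
#'
#' Intensities are stored as 16-bit integer camera counts (values are clipped
#' to `[0, 65535]` and rounded); pixel size, frame interval and start time go
#' to a JSON sidecar `<path>.meta.json` so [read_timelapse()] can recover
#' them. Reading back a written stack reproduces the (rounded) pixel values
#' bit-exactly.
#'
#' @param tl a [timelapse()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(tl, path) {
  meta <- jsonlite::toJSON(list(pixel_size = tl$frames[[1]]$pixel_size,
                                frame_interval = tl$frame_interval,
                                t_start = tl$frames[[1]]$t),
                           auto_unbox = TRUE, digits = NA)
  mats <- lapply(tl$frames, function(f)
    pmin(pmax(round(f$intensities), 0), 65535) / 65535)
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  writeLines(as.character(meta), paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a droplet boundary annotation
#'
#' Accepts either a CSV of ordered vertices (columns `x_px`, `y_px`, or the
#' first two columns) or a single-polygon ImageJ-dialect `.roi` file. Vertex
#' order is preserved; coordinates are pixels of the annotated frame.
#'
#' @param path `.csv` or `.roi` file.
#' @return A [boundary_annotation()].
#' @export
read_boundary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") return(read_boundary_roi(path))
  df <- utils::read.csv(path)
  cols <- if (all(c("x_px", "y_px") %in% names(df))) c("x_px", "y_px") else 1:2
  boundary_annotation(as.matrix(df[, cols]))
}

# Minimal parser for the de-facto ImageJ .roi dialect, polygon type only.
read_boundary_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ-dialect .roi file: ", path)
  be_i2 <- function(off, n = 1L)            # signed big-endian int16 at byte offset
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = TRUE, endian = "big")
  type <- as.integer(raw[7L])               # byte offset 6
  if (type != 0L)
    stop("only polygon-type (.roi type 0) annotations are supported")
  top <- be_i2(8L); left <- be_i2(10L)
  n <- be_i2(16L)
  if (n < 3L) stop("a boundary annotation needs at least 3 vertices")
  x <- be_i2(64L, n) + left
  y <- be_i2(64L + 2L * n, n) + top
  boundary_annotation(cbind(x_px = x, y_px = y))
}

#' Write a polygon as an ImageJ-dialect .roi file
#'
#' Coordinates are rounded to integer pixels (the dialect stores 16-bit
#' integers). Mainly used for round-trip interoperability with image viewers.
#'
#' @param annotation a [boundary_annotation()].
#' @param path output `.roi` file.
#' @return `path`, invisibly.
#' @export
write_boundary_roi <- function(annotation, path) {
  v <- round(annotation$vertices)
  n <- nrow(v)
  left <- min(v[, 1]); top <- min(v[, 2])
  hdr <- raw(64L)
  hdr[1:4] <- charToRaw("Iout")
  be2 <- function(val) rev(writeBin(as.integer(val), raw(), size = 2L,
                                    endian = "little"))
  hdr[5:6] <- be2(227L)                     # header version
  hdr[7L] <- as.raw(0L)                     # type 0 = polygon
  hdr[9:10] <- be2(top); hdr[11:12] <- be2(left)
  hdr[13:14] <- be2(max(v[, 2]) + 1L); hdr[15:16] <- be2(max(v[, 1]) + 1L)
  hdr[17:18] <- be2(n)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.integer(v[, 1] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2L, endian = "big")
  invisible(path)
}

#' Write a CSV vertex list for a boundary annotation
#' @param annotation a [boundary_annotation()].
#' @param path output `.csv` file.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(annotation, path) {
  utils::write.csv(as.data.frame(annotation$vertices), path, row.names = FALSE)
  invisible(path)
}

#' Write tidy long-format result tables
#'
#' Each table gains a `schema_version` column and is written as
#' `<out_dir>/<name>.csv`. The long format (one row per droplet x time or per
#' droplet x annulus) is directly consumable by external mixed-model tooling.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    df <- tables[[nm]]
    if (!"schema_version" %in% names(df))
      df$schema_version <- if (nrow(df)) "1" else character(0)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
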