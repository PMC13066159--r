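#' Derive circular reference geometry from an annotated droplet boundary
#'
#' The annotated polygon is reduced to a family of concentric circles sharing
#' the polygon's area centroid as center:
#' * `r_inner` — radius of the largest centered circle that lies entirely
#'   inside the polygon (minimum distance from the center to any polygon edge),
#' * `r_outer` — radius of the smallest centered circle containing every
#'   vertex (maximum center-to-vertex distance),
#' * `r_middle = (r_inner + r_outer) / 2` — the middle boundary, which splits
#'   the image into droplet interior and exterior.
#'
#' The normalizing droplet radius is `R := r_middle`, so the dimensionless
#' radial coordinate `r/R` equals 1 at the middle boundary. All radii are in
#' micrometres; the center is in pixels.
#'
#' @param annotation a [boundary_annotation()].
#' @param pixel_size micrometres per pixel.
#' @return An object of class `droplet_boundary` with fields `polygon`,
#'   `center` (px), `r_inner`, `r_outer`, `r_middle`, `R` (um), `pixel_size`.
#' @export
build_boundary <- function(annotation, pixel_size) {
  stopifnot(inherits(annotation, "boundary_annotation"))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  v <- annotation$vertices
  ctr <- polygon_centroid(v)
  inside <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]),
                         matrix(ctr, ncol = 2))
  if (!inside)
    stop("polygon centroid lies outside the polygon (extreme concavity); ",
         "re-annotate the droplet boundary")
  r_inner_px <- min(point_segment_distances(ctr, v))
  r_outer_px <- max(sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2))
  r_inner <- r_inner_px * pixel_size
  r_outer <- r_outer_px * pixel_size
  r_middle <- (r_inner + r_outer) / 2
  structure(
    list(polygon = annotation, center = ctr,
         r_inner = r_inner, r_outer = r_outer, r_middle = r_middle,
         R = r_middle, pixel_size = pixel_size),
    class = "droplet_boundary")
}

#' @export
print.droplet_boundary <- function(x, ...) {
  cat(sprintf(paste0("<droplet_boundary> center (%.1f, %.1f) px; ",
                     "r_inner/middle/outer = %.1f / %.1f / %.1f um\n"),
              x$center[1], x$center[2], x$r_inner, x$r_middle, x$r_outer))
  invisible(x)
}

# Area centroid of a simple polygon (shoelace); falls back to the vertex mean
# for (near-)degenerate polygons with vanishing signed area.
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

# Distances from point p to every edge (closed) of polygon v, vectorized.
point_segment_distances <- function(p, v) {
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- ((p[1] - x1) * dx + (p[2] - y1) * dy) / pmax(len2, .Machine$double.eps)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- x1 + tt * dx; qy <- y1 + tt * dy
  sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
}

#' Assign every image pixel to a 1-px-spaced concentric ring
#'
#' Pixel at `(x, y)` belongs to ring `round(sqrt((x - cx)^2 + (y - cy)^2))`
#' (radius in pixels). Rings are enumerated out to the farthest in-bounds
#' pixel; rings with no in-bounds pixels are dropped. Together the rings
#' partition the image: every pixel belongs to exactly one ring.
#'
#' @param boundary a [build_boundary()] result (provides the center).
#' @param image_shape integer `(rows, cols)`.
#' @return An object of class `ring_set` with the per-pixel integer ring-radius
#'   matrix (`ring_px`), the in-bounds pixel count per ring (`counts`, indexed
#'   by `radii_px`), the center and the pixel size.
#' @export
build_rings <- function(boundary, image_shape) {
  stopifnot(inherits(boundary, "droplet_boundary"))
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  ctr <- boundary$center
  if (ctr[1] < 0 || ctr[1] > nc - 1 || ctr[2] < 0 || ctr[2] > nr - 1)
    stop("droplet center lies outside the image bounds")
  d <- pixel_distance_matrix(nr, nc, ctr)
  ring <- matrix(as.integer(round(d)), nr, nc)
  counts <- tabulate(ring + 1L)
  radii <- which(counts > 0L) - 1L
  structure(
    list(ring_px = ring, counts = counts[radii + 1L], radii_px = radii,
         center = ctr, pixel_size = boundary$pixel_size,
         image_shape = c(nr, nc)),
    class = "ring_set")
}

# Distance (px) from every pixel center to `ctr`, in matrix layout (0-based
# pixel-center coordinates: element [i, j] is the pixel at x = j-1, y = i-1).
pixel_distance_matrix <- function(nr, nc, ctr) {
  dx2 <- ((0:(nc - 1)) - ctr[1])^2
  dy2 <- ((0:(nr - 1)) - ctr[2])^2
  sqrt(outer(dy2, dx2, `+`))
}

#' Divide the image into concentric annular subregions
#'
#' The droplet interior (inside the middle boundary) is divided into exactly
#' 10 half-open annuli `[k*dr, (k+1)*dr)` of equal radial step
#' `dr = r_middle / 10`; the exterior is divided with the same step, enumerated
#' outward until the first annulus with no in-bounds pixels. Per-annulus
#' in-bounds areas `A_T` are in square micrometres. Pixels are assigned by
#' their exact (un-rounded) center distance.
#'
#' @param boundary a [build_boundary()] result.
#' @param rings a [build_rings()] result (provides center and image shape).
#' @param pixel_size micrometres per pixel; defaults to the boundary's.
#' @return An object of class `subregion_set`: `code` is a per-pixel integer
#'   matrix (interior annuli `0..9`, exterior annuli `10 + k`, `NA` beyond the
#'   last retained annulus), `table` the per-annulus record
#'   (`annulus`, `side`, `r_lo_um`, `r_hi_um`, `r_over_R_mid`, `area_um2`),
#'   plus `dr_um` and `dr_norm` (`= dr/R = 0.1`).
#' @export
build_subregions <- function(boundary, rings, pixel_size = boundary$pixel_size) {
  stopifnot(inherits(boundary, "droplet_boundary"), inherits(rings, "ring_set"))
  dr <- boundary$r_middle / 10
  if (dr < pixel_size)
    stop(sprintf(paste0("r_middle (%.1f um) too small for 10 annuli of at ",
                        "least one pixel width at %.3g um/px"),
                 boundary$r_middle, pixel_size))
  nr <- rings$image_shape[1]; nc <- rings$image_shape[2]
  d_um <- pixel_distance_matrix(nr, nc, rings$center) * pixel_size
  code <- matrix(NA_integer_, nr, nc)
  interior <- d_um < boundary$r_middle
  code[interior] <- pmin(as.integer(d_um[interior] %/% dr), 9L)
  code[!interior] <- 10L + as.integer((d_um[!interior] - boundary$r_middle) %/% dr)
  counts <- tabulate(code + 1L)
  if (any(counts[1:10] == 0L))
    stop("an interior annulus contains no in-bounds pixels; ",
         "the droplet center must lie inside the image")
  # retain exterior annuli up to the first empty one
  n_ext <- 0L
  while (10L + n_ext + 1L <= length(counts) && counts[10L + n_ext + 1L] > 0L)
    n_ext <- n_ext + 1L
  keep_max <- 10L + n_ext - 1L
  code[!is.na(code) & code > keep_max] <- NA_integer_
  ann <- 0:keep_max
  side <- ifelse(ann < 10L, "interior", "exterior")
  r_lo <- ifelse(ann < 10L, ann * dr, boundary$r_middle + (ann - 10L) * dr)
  tbl <- data.frame(
    annulus = ann, side = side,
    r_lo_um = r_lo, r_hi_um = r_lo + dr,
    r_over_R_mid = (r_lo + dr / 2) / boundary$R,
    area_um2 = counts[ann + 1L] * pixel_size^2)
  structure(list(code = code, table = tbl, dr_um = dr,
                 dr_norm = dr / boundary$R, pixel_size = pixel_size),
            class = "subregion_set")
}
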