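#' Label bacterial aggregates in a binary mask
#'
#' Connected components are found under 8-connectivity (pixels touching by an
#' edge or a corner belong to the same aggregate, matching the default of the
#' common particle-analysis tools); areas are pixel counts times
#' `pixel_size^2`; the radial position of a component is the distance from its
#' centroid to the droplet center, and a component is flagged `inside` when
#' that distance is below the middle boundary `r_middle`.
#'
#' @param mask a [binarize()] result.
#' @param boundary a [build_boundary()] result.
#' @param connectivity 8 (default) or 4.
#' @return An object of class `aggregate_set`: `labels` (integer matrix, 0 =
#'   background), `table` (`label`, `area_um2`, `n_px`, `centroid_x`,
#'   `centroid_y`, `r_um`, `inside`), `pixel_size`, `min_area_um2` (0 until
#'   filtered).
#' @export
label_aggregates <- function(mask, boundary, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"), inherits(boundary, "droplet_boundary"))
  lab <- label_components(mask$mask, connectivity = connectivity)
  n <- max(lab)
  ps <- mask$pixel_size
  if (n == 0L) {
    tbl <- data.frame(label = integer(0), area_um2 = numeric(0),
                      n_px = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), r_um = numeric(0),
                      inside = logical(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    i <- (idx - 1L) %% nrow(lab) + 1L       # row (y + 1)
    j <- (idx - 1L) %/% nrow(lab) + 1L      # col (x + 1)
    npx <- tabulate(l, nbins = n)
    cx <- rowsum(as.numeric(j - 1L), l)[, 1] / npx
    cy <- rowsum(as.numeric(i - 1L), l)[, 1] / npx
    r_um <- sqrt((cx - boundary$center[1])^2 + (cy - boundary$center[2])^2) * ps
    tbl <- data.frame(label = seq_len(n), area_um2 = npx * ps^2, n_px = npx,
                      centroid_x = cx, centroid_y = cy, r_um = r_um,
                      inside = r_um < boundary$r_middle)
  }
  structure(list(labels = lab, table = tbl, pixel_size = ps,
                 min_area_um2 = 0),
            class = "aggregate_set")
}

# Connected-component labeling. EBImage::bwlabel provides fast 4-connected
# labels; for 8-connectivity, labels that touch diagonally are merged with a
# union-find over the (small) set of adjacent label pairs.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # diagonal "\" neighbors
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # diagonal "/" neighbors
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))  # compact 1..n_components
  lut <- c(0L, relab)
  matrix(lut[lab + 1L], nr, nc)
}

#' Filter aggregates by minimum area
#'
#' Keeps components with area strictly greater than `min_area` (default
#' 27 um^2, about ten bacteria — aggregates at or below this size are treated
#' as noise or single swimmers). The label image of removed components is
#' zeroed so downstream per-pixel area measurements see only survivors.
#'
#' @param aggs an [label_aggregates()] result.
#' @param min_area minimum area in square micrometres (strict `>`).
#' @return A filtered `aggregate_set`.
#' @export
filter_by_area <- function(aggs, min_area = 27) {
  stopifnot(inherits(aggs, "aggregate_set"))
  if (min_area < 0) stop("min_area must be non-negative")
  keep <- aggs$table$area_um2 > min_area
  drop_labels <- aggs$table$label[!keep]
  lab <- aggs$labels
  if (length(drop_labels))
    lab[lab %in% drop_labels] <- 0L
  structure(list(labels = lab, table = aggs$table[keep, , drop = FALSE],
                 pixel_size = aggs$pixel_size, min_area_um2 = min_area),
            class = "aggregate_set")
}

#' Normalized radial aggregation profile
#'
#' For each annular subregion, `A_C` is the white-pixel area (um^2) of the
#' surviving aggregates falling in that annulus — components straddling an
#' annulus edge contribute per pixel to each side — and the normalized cluster
#' fraction is `P1 = (A_C / A_T) / dr_norm`, with `A_T` the in-bounds annulus
#' area and `dr_norm = dr / R = 0.1` the dimensionless radial step, making
#' `P1` comparable across droplets of different sizes.
#'
#' @param aggs a (filtered) [aggregate_set][label_aggregates()].
#' @param subregions a [build_subregions()] result.
#' @param boundary a [build_boundary()] result.
#' @return Data frame of class `aggregation_profile`: `annulus`, `side`,
#'   `r_over_R_mid`, `A_C_um2`, `A_T_um2`, `P1`.
#' @export
aggregation_profile <- function(aggs, subregions, boundary) {
  stopifnot(inherits(aggs, "aggregate_set"), inherits(subregions, "subregion_set"))
  tbl <- subregions$table
  keep <- tbl$area_um2 > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " annulus/annuli with zero in-bounds area")
    tbl <- tbl[keep, , drop = FALSE]
  }
  white <- aggs$labels > 0L
  code <- subregions$code
  cnt <- tabulate(code[white] + 1L, nbins = max(tbl$annulus) + 1L)
  a_c <- cnt[tbl$annulus + 1L] * aggs$pixel_size^2
  out <- data.frame(
    annulus = tbl$annulus, side = tbl$side, r_over_R_mid = tbl$r_over_R_mid,
    A_C_um2 = a_c, A_T_um2 = tbl$area_um2,
    P1 = (a_c / tbl$area_um2) / subregions$dr_norm)
  class(out) <- c("aggregation_profile", "data.frame")
  out
}

#' Total fraction of aggregated bacteria outside the droplet
#'
#' The total white-pixel area in the exterior region (outside the middle
#' boundary, in-bounds) divided by the total area of that region. Following
#' the measurement definition, this uses all white pixels of the binarized
#' frame, not only the size-filtered aggregates; pass a filtered mask for a
#' sensitivity variant.
#'
#' @param mask a [binarize()] result.
#' @param boundary a [build_boundary()] result.
#' @param subregions a [build_subregions()] result.
#' @return Fraction in `[0, 1]`.
#' @export
total_exterior_fraction <- function(mask, boundary, subregions) {
  stopifnot(inherits(mask, "binary_mask"), inherits(subregions, "subregion_set"))
  ext <- !is.na(subregions$code) & subregions$code >= 10L
  n_ext <- sum(ext)
  if (n_ext == 0L) stop("no in-bounds exterior area")
  sum(mask$mask[ext]) / n_ext
}
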