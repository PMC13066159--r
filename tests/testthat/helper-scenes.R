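# Shared scene configurations used across test files. Small quarter-field
# scenes (512 px at 2 um/px, droplet center near a corner, full 916 um
# droplet radius) mirror the acquisition geometry at test-friendly size;
# tiny scenes (160 px, 120 um droplet) are for fast structural checks.

quarter_scene_params <- function(..., preset = scene_params) {
  do.call(preset, utils::modifyList(
    list(image_shape = c(512L, 512L), pixel_size = 2,
         droplet_center = c(20, 20), n_frames = 1L, t_start = 120),
    list(...)))
}

tiny_scene_params <- function(...) {
  do.call(scene_params, utils::modifyList(
    list(image_shape = c(160L, 160L), pixel_size = 2, droplet_radius = 120,
         boundary_modes = list(c(2, 2), c(3, 1.5)),
         exterior_density = 0.02, aggregate_count = 6L,
         aggregate_area_law = c(log(40), 0.4), n_frames = 1L),
    list(...)))
}

# A circular-boundary variant: boundary modes effectively zero so the
# closed-form radial expectation is exact in ring coordinates.
circular_scene_params <- function(...) {
  quarter_scene_params(boundary_modes = list(c(2, 1e-9)), ...)
}

analysis_config_synthetic <- function(...) {
  analysis_config(subtract_bg = FALSE, ...)
}

# Regular-polygon annotation approximating a circle (radius um, center px).
circle_annotation <- function(radius_um, center_px, pixel_size, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  boundary_annotation(cbind(center_px[1] + radius_um / pixel_size * cos(th),
                            center_px[2] + radius_um / pixel_size * sin(th)))
}

# Analytic disc-in-annulus configuration: droplet with r_middle = 300 um
# (dr = 30 um), one white disc of area 565.49 um^2 (radius 0.447 dr) centered
# in interior annulus 2 ([60, 90) um), so that A_C/A_T = 0.04 and P1 = 0.4
# analytically. Returns the measured values at the given pixel size.
disc_in_annulus_case <- function(ps) {
  n <- as.integer(660 / ps)
  ctr <- rep((n - 1) / 2, 2)
  b <- build_boundary(circle_annotation(300, ctr, ps), ps)
  rings <- build_rings(b, c(n, n))
  sub <- build_subregions(b, rings)
  rad_um <- 30 * sqrt(0.2)                  # disc area = 0.04 * annulus area
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  d <- sqrt((xs - (ctr[1] + 75 / ps))^2 + (ys - ctr[2])^2) * ps
  m <- d <= rad_um
  mk <- structure(list(mask = m, threshold_used = 0.5, pixel_size = ps),
                  class = "binary_mask")
  prof <- aggregation_profile(filter_by_area(label_aggregates(mk, b), 27),
                              sub, b)
  list(p1 = prof$P1[prof$annulus == 2L],
       frac = prof$A_C_um2[prof$annulus == 2L] /
         prof$A_T_um2[prof$annulus == 2L],
       others = prof$P1[prof$annulus != 2L])
}

# Hand-built radial_profile data frame (for direct fit tests).
make_profile <- function(r_um, intensity, R = max(r_um), pixel_size = 1) {
  out <- data.frame(r_px = r_um / pixel_size, r_um = r_um,
                    r_over_R = r_um / R, intensity = intensity,
                    n_px = rep(100L, length(r_um)))
  class(out) <- c("radial_profile", "data.frame")
  out
}
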