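#' Synthetic scene parameters
#'
#' Describes one synthetic fluorescence time-lapse of a mucus droplet meeting
#' a suspension of motile fluorescent bacteria. Defaults mirror the reference
#' acquisition: 2048 x 2048 px frames at 1.3 um/px (5X objective on a 6.5 um
#' sensor pitch), one frame every 2 minutes, a roughly circular droplet of
#' 916 um radius perturbed by low-order cosine harmonics.
#'
#' The rendered bacterial signal is built so that the expected radial
#' intensity has a closed form: an exterior plateau
#' `exterior_density * pixel_size^2 * per_bacterium_intensity` (per pixel),
#' a half-Gaussian interface accumulation layer of amplitude
#' `interface_peak_amplitude` and width `interface_peak_width` whose maximum
#' sits on the droplet boundary and which extends outward only (bacteria that
#' cannot cross the boundary pile up on its exterior side), and an
#' interior exponential decay
#' `B_true + A_true * exp(-s / lambda_p(t))` with `s` the inward distance from
#' the boundary (um). With `shot_noise = TRUE` the signal is realized as
#' discrete Poisson point emitters of intensity `per_bacterium_intensity`
#' whose rate reproduces that expectation; with `shot_noise = FALSE` the
#' deterministic expected field is rendered. Aggregates are filled discs of
#' intensity `aggregate_intensity`, with lognormal areas and a radial
#' placement law selected by `aggregate_radial_mode`:
#' `"exterior_peaked"` concentrates aggregates just outside the middle
#' boundary (the low-penetration phenotype), `"interior_peaked"` just inside
#' it (the high-penetration phenotype). Frames are digitized to integer
#' camera counts in `[0, 65535]`.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param droplet_center `(x, y)` in px (0-based pixel centers).
#' @param droplet_radius mean droplet radius, um.
#' @param boundary_modes list of `c(k, amplitude_um)` cosine perturbations of
#'   the boundary radius (phases drawn from the seed).
#' @param interface_peak_amplitude,interface_peak_width half-Gaussian
#'   interface accumulation-layer height (counts) and width (um).
#' @param interior_offset,interior_amplitude `B_true` and `A_true` (counts).
#' @param lambda_p_schedule function `t (min) -> lambda_p (um)`, positive and
#'   non-decreasing over the generated times; see
#'   [lambda_schedule_saturating()].
#' @param exterior_density bacteria per um^2 in the suspension.
#' @param per_bacterium_intensity counts contributed by one bacterium.
#' @param aggregate_count number of aggregates to place.
#' @param aggregate_area_law `c(meanlog, sdlog)` of the lognormal disc-area
#'   law, areas in um^2.
#' @param aggregate_radial_mode `"exterior_peaked"` or `"interior_peaked"`.
#' @param aggregate_intensity counts added inside an aggregate disc.
#' @param shot_noise realize the bacterial signal as Poisson emitters.
#' @param read_noise_sd Gaussian read noise, counts (0 = off).
#' @param illumination_base flat illumination level, counts.
#' @param illumination_tilt `(per-px-x, per-px-y)` linear illumination
#'   gradient, counts per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 1).
#' @param t_start acquisition time of the first frame, min.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(2048L, 2048L),
                         pixel_size = 1.3,
                         droplet_center = NULL,
                         droplet_radius = 916,
                         boundary_modes = list(c(2, 12), c(3, 8)),
                         interface_peak_amplitude = 300,
                         interface_peak_width = 12,
                         interior_offset = 5,
                         interior_amplitude = 400,
                         lambda_p_schedule = lambda_schedule_saturating(50),
                         exterior_density = 0.05,
                         per_bacterium_intensity = 1200,
                         aggregate_count = 60L,
                         aggregate_area_law = c(log(60), 0.5),
                         aggregate_radial_mode = c("exterior_peaked",
                                                   "interior_peaked"),
                         aggregate_intensity = 1500,
                         shot_noise = TRUE,
                         read_noise_sd = 3,
                         illumination_base = 100,
                         illumination_tilt = c(0, 0),
                         frame_interval = 2,
                         n_frames = 1L,
                         t_start = 0,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            droplet_center = droplet_center, droplet_radius = droplet_radius,
            boundary_modes = boundary_modes,
            interface_peak_amplitude = interface_peak_amplitude,
            interface_peak_width = interface_peak_width,
            interior_offset = interior_offset,
            interior_amplitude = interior_amplitude,
            lambda_p_schedule = lambda_p_schedule,
            exterior_density = exterior_density,
            per_bacterium_intensity = per_bacterium_intensity,
            aggregate_count = as.integer(aggregate_count),
            aggregate_area_law = aggregate_area_law,
            aggregate_radial_mode = match.arg(aggregate_radial_mode),
            aggregate_intensity = aggregate_intensity,
            shot_noise = isTRUE(shot_noise), read_noise_sd = read_noise_sd,
            illumination_base = illumination_base,
            illumination_tilt = illumination_tilt,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            t_start = t_start, seed = as.integer(seed))
  if (is.null(p$droplet_center))
    p$droplet_center <- (rev(p$image_shape) - 1) / 2
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  stopifnot(length(p$image_shape) == 2L, all(p$image_shape >= 8L))
  if (p$pixel_size <= 0) stop("pixel_size must be > 0")
  if (p$droplet_radius <= 0) stop("droplet_radius must be > 0")
  amp_ok <- all(vapply(p$boundary_modes, function(m) m[2] >= 0, logical(1)))
  if (!amp_ok) stop("boundary mode amplitudes must be >= 0")
  stopifnot(p$interface_peak_amplitude >= 0, p$interface_peak_width > 0,
            p$interior_offset >= 0, p$interior_amplitude >= 0,
            p$exterior_density >= 0, p$per_bacterium_intensity > 0,
            p$aggregate_count >= 0, p$aggregate_intensity >= 0,
            p$read_noise_sd >= 0, p$n_frames >= 1L, p$frame_interval > 0)
  tt <- p$t_start + (seq_len(p$n_frames) - 1L) * p$frame_interval
  lp <- vapply(tt, p$lambda_p_schedule, numeric(1))
  if (any(lp <= 0)) stop("lambda_p_schedule must be positive at all frame times")
  if (any(diff(lp) < 0)) stop("lambda_p_schedule must be non-decreasing in t")
  invisible(p)
}

#' Saturating penetration-length schedule
#'
#' `lambda_p(t) = lambda0 + (lambda_inf - lambda0) * (1 - exp(-t / tau))`:
#' penetration accumulates from a small floor `lambda0` toward the plateau
#' `lambda_inf`. Positive and non-decreasing for all `t >= 0`.
#'
#' @param lambda_inf plateau penetration length, um.
#' @param tau time constant, min.
#' @param lambda0 floor at `t = 0`, um (> 0 so the length is always defined).
#' @return A function `t (min) -> lambda_p (um)`.
#' @export
lambda_schedule_saturating <- function(lambda_inf, tau = 40, lambda0 = 5) {
  force(lambda_inf); force(tau); force(lambda0)
  function(t) lambda0 + (lambda_inf - lambda0) * (1 - exp(-t / tau))
}

#' Constant penetration-length schedule
#' @param lambda_p constant penetration length, um.
#' @return A function `t -> lambda_p`.
#' @export
lambda_schedule_constant <- function(lambda_p) {
  force(lambda_p)
  function(t) rep_len(lambda_p, length(t))
}

#' Phenotype presets for the scene generator
#'
#' `preset_suckling()`: low penetration (`lambda_inf = 37` um) with
#' exterior-peaked aggregation and a strong exterior interface accumulation
#' layer — bacteria pile up and aggregate just outside the droplet boundary.
#' `preset_weaned()`: high penetration (`lambda_inf = 115` um) with
#' interior-peaked aggregation and only a weak exterior layer (bacteria swim
#' in instead of accumulating). The plateau values are the two group means of
#' the phenotypes the generator emulates at T = 120 min; both presets are
#' plain parameter sets and fully overridable.
#'
#' @param ... overrides forwarded to [scene_params()].
#' @return A `scene_params` object.
#' @export
preset_suckling <- function(...) {
  args <- list(lambda_p_schedule = lambda_schedule_saturating(37),
               aggregate_radial_mode = "exterior_peaked",
               interface_peak_amplitude = 600)
  do.call(scene_params, utils::modifyList(args, list(...)))
}

#' @rdname preset_suckling
#' @export
preset_weaned <- function(...) {
  args <- list(lambda_p_schedule = lambda_schedule_saturating(115),
               aggregate_radial_mode = "interior_peaked",
               interface_peak_amplitude = 150)
  do.call(scene_params, utils::modifyList(args, list(...)))
}

#' Generate a synthetic droplet/suspension time-lapse with ground truth
#'
#' Renders `n_frames` frames per the model described in [scene_params()] and
#' returns both the stack and a full ground-truth record: the boundary
#' polygon (360 vertices of the perturbed circle, px), the true
#' `lambda_p` per frame, the aggregate catalog (centers, areas, side flags
#' relative to the middle boundary derived from the polygon) and the
#' closed-form expected intensity as a function of inward distance.
#'
#' @param params a [scene_params()] object.
#' @return List with elements `stack` (a [timelapse()]) and `truth`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_local_seed(params$seed, render_scene(params))
}

render_scene <- function(p) {
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  ps <- p$pixel_size
  ctr <- p$droplet_center
  # boundary shape: R_b(theta) = R + sum_k a_k cos(k theta + phi_k)
  phases <- stats::runif(length(p$boundary_modes), 0, 2 * pi)
  radius_at <- function(theta) {
    r <- rep(p$droplet_radius, length(theta))
    for (i in seq_along(p$boundary_modes)) {
      m <- p$boundary_modes[[i]]
      r <- r + m[2] * cos(m[1] * theta + phases[i])
    }
    r
  }
  theta_v <- seq(0, 2 * pi, length.out = 361L)[-361L]
  verts <- cbind(x_px = ctr[1] + radius_at(theta_v) / ps * cos(theta_v),
                 y_px = ctr[2] + radius_at(theta_v) / ps * sin(theta_v))
  truth_boundary <- build_boundary(boundary_annotation(verts), ps)

  # per-pixel geometry (um): signed inward distance from the boundary
  xg <- matrix(rep(0:(nc - 1), each = nr), nr) - ctr[1]
  yg <- matrix(rep(0:(nr - 1), times = nc), nr) - ctr[2]
  d_um <- sqrt(xg^2 + yg^2) * ps
  s_um <- radius_at(atan2(yg, xg)) - d_um    # > 0 inside the droplet

  illum <- p$illumination_base + p$illumination_tilt[1] * (xg + ctr[1]) +
    p$illumination_tilt[2] * (yg + ctr[2])

  plateau <- p$exterior_density * ps^2 * p$per_bacterium_intensity
  inside <- s_um > 0
  # accumulation layer outside the boundary only; maximum on the boundary
  bump <- ifelse(inside, 0,
                 p$interface_peak_amplitude *
                   exp(-s_um^2 / (2 * p$interface_peak_width^2)))

  agg <- place_aggregates(p, ctr, truth_boundary, nr, nc)
  agg_img <- agg$image

  tt <- p$t_start + (seq_len(p$n_frames) - 1L) * p$frame_interval
  lambda_true <- vapply(tt, p$lambda_p_schedule, numeric(1))
  frames <- vector("list", p$n_frames)
  for (k in seq_len(p$n_frames)) {
    expected <- bump
    expected[inside] <- expected[inside] + p$interior_offset +
      p$interior_amplitude * exp(-s_um[inside] / lambda_true[k])
    expected[!inside] <- expected[!inside] + plateau
    bact <- if (p$shot_noise) {
      counts <- stats::rpois(length(expected),
                             pmax(expected, 0) / p$per_bacterium_intensity)
      matrix(counts * p$per_bacterium_intensity, nr, nc)
    } else expected
    img <- illum + bact + agg_img
    if (p$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, p$read_noise_sd)
    img <- pmin(pmax(round(img), 0), 65535)
    frames[[k]] <- calibrated_frame(img, ps, t = tt[k],
                                    source_id = sprintf("scene-seed%d", p$seed))
  }
  expected_field <- local({
    A <- p$interior_amplitude; B <- p$interior_offset
    amp <- p$interface_peak_amplitude; w <- p$interface_peak_width
    plt <- plateau; sched <- p$lambda_p_schedule
    function(s, t) {
      ifelse(s > 0, B + A * exp(-s / sched(t)),
             amp * exp(-s^2 / (2 * w^2)) + plt)
    }
  })
  list(stack = timelapse(frames, p$frame_interval),
       truth = list(boundary_polygon = verts, boundary = truth_boundary,
                    t_min = tt, lambda_p = lambda_true,
                    aggregates = agg$catalog, expected_field = expected_field,
                    plateau = plateau, params = p))
}

# Sample aggregate discs (lognormal areas; radial law set by the phenotype
# mode), render them into an intensity image and catalog them. Discs must lie
# fully inside the image; placement is rejection-sampled.
place_aggregates <- function(p, ctr, truth_boundary, nr, nc) {
  img <- matrix(0, nr, nc)
  n <- p$aggregate_count
  cat_df <- data.frame(x_px = numeric(0), y_px = numeric(0),
                       area_um2 = numeric(0), r_um = numeric(0),
                       inside = logical(0))
  if (n == 0L) return(list(image = img, catalog = cat_df))
  ps <- p$pixel_size
  r_mid <- truth_boundary$r_middle
  dr <- r_mid / 10
  areas <- stats::rlnorm(n, p$aggregate_area_law[1], p$aggregate_area_law[2])
  disc_r_px <- sqrt(areas / pi) / ps
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      off <- switch(p$aggregate_radial_mode,
        exterior_peaked = stats::rnorm(1, 0.6 * dr, 0.8 * dr),      # outward +
        interior_peaked = -(0.1 * dr + abs(stats::rnorm(1, 0, 1.8 * dr))))
      r_c <- r_mid + off
      if (r_c <= 0) next
      th <- stats::runif(1, 0, 2 * pi)
      xc <- ctr[1] + r_c / ps * cos(th)
      yc <- ctr[2] + r_c / ps * sin(th)
      rr <- disc_r_px[i]
      if (xc - rr < 0 || xc + rr > nc - 1 || yc - rr < 0 || yc + rr > nr - 1)
        next
      cols <- max(1L, floor(xc - rr) + 1L):min(nc, ceiling(xc + rr) + 1L)
      rows <- max(1L, floor(yc - rr) + 1L):min(nr, ceiling(yc + rr) + 1L)
      sub_x <- matrix(rep(cols - 1L, each = length(rows)), length(rows)) - xc
      sub_y <- matrix(rep(rows - 1L, times = length(cols)), length(rows)) - yc
      hit <- sub_x^2 + sub_y^2 <= rr^2
      img[rows, cols][hit] <- img[rows, cols][hit] + p$aggregate_intensity
      cat_df <- rbind(cat_df, data.frame(
        x_px = xc, y_px = yc, area_um2 = areas[i], r_um = r_c,
        inside = r_c < r_mid))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("aggregate %d could not be placed within image bounds after 200 attempts", i))
  }
  list(image = img, catalog = cat_df)
}

#' Generate an inert-bead control scene
#'
#' As [generate_scene()], but the particles are passive: they neither
#' penetrate the droplet nor accumulate at its interface, so the interior
#' intensity and the interface bump are zero at all times and only the
#' exterior suspension plateau is rendered (`A_true = 0`, `B_true = 0`,
#' no aggregates). The true `lambda_p` is undefined (`NA`): there is no decay
#' to fit, and the analysis pipeline flags the fit accordingly.
#'
#' @param params a [scene_params()] object.
#' @return List with `stack` and `truth` (with `lambda_p = NA`).
#' @export
generate_bead_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  p$interior_amplitude <- 0
  p$interior_offset <- 0
  p$interface_peak_amplitude <- 0
  p$aggregate_count <- 0L
  out <- with_local_seed(p$seed, render_scene(p))
  out$truth$lambda_p <- rep(NA_real_, length(out$truth$lambda_p))
  out
}
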