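#' Radial intensity profile
#'
#' For each 1-px-spaced concentric ring, the intensity is the sum of the ring's
#' in-bounds pixel values divided by the number of in-bounds pixels at that
#' radius. The profile is reported against radius in micrometres and against
#' the dimensionless `r/R` with `R` the droplet radius (middle boundary).
#'
#' @param frame a [calibrated_frame()].
#' @param rings a [build_rings()] result computed on this frame's geometry.
#' @param boundary the [build_boundary()] result (for `R`).
#' @return A data frame of class `radial_profile` with columns `r_px`, `r_um`,
#'   `r_over_R`, `intensity`, `n_px`.
#' @export
radial_profile <- function(frame, rings, boundary) {
  stopifnot(inherits(frame, "calibrated_frame"), inherits(rings, "ring_set"),
            inherits(boundary, "droplet_boundary"))
  if (!all(dim(frame$intensities) == rings$image_shape))
    stop("frame shape does not match the ring set")
  sums <- rowsum(as.vector(frame$intensities), as.vector(rings$ring_px),
                 reorder = TRUE)
  radii <- as.integer(rownames(sums))
  counts <- rings$counts[match(radii, rings$radii_px)]
  out <- data.frame(
    r_px = radii,
    r_um = radii * frame$pixel_size,
    r_over_R = radii * frame$pixel_size / boundary$R,
    intensity = as.vector(sums) / counts,
    n_px = counts)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Locate the interface peak of a radial profile
#'
#' The peak is the argmax of the profile intensity over radii up to the outer
#' boundary `r_outer`. Ties break toward the largest radius: the peak sits at
#' the droplet interface, so the outermost candidate is the physical one.
#'
#' @param profile a [radial_profile()].
#' @param boundary the [build_boundary()] result.
#' @return Peak radius `r_peak` in micrometres.
#' @export
locate_peak <- function(profile, boundary) {
  adm <- profile$r_um <= boundary$r_outer
  if (!any(adm)) stop("no profile points inside r_outer")
  r <- profile$r_um[adm]; y <- profile$intensity[adm]
  cand <- which(y >= max(y) - 0)            # exact ties
  max(r[cand])
}

#' Fit the penetration decay and extract the penetration length
#'
#' Fits `y(x) = A * exp(-lambda * x) + B` by bounded nonlinear least squares
#' to the portion of the radial profile extending inward from the peak, with
#' `x = r_peak - r >= 0` (micrometres, down to the innermost in-bounds ring)
#' and constraints `A >= 0`, `lambda > 0`, `B >= 0`. The penetration length is
#' `lambda_p = 1 / lambda`, the characteristic inward decay length of the
#' bacterial fluorescence.
#'
#' Initialization: `B0 = min(y)`, `A0 = y(0) - B0`, `lambda0 = ln 2 / x_half`
#' (first half-amplitude crossing). The fit is flagged not-ok (`fit_ok =
#' FALSE`, `lambda_p = NA`) when the profile has no decaying amplitude, the
#' optimizer fails, the fit quality `r_squared` falls below `r2_min`,
#' `lambda` ends on its lower bound, or the fitted `lambda_p` is below the
#' profile's radial spacing (a decay shorter than one ring cannot be resolved
#' and indicates a step artifact, e.g. passive particles piled outside the
#' boundary); these quality gates are configurable.
#'
#' @param profile a [radial_profile()].
#' @param r_peak peak radius in micrometres, from [locate_peak()].
#' @param r2_min minimum coefficient of determination to accept a fit.
#' @param min_points minimum number of profile points inward of the peak
#'   (fewer is an error, as distinct from a fit failure).
#' @return An object of class `penetration_fit`: `A`, `lambda` (1/um), `B`,
#'   `lambda_p` (um), `r_peak`, `n_points`, `r_squared`, `fit_ok`, `reason`.
#' @export
fit_penetration <- function(profile, r_peak, r2_min = 0.2, min_points = 5L) {
  sel <- profile$r_um <= r_peak
  x <- r_peak - profile$r_um[sel]
  y <- profile$intensity[sel]
  o <- order(x); x <- x[o]; y <- y[o]
  if (length(x) < min_points)
    stop(sprintf("need at least %d profile points inward of the peak, got %d",
                 min_points, length(x)))
  res <- list(A = NA_real_, lambda = NA_real_, B = NA_real_,
              lambda_p = NA_real_, r_peak = r_peak, n_points = length(x),
              r_squared = NA_real_, fit_ok = FALSE, reason = "")
  class(res) <- "penetration_fit"
  B0 <- min(y); A0 <- y[1] - B0
  if (A0 <= 0 || stats::sd(y) == 0) {
    res$reason <- "no decaying amplitude"
    return(res)
  }
  half <- which(y <= B0 + A0 / 2 & x > 0)
  lam0 <- if (length(half)) log(2) / x[half[1]] else 2 / max(x)
  lam_lower <- 1e-8
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-lam * x) + B,
                      start = list(A = A0, lam = lam0, B = B0),
                      lower = c(A = 0, lam = lam_lower, B = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res$reason <- "optimizer failed"
    return(res)
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  res$A <- unname(cf["A"]); res$lambda <- unname(cf["lam"])
  res$B <- unname(cf["B"])
  res$r_squared <- 1 - rss / tss
  spacing <- min(diff(x))
  if (res$lambda <= 2 * lam_lower) {
    res$reason <- "lambda on lower bound"
  } else if (1 / res$lambda < spacing) {
    res$reason <- sprintf("decay below radial resolution (%.3g um)", spacing)
  } else if (res$r_squared < r2_min) {
    res$reason <- sprintf("r_squared %.3f < %.2f", res$r_squared, r2_min)
  } else {
    res$fit_ok <- TRUE
    res$lambda_p <- 1 / res$lambda
  }
  res
}

#' @export
print.penetration_fit <- function(x, ...) {
  if (x$fit_ok)
    cat(sprintf("<penetration_fit> lambda_p = %.2f um (A = %.3g, B = %.3g, r2 = %.3f)\n",
                x$lambda_p, x$A, x$B, x$r_squared))
  else
    cat(sprintf("<penetration_fit> not ok (%s)\n", x$reason))
  invisible(x)
}

#' Penetration length over time for a time-lapse stack
#'
#' Geometry (rings, subregions) is derived once from the boundary annotated on
#' the first frame and reused for every frame, as the droplet is static. Each
#' frame is optionally background-subtracted, profiled, and fitted; per-frame
#' failures are reported as flagged rows, never abort the series.
#'
#' @param stack a [timelapse()].
#' @param boundary a [build_boundary()] result (annotation drawn at T = 0).
#' @param subtract_bg subtract the rolling-ball background before profiling.
#' @param ball_radius_px background ball radius, pixels.
#' @param r2_min,min_points fit quality gates, see [fit_penetration()].
#' @return Data frame with one row per frame: `t_min`, `lambda_p_um`,
#'   `fit_ok`, `r_squared`, `r_peak_um`, `A`, `B`.
#' @export
lambda_timeseries <- function(stack, boundary, subtract_bg = TRUE,
                              ball_radius_px = 50L, r2_min = 0.2,
                              min_points = 5L) {
  stopifnot(inherits(stack, "timelapse"), inherits(boundary, "droplet_boundary"))
  rings <- build_rings(boundary, dim(stack$frames[[1]]$intensities))
  rows <- lapply(stack$frames, function(fr) {
    out <- tryCatch({
      if (subtract_bg) fr <- subtract_background(fr, ball_radius_px)
      prof <- radial_profile(fr, rings, boundary)
      rp <- locate_peak(prof, boundary)
      fit <- fit_penetration(prof, rp, r2_min = r2_min, min_points = min_points)
      data.frame(t_min = fr$t, lambda_p_um = fit$lambda_p, fit_ok = fit$fit_ok,
                 r_squared = fit$r_squared, r_peak_um = fit$r_peak,
                 A = fit$A, B = fit$B)
    }, error = function(e)
      data.frame(t_min = fr$t, lambda_p_um = NA_real_, fit_ok = FALSE,
                 r_squared = NA_real_, r_peak_um = NA_real_,
                 A = NA_real_, B = NA_real_))
    out
  })
  do.call(rbind, rows)
}
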