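#' Default analysis configuration
#'
#' Every knob the measurement procedure leaves open, with its default:
#' rolling-ball radius 50 px, 256 histogram bins, 27 um^2 aggregate size
#' threshold, fit gates (`r_squared >= 0.2`, at least 5 profile points).
#' `subtract_bg = FALSE` is appropriate for synthetic frames rendered with
#' flat illumination, where there is no background to remove.
#'
#' @param ... overrides of the defaults.
#' @return Named list of analysis settings.
#' @export
analysis_config <- function(...) {
  cfg <- list(subtract_bg = TRUE, ball_radius_px = 50L, hist_bins = 256L,
              min_area_um2 = 27, r2_min = 0.2, min_points = 5L)
  utils::modifyList(cfg, list(...))
}

#' Analyze one droplet time-lapse
#'
#' Runs the full measurement chain on one stack: boundary geometry from the
#' T = 0 annotation (centroid, inscribed/circumscribed/middle circles, rings,
#' annular subregions), the penetration-length time series, and — on the
#' final frame — Triangle binarization, 8-connected aggregate labeling with
#' the size threshold, the normalized radial aggregation profile `P1` and the
#' total exterior aggregated fraction.
#'
#' @param stack a [timelapse()].
#' @param annotation a [boundary_annotation()] drawn on the first frame.
#' @param config an [analysis_config()].
#' @return List: `lambda` (per-frame table), `aggregation` (per-annulus
#'   table), `exterior_fraction`, `boundary`, `qc` (fit-ok rate, threshold,
#'   geometry summary).
#' @export
analyze_droplet <- function(stack, annotation, config = analysis_config()) {
  stopifnot(inherits(stack, "timelapse"),
            inherits(annotation, "boundary_annotation"))
  ps <- stack$frames[[1]]$pixel_size
  boundary <- build_boundary(annotation, ps)
  rings <- build_rings(boundary, dim(stack$frames[[1]]$intensities))
  subregions <- build_subregions(boundary, rings)
  lambda <- lambda_timeseries(stack, boundary,
                              subtract_bg = config$subtract_bg,
                              ball_radius_px = config$ball_radius_px,
                              r2_min = config$r2_min,
                              min_points = config$min_points)
  final <- stack$frames[[length(stack$frames)]]
  if (config$subtract_bg)
    final <- subtract_background(final, config$ball_radius_px)
  mask <- binarize(final, n_bins = config$hist_bins)
  aggs <- filter_by_area(label_aggregates(mask, boundary),
                         min_area = config$min_area_um2)
  profile <- aggregation_profile(aggs, subregions, boundary)
  ext_frac <- total_exterior_fraction(mask, boundary, subregions)
  list(lambda = lambda, aggregation = profile, exterior_fraction = ext_frac,
       boundary = boundary,
       qc = list(fit_ok_rate = mean(lambda$fit_ok),
                 threshold_used = mask$threshold_used,
                 n_aggregates = nrow(aggs$table),
                 r_inner_um = boundary$r_inner,
                 r_middle_um = boundary$r_middle,
                 r_outer_um = boundary$r_outer))
}

#' Analyze a manifest of droplet stacks
#'
#' Pre-flight checks that every referenced stack and boundary file exists
#' (hard error listing the missing files before any computation), then runs
#' [analyze_droplet()] per row. Per-droplet failures become flagged rows in
#' the output tables, never silent drops.
#'
#' @param manifest data frame with `file`, `boundary_file`, `group`, `sample`,
#'   `replicate` (as written by [generate_group()]).
#' @param base_dir directory the manifest paths are relative to.
#' @param pixel_size,frame_interval calibration passed to [read_timelapse()]
#'   (overridden by embedded metadata when present).
#' @param config an [analysis_config()].
#' @return List of long-format tables: `lambda_table` (one row per droplet x
#'   frame), `aggregation_table` (per droplet x annulus), `droplet_table`
#'   (per droplet: exterior fraction, geometry, error flag).
#' @export
analyze_manifest <- function(manifest, base_dir, pixel_size = NULL,
                             frame_interval = NULL,
                             config = analysis_config()) {
  need <- c("file", "boundary_file", "group", "sample", "replicate")
  stopifnot(all(need %in% names(manifest)))
  paths <- file.path(base_dir, c(manifest$file, manifest$boundary_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(basename(missing), collapse = ", "))
  lam <- list(); agg <- list(); drp <- list()
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    res <- tryCatch({
      stack <- read_timelapse(file.path(base_dir, row$file),
                              pixel_size = pixel_size,
                              frame_interval = frame_interval)
      ann <- read_boundary(file.path(base_dir, row$boundary_file))
      analyze_droplet(stack, ann, config = config)
    }, error = function(e) e)
    id <- data.frame(group = row$group, sample = row$sample,
                     replicate = row$replicate)
    if (inherits(res, "error")) {
      drp[[k]] <- cbind(id, data.frame(exterior_fraction = NA_real_,
                                       r_middle_um = NA_real_,
                                       fit_ok_rate = NA_real_,
                                       error = conditionMessage(res)))
      next
    }
    lam[[k]] <- cbind(id[rep(1, nrow(res$lambda)), , drop = FALSE], res$lambda)
    agg[[k]] <- cbind(id[rep(1, nrow(res$aggregation)), , drop = FALSE],
                      res$aggregation)
    drp[[k]] <- cbind(id, data.frame(exterior_fraction = res$exterior_fraction,
                                     r_middle_um = res$qc$r_middle_um,
                                     fit_ok_rate = res$qc$fit_ok_rate,
                                     error = ""))
  }
  bindr <- function(l) if (length(l <- Filter(Negate(is.null), l)))
    do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL
  list(lambda_table = bindr(lam), aggregation_table = bindr(agg),
       droplet_table = bindr(drp))
}

#' End-to-end synthetic experiment: simulate, analyze, test
#'
#' Generates a two-group synthetic experiment ([generate_group()]), analyzes
#' every droplet through the measurement chain, summarizes per group
#' (replicates averaged within sample, mean +/- SEM across samples), and runs
#' the exact Mann-Whitney test on the final-frame penetration lengths and on
#' the first-exterior-annulus `P1`. All tables are written to `out_dir`
#' together with a JSON echo of the configuration; the run is fully
#' determined by (configuration, seed).
#'
#' @param out_dir output directory.
#' @param n_per_group,replicates experiment design.
#' @param params_suckling,params_weaned group presets.
#' @param seed master seed.
#' @param radius_sd droplet-radius jitter, um.
#' @param config an [analysis_config()].
#' @param keep_images keep the generated TIFF stacks (default: delete after
#'   analysis, keeping only tables).
#' @return List: the three long-format tables, `summary_lambda`,
#'   `summary_P1`, `tests` (Mann-Whitney results), and the output paths.
#' @export
run_full_synthetic <- function(out_dir,
                               n_per_group = 2L, replicates = 2L,
                               params_suckling = preset_suckling(),
                               params_weaned = preset_weaned(),
                               seed = 1L, radius_sd = 96,
                               config = analysis_config(subtract_bg = FALSE),
                               keep_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  manifest <- generate_group(params_suckling, params_weaned, n_per_group,
                             replicates, img_dir, seed = seed,
                             radius_sd = radius_sd)
  res <- analyze_manifest(manifest, img_dir, config = config)
  t_final <- max(res$lambda_table$t_min)
  lam_final <- res$lambda_table[res$lambda_table$t_min == t_final, ]
  summary_lambda <- summarize_group(res$lambda_table, "t_min", "lambda_p_um")
  summary_P1 <- summarize_group(res$aggregation_table, "r_over_R_mid", "P1")
  sample_means <- function(df, col) {
    sm <- stats::aggregate(df[[col]], by = list(group = df$group,
                                                sample = df$sample),
                           FUN = function(v) mean(v, na.rm = TRUE))
    split(sm$x, sm$group)
  }
  lam_means <- sample_means(lam_final, "lambda_p_um")
  first_ext <- res$aggregation_table[res$aggregation_table$annulus == 10L, ]
  p1_means <- sample_means(first_ext, "P1")
  tests <- list(
    lambda_final = mann_whitney_exact(lam_means$suckling, lam_means$weaned),
    P1_first_exterior = mann_whitney_exact(p1_means$suckling, p1_means$weaned))
  tables <- list(lambda_p = res$lambda_table,
                 aggregation = res$aggregation_table,
                 droplets = res$droplet_table,
                 summary_lambda = summary_lambda,
                 summary_P1 = summary_P1)
  paths <- write_results(tables, out_dir)
  cfg_echo <- list(n_per_group = n_per_group, replicates = replicates,
                   seed = seed, radius_sd = radius_sd, config = config,
                   t_final = t_final)
  writeLines(as.character(jsonlite::toJSON(cfg_echo, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(out_dir, "run_config.json"))
  if (!keep_images) unlink(img_dir, recursive = TRUE)
  c(res, list(summary_lambda = summary_lambda, summary_P1 = summary_P1,
              tests = tests, sample_lambda_means = lam_means,
              sample_P1_first_exterior = p1_means,
              t_final = t_final, paths = paths, out_dir = out_dir))
}

#' Markdown QC report for a full-synthetic or manifest run
#'
#' Writes a small human-readable summary: droplet counts and failures,
#' fit-ok rates, the per-group penetration-length summary at the final time,
#' and the per-group normalized aggregation profile around the droplet
#' boundary.
#'
#' @param results a [run_full_synthetic()] result (or a compatible list of
#'   tables).
#' @param path output markdown file.
#' @return `path`, invisibly.
#' @export
qc_report <- function(results, path) {
  lines <- c("# Droplet run QC report", "")
  drp <- results$droplet_table
  if (is.null(drp) || nrow(drp) == 0L) {
    lines <- c(lines, "no droplets")
    writeLines(lines, path)
    return(invisible(path))
  }
  lines <- c(lines,
             sprintf("- droplets analyzed: %d (%d failed)", nrow(drp),
                     sum(nzchar(drp$error))),
             sprintf("- mean fit-ok rate: %.2f",
                     mean(drp$fit_ok_rate, na.rm = TRUE)), "")
  sl <- results$summary_lambda
  tf <- max(sl$t_min)
  lines <- c(lines, sprintf("## Penetration length at T = %g min", tf), "",
             "| group | mean lambda_p (um) | SEM | n |",
             "|---|---|---|---|")
  slf <- sl[sl$t_min == tf, ]
  for (i in seq_len(nrow(slf)))
    lines <- c(lines, sprintf("| %s | %.1f | %.1f | %d |", slf$group[i],
                              slf$mean[i], slf$sem[i], slf$n_samples[i]))
  sp <- results$summary_P1
  lines <- c(lines, "", "## Normalized aggregation profile P1 (mean)", "",
             "| group | r/R mid | P1 |", "|---|---|---|")
  for (i in seq_len(nrow(sp)))
    lines <- c(lines, sprintf("| %s | %.2f | %.3f |", sp$group[i],
                              sp$r_over_R_mid[i], sp$mean[i]))
  writeLines(lines, path)
  invisible(path)
}
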