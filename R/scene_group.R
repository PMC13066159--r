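#' Generate a two-group synthetic experiment on disk
#'
#' Writes `n_per_group x replicates` time-lapse stacks per group (16-bit
#' multi-page TIFF), each with its ground-truth boundary polygon as a CSV
#' vertex list and a JSON parameter sidecar, plus a manifest mapping files to
#' group/sample/replicate. Each droplet gets its own radius, drawn from
#' `N(droplet_radius, radius_sd)`, emulating droplet-to-droplet size
#' variability; every stack's seed is derived deterministically from the
#' master seed (see [derive_seed()]), so the experiment is reproducible
#' file-by-file.
#'
#' @param params_suckling,params_weaned [scene_params()] for the two
#'   phenotypes (see [preset_suckling()] / [preset_weaned()]).
#' @param n_per_group biological samples per group.
#' @param replicates technical replicates (droplets) per sample.
#' @param out_dir output directory (created; must be writable).
#' @param seed master seed.
#' @param radius_sd droplet-radius jitter SD, um.
#' @return The manifest data frame (`file`, `boundary_file`, `group`,
#'   `sample`, `replicate`, `seed`, `droplet_radius_um`), invisibly; also
#'   written as `manifest.csv` in `out_dir`.
#' @export
generate_group <- function(params_suckling, params_weaned, n_per_group,
                           replicates, out_dir, seed = 1L, radius_sd = 96) {
  stopifnot(n_per_group >= 1L, replicates >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  groups <- list(suckling = params_suckling, weaned = params_weaned)
  rows <- list()
  idx <- 0L
  for (g in names(groups)) {
    for (s in seq_len(n_per_group)) {
      for (r in seq_len(replicates)) {
        idx <- idx + 1L
        stack_seed <- derive_seed(seed, idx)
        radius <- with_local_seed(derive_seed(seed, idx + 100000L),
                                  stats::rnorm(1, groups[[g]]$droplet_radius,
                                               radius_sd))
        radius <- max(radius, 10 * groups[[g]]$pixel_size)
        p <- groups[[g]]
        p$droplet_radius <- radius
        p$seed <- stack_seed
        validate_scene_params(p)
        sc <- generate_scene(p)
        base <- sprintf("%s_s%02d_r%02d", g, s, r)
        stack_file <- paste0(base, ".tif")
        bnd_file <- paste0(base, "_boundary.csv")
        write_timelapse(sc$stack, file.path(out_dir, stack_file))
        write_boundary_csv(boundary_annotation(sc$truth$boundary_polygon),
                           file.path(out_dir, bnd_file))
        sidecar <- params_to_json(p)
        writeLines(sidecar, file.path(out_dir, paste0(base, "_params.json")))
        rows[[idx]] <- data.frame(
          file = stack_file, boundary_file = bnd_file, group = g,
          sample = s, replicate = r, seed = stack_seed,
          droplet_radius_um = radius)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Deterministic per-stack seed derivation
#'
#' Mixes the master seed and a stack index through one step of a
#' linear-congruential map modulo the Mersenne prime `2^31 - 1`:
#' `seed_i = (master * 48271 + i * 1664525 + 12345) mod (2^31 - 1)`.
#' Documented so a single stack of a generated experiment can be re-rendered
#' in isolation.
#'
#' @param master master seed (integer).
#' @param i stack index (integer).
#' @return A positive integer seed below `2^31 - 1`.
#' @export
derive_seed <- function(master, i) {
  m <- 2147483647
  as.integer((((as.double(master) %% m) * 48271 +
                 as.double(i) * 1664525 + 12345) %% m) + 1)
}

params_to_json <- function(p) {
  q <- unclass(p)
  tt <- p$t_start + (seq_len(p$n_frames) - 1L) * p$frame_interval
  q$lambda_p_schedule <- NULL
  q$lambda_p_at_frames <- vapply(tt, p$lambda_p_schedule, numeric(1))
  jsonlite::toJSON(q, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read back an experiment manifest
#' @param path `manifest.csv` written by [generate_group()].
#' @return The manifest data frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
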