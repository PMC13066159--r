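test_that("an empty noise-free scene renders exactly the illumination plane", {
  p <- tiny_scene_params(exterior_density = 0, aggregate_count = 0L,
                         shot_noise = FALSE, read_noise_sd = 0,
                         interface_peak_amplitude = 0, interior_amplitude = 0,
                         interior_offset = 0, illumination_base = 17)
  sc <- generate_scene(p)
  expect_true(all(sc$stack$frames[[1]]$intensities == 17))
})

test_that("generation is deterministic in (params, seed) and seed-sensitive", {
  p <- tiny_scene_params(seed = 5L)
  a <- generate_scene(p); b <- generate_scene(p)
  expect_identical(a$stack$frames[[1]]$intensities,
                   b$stack$frames[[1]]$intensities)
  expect_identical(a$truth$aggregates, b$truth$aggregates)
  d <- generate_scene(tiny_scene_params(seed = 6L))
  expect_false(identical(a$stack$frames[[1]]$intensities,
                         d$stack$frames[[1]]$intensities))
})

test_that("the rendered interior profile matches the closed form (brute-force binning oracle)", {
  p <- circular_scene_params(shot_noise = FALSE, read_noise_sd = 0,
                             aggregate_count = 0L,
                             lambda_p_schedule = lambda_schedule_constant(50))
  sc <- generate_scene(p)
  img <- sc$stack$frames[[1]]$intensities
  ctr <- p$droplet_center
  orc <- oracle_radial_profile(img, ctr[1], ctr[2])
  r_um <- orc$r_px * p$pixel_size
  s <- p$droplet_radius - r_um
  inner <- s > 3 * p$interface_peak_width & r_um > 0
  expected <- p$illumination_base + sc$truth$expected_field(s[inner], 120)
  rel_rms <- sqrt(mean((orc$intensity[inner] - expected)^2)) / mean(expected)
  expect_lt(rel_rms, 0.02)
})

test_that("with shot noise the total bacterial intensity is an exact emitter multiple near its expectation", {
  p <- circular_scene_params(aggregate_count = 0L, read_noise_sd = 0,
                             illumination_base = 0,
                             lambda_p_schedule = lambda_schedule_constant(40))
  sc <- generate_scene(p)
  img <- sc$stack$frames[[1]]$intensities
  total <- sum(img)
  expect_equal(total %% p$per_bacterium_intensity, 0)
  # expectation from the noise-free render of the same scene
  p0 <- circular_scene_params(aggregate_count = 0L, read_noise_sd = 0,
                              illumination_base = 0, shot_noise = FALSE,
                              lambda_p_schedule = lambda_schedule_constant(40))
  mu <- sum(generate_scene(p0)$stack$frames[[1]]$intensities)
  sd_tot <- sqrt(mu * p$per_bacterium_intensity)
  expect_lt(abs(total - mu), 4 * sd_tot)
})

test_that("changing only the seed leaves the expected radial profile stable", {
  profs <- lapply(1:20, function(s) {
    p <- circular_scene_params(aggregate_count = 0L, seed = s,
                               lambda_p_schedule = lambda_schedule_constant(60))
    sc <- generate_scene(p)
    b <- sc$truth$boundary
    rings <- build_rings(b, p$image_shape)
    radial_profile(sc$stack$frames[[1]], rings, b)$intensity
  })
  n <- min(lengths(profs))
  m <- sapply(profs, `[`, 1:n)
  mean_prof <- rowMeans(m)
  sd_prof <- apply(m, 1, sd)
  # every single-seed profile stays within 3 sd bands of the cross-seed mean
  frac_out <- mean(abs(m - mean_prof) > 3 * pmax(sd_prof, 1e-9))
  expect_lt(frac_out, 0.02)
})

test_that("aggregate catalog entries lie in bounds with side flags consistent with the middle boundary", {
  p <- tiny_scene_params(aggregate_count = 12L, seed = 3L)
  sc <- generate_scene(p)
  cat_df <- sc$truth$aggregates
  expect_equal(nrow(cat_df), 12L)
  rad_px <- sqrt(cat_df$area_um2 / pi) / p$pixel_size
  expect_true(all(cat_df$x_px - rad_px >= 0 &
                    cat_df$x_px + rad_px <= p$image_shape[2] - 1))
  expect_true(all(cat_df$y_px - rad_px >= 0 &
                    cat_df$y_px + rad_px <= p$image_shape[1] - 1))
  expect_identical(cat_df$inside,
                   cat_df$r_um < sc$truth$boundary$r_middle)
})

test_that("an unplaceable aggregate raises an error naming its index", {
  p <- tiny_scene_params(aggregate_count = 1L,
                         aggregate_area_law = c(log(4e5), 1e-6))
  expect_error(generate_scene(p), "aggregate 1")
})

test_that("the bead scene has a flat interior and the same exterior plateau as a matched bacterial scene", {
  p <- circular_scene_params(aggregate_count = 0L,
                             interface_peak_amplitude = 0, seed = 9L)
  bead <- generate_bead_scene(p)
  expect_true(all(is.na(bead$truth$lambda_p)))
  img <- bead$stack$frames[[1]]$intensities
  ctr <- p$droplet_center
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  d_um <- sqrt((matrix(rep(0:(nc - 1), each = nr), nr) - ctr[1])^2 +
                 (matrix(rep(0:(nr - 1), nc), nr) - ctr[2])^2) * p$pixel_size
  interior <- d_um < p$droplet_radius - 30
  exterior <- d_um > p$droplet_radius + 30
  expect_lt(mean(img[interior]),
            p$illumination_base + p$interior_offset + 3 * p$read_noise_sd)
  bact <- generate_scene(p)
  expect_equal(mean(img[exterior]),
               mean(bact$stack$frames[[1]]$intensities[exterior]),
               tolerance = 0.02)
})

test_that("group generation writes the full design with a roundtrippable manifest and derived seeds", {
  dir <- file.path(withr::local_tempdir(), "exp")
  ps <- tiny_scene_params()
  pw <- tiny_scene_params(aggregate_radial_mode = "interior_peaked")
  man <- generate_group(ps, pw, n_per_group = 2L, replicates = 2L,
                        out_dir = dir, seed = 31L, radius_sd = 10)
  expect_equal(nrow(man), 8L)
  expect_equal(sum(file.exists(file.path(dir, man$file))), 8L)
  expect_equal(sum(file.exists(file.path(dir, man$boundary_file))), 8L)
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(back$group, man$group)
  expect_equal(back$sample, man$sample)
  expect_equal(back$replicate, man$replicate)
  expect_equal(back$seed, man$seed)
  expect_equal(table(man$group), table(c(rep("suckling", 4), rep("weaned", 4))),
               ignore_attr = TRUE)
  # minimal design
  dir2 <- file.path(withr::local_tempdir(), "exp2")
  man2 <- generate_group(ps, pw, 1L, 1L, dir2, seed = 31L)
  expect_equal(nrow(man2), 2L)
  # deterministic seed mixing
  expect_equal(derive_seed(31L, 1L), derive_seed(31L, 1L))
  expect_false(derive_seed(31L, 1L) == derive_seed(31L, 2L))
  expect_true(all(man$seed > 0 & man$seed < 2^31))
})
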