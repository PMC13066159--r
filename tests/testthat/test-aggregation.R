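boundary_for_mask <- function(n, r_um = 10, ps = 1)
  build_boundary(circle_annotation(r_um, c((n - 1) / 2, (n - 1) / 2), ps), ps)

test_that("component labeling is 8-connected by default and matches a flood-fill oracle", {
  b <- boundary_for_mask(8)
  m <- matrix(FALSE, 8, 8); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  mk <- structure(list(mask = m, threshold_used = 0.5, pixel_size = 1),
                  class = "binary_mask")
  expect_equal(nrow(label_aggregates(mk, b)$table), 1L)
  expect_equal(nrow(label_aggregates(mk, b, connectivity = 4L)$table), 2L)

  set.seed(51)
  for (trial in 1:100) {
    m <- matrix(runif(24 * 24) < 0.35, 24, 24)
    mk <- structure(list(mask = m, threshold_used = 0.5, pixel_size = 1),
                    class = "binary_mask")
    bb <- boundary_for_mask(24)
    mine <- label_aggregates(mk, bb)
    orc <- oracle_flood_fill(m, 8L)
    expect_equal(nrow(mine$table), max(orc))
    expect_equal(sort(mine$table$n_px), sort(tabulate(orc[orc > 0L])))
    # identical partition: labels agree up to renaming
    if (max(orc) > 0)
      expect_equal(length(unique(paste(mine$labels[m], orc[m]))), max(orc))
  }
})

test_that("aggregate positions and side flags follow the middle boundary", {
  b <- boundary_for_mask(64, r_um = 20)
  m <- matrix(FALSE, 64, 64)
  m[32, 32] <- TRUE                          # at center: inside
  m[32, 62] <- TRUE                          # x = 61, distance 29.5: outside
  mk <- structure(list(mask = m, threshold_used = 0.5, pixel_size = 1),
                  class = "binary_mask")
  tab <- label_aggregates(mk, b)$table
  tab <- tab[order(tab$r_um), ]
  expect_equal(tab$inside, c(TRUE, FALSE))
  expect_equal(tab$r_um[1], sqrt(2 * 0.5^2), tolerance = 1e-9)
})

test_that("the strict 27 um^2 size filter keeps and drops the documented boundary cases", {
  # components of 15 px and 16 px at 1.3 um/px: 25.35 vs 27.04 um^2
  m <- matrix(FALSE, 32, 32)
  m[2:6, 2:4] <- TRUE                        # 15 px
  m[20:23, 20:23] <- TRUE                    # 16 px
  mk <- structure(list(mask = m, threshold_used = 0.5, pixel_size = 1.3),
                  class = "binary_mask")
  b <- boundary_for_mask(32, r_um = 15, ps = 1.3)
  aggs <- label_aggregates(mk, b)
  expect_equal(sort(aggs$table$area_um2), c(15, 16) * 1.3^2)
  kept <- filter_by_area(aggs, 27)
  expect_equal(kept$table$n_px, 16L)
  expect_equal(sum(kept$labels > 0), 16L)

  # areas {10, 27, 30} at 1 um/px: keep only 30 (strict >)
  m2 <- matrix(FALSE, 40, 40)
  m2[2:11, 2] <- TRUE                        # 10 px
  m2[2:28, 6] <- TRUE                        # 27 px
  m2[2:31, 10] <- TRUE                       # 30 px
  mk2 <- structure(list(mask = m2, threshold_used = 0.5, pixel_size = 1),
                   class = "binary_mask")
  aggs2 <- label_aggregates(mk2, boundary_for_mask(40))
  expect_equal(filter_by_area(aggs2, 27)$table$n_px, 30L)
  expect_equal(nrow(filter_by_area(aggs2, 0)$table), 3L)
  expect_error(filter_by_area(aggs2, -1), "non-negative")
})

test_that("removing the size filter can only increase per-annulus aggregate area", {
  sc <- generate_scene(tiny_scene_params(seed = 8L, aggregate_count = 10L))
  b <- sc$truth$boundary
  rings <- build_rings(b, dim(sc$stack$frames[[1]]$intensities))
  sub <- build_subregions(b, rings)
  mask <- binarize(sc$stack$frames[[1]])
  aggs <- label_aggregates(mask, b)
  p_all <- aggregation_profile(filter_by_area(aggs, 0), sub, b)
  p_flt <- aggregation_profile(filter_by_area(aggs, 27), sub, b)
  expect_true(all(p_all$A_C_um2 >= p_flt$A_C_um2))
  expect_true(sum(p_flt$A_C_um2) <=
                sum(filter_by_area(aggs, 27)$labels > 0) * b$pixel_size^2 + 1e-9)
})

test_that("a disc inside one annulus yields the analytic P1, converging under refinement", {
  res <- lapply(c(1, 0.25), function(ps) disc_in_annulus_case(ps))
  expect_equal(res[[1]]$p1, 0.4, tolerance = 0.05)
  expect_equal(res[[2]]$p1, 0.4, tolerance = 0.01)
  expect_equal(res[[1]]$frac, 0.04, tolerance = 0.05)
  expect_true(all(res[[1]]$others == 0))
  # P1 stable under uniform scene rescaling (4x finer grid)
  expect_equal(res[[1]]$p1, res[[2]]$p1, tolerance = 0.03)
})

test_that("aggregation profiles vanish without aggregates and P1 follows its definition", {
  sc <- generate_scene(tiny_scene_params(seed = 4L, aggregate_count = 0L,
                                         exterior_density = 0,
                                         interface_peak_amplitude = 0,
                                         interior_amplitude = 30,
                                         shot_noise = FALSE))
  b <- sc$truth$boundary
  rings <- build_rings(b, dim(sc$stack$frames[[1]]$intensities))
  sub <- build_subregions(b, rings)
  mask <- binarize(sc$stack$frames[[1]])
  prof <- aggregation_profile(filter_by_area(label_aggregates(mask, b), 1e9),
                              sub, b)
  expect_true(all(prof$P1 == 0))
  expect_equal(prof$P1, (prof$A_C_um2 / prof$A_T_um2) / 0.1)
})

test_that("exterior-peaked scenes place the P1 maximum in the first exterior annulus", {
  hits <- vapply(1:20, function(s) {
    sc <- generate_scene(quarter_scene_params(preset = preset_suckling,
                                              seed = s))
    res <- analyze_droplet(sc$stack,
                           boundary_annotation(sc$truth$boundary_polygon),
                           config = analysis_config_synthetic())
    am <- res$aggregation
    am$annulus[which.max(am$P1)] == 10L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the total exterior fraction is an exact pixel census with correct extremes", {
  n <- 160L
  sc <- generate_scene(tiny_scene_params(seed = 2L))
  b <- sc$truth$boundary
  rings <- build_rings(b, c(n, n))
  sub <- build_subregions(b, rings)
  all_white <- structure(list(mask = matrix(TRUE, n, n), threshold_used = 0,
                              pixel_size = 2), class = "binary_mask")
  expect_equal(total_exterior_fraction(all_white, b, sub), 1)
  none <- all_white; none$mask[] <- FALSE
  expect_equal(total_exterior_fraction(none, b, sub), 0)
  set.seed(52)
  rnd <- all_white; rnd$mask <- matrix(runif(n * n) < 0.3, n, n)
  ext <- !is.na(sub$code) & sub$code >= 10L
  expect_equal(total_exterior_fraction(rnd, b, sub),
               sum(rnd$mask & ext) / sum(ext))
})
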