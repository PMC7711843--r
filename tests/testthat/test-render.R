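test_that("a single SUV renders as a shell peaking at its outer radius", {
  sc <- suv_only_scene(matrix(c(0, 0, 0), 1), radii = 40)
  op <- optics_params(voxel_size = 1, noise_sigma = 0,
                      wedge_half_angle = 90)
  vol <- render_volume(sc, op, dims = c(100, 100, 100),
                       origin = c(-49.5, -49.5, -49.5), check_fit = FALSE)
  ax <- seq(-49.5, 49.5, by = 1)
  r <- sqrt(tomodock:::outer3(ax^2, ax^2, ax^2))
  prof <- tapply(as.numeric(vol$grid), round(r), mean)
  # at 1 nm voxels both leaflets resolve; the outer-leaflet peak is the
  # outermost local maximum of the radial profile
  rr <- as.numeric(names(prof))
  loc <- which(diff(sign(diff(prof))) == -2) + 1
  loc <- loc[prof[loc] > 0.5 * max(prof)]   # leaflet peaks, not tail ripple
  peak_r <- max(rr[loc])
  expect_lte(abs(peak_r - 40), 0.5 + 1e-9)
  # and it is a dominant peak, not a shoulder
  expect_gte(prof[as.character(peak_r)], 0.9 * max(prof))
})

test_that("the missing wedge region carries no amplitude", {
  sc <- generate_scene(scene_params(n_junctions = 1, seed = 2))
  vol <- render_volume(sc, optics_params(noise_sigma = 0), seed = 1)
  FT <- stats::fft(vol$grid)
  mask <- tomodock:::wedge_transfer(dim(vol$grid), vol$voxel_size,
                                    blur_sigma = 0, wedge_half_angle = 60)
  in_wedge <- mask == 0
  expect_true(any(in_wedge))
  expect_lte(max(Mod(FT)[in_wedge]) / max(Mod(FT)), 1e-6)
})

test_that("additive noise has the configured standard deviation", {
  sc <- generate_scene(scene_params(n_junctions = 1, seed = 3))
  dims <- c(100, 100, 100)
  v0 <- render_volume(sc, optics_params(noise_sigma = 0), dims = dims,
                      check_fit = FALSE)
  s <- 0.2
  v1 <- render_volume(sc, optics_params(noise_sigma = s), dims = dims,
                      seed = 9, check_fit = FALSE)
  d <- v1$grid - v0$grid
  expect_gte(length(d), 1e6)
  expect_equal(stats::sd(as.numeric(d)), s, tolerance = 0.05)
})

test_that("rendering is linear in scene content before noise", {
  sc2 <- generate_scene(scene_params(n_junctions = 2, seed = 5))
  guv_only <- sc2
  guv_only$junctions <- list()
  one <- sc2; one$junctions <- sc2$junctions[1]
  two <- sc2; two$junctions <- sc2$junctions[2]
  op <- optics_params(noise_sigma = 0)
  dims <- c(64, 64, 64)
  bb <- tomodock:::scene_bbox(sc2)
  origin <- (bb[, 1] + bb[, 2]) / 2 - (dims - 1) / 2 * op$voxel_size
  r_all <- render_volume(sc2, op, origin = origin, dims = dims,
                         check_fit = FALSE)
  r_guv <- render_volume(guv_only, op, origin = origin, dims = dims,
                         check_fit = FALSE)
  r1 <- render_volume(one, op, origin = origin, dims = dims,
                      check_fit = FALSE)
  r2 <- render_volume(two, op, origin = origin, dims = dims,
                      check_fit = FALSE)
  lhs <- r_all$grid
  rhs <- r1$grid + r2$grid - r_guv$grid
  expect_lte(max(abs(lhs - rhs)), 1e-6 * max(abs(lhs)))
})

test_that("oversized voxels trigger the unresolvable-features warning", {
  sc <- generate_scene(scene_params(n_junctions = 0, seed = 1))
  expect_warning(render_volume(sc, optics_params(voxel_size = 6),
                               dims = c(16, 16, 16), check_fit = FALSE),
                 "unresolvable")
})
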