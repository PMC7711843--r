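test_that("a blank volume yields no detections", {
  v <- tomo_volume(array(0, c(48, 48, 48)), voxel_size = 2.34)
  expect_identical(nrow(detect_suvs(v)), 0L)
})

test_that("three clean SUVs are recovered with accurate centres and radii", {
  centers <- rbind(c(-70, -60, 0), c(0, 40, 10), c(80, -30, -20))
  radii <- c(20, 40, 60)
  sc <- suv_only_scene(centers, radii)
  op <- optics_params(voxel_size = 2.34, noise_sigma = 0)
  vol <- render_volume(sc, op, dims = c(108, 96, 80),
                       origin = c(-125, -110, -90), check_fit = FALSE)
  det <- detect_suvs(vol)
  expect_identical(nrow(det), 3L)
  vox <- vol$voxel_size
  for (i in 1:3) {
    d <- sqrt(rowSums(sweep(as.matrix(det[, c("x", "y", "z")]), 2,
                            centers[i, ])^2))
    k <- which.min(d)
    expect_lte(d[k], vox)                      # centre within 1 voxel
    r_mid_true <- radii[i] - 2                 # bilayer midplane ridge
    expect_lte(abs(det$radius_nm[k] - r_mid_true), 2 * vox)
  }
})

test_that("shells outside the admissible radius range are not reported", {
  # small vesicle nested inside a larger-than-range shell
  sc <- suv_only_scene(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(30, 90))
  op <- optics_params(noise_sigma = 0)
  vol <- render_volume(sc, op, dims = c(96, 96, 96),
                       origin = -(c(96, 96, 96) - 1) / 2 * op$voxel_size,
                       check_fit = FALSE)
  det <- detect_suvs(vol, detection_params(suv_radius_range = c(10, 75)))
  expect_gte(nrow(det), 1L)
  expect_true(all(abs(det$radius_nm - 28) < 5))   # only the small shell
})

test_that("docking sites obey the distance cutoff and density rule", {
  # clean phantoms (no wedge, no noise) isolate the rule itself
  op <- optics_params(noise_sigma = 0, wedge_half_angle = 90)

  # SUV 60 nm from the GUV: beyond the 50 nm cutoff
  far <- forced_scene("clustered", sep = 60, seed = 2,
                      protrusion_prob_given_class = c(0, 0, 0))
  expect_length(find_docking_sites(render_junction(far, op)), 0)

  # SUV 30 nm away with no protein density: rejected
  bare <- forced_scene("clustered", sep = 30, seed = 3,
                       density_count_range = c(0, 0),
                       protrusion_prob_given_class = c(0, 0, 0))
  expect_length(find_docking_sites(render_junction(bare, op)), 0)

  # same geometry with densities: accepted
  dock <- forced_scene("clustered", sep = 25, seed = 3,
                       density_count_range = c(6, 6),
                       protrusion_prob_given_class = c(0, 0, 0))
  sites <- find_docking_sites(render_junction(dock, op))
  expect_gte(length(sites), 1)
  expect_identical(sites[[1]]$has_intermembrane_density, 1L)
})

test_that("extraction rotations are orthonormal and map the axis to +z", {
  set.seed(4)
  v <- tomo_volume(array(rnorm(40^3), c(40, 40, 40)), voxel_size = 2)
  for (i in 1:10) {
    axis <- tomodock:::unit(rnorm(3))
    site <- list(midpoint = c(39, 39, 39), docking_axis = axis)
    sub <- extract_subtomogram(v, site, detection_params(box_size = 40))
    M <- sub$metadata$rotation
    expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
    expect_equal(as.numeric(M %*% c(0, 0, 1)), axis, tolerance = 1e-9)
  }
})

test_that("extraction along +z is an exact crop", {
  set.seed(8)
  v <- tomo_volume(array(rnorm(41^3), c(41, 41, 41)), voxel_size = 2,
                   origin = c(-40, -40, -40))
  site <- list(midpoint = c(0, 0, 0), docking_axis = c(0, 0, 1))
  sub <- extract_subtomogram(v, site, detection_params(box_size = 30))
  n <- dim(sub$grid)[1]
  half <- (n - 1) / 2
  crop <- v$grid[21 + (-half:half), 21 + (-half:half), 21 + (-half:half)]
  expect_lt(max(abs(sub$grid - crop)), 1e-6)
})

test_that("an axis along +x puts the SUV on the +z axis of the box", {
  sc <- forced_scene("clustered", sep = 10, seed = 6,
                     patch_normal_tilt_max = 1e-6,
                     protrusion_prob_given_class = c(0, 0, 0))
  vol <- render_junction(sc, optics_params(noise_sigma = 0))
  site <- first_site(vol)
  expect_false(is.null(site))
  c_loc <- site$local_site$center
  expect_lte(max(abs(c_loc[1:2])), vol$voxel_size)
  expect_gt(c_loc[3], 0)
})

test_that("rigid extraction preserves blob positions across frames", {
  # localise the same blobs in world frame and in the oriented frame;
  # pairwise distances must agree within half a voxel
  sc <- forced_scene("ring_like", sep = 6, seed = 9,
                     density_count_range = c(5, 5))
  vol <- render_junction(sc, optics_params(noise_sigma = 0,
                                           wedge_half_angle = 90))
  site <- first_site(vol)
  expect_false(is.null(site))
  sub <- site$subtomogram
  M <- sub$metadata$rotation
  truth <- sc$junctions[[1]]$density_points
  loc_truth <- sweep(truth, 2, site$midpoint) %*% M
  refine <- function(grid, origin, vox, p0) {
    ci <- (p0 - origin) / vox + 1
    ii <- round(ci)
    out <- ci
    for (a in 1:3) {
      idx <- lapply(1:3, function(b) ii[b])
      prof <- vapply(-1:1, function(o) {
        idx2 <- idx; idx2[[a]] <- ii[a] + o
        grid[idx2[[1]], idx2[[2]], idx2[[3]]]
      }, 0)
      out[a] <- ci[a] + tomodock:::parabolic_offset(prof, 2) +
        (ii[a] - ci[a])
    }
    origin + (out - 1) * vox
  }
  pw <- function(p) as.numeric(dist(p))
  w_pos <- t(apply(truth, 1, function(p)
    refine(vol$grid, vol$origin, vol$voxel_size, p)))
  l_pos <- t(apply(loc_truth, 1, function(p)
    refine(sub$grid, sub$origin, sub$voxel_size, p)))
  expect_lt(max(abs(pw(w_pos) - pw(l_pos))), 0.5 * vol$voxel_size)
})

test_that("vesicle detection recall holds on noise-free and default phantoms", {
  hits <- function(noise, seeds) {
    found <- 0; fp <- 0
    for (seed in seeds) {
      sc <- generate_scene(scene_params(n_junctions = 1, seed = seed))
      vol <- render_junction(sc, optics_params(noise_sigma = noise),
                             seed = seed + 500)
      sm <- tomodock:::gauss_smooth3(vol$grid, 1)
      pl <- tryCatch(fit_guv_plane(vol, params = detection_params(),
                                   sm = sm), error = function(e) NULL)
      det <- detect_suvs(vol, exclude_plane = pl)
      truth <- sc$junctions[[1]]$suv_center
      ok <- FALSE
      for (r in seq_len(nrow(det))) {
        dd <- sqrt(sum((as.numeric(det[r, c("x", "y", "z")]) - truth)^2))
        if (dd < 8) ok <- TRUE else fp <- fp + 1
      }
      found <- found + ok
    }
    c(recall = found / length(seeds), fp_rate = fp / length(seeds))
  }
  clean <- hits(0, 1:20)
  expect_gte(clean["recall"], 0.95)
  expect_lte(clean["fp_rate"], 0.05)
  noisy <- hits(0.15, 1:12)
  expect_gte(noisy["recall"], 0.8)
})
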