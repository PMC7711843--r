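clean_op <- function() optics_params(noise_sigma = 0)

site_and_measure <- function(scene, op = clean_op(), seed = 1) {
  vol <- render_junction(scene, op, seed = seed)
  site <- first_site_nogate(vol)
  if (is.null(site)) return(NULL)
  measure_junction(site$subtomogram, site)
}

test_that("membrane separation is recovered within a voxel on phantoms", {
  errs <- c()
  for (seed in 1:8) {
    sep_true <- c(6, 9, 12, 15, 18, 21, 24, 10)[seed]
    sc <- forced_scene("clustered", sep = sep_true, seed = seed,
                       protrusion_prob_given_class = c(0, 0, 0),
                       density_count_range = c(4, 4))
    mj <- site_and_measure(sc, seed = seed)
    if (!is.null(mj) && !is.na(mj$separation))
      errs <- c(errs, abs(mj$separation - sep_true))
  }
  expect_gte(length(errs), 6)
  expect_lte(mean(errs), 2.34)         # <= 1 voxel on average
  expect_lte(max(errs), 2 * 2.34)
})

test_that("touching membranes measure zero separation", {
  sc <- forced_scene("ring_like", sep = 0, seed = 4,
                     contact_diameter_dist = list(mean = 14, sd = 1e-6,
                                                  range = c(14, 14)),
                     suv_diameter_dist = list(mean = 80, sd = 1e-6,
                                              range = c(80, 80)))
  expect_gt(sc$ground_truth$contact_diameter_nm, 0)
  mj <- site_and_measure(sc, seed = 2)
  expect_false(is.null(mj))
  expect_lte(mj$separation, 1)
})

test_that("flattened contact interfaces are sized from the gap model", {
  errs <- c()
  for (seed in c(3, 11, 21)) {
    sc <- forced_scene("ring_like", sep = 0, seed = seed,
                       contact_diameter_dist = list(mean = 16, sd = 1e-6,
                                                    range = c(16, 16)),
                       suv_diameter_dist = list(mean = 80, sd = 1e-6,
                                                range = c(80, 80)))
    mj <- site_and_measure(sc, seed = seed)
    if (!is.null(mj)) errs <- c(errs, abs(mj$contact_diameter - 16))
  }
  expect_gte(length(errs), 2)
  expect_lte(stats::median(errs), 2 * 2.34)
  # separated membranes report zero contact
  sc2 <- forced_scene("clustered", sep = 12, seed = 5,
                      protrusion_prob_given_class = c(0, 0, 0))
  mj2 <- site_and_measure(sc2, seed = 5)
  expect_identical(mj2$contact_diameter, 0)
})

test_that("protrusions are called above and not below the height threshold", {
  # flat GUV: no protrusion
  flat <- forced_scene("clustered", sep = 12, seed = 6,
                       protrusion_prob_given_class = c(0, 0, 0))
  mj <- site_and_measure(flat, seed = 6)
  expect_identical(mj$protrusion$flag, 0L)
  expect_lt(abs(mj$protrusion$height), 2)

  # ~5 nm protrusion: flagged, height within 1.5 nm. Ring-class
  # densities keep the protrusion window clear of confounding blobs.
  bump <- forced_scene("ring_like", sep = 6, seed = 7,
                       density_count_range = c(6, 6))
  jb <- bump$junctions[[1]]
  bump$guv$bumps <- data.frame(u = jb$base_uv[1], v = jb$base_uv[2],
                               height = 5, sigma = 20 / 2.355)
  bump$junctions[[1]]$suv_center <- jb$suv_center + 5 * jb$axis
  bump$junctions[[1]]$density_points <-
    sweep(jb$density_points, 2, -5 * jb$axis)
  mjb <- site_and_measure(bump, seed = 7)
  expect_identical(mjb$protrusion$flag, 1L)
  expect_lte(abs(mjb$protrusion$height - 5), 2)

  # a 2 nm bump stays below the 3 nm criterion (ring-class densities sit
  # away from the protrusion window centre, so the bump is unconfounded)
  low <- forced_scene("ring_like", sep = 6, seed = 8,
                      density_count_range = c(6, 6))
  jl <- low$junctions[[1]]
  low$guv$bumps <- data.frame(u = jl$base_uv[1], v = jl$base_uv[2],
                              height = 2, sigma = 20 / 2.355)
  low$junctions[[1]]$suv_center <- jl$suv_center + 2 * jl$axis
  low$junctions[[1]]$density_points <-
    sweep(jl$density_points, 2, -2 * jl$axis)
  mjl <- site_and_measure(low, optics_params(noise_sigma = 0,
                                             wedge_half_angle = 90),
                          seed = 8)
  expect_identical(mjl$protrusion$flag, 0L)
  expect_lt(mjl$protrusion$height, 3)
})

test_that("well-separated density blobs are found near their true positions", {
  # five blobs on a flat membrane, mutually > 2 merge radii apart
  blobs <- rbind(c(15, 0, -3), c(-12, 9, -2), c(0, -16, -4),
                 c(-5, -1, -1), c(8, 14, -3))
  fx <- plane_blob_subtomo(blobs)
  lm <- detect_density_landmarks(fx$sub, fx$site)
  expect_identical(nrow(lm), 5L)
  matched <- vapply(seq_len(nrow(lm)), function(q)
    min(sqrt((blobs[, 1] - lm$x[q])^2 + (blobs[, 2] - lm$y[q])^2)), 0)
  expect_lte(max(matched), 2)          # within one (2 nm) voxel
})

test_that("nearby blobs merge into one landmark", {
  fx <- plane_blob_subtomo(rbind(c(-1.5, 0, -3), c(1.5, 0, -3)))
  lm <- detect_density_landmarks(fx$sub, fx$site)
  expect_identical(nrow(lm), 1L)
  expect_lt(abs(lm$x), 2)
  # the same two blobs far apart stay separate
  fx2 <- plane_blob_subtomo(rbind(c(-8, 0, -3), c(8, 0, -3)))
  expect_identical(nrow(detect_density_landmarks(fx2$sub, fx2$site)), 2L)
})

test_that("blobs below the detection threshold yield no landmarks", {
  fx <- plane_blob_subtomo(rbind(c(10, 0, -3), c(-10, 5, -2)), amp = 0.04)
  lm <- detect_density_landmarks(fx$sub, fx$site)
  expect_identical(nrow(lm), 0L)
})

test_that("raising the detection threshold never increases the count", {
  site <- NULL
  for (seed in c(14, 15, 16, 17)) {
    sc <- forced_scene("intermediate", sep = 6, seed = seed,
                       density_count_range = c(10, 10))
    vol <- render_junction(sc, optics_params(noise_sigma = 0.15),
                           seed = seed + 30)
    site <- first_site_nogate(vol)
    if (!is.null(site)) break
  }
  expect_false(is.null(site))
  counts <- vapply(c(0.08, 0.12, 0.2, 0.3, 0.5), function(thr)
    nrow(detect_density_landmarks(site$subtomogram, site,
                                  metric_params(density_threshold = thr))),
    0L)
  expect_true(all(diff(counts) <= 0))
})
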