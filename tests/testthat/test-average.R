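blob_volume <- function(center, dims = c(33, 33, 33), vox = 1,
                        sigma = 2, noise = 0, seed = NULL) {
  half <- (dims - 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1 - half[a]) * vox)
  g <- exp(-tomodock:::outer3((ax[[1]] - center[1])^2,
                              (ax[[2]] - center[2])^2,
                              (ax[[3]] - center[3])^2) / (2 * sigma^2))
  if (noise > 0)
    g <- g + tomodock:::with_seed(seed, array(rnorm(prod(dims), 0, noise),
                                              dims))
  tomo_volume(g, voxel_size = vox, origin = -half * vox)
}

test_that("alignment translates the landmark to the origin", {
  v <- blob_volume(c(3, -2, 5))
  expect_identical(align_to_reference(v, c(0, 0, 0))$grid, v$grid)
  al <- align_to_reference(v, c(3, -2, 5))
  # blob now centred at the origin: central voxel is the global max
  ctr <- which(al$grid == max(al$grid), arr.ind = TRUE)[1, ]
  expect_equal(unname(ctr), c(17, 17, 17))
  expect_equal(max(al$grid), 1, tolerance = 1e-6)
  expect_error(align_to_reference(v, c(100, 0, 0)), "outside")
})

test_that("translate and untranslate round-trips within interpolation error", {
  # trilinear interpolation error scales as h^2 * f'' / 8 per pass: for a
  # smooth (sigma = 6 voxels) phantom two passes stay well under 2% of the
  # dynamic range in the interior
  v <- blob_volume(c(2.3, -1.7, 0.9), sigma = 6)
  fwd <- align_to_reference(v, c(2.3, -1.7, 0.9))
  back <- align_to_reference(fwd, -c(2.3, -1.7, 0.9))
  core <- 9:25
  rng <- diff(range(v$grid))
  expect_lt(max(abs(back$grid[core, core, core] -
                      v$grid[core, core, core])), 0.02 * rng)
})

test_that("averaging identical members reproduces the member", {
  v <- blob_volume(c(0, 0, 0))
  avg <- average_class(list(v, v, v))
  expect_equal(avg$average$grid, v$grid, tolerance = 1e-12)
  expect_identical(avg$n_subtomograms, 3L)
})

test_that("averaging is order-invariant and pools overlays", {
  vols <- lapply(1:4, function(i) blob_volume(c(0, 0, 0), noise = 0.3,
                                              seed = i))
  pts <- lapply(1:4, function(i)
    data.frame(x = rnorm(i), y = rnorm(i), z = rnorm(i)))
  a <- average_class(vols, overlay_points = pts)
  perm <- c(3, 1, 4, 2)
  b <- average_class(vols[perm], overlay_points = pts[perm])
  expect_lt(max(abs(a$average$grid - b$average$grid)), 1e-12)
  expect_identical(nrow(a$overlay_points), sum(1:4))
  expect_error(average_class(list(blob_volume(c(0, 0, 0)),
                                  blob_volume(c(0, 0, 0),
                                              dims = c(17, 17, 17)))),
               "grids")
})

test_that("averaging N noisy copies shrinks noise by sqrt(N)", {
  phantom <- blob_volume(c(0, 0, 0), sigma = 3)
  sigma <- 0.5; N <- 64
  members <- lapply(1:N, function(i)
    tomo_volume(phantom$grid +
                  tomodock:::with_seed(i, array(rnorm(length(phantom$grid)),
                                                dim(phantom$grid))) * sigma,
                voxel_size = 1, origin = phantom$origin))
  avg <- average_class(members)$average
  resid_sd <- sd(as.numeric(avg$grid - phantom$grid))
  expect_equal(resid_sd, sigma / sqrt(N), tolerance = 0.15)
})

test_that("radial profiles are flat for uniform volumes and peak on rings", {
  u <- tomo_volume(array(1, c(41, 41, 21)), voxel_size = 1,
                   origin = c(-20, -20, -10))
  pr <- radial_profile(u, z_window = c(-5, 5), max_radius = 15)
  expect_lt(diff(range(pr$density)), 1e-12)
  # ring of density at radius 12
  half <- c(20, 20, 10)
  ax <- lapply(1:3, function(a) seq_len(dim(u$grid)[a]) - 1 - half[a])
  rho <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  g <- array(0, dim(u$grid))
  for (k in 8:14) g[, , k] <- exp(-(rho - 12)^2 / 4)
  rv <- tomo_volume(g, voxel_size = 1, origin = -half)
  pr2 <- radial_profile(rv, z_window = c(-3, 3), max_radius = 18)
  expect_lte(abs(pr2$radius[which.max(pr2$density)] - 12), 1)
})
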