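ring_pts <- function(rho, theta, z = 0) {
  data.frame(x = rho * cos(theta), y = rho * sin(theta),
             z = rep_len(z, length(rho)))
}

test_that("the cylinder rule reproduces the three class definitions", {
  p <- classification_params()   # r_ex = 10, min_ring_points = 3
  inside5 <- ring_pts(runif(5, 0, 8), runif(5, 0, 2 * pi))
  expect_identical(classify_junction(inside5, params = p)$class_code, 0)
  ring6 <- ring_pts(runif(6, 15, 25), seq(0, 5) * pi / 3)
  expect_identical(classify_junction(ring6, params = p)$class_code, 1)
  mixed <- rbind(ring_pts(c(3, 6), c(0, 1)), ring_pts(runif(4, 12, 20),
                                                      runif(4, 0, 2 * pi)))
  cl <- classify_junction(mixed, params = p)
  expect_identical(cl$class_code, 0.5)
  expect_identical(cl$n_inside, 2L)
  expect_identical(cl$n_outside, 4L)
  # too few outside points for a ring call
  two_out <- ring_pts(c(15, 18), c(0, pi))
  expect_identical(classify_junction(two_out, params = p)$class_code, 0.5)
})

test_that("zero density points give an undefined, flagged class", {
  cl <- classify_junction(data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0)))
  expect_true(is.na(cl$class_code))
  expect_true(cl$flagged)
})

test_that("classification is rotation-invariant about the docking axis", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pts <- ring_pts(runif(n, 0, 25), runif(n, 0, 2 * pi),
                    z = runif(n, 0, 5))
    base <- classify_junction(pts)
    ang <- runif(1, 0, 2 * pi)
    rot <- data.frame(x = pts$x * cos(ang) - pts$y * sin(ang),
                      y = pts$x * sin(ang) + pts$y * cos(ang), z = pts$z)
    got <- classify_junction(rot)
    expect_identical(got$class_code, base$class_code)
    expect_identical(got$n_inside, base$n_inside)
    # completeness uses fixed angular bins: invariant up to one bin
    expect_lte(abs(got$ring_completeness - base$ring_completeness),
               1 / 12 + 1e-9)
  }
})

test_that("shrinking r_ex only moves classes toward ring-like", {
  set.seed(9)
  order_code <- c("0" = 1, "0.5" = 2, "1" = 3)
  for (i in 1:30) {
    n <- sample(1:15, 1)
    pts <- ring_pts(runif(n, 0, 25), runif(n, 0, 2 * pi))
    radii <- c(14, 10, 6, 3)
    codes <- vapply(radii, function(rx)
      classify_junction(pts, params = classification_params(
        exclusion_radius = rx))$class_code, 0)
    ranks <- order_code[as.character(codes)]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("ring completeness counts occupied angular bins", {
  p <- classification_params(angular_bins = 12)
  even12 <- ring_pts(rep(15, 12), (0:11) * pi / 6 + 0.01)
  expect_equal(ring_completeness(even12, params = p), 1.0)
  quadrant3 <- ring_pts(rep(15, 3), c(0.1, 0.6, 1.2))  # within one 90 deg arc
  expect_equal(ring_completeness(quadrant3, params = p), 3 / 12)
  expect_equal(ring_completeness(ring_pts(numeric(0), numeric(0)),
                                 params = p), 0)
  # inside-only points contribute nothing
  expect_equal(ring_completeness(ring_pts(c(2, 4), c(0, 2)), params = p), 0)
})
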