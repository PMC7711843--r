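test_that("scene generation is deterministic given the seed", {
  p <- scene_params(n_junctions = 4, seed = 11)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$junctions[[2]]$density_points,
                   b$junctions[[2]]$density_points)
  va <- render_volume(a, optics_params(), seed = 5)
  vb <- render_volume(b, optics_params(), seed = 5)
  expect_identical(va$grid, vb$grid)
})

test_that("an empty scene has a GUV but no junctions", {
  sc <- generate_scene(scene_params(n_junctions = 0, seed = 1))
  expect_length(sc$junctions, 0)
  expect_identical(nrow(sc$ground_truth), 0L)
  vol <- render_volume(sc, optics_params(noise_sigma = 0),
                       dims = c(32, 32, 32), check_fit = FALSE)
  expect_gt(max(vol$grid), 0.3)   # membrane is rendered
})

test_that("forced ring-like class pins code, separation and exclusion", {
  sc <- forced_scene("ring_like", sep = 2, seed = 3)
  gt <- sc$ground_truth
  expect_identical(gt$class_code, 1)
  expect_equal(gt$separation_nm, 2)
  expect_identical(sc$junctions[[1]]$n_inside, 0L)
  expect_gt(sc$junctions[[1]]$n_outside, 0L)
})

test_that("per-junction class invariants hold across seeds", {
  for (seed in 1:10) {
    sc <- generate_scene(scene_params(n_junctions = 3, seed = seed))
    for (j in sc$junctions) {
      rng <- scene_params()$separation_ranges[[j$class]]
      expect_lte(j$separation, rng[2] + 1e-9)
      if (j$class == "clustered") expect_identical(j$n_outside, 0L)
      if (j$class == "ring_like") expect_identical(j$n_inside, 0L)
      if (j$class == "intermediate") {
        expect_gte(j$n_inside, 1L)
        expect_gte(j$n_outside, 1L)
      }
      expect_identical(j$n_densities, nrow(j$density_points))
    }
  }
})

test_that("class-conditional separations are uniform within their ranges", {
  sc <- generate_scene(scene_params(n_junctions = 1000, seed = 42))
  gt <- sc$ground_truth
  ranges <- scene_params()$separation_ranges
  for (cl in c("clustered", "intermediate", "ring_like")) {
    sep <- gt$separation_nm[gt$class == cl]
    rng <- ranges[[cl]]
    expect_true(all(sep >= rng[1] - 1e-9 | sep == 0))
    expect_true(all(sep <= rng[2] + 1e-9))
    # drop snap-to-contact zeros for the distribution test
    sep <- sep[sep > 0.5]
    ks <- suppressWarnings(stats::ks.test(sep, "punif", rng[1], rng[2]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("defaults at n = 300 reproduce the per-class separation ranges", {
  sc <- generate_scene(scene_params(n_junctions = 300, seed = 42))
  gt <- sc$ground_truth
  for (cl in c("clustered", "intermediate", "ring_like")) {
    rng <- scene_params()$separation_ranges[[cl]]
    sep <- gt$separation_nm[gt$class == cl]
    expect_gte(min(sep), 0)
    expect_gte(min(sep[sep > 0]), rng[1] - 1e-9)
    expect_lte(max(sep), rng[2])
  }
})

test_that("infeasible geometry and invalid parameters are rejected", {
  expect_error(generate_scene(scene_params(n_junctions = 20,
                                           patch_radius = 50)),
               "infeasible")
  expect_error(scene_params(class_probs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(scene_params(separation_ranges =
                              list(clustered = c(5, 2),
                                   intermediate = c(3, 8),
                                   ring_like = c(0, 7))),
               "max >= min")
  expect_error(scene_params(guv_shape = "tubulated"), "tubulated")
})
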