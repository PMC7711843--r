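# Shared fixtures, built in code at test time.

# Scene with a single junction of a forced class/separation.
forced_scene <- function(class = c("clustered", "intermediate", "ring_like"),
                         sep = NULL, seed = 1, ...) {
  class <- match.arg(class)
  probs <- c(clustered = 0, intermediate = 0, ring_like = 0)
  probs[class] <- 1
  args <- list(n_junctions = 1, class_probs = probs, seed = seed, ...)
  if (!is.null(sep)) {
    ranges <- list(clustered = c(5, 26), intermediate = c(3, 8),
                   ring_like = c(0, 7))
    ranges[[class]] <- c(sep, sep)
    args$separation_ranges <- ranges
  }
  generate_scene(do.call(scene_params, args))
}

# Bare multi-SUV phantom scene (GUV patch pushed far outside any sensible
# render box), for vesicle-detection tests without a target membrane.
suv_only_scene <- function(centers, radii) {
  base <- generate_scene(scene_params(n_junctions = 0, seed = 1))
  base$guv$p0 <- c(-5000, 0, 0)
  base$junctions <- lapply(seq_len(nrow(centers)), function(i) {
    list(id = i, class = "clustered", class_code = 0,
         separation = 10, suv_diameter = 2 * radii[i],
         suv_center = centers[i, ], axis = c(1, 0, 0),
         base_uv = c(0, 0), foot = centers[i, ] - c(radii[i] + 10, 0, 0),
         contact_diameter = 0, protrusion_flag = 0L,
         protrusion_height = 0, ring_radius = 14, n_densities = 0L,
         density_points = matrix(numeric(0), 0, 3),
         density_rho = numeric(0),
         density_compartment = character(0),
         n_inside = 0L, n_outside = 0L)
  })
  base
}

# Render a one-junction scene the way the pipeline does (lateral extent
# large enough for the analysis annulus).
render_junction <- function(scene, optics = optics_params(), seed = 1,
                            min_lateral = 100) {
  bb <- tomodock:::scene_bbox(scene)
  ext <- bb[, 2] - bb[, 1]
  ext[2:3] <- pmax(ext[2:3], min_lateral)
  dims <- vapply(1:3, function(a)
    tomodock:::next_fft_size(ceiling(ext[a] / optics$voxel_size) + 1L), 1L)
  ctr <- (bb[, 1] + bb[, 2]) / 2
  origin <- ctr - (dims - 1) / 2 * optics$voxel_size
  render_volume(scene, optics, origin = origin, dims = dims, seed = seed,
                check_fit = FALSE)
}

# First analysed site of a rendered one-junction scene, or NULL.
first_site <- function(vol) {
  sites <- find_docking_sites(vol)
  if (length(sites)) sites[[1]] else NULL
}

# Site acquisition with a permissive density gate, for tests that target
# the geometric measurements rather than the docking rule itself.
first_site_nogate <- function(vol) {
  sites <- find_docking_sites(
    vol, mparams = metric_params(density_threshold = 0.02))
  if (length(sites)) sites[[1]] else NULL
}

# Minimal landmark-rule fixture: a flat membrane at local z = z0 with
# Gaussian blobs above it, and a site whose SUV lies far outside the box
# (so the detector sees a single membrane and nothing else).
plane_blob_subtomo <- function(blobs, amp = 1, z0 = -10, n = 55, vox = 2,
                               sigma = 2, noise = 0, seed = 1) {
  half <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - half) * vox
  g <- array(0, c(n, n, n))
  zprof <- exp(-(ax - (z0 - 2))^2 / (2 * 1.6^2)) +
    exp(-(ax - (z0 + 2))^2 / (2 * 1.6^2))
  for (k in seq_len(n)) g[, , k] <- zprof[k]
  for (q in seq_len(nrow(blobs))) {
    b <- blobs[q, ]
    g <- g + amp * exp(-tomodock:::outer3((ax - b[1])^2, (ax - b[2])^2,
                                          (ax - b[3])^2) / (2 * sigma^2))
  }
  if (noise > 0)
    g <- g + tomodock:::with_seed(seed,
      array(rnorm(n^3, 0, noise), dim(g)))
  sub <- tomo_volume(g, voxel_size = vox, origin = rep(-half * vox, 3))
  site <- list(local_site = list(center = c(0, 0, 120), r_mid = 20,
                                 gap = 100, guv_level = z0))
  list(sub = sub, site = site)
}
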