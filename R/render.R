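# Rendering of synthetic scenes into tomogram-like volumes.
#
# Membranes are rendered as two Gaussian leaflet shells separated by the
# bilayer thickness, protein densities as isotropic Gaussian blobs. The
# imaging model is: optics blur (Gaussian) and the missing wedge (hard
# Fourier mask) applied in Fourier space, then additive white Gaussian
# noise. The simulated tilt axis is y and the beam axis z: the missing
# wedge is the set of spatial frequencies whose (kx, kz) direction lies
# within (90 - wedge_half_angle) degrees of the kz axis, i.e. a tilt range
# of +/- wedge_half_angle about y.

#' Optical/rendering parameters for synthetic tomograms
#'
#' @param voxel_size rendered voxel size in nm. The default 2.34 nm
#'   corresponds to a 150 nm box sampled on 64 voxels, comparable to
#'   4x-binned data acquired at ~5.3 Angstrom pixels.
#' @param bilayer_thickness leaflet-peak separation in nm.
#' @param leaflet_sigma Gaussian width of each leaflet shell (nm).
#' @param blur_sigma optics blur applied in Fourier space (nm).
#' @param wedge_half_angle tilt half-range in degrees (default 60,
#'   i.e. a +/-60 degree tilt series); 90 disables the wedge.
#' @param noise_sigma standard deviation of the additive white noise, in
#'   units of the membrane peak amplitude.
#' @param density_blob_sigma Gaussian width of protein-density blobs (nm).
#' @param membrane_amplitude,density_amplitude rendered peak amplitudes.
#' @return list of class `optics_params`.
#' @export
optics_params <- function(voxel_size = 2.34,
                          bilayer_thickness = 4,
                          leaflet_sigma = 1.2,
                          blur_sigma = 1.0,
                          wedge_half_angle = 60,
                          noise_sigma = 0.15,
                          density_blob_sigma = 2.0,
                          membrane_amplitude = 1,
                          density_amplitude = 1) {
  stopifnot(voxel_size > 0, wedge_half_angle > 0, wedge_half_angle <= 90,
            noise_sigma >= 0, leaflet_sigma > 0, density_blob_sigma > 0,
            bilayer_thickness > 0, blur_sigma >= 0)
  structure(list(voxel_size = voxel_size,
                 bilayer_thickness = bilayer_thickness,
                 leaflet_sigma = leaflet_sigma, blur_sigma = blur_sigma,
                 wedge_half_angle = wedge_half_angle,
                 noise_sigma = noise_sigma,
                 density_blob_sigma = density_blob_sigma,
                 membrane_amplitude = membrane_amplitude,
                 density_amplitude = density_amplitude),
            class = "optics_params")
}

# World-coordinate component arrays for a grid.
grid_coords <- function(dims, origin, voxel) {
  x <- origin[1] + (seq_len(dims[1]) - 1) * voxel
  y <- origin[2] + (seq_len(dims[2]) - 1) * voxel
  z <- origin[3] + (seq_len(dims[3]) - 1) * voxel
  list(x = x, y = y, z = z)
}

# array[i,j,k] = ax[i] + ay[j] + az[k]
outer3 <- function(ax, ay, az) outer(outer(ax, ay, `+`), az, `+`)

two_leaflets <- function(d, amp, sigma, half_t) {
  amp * (exp(-(d - half_t)^2 / (2 * sigma^2)) +
           exp(-(d + half_t)^2 / (2 * sigma^2)))
}

# Signed distance (along the surface normal) from every grid point to the
# GUV bilayer midplane, including protrusion bumps.
guv_signed_distance <- function(scene, co, dims) {
  g <- scene$guv
  if (g$shape == "sphere") {
    r2 <- outer3((co$x - g$center[1])^2, (co$y - g$center[2])^2,
                 (co$z - g$center[3])^2)
    base <- sqrt(r2) - g$radius
  } else {
    base <- outer3((co$x - g$p0[1]) * g$normal[1],
                   (co$y - g$p0[2]) * g$normal[2],
                   (co$z - g$p0[3]) * g$normal[3])
  }
  if (nrow(g$bumps)) {
    u <- outer3((co$x - g$p0[1]) * g$e1[1], (co$y - g$p0[2]) * g$e1[2],
                (co$z - g$p0[3]) * g$e1[3])
    v <- outer3((co$x - g$p0[1]) * g$e2[1], (co$y - g$p0[2]) * g$e2[2],
                (co$z - g$p0[3]) * g$e2[3])
    for (b in seq_len(nrow(g$bumps))) {
      bb <- g$bumps[b, ]
      base <- base - bb$height *
        exp(-((u - bb$u)^2 + (v - bb$v)^2) / (2 * bb$sigma^2))
    }
  }
  base
}

# Add one SUV's leaflet shells (possibly with a flattened contact zone) to
# the field.
add_suv <- function(field, j, co, optics) {
  t_bl <- optics$bilayer_thickness
  r_out <- j$suv_diameter / 2
  dx2 <- (co$x - j$suv_center[1])^2
  dy2 <- (co$y - j$suv_center[2])^2
  dz2 <- (co$z - j$suv_center[3])^2
  r <- sqrt(outer3(dx2, dy2, dz2))
  if (j$contact_diameter > 0) {
    rc <- j$contact_diameter / 2
    a_cut <- -sqrt(max(r_out^2 - rc^2, 0))
    a <- outer3((co$x - j$suv_center[1]) * j$axis[1],
                (co$y - j$suv_center[2]) * j$axis[2],
                (co$z - j$suv_center[3]) * j$axis[3])
    rho <- sqrt(pmax(r^2 - a^2, 0))
    on_sphere <- a * r_out >= a_cut * r
    d_out <- ifelse(on_sphere, abs(r - r_out),
                    sqrt(pmax(rho - rc, 0)^2 + (a - a_cut)^2))
    d_in <- ifelse(on_sphere, abs(r - (r_out - t_bl)),
                   sqrt(pmax(rho - rc, 0)^2 + (a - (a_cut + t_bl))^2))
    field + optics$membrane_amplitude *
      (exp(-d_out^2 / (2 * optics$leaflet_sigma^2)) +
         exp(-d_in^2 / (2 * optics$leaflet_sigma^2)))
  } else {
    field +
      two_leaflets(r - (r_out - t_bl / 2), optics$membrane_amplitude,
                   optics$leaflet_sigma, t_bl / 2)
  }
}

# Add a Gaussian blob at world point q, computed in a local sub-box.
add_blob <- function(field, q, amp, sigma, origin, voxel) {
  d <- dim(field)
  ctr <- (q - origin) / voxel + 1
  r <- ceiling(4 * sigma / voxel)
  rng <- function(dn, cc) {
    lo <- max(1, floor(cc) - r); hi <- min(dn, ceiling(cc) + r)
    if (lo > hi) integer(0) else lo:hi
  }
  i <- rng(d[1], ctr[1]); jj <- rng(d[2], ctr[2]); k <- rng(d[3], ctr[3])
  if (!length(i) || !length(jj) || !length(k)) return(field)
  dx2 <- ((i - ctr[1]) * voxel)^2
  dy2 <- ((jj - ctr[2]) * voxel)^2
  dz2 <- ((k - ctr[3]) * voxel)^2
  field[i, jj, k] <- field[i, jj, k] +
    as.vector(amp * exp(-outer3(dx2, dy2, dz2) / (2 * sigma^2)))
  field
}

# Fourier transfer function: Gaussian blur x missing-wedge mask. The
# mask is exactly zero inside the missing wedge; a raised-cosine taper
# over `taper_deg` inside the sampled region softens the edge, as the
# reconstruction filter of real tomograms does, and suppresses the hard
# ringing a binary edge would create.
wedge_transfer <- function(dims, voxel, blur_sigma, wedge_half_angle,
                           taper_deg = 6) {
  kx <- fft_freqs(dims[1], voxel)
  ky <- fft_freqs(dims[2], voxel)
  kz <- fft_freqs(dims[3], voxel)
  k2 <- outer3(kx^2, ky^2, kz^2)
  tf <- exp(-2 * pi^2 * blur_sigma^2 * k2)
  if (wedge_half_angle < 90) {
    akx <- array(abs(kx), dims)
    akz <- array(rep(abs(kz), each = dims[1] * dims[2]), dims)
    ang <- atan2(akz, akx) * 180 / pi
    w <- numeric(length(ang))
    w[ang <= wedge_half_angle - taper_deg] <- 1
    edge <- ang > wedge_half_angle - taper_deg & ang <= wedge_half_angle
    w[edge] <- 0.5 * (1 + cos(pi * (ang[edge] -
      (wedge_half_angle - taper_deg)) / taper_deg))
    dim(w) <- dims
    tf <- tf * w
  }
  tf
}

#' Render a scene into a noisy, wedge-filtered volume
#'
#' Renders the scene's membranes and density points on a physical grid,
#' applies the Gaussian optics blur and the hard missing-wedge Fourier
#' mask, and finally adds white Gaussian noise. Everything before the noise
#' step is linear in the scene content.
#'
#' @param scene a [generate_scene()] result.
#' @param optics an [optics_params()].
#' @param origin,dims optional grid placement (nm) and dimensions; by
#'   default a grid enclosing the scene bounding box (FFT-friendly sizes)
#'   is used. Supplying a grid that does not contain the scene bounding box
#'   is an error.
#' @param seed seed for the noise draw.
#' @param check_fit set `FALSE` to deliberately render a sub-region.
#' @return A [tomo_volume()]; `metadata` records optics, grid and wedge
#'   convention (tilt axis y, beam axis z).
#' @export
render_volume <- function(scene, optics = optics_params(), origin = NULL,
                          dims = NULL, seed = NULL, check_fit = TRUE) {
  stopifnot(inherits(scene, "tomo_scene"), inherits(optics, "optics_params"))
  vox <- optics$voxel_size
  if (vox > 2 * optics$density_blob_sigma ||
      vox > optics$bilayer_thickness)
    warning("voxel_size exceeds the membrane/blob feature scales; ",
            "rendered features will be unresolvable")
  bb <- scene_bbox(scene)
  if (is.null(dims)) {
    dims <- vapply(1:3, function(i)
      next_fft_size(ceiling((bb[i, 2] - bb[i, 1]) / vox) + 1L), 1L)
    origin <- origin %||% ((bb[, 1] + bb[, 2]) / 2 - (dims - 1) / 2 * vox)
  } else {
    dims <- as.integer(dims)
    origin <- origin %||% ((bb[, 1] + bb[, 2]) / 2 - (dims - 1) / 2 * vox)
    if (check_fit) {
      hi <- origin + (dims - 1) * vox
      core <- scene_bbox(scene, pad = 0)
      if (any(core[, 1] < origin - 1e-6) || any(core[, 2] > hi + 1e-6))
        stop("scene bounding box does not fit the requested grid; ",
             "enlarge dims or set check_fit = FALSE")
    }
  }
  co <- grid_coords(dims, origin, vox)
  half_t <- optics$bilayer_thickness / 2

  d_guv <- guv_signed_distance(scene, co, dims)
  field <- two_leaflets(d_guv, optics$membrane_amplitude,
                        optics$leaflet_sigma, half_t)
  rm(d_guv)
  lo <- origin; hi <- origin + (dims - 1) * vox
  for (j in scene$junctions) {
    r <- j$suv_diameter / 2 + 10
    if (any(j$suv_center + r < lo) || any(j$suv_center - r > hi)) next
    field <- add_suv(field, j, co, optics)
    for (q in seq_len(nrow(j$density_points)))
      field <- add_blob(field, j$density_points[q, ],
                        optics$density_amplitude,
                        optics$density_blob_sigma, origin, vox)
  }

  tf <- wedge_transfer(dims, vox, optics$blur_sigma, optics$wedge_half_angle)
  field <- Re(stats::fft(stats::fft(field) * tf, inverse = TRUE)) /
    prod(dims)
  if (optics$noise_sigma > 0)
    field <- field + with_seed(seed,
      array(stats::rnorm(prod(dims), 0, optics$noise_sigma), dims))
  tomo_volume(field, voxel_size = vox, origin = origin,
              metadata = list(optics = unclass(optics),
                              wedge = "tilt axis = y, beam = z; missing wedge is the cone about kz in the kx-kz plane",
                              n_junctions = length(scene$junctions),
                              seed = seed))
}
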