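# Synthetic docking-scene generator.
#
# A scene describes, in physical (nm, world-frame) coordinates, one GUV
# membrane region (flat patch by default, optionally a sphere), a set of
# docked SUVs, and the protein-density points at each junction, together
# with per-junction ground truth (morphology class, membrane separation,
# protrusion, density count). The statistical structure follows the study
# conditions being emulated: three morphology classes (clustered /
# intermediate / ring-like, coded 0 / 0.5 / 1) with class-conditional
# uniform membrane separations of 5-26, 3-8 and 0-7 nm, 2-34 protein
# densities per site, SUV diameters of 20-150 nm (mean 80), and GUV
# protrusions predominantly at clustered junctions.

#' Parameters of the synthetic docking-scene generator
#'
#' @param n_junctions number of docked SUVs to generate.
#' @param class_probs probabilities of the (clustered, intermediate,
#'   ring_like) morphology classes; must sum to 1.
#' @param separation_ranges per-class `(min, max)` membrane separation in nm.
#' @param suv_diameter_dist SUV outer diameter distribution: truncated
#'   normal with `mean`, `sd`, truncation `range` (nm).
#' @param density_count_range inclusive integer range of protein densities
#'   per junction, drawn uniformly.
#' @param protrusion_prob_given_class probability of a GUV protrusion for
#'   (clustered, intermediate, ring_like) junctions.
#' @param protrusion_height mean protrusion height in nm (sd 0.5, truncated
#'   to [3.5, 8]).
#' @param protrusion_fwhm lateral FWHM of the protrusion bump in nm.
#' @param ring_radius_dist ring radius distribution (truncated normal, nm);
#'   `range` defaults to `[exclusion_radius + 1, 22]`.
#' @param exclusion_radius radius (nm) of the exclusion cylinder about the
#'   docking axis separating "inside" from "outside" density points.
#' @param guv_shape GUV geometry; `"flat_patch"` (default) or `"sphere"`.
#'   Tubulated GUVs require a user-supplied surface and are not generated.
#' @param guv_radius GUV radius in nm for `guv_shape = "sphere"`.
#' @param patch_normal_tilt_max maximal random tilt (degrees) of the GUV
#'   patch normal away from +x. The default keeps membranes nearly parallel
#'   to the beam axis, emulating that analysable junctions are those whose
#'   membranes are well sampled under the missing wedge.
#' @param contact_snap separations drawn below this value (nm) become
#'   direct membrane contact: separation 0 with a flattened interface.
#' @param contact_diameter_dist contact-interface diameter distribution for
#'   flattened contacts (truncated normal, nm).
#' @param patch_radius half-extent of the GUV patch (nm); default sized to
#'   fit the requested junctions.
#' @param bilayer_thickness leaflet-peak separation of the membrane (nm).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_junctions = 1,
                         class_probs = c(clustered = 1/3, intermediate = 1/3,
                                         ring_like = 1/3),
                         separation_ranges = list(clustered = c(5, 26),
                                                  intermediate = c(3, 8),
                                                  ring_like = c(0, 7)),
                         suv_diameter_dist = list(mean = 80, sd = 25,
                                                  range = c(20, 150)),
                         density_count_range = c(2, 34),
                         protrusion_prob_given_class = c(clustered = 0.8,
                                                         intermediate = 0.3,
                                                         ring_like = 0.0),
                         protrusion_height = 5,
                         protrusion_fwhm = 20,
                         ring_radius_dist = list(mean = 14, sd = 3,
                                                 range = NULL),
                         exclusion_radius = 10,
                         guv_shape = c("flat_patch", "sphere", "tubulated"),
                         guv_radius = 400,
                         patch_normal_tilt_max = 10,
                         contact_snap = 0.5,
                         contact_diameter_dist = list(mean = 16, sd = 8,
                                                      range = c(4, 36)),
                         patch_radius = NULL,
                         bilayer_thickness = 4,
                         seed = NULL) {
  guv_shape <- match.arg(guv_shape)
  if (guv_shape == "tubulated")
    stop("tubulated GUVs are not generated; supply a surface explicitly")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must sum to 1 (within 1e-9)")
  if (any(class_probs < 0)) stop("class_probs must be non-negative")
  stopifnot(n_junctions >= 0,
            length(separation_ranges) == 3,
            all(vapply(separation_ranges, length, 1L) == 2),
            density_count_range[1] >= 0,
            density_count_range[2] >= density_count_range[1],
            exclusion_radius > 0, bilayer_thickness > 0,
            suv_diameter_dist$range[1] > 0)
  if (any(vapply(separation_ranges, function(r) r[2] < r[1] || r[1] < 0, TRUE)))
    stop("separation ranges must be non-negative with max >= min")
  if (is.null(ring_radius_dist$range))
    ring_radius_dist$range <- c(exclusion_radius + 1, 22)
  p <- list(n_junctions = n_junctions, class_probs = class_probs,
            separation_ranges = separation_ranges,
            suv_diameter_dist = suv_diameter_dist,
            density_count_range = density_count_range,
            protrusion_prob_given_class = protrusion_prob_given_class,
            protrusion_height = protrusion_height,
            protrusion_fwhm = protrusion_fwhm,
            ring_radius_dist = ring_radius_dist,
            exclusion_radius = exclusion_radius,
            guv_shape = guv_shape, guv_radius = guv_radius,
            patch_normal_tilt_max = patch_normal_tilt_max,
            contact_snap = contact_snap,
            contact_diameter_dist = contact_diameter_dist,
            patch_radius = patch_radius,
            bilayer_thickness = bilayer_thickness,
            seed = seed)
  class(p) <- "scene_params"
  p
}

CLASS_LEVELS <- c("clustered", "intermediate", "ring_like")
CLASS_CODES <- c(clustered = 0, intermediate = 0.5, ring_like = 1)

rtrunc_list <- function(n, d) rtruncnorm(n, d$mean, d$sd, d$range[1], d$range[2])

# Sample density points for one junction in the junction's cylindrical
# frame: z measured upward from the GUV outer leaflet at the docking axis,
# rho the cylindrical radius about the axis. Returns matrix (rho, theta, z).
#
# Outside (ring) points are placed in the crevice between the GUV surface
# and the curving SUV underside, at radii where the local membrane gap
# (separation + spherical sag, accounting for a flattened contact zone)
# accommodates a protein-sized density -- the steric-exclusion geometry
# that produces ring-like arrangements in the first place. Inside points
# sit between the membranes on the docking axis side.
sample_density_points <- function(class, n, sep, r_ex, ring_radius,
                                  r_out, rc = 0) {
  local_gap <- function(rho) {
    sep + pmax(rho^2 - rc^2, 0) / (2 * r_out)
  }
  # Each generated point is one *resolvable* density (possibly several
  # proteins), so points are drawn with a minimum mutual spacing; the
  # spacing is relaxed when the drawn count cannot otherwise fit.
  draw_spaced <- function(k, rfun, spacing = 4) {
    pts <- matrix(numeric(0), 0, 3)
    sp <- spacing
    tries <- 0L
    while (nrow(pts) < k) {
      cand <- rfun(1)
      ok <- TRUE
      if (nrow(pts) > 0) {
        dx <- pts[, 1] * cos(pts[, 2]) - cand[1] * cos(cand[2])
        dy <- pts[, 1] * sin(pts[, 2]) - cand[1] * sin(cand[2])
        dz <- pts[, 3] - cand[3]
        ok <- all(dx^2 + dy^2 + dz^2 >= sp^2)
      }
      if (ok) {
        pts <- rbind(pts, cand)
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 30L) { sp <- sp * 0.7; tries <- 0L }
      }
    }
    colnames(pts) <- c("rho", "theta", "z")
    pts
  }
  inside_one <- function(zmin, zmax) function(k) {
    rho <- 0.6 * r_ex * sqrt(stats::runif(k))
    z <- if (zmax > zmin) stats::runif(k, zmin, zmax) else
      rep((zmin + zmax) / 2, k)
    cbind(rho, stats::runif(k, 0, 2 * pi), z)
  }
  outside_one <- function(k) {
    gap_needed <- 4.5                   # nm a density blob needs to fit
    rho_min <- if (sep >= gap_needed) 0 else
      sqrt(rc^2 + 2 * r_out * (gap_needed - sep))
    rho <- pmax(ring_radius + stats::rnorm(k, 0, 1.5), r_ex + 0.5, rho_min)
    rho <- pmin(rho, 28)
    zmax <- pmin(5.5, sep + local_gap(rho) - 2)
    zmax <- pmax(zmax, 2.6)
    cbind(rho, stats::runif(k, 0, 2 * pi),
          2.5 + stats::runif(k) * (zmax - 2.5))
  }
  switch(class,
    clustered = draw_spaced(n, inside_one(min(2.5, sep / 2),
                                          max(sep - 2.5, sep / 2))),
    ring_like = draw_spaced(n, outside_one),
    intermediate = {
      n_in <- if (n <= 2) 1L else 1L + stats::rbinom(1, n - 2, 0.4)
      # remaining inside densities sit directly beneath the SUV base
      f_in <- inside_one(min(1.5, sep / 2), max(sep - 1.5, sep / 2))
      f_in2 <- function(k) { p <- f_in(k); p[, 1] <- p[, 1] * 0.6; p }
      rbind(draw_spaced(n_in, f_in2),
            draw_spaced(n - n_in, outside_one))
    })
}

#' Generate a synthetic docking scene with ground truth
#'
#' Draws per-junction morphology classes, separations, SUV sizes,
#' protrusions and density-point arrangements per the configured
#' distributions, places the junctions without overlap on the GUV surface,
#' and returns the geometric scene description together with a ground-truth
#' table. Deterministic given `params$seed`.
#'
#' Class-conditional density arrangements satisfy, by construction: all
#' clustered points lie inside the exclusion cylinder (radius
#' `exclusion_radius` about the docking axis), no ring-like point lies
#' inside it, and intermediate junctions have at least one point on either
#' side. Separations drawn below `contact_snap` become direct contacts
#' (separation 0) with a flattened membrane interface of positive contact
#' diameter.
#'
#' @param params a [scene_params()].
#' @return A list of class `tomo_scene` with elements `params`, `guv`
#'   (surface frame: `p0`, unit vectors `e1`, `e2`, `normal`, plus shape
#'   and bump table), `junctions` (per-junction geometry in world nm) and
#'   `ground_truth` (data frame, one row per junction).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  n <- p$n_junctions
  t_bl <- p$bilayer_thickness
  # Patch orientation: normal within patch_normal_tilt_max degrees of +x.
  tilt <- p$patch_normal_tilt_max * pi / 180 * sqrt(stats::runif(1))
  azim <- stats::runif(1, 0, 2 * pi)
  normal <- unit(c(cos(tilt), sin(tilt) * cos(azim), sin(tilt) * sin(azim)))
  fr <- orthobasis(normal)
  p0 <- c(0, 0, 0)

  # Junction properties.
  cls <- if (n > 0)
    sample(CLASS_LEVELS, n, replace = TRUE, prob = p$class_probs)
  else character(0)
  sep <- vapply(cls, function(cl) {
    r <- p$separation_ranges[[cl]]
    stats::runif(1, r[1], r[2])
  }, 0)
  contact <- sep < p$contact_snap
  sep[contact] <- 0
  dia <- rtrunc_list(n, p$suv_diameter_dist)
  cd <- numeric(n)
  if (any(contact)) {
    cdd <- p$contact_diameter_dist
    cd[contact] <- pmin(rtrunc_list(sum(contact), cdd), 0.8 * dia[contact])
  }
  prot <- stats::rbinom(n, 1, p$protrusion_prob_given_class[
    match(cls, CLASS_LEVELS)])
  ph <- ifelse(prot == 1,
               rtruncnorm(n, p$protrusion_height, 0.5, 3.5, 8), 0)
  count_vals <- seq.int(p$density_count_range[1], p$density_count_range[2])
  nd <- if (n == 0) integer(0)
  else if (length(count_vals) == 1L) rep(count_vals, n)
  else sample(count_vals, n, replace = TRUE)
  ring_r <- rtrunc_list(n, p$ring_radius_dist)

  # Placement on the patch: jittered grid, spacing from the largest SUV.
  cell <- max(dia, 0) + 30
  if (n > 0) {
    side <- ceiling(sqrt(n))
    gu <- (rep(seq_len(side), length.out = n) - (side + 1) / 2) * cell
    gv <- (rep(seq_len(side), each = side)[seq_len(n)] - (side + 1) / 2) * cell
    gu <- gu + stats::runif(n, -5, 5)
    gv <- gv + stats::runif(n, -5, 5)
    need_radius <- max(sqrt(gu^2 + gv^2)) + max(dia) / 2 + 40
  } else {
    gu <- gv <- numeric(0)
    need_radius <- 200
  }
  patch_radius <- p$patch_radius %||% max(need_radius, 200)
  if (patch_radius < need_radius)
    stop(sprintf(paste0("infeasible geometry: %d junction(s) with SUVs up to ",
                        "%.0f nm need a patch radius of at least %.0f nm ",
                        "(got %.0f nm)"), n, max(dia, 0), need_radius,
                 patch_radius))

  sigma_bump <- p$protrusion_fwhm / (2 * sqrt(2 * log(2)))
  junctions <- vector("list", n)
  bumps <- data.frame(u = numeric(0), v = numeric(0), height = numeric(0),
                      sigma = numeric(0))
  for (i in seq_len(n)) {
    foot <- p0 + gu[i] * fr$e1 + gv[i] * fr$e2   # on GUV bilayer midplane
    r_out <- dia[i] / 2
    if (prot[i] == 1)
      bumps <- rbind(bumps, data.frame(u = gu[i], v = gv[i], height = ph[i],
                                       sigma = sigma_bump))
    elev0 <- (if (prot[i] == 1) ph[i] else 0) + t_bl / 2  # outer leaflet at axis
    zc <- if (cd[i] > 0) {
      elev0 + sqrt(max(r_out^2 - (cd[i] / 2)^2, 0))
    } else {
      elev0 + sep[i] + r_out
    }
    suv_center <- foot + zc * normal
    pts <- sample_density_points(cls[i], nd[i], sep[i], p$exclusion_radius,
                                 ring_r[i], r_out, rc = cd[i] / 2)
    # Density world coordinates: follow the local membrane elevation so
    # points stay between / on the membranes under the protrusion bump.
    rho <- pts[, 1]; th <- pts[, 2]; zz <- pts[, 3]
    bump_at <- if (prot[i] == 1) ph[i] * exp(-rho^2 / (2 * sigma_bump^2)) else 0
    elev <- bump_at + t_bl / 2 + zz
    dp <- sweep(outer(rho * cos(th), fr$e1) + outer(rho * sin(th), fr$e2) +
                  outer(elev, normal), 2, foot, `+`)
    inside <- rho <= p$exclusion_radius
    comp <- rep("intermembrane", nd[i])
    comp[zz <= 2.5] <- "guv_membrane"
    dsuv <- sqrt(rowSums(sweep(dp, 2, suv_center)^2)) - r_out
    comp[abs(dsuv) <= 2.5] <- "suv_membrane"
    junctions[[i]] <- list(
      id = i, class = cls[i], class_code = unname(CLASS_CODES[cls[i]]),
      separation = sep[i], suv_diameter = dia[i], suv_center = suv_center,
      axis = normal, base_uv = c(gu[i], gv[i]), foot = foot,
      contact_diameter = cd[i], protrusion_flag = prot[i],
      protrusion_height = if (prot[i] == 1) ph[i] else 0,
      ring_radius = ring_r[i], n_densities = nd[i],
      density_points = dp, density_rho = rho,
      density_compartment = comp, n_inside = sum(inside),
      n_outside = sum(!inside))
  }

  # Ground-truth invariants (defensive: the constructions above guarantee
  # them, but a violated invariant is a bug worth failing loudly on).
  for (j in junctions) {
    rng <- p$separation_ranges[[j$class]]
    if (j$separation > rng[2] + 1e-9 ||
        (j$separation > 0 && j$separation < rng[1] - 1e-9))
      stop("internal error: separation outside class range")
    if (j$class == "clustered" && j$n_outside > 0)
      stop("internal error: clustered junction has points outside r_ex")
    if (j$class == "ring_like" && j$n_inside > 0)
      stop("internal error: ring-like junction has points inside r_ex")
    if (j$class == "intermediate" && (j$n_inside < 1 || j$n_outside < 1))
      stop("internal error: intermediate junction lacks inside/outside points")
  }

  gt <- data.frame(
    row.names = NULL,
    junction_id = seq_len(n),
    class = cls, class_code = unname(CLASS_CODES[cls]),
    separation_nm = unname(sep), suv_diameter_nm = dia,
    contact_diameter_nm = cd, protrusion_flag = prot,
    protrusion_height_nm = ifelse(prot == 1, ph, 0),
    n_densities = nd,
    suv_center_x = vapply(junctions, function(j) j$suv_center[1], 0),
    suv_center_y = vapply(junctions, function(j) j$suv_center[2], 0),
    suv_center_z = vapply(junctions, function(j) j$suv_center[3], 0),
    axis_x = rep(normal[1], n), axis_y = rep(normal[2], n),
    axis_z = rep(normal[3], n),
    stringsAsFactors = FALSE)

  scene <- list(params = p,
                guv = list(shape = p$guv_shape, p0 = p0, normal = normal,
                           e1 = fr$e1, e2 = fr$e2,
                           radius = if (p$guv_shape == "sphere") p$guv_radius
                                    else patch_radius,
                           center = if (p$guv_shape == "sphere")
                                      p0 - p$guv_radius * normal else NULL,
                           bumps = bumps,
                           bilayer_thickness = t_bl),
                junctions = junctions,
                ground_truth = gt)
  class(scene) <- "tomo_scene"
  scene
}

#' @export
print.tomo_scene <- function(x, ...) {
  cat(sprintf("<tomo_scene> %s GUV, %d junction(s)\n",
              x$guv$shape, length(x$junctions)))
  if (nrow(x$ground_truth))
    print(table(x$ground_truth$class))
  invisible(x)
}

# Bounding box (3 x 2, nm) containing the scene's junction neighbourhoods.
scene_bbox <- function(scene, pad = 15) {
  pts <- rbind(scene$guv$p0)
  for (j in scene$junctions) {
    r <- j$suv_diameter / 2
    pts <- rbind(pts, j$suv_center + r, j$suv_center - r, j$density_points,
                 j$foot)
  }
  cbind(apply(pts, 2, min) - pad, apply(pts, 2, max) + pad)
}
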