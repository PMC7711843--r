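# SUV detection and docking-site extraction.
#
# SUVs are located with a spherical-shell matched filter over a radius grid
# applied to the thresholded, smoothed volume (optionally at reduced
# resolution), then refined to sub-voxel centre/radius on the full-
# resolution volume. The GUV surface is fitted as a plane (flat-patch
# membranes) or taken from a user-supplied description. A docking site is
# emitted where the SUV-GUV outer-leaflet gap is within the docking cutoff
# and protein density is present at the junction.

#' Detection parameters
#'
#' @param docking_distance_cutoff maximal SUV-GUV outer-leaflet gap (nm)
#'   for a docking site (default 50).
#' @param box_size physical edge length (nm) of extracted subtomograms
#'   (default 150).
#' @param suv_radius_range admissible SUV radius range in nm.
#' @param membrane_threshold absolute density threshold for membrane
#'   voxels, or `NULL` for the robust automatic threshold
#'   median + `threshold_nmads` * MAD of the smoothed volume.
#' @param threshold_nmads MADs above the median for the automatic
#'   membrane threshold.
#' @param radius_step spacing (nm) of the matched-filter radius grid.
#' @param shell_width half-thickness (nm) of the matched-filter shell.
#' @param score_min minimal matched-filter score (fraction of shell
#'   occupied by membrane voxels minus the occupancy of the shell
#'   interior, so filled structures such as membrane slabs score low)
#'   for a detection.
#' @param downsample integer factor for the matched-filter stage.
#' @param smooth_sigma Gaussian pre-smoothing sigma in voxels.
#' @param coverage_min minimal angular coverage (fraction of direction
#'   bins of the candidate shell containing membrane voxels) for a valid
#'   vesicle; rejects planes and tangent caps.
#' @param interior_max maximal fraction of above-threshold voxels allowed
#'   inside the candidate shell (a vesicle lumen is empty; shells hugging
#'   a membrane cap are not).
#' @param bilayer_thickness leaflet-peak separation assumed when converting
#'   bilayer-midplane measurements to outer-leaflet positions (nm).
#' @param size_similarity_exclusion vesicle pairs whose radii differ by
#'   less than this fraction are excluded (applies when the target membrane
#'   is itself a detected/supplied sphere; a fitted plane has no radius).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(docking_distance_cutoff = 50,
                             box_size = 150,
                             suv_radius_range = c(10, 75),
                             membrane_threshold = NULL,
                             threshold_nmads = 5,
                             radius_step = 7,
                             shell_width = 4,
                             score_min = 0.1,
                             downsample = 2,
                             smooth_sigma = 1,
                             coverage_min = 0.7,
                             interior_max = 0.05,
                             bilayer_thickness = 4,
                             size_similarity_exclusion = 0.2) {
  stopifnot(docking_distance_cutoff > 0, box_size > 0,
            length(suv_radius_range) == 2,
            suv_radius_range[1] > 0,
            suv_radius_range[2] > suv_radius_range[1],
            radius_step > 0, shell_width > 0, downsample >= 1)
  structure(list(docking_distance_cutoff = docking_distance_cutoff,
                 box_size = box_size, suv_radius_range = suv_radius_range,
                 membrane_threshold = membrane_threshold,
                 threshold_nmads = threshold_nmads,
                 radius_step = radius_step, shell_width = shell_width,
                 score_min = score_min, downsample = as.integer(downsample),
                 smooth_sigma = smooth_sigma, coverage_min = coverage_min,
                 interior_max = interior_max,
                 bilayer_thickness = bilayer_thickness,
                 size_similarity_exclusion = size_similarity_exclusion),
            class = "detection_params")
}

# 2x block-mean reduction (general integer factor).
block_reduce <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a) %/% f * f
  a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  out <- array(0, d %/% f)
  for (i in 0:(f - 1)) for (j in 0:(f - 1)) for (k in 0:(f - 1))
    out <- out + a[seq(1 + i, d[1], f), seq(1 + j, d[2], f),
                   seq(1 + k, d[3], f)]
  out / f^3
}

# Wrapped voxel distances from voxel (1,1,1).
wrap_dist <- function(dims, voxel) {
  dd <- function(n) pmin(0:(n - 1), n - (0:(n - 1))) * voxel
  sqrt(outer3(dd(dims[1])^2, dd(dims[2])^2, dd(dims[3])^2))
}

# Wrapped spherical-shell kernel, unit sum, centred at voxel (1,1,1).
shell_kernel <- function(dims, voxel, radius, width) {
  dist <- wrap_dist(dims, voxel)
  k <- as.numeric(abs(dist - radius) <= width)
  dim(k) <- dims
  k / sum(k)
}

# Wrapped solid-ball kernel, unit sum.
ball_kernel <- function(dims, voxel, radius) {
  dist <- wrap_dist(dims, voxel)
  k <- as.numeric(dist <= radius)
  dim(k) <- dims
  k / sum(k)
}

# Robust automatic membrane threshold: median + n MADs of the smoothed
# map, floored at a fraction of the bright-feature contrast so that
# noise-free volumes (MAD ~ 0) still threshold sensibly.
auto_threshold <- function(sm, params) {
  med <- stats::median(sm)
  med + max(params$threshold_nmads * stats::mad(sm),
            0.25 * (stats::quantile(sm, 0.999, names = FALSE) - med))
}

# Angular coverage of a candidate sphere: fraction of direction bins
# (8 azimuth x 6 elevation, z-caps excluded for missing-wedge tolerance)
# containing membrane voxels in the shell band. A true vesicle covers most
# directions; planes and tangent caps cover a single band.
sphere_validation <- function(sm, vol, c0, r0, thr, band = 3,
                              exclude_plane = NULL) {
  d <- dim(sm); vox <- vol$voxel_size
  ci <- (c0 - vol$origin) / vox + 1
  hw <- ceiling((r0 + band + 1) / vox)
  i <- max(1, round(ci[1]) - hw):min(d[1], round(ci[1]) + hw)
  j <- max(1, round(ci[2]) - hw):min(d[2], round(ci[2]) + hw)
  k <- max(1, round(ci[3]) - hw):min(d[3], round(ci[3]) + hw)
  xs <- vol$origin[1] + (i - 1) * vox - c0[1]
  ys <- vol$origin[2] + (j - 1) * vox - c0[2]
  zs <- vol$origin[3] + (k - 1) * vox - c0[3]
  nb <- c(length(xs), length(ys), length(zs))
  X <- array(xs, nb)
  Y <- array(rep(ys, each = nb[1]), nb)
  Z <- array(rep(zs, each = nb[1] * nb[2]), nb)
  dist <- sqrt(X^2 + Y^2 + Z^2)
  hot <- sm[i, j, k] > thr
  off_plane <- TRUE
  if (!is.null(exclude_plane)) {
    n <- exclude_plane$normal
    dpl <- (X + c0[1] - exclude_plane$point[1]) * n[1] +
      (Y + c0[2] - exclude_plane$point[2]) * n[2] +
      (Z + c0[3] - exclude_plane$point[3]) * n[3]
    off_plane <- abs(dpl) > 6
  }
  inner <- dist <= max(r0 - 7, 2) & off_plane
  interior_frac <- if (any(inner)) mean(hot[inner]) else 0
  m <- abs(dist - r0) <= band & hot & off_plane & dist > 1e-6
  if (!any(m))
    return(list(coverage = 0, interior = interior_frac))
  mu <- Z[m] / dist[m]
  az <- atan2(Y[m], X[m])
  keep <- abs(mu) <= 0.87
  if (!any(keep)) return(list(coverage = 0, interior = interior_frac))
  bin_az <- pmin(floor((az[keep] + pi) / (2 * pi) * 8), 7)
  bin_el <- pmin(floor((mu[keep] + 0.87) / 1.74 * 6), 5)
  list(coverage = length(unique(bin_az * 6 + bin_el)) / 48,
       interior = interior_frac)
}

# 3x3x3 max filter via separable per-dimension maxima.
maxfilter3 <- function(a) {
  for (dm in 1:3)
    a <- pmax(shift_array(a, -1L, dm), a, shift_array(a, 1L, dm))
  a
}

# Sphere refinement: weighted algebraic (Kasa) least-squares fit to the
# membrane-ridge voxels in a band around the current estimate. The
# algebraic fit is robust to missing caps (missing wedge, excluded GUV
# slab), which a shell-centroid update is not. Two band/fit iterations.
refine_sphere <- function(sm, vol, c0, r0, exclude_plane = NULL,
                          band = 4, thr = 0, iterations = 15) {
  d <- dim(sm); vox <- vol$voxel_size
  for (it in seq_len(iterations)) {
    c_prev <- c0; r_prev <- r0
    ci <- (c0 - vol$origin) / vox + 1
    hw <- ceiling((r0 + band + 2) / vox)
    i <- max(1, round(ci[1]) - hw):min(d[1], round(ci[1]) + hw)
    j <- max(1, round(ci[2]) - hw):min(d[2], round(ci[2]) + hw)
    k <- max(1, round(ci[3]) - hw):min(d[3], round(ci[3]) + hw)
    xs <- vol$origin[1] + (i - 1) * vox
    ys <- vol$origin[2] + (j - 1) * vox
    zs <- vol$origin[3] + (k - 1) * vox
    nb <- c(length(xs), length(ys), length(zs))
    X <- array(xs, nb)
    Y <- array(rep(ys, each = nb[1]), nb)
    Z <- array(rep(zs, each = nb[1] * nb[2]), nb)
    w <- pmax(sm[i, j, k] - thr, 0)
    dist <- sqrt((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2)
    m <- abs(dist - r0) <= band & w > 0
    if (!is.null(exclude_plane)) {
      n <- exclude_plane$normal
      dpl <- (X - exclude_plane$point[1]) * n[1] +
        (Y - exclude_plane$point[2]) * n[2] +
        (Z - exclude_plane$point[3]) * n[3]
      m <- m & abs(dpl) > 5
    }
    if (sum(m) < 30) break
    px <- X[m]; py <- Y[m]; pz <- Z[m]; pw <- w[m]
    A <- cbind(2 * px, 2 * py, 2 * pz, 1)
    yv <- px^2 + py^2 + pz^2
    fit <- tryCatch(stats::lm.wfit(A, yv, pw), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    cf <- unname(fit$coefficients)
    c_new <- cf[1:3]
    r2 <- cf[4] + sum(c_new^2)
    if (!is.finite(r2) || r2 <= 0) break
    c0 <- as.numeric(c_new)
    r0 <- sqrt(r2)
    if (sqrt(sum((c0 - c_prev)^2)) < 0.05 && abs(r0 - r_prev) < 0.05)
      break
  }
  list(center = c0, radius = r0)
}

#' Detect SUVs with a spherical-shell matched filter
#'
#' @param vol a [tomo_volume()] with membrane contrast positive (density
#'   above background); invert beforehand if needed.
#' @param params a [detection_params()].
#' @param refine refine centre and radius on the full-resolution volume
#'   (disable to get the coarse matched-filter candidates, e.g. before a
#'   membrane-surface fit that the refinement should exclude).
#' @param exclude_plane optional plane `list(point, normal)` whose
#'   membrane slab is masked out before matched filtering and excluded
#'   from the refinement.
#' @return data frame with one row per detection: world-frame centre
#'   (`x`, `y`, `z`, nm), `radius_nm` (bilayer-midplane ridge radius),
#'   matched-filter `score` and angular `coverage`, sorted by decreasing
#'   score. May be empty.
#' @export
detect_suvs <- function(vol, params = detection_params(), refine = TRUE,
                        exclude_plane = NULL) {
  stopifnot(inherits(vol, "tomo_volume"))
  sm <- gauss_smooth3(vol$grid, params$smooth_sigma)
  thr <- params$membrane_threshold %||% auto_threshold(sm, params)
  b <- array(as.numeric(sm > thr), dim(sm))
  if (!is.null(exclude_plane)) {
    co <- grid_coords(dim(b), vol$origin, vol$voxel_size)
    n <- exclude_plane$normal
    dpl <- outer3((co$x - exclude_plane$point[1]) * n[1],
                  (co$y - exclude_plane$point[2]) * n[2],
                  (co$z - exclude_plane$point[3]) * n[3])
    b[abs(dpl) < 6] <- 0
  }
  f <- params$downsample
  bd <- block_reduce(b, f)
  voxd <- vol$voxel_size * f
  dims <- dim(bd)
  radii <- seq(params$suv_radius_range[1], params$suv_radius_range[2],
               by = params$radius_step)
  radii <- radii[2 * (radii + params$shell_width) <
                   min(dims) * voxd]
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius_nm = numeric(0), score = numeric(0))
  if (!length(radii)) return(empty)
  Fb <- stats::fft(bd)
  # per-radius peak lists so every scale contributes candidates (small
  # junction blobs otherwise crowd out large-vesicle peaks)
  cands <- list()
  for (r in radii) {
    kern <- shell_kernel(dims, voxd, r, params$shell_width)
    ball <- ball_kernel(dims, voxd, max(r - 2 * params$shell_width, 2))
    sc_r <- Re(stats::fft(Fb * stats::fft(kern - ball), inverse = TRUE)) /
      prod(dims)
    mx <- maxfilter3(sc_r)
    pk <- which(sc_r >= mx & sc_r >= params$score_min)
    if (!length(pk)) next
    pk <- pk[order(-sc_r[pk])]
    idx <- arrayInd(pk, dims)
    # thin peaks of this radius to >= 0.7 r apart, keep the top few
    keep <- integer(0)
    for (i in seq_len(nrow(idx))) {
      ok <- TRUE
      for (j in keep) {
        dd <- sqrt(sum((idx[i, ] - idx[j, ])^2)) * voxd
        if (dd < 0.7 * r) { ok <- FALSE; break }
      }
      if (ok) keep <- c(keep, i)
      if (length(keep) >= 8) break
    }
    idx <- idx[keep, , drop = FALSE]
    cands[[length(cands) + 1]] <- data.frame(
      x = vol$origin[1] + (f * (idx[, 1] - 1) + (f - 1) / 2) * vol$voxel_size,
      y = vol$origin[2] + (f * (idx[, 2] - 1) + (f - 1) / 2) * vol$voxel_size,
      z = vol$origin[3] + (f * (idx[, 3] - 1) + (f - 1) / 2) * vol$voxel_size,
      radius_nm = r, score = sc_r[pk[keep]])
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand$coverage <- NA_real_
  cand$interior <- NA_real_
  if (refine) {
    # refine large-radius candidates first; once a sphere is accepted,
    # candidates inside it are redundant seeds and are skipped
    cand <- cand[order(-cand$radius_nm, -cand$score), , drop = FALSE]
    acc <- list()
    ok <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      c_coarse <- as.numeric(cand[i, 1:3])
      inside <- FALSE
      for (a in acc)
        if (sqrt(sum((c_coarse - a$center)^2)) < a$radius + 5) {
          inside <- TRUE; break
        }
      if (inside) next
      ref <- refine_sphere(sm, vol, c_coarse, cand$radius_nm[i],
                           exclude_plane = exclude_plane, thr = thr * 0.5)
      cand[i, 1:3] <- ref$center
      cand$radius_nm[i] <- ref$radius
      v <- sphere_validation(sm, vol, ref$center, ref$radius, thr,
                             exclude_plane = exclude_plane)
      cand$coverage[i] <- v$coverage
      cand$interior[i] <- v$interior
      good <- v$coverage >= params$coverage_min &&
        v$interior <= params$interior_max &&
        ref$radius >= params$suv_radius_range[1] &&
        ref$radius <= params$suv_radius_range[2]
      if (good && !is.null(exclude_plane)) {
        dist_pl <- sum((ref$center - exclude_plane$point) *
                         exclude_plane$normal)
        good <- abs(dist_pl) >= ref$radius - 2
      }
      if (good) {
        ok[i] <- TRUE
        acc[[length(acc) + 1]] <- list(center = ref$center,
                                       radius = ref$radius)
      }
    }
    cand <- cand[ok, , drop = FALSE]
    # rank by angular coverage (full vesicles first), then filter score
    cand <- cand[order(-cand$coverage, -cand$score), , drop = FALSE]
  }
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in keep) {
      dd <- sqrt(sum((as.numeric(cand[i, 1:3]) -
                        as.numeric(cand[j, 1:3]))^2))
      if (dd < 0.6 * (cand$radius_nm[i] + cand$radius_nm[j])) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Fit the GUV membrane as a plane
#'
#' RANSAC over membrane-voxel triples (the GUV patch is the dominant
#' planar structure; vesicle shells never gather comparable inlier
#' counts), followed by least-squares refinement on the inliers.
#' Detected SUVs, when supplied, are excluded up front.
#'
#' @param vol a [tomo_volume()].
#' @param suvs optional [detect_suvs()] table whose neighbourhoods are
#'   excluded from the fit.
#' @param params a [detection_params()] (supplies the membrane
#'   threshold).
#' @param sm optional pre-smoothed grid.
#' @param n_trials RANSAC iterations.
#' @param inlier_tol inlier distance (nm).
#' @return `list(point, normal)`; the normal is oriented toward the SUVs
#'   (or +x when none are given).
#' @export
fit_guv_plane <- function(vol, suvs = NULL, params = detection_params(),
                          sm = NULL, n_trials = 150, inlier_tol = 4) {
  sm <- sm %||% gauss_smooth3(vol$grid, params$smooth_sigma)
  thr <- params$membrane_threshold %||% auto_threshold(sm, params)
  idx <- which(sm > thr)
  if (length(idx) < 100) stop("too few membrane voxels to fit a GUV surface")
  if (length(idx) > 20000) idx <- sample(idx, 20000)
  ai <- arrayInd(idx, dim(sm))
  pts <- sweep((ai - 1) * vol$voxel_size, 2, vol$origin, `+`)
  if (!is.null(suvs)) for (i in seq_len(nrow(suvs))) {
    c0 <- as.numeric(suvs[i, c("x", "y", "z")])
    d2 <- rowSums(sweep(pts, 2, c0)^2)
    pts <- pts[d2 > (suvs$radius_nm[i] + 8)^2, , drop = FALSE]
  }
  if (nrow(pts) < 50) stop("too few GUV membrane voxels after SUV exclusion")
  samp <- if (nrow(pts) > 4000) pts[sample(nrow(pts), 4000), ] else pts
  best <- NULL; best_n <- -1L
  for (tr in seq_len(n_trials)) {
    tri <- samp[sample(nrow(samp), 3), ]
    n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
             (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
           (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
             (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
           (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
             (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    nn <- sqrt(sum(n^2))
    if (nn < 1e-9) next
    n <- n / nn
    resid <- abs(sweep(samp, 2, tri[1, ]) %*% n)
    cnt <- sum(resid < inlier_tol)
    if (cnt > best_n) { best_n <- cnt; best <- list(point = tri[1, ], normal = n) }
  }
  if (is.null(best)) stop("GUV plane fit failed")
  for (it in 1:2) {   # LS refinement on inliers
    resid <- abs(sweep(pts, 2, best$point) %*% best$normal)
    inl <- pts[resid < inlier_tol + 1, , drop = FALSE]
    if (nrow(inl) < 50) break
    ctr <- colMeans(inl)
    sv <- svd(sweep(inl, 2, ctr), nu = 0)
    best <- list(point = ctr, normal = sv$v[, 3])
  }
  normal <- best$normal
  if (!is.null(suvs) && nrow(suvs) > 0) {
    mean_side <- mean(as.matrix(sweep(as.matrix(suvs[, c("x", "y", "z")]),
                                      2, best$point)) %*% normal)
    if (mean_side < 0) normal <- -normal
  } else if (normal[1] < 0) normal <- -normal
  list(point = best$point, normal = unit(normal))
}

#' Find SUV-GUV docking sites
#'
#' Combines SUV detections with the fitted GUV surface: a docking site is
#' emitted when the SUV-GUV outer-leaflet gap is at most the docking
#' cutoff and protein density is detected at the junction. Each emitted
#' site carries an oriented subtomogram (docking axis mapped to +z).
#'
#' @param vol a [tomo_volume()].
#' @param suvs optional SUV table from [detect_suvs()]; detected if `NULL`.
#' @param guv optional GUV surface: `list(point =, normal =)` for a plane
#'   or `list(type = "sphere", center =, radius =)`; fitted as a plane if
#'   `NULL`.
#' @param params a [detection_params()].
#' @param mparams a [metric_params()] used for the junction density
#'   check.
#' @return list of `docking_site` objects (possibly empty). Each has the
#'   SUV centre/radius, closest-approach points, midpoint, docking axis,
#'   outer-leaflet gap estimate, rotation matrix, oriented subtomogram and
#'   the `has_intermembrane_density` flag. Candidates failing the gap or
#'   density rule (or the vesicle size-similarity rule for spherical
#'   targets) are dropped.
#' @export
find_docking_sites <- function(vol, suvs = NULL, guv = NULL,
                               params = detection_params(),
                               mparams = NULL) {
  stopifnot(inherits(vol, "tomo_volume"))
  mp <- mparams %||% metric_params(bilayer_thickness = params$bilayer_thickness)
  sm <- gauss_smooth3(vol$grid, params$smooth_sigma)
  t_bl <- params$bilayer_thickness
  fitted_plane <- NULL
  if (is.null(guv)) {
    fitted_plane <- tryCatch(fit_guv_plane(vol, params = params, sm = sm),
                             error = function(e) NULL)
    if (is.null(fitted_plane)) return(list())
  }
  plane_for_detect <- if (!is.null(fitted_plane)) fitted_plane
    else if (is.null(guv$type) || guv$type != "sphere") guv
  if (is.null(suvs))
    suvs <- detect_suvs(vol, params, refine = TRUE,
                        exclude_plane = plane_for_detect)
  if (nrow(suvs) == 0) return(list())
  sites <- list()
  for (i in seq_len(nrow(suvs))) {
    c0 <- as.numeric(suvs[i, c("x", "y", "z")])
    r0 <- suvs$radius_nm[i]
    if (is.null(guv)) {
      pl <- fitted_plane
      if (is.null(pl)) next
      if (sum((c0 - pl$point) * pl$normal) < 0) pl$normal <- -pl$normal
    } else if (!is.null(guv$type) && guv$type == "sphere") {
      nrm <- unit(c0 - guv$center)
      pl <- list(point = guv$center + guv$radius * nrm, normal = nrm)
      rel <- abs(r0 - guv$radius) / max(r0, guv$radius)
      if (rel < params$size_similarity_exclusion) next  # ambiguous pair
    } else {
      pl <- guv
      if (sum((c0 - pl$point) * pl$normal) < 0)
        pl$normal <- -pl$normal
    }
    thr_i <- params$membrane_threshold %||% auto_threshold(sm, params)
    ref <- refine_sphere(sm, vol, c0, r0, exclude_plane = pl,
                         thr = thr_i * 0.5)
    c0 <- ref$center; r0 <- ref$radius
    if (r0 < params$suv_radius_range[1] ||
        r0 > params$suv_radius_range[2]) next
    v <- sphere_validation(sm, vol, c0, r0, thr_i, exclude_plane = pl)
    if (v$coverage < params$coverage_min ||
        v$interior > params$interior_max) next
    axis <- pl$normal
    dist_pl <- sum((c0 - pl$point) * axis)
    if (dist_pl < r0 - 2) next     # centre would intersect the target membrane
    dup <- FALSE
    for (st in sites)
      if (sqrt(sum((st$suv_center - c0)^2)) <
            0.6 * (st$suv_radius + r0)) { dup <- TRUE; break }
    if (dup) next
    gap <- dist_pl - (r0 + t_bl / 2) - t_bl / 2   # outer leaflet to outer leaflet
    if (gap > params$docking_distance_cutoff) next
    cap_suv <- c0 - (r0 + t_bl / 2) * axis
    cap_guv <- c0 - (dist_pl - t_bl / 2) * axis
    midpoint <- (cap_suv + cap_guv) / 2
    site <- structure(list(
      site_id = length(sites) + 1L,
      suv_center = c0, suv_radius = r0,
      closest_approach_point_suv = cap_suv,
      closest_approach_point_guv = cap_guv,
      midpoint = midpoint, docking_axis = axis,
      gap = max(gap, 0), score = suvs$score[i]), class = "docking_site")
    sub <- tryCatch(extract_subtomogram(vol, site, params),
                    error = function(e) NULL)
    if (is.null(sub)) next
    site$subtomogram <- sub
    site$rotation <- sub$metadata$rotation
    site$local_site <- local_site_from(site, sub)
    lm <- detect_density_landmarks(sub, site, mp)
    site$landmarks <- lm
    site$has_intermembrane_density <- as.integer(nrow(lm) > 0)
    if (site$has_intermembrane_density == 0) next
    sites[[length(sites) + 1L]] <- site
  }
  for (k in seq_along(sites)) sites[[k]]$site_id <- k
  sites
}

# Local-frame (subtomogram) geometry of a site: SUV centre, midplane
# radius, coarse outer-leaflet gap and GUV bilayer-midplane level.
local_site_from <- function(site, sub) {
  M <- sub$metadata$rotation
  c_loc <- as.numeric(t(M) %*% (site$suv_center - site$midpoint))
  list(center = c_loc, r_mid = site$suv_radius, gap = site$gap,
       guv_level = -site$gap / 2 - sub$metadata$bilayer_thickness / 2)
}

#' @export
print.docking_site <- function(x, ...) {
  cat(sprintf("<docking_site %s> SUV r = %.1f nm, outer-leaflet gap = %.1f nm\n",
              x$site_id, x$suv_radius, x$gap))
  cat(sprintf("  centre (%.1f, %.1f, %.1f) nm, axis (%.2f, %.2f, %.2f)\n",
              x$suv_center[1], x$suv_center[2], x$suv_center[3],
              x$docking_axis[1], x$docking_axis[2], x$docking_axis[3]))
  invisible(x)
}

#' Extract an oriented subtomogram around a docking site
#'
#' Crops a cube of physical edge `box_size` centred on the site midpoint
#' and rotates it so the docking axis lies along +z (trilinear
#' interpolation; voxels sampled outside the source volume are zero and
#' recorded in an outside-fraction). The local frame has its origin at the
#' midpoint.
#'
#' @param vol source [tomo_volume()].
#' @param site a `docking_site` (any list with `midpoint` and
#'   `docking_axis` works).
#' @param params a [detection_params()] (supplies `box_size`).
#' @return A [tomo_volume()] whose metadata records the rotation matrix
#'   (local -> world), the world midpoint and the outside fraction.
#' @export
extract_subtomogram <- function(vol, site, params = detection_params()) {
  d <- dim(vol$grid)
  ci <- world_to_index(vol, site$midpoint)
  if (any(ci < 1) || any(ci > d))
    stop("site midpoint lies outside the volume")
  vox <- vol$voxel_size
  n <- 2L * floor(params$box_size / (2 * vox)) + 1L
  half <- (n - 1) / 2
  M <- frame_matrix(site$docking_axis)
  ax <- (-half:half) * vox
  q <- cbind(rep(ax, times = n * n),
             rep(rep(ax, each = n), times = n),
             rep(ax, each = n * n))
  pw <- q %*% t(M)
  pw <- sweep(pw, 2, site$midpoint, `+`)
  pi_ <- sweep(pw, 2, vol$origin, `-`) / vox + 1
  vals <- interp3(vol$grid, pi_, fill = 0)
  inside <- pi_[, 1] >= 1 & pi_[, 1] <= d[1] & pi_[, 2] >= 1 &
    pi_[, 2] <= d[2] & pi_[, 3] >= 1 & pi_[, 3] <= d[3]
  tomo_volume(array(vals, c(n, n, n)), voxel_size = vox,
              origin = c(-half, -half, -half) * vox,
              metadata = list(rotation = M, center_world = site$midpoint,
                              outside_fraction = 1 - mean(inside),
                              bilayer_thickness =
                                params$bilayer_thickness %||% 4,
                              site_id = site$site_id %||% NA))
}
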