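# Per-junction quantification on oriented subtomograms.
#
# All measurements run in the subtomogram's local frame: origin at the
# site midpoint, docking axis = +z, GUV below, SUV above. Membrane
# positions are localised as bilayer ridges (the merged two-leaflet peak
# at typical tomogram voxel sizes marks the bilayer midplane) on
# per-column density profiles along z, with sub-voxel parabolic
# refinement; outer-leaflet positions are obtained by offsetting half a
# bilayer thickness toward the partner membrane.

#' Measurement parameters
#'
#' @param bilayer_thickness leaflet-peak separation (nm) used to convert
#'   bilayer-midplane ridge positions to outer-leaflet positions.
#' @param smooth_sigma Gaussian smoothing (voxels) applied before
#'   measurement, mirroring the 3x3x3 display filter used for visual
#'   annotation of this kind of data.
#' @param contact_epsilon separations at or below this value (nm; default
#'   one voxel) count as direct membrane contact.
#' @param merge_radius density maxima closer than this (nm) are merged
#'   into one landmark (nearby proteins are not separately resolved).
#' @param density_threshold absolute threshold for density maxima; default
#'   `NULL` uses background mean + 3 SD.
#' @param membrane_clearance minimal height (nm) of a density candidate
#'   above the GUV bilayer midplane.
#' @param suv_clearance minimal distance (nm) of a candidate from the SUV
#'   bilayer midplane.
#' @param considered_radius densities beyond this cylindrical radius (nm)
#'   about the docking axis are ignored.
#' @param slab_top maximal candidate height (nm) above the GUV midplane.
#' @param protrusion_window radius (nm) of the region around the axis in
#'   which GUV surface elevation counts as a protrusion.
#' @param protrusion_min_height minimal elevation (nm) above the baseline
#'   plane for a positive protrusion call.
#' @param baseline_annulus radial range (nm) of GUV surface columns used
#'   to fit the protrusion baseline plane.
#' @param window_radius lateral half-extent (nm) of the analysed window.
#' @return list of class `metric_params`.
#' @export
metric_params <- function(bilayer_thickness = 4,
                          smooth_sigma = 1,
                          contact_epsilon = NULL,
                          merge_radius = 5,
                          density_threshold = NULL,
                          membrane_clearance = 3,
                          suv_clearance = 3.5,
                          considered_radius = 30,
                          slab_top = 28,
                          protrusion_window = 25,
                          protrusion_min_height = 3,
                          baseline_annulus = c(25, 40),
                          window_radius = 42) {
  structure(list(bilayer_thickness = bilayer_thickness,
                 smooth_sigma = smooth_sigma,
                 contact_epsilon = contact_epsilon,
                 merge_radius = merge_radius,
                 density_threshold = density_threshold,
                 membrane_clearance = membrane_clearance,
                 suv_clearance = suv_clearance,
                 considered_radius = considered_radius,
                 slab_top = slab_top,
                 protrusion_window = protrusion_window,
                 protrusion_min_height = protrusion_min_height,
                 baseline_annulus = baseline_annulus,
                 window_radius = window_radius),
            class = "metric_params")
}



# Separable 2D min/max filters with NA handling (radius r columns).
rankfilter2 <- function(E, r, fun) {
  for (pass in 1:2) {
    ni <- nrow(E); nj <- ncol(E)
    out <- E
    for (d in seq_len(r)) {
      for (sgn in c(-d, d)) {
        Es <- matrix(NA_real_, ni, nj)
        if (pass == 1) {
          si <- max(1, 1 + sgn):min(ni, ni + sgn)
          Es[si - sgn, ] <- E[si, ]
        } else {
          sj <- max(1, 1 + sgn):min(nj, nj + sgn)
          Es[, sj - sgn] <- E[, sj]
        }
        out <- fun(out, Es)
      }
    }
    E <- out
  }
  E
}
pmin_na <- function(a, b) ifelse(is.na(a), b, ifelse(is.na(b), a, pmin(a, b)))
pmax_na <- function(a, b) ifelse(is.na(a), b, ifelse(is.na(b), a, pmax(a, b)))

# Morphological opening (lower envelope) of a surface map: protein blobs
# fused with a membrane ridge only ever raise it, and are narrow compared
# with membrane-scale features, so min-then-max filtering recovers the
# membrane surface while preserving protrusion-scale relief.
open_surface <- function(H, r = 2) {
  smooth2_na(rankfilter2(rankfilter2(H, r, pmin_na), r, pmax_na))
}
close_surface <- function(H, r = 2) {
  smooth2_na(rankfilter2(rankfilter2(H, r, pmax_na), r, pmin_na))
}

# NA-aware 3x3 mean filter for column maps.
smooth2_na <- function(E) {
  ni <- nrow(E); nj <- ncol(E)
  acc <- matrix(0, ni, nj); cnt <- matrix(0, ni, nj)
  for (di in -1:1) for (dj in -1:1) {
    Es <- matrix(NA_real_, ni, nj)
    si <- max(1, 1 + di):min(ni, ni + di)
    sj <- max(1, 1 + dj):min(nj, nj + dj)
    Es[si - di, sj - dj] <- E[si, sj]
    hit <- !is.na(Es)
    acc[hit] <- acc[hit] + Es[hit]
    cnt <- cnt + hit
  }
  ifelse(cnt > 0, acc / cnt, NA)
}

# Accept either a docking_site (with $local_site) or a bare local-site
# list(center, r_mid, gap, guv_level).
as_local_site <- function(site) {
  if (!is.null(site$local_site)) site$local_site else site
}

# Masked per-column ridge search: P is (n_columns x nz) profile matrix,
# lo/hi are per-column z bounds. mode "max" returns the strongest value in
# the window; mode "lowest" returns the lowest-z local maximum whose value
# reaches at least `rel_min` of the window maximum -- the robust choice
# for a membrane ridge with protein blobs stacked above it. Returns
# sub-voxel ridge z and peak value.
ridge_search <- function(P, zv, lo, hi, mode = c("max", "lowest", "highest"),
                         rel_min = 0.55) {
  mode <- match.arg(mode)
  nc <- nrow(P); nz <- ncol(P)
  Zm <- matrix(zv, nc, nz, byrow = TRUE)
  OK <- Zm >= lo & Zm <= hi       # lo, hi recycle down columns (length nc)
  Pm <- P
  Pm[!OK] <- -Inf
  if (mode == "max") {
    ks <- max.col(Pm, ties.method = "first")
  } else {
    row_max <- Pm[cbind(seq_len(nc), max.col(Pm, ties.method = "first"))]
    up <- cbind(P[, -1, drop = FALSE], -Inf)
    dn <- cbind(-Inf, P[, -nz, drop = FALSE])
    qual <- OK & P >= up & P >= dn & Pm >= rel_min * row_max
    # lowest/highest qualifying z: weight end of interest higher
    wt <- if (mode == "lowest")
      matrix(rep(nz:1, each = nc), nc, nz)
    else matrix(rep(1:nz, each = nc), nc, nz)
    ks <- max.col(qual * wt, ties.method = "first")
    none <- rowSums(qual) == 0
    ks[none] <- max.col(Pm, ties.method = "first")[none]
  }
  val <- Pm[cbind(seq_len(nc), ks)]
  valid <- is.finite(val)
  km <- pmax(ks - 1L, 1L); kp <- pmin(ks + 1L, nz)
  y0 <- P[cbind(seq_len(nc), ks)]
  y1 <- P[cbind(seq_len(nc), km)]
  y2 <- P[cbind(seq_len(nc), kp)]
  den <- y1 - 2 * y0 + y2
  off <- ifelse(is.finite(den) & abs(den) > 1e-12,
                pmax(-0.5, pmin(0.5, 0.5 * (y1 - y2) / den)), 0)
  off[ks == 1L | ks == nz] <- 0
  dz <- zv[2] - zv[1]
  list(z = ifelse(valid, zv[ks] + off * dz, NA_real_),
       value = ifelse(valid, val, NA_real_))
}

# Column-wise membrane surface maps of a junction: GUV bilayer-midplane
# height, SUV bottom bilayer-midplane height, per-column outer-leaflet gap
# and a merged (unresolvable gap / direct contact) flag.
junction_surface_maps <- function(sub, site, params = metric_params(),
                                  sm = NULL) {
  ls <- as_local_site(site)
  vox <- sub$voxel_size
  t_bl <- params$bilayer_thickness
  sm <- sm %||% gauss_smooth3(sub$grid, params$smooth_sigma)
  ax <- vol_axes(sub)
  wr <- params$window_radius
  cx <- ls$center[1]; cy <- ls$center[2]; cz <- ls$center[3]
  ii <- which(abs(ax[[1]] - cx) <= wr)
  jj <- which(abs(ax[[2]] - cy) <= wr)
  ni <- length(ii); nj <- length(jj); nz <- dim(sub$grid)[3]
  P <- matrix(sm[ii, jj, ], ni * nj, nz)
  xs <- rep(ax[[1]][ii], times = nj)
  ys <- rep(ax[[2]][jj], each = ni)
  rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
  zv <- ax[[3]]
  r_mid <- ls$r_mid
  z_s_pred <- ifelse(rho <= r_mid - 1,
                     cz - sqrt(pmax(r_mid^2 - rho^2, 0)), NA_real_)
  g0 <- ls$guv_level
  hi_g <- pmin(g0 + 12, z_s_pred - 4, na.rm = FALSE)
  hi_g[is.na(hi_g)] <- g0 + 12
  guv <- ridge_search(P, zv, g0 - 6, hi_g, mode = "lowest")
  lo_s <- z_s_pred - 4.5; hi_s <- z_s_pred + 4.5
  lo_s[is.na(lo_s)] <- Inf; hi_s[is.na(hi_s)] <- -Inf
  suv <- ridge_search(P, zv, lo_s, hi_s, mode = "highest")
  # Envelope-corrected surfaces: blobs fused with a ridge bias it toward
  # the partner membrane; opening/closing recovers the membrane surfaces.
  h_open <- as.numeric(open_surface(matrix(guv$z, ni, nj)))
  z_close <- as.numeric(close_surface(matrix(suv$z, ni, nj)))
  # the rank filters fill NAs from neighbours; the SUV surface only
  # exists inside its silhouette
  z_close[is.na(z_s_pred)] <- NA
  gap <- z_close - h_open - t_bl       # outer leaflet to outer leaflet
  merged <- !is.na(gap) & gap < 1
  list(x = xs, y = ys, rho = rho,
       h_guv = h_open, h_raw = guv$z, peak_guv = guv$value,
       z_suv = z_close, z_suv_raw = suv$z, peak_suv = suv$value,
       gap = gap, merged = merged,
       ni = ni, nj = nj, voxel_size = vox,
       center = c(cx, cy, cz), r_mid = r_mid, t_bl = t_bl)
}

#' Measure the SUV-GUV membrane separation
#'
#' Distance from the SUV outer membrane leaflet at the point of closest
#' approach to the GUV outer leaflet, from per-column bilayer ridge
#' positions near the docking axis (sphere-sag corrected, median over the
#' central columns). Merged ridges (unresolvable gap) give separation 0.
#'
#' @param sub oriented subtomogram from [extract_subtomogram()].
#' @param site the corresponding `docking_site` (or a local-site list).
#' @param params a [metric_params()].
#' @param maps optional precomputed [junction_surface_maps()] output.
#' @return list with `separation` (nm; `NA` when the membranes could not
#'   be localised, with `flagged = TRUE`), `n_columns`, `flagged`.
#' @export
measure_separation <- function(sub, site, params = metric_params(),
                               maps = NULL) {
  m <- maps %||% junction_surface_maps(sub, site, params)
  central <- m$rho <= 5
  ok <- central & !is.na(m$gap)
  if (!any(ok))
    return(list(separation = NA_real_, n_columns = 0L, flagged = TRUE))
  sag <- m$r_mid - sqrt(pmax(m$r_mid^2 - m$rho[ok]^2, 0))
  sep_cols <- m$gap[ok] - sag
  sep <- stats::median(sep_cols)
  if (mean(m$merged[central], na.rm = TRUE) >= 0.5) sep <- 0
  list(separation = max(sep, 0), n_columns = sum(ok), flagged = FALSE)
}

#' Measure the membrane contact-interface diameter
#'
#' For junctions in direct contact (separation at most `contact_epsilon`,
#' default one voxel), estimates the diameter of the flattened zero-gap
#' contact zone. Membrane ridge pairs are unresolvable until the true
#' gap reaches the ridge-merge floor (~4.5 nm outer-leaflet gap at these
#' voxel sizes, calibrated on noise-free flattened-contact phantoms), so
#' the merged-column zone extends beyond the true contact: its
#' equivalent-circle radius rho_m satisfies
#' `rho_m^2 = rc^2 + 2 R g_floor` under the spherical gap model, which
#' is inverted for the contact radius `rc`. Returns 0 for separated
#' membranes.
#'
#' @inheritParams measure_separation
#' @param separation optionally the precomputed separation (nm).
#' @param gap_floor outer-leaflet gap (nm) below which the two
#'   bilayer ridges merge into one.
#' @return contact diameter in nm.
#' @export
measure_contact_diameter <- function(sub, site, params = metric_params(),
                                     maps = NULL, separation = NULL,
                                     gap_floor = 4.45) {
  m <- maps %||% junction_surface_maps(sub, site, params)
  eps <- params$contact_epsilon %||% sub$voxel_size
  if (is.null(separation))
    separation <- measure_separation(sub, site, params, maps = m)$separation
  if (is.na(separation) || separation > eps) return(0)
  r_out <- m$r_mid + m$t_bl / 2
  n_merged <- sum(m$merged & m$rho <= params$considered_radius,
                  na.rm = TRUE)
  rho_m2 <- n_merged * m$voxel_size^2 / pi   # equivalent-circle radius^2
  rc2 <- rho_m2 - 2 * r_out * gap_floor
  2 * sqrt(max(rc2, 0))
}

#' Detect a GUV membrane protrusion at a junction
#'
#' Fits a baseline plane to the GUV surface in an annulus outside the
#' junction (the region under the SUV is excluded from the fit) and
#' reports the maximal smoothed surface elevation toward the SUV within
#' the protrusion window. The flag is 1 when the elevation exceeds
#' `protrusion_min_height`.
#'
#' @inheritParams measure_separation
#' @param landmarks density landmarks of the site (from
#'   [detect_density_landmarks()]); columns within `merge_radius` of a
#'   landmark are excluded from the elevation maximum, so that a
#'   membrane-attached density is not mistaken for a protrusion. Computed
#'   on the fly when `NULL`.
#' @return list with `flag` (0/1), `height` (nm) and `flagged` (TRUE when
#'   the baseline fit is rank-deficient or under-determined).
#' @export
detect_protrusion <- function(sub, site, params = metric_params(),
                              maps = NULL, landmarks = NULL) {
  m <- maps %||% junction_surface_maps(sub, site, params)
  if (is.null(landmarks))
    landmarks <- detect_density_landmarks(sub, site, params, maps = m)
  ann <- params$baseline_annulus
  base_sel <- m$rho > ann[1] & m$rho <= ann[2] & !is.na(m$h_guv) &
    !(m$merged %in% TRUE)
  if (sum(base_sel) < 12)
    return(list(flag = NA_integer_, height = NA_real_, flagged = TRUE))
  X <- cbind(1, m$x[base_sel], m$y[base_sel])
  qrX <- qr(X)
  if (qrX$rank < 3)
    return(list(flag = NA_integer_, height = NA_real_, flagged = TRUE))
  beta <- qr.coef(qrX, m$h_guv[base_sel])
  pred <- beta[1] + beta[2] * m$x + beta[3] * m$y
  elev <- m$h_guv - pred
  elev[m$merged %in% TRUE] <- NA
  if (nrow(landmarks)) {
    for (q in seq_len(nrow(landmarks))) {
      d2 <- (m$x - landmarks$x[q])^2 + (m$y - landmarks$y[q])^2
      elev[d2 <= params$merge_radius^2] <- NA
    }
  }
  Esm <- matrix(elev, m$ni, m$nj)
  win <- m$rho <= params$protrusion_window
  h <- suppressWarnings(max(Esm[matrix(win, m$ni, m$nj)], na.rm = TRUE))
  if (!is.finite(h))
    return(list(flag = NA_integer_, height = NA_real_, flagged = TRUE))
  list(flag = as.integer(h > params$protrusion_min_height),
       height = h, flagged = FALSE)
}

#' Detect protein-density landmarks at a junction
#'
#' Each subtomogram column (along the docking axis) is modelled as a sum
#' of two membrane templates -- the empirical membrane profile measured on
#' columns outside the junction -- placed at the local GUV and SUV ridge
#' positions, with per-column amplitudes and small shift refinement.
#' Protein densities are then detected laterally on two channels:
#' \itemize{
#'   \item free densities: lateral maxima of the maximum fit residual in
#'     the space between the membranes;
#'   \item membrane-attached densities: lateral maxima of the fitted
#'     membrane amplitude excess over its annulus baseline (a density
#'     lying on a membrane is inseparable from it along z, but brightens
#'     the ridge where it sits).
#' }
#' Maxima must exceed their channel background by 3 robust SD; shoulders
#' connected to a stronger maximum by a high density saddle are merged
#' with it, as are maxima closer than `merge_radius` (one landmark may
#' correspond to more than one protein). Each landmark is tagged with the
#' membrane compartment it sits in.
#'
#' @inheritParams measure_separation
#' @return data frame with local-frame coordinates `x`, `y`, `z` (nm),
#'   `rho` (cylindrical radius about the docking axis), `intensity`
#'   (background-corrected excess) and `compartment` (`suv_membrane`,
#'   `guv_membrane` or `intermembrane`). Zero rows when nothing is
#'   detected.
#' @export
detect_density_landmarks <- function(sub, site, params = metric_params(),
                                     maps = NULL) {
  sm <- gauss_smooth3(sub$grid, params$smooth_sigma)
  m <- maps %||% junction_surface_maps(sub, site, params, sm = sm)
  vox <- sub$voxel_size
  ax <- vol_axes(sub)
  cx <- m$center[1]; cy <- m$center[2]; czc <- m$center[3]
  ii <- which(abs(ax[[1]] - cx) <= params$window_radius)
  jj <- which(abs(ax[[2]] - cy) <= params$window_radius)
  ni <- m$ni; nj <- m$nj
  g0 <- stats::median(m$h_guv, na.rm = TRUE)
  kk <- which(ax[[3]] >= g0 - 7 & ax[[3]] <= g0 + params$slab_top + 7)
  if (length(kk) < 5) return(empty_landmarks())
  nzk <- length(kk)
  zv <- ax[[3]][kk]
  S <- sm[ii, jj, kk, drop = FALSE]
  nc <- ni * nj
  Smat <- matrix(S, nc, nzk)
  rho_c <- m$rho
  hg <- m$h_guv                       # envelope-corrected GUV surface
  zs <- m$z_suv
  hg_raw <- m$h_raw                   # raw ridges: blobs only lift hg_raw
  zs_raw <- m$z_suv_raw               # and only pull zs_raw down

  # Empirical membrane template from annulus columns (profile vs height
  # about the GUV ridge), peak-normalised.
  ann <- rho_c > params$considered_radius + 3 & !is.na(hg)
  if (sum(ann) < 40) ann <- !is.na(hg)
  zrel_ann <- outer(-hg[ann], zv, `+`)          # z - hg per annulus column
  zb <- round(zrel_ann / vox)
  vals <- Smat[ann, , drop = FALSE]
  bins <- sort(unique(as.integer(zb)))
  tmpl <- vapply(bins, function(b) stats::median(vals[zb == b]), 0)
  tmpl <- tmpl - min(tmpl)
  pkv <- max(tmpl)
  if (pkv <= 0) return(empty_landmarks())
  T_at <- function(dz) {
    b <- dz / vox                      # continuous bin coordinate
    i <- findInterval(b, bins, all.inside = TRUE)
    i <- pmin(i, length(bins) - 1L)
    w <- (b - bins[i]) / (bins[i + 1] - bins[i])
    w <- pmin(pmax(w, 0), 1)
    out <- (1 - w) * tmpl[i] + w * tmpl[i + 1]
    out[b < bins[1] | b > bins[length(bins)]] <- 0
    out
  }

  # Per-column two-template fit with sub-voxel shift refinement. Fit
  # centres are the envelope-corrected surfaces -- the best estimates of
  # the true membranes -- so that protein blobs stacked against a
  # membrane cannot be absorbed into a conveniently shifted template and
  # instead remain in the residual. The SUV template is stretched by the
  # local surface tilt (a membrane inclined by theta is broader by
  # 1/cos(theta) along the column). In crevices narrower than ~12 nm the
  # two templates overlap and would trade amplitudes, so they share one.
  # All columns are fitted at once per shift combination.
  shifts_g <- seq(-1.2, 1.2, by = 0.6)
  shifts_s <- seq(-1.2, 1.2, by = 0.6)
  cth <- sqrt(pmax(1 - (rho_c / m$r_mid)^2, 0.15))
  Zcol <- matrix(zv, nc, nzk, byrow = TRUE)
  hg0 <- ifelse(is.na(hg), 0, hg)
  zs0 <- ifelse(is.na(zs), 0, zs)
  has_g <- !is.na(hg)
  has_s <- !is.na(zs)
  tight <- has_s & (zs0 - hg0 < 12)
  Y <- Smat
  yy <- rowSums(Y * Y)
  T_mat <- function(ctr, scale = 1) {
    A <- (Zcol - ctr) * scale          # ctr, scale recycle down columns
    out <- T_at(as.numeric(A))
    dim(out) <- dim(A)
    out
  }
  Tg <- lapply(shifts_g, function(d) T_mat(hg0 + d))
  Ts <- lapply(shifts_s, function(d) T_mat(zs0 + d, cth))
  best_rss <- rep(Inf, nc)
  best_a <- best_b <- numeric(nc)
  best_i <- best_j <- rep(1L, nc)
  for (i1 in seq_along(Tg)) {
    T1 <- Tg[[i1]]
    g11 <- rowSums(T1 * T1)
    t1y <- rowSums(T1 * Y)
    for (j1 in seq_along(Ts)) {
      T2 <- Ts[[j1]]
      g22 <- rowSums(T2 * T2)
      g12 <- rowSums(T1 * T2)
      t2y <- rowSums(T2 * Y)
      # single-membrane columns
      a_single <- pmax(t1y / pmax(g11, 1e-9), 0)
      rss_single <- yy - 2 * a_single * t1y + a_single^2 * g11
      # tight crevice: shared amplitude
      gcc <- g11 + g22 + 2 * g12
      a_tight <- pmax((t1y + t2y) / pmax(gcc, 1e-9), 0)
      rss_tight <- yy - 2 * a_tight * (t1y + t2y) + a_tight^2 * gcc
      # independent amplitudes
      det2 <- pmax(g11 * g22 - g12^2, 1e-9)
      a_ind <- pmax((g22 * t1y - g12 * t2y) / det2, 0)
      b_ind <- pmax((g11 * t2y - g12 * t1y) / det2, 0)
      rss_ind <- yy - 2 * a_ind * t1y - 2 * b_ind * t2y +
        a_ind^2 * g11 + b_ind^2 * g22 + 2 * a_ind * b_ind * g12
      # an SUV template without in-box support degenerates the 2x2 solve
      no_t2 <- !has_s | g22 < 1e-6
      aa <- ifelse(no_t2, a_single, ifelse(tight, a_tight, a_ind))
      bb <- ifelse(no_t2, 0, ifelse(tight, a_tight, b_ind))
      rss <- ifelse(no_t2, rss_single, ifelse(tight, rss_tight, rss_ind))
      upd <- rss < best_rss
      best_rss[upd] <- rss[upd]
      best_a[upd] <- aa[upd]
      best_b[upd] <- bb[upd]
      best_i[upd] <- i1
      best_j[upd] <- j1
    }
  }
  a_fit <- best_a
  b_fit <- best_b
  R <- Y
  for (i1 in seq_along(Tg)) for (j1 in seq_along(Ts)) {
    rows <- which(best_i == i1 & best_j == j1)
    if (!length(rows)) next
    R[rows, ] <- Y[rows, , drop = FALSE] -
      best_a[rows] * Tg[[i1]][rows, , drop = FALSE] -
      ifelse(has_s[rows], 1, 0) * best_b[rows] *
        Ts[[j1]][rows, , drop = FALSE]
  }
  R[!has_g, ] <- NA
  a_fit[!has_g] <- NA

  # candidate z-range per voxel: between the membranes, clear of both
  Zm <- matrix(zv, nc, nzk, byrow = TRUE)
  zrel <- Zm - hg
  below <- zs - Zm
  dsuv3 <- sqrt(matrix((m$x - cx)^2 + (m$y - cy)^2, nc, nzk) +
                  (Zm - czc)^2) - m$r_mid
  ok <- !is.na(zrel) & zrel >= params$membrane_clearance &
    zrel <= params$slab_top &
    (is.na(below) | below >= params$suv_clearance) &
    abs(dsuv3) >= params$suv_clearance + 0.5 &
    rho_c <= params$considered_radius
  Rm <- R
  Rm[!ok | is.na(Rm)] <- -Inf
  M_free <- matrix(apply(Rm, 1, max), ni, nj)
  K_free <- matrix(apply(Rm, 1, which.max), ni, nj)
  depth <- matrix(rowSums(is.finite(Rm)), ni, nj)
  ok_ann <- !is.na(zrel) & zrel >= params$membrane_clearance &
    zrel <= params$slab_top & rho_c > params$considered_radius + 3
  Ra <- R
  Ra[!ok_ann | is.na(Ra)] <- -Inf
  # per-voxel residual noise scale from the annulus
  sd_R <- stats::mad(Ra[is.finite(Ra)])
  med_R <- stats::median(Ra[is.finite(Ra)])
  amp_ann <- pkv * a_fit[ann & is.finite(a_fit)]
  amp_base <- stats::median(amp_ann)
  sd_R <- max(sd_R, 0.02 * amp_base)   # floor for artifact-free renders
  # The free statistic is a maximum over the column depth, screened over
  # ~10^3 columns, so the noise bound must grow with the depth of the
  # searched column (extreme-value scaling); shallow crevice columns get
  # a correspondingly lower bound.
  thr_free_map <- if (is.null(params$density_threshold))
    med_R + sd_R * (1.2 + 1.4 * sqrt(2 * log(pmax(depth, 2)))) + 0.02
  else matrix(params$density_threshold, ni, nj)
  # site-level density mass: mean positive residual between the
  # membranes versus the same statistic in the annulus, standardised by
  # the annulus spread (used as the docking "visible density" gate
  # upstream)
  pos_mean <- function(v) { v <- v[is.finite(v)]; if (!length(v)) return(NA)
    mean(pmax(v, 0)) }
  n_ok <- sum(ok, na.rm = TRUE)
  Rin <- R; Rin[!ok | is.na(Rin)] <- NA
  Rann <- R; Rann[!ok_ann | is.na(Rann)] <- NA
  m_in <- pos_mean(Rin); m_ann <- pos_mean(Rann)
  excess_z <- if (n_ok > 0 && sd_R > 0 && is.finite(m_in) &&
                  is.finite(m_ann))
    (m_in - m_ann) * sqrt(n_ok) / sd_R else 0

  # membrane-attached channel: fitted amplitude excess
  # GUV ridge amplitude channel only: the SUV amplitude has no valid
  # flat-membrane baseline on the tilted parts of the sphere.
  amp <- pkv * a_fit                    # GUV ridge amplitude per column
  bg_amp <- amp[ann & is.finite(amp)]
  base_a <- stats::median(bg_amp)
  mad_a <- stats::mad(bg_amp)
  M_mem <- matrix(amp - base_a, ni, nj)
  M_mem[is.na(M_mem)] <- -Inf
  gap2 <- matrix(m$gap, ni, nj)
  # contact / unresolved-gap columns have double-membrane peaks; drop them
  mem_valid <- (is.na(gap2) | gap2 >= 2.5) & matrix(rho_c, ni, nj) <=
    params$considered_radius
  thr_mem <- if (is.null(params$density_threshold))
    3 * mad_a + 0.03 else params$density_threshold

  inner2 <- matrix(rho_c, ni, nj) <= params$considered_radius
  peaks2 <- function(M, valid, thr) {
    M2 <- ifelse(valid, M, -Inf)
    pk <- matrix(TRUE, ni, nj)
    nfin <- matrix(0L, ni, nj)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      Msh <- matrix(-Inf, ni, nj)
      si <- max(1, 1 + di):min(ni, ni + di)
      sj <- max(1, 1 + dj):min(nj, nj + dj)
      Msh[si - di, sj - dj] <- M2[si, sj]
      nfin <- nfin + is.finite(Msh)
      pk <- pk & (!is.finite(Msh) | M2 > Msh)
    }
    # a peak must beat its measurable neighbours and have most of them
    # measurable: columns on the edge of the valid region (masked on one
    # side) are not trustworthy maxima
    which(pk & nfin >= 5 & is.finite(M2) & M2 >= thr, arr.ind = TRUE)
  }
  hg2 <- matrix(hg, ni, nj)
  zs2 <- matrix(zs, ni, nj)
  collect <- function(pidx, M, zfun) {
    if (is.null(pidx) || !nrow(pidx)) return(NULL)
    out <- matrix(0, nrow(pidx), 4)
    for (q in seq_len(nrow(pidx))) {
      i <- pidx[q, 1]; j <- pidx[q, 2]
      Mc <- ifelse(is.finite(M), M, NA)
      oi <- if (i > 1 && i < ni && !anyNA(Mc[(i - 1):(i + 1), j]))
        parabolic_offset(Mc[, j], i) else 0
      oj <- if (j > 1 && j < nj && !anyNA(Mc[i, (j - 1):(j + 1)]))
        parabolic_offset(Mc[i, ], j) else 0
      out[q, ] <- c(ax[[1]][ii[1]] + (i - 1 + oi) * vox,
                    ax[[2]][jj[1]] + (j - 1 + oj) * vox,
                    zfun(i, j), M[i, j])
    }
    out
  }
  # Greedy saddle non-maximum suppression across both channels: a
  # candidate is suppressed when a stronger accepted detection nearby is
  # connected to it by a density saddle above half its own height (it is
  # then a shoulder of that density); candidates within merge_radius of
  # an accepted detection are merged regardless (nearby proteins are not
  # separately resolved). Chords across a ring of density dip through the
  # empty interior, so distinct points around a continuous ring survive.
  pk_free <- peaks2(M_free, inner2 & M_free >= thr_free_map, 0)
  p_free <- collect(pk_free, M_free,
                    function(i, j) zv[K_free[i, j]])
  p_mem <- collect(peaks2(M_mem, mem_valid, thr_mem), M_mem,
                   function(i, j) hg2[i, j] + 3)
  res0 <- rbind(p_free, p_mem)
  if (is.null(res0) || nrow(res0) == 0) {
    el <- empty_landmarks()
    attr(el, "excess_zscore") <- excess_z
    return(el)
  }
  Mcomb <- pmax(ifelse(is.finite(M_free), M_free, -Inf),
                ifelse(is.finite(M_mem), M_mem, -Inf))
  x0 <- ax[[1]][ii[1]]; y0 <- ax[[2]][jj[1]]
  saddle_to <- function(pa, pb) {
    ia <- (pa[1] - x0) / vox + 1; ja <- (pa[2] - y0) / vox + 1
    ib <- (pb[1] - x0) / vox + 1; jb <- (pb[2] - y0) / vox + 1
    dd <- sqrt(sum((pa[1:2] - pb[1:2])^2))
    ns <- max(2L, ceiling(dd / vox) + 1L)
    tseq <- seq(0, 1, length.out = ns)
    li <- pmin(pmax(round(ia + tseq * (ib - ia)), 1), ni)
    lj <- pmin(pmax(round(ja + tseq * (jb - ja)), 1), nj)
    lv <- Mcomb[cbind(li, lj)]
    fin <- is.finite(lv)
    if (mean(fin) >= 0.5) min(lv[fin]) else -Inf
  }
  ord <- order(-res0[, 4])
  acc <- list()
  for (o in ord) {
    cand <- res0[o, ]
    ok_pt <- TRUE
    for (a in acc) {
      dd <- sqrt(sum((cand[1:2] - a[1:2])^2))
      if (dd <= params$merge_radius) { ok_pt <- FALSE; break }
      if (dd <= 14 && saddle_to(cand, a) >= 0.55 * cand[4]) {
        ok_pt <- FALSE; break
      }
    }
    if (ok_pt) acc[[length(acc) + 1]] <- cand
  }
  out <- acc
  res <- do.call(rbind, out)
  x <- res[, 1]; y <- res[, 2]; z <- res[, 3]
  rho <- sqrt((x - cx)^2 + (y - cy)^2)
  hz <- interp_h(m, x, y)
  dz_suv <- abs(sqrt((x - cx)^2 + (y - cy)^2 + (z - czc)^2) - m$r_mid)
  comp <- ifelse(dz_suv <= 5, "suv_membrane",
                 ifelse(!is.na(hz) & z - hz <= 4.5, "guv_membrane",
                        "intermembrane"))
  out_df <- data.frame(x = x, y = y, z = z, rho = rho,
                       intensity = res[, 4],
                       compartment = comp, stringsAsFactors = FALSE)
  attr(out_df, "excess_zscore") <- excess_z
  out_df
}

empty_landmarks <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             rho = numeric(0), intensity = numeric(0),
             compartment = character(0), stringsAsFactors = FALSE)
}

# Nearest-column GUV height lookup for points (x, y).
interp_h <- function(m, x, y) {
  H <- matrix(m$h_guv, m$ni, m$nj)
  xs <- unique(m$x)[order(unique(m$x))]
  ys <- unique(m$y)[order(unique(m$y))]
  i <- pmin(pmax(round((x - xs[1]) / (xs[2] - xs[1])) + 1, 1), m$ni)
  j <- pmin(pmax(round((y - ys[1]) / (ys[2] - ys[1])) + 1, 1), m$nj)
  H[cbind(i, j)]
}

#' Measure everything at one docking site
#'
#' Convenience wrapper computing the surface maps once and returning
#' separation, contact diameter, protrusion call, density landmarks and
#' the morphology classification for a site.
#'
#' @inheritParams measure_separation
#' @param cparams a [classification_params()].
#' @return list with `separation`, `contact_diameter`, `protrusion`
#'   (flag/height), `landmarks`, `n_densities` and `class` (a
#'   `junction_class`).
#' @export
measure_junction <- function(sub, site, params = metric_params(),
                             cparams = classification_params()) {
  sm <- gauss_smooth3(sub$grid, params$smooth_sigma)
  m <- junction_surface_maps(sub, site, params, sm = sm)
  sep <- measure_separation(sub, site, params, maps = m)
  cd <- measure_contact_diameter(sub, site, params, maps = m,
                                 separation = sep$separation)
  lm <- detect_density_landmarks(sub, site, params, maps = m)
  pr <- detect_protrusion(sub, site, params, maps = m, landmarks = lm)
  ls <- as_local_site(site)
  base <- c(ls$center[1], ls$center[2],
            ls$center[3] - (ls$r_mid + params$bilayer_thickness / 2))
  cls <- classify_junction(lm, suv_base_point = base, params = cparams)
  list(separation = sep$separation, separation_flagged = sep$flagged,
       contact_diameter = cd, protrusion = pr, landmarks = lm,
       n_densities = nrow(lm), class = cls, maps = m)
}
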