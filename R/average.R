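# Landmark-based class averaging of oriented subtomograms.
#
# Members of a morphology class are aligned by pure translation (placing
# the SUV-base landmark at the common origin; the subtomograms are
# already axis-oriented) and averaged voxelwise. No angular search or
# iterative refinement is performed, and no missing-wedge compensation is
# applied.

#' Translate a subtomogram so a landmark sits at the origin
#'
#' Applies the pure translation that maps `suv_base_point` (local-frame
#' nm) to the origin, resampling on the same grid by trilinear
#' interpolation.
#'
#' @param sub oriented subtomogram ([tomo_volume()]).
#' @param suv_base_point the SUV base landmark in the subtomogram frame.
#' @return A [tomo_volume()] on the same grid; metadata records the
#'   translation applied (`shift`, nm).
#' @export
align_to_reference <- function(sub, suv_base_point) {
  stopifnot(inherits(sub, "tomo_volume"), length(suv_base_point) == 3)
  d <- dim(sub$grid)
  idx <- world_to_index(sub, rbind(suv_base_point))
  if (any(idx < 1) || any(idx > d))
    stop("landmark lies outside the subtomogram box")
  sh <- as.numeric(suv_base_point)
  if (all(abs(sh) < 1e-12)) {
    out <- sub
    out$metadata$shift <- c(0, 0, 0)
    return(out)
  }
  ax <- vol_axes(sub)
  n <- d[1]
  q <- cbind(rep(ax[[1]], times = d[2] * d[3]),
             rep(rep(ax[[2]], each = d[1]), times = d[3]),
             rep(ax[[3]], each = d[1] * d[2]))
  src <- sweep(q, 2, sh, `+`)
  vals <- interp3(sub$grid, sweep(src, 2, sub$origin, `-`) /
                    sub$voxel_size + 1)
  tomo_volume(array(vals, d), voxel_size = sub$voxel_size,
              origin = sub$origin,
              metadata = c(sub$metadata, list(shift = -sh)))
}

#' Average aligned subtomograms of one morphology class
#'
#' Voxelwise arithmetic mean over members on identical grids, with the
#' union of the members' density points (mapped by the members' recorded
#' shifts) as landmark overlay.
#'
#' @param volumes list of aligned [tomo_volume()]s with identical grids.
#' @param overlay_points optional list of per-member density point data
#'   frames (columns `x`, `y`, `z`, in each member's pre-alignment
#'   frame); the member's recorded `shift` is applied before pooling.
#' @param class_code class code the average represents (bookkeeping).
#' @param normalize normalise each member to zero mean / unit SD before
#'   averaging (default off).
#' @return object of class `class_average` with `average`
#'   ([tomo_volume()]), `n_subtomograms`, `class_code`, `overlay_points`.
#' @export
average_class <- function(volumes, overlay_points = NULL, class_code = NA,
                          normalize = FALSE) {
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]]$grid)
  for (v in volumes)
    if (!identical(dim(v$grid), d))
      stop("member grids differ; class averaging needs identical boxes")
  acc <- array(0, d)
  for (v in volumes) {
    g <- v$grid
    if (normalize) g <- (g - mean(g)) / stats::sd(g)
    acc <- acc + g
  }
  avg <- tomo_volume(acc / length(volumes),
                     voxel_size = volumes[[1]]$voxel_size,
                     origin = volumes[[1]]$origin,
                     metadata = list(n_members = length(volumes),
                                     class_code = class_code))
  overlay <- NULL
  if (!is.null(overlay_points)) {
    stopifnot(length(overlay_points) == length(volumes))
    pooled <- list()
    for (i in seq_along(volumes)) {
      pts <- overlay_points[[i]]
      if (is.null(pts) || nrow(pts) == 0) next
      sh <- volumes[[i]]$metadata$shift %||% c(0, 0, 0)
      p <- pts[, c("x", "y", "z"), drop = FALSE]
      p$x <- p$x + sh[1]; p$y <- p$y + sh[2]; p$z <- p$z + sh[3]
      p$member <- i
      pooled[[length(pooled) + 1]] <- p
    }
    overlay <- if (length(pooled)) do.call(rbind, pooled) else
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 member = integer(0))
  }
  structure(list(class_code = class_code,
                 n_subtomograms = length(volumes),
                 average = avg, overlay_points = overlay),
            class = "class_average")
}

#' @export
print.class_average <- function(x, ...) {
  cat(sprintf("<class_average> code %s, %d member(s)\n",
              format(x$class_code), x$n_subtomograms))
  print(x$average)
  if (!is.null(x$overlay_points))
    cat(sprintf("  overlay: %d density points\n", nrow(x$overlay_points)))
  invisible(x)
}

#' Cylindrical radial density profile of a class average
#'
#' Mean density in cylindrical shells about the docking axis (+z through
#' the aligned origin) within a height window at the intermembrane level.
#' The default window sits just below the aligned SUV base, where
#' intermembrane protein density accumulates but neither membrane of a
#' typical member does.
#'
#' @param avg a `class_average` or [tomo_volume()].
#' @param z_window height window (nm, relative to the aligned SUV base).
#' @param dr radial bin width (nm; default one voxel).
#' @param max_radius largest radius evaluated (nm).
#' @return data frame with `radius` (bin centre, nm) and `density`.
#' @export
radial_profile <- function(avg, z_window = c(-4.5, -1.5), dr = NULL,
                           max_radius = 40) {
  vol <- if (inherits(avg, "class_average")) avg$average else avg
  stopifnot(inherits(vol, "tomo_volume"))
  dr <- dr %||% vol$voxel_size
  ax <- vol_axes(vol)
  kk <- which(ax[[3]] >= z_window[1] & ax[[3]] <= z_window[2])
  if (!length(kk)) stop("z_window contains no voxel layers")
  d <- dim(vol$grid)
  rho <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  bins <- seq(0, max_radius + dr, by = dr)
  bin_of <- findInterval(rho, bins)
  sel <- rho <= max_radius
  sums <- numeric(length(bins) - 1)
  cnts <- numeric(length(bins) - 1)
  for (k in kk) {
    sl <- vol$grid[, , k]
    t1 <- tapply(sl[sel], bin_of[sel], sum)
    t2 <- tapply(rep(1, sum(sel)), bin_of[sel], sum)
    ix <- as.integer(names(t1))
    ok <- ix >= 1 & ix <= length(sums)
    sums[ix[ok]] <- sums[ix[ok]] + t1[ok]
    cnts[ix[ok]] <- cnts[ix[ok]] + t2[ok]
  }
  keep <- cnts > 0
  data.frame(radius = (bins[-length(bins)] + dr / 2)[keep],
             density = (sums / pmax(cnts, 1))[keep])
}
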