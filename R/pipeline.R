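# End-to-end drivers: volume-level analysis and simulation studies.

#' Analyse all docking sites in a volume
#'
#' Runs detection, oriented extraction and per-site quantification,
#' returning the per-site measurement table (the `sites.csv` content) and
#' the site objects.
#'
#' @param vol a [tomo_volume()].
#' @param params a [detection_params()].
#' @param mparams a [metric_params()].
#' @param cparams a [classification_params()].
#' @param condition condition label recorded in the table.
#' @return list with `table` (one row per site: geometry, separation,
#'   contact diameter, protrusion, density count, class code and ring
#'   completeness) and `sites` (list of `docking_site` objects, each with
#'   a `measurements` element).
#' @export
analyze_docking_volume <- function(vol, params = detection_params(),
                                   mparams = metric_params(),
                                   cparams = classification_params(),
                                   condition = "default") {
  sites <- find_docking_sites(vol, params = params, mparams = mparams)
  rows <- list()
  for (s in sites) {
    mj <- tryCatch(measure_junction(s$subtomogram, s, mparams, cparams),
                   error = function(e) NULL)
    if (is.null(mj)) next
    sites[[s$site_id]]$measurements <- mj
    rows[[length(rows) + 1]] <- data.frame(
      site_id = s$site_id, condition = condition,
      x = s$suv_center[1], y = s$suv_center[2], z = s$suv_center[3],
      suv_radius_nm = s$suv_radius,
      separation_nm = mj$separation,
      contact_diameter_nm = mj$contact_diameter,
      protrusion_flag = mj$protrusion$flag,
      protrusion_height_nm = mj$protrusion$height,
      n_densities = mj$n_densities,
      class_code = mj$class$class_code,
      n_inside = mj$class$n_inside, n_outside = mj$class$n_outside,
      ring_completeness = mj$class$ring_completeness,
      stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  list(table = table, sites = sites)
}

#' Simulate a junction population and analyse it through the full path
#'
#' For each junction: generates a one-junction scene with the configured
#' generator defaults, renders it into a noisy wedge-filtered volume,
#' runs the full detection/measurement pipeline, and pairs the recovered
#' values with the ground truth. This is the workhorse behind the
#' parameter-recovery validation.
#'
#' @param n number of junctions.
#' @param seed base seed; junction `i` uses seeds derived from it.
#' @param scene_args named list of [scene_params()] overrides.
#' @param optics an [optics_params()].
#' @param params,mparams,cparams analysis parameter objects.
#' @param min_lateral_extent minimal rendered lateral extent (nm), so the
#'   analysis window around each junction is fully covered.
#' @param keep_sites also return the per-junction site objects.
#' @param progress print a dot every 25 junctions.
#' @return data frame with one row per junction: ground truth columns
#'   (prefix `true_`), recovered columns (prefix `est_`), `detected`
#'   flag and `n_extra_sites` (spurious detections in the same volume).
#' @export
simulate_junction_study <- function(n, seed = 1, scene_args = list(),
                                    optics = optics_params(),
                                    params = detection_params(),
                                    mparams = metric_params(),
                                    cparams = classification_params(),
                                    min_lateral_extent = 100,
                                    keep_sites = FALSE,
                                    progress = FALSE) {
  rows <- vector("list", n)
  site_list <- if (keep_sites) vector("list", n)
  for (i in seq_len(n)) {
    sp <- do.call(scene_params,
                  c(list(n_junctions = 1, seed = seed + 7L * i),
                    scene_args))
    sc <- generate_scene(sp)
    gt <- sc$ground_truth
    bb <- scene_bbox(sc)
    ext <- bb[, 2] - bb[, 1]
    ext[2:3] <- pmax(ext[2:3], min_lateral_extent)
    dims <- vapply(1:3, function(a)
      next_fft_size(ceiling(ext[a] / optics$voxel_size) + 1L), 1L)
    ctr <- (bb[, 1] + bb[, 2]) / 2
    origin <- ctr - (dims - 1) / 2 * optics$voxel_size
    vol <- render_volume(sc, optics, origin = origin, dims = dims,
                         seed = seed + 7L * i + 3L, check_fit = FALSE)
    sites <- tryCatch(find_docking_sites(vol, params = params,
                                         mparams = mparams),
                      error = function(e) list())
    truth_center <- sc$junctions[[1]]$suv_center
    best <- NULL; best_d <- Inf
    for (s in sites) {
      dd <- sqrt(sum((s$suv_center - truth_center)^2))
      if (dd < best_d) { best <- s; best_d <- dd }
    }
    matched <- !is.null(best) && best_d < 20
    row <- data.frame(
      junction_id = i,
      true_class = gt$class, true_code = gt$class_code,
      true_separation = gt$separation_nm,
      true_protrusion = gt$protrusion_flag,
      true_n_densities = gt$n_densities,
      true_contact_diameter = gt$contact_diameter_nm,
      true_suv_diameter = gt$suv_diameter_nm,
      detected = matched,
      n_extra_sites = max(length(sites) - as.integer(matched), 0L),
      est_separation = NA_real_, est_code = NA_real_,
      est_protrusion = NA_integer_, est_n_densities = NA_integer_,
      est_contact_diameter = NA_real_, est_suv_radius = NA_real_,
      stringsAsFactors = FALSE)
    if (matched) {
      mj <- tryCatch(measure_junction(best$subtomogram, best, mparams,
                                      cparams),
                     error = function(e) NULL)
      if (!is.null(mj)) {
        row$est_separation <- mj$separation
        row$est_code <- mj$class$class_code
        row$est_protrusion <- mj$protrusion$flag
        row$est_n_densities <- mj$n_densities
        row$est_contact_diameter <- mj$contact_diameter
        row$est_suv_radius <- best$suv_radius
      }
      if (keep_sites) {
        best$truth <- sc$junctions[[1]]
        site_list[[i]] <- best
      }
    }
    rows[[i]] <- row
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  if (keep_sites) attr(out, "sites") <- site_list
  out
}

#' Simulate class-conditional junction codes and separations
#'
#' Draws morphology classes and class-conditional uniform separations
#' without rendering -- the population model behind the class-separation
#' correlation. Useful for statistical checks at large n.
#'
#' @param n number of junctions.
#' @param class_probs class probabilities (clustered, intermediate,
#'   ring_like).
#' @param separation_ranges per-class uniform ranges (nm).
#' @param seed RNG seed.
#' @return data frame with `class`, `class_code`, `separation_nm`.
#' @export
simulate_code_separation <- function(n,
                                     class_probs = c(1, 1, 1) / 3,
                                     separation_ranges =
                                       list(clustered = c(5, 26),
                                            intermediate = c(3, 8),
                                            ring_like = c(0, 7)),
                                     seed = NULL) {
  with_seed(seed, {
    cls <- sample(CLASS_LEVELS, n, replace = TRUE, prob = class_probs)
    sep <- vapply(cls, function(cl) {
      r <- separation_ranges[[cl]]
      stats::runif(1, r[1], r[2])
    }, 0)
    data.frame(class = cls, class_code = unname(CLASS_CODES[cls]),
               separation_nm = sep, stringsAsFactors = FALSE)
  })
}
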