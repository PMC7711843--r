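# Junction morphology classification.
#
# Operational definition of the three verbal morphology classes: density
# points are split by an exclusion cylinder of radius r_ex about the
# docking axis through the SUV base. All points inside -> clustered (0);
# none inside and at least min_ring_points outside -> ring-like (1);
# anything mixed -> intermediate (0.5).

#' Classification parameters
#'
#' @param exclusion_radius cylinder radius r_ex (nm) about the docking
#'   axis separating inside from outside points (default 10, half the
#'   scale of typical ring contact diameters).
#' @param min_ring_points minimal number of outside points for a
#'   ring-like call.
#' @param angular_bins number of angular bins for [ring_completeness()].
#' @return list of class `classification_params`.
#' @export
classification_params <- function(exclusion_radius = 10,
                                  min_ring_points = 3,
                                  angular_bins = 12) {
  stopifnot(exclusion_radius > 0, angular_bins >= 4, min_ring_points >= 1)
  structure(list(exclusion_radius = exclusion_radius,
                 min_ring_points = min_ring_points,
                 angular_bins = angular_bins),
            class = "classification_params")
}

# Coordinates of points relative to the docking axis through `base`
# (axis = +z of the frame the points live in).
axis_coords <- function(points, suv_base_point) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- rbind(points)
  dx <- points[, 1] - suv_base_point[1]
  dy <- points[, 2] - suv_base_point[2]
  list(rho = sqrt(dx^2 + dy^2), theta = atan2(dy, dx),
       z = points[, 3] - suv_base_point[3])
}

#' Classify a junction's density arrangement
#'
#' @param points density landmarks as a data frame with columns
#'   `x`, `y`, `z` (from [detect_density_landmarks()]) or an n x 3 matrix,
#'   in the oriented frame (docking axis = +z).
#' @param suv_base_point the SUV base (closest-approach point on the SUV)
#'   in the same frame; the exclusion cylinder runs through its (x, y).
#' @param params a [classification_params()].
#' @return object of class `junction_class`: list with `class_code`
#'   (0, 0.5 or 1; `NA` with `flagged = TRUE` for zero points),
#'   `class` label, `n_inside`, `n_outside` and `ring_completeness`.
#' @export
classify_junction <- function(points, suv_base_point = c(0, 0, 0),
                              params = classification_params()) {
  n <- if (is.data.frame(points)) nrow(points) else nrow(rbind(points))
  if (is.null(n) || n == 0) {
    return(structure(list(class_code = NA_real_, class = NA_character_,
                          n_inside = 0L, n_outside = 0L,
                          ring_completeness = NA_real_, flagged = TRUE),
                     class = "junction_class"))
  }
  ac <- axis_coords(points, suv_base_point)
  inside <- ac$rho <= params$exclusion_radius
  n_in <- sum(inside); n_out <- sum(!inside)
  code <- if (n_in >= 1 && n_out == 0) 0
  else if (n_in == 0 && n_out >= params$min_ring_points) 1
  else 0.5
  structure(list(
    class_code = code,
    class = c("0" = "clustered", "0.5" = "intermediate",
              "1" = "ring_like")[as.character(code)],
    n_inside = n_in, n_outside = n_out,
    ring_completeness = ring_completeness(points, suv_base_point, params),
    flagged = FALSE), class = "junction_class")
}

#' @export
print.junction_class <- function(x, ...) {
  cat(sprintf("<junction_class> %s (code %s): %d inside / %d outside r_ex, completeness %.2f\n",
              x$class %||% "undefined", format(x$class_code), x$n_inside,
              x$n_outside, x$ring_completeness %||% NA))
  invisible(x)
}

#' Angular completeness of the outside-point ring
#'
#' Fraction of angular bins about the docking axis that contain at least
#' one density point outside the exclusion cylinder.
#'
#' @inheritParams classify_junction
#' @return fraction in `[0, 1]`; 0 when there are no outside points.
#' @export
ring_completeness <- function(points, suv_base_point = c(0, 0, 0),
                              params = classification_params()) {
  n <- if (is.data.frame(points)) nrow(points) else nrow(rbind(points))
  if (is.null(n) || n == 0) return(0)
  ac <- axis_coords(points, suv_base_point)
  out <- ac$rho > params$exclusion_radius
  if (!any(out)) return(0)
  b <- floor((ac$theta[out] + pi) / (2 * pi) * params$angular_bins)
  b[b >= params$angular_bins] <- params$angular_bins - 1L
  length(unique(b)) / params$angular_bins
}
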