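# Landmark coordinate tables.
#
# On-disk dialect: CSV with header `site_id,kind,x_nm,y_nm,z_nm,compartment`
# and optional `#`-prefixed metadata lines, e.g.
#   # units: voxel
#   # voxel_size_nm: 2.34
# Coordinates are nm unless a `# units: voxel` line (or the `units` argument)
# declares voxel units, in which case a voxel size must be available and
# 0-based voxel coordinates are converted to nm. `kind` is one of
# "suv_center", "midpoint", "suv_outer_leaflet", "density"; `compartment`
# tags density points as "suv_membrane", "guv_membrane" or "intermembrane"
# and is empty for the geometric landmarks.

LANDMARK_COLUMNS <- c("site_id", "kind", "x_nm", "y_nm", "z_nm", "compartment")
LANDMARK_KINDS <- c("suv_center", "midpoint", "suv_outer_leaflet", "density")
COMPARTMENTS <- c("suv_membrane", "guv_membrane", "intermembrane")

#' Read a landmark table
#'
#' @param path CSV file in the dialect documented above.
#' @param units coordinate units of the file; default `"auto"` honours a
#'   `# units:` metadata line and otherwise assumes nm.
#' @param voxel_size voxel size in nm, required when coordinates are in
#'   voxels and the file carries no `# voxel_size_nm:` line.
#' @return A list of landmark sets, one per `site_id`. Each set is a list
#'   with `site_id`, the named 3-vectors `suv_center`, `midpoint`,
#'   `suv_outer_leaflet_point` (when present), a data frame `density_points`
#'   (`x`, `y`, `z`, `compartment` plus any extra columns of the file), and
#'   `extra`, a data frame of unrecognised columns for the geometric rows.
#' @export
read_landmarks <- function(path, units = c("auto", "nm", "voxel"),
                           voxel_size = NULL) {
  units <- match.arg(units)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^\\s*#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_. ]+?)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[gsub("\\s+", "_", tolower(m[2]))]] <- trimws(m[3])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) <= 1)
    return(list())
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(missing_cols))
    stop("landmark table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (units == "auto")
    units <- if (identical(meta$units, "voxel")) "voxel" else "nm"
  if (units == "voxel") {
    vs <- voxel_size %||% as.numeric(meta$voxel_size_nm %||% NA)
    if (!is.finite(vs) || vs <= 0)
      stop("voxel-unit landmark table requires a positive voxel size ",
           "(voxel_size argument or '# voxel_size_nm:' metadata line)")
    df[c("x_nm", "y_nm", "z_nm")] <- df[c("x_nm", "y_nm", "z_nm")] * vs
  }
  bad <- !is.finite(df$x_nm) | !is.finite(df$y_nm) | !is.finite(df$z_nm)
  if (any(bad)) stop("landmark table contains non-finite coordinates")
  dens <- df$kind == "density"
  bad_comp <- dens & !(df$compartment %in% COMPARTMENTS)
  if (any(bad_comp))
    stop("unknown density compartment tag(s): ",
         paste(unique(df$compartment[bad_comp]), collapse = ", "))
  extra_cols <- setdiff(names(df), LANDMARK_COLUMNS)
  sets <- lapply(split(df, df$site_id), function(s) {
    pt <- function(kind) {
      r <- s[s$kind == kind, , drop = FALSE]
      if (nrow(r) == 0) NULL else c(x = r$x_nm[1], y = r$y_nm[1], z = r$z_nm[1])
    }
    dd <- s[s$kind == "density", , drop = FALSE]
    dp <- data.frame(x = dd$x_nm, y = dd$y_nm, z = dd$z_nm,
                     compartment = dd$compartment, stringsAsFactors = FALSE)
    if (length(extra_cols)) dp <- cbind(dp, dd[extra_cols])
    list(site_id = s$site_id[1],
         suv_center = pt("suv_center"),
         midpoint = pt("midpoint"),
         suv_outer_leaflet_point = pt("suv_outer_leaflet"),
         density_points = dp,
         extra = s[s$kind != "density", extra_cols, drop = FALSE])
  })
  unname(sets)
}

#' Write a landmark table
#'
#' @param sets list of landmark sets in the layout returned by
#'   [read_landmarks()] (a single set may be passed directly).
#' @param path output CSV path.
#' @param digits coordinate precision (decimal places) written.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path, digits = 6) {
  if (!is.null(sets$site_id)) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    out <- list()
    geo <- function(kind, p) {
      if (is.null(p)) return(NULL)
      data.frame(site_id = s$site_id, kind = kind,
                 x_nm = p[1], y_nm = p[2], z_nm = p[3],
                 compartment = "", stringsAsFactors = FALSE)
    }
    out$c <- geo("suv_center", s$suv_center)
    out$m <- geo("midpoint", s$midpoint)
    out$o <- geo("suv_outer_leaflet", s$suv_outer_leaflet_point)
    dp <- s$density_points
    if (!is.null(dp) && nrow(dp) > 0)
      out$d <- data.frame(site_id = s$site_id, kind = "density",
                          x_nm = dp$x, y_nm = dp$y, z_nm = dp$z,
                          compartment = as.character(dp$compartment),
                          stringsAsFactors = FALSE)
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- stats::setNames(
      data.frame(character(), character(), numeric(), numeric(), numeric(),
                 character(), stringsAsFactors = FALSE), LANDMARK_COLUMNS)
  num <- c("x_nm", "y_nm", "z_nm")
  df[num] <- lapply(df[num], function(x) round(x, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dataset manifest
#'
#' Serialises a named list of provenance/parameters as pretty-printed JSON,
#' the per-dataset manifest that accompanies volumes and landmark tables.
#'
#' @param x named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
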