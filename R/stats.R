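# Correlation statistics and summary tables over junction measurements.

CC_VARS <- c("class_code", "separation_nm", "protrusion_flag", "n_densities")

#' Pearson correlation matrix over junction parameters
#'
#' Computes pairwise Pearson correlations between the four measured
#' junction parameters (morphology class code, membrane separation,
#' protrusion flag, number of protein densities), with two-sided p-values
#' from the t statistic `t = r * sqrt((n - 2) / (1 - r^2))` and strength
#' labels. Correlations are computed per condition and pooled. The coded
#' class (0 / 0.5 / 1) and protrusion flag (0 / 1) enter as plain numeric
#' values, exactly as coded.
#'
#' @param table data frame with columns `class_code`, `separation_nm`,
#'   `protrusion_flag`, `n_densities` and optionally `condition`.
#' @param vars variables to correlate (default the four above).
#' @param by grouping column name (default `"condition"` when present).
#' @return object of class `cc_result`: a list with one element per group
#'   (plus `"pooled"`), each holding matrices `r`, `p`, `n`, a character
#'   matrix `strength`, and `p_bonferroni` (Bonferroni-adjusted p-values,
#'   emitted for transparency; the headline p-values are unadjusted).
#'   Zero-variance variables give `NA` (not 0) correlations.
#' @examples
#' tb <- data.frame(class_code = c(0, 0.5, 1, 0, 1),
#'                  separation_nm = c(20, 6, 2, 15, 1),
#'                  protrusion_flag = c(1, 0, 0, 1, 0),
#'                  n_densities = c(5, 8, 11, 3, 9))
#' cc_matrix(tb)$pooled$r
#' @export
cc_matrix <- function(table, vars = CC_VARS, by = NULL) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("junction table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(by) && "condition" %in% names(table)) by <- "condition"
  groups <- list(pooled = table)
  if (!is.null(by) && by %in% names(table) &&
      length(unique(table[[by]])) > 1)
    groups <- c(groups, split(table, table[[by]]))
  out <- lapply(groups, function(g) cc_one_group(g, vars))
  structure(out, class = "cc_result")
}

cc_one_group <- function(g, vars) {
  g <- g[stats::complete.cases(g[vars]), vars, drop = FALSE]
  k <- length(vars)
  n <- nrow(g)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  if (n >= 3) {
    for (a in 1:k) for (b in 1:k) {
      x <- g[[a]]; y <- g[[b]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r[a, b] <- NA
        next
      }
      rr <- stats::cor(x, y)
      r[a, b] <- rr
      if (a == b) {
        p[a, b] <- 0
      } else if (abs(rr) < 1) {
        tval <- rr * sqrt((n - 2) / (1 - rr^2))
        p[a, b] <- 2 * stats::pt(-abs(tval), df = n - 2)
      } else p[a, b] <- 0
    }
  } else warning("fewer than 3 complete rows; correlations undefined")
  m_tests <- k * (k - 1) / 2
  list(r = r, p = p, n = n,
       strength = matrix(strength_label(r), k, k,
                         dimnames = dimnames(r)),
       p_bonferroni = pmin(p * m_tests, 1))
}

#' @export
print.cc_result <- function(x, digits = 3, ...) {
  for (g in names(x)) {
    cat("==", g, sprintf("(n = %d)\n", x[[g]]$n))
    print(round(x[[g]]$r, digits))
  }
  invisible(x)
}

#' Correlation strength labels
#'
#' Labels correlation magnitudes: below 0.1 `negligible`, 0.1 to below
#' 0.3 `small`, 0.3 to below 0.5 `moderate`, 0.5 and above `strong`
#' (intervals closed on the left). `NA`/NaN values give `NA`.
#'
#' @param r numeric vector of correlation coefficients (|r| <= 1).
#' @return character vector.
#' @examples
#' strength_label(c(-0.76, 0.22, 0.05))
#' @export
strength_label <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  a <- abs(r)
  out <- rep(NA_character_, length(r))
  ok <- !is.na(a) & is.finite(a)
  out[ok & a < 0.1] <- "negligible"
  out[ok & a >= 0.1 & a < 0.3] <- "small"
  out[ok & a >= 0.3 & a < 0.5] <- "moderate"
  out[ok & a >= 0.5] <- "strong"
  out
}

#' Summary statistics of a junction table
#'
#' Per condition: fraction of sites with separation below 10 nm, count
#' above 20 nm, per-class separation ranges, mean and SD of the density
#' count, mean and SD of the contact diameter over ring-like contacts,
#' and 1-nm-binned stacked histogram counts of separation by class.
#'
#' @param table junction data frame (columns `class_code`,
#'   `separation_nm`, `n_densities`; optionally `contact_diameter_nm`,
#'   `condition`).
#' @param by grouping column (default `"condition"` when present).
#' @return named list of per-condition summaries (class
#'   `junction_summary`). Conditions with no rows give `NA` summaries.
#' @export
summarize_junctions <- function(table, by = NULL) {
  if (is.null(by) && "condition" %in% names(table)) by <- "condition"
  groups <- if (!is.null(by) && by %in% names(table))
    split(table, table[[by]], drop = FALSE)
  else list(all = table)
  out <- lapply(groups, function(g) {
    if (nrow(g) == 0 || all(is.na(g$separation_nm)))
      return(list(n = nrow(g), frac_sep_lt_10 = NA, n_sep_gt_20 = NA,
                  sep_range_by_class = NULL, densities_mean = NA,
                  densities_sd = NA, contact_diameter_mean = NA,
                  contact_diameter_sd = NA, histogram = NULL))
    sep <- g$separation_nm
    cls <- g$class_code
    rng <- tapply(sep, cls, function(v) range(v, na.rm = TRUE))
    cd <- if ("contact_diameter_nm" %in% names(g))
      g$contact_diameter_nm[cls == 1 & g$contact_diameter_nm > 0]
    else numeric(0)
    breaks <- seq(0, max(ceiling(max(sep, na.rm = TRUE)), 1), by = 1)
    if (max(breaks) <= max(sep, na.rm = TRUE))
      breaks <- c(breaks, max(breaks) + 1)
    hist_counts <- t(vapply(sort(unique(cls)), function(cc) {
      h <- graphics::hist(sep[cls == cc], breaks = breaks, plot = FALSE)
      h$counts
    }, numeric(length(breaks) - 1)))
    rownames(hist_counts) <- paste0("class_", sort(unique(cls)))
    list(n = nrow(g),
         frac_sep_lt_10 = mean(sep < 10, na.rm = TRUE),
         n_sep_gt_20 = sum(sep > 20, na.rm = TRUE),
         sep_range_by_class = rng,
         densities_mean = mean(g$n_densities, na.rm = TRUE),
         densities_sd = stats::sd(g$n_densities),
         contact_diameter_mean = if (length(cd)) mean(cd) else NA,
         contact_diameter_sd = if (length(cd) > 1) stats::sd(cd) else NA,
         histogram = list(breaks = breaks, counts = hist_counts))
  })
  structure(out, class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  for (g in names(x)) {
    s <- x[[g]]
    cat(sprintf("== %s: n = %d", g, s$n))
    if (!is.na(s$frac_sep_lt_10))
      cat(sprintf(", %.0f%% below 10 nm separation, %d above 20 nm",
                  100 * s$frac_sep_lt_10, s$n_sep_gt_20))
    cat("\n")
    if (!is.na(s$densities_mean))
      cat(sprintf("   densities per site: %.1f +/- %.1f\n",
                  s$densities_mean, s$densities_sd %||% NA))
  }
  invisible(x)
}
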