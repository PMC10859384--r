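#' Filter subsampling layout
#'
#' Geometry of the subsampled imaging regions on a membrane filter. Defaults
#' describe a 25 mm aluminum-oxide filter whose 2.5 mm outer polypropylene
#' ring leaves a 20 mm active diameter, subsampled by nine evenly spaced
#' 480 um x 640 um regions. With that geometry the geometric coverage is
#' 0.880%; `coverage_override` lets a caller impose an externally reported
#' coverage (e.g. a printed 0.87%) instead, and its use is flagged with a
#' warning.
#'
#' @param filter_diameter_mm Overall filter diameter.
#' @param active_diameter_mm Diameter of the particle-bearing area.
#' @param region_width_um,region_height_um Region extent in um.
#' @param n_regions Number of subsampled regions.
#' @param region_centers_mm Optional `n_regions x 2` matrix of region centre
#'   coordinates (mm, origin at filter centre); default is a centred 3 x 3
#'   grid at 6 mm spacing when `n_regions == 9`.
#' @param coverage_override Optional externally specified coverage fraction.
#' @return An object of class `filter_layout`.
#' @export
filter_layout <- function(filter_diameter_mm = 25, active_diameter_mm = 20,
                          region_width_um = 640, region_height_um = 480,
                          n_regions = 9, region_centers_mm = NULL,
                          coverage_override = NULL) {
  if (active_diameter_mm <= 0 || active_diameter_mm > filter_diameter_mm) {
    stop_param("active diameter must be positive and <= filter diameter")
  }
  if (is.null(region_centers_mm)) {
    if (n_regions == 9) {
      g <- c(-6, 0, 6)
      region_centers_mm <- as.matrix(expand.grid(x = g, y = g))
    } else if (n_regions == 1) {
      region_centers_mm <- matrix(0, 1, 2)
    } else {
      stop_param("supply region_centers_mm for layouts other than 1 or 9 regions")
    }
  }
  region_centers_mm <- as.matrix(region_centers_mm)
  if (nrow(region_centers_mm) != n_regions) {
    stop_param("need one centre per region")
  }
  half_diag <- sqrt((region_width_um / 2000)^2 + (region_height_um / 2000)^2)
  r_active <- active_diameter_mm / 2
  if (any(sqrt(rowSums(region_centers_mm^2)) + half_diag > r_active + 1e-9)) {
    stop_param("regions must fit inside the active filter area")
  }
  structure(
    list(filter_diameter_mm = filter_diameter_mm,
         active_diameter_mm = active_diameter_mm,
         region_width_um = region_width_um,
         region_height_um = region_height_um,
         n_regions = n_regions,
         region_centers_mm = region_centers_mm,
         coverage_override = coverage_override),
    class = "filter_layout"
  )
}

#' Coverage fraction of the subsampled regions
#'
#' Summed region area divided by the active filter area, or the layout's
#' `coverage_override` when one is set (reported with a warning so the
#' substitution is never silent).
#'
#' @param layout A `filter_layout`.
#' @return Coverage fraction in (0, 1\].
#' @export
coverage_fraction <- function(layout) {
  if (!is.null(layout$coverage_override)) {
    warning(sprintf("using coverage_override = %g instead of geometric coverage",
                    layout$coverage_override))
    return(layout$coverage_override)
  }
  region_mm2 <- layout$region_width_um * layout$region_height_um / 1e6
  active_mm2 <- pi * (layout$active_diameter_mm / 2)^2
  cov <- layout$n_regions * region_mm2 / active_mm2
  if (cov <= 0 || cov > 1) stop_param("coverage fraction outside (0, 1]")
  cov
}

#' Extrapolate subsample counts to the whole filter
#'
#' Replicate subsample counts (particles seen across the subsampled regions
#' of one filter, one value per replicate filter) are summarized as
#' mean +/- sd and divided by the coverage fraction. Replicates are the unit
#' of uncertainty; sd scales by the same factor as the mean (no Poisson
#' correction).
#'
#' @param counts Numeric vector of per-replicate subsample counts.
#' @param coverage Coverage fraction in (0, 1).
#' @return An object of class `quant_estimate` with `mean_count`, `sd_count`,
#'   `coverage`, `filter_total_mean`, `filter_total_sd`.
#' @export
extrapolate <- function(counts, coverage) {
  if (!length(counts)) stop_data("need at least one replicate count")
  if (any(counts < 0)) stop_data("counts must be non-negative")
  if (coverage <= 0 || coverage > 1) stop_param("coverage must be in (0, 1]")
  m <- mean(counts)
  s <- if (length(counts) > 1L) stats::sd(counts) else 0
  structure(
    list(mean_count = m, sd_count = s, coverage = coverage,
         filter_total_mean = m / coverage, filter_total_sd = s / coverage,
         n_units = NA_integer_, per_unit_mean = NA_real_,
         per_unit_sd = NA_real_),
    class = "quant_estimate"
  )
}

#' Manually specified whole-filter estimate
#'
#' Wraps an already extrapolated total (e.g. a reported filter count with
#' its sd) in a `quant_estimate` for downstream per-unit normalization.
#'
#' @param total_mean,total_sd Whole-filter particle count mean and sd.
#' @return A `quant_estimate`.
#' @export
quant_estimate <- function(total_mean, total_sd = 0) {
  if (total_mean < 0 || total_sd < 0) stop_data("totals must be non-negative")
  structure(
    list(mean_count = NA_real_, sd_count = NA_real_, coverage = NA_real_,
         filter_total_mean = total_mean, filter_total_sd = total_sd,
         n_units = NA_integer_, per_unit_mean = NA_real_,
         per_unit_sd = NA_real_),
    class = "quant_estimate"
  )
}

#' Normalize a whole-filter estimate per released unit
#'
#' Divides the filter total (mean and sd) by the number of source units
#' steeped onto the filter (e.g. three teabags per replicate), giving the
#' per-unit release. Printed to 1 decimal by `print()`; full precision
#' retained.
#'
#' @param est A `quant_estimate`.
#' @param n_units Integer >= 1.
#' @return The estimate with `per_unit_mean` / `per_unit_sd` filled in.
#' @export
per_unit <- function(est, n_units) {
  if (!inherits(est, "quant_estimate")) stop_param("est must be a quant_estimate")
  if (n_units < 1) stop_param("n_units must be >= 1")
  est$n_units <- as.integer(n_units)
  est$per_unit_mean <- est$filter_total_mean / n_units
  est$per_unit_sd <- est$filter_total_sd / n_units
  est
}

#' @export
print.quant_estimate <- function(x, ...) {
  cat(sprintf("<quant_estimate> filter total %.1f +/- %.1f\n",
              x$filter_total_mean, x$filter_total_sd))
  if (!is.na(x$n_units)) {
    cat(sprintf("  per unit (n = %d): %.1f +/- %.1f\n",
                x$n_units, x$per_unit_mean, x$per_unit_sd))
  }
  invisible(x)
}

#' Mass of counted spheres
#'
#' Total mass in mg of `count` spheres of the given diameter and density
#' (`count * density * pi * d^3 / 6`), used for the microsphere
#' representativeness check. The default diameter is the midpoint of the
#' supplier's 15-20 um range.
#'
#' @param count Number of spheres (>= 0).
#' @param diameter_um Sphere diameter in um (sanity range 1-100).
#' @param density_g_cm3 Material density (nylon default 1.13).
#' @return Mass in mg.
#' @export
sphere_mass <- function(count, diameter_um = 17.5, density_g_cm3 = 1.13) {
  if (count < 0) stop_data("count must be >= 0")
  if (diameter_um <= 0) stop_param("diameter must be positive")
  if (diameter_um < 1 || diameter_um > 100) {
    stop_param("diameter outside the 1-100 um sanity range")
  }
  vol_cm3 <- pi * (diameter_um * 1e-4)^3 / 6
  count * density_g_cm3 * vol_cm3 * 1000
}

#' Representativeness ratio of a subsampling scheme
#'
#' Ratio of the mass estimated from extrapolated particle counts to the
#' nominally deposited mass; values above 1 flag overestimation.
#'
#' @param estimated_mass_mg Extrapolated mass on the filter.
#' @param nominal_mass_mg Mass actually deposited (> 0), default 0.05 mg.
#' @return The quotient.
#' @export
representativeness_ratio <- function(estimated_mass_mg, nominal_mass_mg = 0.05) {
  if (nominal_mass_mg <= 0) stop_param("nominal mass must be > 0")
  estimated_mass_mg / nominal_mass_mg
}

#' MP / all-particle ratio
#'
#' Fraction of detected particles classified MP; the score used to compare
#' contamination-reduction treatments.
#'
#' @param records Data frame with a `class` column (`"MP"` / `"NON_MP"`).
#' @return Fraction in \[0, 1\].
#' @export
mp_all_ratio <- function(records) {
  if (!nrow(records)) stop_data("no particles")
  mean(records$class == "MP")
}

#' Compare MP/All ratios between two treatments
#'
#' Paired t-test for before/after measurements of the same filter regions,
#' or a Welch two-sample t-test for independent groups ("normal" t-test with
#' the safer unequal-variance default; `var_equal = TRUE` gives the pooled
#' version).
#'
#' @param a,b Numeric vectors of MP/All ratios.
#' @param paired Paired or two-sample comparison.
#' @param alpha Significance level.
#' @param var_equal Pooled-variance two-sample test instead of Welch.
#' @return List with `statistic`, `df`, `p_value`, `significant`, `method`,
#'   `alpha`.
#' @export
compare_treatments <- function(a, b, paired = FALSE, alpha = 0.05,
                               var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop_data("need >= 2 values per group")
  if (paired && length(a) != length(b)) {
    stop_data("paired comparison requires equal lengths")
  }
  # zero-variance comparisons (e.g. identical groups) have no t distribution;
  # report the limit instead of failing
  degenerate <- if (paired) stats::sd(a - b) == 0 else {
    stats::sd(a) == 0 && stats::sd(b) == 0
  }
  if (degenerate) {
    delta <- mean(a) - mean(b)
    return(list(statistic = if (delta == 0) 0 else Inf * sign(delta),
                df = NA_real_,
                p_value = if (delta == 0) 1 else 0,
                significant = delta != 0,
                method = if (paired) "Paired t-test (degenerate)" else
                  "Two-sample t-test (degenerate)",
                alpha = alpha))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       significant = tt$p.value < alpha,
       method = tt$method,
       alpha = alpha)
}

#' Write / read a filter layout as JSON
#'
#' @param layout A `filter_layout`.
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` the
#'   restored `filter_layout`.
#' @export
write_layout <- function(layout, path) {
  l <- unclass(layout)
  l$region_centers_mm <- apply(layout$region_centers_mm, 1L, as.numeric,
                               simplify = FALSE)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_layout(
    filter_diameter_mm = l$filter_diameter_mm,
    active_diameter_mm = l$active_diameter_mm,
    region_width_um = l$region_width_um,
    region_height_um = l$region_height_um,
    n_regions = l$n_regions,
    region_centers_mm = if (is.list(l$region_centers_mm)) {
      do.call(rbind, l$region_centers_mm)
    } else l$region_centers_mm,
    coverage_override = l$coverage_override
  )
}
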