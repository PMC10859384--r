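#' Pearson correlation between two spectra
#'
#' Standard Pearson correlation, optionally restricted to a subset of
#' wavenumbers (e.g. the four discriminative bands) before correlating.
#'
#' @param a,b Numeric intensity vectors or `optir_spectrum` objects on the
#'   same grid.
#' @param wavenumber Grid for plain numeric inputs; taken from the spectra
#'   when `a`/`b` are `optir_spectrum` objects.
#' @param restrict Optional wavenumbers to correlate over; each must lie on
#'   the grid.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b, wavenumber = NULL, restrict = NULL) {
  if (inherits(a, "optir_spectrum")) {
    wavenumber <- wavenumber %||% a$wavenumber
    a <- a$intensity
  }
  if (inherits(b, "optir_spectrum")) {
    wavenumber <- wavenumber %||% b$wavenumber
    b <- b$intensity
  }
  if (length(a) != length(b)) stop_data("spectra must share one grid")
  if (!is.null(restrict)) {
    if (is.null(wavenumber)) {
      stop_param("restrict requires the wavenumber grid")
    }
    idx <- match(restrict, wavenumber)
    if (any(is.na(idx))) {
      stop_param(sprintf("restriction wavenumbers not on grid: %s",
                         paste(restrict[is.na(idx)], collapse = ", ")))
    }
    a <- a[idx]
    b <- b[idx]
  }
  if (length(a) < 2L) stop_degenerate("need >= 2 points after restriction")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_degenerate("Pearson correlation undefined for zero-variance input")
  }
  stats::cor(a, b)
}

#' Decide a particle verdict from spot correlations
#'
#' Pure threshold rule on correlation coefficients: `MP` if any r exceeds
#' 0.7, otherwise `MANUAL_REVIEW` if the best r reaches the 0.6--0.7 band
#' (both boundaries inclusive: an r of exactly 0.6 or 0.7 is flagged for
#' review, the literal reading of a strict greater-than / smaller-than rule),
#' otherwise `NON_MP`.
#'
#' @param r_values Numeric correlations in \[-1, 1\].
#' @param upper,lower Decision thresholds.
#' @return `"MP"`, `"MANUAL_REVIEW"` or `"NON_MP"`.
#' @export
correlation_decision <- function(r_values, upper = 0.7, lower = 0.6) {
  if (any(!is.finite(r_values)) || any(abs(r_values) > 1 + 1e-12)) {
    stop_data("r_values must be finite correlations in [-1, 1]")
  }
  if (any(r_values > upper)) return("MP")
  if (max(r_values) >= lower) return("MANUAL_REVIEW")
  "NON_MP"
}

#' Identify one particle from three spot spectra
#'
#' Each spot spectrum is preprocessed with `prep`, then correlated against
#' the identically preprocessed parent-plastic reference; the verdict follows
#' [correlation_decision()]. Three spots per particle is the intended
#' protocol; fewer are accepted with a warning (small particles may not
#' offer three distinct spots).
#'
#' @param spot_spectra List of up to 3 `optir_spectrum` objects (or numeric
#'   vectors on `reference`'s grid).
#' @param reference Parent-plastic reference spectrum (`optir_spectrum`).
#' @param prep A `preprocess_spec`; default smooths, baseline-corrects and
#'   min-max normalizes.
#' @param restrict Optional wavenumbers restricting the correlation (e.g.
#'   the four selected bands); default uses the full grid.
#' @param particle_id Identifier echoed in the verdict.
#' @return A list of class `correlation_verdict` with `particle_id`,
#'   `r_values` and `decision`.
#' @export
identify_particle <- function(spot_spectra, reference,
                              prep = prep_default_identify(),
                              restrict = NULL, particle_id = NA) {
  if (!is.list(spot_spectra) || length(spot_spectra) < 1L) {
    stop_data("spot_spectra must be a non-empty list")
  }
  if (length(spot_spectra) > 3L) {
    stop_data("at most three spot spectra per particle")
  }
  if (length(spot_spectra) < 3L) {
    warning(sprintf("particle %s: only %d spot spectra (3 intended)",
                    particle_id, length(spot_spectra)))
  }
  wn <- if (inherits(reference, "optir_spectrum")) reference$wavenumber else NULL
  ref_p <- apply_preprocess(reference, prep)
  r <- vapply(spot_spectra, function(s) {
    pearson_r(apply_preprocess(s, prep), ref_p,
              wavenumber = wn, restrict = restrict)
  }, numeric(1))
  structure(list(particle_id = particle_id, r_values = r,
                 decision = correlation_decision(r)),
            class = "correlation_verdict")
}

#' @export
print.correlation_verdict <- function(x, ...) {
  cat(sprintf("<correlation_verdict> particle %s: r = {%s} -> %s\n",
              x$particle_id, paste(sprintf("%.3f", x$r_values), collapse = ", "),
              x$decision))
  invisible(x)
}
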