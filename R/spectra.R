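#' Default O-PTIR wavenumber grid
#'
#' The instrument's tunable range runs from 769 to 1801 cm^-1 and spectra are
#' recorded at a 2 cm^-1 step, giving 517 points. Grids are always stored
#' ascending; file readers sort descending input and note the original order.
#'
#' @param from,to Range endpoints in cm^-1 (inclusive).
#' @param by Grid step in cm^-1.
#' @return Numeric vector of wavenumbers, strictly ascending.
#' @examples
#' length(default_grid()) # 517
#' @export
default_grid <- function(from = 769, to = 1801, by = 2) {
  wn <- seq(from, to, by = by)
  check_grid(wn)
  wn
}

check_grid <- function(wn) {
  if (!is.numeric(wn) || length(wn) < 2L) {
    stop_param("wavenumber grid must be numeric with at least 2 points")
  }
  if (any(!is.finite(wn)) || any(diff(wn) <= 0)) {
    stop_param("wavenumber grid must be finite and strictly ascending")
  }
  invisible(wn)
}

#' Construct a single spectrum
#'
#' A spectrum is a set of intensities (arbitrary units) on a shared
#' wavenumber grid, with free-form provenance metadata (particle id, spot id).
#'
#' @param wavenumber Ascending numeric grid (cm^-1).
#' @param intensity Numeric intensities, same length as `wavenumber`.
#' @param meta Named list of provenance fields.
#' @return An object of class `optir_spectrum`.
#' @export
optir_spectrum <- function(wavenumber, intensity, meta = list()) {
  check_grid(wavenumber)
  if (length(intensity) != length(wavenumber)) {
    stop_data("intensity length does not match wavenumber grid length")
  }
  if (any(!is.finite(intensity))) {
    stop_data("spectrum intensities must all be finite")
  }
  structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         meta = meta),
    class = "optir_spectrum"
  )
}

#' @export
print.optir_spectrum <- function(x, ...) {
  cat(sprintf("<optir_spectrum> %d points, %g-%g cm-1, intensity [%.4g, %.4g]\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Construct a labelled spectra set
#'
#' Rows of `x` are spectra on a common wavenumber grid; `labels`, when
#' present, tags each row `"MP"` or `"NON_MP"` for discriminant training.
#'
#' @param wavenumber Ascending numeric grid (cm^-1).
#' @param x Numeric matrix, one spectrum per row, `ncol(x) == length(wavenumber)`.
#' @param labels Optional character vector (`"MP"`/`"NON_MP"`) per row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, x, labels = NULL) {
  check_grid(wavenumber)
  x <- as.matrix(x)
  if (ncol(x) != length(wavenumber)) {
    stop_data(sprintf("spectra have %d columns but grid has %d points",
                      ncol(x), length(wavenumber)))
  }
  if (any(!is.finite(x))) stop_data("spectra intensities must all be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(x)) {
      stop_data("labels must have one entry per spectrum row")
    }
    bad <- setdiff(unique(labels), c("MP", "NON_MP"))
    if (length(bad)) {
      stop_data(paste0("unknown class labels: ", paste(bad, collapse = ", ")))
    }
  }
  structure(list(wavenumber = as.numeric(wavenumber), x = x, labels = labels),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabelled" else {
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
          collapse = ", ")
  }
  cat(sprintf("<spectra_set> %d spectra x %d wavenumbers (%s)\n",
              nrow(x$x), ncol(x$x), lab))
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count of rows.
#' @export
n_spectra <- function(set) nrow(set$x)

#' Read / write a single spectrum as two-column delimited text
#'
#' The file holds a header line and two columns, `wavenumber_cm.1` (any name
#' is accepted for reading) and intensity. Descending files are sorted
#' ascending on read and the original order is recorded in
#' `meta$original_order`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_spectrum()` returns an `optir_spectrum`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 2L) stop_data(sprintf("'%s': expected 2 columns", path))
  wn <- as.numeric(d[[1L]])
  it <- as.numeric(d[[2L]])
  ord <- "ascending"
  if (all(diff(wn) < 0)) {
    wn <- rev(wn)
    it <- rev(it)
    ord <- "descending"
  }
  optir_spectrum(wn, it, meta = list(path = path, original_order = ord))
}

#' @param s An `optir_spectrum`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(s, path, sep = "\t") {
  d <- data.frame(wavenumber_cm.1 = s$wavenumber, intensity = s$intensity)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a spectra set as delimited text
#'
#' First row holds the wavenumber grid; each later row is one spectrum. An
#' optional leading `label` column carries `"MP"`/`"NON_MP"` class tags.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_spectra_set()` returns a `spectra_set`;
#'   `write_spectra_set()` returns `path` invisibly.
#' @export
read_spectra_set <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (identical(names(d)[1L], "label")) {
    labels <- as.character(d[[1L]])
    d <- d[-1L]
  }
  wn <- as.numeric(names(d))
  if (any(is.na(wn))) stop_data(sprintf("'%s': header is not a numeric grid", path))
  x <- as.matrix(d)
  dimnames(x) <- NULL
  if (any(diff(wn) < 0)) {
    o <- order(wn)
    wn <- wn[o]
    x <- x[, o, drop = FALSE]
  }
  spectra_set(wn, x, labels)
}

#' @param set A `spectra_set`.
#' @rdname read_spectra_set
#' @export
write_spectra_set <- function(set, path, sep = "\t") {
  d <- as.data.frame(set$x)
  names(d) <- format(set$wavenumber, trim = TRUE, scientific = FALSE)
  if (!is.null(set$labels)) d <- cbind(label = set$labels, d)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
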