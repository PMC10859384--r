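# Seeded generators for class-structured spectra, DFIR particle scenes and
# whole-filter experiments, with ground truth, so every pipeline stage is
# testable without instrument data.

#' Spectral class templates
#'
#' Each template is a sum of Gaussian bands plus, at generation time, a
#' multiplicative scatter factor, a random low-order polynomial baseline and
#' additive Gaussian noise. Defaults emulate the three particle classes seen
#' on nylon-release filters: nylon MP with the amide I/II pair at 1635 and
#' 1541 cm^-1 plus minor bands at 1464/1416/1370 cm^-1; "type I" non-MP with
#' a sharp carbonyl band at 1740 cm^-1 (within the 1700-1800 cm^-1 carbonyl
#' region); "type II" non-MP with a broad 1000-1200 cm^-1 envelope centred at
#' 1077 cm^-1, modelled as a wide base plus a narrower core so the envelope
#' has curvature at its centre rather than a flat plateau. Band amplitudes
#' are chosen so the four class-contrast bands (1635, 1541, 1740,
#' 1077 cm^-1) dominate the between-class differences and coefficient-based
#' selection can recover them.
#'
#' @param name `"MP"`, `"NONMP_TYPE1"` or `"NONMP_TYPE2"`.
#' @param bands Data frame `center`, `width` (Gaussian sigma, cm^-1),
#'   `amplitude`; defaults depend on `name`.
#' @param noise_sd Additive noise sd (a.u.).
#' @param scatter_range Multiplicative scatter factor interval.
#' @param baseline_mag Length-2: max constant offset and max linear tilt of
#'   the random baseline.
#' @return An object of class `class_template`.
#' @export
class_template <- function(name = c("MP", "NONMP_TYPE1", "NONMP_TYPE2"),
                           bands = NULL, noise_sd = 0.02,
                           scatter_range = c(0.7, 1.3),
                           baseline_mag = c(0.1, 0.05)) {
  name <- match.arg(name)
  if (is.null(bands)) {
    bands <- switch(name,
      MP = data.frame(
        center = c(1635, 1541, 1464, 1416, 1370),
        width = c(8, 8, 6, 6, 6),
        amplitude = c(1.0, 0.9, 0.1, 0.08, 0.08)),
      NONMP_TYPE1 = data.frame(center = 1740, width = 12, amplitude = 1.0),
      NONMP_TYPE2 = data.frame(center = c(1077, 1077), width = c(60, 15),
                               amplitude = c(0.7, 0.5)))
  }
  if (!nrow(bands)) stop_param("a template needs at least one band")
  if (any(bands$width <= 0) || any(bands$amplitude < 0)) {
    stop_param("band widths must be > 0 and amplitudes >= 0")
  }
  structure(list(name = name, bands = bands, noise_sd = noise_sd,
                 scatter_range = scatter_range, baseline_mag = baseline_mag),
            class = "class_template")
}

#' Noise-free template spectrum
#'
#' The analytic sum of a template's Gaussian bands on a grid, before
#' scatter, baseline or noise.
#'
#' @param template A `class_template`.
#' @param wavenumber Numeric grid (cm^-1).
#' @return Numeric intensities.
#' @export
clean_template_spectrum <- function(template, wavenumber) {
  out <- numeric(length(wavenumber))
  for (i in seq_len(nrow(template$bands))) {
    b <- template$bands[i, ]
    out <- out + b$amplitude * exp(-(wavenumber - b$center)^2 / (2 * b$width^2))
  }
  out
}

draw_spectrum <- function(template, wavenumber) {
  clean <- clean_template_spectrum(template, wavenumber)
  scatter <- stats::runif(1, template$scatter_range[1L],
                          template$scatter_range[2L])
  t01 <- (wavenumber - wavenumber[1L]) /
    (wavenumber[length(wavenumber)] - wavenumber[1L])
  b0 <- stats::runif(1, 0, template$baseline_mag[1L])
  b1 <- stats::runif(1, -template$baseline_mag[2L], template$baseline_mag[2L])
  noise <- if (template$noise_sd > 0) {
    stats::rnorm(length(wavenumber), 0, template$noise_sd)
  } else 0
  scatter * clean + b0 + b1 * t01 + noise
}

#' Generate one synthetic spectrum
#'
#' @param template A `class_template`.
#' @param wavenumber Numeric grid (cm^-1); default the instrument grid.
#' @param seed Integer seed (deterministic per seed).
#' @return An `optir_spectrum` with the template name in `meta$class`.
#' @export
gen_spectrum <- function(template, wavenumber = default_grid(), seed = 1) {
  set.seed(as.integer(seed))
  optir_spectrum(wavenumber, draw_spectrum(template, wavenumber),
                 meta = list(class = template$name, seed = seed))
}

#' Generate a labelled synthetic spectra set
#'
#' `n_mp` MP spectra followed by `n_nonmp` non-MP spectra; the non-MP rows
#' are split between the two non-MP templates by `type1_fraction`
#' (`round(type1_fraction * n_nonmp)` of type I). Row subtypes are kept in
#' `attr(, "subtype")`.
#'
#' @param n_mp,n_nonmp Class sizes (>= 1).
#' @param type1_fraction Fraction of non-MP rows drawn from the sharp-band
#'   type I template.
#' @param wavenumber Grid.
#' @param seed Integer seed.
#' @param templates Named list of `class_template`s (`MP`, `NONMP_TYPE1`,
#'   `NONMP_TYPE2`).
#' @return A labelled `spectra_set`.
#' @export
gen_spectra_set <- function(n_mp = 600, n_nonmp = 600, type1_fraction = 0.5,
                            wavenumber = default_grid(), seed = 1,
                            templates = default_templates()) {
  if (n_mp < 1 || n_nonmp < 1) stop_param("need >= 1 spectrum per class")
  if (type1_fraction < 0 || type1_fraction > 1) {
    stop_param("type1_fraction must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  n1 <- round(type1_fraction * n_nonmp)
  sub <- c(rep("MP", n_mp), rep("NONMP_TYPE1", n1),
           rep("NONMP_TYPE2", n_nonmp - n1))
  x <- t(vapply(sub, function(s) draw_spectrum(templates[[s]], wavenumber),
                numeric(length(wavenumber))))
  dimnames(x) <- NULL
  set <- spectra_set(wavenumber, x,
                     ifelse(sub == "MP", "MP", "NON_MP"))
  attr(set, "subtype") <- sub
  set
}

#' @rdname gen_spectra_set
#' @export
default_templates <- function() {
  list(MP = class_template("MP"),
       NONMP_TYPE1 = class_template("NONMP_TYPE1"),
       NONMP_TYPE2 = class_template("NONMP_TYPE2"))
}

rasterize_particle <- function(shape, ci, cj, r, aspect, theta, h, w) {
  ii <- pmax(1L, floor(ci - r - 1)):pmin(h, ceiling(ci + r + 1))
  jj <- pmax(1L, floor(cj - r - 1)):pmin(w, ceiling(cj + r + 1))
  g <- expand.grid(i = ii, j = jj)
  dx <- g$i - ci
  dy <- g$j - cj
  inside <- switch(shape,
    disk = dx^2 + dy^2 <= r^2,
    ellipse = {
      a <- r
      b <- r * aspect
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      (u / a)^2 + (v / b)^2 <= 1
    },
    rectangle = abs(dx) <= r & abs(dy) <= r * aspect)
  cbind(g$i[inside], g$j[inside])
}

#' Generate a synthetic DFIR particle scene with ground truth
#'
#' Places non-overlapping particles (disks, ellipses, rectangles) in a
#' region and renders one intensity channel per wavenumber: a particle's
#' pixels carry its class template evaluated at the channel wavenumbers,
#' jittered per pixel by a multiplicative scatter factor plus additive
#' noise; background pixels carry the background level plus noise. The mask
#' is the union of particle pixels and the ground-truth label map and class
#' table are returned alongside.
#'
#' @param n_particles Number of particles.
#' @param wavenumbers Channel wavenumbers (cm^-1).
#' @param shape Region shape in pixels `c(height, width)`.
#' @param pixel_size Pixel edge in um.
#' @param classes Optional explicit template name per particle
#'   (`"MP"`/`"NONMP_TYPE1"`/`"NONMP_TYPE2"`); default draws classes with
#'   `mp_fraction` MP and splits non-MP by `type1_fraction`.
#' @param mp_fraction,type1_fraction Class mix when `classes` is `NULL`.
#' @param radius_range_px Particle size range (primary radius, px).
#' @param shapes Shape pool drawn from per particle.
#' @param background Background intensity level.
#' @param noise_sd Additive per-pixel noise sd.
#' @param scatter_range Per-pixel multiplicative jitter interval.
#' @param seed Integer seed.
#' @param templates Named template list.
#' @return List with `stack` (`dfir_stack`), `mask` (logical matrix),
#'   `truth_labels` (integer matrix) and `truth_classes` (data frame `id`,
#'   `class`, `subtype`).
#' @export
gen_scene <- function(n_particles = 12,
                      wavenumbers = c(1077, 1541, 1635, 1740),
                      shape = c(240, 320), pixel_size = 2, classes = NULL,
                      mp_fraction = 0.5, type1_fraction = 0.5,
                      radius_range_px = c(4, 12),
                      shapes = c("disk", "ellipse", "rectangle"),
                      background = 0.02, noise_sd = 0.02,
                      scatter_range = c(0.8, 1.2), seed = 1,
                      templates = default_templates()) {
  set.seed(as.integer(seed))
  h <- shape[1L]
  w <- shape[2L]
  if (is.null(classes)) {
    classes <- ifelse(stats::runif(n_particles) < mp_fraction, "MP",
                      ifelse(stats::runif(n_particles) < type1_fraction,
                             "NONMP_TYPE1", "NONMP_TYPE2"))
  } else if (length(classes) != n_particles) {
    stop_param("classes must have one entry per particle")
  }
  labels <- matrix(0L, h, w)
  placed <- 0L
  boxes <- matrix(numeric(0), 0L, 3L) # ci, cj, r
  truth <- list()
  attempts <- 0L
  while (placed < n_particles) {
    attempts <- attempts + 1L
    if (attempts > 2000L * n_particles) {
      stop_param("could not place all particles without overlap; reduce size or count")
    }
    r <- stats::runif(1, radius_range_px[1L], radius_range_px[2L])
    ci <- stats::runif(1, r + 2, h - r - 1)
    cj <- stats::runif(1, r + 2, w - r - 1)
    # 3 px clearance so neighbouring particles stay 8-disconnected
    if (nrow(boxes) && any(sqrt((boxes[, 1L] - ci)^2 + (boxes[, 2L] - cj)^2) <
                             boxes[, 3L] + r + 3)) next
    placed <- placed + 1L
    sh <- sample(shapes, 1L)
    px <- rasterize_particle(sh, ci, cj, r,
                             aspect = stats::runif(1, 0.4, 0.9),
                             theta = stats::runif(1, 0, pi), h = h, w = w)
    if (nrow(px) < 1L) {
      placed <- placed - 1L
      next
    }
    labels[px] <- placed
    boxes <- rbind(boxes, c(ci, cj, r))
    truth[[placed]] <- data.frame(id = placed, class = unname(
      ifelse(classes[placed] == "MP", "MP", "NON_MP")),
      subtype = classes[placed])
  }
  chans <- array(0, dim = c(h, w, length(wavenumbers)))
  for (k in seq_along(wavenumbers)) {
    chans[, , k] <- background +
      (if (noise_sd > 0) matrix(stats::rnorm(h * w, 0, noise_sd), h, w) else 0)
  }
  if (n_particles > 0) {
    scatter <- matrix(stats::runif(h * w, scatter_range[1L], scatter_range[2L]),
                      h, w)
    for (id in seq_len(placed)) {
      idx <- which(labels == id)
      tpl <- templates[[classes[id]]]
      base <- clean_template_spectrum(tpl, wavenumbers)
      for (k in seq_along(wavenumbers)) {
        ch <- chans[, , k]
        ch[idx] <- ch[idx] + base[k] * scatter[idx]
        chans[, , k] <- ch
      }
    }
  }
  list(stack = dfir_stack(chans, wavenumbers, pixel_size),
       mask = labels > 0L,
       truth_labels = labels,
       truth_classes = if (length(truth)) do.call(rbind, truth) else
         data.frame(id = integer(0), class = character(0),
                    subtype = character(0)))
}

#' Simulate a whole-filter counting experiment
#'
#' Drops `total_particles` particles uniformly at random on the active
#' filter area (each independently MP with probability `mp_fraction`) and
#' counts how many land in each of the layout's subsampled regions.
#'
#' @param layout A `filter_layout`.
#' @param total_particles Ground-truth particle count on the filter.
#' @param mp_fraction Probability a particle is MP.
#' @param seed Integer seed.
#' @return List with `region_counts` (data frame `region`, `total`, `mp`),
#'   `subsample_total`, `subsample_mp`, and `truth` (`total`, `mp`).
#' @export
gen_filter_experiment <- function(layout, total_particles, mp_fraction = 0.1,
                                  seed = 1) {
  if (total_particles < 0) stop_param("total_particles must be >= 0")
  set.seed(as.integer(seed))
  R <- layout$active_diameter_mm / 2
  n <- as.integer(total_particles)
  rr <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- rr * cos(th)
  y <- rr * sin(th)
  is_mp <- stats::runif(n) < mp_fraction
  hw <- layout$region_width_um / 2000  # mm
  hh <- layout$region_height_um / 2000
  counts <- lapply(seq_len(layout$n_regions), function(r) {
    c0 <- layout$region_centers_mm[r, ]
    inside <- abs(x - c0[1L]) <= hw & abs(y - c0[2L]) <= hh
    data.frame(region = r, total = sum(inside), mp = sum(inside & is_mp))
  })
  counts <- do.call(rbind, counts)
  list(region_counts = counts,
       subsample_total = sum(counts$total),
       subsample_mp = sum(counts$mp),
       truth = list(total = n, mp = sum(is_mp)))
}
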