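# High-level workflows: spectra database -> full model -> wavenumber
# selection -> reduced model -> metrics; and stack + mask + model ->
# particle table.

#' Train, select wavenumbers, and evaluate both discriminant models
#'
#' Runs the model-development path end to end: stratified split, full-grid
#' linear SVM, coefficient-based importance, greedy wavenumber selection,
#' reduced model on the selected wavenumbers, and held-out metrics
#' (sensitivity, specificity, CCR, MCC) for both models.
#'
#' @param set Labelled `spectra_set`.
#' @param train_fraction Per-class training fraction.
#' @param seed Integer seed (split reproducibility).
#' @param C Soft-margin cost for both models.
#' @param k Number of wavenumbers to select.
#' @param min_separation Minimum pairwise selection distance (cm^-1).
#' @return List with `full_model`, `reduced_model`, `importance`,
#'   `selected_wavenumbers`, `metrics_full`, `metrics_reduced`,
#'   `counts_full`, `counts_reduced`, `split_sizes`.
#' @export
run_train_select <- function(set, train_fraction = 2 / 3, seed = 1, C = 1.0,
                             k = 4, min_separation = 20) {
  parts <- split_train_test(set, train_fraction, seed)
  full <- train_discriminant(parts$train, C = C, seed = seed)
  imp <- feature_importance(full)
  sel <- select_wavenumbers(imp, k = k, min_separation = min_separation)
  red <- train_discriminant(parts$train, wavenumbers = sel, C = C, seed = seed)
  pf <- predict(full, parts$test)
  pr <- predict(red, parts$test)
  cf <- count_confusion(pf, parts$test$labels)
  cr <- count_confusion(pr, parts$test$labels)
  list(full_model = full,
       reduced_model = red,
       importance = imp,
       selected_wavenumbers = sel,
       metrics_full = metrics_from_counts(cf),
       metrics_reduced = metrics_from_counts(cr),
       counts_full = cf,
       counts_reduced = cr,
       split_sizes = c(train = n_spectra(parts$train),
                       test = n_spectra(parts$test)))
}

#' Classify a DFIR stack into a particle table
#'
#' Application path for one imaged region: per-pixel classification within
#' the mask, particle segmentation, per-particle majority vote, and
#' morphometry, merged into one record per particle.
#'
#' @param stack A `dfir_stack`.
#' @param mask Logical region-of-interest matrix.
#' @param model A reduced `discriminant_model`.
#' @param connectivity,min_pixels Segmentation parameters
#'   (see [segment_particles()]).
#' @param pixel_prep Per-pixel normalization mode (see [classify_pixels()]).
#' @return List with `particles` (data frame: `id`, `class`,
#'   `mp_vote_fraction`, `pixel_count`, `area_um2`, `length_um`, `width_um`,
#'   `circularity`), `label_map`, `class_map`.
#' @export
run_classify_image <- function(stack, mask, model, connectivity = 8,
                               min_pixels = 2, pixel_prep = "snv") {
  class_map <- classify_pixels(stack, mask, model, pixel_prep = pixel_prep)
  label_map <- segment_particles(mask, connectivity = connectivity,
                                 min_pixels = min_pixels)
  votes <- vote_particle_class(label_map, class_map)
  particles <- morphometrics(label_map, pixel_size = stack$pixel_size,
                             classes = votes)
  list(particles = particles, label_map = label_map, class_map = class_map)
}

#' Write a particle table as CSV
#'
#' @param particles Data frame from [run_classify_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Metrics report for a train/select run
#'
#' Flat list with display-rounded headline metrics (CCR to 2 decimals as a
#' percentage, sensitivity/specificity/MCC to 4) plus raw confusion counts,
#' suitable for JSON serialization.
#'
#' @param run Result of [run_train_select()].
#' @return Named list.
#' @export
train_select_report <- function(run) {
  fmt <- function(m, c) list(
    sensitivity = round(m$sensitivity, 4),
    specificity = round(m$specificity, 4),
    ccr_pct = round(m$ccr, 2),
    mcc = if (m$mcc_undefined) "UNDEFINED" else round(m$mcc, 4),
    counts = unclass(c))
  list(selected_wavenumbers = run$selected_wavenumbers,
       split_sizes = as.list(run$split_sizes),
       full = fmt(run$metrics_full, run$counts_full),
       reduced = fmt(run$metrics_reduced, run$counts_reduced))
}
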