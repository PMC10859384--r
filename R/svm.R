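#' Stratified train/test split of a labelled spectra set
#'
#' Per class, `floor(train_fraction * n)` spectra go to the training set and
#' the remainder to the test set (deterministic rounding convention,
#' stratified, reproducible for a fixed seed).
#'
#' @param set Labelled `spectra_set`.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer RNG seed.
#' @return `list(train =, test =)` of `spectra_set`s whose rows partition
#'   `set`.
#' @export
split_train_test <- function(set, train_fraction = 2 / 3, seed = 1) {
  if (is.null(set$labels)) stop_data("split requires class labels")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_param("train_fraction must be in (0, 1) so both parts are non-empty")
  }
  classes <- unique(set$labels)
  if (length(classes) < 2L) stop_data("need both classes present")
  counts <- table(set$labels)
  if (any(counts < 2L)) stop_data("every class needs >= 2 spectra")
  set.seed(as.integer(seed))
  tr_idx <- integer(0)
  for (cl in sort(classes)) {
    idx <- which(set$labels == cl)
    n_tr <- floor(train_fraction * length(idx))
    if (n_tr < 1L || n_tr >= length(idx)) {
      stop_param("train_fraction leaves a class empty in train or test")
    }
    tr_idx <- c(tr_idx, sort(sample(idx, n_tr)))
  }
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_len(nrow(set$x)), tr_idx)
  list(
    train = spectra_set(set$wavenumber, set$x[tr_idx, , drop = FALSE],
                        set$labels[tr_idx]),
    test = spectra_set(set$wavenumber, set$x[te_idx, , drop = FALSE],
                       set$labels[te_idx])
  )
}

#' Train a linear support-vector discriminator
#'
#' Fits a maximum-margin linear classifier (hinge loss, cost `C`) on
#' SNV-pretreated spectra; the decision score for a feature vector `x` is
#' `w . x + bias`, positive for MP. With `wavenumbers = NULL` the model uses
#' the full grid (`kind = "FULL"`, SNV across the whole spectrum); otherwise
#' a reduced model is trained on the given wavenumbers. A linear kernel is
#' the only kernel offered: per-wavenumber coefficient importance, the basis
#' of wavenumber selection, exists only for a linear decision function.
#'
#' For reduced models the `feature_mode` controls where SNV is applied.
#' `"snv_extracted"` (default) extracts the raw intensities at the selected
#' wavenumbers and SNV-normalizes across those few values — the only
#' normalization also available to an application pixel, which carries
#' nothing but the selected-channel intensities, so training and pixel
#' classification see features in the same space. `"snv_full"` SNV-treats
#' the full spectrum first and then extracts; it is retained for comparison
#' but its features are inaccessible at pixel-classification time.
#'
#' @param train Labelled `spectra_set`.
#' @param wavenumbers Optional wavenumbers for a reduced model; all must lie
#'   on the grid.
#' @param feature_mode Reduced-model feature construction (see above).
#' @param C Soft-margin cost.
#' @param seed Integer recorded in the model metadata (the linear fit itself
#'   is deterministic).
#' @return An object of class `discriminant_model` with fields
#'   `kind`, `wavenumbers_used`, `weights`, `bias`, `prep`, `train_meta`.
#' @export
train_discriminant <- function(train, wavenumbers = NULL,
                               feature_mode = c("snv_extracted", "snv_full"),
                               C = 1.0, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  if (is.null(train$labels)) stop_data("training requires class labels")
  if (length(unique(train$labels)) < 2L) {
    stop_data("training requires both classes present")
  }
  used <- train$wavenumber
  kind <- "FULL"
  if (is.null(wavenumbers)) {
    feature_mode <- "snv_full"
    feats <- snv(train$x)
  } else {
    idx <- match(wavenumbers, train$wavenumber)
    if (any(is.na(idx))) {
      stop_param(sprintf("wavenumbers not on grid: %s",
                         paste(wavenumbers[is.na(idx)], collapse = ", ")))
    }
    used <- train$wavenumber[idx]
    kind <- "REDUCED"
    feats <- if (feature_mode == "snv_full") {
      snv(train$x)[, idx, drop = FALSE]
    } else {
      snv(train$x[, idx, drop = FALSE])
    }
  }
  y <- factor(train$labels, levels = c("MP", "NON_MP"))
  fit <- e1071::svm(x = feats, y = y, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # normalize the sign convention: MP scores positive
  mp_mean <- mean(feats[train$labels == "MP", , drop = FALSE] %*% w + b)
  np_mean <- mean(feats[train$labels == "NON_MP", , drop = FALSE] %*% w + b)
  if (mp_mean < np_mean) {
    w <- -w
    b <- -b
  }
  structure(
    list(kind = kind,
         wavenumbers_used = used,
         weights = w,
         bias = b,
         prep = list(feature_mode = feature_mode, C = C),
         train_meta = list(seed = as.integer(seed),
                           class_counts = as.list(table(train$labels)),
                           n_features = length(used))),
    class = "discriminant_model"
  )
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s, %d wavenumbers, bias %.4g\n",
              x$kind, length(x$wavenumbers_used), x$bias))
  invisible(x)
}

#' Linear decision scores
#'
#' @param model A `discriminant_model`.
#' @param x Feature matrix with columns matching `model$wavenumbers_used`
#'   (already preprocessed).
#' @return Numeric scores `x %*% weights + bias`.
#' @export
decision_scores <- function(model, x) {
  x <- rbind(x)
  if (ncol(x) != length(model$weights)) {
    stop_data(sprintf("feature width %d does not match model width %d",
                      ncol(x), length(model$weights)))
  }
  as.numeric(x %*% model$weights + model$bias)
}

#' Predict MP / non-MP labels for spectra
#'
#' Applies the model's recorded feature construction (full-spectrum SNV for
#' the full model; extraction at the model wavenumbers followed by SNV
#' across the extracted values, or full-SNV-then-extract, for reduced
#' models) and labels each spectrum by the sign of its decision score; a
#' score of exactly zero is labelled `NON_MP` (conservative tie rule).
#'
#' @param object A `discriminant_model`.
#' @param newdata A `spectra_set` (or matrix on the full grid accompanied by
#'   `wavenumber`).
#' @param wavenumber Grid for matrix input.
#' @param ... Unused.
#' @return Character vector of `"MP"` / `"NON_MP"`.
#' @export
predict.discriminant_model <- function(object, newdata, wavenumber = NULL, ...) {
  if (inherits(newdata, "spectra_set")) {
    wavenumber <- newdata$wavenumber
    newdata <- newdata$x
  }
  if (is.null(wavenumber)) stop_param("matrix input requires its grid")
  newdata <- rbind(newdata)
  idx <- match(object$wavenumbers_used, wavenumber)
  if (any(is.na(idx))) {
    stop_data(sprintf(
      "model wavenumbers {%s} not all on the data grid (%g-%g cm-1)",
      paste(object$wavenumbers_used[is.na(idx)], collapse = ", "),
      min(wavenumber), max(wavenumber)))
  }
  feats <- if (identical(object$prep$feature_mode, "snv_extracted")) {
    snv(newdata[, idx, drop = FALSE])
  } else {
    snv(newdata)[, idx, drop = FALSE]
  }
  sc <- decision_scores(object, feats)
  ifelse(sc > 0, "MP", "NON_MP")
}

#' Coefficient-based feature importance
#'
#' The importance of each wavenumber is the absolute value of its linear SVM
#' weight; the signed weight is retained for plotting. Only meaningful on the
#' full-grid model.
#'
#' @param model A `discriminant_model` with `kind == "FULL"`.
#' @return Data frame with `wavenumber`, `weight`, `importance`.
#' @export
feature_importance <- function(model) {
  if (!identical(model$kind, "FULL")) {
    stop_param("feature importance is defined on the FULL-grid model only")
  }
  data.frame(wavenumber = model$wavenumbers_used,
             weight = model$weights,
             importance = abs(model$weights))
}

#' Select discriminative wavenumbers from an importance profile
#'
#' Greedy pick of the `k` highest-importance wavenumbers subject to a
#' pairwise separation of at least `min_separation` cm^-1, so one broad peak
#' cannot claim several adjacent grid points. Returned sorted descending by
#' importance. With `min_separation = 0` this reduces to a plain top-k.
#'
#' @param profile Data frame from [feature_importance()] (columns
#'   `wavenumber`, `importance`).
#' @param k Number of wavenumbers to select.
#' @param min_separation Minimum pairwise distance in cm^-1.
#' @return Numeric wavenumbers, length `k`, descending importance.
#' @export
select_wavenumbers <- function(profile, k = 4, min_separation = 20) {
  if (k < 1L) stop_param("k must be >= 1")
  if (any(profile$importance < 0)) stop_data("importance must be non-negative")
  ord <- order(profile$importance, decreasing = TRUE)
  chosen <- numeric(0)
  for (i in ord) {
    wn <- profile$wavenumber[i]
    if (all(abs(wn - chosen) >= min_separation)) {
      chosen <- c(chosen, wn)
      if (length(chosen) == k) return(chosen)
    }
  }
  stop_param(sprintf(
    "separation constraint %g cm-1 admits only %d wavenumbers (k = %d)",
    min_separation, length(chosen), k))
}

#' Serialize / restore a discriminant model as JSON
#'
#' Numbers are written at full precision so a write/read round trip restores
#' the model bit-identically.
#'
#' @param model A `discriminant_model`.
#' @param path Output / input file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the `discriminant_model`.
#' @export
write_model <- function(model, path) {
  # I(17) significant digits: doubles survive the write/read loop exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$wavenumbers_used <- as.numeric(m$wavenumbers_used)
  m$weights <- as.numeric(m$weights)
  m$bias <- as.numeric(m$bias)
  m$train_meta$seed <- as.integer(m$train_meta$seed)
  structure(m, class = "discriminant_model")
}
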