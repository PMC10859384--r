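#' Discrete-frequency IR image stack
#'
#' One intensity image per selected wavenumber over a rectangular region
#' (default acquisition geometry: 240 x 320 pixels of 2 um, i.e. a
#' 480 um x 640 um field). Channels are stored in ascending wavenumber
#' order.
#'
#' @param channels Numeric array `height x width x n_channels` (or a list of
#'   equally sized matrices).
#' @param wavenumbers Channel wavenumbers (cm^-1), unique.
#' @param pixel_size Pixel edge length in um.
#' @return An object of class `dfir_stack`.
#' @export
dfir_stack <- function(channels, wavenumbers, pixel_size = 2) {
  if (is.list(channels)) {
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1L) stop_data("all channels must share one shape")
    channels <- array(unlist(channels),
                      dim = c(dims[[1L]], length(channels)))
  }
  if (length(dim(channels)) != 3L) {
    stop_data("channels must be a height x width x n_channels array")
  }
  if (dim(channels)[3L] != length(wavenumbers)) {
    stop_data("one wavenumber per channel required")
  }
  if (anyDuplicated(wavenumbers)) stop_data("channel wavenumbers must be unique")
  if (pixel_size <= 0) stop_param("pixel_size must be > 0")
  o <- order(wavenumbers)
  structure(
    list(channels = channels[, , o, drop = FALSE],
         wavenumbers = as.numeric(wavenumbers[o]),
         pixel_size = pixel_size),
    class = "dfir_stack"
  )
}

#' @export
print.dfir_stack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<dfir_stack> %d x %d px (%g um/px), channels: %s cm-1\n",
              d[1L], d[2L], x$pixel_size,
              paste(x$wavenumbers, collapse = ", ")))
  invisible(x)
}

#' Min-max normalize each channel to [0, 1]
#'
#' Visualization convenience (chemical images shown "normalized to the same
#' range"); pixel classification uses its own per-pixel normalization.
#'
#' @param stack A `dfir_stack`.
#' @return The stack with each channel independently rescaled to \[0, 1\].
#' @export
normalize_channels <- function(stack) {
  for (k in seq_along(stack$wavenumbers)) {
    ch <- stack$channels[, , k]
    r <- range(ch)
    if (r[1L] == r[2L]) {
      stop_degenerate(sprintf("channel %g cm-1 is constant", stack$wavenumbers[k]))
    }
    stack$channels[, , k] <- (ch - r[1L]) / (r[2L] - r[1L])
  }
  stack
}

#' Threshold an image into a region-of-interest mask
#'
#' Stand-in for manual background masking: pixels brighter (or, in dark
#' mode, darker) than `threshold` form the mask.
#'
#' @param image Numeric matrix.
#' @param threshold Intensity cutoff.
#' @param dark If `TRUE`, keep pixels below the threshold instead.
#' @return Logical matrix with attribute `provenance = "THRESHOLD"`.
#' @export
threshold_mask <- function(image, threshold, dark = FALSE) {
  if (min(image) == max(image)) stop_degenerate("image is constant")
  m <- if (dark) image < threshold else image > threshold
  if (!any(m)) warning("threshold outside image range: mask is empty")
  attr(m, "provenance") <- "THRESHOLD"
  m
}

#' Classify every masked pixel as MP or non-MP
#'
#' Each masked pixel's channel vector is normalized (default: SNV across the
#' channel values, the same per-observation normalization reduced models are
#' trained with, so training and application features live in one space;
#' `"raw"` skips normalization) and scored with the reduced model's linear
#' decision function; the label is the sign of the score. An application
#' pixel carries only the selected-channel intensities, never the full
#' spectrum, which is why reduced models default to channel-wise SNV
#' training features (see [train_discriminant()]); classifying with a
#' `"snv_full"`-trained model emits a warning about the feature-space
#' mismatch. A constant pixel vector (SNV undefined) falls back to a zero
#' feature vector, i.e. the model bias decides.
#'
#' @param stack A `dfir_stack` whose wavenumbers equal the model's.
#' @param mask Logical matrix, same shape as the stack.
#' @param model A `discriminant_model` with `kind == "REDUCED"`.
#' @param pixel_prep `"snv"` (default) or `"raw"`.
#' @return Integer matrix: `NA` outside the mask, `1` for MP, `0` for non-MP.
#' @export
classify_pixels <- function(stack, mask, model, pixel_prep = c("snv", "raw")) {
  pixel_prep <- match.arg(pixel_prep)
  if (pixel_prep == "snv" &&
      !identical(model$prep$feature_mode, "snv_extracted")) {
    warning(paste("model was trained on full-spectrum SNV features;",
                  "pixel-wise SNV features live in a different space"))
  }
  if (!identical(model$kind, "REDUCED")) {
    stop_param("pixel classification requires a REDUCED model")
  }
  d <- dim(stack$channels)
  if (!identical(dim(mask), d[1:2])) stop_data("mask shape must match stack")
  if (!any(mask)) stop_data("mask is empty")
  if (!setequal(stack$wavenumbers, model$wavenumbers_used)) {
    stop_data(sprintf(
      "stack channels {%s} do not match model wavenumbers {%s}",
      paste(stack$wavenumbers, collapse = ", "),
      paste(model$wavenumbers_used, collapse = ", ")))
  }
  ord <- match(model$wavenumbers_used, stack$wavenumbers)
  idx <- which(mask)
  feats <- vapply(ord, function(k) stack$channels[, , k][idx],
                  numeric(length(idx)))
  feats <- rbind(feats)
  if (pixel_prep == "snv") {
    mu <- rowMeans(feats)
    sdv <- apply(feats, 1L, stats::sd)
    feats <- (feats - mu) / ifelse(sdv > 0, sdv, 1)
    feats[sdv == 0, ] <- 0
  }
  sc <- decision_scores(model, feats)
  out <- matrix(NA_integer_, d[1L], d[2L])
  out[idx] <- as.integer(sc > 0)
  out
}

#' Segment a mask into particles by connected components
#'
#' Connected components of the mask (8- or 4-connectivity), with components
#' smaller than `min_pixels` discarded as noise (2 um pixels mean any real
#' particle of a few um spans several pixels). Ids are assigned in
#' raster-scan order (row-major, origin top-left) of each component's first
#' pixel and are contiguous from 1.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (edges + corners) or 4 (edges only).
#' @param min_pixels Minimum component size kept.
#' @return Integer label matrix, 0 = background.
#' @export
segment_particles <- function(mask, connectivity = 8, min_pixels = 2) {
  if (!any(mask)) stop_data("mask is empty")
  if (!connectivity %in% c(4, 8)) stop_param("connectivity must be 4 or 8")
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  nxt <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && mask[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L && mask[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
      if (connectivity == 8) {
        if (i > 1L && j > 1L && mask[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i > 1L && j < w && mask[i - 1L, j + 1L]) nb <- c(nb, lab[i - 1L, j + 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        r0 <- min(roots)
        lab[i, j] <- r0
        for (r in roots[roots != r0]) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) stop_data("mask is empty")
  root_of <- vapply(seq_len(nxt), find, integer(1))
  # relabel by raster order of first occurrence, row-major
  labs_t <- t(lab)
  filled <- labs_t[labs_t > 0L]
  roots_seq <- root_of[filled]
  first_seen <- unique(roots_seq)
  remap <- integer(nxt)
  remap[first_seen] <- seq_along(first_seen)
  out <- matrix(0L, h, w)
  out[lab > 0L] <- remap[root_of[lab[lab > 0L]]]
  # drop small components, keep ids contiguous in raster order
  sizes <- tabulate(out[out > 0L])
  keep <- which(sizes >= min_pixels)
  remap2 <- integer(length(sizes))
  out_t <- t(out)
  order_first <- unique(out_t[out_t > 0L])
  kept_in_order <- order_first[order_first %in% keep]
  remap2[kept_in_order] <- seq_along(kept_in_order)
  res <- matrix(0L, h, w)
  res[out > 0L] <- remap2[out[out > 0L]]
  res
}

#' Majority-vote class per particle
#'
#' A particle is MP iff its MP pixels strictly outnumber its non-MP pixels;
#' a tie goes to non-MP (conservative against false positives).
#'
#' @param label_map Integer particle label matrix from
#'   [segment_particles()].
#' @param class_map Per-pixel class matrix from [classify_pixels()]
#'   (`1` MP, `0` non-MP, `NA` unclassified).
#' @return Data frame `id`, `class`, `mp_vote_fraction`, `pixel_count`.
#' @export
vote_particle_class <- function(label_map, class_map) {
  if (!identical(dim(label_map), dim(class_map))) {
    stop_data("label map and class map must share one shape")
  }
  ids <- sort(unique(label_map[label_map > 0L]))
  if (!length(ids)) stop_data("no particles in label map")
  out <- lapply(ids, function(id) {
    cl <- class_map[label_map == id]
    if (any(is.na(cl))) {
      stop_data(sprintf("particle %d has unclassified pixels", id))
    }
    n_mp <- sum(cl == 1L)
    n <- length(cl)
    data.frame(id = id,
               class = if (n_mp > n - n_mp) "MP" else "NON_MP",
               mp_vote_fraction = n_mp / n,
               pixel_count = n)
  })
  do.call(rbind, out)
}

#' Write / read a DFIR stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF page per wavenumber. Pages are stored rescaled to
#' \[0, 1\]; the per-channel offset/scale needed to restore physical
#' intensities is recorded in the sidecar together with the channel
#' wavenumbers and pixel size.
#'
#' @param stack A `dfir_stack`.
#' @param tiff_path Path of the multi-page TIFF.
#' @param json_path Sidecar path; default replaces the extension with
#'   `.json`.
#' @param region_id Optional region identifier stored in the sidecar.
#' @return `write_dfir_stack()` returns `tiff_path` invisibly;
#'   `read_dfir_stack()` returns the restored `dfir_stack`.
#' @export
write_dfir_stack <- function(stack, tiff_path,
                             json_path = sub("\\.tiff?$", ".json", tiff_path),
                             region_id = NULL) {
  pages <- list()
  offs <- numeric(0)
  scls <- numeric(0)
  for (k in seq_along(stack$wavenumbers)) {
    ch <- stack$channels[, , k]
    off <- min(ch)
    scl <- max(ch) - off
    if (scl == 0) scl <- 1
    pages[[k]] <- (ch - off) / scl
    offs[k] <- off
    scls[k] <- scl
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channel_wavenumbers = stack$wavenumbers,
         pixel_size_um = stack$pixel_size,
         channel_offset = offs,
         channel_scale = scls,
         region_id = region_id),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tiff_path)
}

#' @rdname write_dfir_stack
#' @export
read_dfir_stack <- function(tiff_path,
                            json_path = sub("\\.tiff?$", ".json", tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (length(pages) != length(meta$channel_wavenumbers)) {
    stop_data("sidecar wavenumber count does not match TIFF page count")
  }
  chans <- lapply(seq_along(pages), function(k) {
    pages[[k]] * meta$channel_scale[k] + meta$channel_offset[k]
  })
  dfir_stack(chans, meta$channel_wavenumbers, meta$pixel_size_um)
}

#' Write / read a binary region-of-interest mask as TIFF
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}
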