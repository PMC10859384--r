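# A small reduced model shared by the imaging tests.
imaging_model <- local({
  set <- gen_spectra_set(n_mp = 120, n_nonmp = 120, seed = 31)
  train_discriminant(set, wavenumbers = c(1077, 1541, 1635, 1739))
})

test_that("channel normalization rescales each channel to [0,1]", {
  sc <- gen_scene(n_particles = 6, seed = 4)
  norm <- normalize_channels(sc$stack)
  for (k in 1:4) {
    ch <- sc$stack$channels[, , k]
    nk <- norm$channels[, , k]
    expect_equal(range(nk), c(0, 1))
    expect_identical(order(nk), order(ch)) # rank order preserved
  }
  const <- dfir_stack(array(1, c(4, 4, 1)), 1500)
  expect_error(normalize_channels(const), class = "mpdfir_degenerate_error")
})

test_that("threshold masks equal a direct comparison and warn when empty", {
  img <- matrix(0.1, 20, 20)
  img[5:9, 5:9] <- 0.9
  m <- threshold_mask(img, 0.5)
  expect_identical(unname(which(m)), unname(which(img > 0.5)))
  expect_identical(attr(m, "provenance"), "THRESHOLD")
  expect_warning(m2 <- threshold_mask(img, 2), "empty")
  expect_false(any(m2))

  set.seed(12)
  noisy <- matrix(runif(900), 30, 30)
  expect_identical(sum(threshold_mask(noisy, 0.7)), sum(noisy > 0.7))
})

test_that("pixel classification equals a brute-force per-pixel oracle", {
  sc <- gen_scene(n_particles = 15, seed = 21,
                  wavenumbers = imaging_model$wavenumbers_used)
  cm <- classify_pixels(sc$stack, sc$mask, imaging_model)

  # masked-out pixels carry no label
  expect_true(all(is.na(cm[!sc$mask])))
  expect_false(anyNA(cm[sc$mask]))

  # independent loop: sign(w . snv(x) + b) pixel by pixel
  ord <- match(imaging_model$wavenumbers_used, sc$stack$wavenumbers)
  w <- imaging_model$weights
  b <- imaging_model$bias
  idx <- which(sc$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- sapply(ord, function(k) sc$stack$channels[idx[r, 1], idx[r, 2], k])
    f <- (v - mean(v)) / sd(v)
    expect_identical(cm[idx[r, 1], idx[r, 2]],
                     as.integer(sum(w * f) + b > 0))
  }

  # reproducible bit-for-bit
  expect_identical(cm, classify_pixels(sc$stack, sc$mask, imaging_model))

  # wavenumber mismatch is refused with both sets named
  bad <- dfir_stack(sc$stack$channels, c(900, 1000, 1100, 1200))
  expect_error(classify_pixels(bad, sc$mask, imaging_model),
               "do not match", class = "mpdfir_data_error")
})

test_that("pixels matching a class template get that template's class", {
  wns <- imaging_model$wavenumbers_used
  tpls <- clean_templates()
  mk_stack <- function(tpl) {
    v <- clean_template_spectrum(tpl, sort(wns))
    dfir_stack(array(rep(v, each = 25), c(5, 5, 4)), sort(wns))
  }
  mask <- matrix(TRUE, 5, 5)
  expect_true(all(classify_pixels(mk_stack(tpls$MP), mask, imaging_model) == 1L))
  expect_true(all(classify_pixels(mk_stack(tpls$NONMP_TYPE1), mask,
                                  imaging_model) == 0L))
  expect_true(all(classify_pixels(mk_stack(tpls$NONMP_TYPE2), mask,
                                  imaging_model) == 0L))
})

test_that("segmentation matches connectivity definitions and a flood-fill oracle", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 8:10] <- TRUE
  lab <- segment_particles(m, 8, 1)
  expect_equal(max(lab), 2)
  expect_equal(unname(table(lab[lab > 0])), c(9L, 9L), ignore_attr = TRUE)

  # diagonal-only touch: one particle at 8-connectivity, two at 4
  d <- matrix(FALSE, 8, 8)
  d[2:3, 2:3] <- TRUE
  d[4:5, 4:5] <- TRUE
  expect_equal(max(segment_particles(d, 8, 1)), 1)
  expect_equal(max(segment_particles(d, 4, 1)), 2)

  # min_pixels discards singletons
  s <- matrix(FALSE, 6, 6)
  s[2, 2] <- TRUE
  s[4:5, 4:5] <- TRUE
  expect_equal(max(segment_particles(s, 8, min_pixels = 2)), 1)

  # random blobby masks against the flood-fill oracle, both connectivities
  for (seed in 1:5) {
    set.seed(seed)
    rb <- matrix(runif(40 * 40) < 0.35, 40, 40)
    for (conn in c(4, 8)) {
      lab <- segment_particles(rb, conn, min_pixels = 1)
      expect_equal(max(lab), flood_fill_count(rb, conn)$count)
    }
  }

  # ids are contiguous from 1 in raster order
  lab <- segment_particles(m, 8, 1)
  expect_identical(sort(unique(as.integer(lab[lab > 0]))), 1:2)

  expect_error(segment_particles(matrix(FALSE, 3, 3)),
               class = "mpdfir_data_error")
})

test_that("majority votes equal a brute-force tally with ties to NON_MP", {
  lab <- matrix(0L, 5, 6)
  lab[1:2, 1:5] <- 1L # 10 px
  lab[4, 1:3] <- 1L   # 13 total
  lab[5, 1:4] <- 2L   # 4 px
  cls <- matrix(NA_integer_, 5, 6)
  cls[lab == 1L] <- c(rep(1L, 10), rep(0L, 3))
  cls[lab == 2L] <- c(1L, 1L, 0L, 0L) # 2/2 tie
  v <- vote_particle_class(lab, cls)
  expect_identical(v$class, c("MP", "NON_MP"))
  expect_equal(v$mp_vote_fraction, c(10 / 13, 0.5))

  # a large random scene against an independent tally
  set.seed(77)
  sc <- gen_scene(n_particles = 30, seed = 77)
  lab <- sc$truth_labels
  cls <- matrix(NA_integer_, nrow(lab), ncol(lab))
  cls[lab > 0] <- rbinom(sum(lab > 0), 1, 0.5)
  v <- vote_particle_class(lab, cls)
  for (id in v$id) {
    px <- cls[lab == id]
    expect_identical(v$class[v$id == id],
                     if (sum(px == 1) > sum(px == 0)) "MP" else "NON_MP")
    expect_equal(v$mp_vote_fraction[v$id == id], mean(px))
  }

  cls[lab == 1][1] <- NA
  expect_error(vote_particle_class(lab, cls), class = "mpdfir_data_error")
})

test_that("morphometry matches analytic shapes", {
  # single pixel convention
  sp <- matrix(FALSE, 5, 5)
  sp[3, 3] <- TRUE
  m1 <- morphometrics(segment_particles(sp, 8, 1), pixel_size = 2)
  expect_equal(m1$area_um2, 4)
  expect_equal(m1$length_um, 2)
  expect_equal(m1$width_um, 2)
  expect_equal(m1$circularity, 1)

  # rasterized disk, r = 15 px = 30 um
  dm <- disk_mask(15)
  md <- morphometrics(segment_particles(dm, 8, 1), pixel_size = 2)
  expect_lt(abs(md$area_um2 - pi * 30^2) / (pi * 30^2), 0.02)
  expect_gte(md$circularity, 0.9)
  expect_lt(abs(md$length_um / md$width_um - 1), 0.05)

  # solid 5 x 20 rectangle: major axis 2L/sqrt(3) from closed-form moments
  rm_ <- matrix(FALSE, 11, 26)
  rm_[4:8, 4:23] <- TRUE
  mr <- morphometrics(segment_particles(rm_, 8, 1), pixel_size = 2)
  expect_lt(abs(mr$length_um - 2 * 20 / sqrt(3) * 2) / (2 * 20 / sqrt(3) * 2), 0.02)
  expect_lt(abs(mr$width_um - 2 * 5 / sqrt(3) * 2) / (2 * 5 / sqrt(3) * 2), 0.02)

  # scale equivariance: pixel_size c scales area by c^2, axes by c,
  # circularity unchanged - exactly
  lab <- segment_particles(dm, 8, 1)
  a <- morphometrics(lab, pixel_size = 2)
  b <- morphometrics(lab, pixel_size = 6)
  expect_identical(b$area_um2, a$area_um2 * 9)
  expect_identical(b$length_um, a$length_um * 3)
  expect_identical(b$width_um, a$width_um * 3)
  expect_identical(b$circularity, a$circularity)
})

test_that("DFIR stacks and masks round-trip through TIFF + JSON sidecar", {
  sc <- gen_scene(n_particles = 8, seed = 14)
  ft <- tempfile(fileext = ".tiff")
  write_dfir_stack(sc$stack, ft, region_id = "region-3")
  back <- read_dfir_stack(ft)
  expect_equal(back$wavenumbers, sc$stack$wavenumbers)
  expect_equal(back$pixel_size, sc$stack$pixel_size)
  expect_lt(max(abs(back$channels - sc$stack$channels)), 1e-6)

  fm <- tempfile(fileext = ".tiff")
  write_mask(sc$mask, fm)
  expect_identical(read_mask(fm), sc$mask)

  # rewriting the same scene gives byte-identical files
  ft2 <- tempfile(fileext = ".tiff")
  write_dfir_stack(sc$stack, ft2)
  expect_identical(unname(tools::md5sum(ft)), unname(tools::md5sum(ft2)))
})
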