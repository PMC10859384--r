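test_that("stratified split follows the floor-to-train convention", {
  set <- gen_spectra_set(n_mp = 1038, n_nonmp = 1052, seed = 7)
  parts <- split_train_test(set, 2 / 3, seed = 7)
  tr_counts <- table(parts$train$labels)
  expect_equal(unname(tr_counts[["MP"]]), floor(2 / 3 * 1038)) # 692
  expect_equal(unname(tr_counts[["NON_MP"]]), floor(2 / 3 * 1052)) # 701
  expect_equal(n_spectra(parts$train) + n_spectra(parts$test), 2090)

  # partition: every row of set appears exactly once across train/test
  key <- function(m) apply(m[, 1:8], 1L, paste, collapse = ",")
  expect_setequal(c(key(parts$train$x), key(parts$test$x)), key(set$x))

  # determinism
  parts2 <- split_train_test(set, 2 / 3, seed = 7)
  expect_identical(parts$train$x, parts2$train$x)

  expect_error(split_train_test(set, 1.0, seed = 1), class = "mpdfir_param_error")
  unl <- spectra_set(set$wavenumber, set$x)
  expect_error(split_train_test(unl, seed = 1), class = "mpdfir_data_error")
})

test_that("linearly separable classes train to a perfect discriminator", {
  wn <- default_grid()
  tpls <- clean_templates()
  x <- rbind(
    t(replicate(20, clean_template_spectrum(tpls$MP, wn) * runif(1, 0.8, 1.2))),
    t(replicate(20, clean_template_spectrum(tpls$NONMP_TYPE1, wn) * runif(1, 0.8, 1.2)))
  )
  set <- spectra_set(wn, x, rep(c("MP", "NON_MP"), each = 20))
  m <- train_discriminant(set)
  expect_identical(m$kind, "FULL")
  expect_identical(predict(m, set), set$labels)

  # predictions equal an independent dot-product sign oracle
  feats <- snv(set$x)
  sc <- as.numeric(feats %*% m$weights + m$bias)
  expect_identical(predict(m, set), ifelse(sc > 0, "MP", "NON_MP"))

  one <- spectra_set(wn, x[1:20, ], rep("MP", 20))
  expect_error(train_discriminant(one), class = "mpdfir_data_error")
})

test_that("a zero decision score is labelled NON_MP", {
  m <- structure(
    list(kind = "REDUCED", wavenumbers_used = c(1000, 1100), weights = c(1, 1),
         bias = 0, prep = list(feature_mode = "snv_extracted", C = 1),
         train_meta = list()),
    class = "discriminant_model")
  # snv of any 2-vector is (-1/sqrt(2), 1/sqrt(2)) * sqrt(2)... summing to 0
  p <- predict(m, matrix(c(3, 7), 1), wavenumber = c(1000, 1100))
  expect_identical(p, "NON_MP")
  expect_equal(decision_scores(m, matrix(c(-5, 5), 1)), 0)
})

test_that("feature importance is |weight| and symmetric for duplicate features", {
  m <- structure(
    list(kind = "FULL", wavenumbers_used = c(1, 2, 3), weights = c(0, -3, 2),
         bias = 0, prep = list(), train_meta = list()),
    class = "discriminant_model")
  expect_equal(feature_importance(m)$importance, c(0, 3, 2))

  r <- structure(m, class = "discriminant_model")
  r$kind <- "REDUCED"
  expect_error(feature_importance(r), class = "mpdfir_param_error")

  # duplicated feature columns share the weight symmetrically
  set.seed(42)
  wn <- seq(1000, 1018, by = 2)
  base <- matrix(rnorm(60 * 10), 60, 10)
  y <- rep(c("MP", "NON_MP"), each = 30)
  base[y == "MP", 4] <- base[y == "MP", 4] + 2
  base[, 5] <- base[, 4] # exact duplicate
  set <- spectra_set(wn, base, y)
  mdl <- train_discriminant(set)
  imp <- feature_importance(mdl)$importance
  expect_lt(abs(imp[4] - imp[5]), 1e-6)
})

test_that("a single planted discriminative band is recovered by importance", {
  wn <- default_grid()
  set.seed(8)
  n <- 80
  x <- matrix(rnorm(2 * n * length(wn), 0, 0.05), 2 * n, length(wn))
  band <- exp(-(wn - 1301)^2 / (2 * 10^2))
  x[1:n, ] <- x[1:n, ] + rep(band, each = n) * runif(n, 0.8, 1.2)
  x <- x + 0.5 # offset so SNV has signal
  set <- spectra_set(wn, x, rep(c("MP", "NON_MP"), each = n))
  imp <- feature_importance(train_discriminant(set))
  expect_lte(abs(imp$wavenumber[which.max(imp$importance)] - 1301), 10)
})

test_that("wavenumber selection is greedy top-k with a separation constraint", {
  wn <- default_grid()
  imp <- data.frame(wavenumber = wn, importance = 0)
  imp$importance[match(c(1711, 1635, 1541, 1077), wn)] <- c(4, 3, 2, 1)
  expect_equal(select_wavenumbers(imp, k = 4), c(1711, 1635, 1541, 1077))
  expect_equal(select_wavenumbers(imp, k = 1), 1711)

  # two adjacent points of one broad peak + one distant peak: brute force
  # over the toy profile says the second pick must be the distant peak
  toy <- data.frame(wavenumber = c(1000, 1002, 1500),
                    importance = c(5, 4.5, 3))
  expect_equal(select_wavenumbers(toy, k = 2, min_separation = 20),
               c(1000, 1500))
  # and with no constraint, plain top-k by a sort oracle
  expect_equal(select_wavenumbers(toy, k = 2, min_separation = 0),
               toy$wavenumber[order(-toy$importance)][1:2])

  expect_error(select_wavenumbers(toy, k = 3, min_separation = 1000),
               class = "mpdfir_param_error")
})

test_that("metrics match Table-2-style print precision and the textbook oracle", {
  m4 <- metrics_from_counts(confusion_counts(tp = 319, fn = 34, fp = 28, tn = 334))
  expect_equal(round(m4$ccr, 2), 91.33)
  expect_equal(round(m4$mcc, 4), 0.8266)
  expect_equal(round(m4$sensitivity, 4), 0.9037)
  expect_equal(round(m4$specificity, 4), 0.9227)

  perfect <- metrics_from_counts(confusion_counts(10, 0, 0, 10))
  expect_equal(perfect$ccr, 100)
  expect_equal(perfect$mcc, 1)

  expect_error(metrics_from_counts(confusion_counts(0, 0, 5, 5)),
               class = "mpdfir_degenerate_error")

  # undefined MCC is flagged, not zeroed
  und <- metrics_from_counts(confusion_counts(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_true(und$mcc_undefined)
  expect_true(is.na(und$mcc))

  # 1000 random count tuples against the textbook formulas
  set.seed(99)
  for (i in 1:1000) {
    v <- sample(0:200, 4, replace = TRUE)
    if (v[1] + v[2] == 0 || v[3] + v[4] == 0) next
    m <- metrics_from_counts(confusion_counts(v[1], v[2], v[3], v[4]))
    o <- metrics_oracle(v[1], v[2], v[3], v[4])
    expect_lt(abs(m$sensitivity - o$sensitivity), 1e-12)
    expect_lt(abs(m$specificity - o$specificity), 1e-12)
    expect_lt(abs(m$ccr - o$ccr), 1e-12)
    if (!m$mcc_undefined) {
      expect_lt(abs(m$mcc - o$mcc), 1e-12)
      expect_lte(abs(m$mcc), 1)
      # MCC invariant under swapping classes with (tp<->tn, fp<->fn)
      sw <- metrics_from_counts(confusion_counts(v[4], v[3], v[2], v[1]))
      expect_equal(m$mcc, sw$mcc, tolerance = 1e-12)
    }
  }
})

test_that("confusion matrices are reconstructed uniquely from printed statistics", {
  c4 <- reconstruct_confusion(fn = 34, fp = 28,
                              sensitivity = 0.9037, specificity = 0.9227)
  expect_equal(unclass(c4)[c("tp", "fn", "fp", "tn")],
               list(tp = 319, fn = 34, fp = 28, tn = 334))

  # the full-model case needs the printed CCR to break a P = 352/353 tie
  expect_error(reconstruct_confusion(fn = 8, fp = 97, sensitivity = 0.9773,
                                     specificity = 0.7320),
               "ambiguous", class = "mpdfir_data_error")
  cf <- reconstruct_confusion(fn = 8, fp = 97, sensitivity = 0.9773,
                              specificity = 0.7320, ccr = 85.31)
  expect_equal(unclass(cf)[c("tp", "fn", "fp", "tn")],
               list(tp = 345, fn = 8, fp = 97, tn = 265))

  # a perfect printed statistic is consistent with any total
  expect_error(reconstruct_confusion(fn = 0, fp = 10, sensitivity = 1.0,
                                     specificity = 0.9),
               class = "mpdfir_data_error")
  # impossible combination
  expect_error(reconstruct_confusion(fn = 10, fp = 10, sensitivity = 0.5001,
                                     specificity = 0.5001),
               class = "mpdfir_data_error")
})

test_that("models serialize to JSON and round-trip bit-identically", {
  set <- gen_spectra_set(n_mp = 60, n_nonmp = 60, seed = 3)
  m <- train_discriminant(set, wavenumbers = c(1077, 1541, 1635, 1739))
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$bias, m$bias)
  expect_identical(m2$wavenumbers_used, m$wavenumbers_used)
  expect_identical(m2$kind, m$kind)

  # identical config + seed => byte-identical serialized model
  set_b <- gen_spectra_set(n_mp = 60, n_nonmp = 60, seed = 3)
  m_b <- train_discriminant(set_b, wavenumbers = c(1077, 1541, 1635, 1739))
  f_b <- tempfile(fileext = ".json")
  write_model(m_b, f_b)
  expect_identical(readLines(f), readLines(f_b))
})
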