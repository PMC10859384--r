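# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct summation, flood fill, brute-force
# tallies.

# Pearson correlation by direct summation of the covariance / sd definition.
pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    (sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2)))
}

# Textbook classification metrics from raw counts.
metrics_oracle <- function(tp, fn, fp, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ccr = 100 * (tp + tn) / (tp + fn + fp + tn),
       mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / den)
}

# Connected components by queue-based flood fill.
flood_fill_count <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  sizes <- integer(0)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- matrix(c(i, j), 1L)
    seen[i, j] <- TRUE
    size <- 0L
    while (nrow(queue)) {
      p <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      size <- size + 1L
      for (k in seq_len(nrow(nb))) {
        ni <- p[1L] + nb[k, 1L]
        nj <- p[2L] + nb[k, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
    sizes[count] <- size
  }
  list(count = count, sizes = sizes)
}

# Rasterized centred disk mask.
disk_mask <- function(r, pad = 3) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- r + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

# Particle-level accuracy of a classified scene against generator truth,
# matching segmented particles to planted ones by pixel overlap.
scene_accuracy <- function(result, scene) {
  pred <- result$particles
  ok <- 0L
  for (r in seq_len(nrow(pred))) {
    px <- result$label_map == pred$id[r]
    tid <- as.integer(names(which.max(table(scene$truth_labels[px]))))
    true_cl <- scene$truth_classes$class[scene$truth_classes$id == tid]
    ok <- ok + (pred$class[r] == true_cl)
  }
  ok / nrow(pred)
}

# Noise-free template variants for deterministic fixtures.
clean_templates <- function() {
  tpls <- default_templates()
  lapply(tpls, function(t) {
    t$noise_sd <- 0
    t$scatter_range <- c(1, 1)
    t$baseline_mag <- c(0, 0)
    t
  })
}
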