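# Independent brute-force oracles and fixture builders shared across the
# test files. Oracles deliberately avoid the package's own computational
# paths: they enumerate, hand-count or finite-difference.

# Brute-force one-vs-rest metrics: expand the confusion matrix into an
# item list and count TP/FP/TN/FN by enumeration.
oracle_items <- function(m) {
  items <- NULL
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] > 0) {
      items <- rbind(items, matrix(rep(c(i - 1L, j - 1L), m[i, j]),
                                   ncol = 2, byrow = TRUE))
    }
  }
  items
}

oracle_class_metrics <- function(m, cl) {
  it <- oracle_items(m)
  tp <- sum(it[, 1] == cl & it[, 2] == cl)
  fn <- sum(it[, 1] == cl & it[, 2] != cl)
  fp <- sum(it[, 1] != cl & it[, 2] == cl)
  tn <- sum(it[, 1] != cl & it[, 2] != cl)
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (re + pr > 0) 2 * re * pr / (re + pr) else 0
  c(TP = tp, FP = fp, TN = tn, FN = fn, RE = re, PR = pr, SP = sp, F1 = f1)
}

# Average precision by exhaustive threshold enumeration: at every distinct
# score value, classify scores >= threshold as positive and record the
# (recall, precision) point; sum P * delta-recall over descending
# thresholds.
oracle_average_precision <- function(y, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1)
  prev_recall <- 0
  ap <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(y[sel] == 1)
    recall <- tp / n_pos
    precision <- tp / sum(sel)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Central finite-difference gradient of the batch loss w.r.t. every
# parameter entry.
fd_gradients <- function(params, x, y, loss, gamma, peephole = TRUE,
                         eps = 1e-5) {
  lossfun <- function(p) {
    lstm_gradients(p, x, y, loss = loss, gamma = gamma,
                   peephole = peephole)$loss
  }
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]]
    for (k in seq_along(g)) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      lp <- lossfun(p2)
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      lm <- lossfun(p2)
      g[k] <- (lp - lm) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# floor absorbs central-difference rounding noise on near-zero gradients
max_rel_err <- function(a, b, floor = 1e-6) {
  stopifnot(identical(names(a), names(b)))
  max(unlist(Map(function(u, v) {
    abs(u - v) / pmax(abs(u), abs(v), floor)
  }, a, b)))
}

# Write a small WFDB fixture (record + annotations) into `dir` and return
# the ground truth. Amplitudes sit exactly on the ADC grid (gain 200) so
# the binary round trip is sample-identical.
write_fixture_record <- function(dir, record_id = "f001", n = 1000L,
                                 fs = 360, n_channels = 2L, seed = 1L) {
  withr::with_seed(seed, {
    adc <- matrix(sample(-200:200, n * n_channels, replace = TRUE),
                  n, n_channels)
    signals <- adc / 200
    write_wfdb_record(signals, dir, record_id, fs = fs)
    list(record_id = record_id, fs = fs, signals = signals)
  })
}
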