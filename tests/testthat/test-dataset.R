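test_that("segmentation windows are R-centered and boundary-safe", {
  sig <- seq_len(250) / 10
  one <- segment_beats(sig, data.frame(sample_index = 125L, symbol = "N"))
  expect_equal(one$n, 1L)
  expect_equal(one$x[1, ], sig)              # exact-fit window
  expect_equal(one$label, 0L)

  none <- segment_beats(sig, data.frame(sample_index = 100L, symbol = "N"))
  expect_equal(none$n, 0L)                   # window [-25, 224] out of bounds
  expect_equal(attr(none, "n_boundary_skipped"), 1L)

  # brute-force window-fit check on a longer fixture
  ann <- data.frame(sample_index = c(50L, 500L, 1000L, 1950L),
                    symbol = rep("L", 4))
  ds <- segment_beats(rep(0, 2000), ann)
  expect_equal(ds$n, 2L)
  expect_equal(ds$r_index, c(500L, 1000L))

  # unmapped symbols are dropped before windowing
  mixed <- segment_beats(rep(0, 2000),
                         data.frame(sample_index = c(500L, 600L),
                                    symbol = c("V", "A")))
  expect_equal(mixed$label, 3L)
})

test_that("every emitted beat has length 250 with the R-peak at position 125", {
  withr::with_seed(5, {
    sig <- rnorm(3000)
    r <- sort(sample(200:2800, 12))
    ds <- segment_beats(sig, data.frame(sample_index = r, symbol = "R"))
    expect_equal(ncol(ds$x), 250L)
    # 0-based position 125 = column 126 holds the annotated sample
    expect_equal(ds$x[, 126], sig[ds$r_index + 1L])
  })
})

test_that("Z-score normalization has the stated moments and degenerate rule", {
  expect_equal(zscore_beat(rep(5, 250)), rep(0, 250))  # constant beat
  pat <- rep(c(-1, 1), 125)
  expect_equal(zscore_beat(pat), pat / sd(pat))        # preserved up to scale
  withr::with_seed(6, {
    b <- rnorm(250, mean = 3, sd = 7)
    z <- zscore_beat(b)
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
    # matrix form agrees with the vector form row-wise
    m <- rbind(b, rep(1, 250))
    zm <- zscore_beat(m)
    expect_equal(unname(zm[1, ]), z)
    expect_equal(unname(zm[2, ]), rep(0, 250))
  })
})

test_that("build_beat_dataset concatenates per-record outputs in order", {
  expect_equal(build_beat_dataset(list())$n, 0L)
  withr::with_seed(7, {
    mk <- function(id, r_peaks) {
      sig <- matrix(rnorm(2000, sd = 0.2), ncol = 1)
      list(record = ecglstm:::new_ecg_record(id, 360, sig),
           annotations = data.frame(sample_index = r_peaks,
                                    symbol = rep("N", length(r_peaks))))
    }
    recs <- list(mk("a", c(300L, 700L, 1100L)),
                 mk("b", c(10L, 300L, 700L, 1100L, 1500L)))
    ds <- build_beat_dataset(recs, denoise = TRUE)
    expect_equal(ds$n, 7L)                   # 3 + 4 (one boundary skip in "b")
    expect_equal(ds$record_id, c(rep("a", 3), rep("b", 4)))
    # every beat z-scored
    expect_lt(max(abs(rowMeans(ds$x))), 1e-9)
  })
})

test_that("stratified split has exact sizes and partitions the dataset", {
  ds <- beat_dataset(matrix(rnorm(1000 * 20), 1000), rep(0:7, 125))
  parts <- split_beat_dataset(ds, 0.10, 0.10, seed = 1)
  expect_equal(parts$test$n, 100L)
  expect_equal(parts$validation$n, 90L)
  expect_equal(parts$train$n, 810L)
  # disjoint and exhaustive: recover every original row exactly once
  key <- function(p) apply(p$x, 1, function(r) paste(r[1:3], collapse = ","))
  all_keys <- c(key(parts$train), key(parts$validation), key(parts$test))
  expect_setequal(all_keys, apply(ds$x, 1, function(r) paste(r[1:3], collapse = ",")))
  expect_equal(length(all_keys), 1000L)
  # determinism
  parts2 <- split_beat_dataset(ds, 0.10, 0.10, seed = 1)
  expect_identical(parts$test$x, parts2$test$x)
  expect_identical(parts$train$x, parts2$train$x)
})

test_that("tiny classes keep at least one member in the training set", {
  ds <- beat_dataset(matrix(rnorm(102 * 20), 102), c(rep(0L, 100), 1L, 1L))
  parts <- split_beat_dataset(ds, 0.10, 0.10, seed = 3)
  expect_gte(sum(parts$train$label == 1L), 1L)
})

test_that("invalid split fractions are rejected", {
  ds <- beat_dataset(matrix(rnorm(200), 10), rep(0L, 10))
  expect_error(split_beat_dataset(ds, 0, 0.1), "fractions")
  expect_error(split_beat_dataset(ds, 0.1, 1), "fractions")
})

test_that("dataset serialization round-trips bit-exactly", {
  withr::with_seed(8, {
    ds <- beat_dataset(matrix(rnorm(12 * 250), 12), sample(0:7, 12, TRUE),
                       record_id = "rec", r_index = 1:12)
    dir <- withr::local_tempdir()
    path <- file.path(dir, "beats.txt")
    write_beat_dataset(ds, path, split = rep("train", 12))
    back <- read_beat_dataset(path)
    expect_identical(back$x, ds$x)           # 17 significant digits round-trip
    expect_identical(back$label, ds$label)
    expect_equal(attr(back, "split"), rep("train", 12))
    expect_error(read_beat_dataset(file.path(dir, "missing.txt")), "missing.txt")
  })
})
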