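# Seeded synthetic ECG beat generator: sum-of-Gaussians morphology
# (McSharry-style) with per-class caricature templates, per-beat jitter
# and additive baseline / powerline / white noise. The class distinctions
# (widened QRS for bundle-branch classes, shifted or absent P waves for
# atrial and junctional classes, ...) are deliberately schematic: they
# make class separability provable by construction so the pipeline can be
# tested without any data download, not clinically faithful.

# Per-class wave tables: center offsets are in samples relative to the
# R-peak position 125 (0-based) at 360 Hz, widths in samples, amplitudes
# in mV.
.beat_templates <- local({
  waves <- function(p, q, r, s, t) {
    m <- rbind(P = p, Q = q, R = r, S = s, T = t)
    colnames(m) <- c("center", "width", "amp")
    m
  }
  list(
    # N: textbook normal sinus beat
    N = waves(p = c(-45, 8, 0.15), q = c(-10, 3, -0.20),
              r = c(0, 5, 1.50), s = c(10, 3, -0.30), t = c(55, 18, 0.35)),
    # LBBB: broad notched-looking QRS, no Q, deep slurred S, inverted T
    LBBB = waves(p = c(-45, 8, 0.12), q = c(-14, 6, 0.25),
                 r = c(0, 12, 1.20), s = c(20, 9, -0.55), t = c(60, 18, -0.30)),
    # RBBB: wide R with a late secondary deflection (rSR'-like)
    RBBB = waves(p = c(-45, 8, 0.12), q = c(-10, 3, -0.15),
                 r = c(0, 6, 1.00), s = c(22, 6, 0.80), t = c(62, 18, -0.20)),
    # APC: premature atrial P close to the QRS, slightly smaller R
    APC = waves(p = c(-28, 5, 0.28), q = c(-10, 3, -0.18),
                r = c(0, 5, 1.30), s = c(10, 3, -0.28), t = c(52, 16, 0.30)),
    # NESC: junctional escape, absent P, broad low T
    NESC = waves(p = c(-45, 8, 0.00), q = c(-10, 3, -0.15),
                 r = c(0, 6, 1.40), s = c(11, 4, -0.25), t = c(58, 22, 0.40)),
    # ABERR: aberrantly conducted atrial premature: early P and wide QRS
    ABERR = waves(p = c(-34, 5, 0.20), q = c(-12, 4, -0.10),
                  r = c(0, 11, 1.10), s = c(18, 7, -0.50), t = c(55, 16, 0.25)),
    # NPC: junctional premature, retrograde (inverted, post-QRS) P
    NPC = waves(p = c(28, 5, -0.18), q = c(-9, 3, -0.15),
                r = c(0, 5, 1.45), s = c(10, 3, -0.27), t = c(58, 16, 0.32)),
    # AESC: atrial escape, remote low-amplitude P, modest T
    AESC = waves(p = c(-62, 10, 0.10), q = c(-10, 3, -0.18),
                 r = c(0, 5, 1.35), s = c(10, 3, -0.26), t = c(50, 14, 0.22))
  )
})

#' Noiseless class templates
#'
#' The eight built-in beat templates evaluated without jitter or noise.
#'
#' @param beat_length Beat length in samples (default 250, R-peak at
#'   position 125).
#' @return 8 x `beat_length` matrix, one template per row, rownames from
#'   [beat_classes()].
#' @export
beat_templates <- function(beat_length = 250L) {
  t(vapply(beat_classes(), function(cl) {
    .eval_template(.beat_templates[[cl]], beat_length)
  }, numeric(beat_length)))
}

.eval_template <- function(w, beat_length, center_jitter = 0, amp_scale = 1) {
  t <- seq_len(beat_length) - 1L
  y <- numeric(beat_length)
  for (k in seq_len(nrow(w))) {
    center <- 125 + w[k, "center"] + (if (length(center_jitter) > 1)
      center_jitter[[k]] else center_jitter)
    amp <- w[k, "amp"] * (if (length(amp_scale) > 1) amp_scale[[k]] else amp_scale)
    y <- y + amp * exp(-(t - center)^2 / (2 * w[k, "width"]^2))
  }
  y
}

#' Noise specification
#'
#' Additive noise model for synthetic ECG: a baseline-wander sinusoid, a
#' powerline sinusoid and white Gaussian noise.
#'
#' @param baseline_amp Baseline-wander amplitude in mV (default 0.1).
#' @param powerline_amp Powerline amplitude in mV (default 0.05).
#' @param white_sd White-noise standard deviation in mV (default 0.05).
#' @param baseline_freq Baseline frequency in Hz (default 0.3).
#' @param powerline_freq Powerline frequency in Hz (default 60).
#' @return Named list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0.1, powerline_amp = 0.05,
                       white_sd = 0.05, baseline_freq = 0.3,
                       powerline_freq = 60) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, white_sd >= 0)
  structure(list(baseline_amp = baseline_amp, powerline_amp = powerline_amp,
                 white_sd = white_sd, baseline_freq = baseline_freq,
                 powerline_freq = powerline_freq),
            class = "noise_spec")
}

#' Add synthetic noise to a signal
#'
#' Adds a random-phase baseline sinusoid, a random-phase powerline
#' sinusoid and white Gaussian noise per the [noise_spec()]. Draws from
#' the current RNG stream (seed with [set.seed()] or via the generator's
#' `seed` arguments); an all-zero spec returns the signal unchanged.
#'
#' @param signal Numeric vector.
#' @param noise A `noise_spec`.
#' @param fs Sampling rate in Hz (default 360).
#' @return Noisy signal, same length.
#' @export
add_noise <- function(signal, noise = noise_spec(), fs = 360) {
  n <- length(signal)
  t <- (seq_len(n) - 1L) / fs
  out <- signal
  if (noise$baseline_amp > 0) {
    out <- out + noise$baseline_amp *
      sin(2 * pi * noise$baseline_freq * t + stats::runif(1, 0, 2 * pi))
  }
  if (noise$powerline_amp > 0) {
    out <- out + noise$powerline_amp *
      sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
  }
  if (noise$white_sd > 0) {
    out <- out + stats::rnorm(n, 0, noise$white_sd)
  }
  out
}

#' Generate one synthetic beat
#'
#' Evaluates the class template (sum of Gaussian waves) with per-beat
#' jitter — wave centers shifted by up to ±3 samples and amplitudes
#' scaled by up to ±10%, drawn per wave — then adds noise per the spec.
#' Draws from the current RNG stream.
#'
#' @param class_id 0-based class index (0..7).
#' @param noise A `noise_spec`; use `noise_spec(0, 0, 0)` for clean beats.
#' @param beat_length Beat length in samples (default 250).
#' @param jitter Apply per-beat jitter (default TRUE).
#' @param fs Sampling rate in Hz (default 360).
#' @return Numeric vector of length `beat_length` (mV).
#' @export
gen_beat <- function(class_id, noise = noise_spec(), beat_length = 250L,
                     jitter = TRUE, fs = 360) {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 0L || class_id > 7L) {
    stop("class_id must lie in 0..7")
  }
  w <- .beat_templates[[class_id + 1L]]
  if (jitter) {
    cj <- stats::runif(nrow(w), -3, 3)
    as <- stats::runif(nrow(w), 0.9, 1.1)
  } else {
    cj <- 0; as <- 1
  }
  add_noise(.eval_template(w, beat_length, cj, as), noise, fs)
}

#' Scale the reference class distribution to a total size
#'
#' Largest-remainder allocation of `n` beats across the eight classes in
#' proportion to the MIT-BIH distribution ([mitbih_class_counts()]); very
#' rare classes may receive zero beats at small `n`.
#'
#' @param n Total number of beats.
#' @return Named integer vector of length 8 summing to `n`.
#' @export
mitbih_proportions <- function(n) {
  ref <- mitbih_class_counts()
  ideal <- n * ref / sum(ref)
  alloc <- floor(ideal)
  extra <- n - sum(alloc)
  if (extra > 0) {
    ord <- order(ideal - alloc, decreasing = TRUE)
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1
  }
  stats::setNames(as.integer(alloc), names(ref))
}

#' Generate a synthetic beat dataset
#'
#' Generates the requested number of beats per class with [gen_beat()],
#' shuffles them deterministically, and (by default) Z-score normalizes
#' each beat so the result is ready for [ecg_lstm()].
#'
#' @param class_counts Named or positional integer vector of per-class
#'   counts; either length 8, or named by class ([beat_classes()]) with
#'   omitted classes at 0. Use [mitbih_proportions()] for the reference
#'   imbalance.
#' @param noise A `noise_spec` (default: mild baseline + powerline +
#'   white noise).
#' @param seed Integer seed; the full dataset is deterministic given it.
#' @param beat_length Beat length (default 250).
#' @param normalize Z-score normalize each beat (default TRUE).
#' @return A `beat_dataset` with exactly the requested class counts.
#' @export
#' @examples
#' ds <- gen_beat_dataset(mitbih_proportions(400), seed = 1)
#' class_distribution(ds)
gen_beat_dataset <- function(class_counts, noise = noise_spec(), seed = 1L,
                             beat_length = 250L, normalize = TRUE) {
  counts <- rep(0L, 8L)
  names(counts) <- beat_classes()
  if (!is.null(names(class_counts)) && any(nzchar(names(class_counts)))) {
    bad <- setdiff(names(class_counts), beat_classes())
    if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = " "))
    counts[names(class_counts)] <- as.integer(class_counts)
  } else {
    stopifnot(length(class_counts) <= 8L)
    counts[seq_along(class_counts)] <- as.integer(class_counts)
  }
  if (any(counts < 0L)) stop("class counts must be >= 0")
  n <- sum(counts)
  if (n == 0L) stop("all class counts are zero")
  .with_seed(seed, {
    labels <- rep(0:7, counts)
    x <- matrix(0, n, beat_length)
    for (k in seq_len(n)) {
      x[k, ] <- gen_beat(labels[[k]], noise, beat_length)
    }
    ord <- sample.int(n)
    ds <- beat_dataset(x[ord, , drop = FALSE], labels[ord],
                       record_id = "synthetic", r_index = 125L)
    if (normalize) zscore_beat(ds) else ds
  })
}
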