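# Synthetic ECG generator.  Beats are a sum of parameterized bumps
# (Gaussian P, piecewise-linear QRS triangle, Gaussian T) placed at RR
# intervals, with class-dependent morphology and rhythm irregularity.
# Every generated record carries ground-truth beat/fiducial annotations so
# that delineation accuracy is measurable.

# Template geometry (seconds, relative to the R peak, at QRS width scale 1)
.TPL <- list(
  qrs_hw     = 0.040,   # Q and S sit at -/+ this offset
  qrs_on_k   = 1.25,    # QRS support starts at -k*hw
  qrs_off_k  = 1.375,   # and ends at +k*hw
  q_frac     = -0.10,   # Q dip as fraction of R amplitude
  s_frac     = -0.20,   # S dip as fraction of R amplitude
  p_center   = -0.180,
  p_sigma    = 0.025,
  t_center   = 0.280,
  t_sigma    = 0.045,
  cross10    = sqrt(2 * log(10))  # Gaussian 10%-amplitude half-width, in sigmas
)

class_defaults <- function(class_label) {
  switch(class_label,
    NSR = list(heart_rate_bpm = 75, rr_jitter_cv = 0.05, p_scale = 1,
               qrs_width_scale = 1, ectopic_rate = 0),
    AFF = list(heart_rate_bpm = 95, rr_jitter_cv = 0.18, p_scale = 0,
               qrs_width_scale = 1, ectopic_rate = 0),
    ARR = list(heart_rate_bpm = 80, rr_jitter_cv = 0.05, p_scale = 1,
               qrs_width_scale = 1, ectopic_rate = 0.2),
    CHF = list(heart_rate_bpm = 90, rr_jitter_cv = 0.005, p_scale = 1,
               qrs_width_scale = 1.5, ectopic_rate = 0),
    stop("unknown class label: ", class_label)
  )
}

#' Parameters for the synthetic ECG generator
#'
#' Class defaults encode the rhythm/morphology rules that make the four
#' classes separable: NSR regular rhythm with P waves; AFF absent P and
#' strongly irregular RR (`rr_jitter_cv >= 0.15`); ARR premature ectopic
#' beats (shortened preceding RR, widened QRS) inserted at rate 0.2/beat;
#' CHF near-zero heart-rate variability (`rr_jitter_cv <= 0.01`) with a
#' prolonged QRS.
#'
#' @param class_label One of `"ARR"`, `"AFF"`, `"CHF"`, `"NSR"`.
#' @param duration_s Record length in seconds (default 3, short
#'   single-lead strips).
#' @param fs Sampling rate in Hz (default 250).
#' @param heart_rate_bpm Mean heart rate; `NULL` uses the class default.
#' @param rr_jitter_cv Coefficient of variation of RR intervals; `NULL`
#'   uses the class default.
#' @param wave_amplitudes Named numeric `c(P=, QRS=, T=)` amplitudes in mV.
#' @param noise_sd Additive white-noise standard deviation in mV.
#' @param baseline_amp Amplitude (mV) of a slow baseline-wander sine.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `ecg_gen_params`.
#' @export
ecg_gen_params <- function(class_label,
                           duration_s = 3,
                           fs = 250,
                           heart_rate_bpm = NULL,
                           rr_jitter_cv = NULL,
                           wave_amplitudes = c(P = 0.15, QRS = 1.0, T = 0.30),
                           noise_sd = 0.01,
                           baseline_amp = 0.02,
                           seed = NULL) {
  class_label <- match.arg(class_label, CVD_CLASSES)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  def <- class_defaults(class_label)
  if (is.null(heart_rate_bpm)) heart_rate_bpm <- def$heart_rate_bpm
  if (is.null(rr_jitter_cv)) rr_jitter_cv <- def$rr_jitter_cv
  if (rr_jitter_cv < 0) stop("rr_jitter_cv must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    class_label = class_label, duration_s = duration_s, fs = fs,
    heart_rate_bpm = heart_rate_bpm, rr_jitter_cv = rr_jitter_cv,
    wave_amplitudes = wave_amplitudes, noise_sd = noise_sd,
    baseline_amp = baseline_amp, seed = seed,
    p_scale = def$p_scale, qrs_width_scale = def$qrs_width_scale,
    ectopic_rate = def$ectopic_rate
  ), class = "ecg_gen_params")
}

# Truth fiducials (seconds relative to R) for one beat.
beat_truth <- function(wscale, p_scale) {
  tpl <- .TPL
  hw <- tpl$qrs_hw * wscale
  out <- list(
    Q = -hw, R = 0, S = hw,
    QRSon = -tpl$qrs_on_k * hw, QRSoff = tpl$qrs_off_k * hw,
    Ton = tpl$t_center - tpl$cross10 * tpl$t_sigma,
    Tpeak = tpl$t_center,
    Toff = tpl$t_center + tpl$cross10 * tpl$t_sigma
  )
  if (p_scale > 0) {
    out$Pon <- tpl$p_center - tpl$cross10 * tpl$p_sigma
    out$Ppeak <- tpl$p_center
    out$Poff <- tpl$p_center + tpl$cross10 * tpl$p_sigma
  } else {
    out$Pon <- out$Ppeak <- out$Poff <- NA_real_
  }
  out
}

# Amplitude contribution of one beat at absolute times tt (seconds),
# R peak at r_t.
beat_wave <- function(tt, r_t, amp, wscale, p_scale) {
  tpl <- .TPL
  rel <- tt - r_t
  hw <- tpl$qrs_hw * wscale
  y <- numeric(length(tt))
  # P and T: Gaussians
  if (p_scale > 0) {
    y <- y + amp[["P"]] * p_scale * exp(-0.5 * ((rel - tpl$p_center) / tpl$p_sigma)^2)
  }
  y <- y + amp[["T"]] * exp(-0.5 * ((rel - tpl$t_center) / tpl$t_sigma)^2)
  # QRS: piecewise-linear through (on,0) (Q,qf) (R,1) (S,sf) (off,0)
  xs <- c(-tpl$qrs_on_k * hw, -hw, 0, hw, tpl$qrs_off_k * hw)
  ys <- amp[["QRS"]] * c(0, tpl$q_frac, 1, tpl$s_frac, 0)
  inside <- rel >= xs[1] & rel <= xs[5]
  if (any(inside)) {
    y[inside] <- y[inside] + stats::approx(xs, ys, xout = rel[inside])$y
  }
  y
}

#' Generate one synthetic labeled ECG record
#'
#' Builds a trace from Gaussian-bump P, triangular QRS and Gaussian T
#' templates placed at (possibly jittered) RR intervals, plus additive
#' Gaussian noise and a slow baseline sine.  Ground-truth beat and
#' fiducial positions are recorded in the returned object.
#'
#' @param params An [ecg_gen_params()] object.
#' @return An `ecg_record` with fields `samples` (mV), `fs`, `label` and
#'   `truth` (data frame of per-beat fiducial sample indices, plus
#'   `r_time` seconds and per-beat metadata).
#' @export
generate_ecg <- function(params) {
  stopifnot(inherits(params, "ecg_gen_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$fs
  n <- round(params$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  mean_rr <- 60 / params$heart_rate_bpm

  # Beat placement: R peaks must leave room for the full template
  left_margin <- 0.30
  right_margin <- 0.38
  r_times <- c()
  wscales <- c()
  cur <- left_margin + 0.05
  repeat {
    ect <- params$ectopic_rate > 0 && stats::runif(1) < params$ectopic_rate
    rr <- mean_rr * max(0.5, stats::rnorm(1, mean = 1, sd = params$rr_jitter_cv))
    if (ect) rr <- rr * 0.6
    if (length(r_times) == 0) {
      r_next <- cur
    } else {
      r_next <- r_times[length(r_times)] + rr
    }
    if (r_next > params$duration_s - right_margin) break
    r_times <- c(r_times, r_next)
    wscales <- c(wscales, params$qrs_width_scale * if (ect) 1.6 else 1)
  }
  if (length(r_times) == 0) {
    stop("duration_s too short to place a single beat (need >= ",
         left_margin + right_margin + 0.1, " s)")
  }

  x <- numeric(n)
  for (b in seq_along(r_times)) {
    x <- x + beat_wave(tt, r_times[b], params$wave_amplitudes,
                       wscales[b], params$p_scale)
  }
  if (params$baseline_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + params$baseline_amp * sin(2 * pi * 0.25 * tt + phase)
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)

  truth <- do.call(rbind, lapply(seq_along(r_times), function(b) {
    ft <- beat_truth(wscales[b], params$p_scale)
    idx <- function(rel) {
      if (is.na(rel)) NA_integer_ else as.integer(round((r_times[b] + rel) * fs) + 1L)
    }
    data.frame(
      beat = b, r_time = r_times[b], qrs_width_scale = wscales[b],
      Pon = idx(ft$Pon), Ppeak = idx(ft$Ppeak), Poff = idx(ft$Poff),
      Q = idx(ft$Q), R = idx(ft$R), S = idx(ft$S),
      QRSon = idx(ft$QRSon), QRSoff = idx(ft$QRSoff),
      Ton = idx(ft$Ton), Tpeak = idx(ft$Tpeak), Toff = idx(ft$Toff)
    )
  }))

  ecg_record(x, fs, label = params$class_label, truth = truth)
}

#' Construct an ECG record
#'
#' @param samples Numeric amplitude vector (mV).
#' @param fs Sampling rate (Hz).
#' @param label Optional class label.
#' @param truth Optional generator ground-truth annotation data frame.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, label = NULL, truth = NULL) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 label = label, truth = truth),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Generate a batch of labeled synthetic records
#'
#' @param n_per_class Records per class.
#' @param classes Class labels to generate.
#' @param duration_s,fs Passed to [ecg_gen_params()].
#' @param seed Integer seed for the whole batch.
#' @param ... Further arguments to [ecg_gen_params()].
#' @return List of `ecg_record`s (classes interleaved in label order).
#' @export
generate_ecg_batch <- function(n_per_class, classes = CVD_CLASSES,
                               duration_s = 3, fs = 250, seed = 1, ...) {
  set.seed(seed)
  recs <- list()
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      p <- ecg_gen_params(cl, duration_s = duration_s, fs = fs, seed = NULL, ...)
      recs[[length(recs) + 1L]] <- generate_ecg(p)
    }
  }
  recs
}

#' Generate a synthetic 54-feature, 4-class table
#'
#' Emulates a feature table extracted from labeled recordings.  A
#' designated informative subset of registry columns carries class
#' structure (class means differ by `separation` standard deviations in a
#' rotating one-class-up pattern); the remaining columns are
#' class-independent standard-normal noise.
#'
#' @param n_per_class Rows per class (>= 1).
#' @param separation Effect size in noise standard deviations (>= 0).
#' @param seed Integer seed.
#' @param n_informative Number of informative columns (default 13).
#' @return A data frame with the 54 registry columns plus `label`, with
#'   attributes `informative` (names of informative columns) and
#'   `separation`.
#' @export
generate_feature_table <- function(n_per_class, separation = 3, seed = 1,
                                   n_informative = 13) {
  stopifnot(n_per_class >= 1, separation >= 0,
            n_informative >= 1, n_informative <= 54)
  set.seed(seed)
  reg <- feature_registry()$name
  classes <- CVD_CLASSES
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  # Informative columns spread across feature groups (stable choice).
  informative <- reg[seq(1, 54, length.out = n_informative)]
  x <- matrix(stats::rnorm(n * 54), nrow = n,
              dimnames = list(NULL, reg))
  for (k in seq_along(informative)) {
    boosted <- classes[((k - 1) %% length(classes)) + 1]
    x[labels == boosted, informative[k]] <-
      x[labels == boosted, informative[k]] + separation
  }
  out <- as.data.frame(x)
  out$label <- labels
  attr(out, "informative") <- informative
  attr(out, "separation") <- separation
  out
}

#' Write ECG records as one-row-per-recording CSV
#'
#' @param records List of `ecg_record`s (equal lengths required).
#' @param path Output CSV path: columns `label`, `s1..sN`.
#' @export
write_ecg_csv <- function(records, path) {
  lens <- vapply(records, function(r) length(r$samples), integer(1))
  stopifnot(length(unique(lens)) == 1)
  m <- do.call(rbind, lapply(records, function(r) r$samples))
  df <- data.frame(label = vapply(records, function(r) r$label %||% NA_character_,
                                  character(1)), m, check.names = FALSE)
  names(df) <- c("label", paste0("s", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ECG records from one-row-per-recording CSV
#'
#' @param path CSV written by [write_ecg_csv()] (or equivalent layout).
#' @param fs Sampling rate of the stored signals.
#' @return List of `ecg_record`s.
#' @export
read_ecg_csv <- function(path, fs = 250) {
  df <- utils::read.csv(path, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ecg_record(as.numeric(df[i, -1]), fs = fs, label = as.character(df$label[i]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
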