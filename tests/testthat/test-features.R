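# helper: build a fiducial_points object directly from index vectors
fp_from <- function(df, fs = 250) {
  structure(list(beats = df, fs = fs), class = "fiducial_points")
}

test_that("the registry has 54 unique names with the stated group counts", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 54)
  expect_false(anyDuplicated(reg$name) > 0)
  counts <- table(reg$group)
  expect_equal(as.integer(counts[c("rate", "morphological", "fiducial",
                                   "statistical", "hrv")]),
               c(1L, 11L, 29L, 4L, 9L))
})

test_that("HRV oracle values match hand computation", {
  h <- compute_hrv(c(0.800, 0.860, 0.840))
  expect_equal(unname(h["NN50"]), 1)
  expect_equal(unname(h["pNN50"]), 50)
  expect_equal(unname(h["RMSSD"]), sqrt((0.060^2 + 0.020^2) / 2),
               tolerance = 1e-12)
  expect_equal(unname(h["RMSSD"]) * 1000, 44.72, tolerance = 1e-3)
  expect_equal(unname(h["SDRR"]), sd(c(0.800, 0.860, 0.840)))
  expect_equal(unname(h["IBIM"]), mean(c(0.800, 0.860, 0.840)))
})

test_that("HRV on constant RR is zero-variability", {
  h <- compute_hrv(rep(0.8, 10))
  expect_equal(unname(h[c("SDRR", "RMSSD", "NN50", "SDSD")]), rep(0, 4))
})

test_that("RRTot equals IBIM times NNTot", {
  set.seed(2)
  for (i in 1:20) {
    rr <- runif(sample(2:30, 1), 0.4, 1.4)
    h <- compute_hrv(rr)
    expect_equal(unname(h["RRTot"]), unname(h["IBIM"] * h["NNTot"]),
                 tolerance = 1e-12)
  }
})

test_that("difference-based HRV is flagged missing below 2 intervals", {
  h <- compute_hrv(0.8)
  expect_true(is.na(h["RMSSD"]))
  expect_true(is.na(h["SDRR"]))
  expect_equal(unname(h["NNTot"]), 1)
})

test_that("heart rate fixtures: 1 s and 0.5 s RR", {
  expect_equal(compute_heart_rate(c(1, 251, 501), 250), 60)
  expect_equal(compute_heart_rate(seq(1, 1001, by = 125), 250), 120)
  expect_true(is.na(compute_heart_rate(100, 250)))
})

test_that("QRS partition ratios are exact and sum to one", {
  df <- data.frame(beat = 1L, Pon = NA, Ppeak = NA, Poff = NA,
                   Q = 1L, R = 11L, S = 21L, Ton = 60L, Tpeak = 70L,
                   Toff = 80L)
  st <- compute_statistical(fp_from(df), 250)
  expect_equal(unname(st["QRtoQSdur"]), 0.5)
  expect_equal(unname(st["RStoQSdur"]), 0.5)
})

test_that("partition ratios sum to 1 on real delineations", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("ARR", duration_s = 10, seed = 4)))
  fp <- suppressMessages(delineate(rec, detect_r_peaks(rec)))
  st <- compute_statistical(fp, 250)
  expect_equal(unname(st["QRtoQSdur"] + st["RStoQSdur"]), 1, tolerance = 1e-12)
})

test_that("RR mean from uniform 1 s spacing is 1 s", {
  df <- data.frame(beat = 1:3, Pon = NA, Ppeak = NA, Poff = NA,
                   Q = c(95, 345, 595), R = c(100, 350, 600),
                   S = c(105, 355, 605), Ton = c(150, 400, 650),
                   Tpeak = c(160, 410, 660), Toff = c(170, 420, 670))
  st <- compute_statistical(fp_from(df), 250)
  expect_equal(unname(st["RRmean"]), 1.0)
})

test_that("geometric oracles: triangle area, right angle, slope, distance", {
  # QRS triangle area: base 0.08 s, height 1 in the (t, z) plane
  # (package computes on z-scored signal; check the shoelace core directly)
  q <- c(0, 0); r <- c(0.04, 1); s <- c(0.08, 0)
  area <- abs(q[1] * (r[2] - s[2]) + r[1] * (s[2] - q[2]) +
                s[1] * (q[2] - r[2])) / 2
  expect_equal(area, 0.04)
  # right angle at Q for P=(0,0), Q=(1,0), R=(1,1)
  expect_equal(cvdmix:::pt_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  # two-point slope
  expect_equal((-0.1 - 0.2) / (0.20 - 0.10), -3)
  # Euclidean distance R-S
  expect_equal(cvdmix:::pt_dist(c(0.24, 1.0), c(0.28, -0.2)),
               sqrt(0.04^2 + 1.2^2))
  expect_equal(sqrt(0.04^2 + 1.2^2), 1.2007, tolerance = 1e-4)
})

test_that("beat-averaged features equal single-beat features for identical beats", {
  # identical noise-free beats on the raw (exactly periodic) record;
  # fiducials taken from generator truth so every beat has exactly the
  # same landmark offsets from its R peak
  # fs = 200 puts every R time on the sample grid, so all beats share
  # exactly the same rounded landmark offsets
  rec <- generate_ecg(
    ecg_gen_params("NSR", duration_s = 6, heart_rate_bpm = 60, fs = 200,
                   rr_jitter_cv = 0, noise_sd = 0, baseline_amp = 0,
                   seed = 1))
  tr <- rec$truth
  mid <- 2:(nrow(tr) - 1)  # interior beats have identical neighborhoods
  beats <- data.frame(beat = seq_along(mid),
                      tr[mid, c("Pon", "Ppeak", "Poff", "Q", "R", "S",
                                "Ton", "Tpeak", "Toff")])
  fp <- fp_from(beats, fs = 200)
  one <- fp; one$beats <- fp$beats[2, , drop = FALSE]
  fa <- compute_fiducial(fp, rec$samples, 200)
  f1 <- compute_fiducial(one, rec$samples, 200)
  expect_equal(fa[grep("^d", names(fa))], f1[grep("^d", names(f1))],
               tolerance = 1e-6)
})

test_that("QRS duration recovers the generated width", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("NSR", duration_s = 10, seed = 17)))
  fp <- suppressMessages(delineate(rec, detect_r_peaks(rec)))
  mo <- compute_morphological(fp, rec$samples, 250)
  expect_lt(abs(mo[["QRSdur"]] - 0.08), 0.02)
})

test_that("feature extraction is deterministic and registry-complete", {
  rec <- butterworth_bandpass(generate_ecg(ecg_gen_params("CHF", seed = 23)))
  v1 <- suppressMessages(extract_features(rec))
  v2 <- suppressMessages(extract_features(rec))
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_registry()$name)
})

test_that("duration and interval features are positive; angles within [0, 180]", {
  recs <- suppressMessages(generate_ecg_batch(3, duration_s = 6, seed = 31))
  recs <- lapply(recs, butterworth_bandpass)
  tab <- suppressMessages(build_feature_table(recs))
  for (f in c("Pdur", "QRSdur", "Tdur", "PQint", "QTint", "RSint")) {
    v <- tab[[f]][!is.na(tab[[f]])]
    expect_true(all(v > 0))
  }
  for (f in grep("^Angle", names(tab), value = TRUE)) {
    v <- tab[[f]][!is.na(tab[[f]])]
    expect_true(all(v >= 0 & v <= 180))
  }
})

test_that("table assembly is row-order invariant and imputation fills NAs", {
  recs <- suppressMessages(generate_ecg_batch(4, duration_s = 6, seed = 41))
  recs <- lapply(recs, butterworth_bandpass)
  t1 <- suppressMessages(build_feature_table(recs))
  t2 <- suppressMessages(build_feature_table(rev(recs)))
  key <- function(tt) do.call(order, unname(tt[c("HR", "QRSdur", "RRTot",
                                                 "QRSarea")]))
  o1 <- t1[key(t1), ]; o2 <- t2[key(t2), ]
  rownames(o1) <- rownames(o2) <- NULL
  attributes(o1) <- attributes(o2) <- NULL
  expect_equal(o1, o2)
  imp <- impute_features(t1)
  expect_false(anyNA(imp[feature_registry()$name]))
  expect_true(any(attr(imp, "imputed")))
})

test_that("single-row tables warn instead of imputing", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("AFF", duration_s = 6, seed = 51)))
  tab <- suppressMessages(build_feature_table(list(rec)))
  expect_warning(impute_features(tab), "single-row")
})
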