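test_that("rescaled filter pair is normalized and QMF-consistent", {
  f <- wavelet_filters()
  expect_equal(sum(f$scaling^2) + sum(f$wavelet^2), 1, tolerance = 1e-12)
  # wavelet filter recomputed from the quadrature-mirror relation
  a <- f$scaling * sqrt(2)
  b_qmf <- (-1)^(0:(f$L - 1)) * rev(a)
  expect_equal(f$wavelet, b_qmf / sqrt(2), tolerance = 1e-14)
  expect_equal(sum(f$scaling), sqrt(2) / sqrt(2), tolerance = 1e-10)
  expect_equal(sum(f$wavelet), 0, tolerance = 1e-10)
})

test_that("constant signals vanish in the wavelet node", {
  d <- modwpt_decompose(rep(3.3, 64), levels = 1)
  expect_lt(max(abs(d$nodes[, 2])), 1e-10)
})

test_that("level 4 yields 16 full-length nodes", {
  x <- rnorm(300)
  d <- modwpt_decompose(x, levels = 4)
  expect_equal(dim(d$nodes), c(300L, 16L))
})

test_that("the transform conserves energy at every level", {
  set.seed(10)
  x <- rnorm(512)
  for (lev in 1:4) {
    d <- modwpt_decompose(x, levels = lev)
    expect_lt(abs(sum(d$nodes^2) - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("all-node reconstruction is the identity for several lengths", {
  set.seed(11)
  for (n in c(64, 250, 750)) {
    x <- rnorm(n)
    d <- modwpt_decompose(x, levels = 4)
    expect_lt(max(abs(imodwpt_reconstruct(d) - x)), 1e-8)
  }
})

test_that("the transform is circular-shift covariant", {
  set.seed(12)
  x <- rnorm(256)
  d <- modwpt_decompose(x, levels = 3)
  s <- 37
  xs <- c(x[(s + 1):256], x[1:s])
  ds <- modwpt_decompose(xs, levels = 3)
  expect_equal(ds$nodes, d$nodes[c((s + 1):256, 1:s), ], tolerance = 1e-12)
})

test_that("nodes 0-3 at level 4 pass 5 Hz and reject 50 Hz", {
  tt <- (0:749) / 250
  s5 <- sin(2 * pi * 5 * tt)
  s50 <- sin(2 * pi * 50 * tt)
  r5 <- imodwpt_reconstruct(modwpt_decompose(s5, levels = 4), 0:3)
  r50 <- imodwpt_reconstruct(modwpt_decompose(s50, levels = 4), 0:3)
  expect_gte(sum(r5^2) / sum(s5^2), 0.95)
  expect_lte(sum(r50^2) / sum(s50^2), 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(modwpt_decompose(rnorm(4), levels = 2), "minimum length")
  d <- modwpt_decompose(rnorm(64), levels = 2)
  expect_error(imodwpt_reconstruct(d, integer(0)), "non-empty")
  expect_error(imodwpt_reconstruct(d, 4), "indices")
})

test_that("R-peak detection matches generator truth on clean NSR", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("NSR", duration_s = 10, heart_rate_bpm = 60,
                   rr_jitter_cv = 0, noise_sd = 0, baseline_amp = 0,
                   seed = 5)))
  rp <- detect_r_peaks(rec)
  expect_equal(length(rp), nrow(rec$truth))
  expect_true(all(abs(rp - rec$truth$R) <= 2))
})

test_that("R-peak output is strictly increasing with refractory spacing", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("AFF", duration_s = 20, seed = 6)))
  rp <- detect_r_peaks(rec, refractory_s = 0.2)
  expect_true(all(diff(rp) > 0))
  expect_true(all(diff(rp) >= 0.2 * 250 - 2 * round(0.024 * 250)))
})

test_that("flat and all-zero signals yield no peaks", {
  expect_identical(detect_r_peaks(ecg_record(rep(0, 500), 250)), integer(0))
  expect_identical(detect_r_peaks(ecg_record(rep(2, 500), 250)), integer(0))
})

test_that("delineation recovers fiducials near generator truth", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("NSR", duration_s = 10, seed = 8)))
  rp <- detect_r_peaks(rec)
  fp <- suppressMessages(delineate(rec, rp))
  expect_s3_class(fp, "fiducial_points")
  tol <- round(0.02 * 250)
  hits <- 0; tot <- 0
  for (j in seq_len(nrow(fp$beats))) {
    ti <- which.min(abs(rec$truth$R - fp$beats$R[j]))
    for (f in c("Pon", "Ppeak", "Poff", "Q", "R", "S", "Ton", "Tpeak", "Toff")) {
      tot <- tot + 1
      if (!is.na(fp$beats[[f]][j]) &&
          abs(fp$beats[[f]][j] - rec$truth[[f]][ti]) <= tol) hits <- hits + 1
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("fiducial indices are strictly ordered within each beat", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("NSR", duration_s = 10, seed = 13)))
  fp <- suppressMessages(delineate(rec, detect_r_peaks(rec)))
  for (j in seq_len(nrow(fp$beats))) {
    v <- unlist(fp$beats[j, c("Pon", "Ppeak", "Poff", "Q", "R", "S",
                              "Ton", "Tpeak", "Toff")])
    v <- v[!is.na(v)]
    expect_true(all(diff(v) > 0))
  }
})

test_that("AFF-like rhythms yield absent P fields", {
  rec <- butterworth_bandpass(generate_ecg(
    ecg_gen_params("AFF", duration_s = 20, seed = 14)))
  fp <- suppressMessages(delineate(rec, detect_r_peaks(rec)))
  expect_gte(mean(is.na(fp$beats$Ppeak)), 0.95)
})

test_that("beats with truncated windows are dropped", {
  rec <- ecg_record(c(1, rep(0, 400)), 250)
  fp <- suppressMessages(delineate(rec, 1L))
  expect_equal(nrow(fp$beats), 0)
})
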