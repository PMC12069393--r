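# The 54-feature registry computation.  Geometric features (areas,
# perimeters, angles, distances, slopes) are measured in the
# (time seconds, z-scored amplitude) plane: the amplitude axis is z-scored
# per record so that angles and distances have a fixed scale convention.

fid_names <- c("Pon", "Ppeak", "Poff", "Q", "R", "S", "Ton", "Tpeak", "Toff")

# per-beat landmark coordinates in the (t, z) plane
beat_points <- function(fp, z, fs) {
  lapply(seq_len(nrow(fp$beats)), function(i) {
    row <- fp$beats[i, ]
    pts <- lapply(fid_names, function(f) {
      idx <- row[[f]]
      if (is.na(idx)) c(NA_real_, NA_real_) else c((idx - 1) / fs, z[idx])
    })
    names(pts) <- fid_names
    pts
  })
}

pt_angle <- function(a, v, b) {
  # planar angle at vertex v formed by rays v->a and v->b, degrees
  u1 <- a - v; u2 <- b - v
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (!is.finite(n1) || !is.finite(n2) || n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(u1 * u2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

pt_dist <- function(a, b) sqrt(sum((a - b)^2))

beat_mean <- function(vals) {
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Morphological features (11) from delineated beats
#'
#' Durations (P, QRS, T, one full cycle), QRS triangle area (shoelace) and
#' perimeter, and five landmark angles, all beat-averaged.  Geometric
#' quantities use the (seconds, z-scored amplitude) plane.
#'
#' @param fp A `fiducial_points` object (>= 1 beat).
#' @param signal The record's amplitude vector.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of length 11 (entries may be NA).
#' @export
compute_morphological <- function(fp, signal, fs) {
  stopifnot(inherits(fp, "fiducial_points"), nrow(fp$beats) >= 1)
  z <- as.numeric(scale(signal))
  pts <- beat_points(fp, z, fs)
  b <- fp$beats
  dur <- function(on, off) (b[[off]] - b[[on]]) / fs
  r_times <- (b$R - 1) / fs
  cyc <- if (nrow(b) >= 2) mean(diff(r_times)) else NA_real_
  per_beat <- function(f) beat_mean(vapply(pts, f, numeric(1)))
  tri <- function(p) {  # shoelace area of (Q, R, S)
    q <- p$Q; r <- p$R; s <- p$S
    if (anyNA(c(q, r, s))) return(NA_real_)
    a <- abs(q[1] * (r[2] - s[2]) + r[1] * (s[2] - q[2]) + s[1] * (q[2] - r[2])) / 2
    if (a < 1e-12) NA_real_ else a
  }
  peri <- function(p) {
    q <- p$Q; r <- p$R; s <- p$S
    if (anyNA(c(q, r, s))) return(NA_real_)
    pt_dist(q, r) + pt_dist(r, s) + pt_dist(s, q)
  }
  c(
    Pdur = beat_mean(dur("Pon", "Poff")),
    QRSdur = beat_mean(dur("Q", "S")),
    Tdur = beat_mean(dur("Ton", "Toff")),
    CycleDur = cyc,
    QRSarea = per_beat(tri),
    QRSperim = per_beat(peri),
    AnglePQR = per_beat(function(p) pt_angle(p$Ppeak, p$Q, p$R)),
    AngleQRS = per_beat(function(p) pt_angle(p$Q, p$R, p$S)),
    AngleRST = per_beat(function(p) pt_angle(p$R, p$S, p$Tpeak)),
    AnglePonPQ = per_beat(function(p) pt_angle(p$Pon, p$Ppeak, p$Q)),
    AngleSTToff = per_beat(function(p) pt_angle(p$S, p$Tpeak, p$Toff))
  )
}

#' Fiducial features (29): intervals, slopes and landmark distances
#'
#' Six peak-to-peak intervals (PQ, PT, QR, QT, RS, ST in seconds), four
#' two-point slopes (z-amplitude per second), and the 19 canonical
#' pairwise Euclidean distances in the (t, z) plane, beat-averaged.
#'
#' @inheritParams compute_morphological
#' @return Named numeric vector of length 29.
#' @export
compute_fiducial <- function(fp, signal, fs) {
  stopifnot(inherits(fp, "fiducial_points"), nrow(fp$beats) >= 1)
  z <- as.numeric(scale(signal))
  pts <- beat_points(fp, z, fs)
  interval <- function(a, b) {
    beat_mean(vapply(pts, function(p) {
      if (anyNA(c(p[[a]], p[[b]]))) NA_real_ else abs(p[[b]][1] - p[[a]][1])
    }, numeric(1)))
  }
  slope <- function(a, b) {
    beat_mean(vapply(pts, function(p) {
      pa <- p[[a]]; pb <- p[[b]]
      if (anyNA(c(pa, pb)) || pb[1] == pa[1]) return(NA_real_)
      (pb[2] - pa[2]) / (pb[1] - pa[1])
    }, numeric(1)))
  }
  out <- c(
    PQint = interval("Ppeak", "Q"), PTint = interval("Ppeak", "Tpeak"),
    QRint = interval("Q", "R"), QTint = interval("Q", "Tpeak"),
    RSint = interval("R", "S"), STint = interval("S", "Tpeak"),
    PQslope = slope("Ppeak", "Q"), QRslope = slope("Q", "R"),
    RSslope = slope("R", "S"), STslope = slope("S", "Tpeak")
  )
  pairs <- registry_distance_pairs()
  dvals <- apply(pairs, 1, function(pr) {
    beat_mean(vapply(pts, function(p) {
      pa <- p[[pr[1]]]; pb <- p[[pr[2]]]
      if (anyNA(c(pa, pb))) NA_real_ else pt_dist(pa, pb)
    }, numeric(1)))
  })
  names(dvals) <- paste0("d", pairs[, 1], pairs[, 2])
  c(out, dvals)
}

#' Statistical features (4)
#'
#' Mean RR and PP intervals (seconds) and the two QRS partition ratios
#' `QRtoQSdur = (R-Q)/(S-Q)` and `RStoQSdur = (S-R)/(S-Q)`, which sum to 1
#' whenever both are defined.
#'
#' @param fp A `fiducial_points` object.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of length 4.
#' @export
compute_statistical <- function(fp, fs) {
  stopifnot(inherits(fp, "fiducial_points"), nrow(fp$beats) >= 1)
  b <- fp$beats
  rr <- if (nrow(b) >= 2) mean(diff(b$R)) / fs else NA_real_
  pp_idx <- b$Ppeak[!is.na(b$Ppeak)]
  pp <- if (length(pp_idx) >= 2) mean(diff(pp_idx)) / fs else NA_real_
  qs <- (b$S - b$Q)
  qr <- (b$R - b$Q)
  rs <- (b$S - b$R)
  ratio1 <- ifelse(qs == 0, NA_real_, qr / qs)
  ratio2 <- ifelse(qs == 0, NA_real_, rs / qs)
  c(RRmean = rr, PPmean = pp,
    QRtoQSdur = beat_mean(ratio1), RStoQSdur = beat_mean(ratio2))
}

#' Heart-rate-variability features (9)
#'
#' Time-domain HRV statistics of an RR-interval series: IBIM (mean RR),
#' SDRR, IBISD (kept as a distinct named output, numerically equal to
#' SDRR under this registry), NN50, pNN50, SDSD, RMSSD, RRTot and NNTot.
#'
#' @param rr_intervals RR intervals in seconds (>= 1; difference-based
#'   measures need >= 2).
#' @return Named numeric vector of length 9 (difference-based entries NA
#'   when fewer than 2 intervals).
#' @export
compute_hrv <- function(rr_intervals) {
  rr <- rr_intervals[is.finite(rr_intervals)]
  nn <- length(rr)
  if (nn == 0) {
    return(c(IBIM = NA, SDRR = NA, IBISD = NA, NN50 = NA, pNN50 = NA,
             SDSD = NA, RMSSD = NA, RRTot = NA, NNTot = 0))
  }
  drr <- diff(rr)
  has_diff <- length(drr) >= 1
  c(
    IBIM = mean(rr),
    SDRR = if (nn >= 2) stats::sd(rr) else NA_real_,
    IBISD = if (nn >= 2) stats::sd(rr) else NA_real_,
    NN50 = if (has_diff) sum(abs(drr) > 0.050) else NA_real_,
    pNN50 = if (has_diff) 100 * sum(abs(drr) > 0.050) / length(drr) else NA_real_,
    SDSD = if (length(drr) >= 2) stats::sd(drr) else if (has_diff) 0 else NA_real_,
    RMSSD = if (has_diff) sqrt(mean(drr^2)) else NA_real_,
    RRTot = sum(rr),
    NNTot = nn
  )
}

#' Heart rate in beats per minute
#'
#' @param r_peaks R-peak sample indices (>= 2).
#' @param fs Sampling rate (Hz).
#' @return 60 / mean RR (bpm); NA with < 2 peaks.
#' @export
compute_heart_rate <- function(r_peaks, fs) {
  if (length(r_peaks) < 2) return(NA_real_)
  60 / (mean(diff(r_peaks)) / fs)
}

#' Extract the full 54-feature vector from one record
#'
#' Runs R-peak detection, delineation and all feature groups.  Returns NA
#' (flagged missing) entries where a quantity is undefined (absent P
#' waves, too few beats); [impute_features()] fills these at table
#' assembly.
#'
#' @param record An `ecg_record` (already band-pass filtered).
#' @param filters A [wavelet_filters()] object.
#' @return Named numeric vector over the full registry, or NULL if no
#'   beat could be delineated.
#' @export
extract_features <- function(record, filters = wavelet_filters()) {
  rp <- detect_r_peaks(record, filters)
  if (length(rp) < 1) return(NULL)
  fp <- delineate(record, rp)
  if (nrow(fp$beats) == 0) return(NULL)
  fs <- record$fs
  rr <- diff(rp) / fs
  v <- c(
    HR = compute_heart_rate(rp, fs),
    compute_morphological(fp, record$samples, fs),
    compute_fiducial(fp, record$samples, fs),
    compute_statistical(fp, fs),
    compute_hrv(rr)
  )
  v[feature_registry()$name]
}

#' Assemble a feature table from many records
#'
#' One row per record over the 54 registry columns plus `label`.  Records
#' with no delineated beat are dropped (logged).  Missing entries are left
#' NA; impute with [impute_features()].
#'
#' @param records List of `ecg_record`s.
#' @param filters A [wavelet_filters()] object.
#' @return Data frame of features + `label`, attribute `kept` giving the
#'   input indices retained.
#' @export
build_feature_table <- function(records, filters = wavelet_filters()) {
  stopifnot(length(records) >= 1)
  reg <- feature_registry()$name
  rows <- vector("list", length(records))
  labs <- character(length(records))
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    v <- extract_features(records[[i]], filters)
    if (is.null(v)) next
    rows[[i]] <- v
    labs[i] <- records[[i]]$label %||% NA_character_
    keep[i] <- TRUE
  }
  if (!all(keep)) {
    cvd_log("build_feature_table: dropped %d record(s) with no delineated beats",
            sum(!keep))
  }
  if (!any(keep)) stop("no record produced a delineated beat")
  tab <- as.data.frame(do.call(rbind, rows[keep]))
  names(tab) <- reg
  tab$label <- labs[keep]
  attr(tab, "kept") <- which(keep)
  tab
}

#' Impute missing feature values by per-class training medians
#'
#' Medians are computed on training rows only (leakage hygiene); a class
#' with no observed value for a feature falls back to the global training
#' median, then 0.  With a single row no imputation is possible: values
#' stay NA with a warning.
#'
#' @param table Feature table from [build_feature_table()].
#' @param train_idx Row indices treated as training data (default: all).
#' @return The table with NAs filled; attribute `imputed` is the logical
#'   mask of filled cells.
#' @export
impute_features <- function(table, train_idx = seq_len(nrow(table))) {
  reg <- intersect(feature_registry()$name, names(table))
  mask <- is.na(as.matrix(table[reg]))
  if (nrow(table) == 1) {
    if (any(mask)) warning("single-row table: missing entries left NA")
    attr(table, "imputed") <- mask
    return(table)
  }
  tr <- table[train_idx, , drop = FALSE]
  for (f in reg) {
    miss <- which(is.na(table[[f]]))
    if (length(miss) == 0) next
    gmed <- stats::median(tr[[f]], na.rm = TRUE)
    if (!is.finite(gmed)) gmed <- 0
    for (cl in unique(table$label[miss])) {
      cmed <- stats::median(tr[[f]][tr$label == cl], na.rm = TRUE)
      if (!is.finite(cmed)) cmed <- gmed
      rows <- miss[table$label[miss] == cl]
      table[[f]][rows] <- cmed
    }
  }
  attr(table, "imputed") <- mask
  table
}
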