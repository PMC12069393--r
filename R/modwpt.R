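# Maximal-overlap discrete wavelet packet transform (MODWPT), its inverse,
# and the wavelet-domain R-peak detector / moving-window delineator.
#
# The transform is undecimated: every node at every level keeps the full
# signal length N.  Level-j coefficients are produced by circularly
# filtering the parent node with the unit-scale filters divided by sqrt(2)
# and upsampled by 2^(j-1).  Which filter (scaling vs wavelet) feeds node n
# follows the n mod 4 rule, which makes the natural node index n
# frequency-ordered (sequency ordering): node n at level j covers the band
# (n, n+1] / 2^(j+1) * fs.

# Orthonormal symlet-4 scaling filter (8 taps, sum = sqrt(2)).
SYM4_SCALING <- c(
  0.032223100604042702,  -0.012603967262037833, -0.099219543576847216,
  0.297857795605277360,   0.803738751805916100,  0.497618667632015450,
 -0.029635527645998510,  -0.075765714789273330
)

#' MODWPT wavelet filters
#'
#' Builds the rescaled (divide-by-sqrt(2)) scaling/wavelet filter pair used
#' by the maximal-overlap transform.  The wavelet filter is derived from
#' the scaling filter by the quadrature-mirror relation
#' `b[l] = (-1)^l a[L-1-l]`.
#'
#' @param name Wavelet identifier; `"sym4"` (default) is built in.
#' @param scaling Optional explicit unit-scale orthonormal scaling filter
#'   (overrides `name`).
#' @return Object of class `wavelet_filters` with rescaled `scaling` and
#'   `wavelet` coefficient vectors of length `L`.
#' @export
wavelet_filters <- function(name = "sym4", scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- switch(name, sym4 = SYM4_SCALING,
                      stop("unknown wavelet: ", name, " (supply `scaling`)"))
  }
  L <- length(scaling)
  wavelet <- (-1)^(0:(L - 1)) * rev(scaling)
  a <- scaling / sqrt(2)
  b <- wavelet / sqrt(2)
  stopifnot(abs(sum(a^2) + sum(b^2) - 1) < 1e-12)
  structure(list(name = name, scaling = a, wavelet = b, L = L),
            class = "wavelet_filters")
}

# Circular filter with upsampled taps: y[t] = sum_l f[l] * x[(t - s*l) mod N]
circ_filter <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f) - 1L) {
    idx <- ((t0 - s * l) %% n) + 1L
    y <- y + f[l + 1L] * x[idx]
  }
  y
}

# Adjoint (circular correlation): y[t] = sum_l f[l] * x[(t + s*l) mod N]
circ_filter_adj <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f) - 1L) {
    idx <- ((t0 + s * l) %% n) + 1L
    y <- y + f[l + 1L] * x[idx]
  }
  y
}

# Filter assignment rule: scaling filter if n mod 4 is 0 or 3, wavelet
# filter if 1 or 2 (gives sequency ordering).
node_filter <- function(filters, n) {
  if ((n %% 4) %in% c(0, 3)) filters$scaling else filters$wavelet
}

#' MODWPT decomposition
#'
#' Decomposes a signal into `2^levels` undecimated wavelet-packet nodes by
#' recursive circular filtering; node indexing is sequency-ordered, so node
#' n at level j covers frequencies in `(n, n+1] / 2^(j+1) * fs`.
#'
#' @param signal Numeric vector, length N >= filter length.
#' @param filters A [wavelet_filters()] object.
#' @param levels Decomposition depth (>= 1; level 4 gives 16 nodes).
#' @param fs Sampling rate carried for band bookkeeping (default 1).
#' @return Object of class `packet_coefficients`: `nodes` is an N x 2^levels
#'   matrix (one column per node).
#' @export
modwpt_decompose <- function(signal, filters = wavelet_filters(),
                             levels = 4, fs = 1) {
  stopifnot(inherits(filters, "wavelet_filters"), levels >= 1)
  n <- length(signal)
  if (n < filters$L) {
    stop(sprintf("signal length %d < filter length %d (minimum length %d)",
                 n, filters$L, filters$L))
  }
  prev <- matrix(signal, ncol = 1)
  for (j in seq_len(levels)) {
    s <- 2^(j - 1)
    cur <- matrix(0, nrow = n, ncol = 2^j)
    for (nd in 0:(2^j - 1)) {
      f <- node_filter(filters, nd)
      cur[, nd + 1L] <- circ_filter(prev[, nd %/% 2 + 1L], f, s)
    }
    prev <- cur
  }
  structure(list(level = levels, nodes = prev, fs = fs, n = n,
                 filters = filters),
            class = "packet_coefficients")
}

#' Inverse MODWPT from a subset of nodes
#'
#' Inverts the decomposition recursion with all non-selected nodes zeroed;
#' selecting all nodes reconstructs the original signal (the per-level
#' analysis operator is an isometry, so its adjoint is the inverse).
#'
#' @param coeffs A `packet_coefficients` object.
#' @param node_subset Zero-based node indices to keep (default: all).
#' @return Numeric vector of length N.
#' @export
imodwpt_reconstruct <- function(coeffs, node_subset = NULL) {
  stopifnot(inherits(coeffs, "packet_coefficients"))
  nn <- 2^coeffs$level
  if (is.null(node_subset)) node_subset <- 0:(nn - 1)
  if (length(node_subset) == 0) stop("node_subset must be non-empty")
  if (any(node_subset < 0 | node_subset >= nn)) {
    stop("node_subset indices must lie in [0, ", nn - 1, "]")
  }
  filters <- coeffs$filters
  cur <- coeffs$nodes
  drop_cols <- setdiff(0:(nn - 1), node_subset)
  if (length(drop_cols)) cur[, drop_cols + 1L] <- 0
  for (j in coeffs$level:1) {
    s <- 2^(j - 1)
    parent <- matrix(0, nrow = coeffs$n, ncol = 2^(j - 1))
    for (m in 0:(2^(j - 1) - 1)) {
      c0 <- 2 * m; c1 <- 2 * m + 1
      parent[, m + 1L] <-
        circ_filter_adj(cur[, c0 + 1L], node_filter(filters, c0), s) +
        circ_filter_adj(cur[, c1 + 1L], node_filter(filters, c1), s)
    }
    cur <- parent
  }
  cur[, 1]
}

#' Detect R peaks via wavelet-band reconstruction
#'
#' Decomposes to level 4, reconstructs from the first four
#' sequency-ordered nodes (0 to fs/8 Hz, the band holding QRS energy), and
#' picks local maxima above an adaptive threshold with a refractory
#' period.  Peak positions are refined to the local maximum of the raw
#' record within a small window.
#'
#' @param record An `ecg_record` (>= 1 s of samples).
#' @param filters A [wavelet_filters()] object.
#' @param levels Decomposition depth (default 4).
#' @param node_subset Nodes used for reconstruction (default 0:3).
#' @param threshold_frac Detection threshold as a fraction of the
#'   reconstruction's global maximum (default 0.5).
#' @param refractory_s Minimum peak spacing in seconds (default 0.2).
#' @param refine_s Half-width (s) of the raw-signal refinement window.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (empty for flat signals).
#' @export
detect_r_peaks <- function(record, filters = wavelet_filters(), levels = 4,
                           node_subset = 0:3, threshold_frac = 0.5,
                           refractory_s = 0.2, refine_s = 0.024) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  if (length(x) < record$fs) stop("record shorter than 1 s")
  if (max(x) == min(x)) return(integer(0))
  dec <- modwpt_decompose(x, filters, levels, fs = record$fs)
  rec <- imodwpt_reconstruct(dec, node_subset)
  thr <- threshold_frac * max(rec)
  n <- length(rec)
  is_peak <- c(FALSE, rec[2:(n - 1)] > rec[1:(n - 2)] &
                       rec[2:(n - 1)] >= rec[3:n], FALSE) & rec > thr
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))
  # refractory: sweep left to right, keep the larger of conflicting peaks
  refr <- round(refractory_s * record$fs)
  keep <- cand[1]
  for (p in cand[-1]) {
    last <- keep[length(keep)]
    if (p - last >= refr) {
      keep <- c(keep, p)
    } else if (rec[p] > rec[last]) {
      keep[length(keep)] <- p
    }
  }
  # refine on the raw record
  w <- round(refine_s * record$fs)
  refined <- vapply(keep, function(p) {
    lo <- max(1, p - w); hi <- min(n, p + w)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  sort(unique(as.integer(refined)))
}

#' Moving-window delineation of P-QRS-T fiducial points
#'
#' For each R peak: Q is the minimum in the 60 ms window before R, S the
#' minimum in the 60 ms window after; the P peak is the maximum in the
#' (R-240 ms, R-60 ms) window (clipped to end after the previous beat's T
#' zone), accepted only above a noise floor relative to the R amplitude;
#' the T peak is the largest-magnitude excursion in (S+80 ms, S+400 ms)
#' (clipped before the next beat's QRS).  Onsets and offsets are the
#' nearest points where the signal recrosses 10% of the peak-to-baseline
#' amplitude.  Beats whose windows would be truncated at the record edges
#' are dropped.
#'
#' @param record An `ecg_record`.
#' @param r_peaks Integer vector of R-peak sample indices (>= 1 peak).
#' @param p_window_s,q_window_s,t_window_s Search windows (seconds):
#'   defaults 0.24 / 0.06 / 0.40.
#' @param onset_frac Amplitude fraction defining onsets/offsets (0.10).
#' @param p_min_frac Minimum P amplitude relative to the R amplitude for a
#'   P wave to be accepted (default 0.08).
#' @return Object of class `fiducial_points`: data frame `beats` with one
#'   row per retained beat (columns Pon, Ppeak, Poff, Q, R, S, Ton, Tpeak,
#'   Toff; P entries may be NA) and field `fs`.
#' @export
delineate <- function(record, r_peaks,
                      p_window_s = 0.24, q_window_s = 0.06, t_window_s = 0.40,
                      onset_frac = 0.10, p_min_frac = 0.08) {
  stopifnot(inherits(record, "ecg_record"), length(r_peaks) >= 1)
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  # onset/offset crossings are read from a lightly smoothed copy (20 ms
  # zero-phase moving average): the 10%-amplitude rule is noise-sensitive
  # where the wave tails flatten, and smoothing shifts a Gaussian flank by
  # well under one sample
  k <- max(1L, 2L * (round(0.010 * fs)) + 1L)
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  sm <- function(sec) round(sec * fs)
  left_need <- sm(p_window_s + 0.08)
  right_need <- sm(t_window_s + 0.06 + 0.12)
  rows <- list()
  dropped <- 0L
  for (k in seq_along(r_peaks)) {
    r <- r_peaks[k]
    if (r - left_need < 1 || r + right_need > n) {
      dropped <- dropped + 1L
      next
    }
    # isoelectric baselines from quiet segments (a median over the whole
    # beat span would be biased by P/QRS/T wave mass); the T wave gets its
    # own local estimate from the ST segment and the post-T tail, since
    # residual wander varies within a beat
    base <- stats::median(x[(r - sm(0.30)):(r - sm(0.25))])
    # Q and S: minima in the +-60 ms windows
    qwin <- (r - sm(q_window_s)):(r - 1)
    swin <- (r + 1):(r + sm(q_window_s))
    qi <- qwin[which.min(x[qwin])]
    si <- swin[which.min(x[swin])]
    ramp <- x[r] - base

    # helper: walk outward from peak until |x-b0| falls under frac*|amp|
    crossing <- function(peak, dir, amp, max_steps, b0 = base) {
      thr <- onset_frac * abs(amp)
      i <- peak
      steps <- 0
      while (steps < max_steps) {
        j <- i + dir
        if (j < 1 || j > n) break
        if (abs(xs[j] - b0) < thr) return(j)
        i <- j
        steps <- steps + 1
      }
      i
    }

    # P wave: window (R-240ms, R-60ms), clipped after previous T zone
    plo <- r - sm(p_window_s)
    if (k > 1) plo <- max(plo, r_peaks[k - 1] + sm(0.40))
    phi <- r - sm(q_window_s)
    pon <- ppk <- poff <- NA_integer_
    if (plo < phi - 2) {
      pwin <- plo:phi
      ppk_cand <- pwin[which.max(x[pwin])]
      pamp <- x[ppk_cand] - base
      if (pamp > p_min_frac * ramp) {
        ppk <- ppk_cand
        pon <- crossing(ppk, -1L, pamp, sm(0.12))
        poff <- crossing(ppk, +1L, pamp, sm(0.12))
      }
    }

    # T wave: extremum in (S+80ms, S+400ms), clipped before next QRS
    tlo <- si + sm(0.08)
    thi <- si + sm(t_window_s)
    if (k < length(r_peaks)) thi <- min(thi, r_peaks[k + 1] - sm(0.10))
    ton <- tpk <- toff <- NA_integer_
    if (thi > tlo + 2) {
      st_seg <- xs[(si + sm(0.06)):(si + sm(0.11))]
      post_hi <- min(n, r + sm(0.46))
      post <- xs[min(n, r + sm(0.40)):post_hi]
      base_t <- stats::median(c(st_seg, post))
      twin <- tlo:thi
      tpk <- twin[which.max(abs(x[twin] - base_t))]
      tamp <- x[tpk] - base_t
      ton <- crossing(tpk, -1L, tamp, sm(0.22), b0 = base_t)
      toff <- crossing(tpk, +1L, tamp, sm(0.22), b0 = base_t)
    }
    if (is.na(tpk)) { dropped <- dropped + 1L; next }

    rows[[length(rows) + 1L]] <- data.frame(
      beat = k, Pon = pon, Ppeak = ppk, Poff = poff,
      Q = qi, R = r, S = si, Ton = ton, Tpeak = tpk, Toff = toff
    )
  }
  if (dropped > 0) {
    cvd_log("delineate: dropped %d beat(s) with truncated windows", dropped)
  }
  beats <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beat = integer(0), Pon = integer(0), Ppeak = integer(0),
               Poff = integer(0), Q = integer(0), R = integer(0),
               S = integer(0), Ton = integer(0), Tpeak = integer(0),
               Toff = integer(0))
  structure(list(beats = beats, fs = fs), class = "fiducial_points")
}
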