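# The frozen 54-feature registry.  Column order of every feature table is
# registry order; serialization and selection tie-breaks refer back to it.

registry_distance_pairs <- function() {
  # 15 unordered pairs over the six core landmarks, plus four onset/offset
  # spans.  19 distances total, all measured in the (time s, z-amplitude)
  # plane.
  core <- c("Pon", "Ppeak", "Q", "R", "S", "Tpeak")
  pairs <- t(utils::combn(core, 2))
  extra <- rbind(
    c("Pon", "Poff"), c("Poff", "Q"), c("S", "Toff"), c("Ton", "Toff")
  )
  rbind(pairs, extra)
}

#' The 54-feature registry
#'
#' Returns the ordered registry of the 54 ECG features computed per
#' recording: 1 heart-rate feature, 11 morphological, 29 fiducial
#' (6 intervals + 4 slopes + 19 landmark distances), 4 statistical and
#' 9 heart-rate-variability features.  Feature tables, serialized strings
#' and importance tables all use this order.
#'
#' @return A data frame with columns `name`, `group` (one of
#'   `"rate"`, `"morphological"`, `"fiducial"`, `"statistical"`, `"hrv"`)
#'   and `unit`.
#' @export
feature_registry <- function() {
  pairs <- registry_distance_pairs()
  dist_names <- paste0("d", pairs[, 1], pairs[, 2])
  reg <- rbind(
    data.frame(name = "HR", group = "rate", unit = "bpm"),
    data.frame(
      name = c("Pdur", "QRSdur", "Tdur", "CycleDur", "QRSarea", "QRSperim",
               "AnglePQR", "AngleQRS", "AngleRST", "AnglePonPQ", "AngleSTToff"),
      group = "morphological",
      unit = c(rep("s", 4), "s*z", "s+z", rep("deg", 5))
    ),
    data.frame(
      name = c("PQint", "PTint", "QRint", "QTint", "RSint", "STint",
               "PQslope", "QRslope", "RSslope", "STslope",
               dist_names),
      group = "fiducial",
      unit = c(rep("s", 6), rep("z/s", 4), rep("s+z", length(dist_names)))
    ),
    data.frame(
      name = c("RRmean", "PPmean", "QRtoQSdur", "RStoQSdur"),
      group = "statistical",
      unit = c("s", "s", "ratio", "ratio")
    ),
    data.frame(
      name = c("IBIM", "SDRR", "IBISD", "NN50", "pNN50", "SDSD", "RMSSD",
               "RRTot", "NNTot"),
      group = "hrv",
      unit = c("s", "s", "s", "count", "%", "s", "s", "s", "count")
    )
  )
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 54L, !anyDuplicated(reg$name))
  reg
}

#' Feature names that depend on a detected P wave
#'
#' These entries are flagged missing for beats without an accepted P wave
#' (e.g. atrial-fibrillation-like rhythms) and later imputed by
#' [impute_features()].
#' @return Character vector of registry names.
#' @export
p_dependent_features <- function() {
  reg <- feature_registry()$name
  p_like <- grepl("Pon|Poff|Ppeak", reg) |
    reg %in% c("Pdur", "AnglePQR", "AnglePonPQ", "PQint", "PTint",
               "PQslope", "PPmean")
  reg[p_like]
}
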