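# End-to-end orchestration: filter -> delineate -> features -> select ->
# serialize/tokenize -> train -> evaluate, reproducible from (config, seed).

#' Stratified train/validation/test split
#'
#' Per-class proportional allocation with largest-remainder rounding;
#' the three index sets are disjoint and exhaustive.
#'
#' @param labels Vector of class labels (or ids), one per row.
#' @param fractions Length-3 fractions (train, val, test) summing to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.7, 0.1, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  set.seed(derive_seed(seed, "split"))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cl)
    if (length(idx) < 10) {
      stop("class ", cl, " has fewer than 10 rows (", length(idx), ")")
    }
    idx <- sample(idx)
    quota <- fractions * length(idx)
    base <- floor(quota)
    rem <- length(idx) - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    if (base[2] > 0) out$val <- c(out$val, idx[(cuts[1] + 1):cuts[2]])
    if (base[3] > 0) out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
  }
  out
}

#' Pipeline configuration
#'
#' @param data Data source: `"synthetic"` (default), a directory/CSV path
#'   of signals, or a pre-extracted feature-table CSV
#'   (`source = "feature-csv"`).
#' @param source One of `"synthetic"`, `"signal-csv"`, `"feature-csv"`.
#' @param n_per_class Synthetic records per class (default 300).
#' @param duration_s Synthetic record length (default 3 s).
#' @param fs Sampling rate (default 250).
#' @param nb_trees Random-forest trees per class for importance
#'   (default 200).
#' @param threshold Importance selection threshold (default 0.02).
#' @param precision Serialization decimals (default 3).
#' @param mconf,tconf Model and training configurations.
#' @param split Train/val/test fractions (default 0.7/0.1/0.2).
#' @param seed Global seed fanned out to per-stage seeds.
#' @param out_dir Output directory for artifacts (NULL: no files).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, source = "synthetic",
                            n_per_class = 300, duration_s = 3, fs = 250,
                            nb_trees = 200, threshold = 0.02, precision = 3,
                            mconf = model_config(), tconf = train_config(),
                            split = c(0.7, 0.1, 0.2), seed = 1,
                            out_dir = NULL) {
  stopifnot(abs(sum(split) - 1) < 1e-9, threshold >= 0)
  mconf$seed <- derive_seed(seed, "train")
  tconf$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Executes filter -> delineate -> features -> select -> serialize/tokenize
#' -> train -> evaluate.  Feature selection and imputation medians are
#' fitted on training rows only; the transformer and the random forests
#' share one stratified split.  Fully reproducible from (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return List: `report` (test-set `evaluation_report`), `selected`,
#'   `importances`, `history`, `model`, `split_idx`, `table`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  counts <- list()

  if (config$source == "feature-csv") {
    table <- utils::read.csv(config$data, check.names = FALSE)
    stopifnot("label" %in% names(table))
  } else {
    records <- if (config$source == "synthetic") {
      generate_ecg_batch(config$n_per_class, duration_s = config$duration_s,
                         fs = config$fs, seed = derive_seed(seed, "generate"))
    } else {
      read_ecg_csv(config$data, fs = config$fs)
    }
    counts$records <- length(records)
    cvd_log("stage filter: %d records in", length(records))
    records <- lapply(records, butterworth_bandpass)
    cvd_log("stage features: extracting %d-column table", 54L)
    table <- build_feature_table(records)
  }
  counts$table_rows <- nrow(table)

  split_idx <- stratified_split(table$label, config$split, seed = seed)
  counts$split <- vapply(split_idx, length, integer(1))
  cvd_log("stage split: train %d / val %d / test %d",
          counts$split[1], counts$split[2], counts$split[3])

  table <- impute_features(table, train_idx = split_idx$train)

  cvd_log("stage selection: %d trees per class, threshold %g",
          config$nb_trees, config$threshold)
  train_tab <- table[split_idx$train, , drop = FALSE]
  importances <- oob_importance(train_tab, nb_trees = config$nb_trees,
                                seed = seed)
  selected <- select_features(importances, config$threshold)
  counts$selected <- length(selected)
  cvd_log("stage selection: %d features selected", length(selected))

  texts <- vapply(seq_len(nrow(table)), function(i) {
    serialize_features(unlist(table[i, feature_registry()$name]),
                       selected, config$precision)
  }, character(1))
  vocab <- load_vocab()
  tk <- tokenize_corpus(texts, table$label, vocab = vocab,
                        max_len = config$mconf$max_len)

  cvd_log("stage train: %d samples, %d epochs",
          length(split_idx$train), config$tconf$epochs)
  fit <- train_token_mixer(tk$samples, config$mconf, config$tconf,
                           vocab_size = vocab$size, split_idx = split_idx)

  te <- split_idx$test
  cb <- classify_batch(tk$samples[te], fit$model)
  y_true <- vapply(tk$samples[te], function(s) s$label_id, integer(1))
  report <- evaluation_report(y_true, cb$pred, scores = cb$probs,
                              labels = tk$encoder$classes)

  manifest <- list(
    seed = seed, source = config$source, counts = counts,
    threshold = config$threshold, nb_trees = config$nb_trees,
    selected = selected,
    config_hash = sum(utils::head(utf8ToInt(paste(
      deparse(config[c("n_per_class", "duration_s", "fs", "nb_trees",
                       "threshold", "precision", "split")]),
      collapse = "")), 10000))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(table, file.path(od, "feature_table.csv"),
                     row.names = FALSE)
    write_importance_csv(importances, file.path(od, "importances.csv"))
    jsonlite::write_json(selected, file.path(od, "selected_features.json"))
    utils::write.csv(fit$history, file.path(od, "history.csv"),
                     row.names = FALSE)
    write_report(report, file.path(od, "report.json"),
                 roc_csv = file.path(od, "roc_points.csv"))
    write_label_encoder(tk$encoder, file.path(od, "label_map.json"))
    saveRDS(list(model = fit$model, config = config),
            file.path(od, "checkpoint.rds"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE)
  }

  list(report = report, selected = selected, importances = importances,
       history = fit$history, model = fit$model, split_idx = split_idx,
       table = table, manifest = manifest, tokenized = tk)
}
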