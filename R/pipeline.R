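#' Validate a pipeline configuration
#'
#' The configuration is a nested list (or a path to a JSON file) with
#' sections `simulate`, `preprocess`, `synthesis`, `features` and
#' `classify`; every field has a default, and invalid combinations
#' (e.g. reversed band edges) are rejected up front.
#'
#' @param config nested list or JSON file path.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (inherits(config, "pipeline_config")) return(config)
  stopifnot(is.list(config))
  dflt <- list(
    seed = 1L,
    simulate = list(classes = c("HC", "IMI", "AMI", "LMI"),
                    duration = 120, mean_rr = 0.8, rr_jitter = 0.05,
                    noise_sd = 0.02, wander_amplitude = 0.1,
                    wander_freq = 0.3, sampling_rate = 500),
    preprocess = list(target_rate = 500, low_hz = 0.5, high_hz = 150,
                      filter_order = 4L),
    synthesis = list(mode = "lstm", L = 150L, hidden = 30L, layers = 2L,
                     epochs = 300L, batch_size = 128L, learning_rate = 1e-3,
                     max_train_windows = 20000L),
    features = list(n = 15L, p = 3L, leads = c("vx", "vy", "vz"),
                    reference_lead = NULL, target_len = 400L),
    classify = list(folds = 5L, smote_k = 5L, hidden = c(300L, 275L),
                    epochs = 200L, batch_size = 64L, learning_rate = 1e-3,
                    validation_frac = 0.1, patience = 20L))
  merged <- utils::modifyList(dflt, config)
  known <- names(dflt)
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  pp <- merged$preprocess
  if (!(pp$low_hz > 0 && pp$low_hz < pp$high_hz))
    stop("preprocess: need 0 < low_hz < high_hz (got ", pp$low_hz, ", ",
         pp$high_hz, ")")
  if (pp$high_hz >= pp$target_rate / 2)
    stop("preprocess: high_hz must be below the Nyquist rate")
  if (!merged$synthesis$mode %in% c("lstm", "mlp", "measured"))
    stop("synthesis mode must be one of lstm, mlp, measured")
  if (!all(merged$simulate$classes %in% mi_classes()))
    stop("unknown class(es) in simulate$classes")
  if (!all(merged$features$leads %in% c("vx", "vy", "vz")))
    stop("features$leads must be a subset of vx, vy, vz")
  if (merged$classify$folds < 2L) stop("classify$folds must be >= 2")
  class(merged) <- "pipeline_config"
  merged
}

#' Stratified k-fold cross-validation of the beat classifier
#'
#' Beats are assigned to folds stratified by class.  SMOTE balancing and
#' feature standardization are fitted inside each training fold only;
#' test folds are never touched by either.  Rows are first brought into
#' a canonical content order (class, then feature values), so the result
#' is invariant to permutations of the input rows.
#'
#' @param X numeric feature matrix.
#' @param y class labels.
#' @param folds number of folds (>= 2).
#' @param seed integer master seed.
#' @param config a [clf_config()] (fold seeds are derived from `seed`).
#' @param smote_k SMOTE neighbor count.
#' @param labels full label set (default [mi_classes()]).
#' @return list of class `cv_result`: `pooled` (a [metrics_report()] over
#'   the summed test-fold confusion matrix), `per_fold` (list of
#'   confusion matrices), `fold_of` (fold id per input row), and
#'   `predictions` (character vector aligned with the input rows).
#' @export
crossvalidate <- function(X, y, folds = 5L, seed = 1L,
                          config = clf_config(), smote_k = 5L,
                          labels = mi_classes()) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), folds >= 2L)
  cnt <- table(y)
  if (any(cnt < folds))
    stop("class(es) too small to stratify into ", folds, " folds: ",
         paste(names(cnt)[cnt < folds], collapse = ", "))

  # canonical content order -> permutation-invariant folds and training
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)),
                                          function(j) X[, j])))
  Xo <- X[ord, , drop = FALSE]
  yo <- y[ord]
  fold_of <- integer(length(yo))
  for (cl in unique(yo)) {
    idx <- which(yo == cl)
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }

  preds <- character(length(yo))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    bal <- smote_oversample(Xo[tr, , drop = FALSE], yo[tr], k = smote_k,
                            seed = seed + f)
    cfg <- config
    cfg$seed <- as.integer(seed + 1000L * f)
    model <- train_classifier(bal$X, bal$y, cfg, labels = labels)
    pr <- predict(model, Xo[!tr, , drop = FALSE])
    preds[!tr] <- pr$class
    per_fold[[f]] <- confusion_matrix(yo[!tr], pr$class, labels)
  }
  pooled_cm <- Reduce(`+`, lapply(per_fold, unclass))
  class(pooled_cm) <- c("confusion_matrix", class(pooled_cm))

  inv <- integer(length(ord)); inv[ord] <- seq_along(ord)
  structure(list(pooled = metrics_report(pooled_cm), per_fold = per_fold,
                 fold_of = fold_of[inv], predictions = preds[inv]),
            class = "cv_result")
}

# 32-bit FNV-1a over serialized bytes; cheap content hash for manifests.
# The xor only touches the low byte; the multiply is done in 16-bit
# halves so every intermediate stays exactly representable in a double.
fnv1a_hash <- function(obj) {
  bytes <- serialize(obj, NULL, version = 3L)
  h <- 2166136261
  prime <- 16777619
  for (b in as.integer(bytes)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full MI-classification pipeline on synthetic data
#'
#' Stages, per class in `config$simulate$classes`: generate a seeded
#' synthetic record (class-conditional morphology), preprocess (resample
#' + band-pass), train the patient-specific synthesizer on leads
#' i/vx/vy/vz and derive the Frank leads from lead I (skipped in
#' `"measured"` mode), detect R peaks on the reference lead, segment and
#' normalize beats, and extract per-beat spline features.  The pooled
#' feature table is then evaluated by stratified cross-validation with
#' per-fold SMOTE.
#'
#' @param config a [pipeline_config()] (list or JSON path accepted).
#' @param out_dir artifact directory (created if needed); `NULL` skips
#'   writing.
#' @return list with `features` (data.frame: beat_id, class, feature
#'   columns), `cv` (a `cv_result`), `fidelity` (per-class synthesis
#'   fidelity, `NULL` in measured mode), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  config <- pipeline_config(config)
  sim <- config$simulate
  syn <- config$synthesis
  feat <- config$features

  feature_leads <- if (syn$mode == "measured") feat$leads
                   else paste0(feat$leads, "_hat")
  reference_lead <- if (!is.null(feat$reference_lead)) feat$reference_lead
                    else feature_leads[1L]
  knots <- build_knots(n = feat$n, p = feat$p)

  rows <- list(); labels_out <- character(0); fidelity <- list()
  for (ci in seq_along(sim$classes)) {
    cl <- sim$classes[ci]
    rec <- generate_record(sim_config(
      duration = sim$duration, sampling_rate = sim$sampling_rate,
      mean_rr = sim$mean_rr, rr_jitter = sim$rr_jitter,
      noise_sd = sim$noise_sd, wander_amplitude = sim$wander_amplitude,
      wander_freq = sim$wander_freq, class_label = cl,
      seed = config$seed + 7L * ci))
    pp <- preprocess_record(rec, target_rate = config$preprocess$target_rate,
                            low = config$preprocess$low_hz,
                            high = config$preprocess$high_hz,
                            order = config$preprocess$filter_order)
    if (syn$mode == "measured") {
      work <- pp
    } else {
      scfg <- synth_config(L = syn$L, hidden = syn$hidden,
                           layers = syn$layers, epochs = syn$epochs,
                           batch_size = syn$batch_size,
                           learning_rate = syn$learning_rate,
                           max_train_windows = syn$max_train_windows,
                           seed = config$seed + 100L * ci)
      model <- if (syn$mode == "lstm") train_synthesizer(pp, scfg)
               else baseline_mlp_synthesizer(pp, scfg)
      derived <- derive_vcg(model, get_lead(pp, "i"))
      fidelity[[cl]] <- fidelity_report(pp, derived)
      derived$edge_exclude <- pp$edge_exclude
      work <- derived
    }
    rp <- detect_r_peaks(get_lead(work, reference_lead), work$sampling_rate)
    beats <- normalize_beats(work, rp, leads = feature_leads,
                             target_len = feat$target_len)
    for (b in beats) {
      rows[[length(rows) + 1L]] <- beat_features(b, knots,
                                                 leads = feature_leads)
      labels_out <- c(labels_out, cl)
    }
  }
  if (!length(rows)) stop("pipeline produced no beats")
  X <- do.call(rbind, rows)
  features <- data.frame(beat_id = seq_len(nrow(X)), class = labels_out,
                         X, check.names = FALSE)

  cv <- crossvalidate(X, labels_out, folds = config$classify$folds,
                      seed = config$seed,
                      config = clf_config(
                        hidden = config$classify$hidden,
                        epochs = config$classify$epochs,
                        batch_size = config$classify$batch_size,
                        learning_rate = config$classify$learning_rate,
                        validation_frac = config$classify$validation_frac,
                        patience = config$classify$patience),
                      smote_k = config$classify$smote_k)

  manifest <- list(
    package = "vcgmi",
    version = as.character(utils::packageVersion("vcgmi")),
    seed = config$seed,
    config = unclass(config),
    config_hash = fnv1a_hash(unclass(config)),
    feature_width = ncol(X),
    n_beats = nrow(X),
    classes = as.list(table(labels_out)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_confusion_delim(cv$pooled$confusion,
                          file.path(out_dir, "confusion.tsv"))
    pc <- cv$pooled$per_class
    utils::write.table(pc, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(features = features, cv = cv,
       fidelity = if (length(fidelity)) fidelity else NULL,
       manifest = manifest)
}

#' Serialize a trained model to a JSON container
#'
#' All weights are written as full-precision JSON arrays together with a
#' small header (model class, shapes, config).  Round trip via
#' [load_model()].
#'
#' @param model a `vcg_synthesizer`, `mlp_synthesizer` or `mi_mlp`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  body <- unclass(model)
  if (!is.null(body$config)) body$config <- unclass(body$config)
  payload <- list(container = "vcgmi-model", format_version = 1L,
                  model_class = class(model)[1L],
                  model = encode_tree(body))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Numeric arrays are stored with explicit dimensions so the reader never
# has to guess shapes from nesting (JSON auto-simplification is lossy
# about list-of-equal-length-vector vs matrix).
encode_tree <- function(x) {
  if (is.numeric(x))
    list(`.num` = TRUE, dim = dim(x), data = as.numeric(x))
  else if (is.list(x)) lapply(x, encode_tree)
  else x
}

decode_tree <- function(x) {
  if (is.list(x) && isTRUE(x$`.num`)) {
    v <- as.numeric(x$data)
    if (!is.null(x$dim) && length(x$dim)) dim(v) <- as.integer(x$dim)
    v
  } else if (is.list(x)) lapply(x, decode_tree)
  else x
}

#' Load a model written by [save_model()]
#' @param path file path.
#' @return the restored model object.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$container, "vcgmi-model"))
    stop("not a vcgmi model container: ", path)
  model <- decode_tree(payload$model)
  restore_cfg <- function(x, cls) { class(x) <- cls; x }
  if (!is.null(model$config)) model$config <- restore_cfg(
    model$config, switch(payload$model_class,
                         mi_mlp = "clf_config", "synth_config"))
  class(model) <- payload$model_class
  model
}
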