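#' Full-pipeline configuration
#'
#' One document holding every stage's parameters: the acquisition protocol,
#' generator settings (for simulated input), preprocessing, clustering,
#' training, consequent order and the RNG seed. Defaults follow the target
#' acquisition setup where stated (1 kHz sampling, 60 Hz notch, 7 movements,
#' 5 repetitions x 5 sessions, 60-rule cap) and this package's documented
#' conventions elsewhere.
#'
#' @param protocol a [protocol()].
#' @param amap an [activation_map()] (simulation only).
#' @param noise a [noise_model()] (simulation only).
#' @param preproc a [preproc_config()].
#' @param cluster a [cluster_config()] (default caps at 60 rules).
#' @param train a [train_config()].
#' @param order consequent order for the trained classifier: `"zero"`
#'   (default; the clustering-seeded Sugeno structure, whose bounded
#'   convex-combination output keeps nearest-code decoding stable) or
#'   `"first"`.
#' @param channels optional channel-id subset used as classifier inputs.
#' @param seed master RNG seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = semgfis::protocol(),
                            amap = activation_map(),
                            noise = noise_model(),
                            preproc = preproc_config(),
                            cluster = cluster_config(max_clusters = 60),
                            train = train_config(),
                            order = c("zero", "first"),
                            channels = NULL, seed = 1L) {
  order <- match.arg(order)
  if (!is.null(channels)) preproc$channels <- channels
  structure(list(protocol = protocol, amap = amap, noise = noise,
                 preproc = preproc, cluster = cluster, train = train,
                 order = order, channels = channels, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a flat document whose top-level sections (`protocol`, `amap`,
#' `noise`, `preproc`, `cluster`, `train`, `order`, `channels`, `seed`)
#' override the corresponding [pipeline_config()] defaults. `amap` may give
#' `crosstalk`/`baseline` scalars rather than a full matrix.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  args <- list()
  if (!is.null(raw$protocol)) args$protocol <- do.call(protocol, raw$protocol)
  if (!is.null(raw$amap)) args$amap <- do.call(activation_map, raw$amap)
  if (!is.null(raw$noise)) args$noise <- do.call(noise_model, raw$noise)
  if (!is.null(raw$preproc)) args$preproc <- do.call(preproc_config, raw$preproc)
  if (!is.null(raw$cluster)) args$cluster <- do.call(cluster_config, raw$cluster)
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  if (!is.null(raw$order)) args$order <- raw$order
  if (!is.null(raw$channels)) args$channels <- as.character(raw$channels)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

#' Train a movement classifier from labeled feature vectors
#'
#' Seeds the rule base by subtractive clustering of the feature vectors,
#' builds the initial Sugeno system (one rule per cluster), and runs hybrid
#' ANFIS training against the movements' target codes. A final least-squares
#' pass re-fits the consequents to the trained premises.
#'
#' @param features feature data.frame from [featurize()] (`label` column plus
#'   per-channel RMS columns).
#' @param cluster a [cluster_config()].
#' @param train a [train_config()].
#' @param order consequent order.
#' @return list with `fis` (trained [sugeno_fis()]), `report` (the
#'   [hybrid_fit()] train report) and `clusters` (the `cluster_result`).
#' @export
train_classifier <- function(features, cluster = cluster_config(max_clusters = 60),
                             train = train_config(),
                             order = c("zero", "first")) {
  order <- match.arg(order)
  fm <- feature_matrix(features)
  y <- encode_movement(fm$labels)
  cr <- subclust(fm$X, cluster)
  fis0 <- build_initial_fis(cr, order, input_names = colnames(fm$X))
  report <- hybrid_fit(fis0, fm$X, y, train)
  fis <- suppressWarnings(lse_consequents(report$fis, fm$X, y))
  list(fis = fis, report = report, clusters = cr)
}

#' Classify feature vectors with a trained system
#'
#' @param fis a trained [sugeno_fis()].
#' @param features feature data.frame from [featurize()].
#' @return data.frame with columns `true` (cued label, if present), `gamma`
#'   (raw network output) and `predicted` (decoded label).
#' @export
classify_features <- function(fis, features) {
  fm <- feature_matrix(features)
  gamma <- fis_eval(fis, fm$X)
  data.frame(true = fm$labels, gamma = gamma,
             predicted = decode_movement(gamma), stringsAsFactors = FALSE)
}

#' Run the complete pipeline on synthetic data
#'
#' Simulate a subject (5 sessions), featurize every session, train on session
#' 1, classify the held-out sessions, and score them: the session-by-movement
#' accuracy table with its average row, the overall accuracy, and the pooled
#' confusion matrix. When `out_dir` is given, all artifacts are written there
#' (features and session results as CSV, the model as JSON, the accuracy
#' table and confusion matrix as CSV).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return list with `model`, `train_report`, `clusters`, `accuracy`
#'   (from [aggregate_accuracy()]), `confusion`, `session_results`
#'   (per held-out session data.frames) and `features` (per session).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sessions <- generate_subject(config$protocol, config$amap, config$noise,
                               seed = config$seed)
  feats <- lapply(sessions, function(s)
    featurize(s$recording, s$cues, config$preproc))
  fit <- train_classifier(feats[[1]], config$cluster, config$train,
                          config$order)
  held_out <- seq_along(feats)[-1]
  session_results <- lapply(held_out, function(i)
    classify_features(fit$fis, feats[[i]]))
  names(session_results) <- paste0("Session ", held_out + 0L)
  rates <- t(vapply(session_results,
                    function(r) score_session(r$true, r$predicted),
                    numeric(7)))
  accuracy <- aggregate_accuracy(rates)
  all_true <- unlist(lapply(session_results, `[[`, "true"))
  all_pred <- unlist(lapply(session_results, `[[`, "predicted"))
  confusion <- confusion_matrix(all_true, all_pred)
  result <- list(model = fit$fis, train_report = fit$report,
                 clusters = fit$clusters, accuracy = accuracy,
                 confusion = confusion, session_results = session_results,
                 features = feats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(feats))
      utils::write.csv(feats[[i]],
                       file.path(out_dir, sprintf("features_session%d.csv", i)),
                       row.names = FALSE)
    fis_to_json(fit$fis, file.path(out_dir, "model.json"))
    utils::write.csv(cbind(session = rownames(accuracy$table),
                           accuracy$table),
                     file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(confusion),
                     file.path(out_dir, "confusion.csv"))
    for (nm in names(session_results))
      utils::write.csv(session_results[[nm]],
                       file.path(out_dir, paste0(gsub(" ", "_", tolower(nm)),
                                                 "_results.csv")),
                       row.names = FALSE)
    utils::write.csv(data.frame(epoch = seq_along(fit$report$errors),
                                rmse = fit$report$errors),
                     file.path(out_dir, "training_error.csv"),
                     row.names = FALSE)
  }
  result
}
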