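# End-to-end orchestration: load or simulate -> featurize -> graph ->
# sampled GCN embeddings -> classifier -> cross-validated report, plus
# a fit/predict pair for scoring new proteins with a trained bundle.

# Run one stage, re-raising any error with a stage tag so failures can
# be located from the command line.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full SIP prediction pipeline
#'
#' Executes load (from disk or a synthetic spec) -> featurize -> graph ->
#' GCN embedding -> classifier -> repeated five-fold cross-validation,
#' and, when `outdir` is given, writes the evaluation report
#' (`report.json`, `metrics.tsv`), per-protein features
#' (`features.tsv`), first-repetition ROC points (`roc.tsv`) and a run
#' manifest (`manifest.json`) recording every setting and seed.
#'
#' @param fasta,pssm_dir,labels Paths of an on-disk dataset (see
#'   [load_dataset()]); ignored when `synthetic` is given.
#' @param synthetic Optional [synthetic_spec()] used instead of disk
#'   input.
#' @param outdir Optional output directory.
#' @param featurizer `"pssm_composition"` (default) or `"ac"`.
#' @param ac_lag Lag bound for the AC featurizer.
#' @param config A [pipeline_config()].
#' @param repetitions Cross-validation repetitions.
#' @param seed Master seed.
#' @param curated,strict Passed to [load_dataset()].
#' @return The [cross_validate()] report, invisibly when writing to
#'   `outdir`.
#' @export
run_pipeline <- function(fasta = NULL, pssm_dir = NULL, labels = NULL,
                         synthetic = NULL, outdir = NULL,
                         featurizer = c("pssm_composition", "ac"),
                         ac_lag = 5L, config = pipeline_config(),
                         repetitions = 1L, seed = 1L,
                         curated = FALSE, strict = TRUE) {
  featurizer <- match.arg(featurizer)
  ds <- run_stage("load", {
    if (!is.null(synthetic)) {
      generate_dataset(synthetic)
    } else {
      if (is.null(fasta) || is.null(pssm_dir) || is.null(labels))
        stop("either a synthetic spec or fasta + pssm_dir + labels ",
             "paths are required")
      load_dataset(fasta, pssm_dir, labels, curated = curated,
                   strict = strict)
    }
  })
  X <- run_stage("featurize",
                 feature_matrix(ds$pssms, scheme = featurizer, lg = ac_lag))
  report <- run_stage("evaluate",
                      cross_validate(X, ds$records$label, config = config,
                                     repetitions = repetitions,
                                     seed = seed))
  if (!is.null(outdir)) {
    run_stage("write", {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      write_report(report, file.path(outdir, "report.json"))
      utils::write.table(format_report(report),
                         file.path(outdir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_features(X, file.path(outdir, "features.tsv"))
      manifest <- list(
        package = "sipgraph",
        version = as.character(utils::packageVersion("sipgraph")),
        r_version = R.version.string,
        seed = seed, repetitions = repetitions,
        featurizer = featurizer, ac_lag = ac_lag,
        config = unclass_deep(config),
        synthetic = if (!is.null(synthetic)) unclass_deep(synthetic),
        inputs = if (is.null(synthetic))
          list(fasta = fasta, pssm_dir = pssm_dir, labels = labels))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
    return(invisible(report))
  }
  report
}

# Recursively strip S3 classes so a config serialises cleanly to JSON.
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Fit the pipeline on a full labelled dataset
#'
#' Trains the graph + sampled GCN + classifier stack on all labelled
#' proteins and packages everything needed to score new proteins later
#' with [predict_pipeline()].
#'
#' @param features n x d feature matrix (e.g. from [feature_matrix()]).
#' @param labels Binary 0/1 vector.
#' @param config A [pipeline_config()].
#' @param seed Seed for training and the classifier.
#' @return Object of class `"sip_model"`.
#' @export
fit_pipeline <- function(features, labels, config = pipeline_config(),
                         seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  graph <- build_knn_graph(features, k = config$graph_k, labels = labels)
  gcn_cfg <- config$gcn
  gcn_cfg$seed <- seed
  model <- train_fastgcn(graph, gcn_cfg)
  E <- extract_embeddings(model, graph)
  classifier <- if (config$classifier == "rf") {
    do.call(rf_fit, c(list(features = E, labels = labels, seed = seed),
                      config$classifier_args))
  } else {
    NULL  # knn/elm refit at prediction time from stored embeddings
  }
  structure(list(config = config, seed = seed, gcn = model,
                 train_features = features, train_labels = labels,
                 train_embeddings = E, classifier = classifier),
            class = "sip_model")
}

#' Score new proteins with a fitted pipeline
#'
#' New proteins are appended to the training nodes, the neighbour graph
#' is rebuilt over the combined feature matrix (transductive embedding),
#' the stored GCN weights produce embeddings for the new nodes, and the
#' stored classifier scores them.
#'
#' @param object A [fit_pipeline()] model.
#' @param new_features m x d matrix of features for proteins to score.
#' @param ... Unused.
#' @return List with `score` and `prediction` for the new proteins.
#' @export
predict.sip_model <- function(object, new_features, ...) {
  new_features <- as.matrix(new_features)
  if (ncol(new_features) != ncol(object$train_features))
    stop("new_features must have ", ncol(object$train_features),
         " columns")
  all_feat <- rbind(object$train_features, new_features)
  graph <- build_knn_graph(all_feat, k = object$config$graph_k)
  E <- extract_embeddings(object$gcn, graph)
  n_train <- nrow(object$train_features)
  E_new <- E[(n_train + 1L):nrow(E), , drop = FALSE]
  E_train <- E[seq_len(n_train), , drop = FALSE]
  cfg <- object$config
  if (cfg$classifier == "rf") {
    predict(object$classifier, E_new)
  } else {
    fit_and_score(cfg, E_train, object$train_labels, E_new,
                  seed = object$seed)
  }
}
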