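#' Configuration for the synthetic end-to-end benchmark
#'
#' Bundles every tunable of the full workflow: the simulated genome and
#' truth-set design, the matching thresholds, the consensus support range,
#' and the classifier settings. All randomness derives from `seed`, so a
#' config determines the benchmark result exactly.
#'
#' The default scale — a 60 Mb toy chromosome with 500 deletions and 900
#' insertions (more insertions than deletions, as in real truth sets) — is
#' chosen so that per-pipeline metrics are stable to a few parts in a
#' hundred while the whole benchmark completes in well under five minutes.
#'
#' @param dataset dataset label.
#' @param seqlengths named vector of simulated sequence lengths.
#' @param n_del,n_ins truth-set deletion and insertion counts.
#' @param spec truth size distribution ([size_spec()]).
#' @param fp_size_spec false-call size distribution (default skews small).
#' @param profiles pipeline noise profiles ([pipeline_profiles()]).
#' @param artifacts include the shared artifact pools (correlated false
#'   calls across pipelines)?
#' @param min_frac,reciprocal,window matching parameters.
#' @param bins size-stratification bin boundaries.
#' @param consensus_ks support thresholds for the consensus curve.
#' @param train_frac,n_trees classifier split fraction and forest size.
#' @param seed master seed.
#' @return An `sv_benchmark_config`.
#' @export
benchmark_config <- function(dataset = "synthetic",
                             seqlengths = c(chr20 = 60e6),
                             n_del = 500, n_ins = 900,
                             spec = size_spec(),
                             fp_size_spec = size_spec(bump_mean = 70,
                                                      bump_sd = 30,
                                                      bump_weight = 0.75),
                             profiles = pipeline_profiles(),
                             artifacts = TRUE,
                             min_frac = 0.5, reciprocal = TRUE, window = 100,
                             bins = default_size_bins(),
                             consensus_ks = 2:7,
                             train_frac = 0.2, n_trees = 500,
                             seed = 1L) {
  stopifnot(min_frac > 0, min_frac <= 1, window >= 0,
            train_frac > 0, train_frac < 1,
            all(consensus_ks >= 1), all(consensus_ks <= length(profiles)))
  structure(list(dataset = dataset, seqlengths = seqlengths,
                 n_del = n_del, n_ins = n_ins, spec = spec,
                 fp_size_spec = fp_size_spec, profiles = profiles,
                 artifacts = artifacts, min_frac = min_frac,
                 reciprocal = reciprocal, window = window, bins = bins,
                 consensus_ks = consensus_ks, train_frac = train_frac,
                 n_trees = n_trees, seed = as.integer(seed)),
            class = "sv_benchmark_config")
}

metrics_row <- function(met, ...) {
  data.frame(..., tp = met$tp, fp = met$fp, fn = met$fn,
             precision = met$precision, recall = met$recall, f1 = met$f1,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic benchmark
#'
#' One call reproduces the whole workflow on simulated data: generate a
#' truth set, corrupt it into seven pipeline-like call sets, evaluate each
#' pipeline (overall and per size bin), build the consensus call set and its
#' F1-vs-support curve, and train and evaluate the random-forest integrator
#' — per SV category throughout. The run is a pure function of the config.
#'
#' @param config an [benchmark_config()].
#' @param outdir optional directory; when given, the report is written as
#'   TSV/JSON plus a YAML provenance record via [write_benchmark_report()].
#' @return An `sv_benchmark_report` list: `pipeline_metrics`,
#'   `stratified`, `consensus` (curve rows), `support_histogram`,
#'   `ml` (per-category metrics and feature contributions), `summary`
#'   (one row per pipeline/consensus/ML entry), and `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), outdir = NULL) {
  stopifnot(inherits(config, "sv_benchmark_config"))
  truth <- simulate_truth_intervals(config$n_del, config$n_ins,
                                    config$seqlengths, spec = config$spec,
                                    seed = config$seed,
                                    dataset = config$dataset)
  pipelines <- simulate_pipeline_callsets(
    truth, seed = derive_seed(config$seed, 2),
    profiles = config$profiles,
    fp_size_spec = config$fp_size_spec,
    artifacts = config$artifacts
  )
  categories <- c("deletion", "insertion")
  pm <- list(); strat <- list(); cons <- list(); hist <- list(); ml <- list()
  for (category in categories) {
    truth_cat <- subset_category(truth, category)
    sets_cat <- lapply(pipelines, subset_category, category = category)
    for (nm in names(sets_cat)) {
      m <- match_category(sets_cat[[nm]], truth_cat, category,
                          min_frac = config$min_frac,
                          reciprocal = config$reciprocal,
                          window = config$window)
      met <- compute_metrics(m)
      pm[[paste(nm, category)]] <- metrics_row(met, pipeline = nm,
                                               category = category)
      sb <- stratify_by_size(m, config$bins)
      sb <- cbind(pipeline = nm, category = category, sb,
                  stringsAsFactors = FALSE)
      strat[[paste(nm, category)]] <- sb
    }
    consensus <- build_consensus(sets_cat, category,
                                 insertion_pad = config$window)
    hist[[category]] <- support_histogram(consensus)
    curve <- consensus_f1_curve(consensus, truth_cat, ks = config$consensus_ks,
                                min_frac = config$min_frac,
                                reciprocal = config$reciprocal,
                                window = config$window)
    cons[[category]] <- cbind(category = category, curve,
                              stringsAsFactors = FALSE)
    rows <- extract_features(sets_cat, truth_cat, category,
                             min_frac = config$min_frac,
                             reciprocal = config$reciprocal,
                             window = config$window)
    ml[[category]] <- if (nrow(rows) >= 2 && length(unique(rows$label)) == 2) {
      split <- split_train_test(rows, train_frac = config$train_frac,
                                seed = derive_seed(config$seed, 3))
      if (length(unique(split$train$label)) < 2) {
        list(note = "single-class training split; classifier skipped")
      } else {
        model <- train_classifier(split$train,
                                  seed = derive_seed(config$seed, 4),
                                  n_trees = config$n_trees)
        ev <- evaluate_classifier(model, split$test)
        list(metrics = ev$metrics, contributions = ev$contributions,
             n_train = nrow(split$train), n_test = nrow(split$test))
      }
    } else {
      list(note = "degenerate labels; classifier skipped")
    }
  }
  pipeline_metrics <- do.call(rbind, pm); rownames(pipeline_metrics) <- NULL
  stratified <- do.call(rbind, strat); rownames(stratified) <- NULL
  consensus_df <- do.call(rbind, cons); rownames(consensus_df) <- NULL
  summary <- rbind(
    cbind(what = paste0("pipeline:", pipeline_metrics$pipeline),
          pipeline_metrics[, c("category", "precision", "recall", "f1")]),
    cbind(what = paste0("consensus>=", consensus_df$k),
          consensus_df[, c("category", "precision", "recall", "f1")]),
    do.call(rbind, lapply(categories, function(category) {
      m <- ml[[category]]$metrics
      if (is.null(m)) return(NULL)
      data.frame(what = "ml", category = category, precision = m$precision,
                 recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
    }))
  )
  rownames(summary) <- NULL
  report <- structure(list(
    pipeline_metrics = pipeline_metrics,
    stratified = stratified,
    consensus = consensus_df,
    support_histogram = hist,
    ml = ml,
    summary = summary,
    config = config
  ), class = "sv_benchmark_report")
  if (!is.null(outdir)) write_benchmark_report(report, outdir)
  report
}

#' @export
print.sv_benchmark_report <- function(x, ...) {
  cat("sv_benchmark_report\n")
  cat("-- per-pipeline metrics --\n")
  print(x$pipeline_metrics[, c("pipeline", "category", "precision", "recall", "f1")],
        digits = 3)
  cat("-- consensus F1 vs support --\n")
  print(x$consensus[, c("category", "k", "precision", "recall", "f1")], digits = 3)
  for (category in names(x$ml)) {
    m <- x$ml[[category]]$metrics
    if (!is.null(m)) {
      cat(sprintf("-- classifier (%s): precision=%.3f recall=%.3f F1=%.3f --\n",
                  category, m$precision, m$recall, m$f1))
    }
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Writes the tables as TSV, the full report as JSON, and a YAML provenance
#' record (config, seeds, package version) from which every number in the
#' report can be recomputed.
#'
#' @param report an `sv_benchmark_report`.
#' @param outdir output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_benchmark_report <- function(report, outdir) {
  stopifnot(inherits(report, "sv_benchmark_report"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    pipelines = file.path(outdir, "pipeline_metrics.tsv"),
    stratified = file.path(outdir, "stratified_metrics.tsv"),
    consensus = file.path(outdir, "consensus_curve.tsv"),
    summary = file.path(outdir, "summary.tsv"),
    contributions = file.path(outdir, "feature_contributions.tsv"),
    json = file.path(outdir, "report.json"),
    provenance = file.path(outdir, "provenance.yaml")
  )
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$pipeline_metrics, paths[["pipelines"]])
  wt(report$stratified, paths[["stratified"]])
  wt(report$consensus, paths[["consensus"]])
  wt(report$summary, paths[["summary"]])
  contrib <- do.call(rbind, lapply(names(report$ml), function(category) {
    co <- report$ml[[category]]$contributions
    if (is.null(co)) return(NULL)
    data.frame(category = category, feature = names(co),
               contribution_pct = unname(co), stringsAsFactors = FALSE)
  }))
  if (is.null(contrib)) {
    contrib <- data.frame(category = character(0), feature = character(0),
                          contribution_pct = numeric(0))
  }
  wt(contrib, paths[["contributions"]])
  json <- list(
    pipeline_metrics = report$pipeline_metrics,
    consensus = report$consensus,
    support_histogram = report$support_histogram,
    ml = lapply(report$ml, function(m) {
      if (is.null(m$metrics)) return(m)
      list(precision = m$metrics$precision, recall = m$metrics$recall,
           f1 = m$metrics$f1, tp = m$metrics$tp, fp = m$metrics$fp,
           fn = m$metrics$fn, contributions = as.list(m$contributions),
           n_train = m$n_train, n_test = m$n_test)
    })
  )
  jsonlite::write_json(json, paths[["json"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  cfg <- report$config
  yaml::write_yaml(list(
    package = "svbenchr",
    version = as.character(utils::packageVersion("svbenchr")),
    dataset = cfg$dataset,
    seed = cfg$seed,
    seqlengths = as.list(cfg$seqlengths),
    n_del = cfg$n_del, n_ins = cfg$n_ins,
    truth_size_spec = unclass(cfg$spec),
    fp_size_spec = unclass(cfg$fp_size_spec),
    artifacts = cfg$artifacts,
    matching = list(min_frac = cfg$min_frac, reciprocal = cfg$reciprocal,
                    window = cfg$window),
    bins = cfg$bins,
    consensus_ks = cfg$consensus_ks,
    train_frac = cfg$train_frac,
    n_trees = cfg$n_trees,
    pipelines = names(cfg$profiles)
  ), paths[["provenance"]])
  invisible(paths)
}
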