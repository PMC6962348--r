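#' Run the full analysis pipeline from a configuration file
#'
#' Executes ingest -> summarise -> (optional) error-model fit -> classify
#' as one reproducible run. The configuration is JSON with blocks:
#' \describe{
#'   \item{\code{seed}}{integer; one registry seed fans out per-stage
#'     sub-seeds deterministically.}
#'   \item{\code{input}}{either \code{\{"simulate": \{"n_responders": ...,
#'     "n_nonresponders": ..., "n_clones": ..., "depth": ...,
#'     "error_rate": ...\}\}} or \code{\{"tables": [paths...],
#'     "dialect": "immunoseq"|"airr", "features": path\}} where
#'     \code{features} is a TSV with \code{sample_id} and \code{response}.}
#'   \item{\code{model_errors}}{optional: \code{\{"grid_min": ...,
#'     "grid_max": ...\}} enabling the error-rate grid fit.}
#'   \item{\code{classify}}{\code{\{"n_splits": ..., "train_fraction": ...,
#'     "features_used": "both"|"convergence"|"clonality"\}}.}
#' }
#' Outputs written to \code{out_dir}: \code{summary.tsv} (one feature row
#' per sample), \code{fit.json} + \code{fit_correlations.tsv} (if the error
#' model ran), \code{cv.json}, \code{roc.tsv}, and \code{manifest.json}
#' (config snapshot, seed registry, input digests, package version,
#' per-stage timings).
#'
#' @param config Path to a JSON configuration file, or an equivalent list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
         else config
  for (block in c("seed", "input", "classify")) {
    if (is.null(cfg[[block]])) {
      stop("pipeline config lacks required block: ", block)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, tool = "tcrconv",
                   version = as.character(utils::packageVersion("tcrconv")),
                   seed_registry = list(), input_digests = list(),
                   timings = list())
  seed <- as.integer(cfg$seed)
  stage_seed <- function(k) (seed * 97L + k) %% 2147483587L + 1L
  manifest$seed_registry <- list(root = seed, simulate = stage_seed(1L),
                                 classify = stage_seed(2L))
  timer <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # --- ingest ---------------------------------------------------------
  st <- timer({
    if (!is.null(cfg$input$simulate)) {
      sim <- cfg$input$simulate
      cohort <- generate_cohort(
        n_responders = sim$n_responders,
        n_nonresponders = sim$n_nonresponders,
        seed = manifest$seed_registry$simulate,
        n_clones = if (is.null(sim$n_clones)) 3000L else sim$n_clones,
        depth = if (is.null(sim$depth)) 150000L else sim$depth,
        error_rate = if (is.null(sim$error_rate)) 0 else sim$error_rate)
      list(repertoires = cohort$repertoires, response = setNames(
        cohort$features$response, cohort$features$sample_id))
    } else {
      if (is.null(cfg$input$tables)) {
        stop("pipeline config input block needs 'simulate' or 'tables'")
      }
      reps <- lapply(cfg$input$tables, read_clonotype_table,
                     dialect = cfg$input$dialect)
      manifest$input_digests <- as.list(tools::md5sum(unlist(cfg$input$tables)))
      resp <- NULL
      if (!is.null(cfg$input$features)) {
        ft <- utils::read.delim(cfg$input$features)
        resp <- setNames(ft$response, ft$sample_id)
      }
      list(repertoires = reps, response = resp)
    }
  })
  ingest <- st$val
  manifest$timings$ingest <- st$secs

  # --- summarise ------------------------------------------------------
  st <- timer({
    do.call(rbind, lapply(ingest$repertoires, repertoire_summary))
  })
  summaries <- st$val
  manifest$timings$summarise <- st$secs
  utils::write.table(summaries, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- error model (optional) ----------------------------------------
  if (!is.null(cfg$model_errors)) {
    me <- cfg$model_errors
    grid <- error_rate_grid(
      grid_min = if (is.null(me$grid_min)) 1e-5 else me$grid_min,
      grid_max = if (is.null(me$grid_max)) 1e-2 else me$grid_max)
    st <- timer(fit_error_rate(ingest$repertoires, summaries$convergence,
                               grid = grid))
    fit <- st$val
    manifest$timings$model_errors <- st$secs
    jsonlite::write_json(list(best_rate = fit$best_rate,
                              best_correlation = fit$best_correlation),
                         file.path(out_dir, "fit.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.table(
      data.frame(error_rate = fit$grid,
                 spearman = fit$correlation_per_rate),
      file.path(out_dir, "fit_correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- classify -------------------------------------------------------
  if (is.null(ingest$response)) {
    stop("classification stage requires response labels ",
         "(simulate input or a features file)")
  }
  features <- data.frame(sample_id = summaries$sample_id,
                         convergence = summaries$convergence,
                         clonality = summaries$clonality,
                         response = unname(
                           ingest$response[summaries$sample_id]),
                         stringsAsFactors = FALSE)
  predictors <- switch(
    if (is.null(cfg$classify$features_used)) "both"
    else cfg$classify$features_used,
    both = c("convergence", "clonality"),
    convergence = "convergence",
    clonality = "clonality",
    stop("classify$features_used must be both/convergence/clonality"))
  st <- timer(lgocv(
    features, predictors = predictors,
    n_splits = if (is.null(cfg$classify$n_splits)) 2000L
               else as.integer(cfg$classify$n_splits),
    train_fraction = if (is.null(cfg$classify$train_fraction)) 0.75
                     else cfg$classify$train_fraction,
    seed = manifest$seed_registry$classify))
  cv <- st$val
  manifest$timings$classify <- st$secs
  jsonlite::write_json(
    list(n_splits = cv$n_splits, train_fraction = cv$train_fraction,
         predictors = cv$predictors, auc = cv$auc,
         operating_point = as.list(cv$operating_point),
         n_redrawn = cv$n_redrawn),
    file.path(out_dir, "cv.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(threshold = cv$roc$threshold,
               sensitivity = cv$roc$sensitivity,
               specificity = cv$roc$specificity),
    file.path(out_dir, "roc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
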