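# End-to-end orchestration: curate -> descriptors -> preprocess -> profile
# -> feature-select -> train -> evaluate -> explain, driven by a YAML (or
# list) configuration with one global seed. Every stage seed derives from
# the global seed via named substreams, so outputs regenerate identically
# from the same configuration.

.defaultConfig <- function() {
  list(
    seed = 1L,
    outdir = "qsarstack-out",
    curation = list(threshold = 0.1, priority = NULL),
    descriptors = list(schema = "mordred2d"),
    profile = list(fingerprint = "morgan", radius = 2L, nbits = 2048L),
    automl = list(model_budget = 3L, n_try = 3L, threshold = 0.05,
                  k = 5L, families = c("random_forest",
                                       "extremely_randomized_trees",
                                       "gradient_boosting",
                                       "extreme_gradient_boosting",
                                       "linear_glm"),
                  penalty = "lasso"),
    shap = list(fraction = 0.1, n_samples = 1000L, method = "auto",
                max_explain = 25L)
  )
}

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list. Must contain either an
#'   \code{input} block (\code{source_a}, \code{source_b} CSV paths) or a
#'   \code{simulate} block (\code{n_a}, \code{n_b}, \code{n_shared},
#'   \code{n_discordant}).
#' @return the merged configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  merged <- utils::modifyList(.defaultConfig(), config)
  if (is.null(merged$input) && is.null(merged$simulate)) {
    stop("config must contain an 'input' block (source_a/source_b files) ",
         "or a 'simulate' block (n_a/n_b/n_shared/n_discordant)")
  }
  merged
}

#' Run the full pipeline
#'
#' Executes curation, descriptor computation, preprocessing, profiling,
#' the four-stage automated modeling workflow, and Shapley explanation,
#' writing \code{audit.json}, \code{report.json}, \code{leaderboard.csv},
#' \code{curated.csv}, \code{selected_features.txt}, \code{shap.tsv} and
#' \code{importance.csv} into the configured output directory. All outputs
#' are deterministic functions of the configuration (including its seed).
#'
#' @param config YAML path or list, see [readPipelineConfig()].
#' @param verbose log one line per stage (default TRUE).
#' @return invisibly, a list with the curated database, matrices, model,
#'   explanation and report.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  cfg <- readPipelineConfig(config)
  seed <- as.integer(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    src <- genSources(nA = s$n_a, nB = s$n_b, nShared = s$n_shared,
                      nDiscordant = s$n_discordant,
                      threshold = cfg$curation$threshold,
                      seed = deriveSeed(seed, "simulate"))
    a <- src$a; b <- src$b
    say("input", "simulated sources: ", length(a), " + ", length(b),
        " records")
  } else {
    inp <- cfg$input
    a <- loadRecords(inp$source_a, format = inp$format %||% "csv",
                     sourceId = inp$source_a_id %||% "A",
                     smilesCol = inp$smiles_col %||% "smiles",
                     pkiCol = inp$pki_col %||% "pKi")
    b <- loadRecords(inp$source_b, format = inp$format %||% "csv",
                     sourceId = inp$source_b_id %||% "B",
                     smilesCol = inp$smiles_col %||% "smiles",
                     pkiCol = inp$pki_col %||% "pKi")
    a <- dedupeWithinSource(a, cfg$curation$threshold)
    b <- dedupeWithinSource(b, cfg$curation$threshold)
    say("input", "loaded sources: ", length(a), " + ", length(b), " records")
  }

  # -- curation -------------------------------------------------------------
  prio <- cfg$curation$priority %||% sourceId(a)
  db <- resolveDuplicates(a, b, threshold = cfg$curation$threshold,
                          priority = prio)
  writeCuratedDatabase(db, file.path(cfg$outdir, "curated.csv"),
                       auditPath = file.path(cfg$outdir, "audit.json"))
  say("curate", "in ", length(a) + length(b), " records -> ",
      length(db), " unique compounds")

  # -- descriptors ----------------------------------------------------------
  ent <- entries(db)
  dm <- computeDescriptors2D(ent$smiles, keys = ent$structure_key,
                             schema = cfg$descriptors$schema %||% "mordred2d")
  pm <- preprocessDescriptors(dm)
  say("descriptors", ncol(dm@values), " columns -> ",
      ncol(pm@values), " after preprocessing")

  # -- profiling ------------------------------------------------------------
  rules <- ruleReport(dm)
  sim <- similaritySummary(ent$smiles,
                           radius = cfg$profile$radius %||% 2L,
                           nbits = cfg$profile$nbits %||% 2048L,
                           seed = deriveSeed(seed, "similarity"))
  ruleCols <- c("MW", "nHBDon", "SLogP", "nHBAcc", "TopoPSA", "nRot")
  corr <- correlationMatrix(cbind(as.data.frame(dm@values[, ruleCols]),
                                  pKi = ent$pKi))
  say("profile", sprintf("similarity median %.3f; %.1f%% pass rule of five",
      sim$median, rules$summary$percent[rules$summary$rule ==
                                          "Complete Lipinski's rules"]))

  # -- modeling -------------------------------------------------------------
  am <- cfg$automl
  fit <- runAutoML(pm, ent$pKi,
                   modelBudget = am$model_budget, nTry = am$n_try,
                   threshold = am$threshold, k = am$k,
                   seed = deriveSeed(seed, "automl"),
                   families = unlist(am$families),
                   penalty = am$penalty %||% "lasso")
  utils::write.csv(fit$leaderboard,
                   file.path(cfg$outdir, "leaderboard.csv"),
                   row.names = FALSE)
  selTab <- data.frame(name = fit$features@names,
                       relative_importance =
                         unname(fit$features@relativeImportance),
                       original_index = match(fit$features@names,
                                              colnames(pm@values)))
  utils::write.table(selTab,
                     file.path(cfg$outdir, "selected_features.txt"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("train", "winner ", fit$leaderboard$id[1],
      sprintf(" (CV RMSE %.4f, R2 %.4f)", fit$model@cvMetrics$rmse,
              fit$model@cvMetrics$r2))

  # -- explanation ----------------------------------------------------------
  sh <- cfg$shap
  Xsel <- pm@values[, fit$features@names, drop = FALSE]
  nBg <- max(2L, ceiling((sh$fraction %||% 0.1) * nrow(Xsel)))
  bgIdx <- .withSeed(deriveSeed(seed, "shap-background"),
                     sample.int(nrow(Xsel), nBg))
  exIdx <- bgIdx[seq_len(min(length(bgIdx), sh$max_explain %||% 25L))]
  shap <- shapValues(fit$model, Xsel[bgIdx, , drop = FALSE],
                     Xsel[exIdx, , drop = FALSE],
                     method = sh$method %||% "auto",
                     nSamples = sh$n_samples %||% 1000L,
                     seed = deriveSeed(seed, "shap"))
  imp <- aggregateImportance(shap)
  utils::write.table(cbind(key = ent$structure_key[exIdx],
                           as.data.frame(shapPhi(shap))),
                     file.path(cfg$outdir, "shap.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(imp, file.path(cfg$outdir, "importance.csv"),
                   row.names = FALSE)
  say("explain", "top feature ", imp$feature[1],
      sprintf(" (mean |phi| = %.4f)", imp$mean_abs_shap[1]))

  # -- report ---------------------------------------------------------------
  report <- list(
    seed = seed,
    curation = auditCounts(db),
    descriptors = list(columns_in = ncol(dm@values),
                       columns_out = ncol(pm@values),
                       dropped = nrow(provenance(pm)$dropped)),
    profile = list(rules = rules$summary,
                   similarity = sim[c("min", "median", "max")],
                   pki = pkiSummary(ent$pKi)[c("n", "min", "max", "mean",
                                               "median")]),
    model = list(
      winner = fit$leaderboard$id[1],
      n_selected_features = length(fit$features@names),
      cv_rmse = fit$model@cvMetrics$rmse,
      cv_r2 = fit$model@cvMetrics$r2,
      baseline_rmse = fit$baseline$rmse,
      baseline_r2 = fit$baseline$r2),
    shap = list(method = shap@method, base_value = baseValue(shap),
                top_features = utils::head(imp, 10)))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, db = db, descriptors = dm, matrix = pm,
                 rules = rules, similarity = sim, correlation = corr,
                 fit = fit, shap = shap, importance = imp,
                 report = report))
}
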