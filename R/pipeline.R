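#' Pipeline configuration
#'
#' Bundles everything a full replication run needs: the data source
#' (either a cohort CSV with its dialect, or a synthetic-cohort
#' configuration), the network training settings, the clustering settings,
#' the evaluation settings and a global seed from which every stage's seed
#' is derived deterministically.
#'
#' @param data Either `NULL` (use `synthetic`) or a list with `path` and
#'   optional `dialect` for [read_cohort()].
#' @param synthetic A [synthetic_config()]; ignored when `data` is given.
#' @param training A [training_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param clustering List with `k` (default 3) and `restarts` (default
#'   50).
#' @param evaluation List with `correction` (default `"2N"`) and `subsets`
#'   (default all three feature subsets) for the leave-one-out stage; set
#'   `subsets = character(0)` to skip it.
#' @param hidden Hidden-unit count (default 2).
#' @param seed Global integer seed.
#' @param out_dir Directory for persisted artifacts, or `NULL` to keep
#'   everything in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, synthetic = synthetic_config(),
                            training = training_config(),
                            clustering = list(k = 3L, restarts = 50L),
                            evaluation = list(
                              correction = "2N",
                              subsets = c("all", "item", "associate")),
                            hidden = 2L, seed = 1L, out_dir = NULL) {
  if (is.null(data) && is.null(synthetic)) {
    stop("either a data path or a synthetic configuration is required")
  }
  if (!is.null(data) && is.null(data$path)) {
    stop("data block needs a 'path'")
  }
  if (is.null(clustering$k)) clustering$k <- 3L
  if (is.null(clustering$restarts)) clustering$restarts <- 50L
  if (is.null(evaluation$correction)) evaluation$correction <- "2N"
  if (is.null(evaluation$subsets)) {
    evaluation$subsets <- c("all", "item", "associate")
  }
  structure(list(data = data, synthetic = synthetic, training = training,
                 clustering = clustering, evaluation = evaluation,
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized blocks mirror [pipeline_config()]: `data` (path, layout,
#' column_map), `synthetic` (any [synthetic_config()] argument except the
#' matrices), `training`, `clustering`, `evaluation`, plus top-level
#' `hidden`, `seed`, `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$data)) {
    list(path = y$data$path,
         dialect = list(layout = y$data$layout %||% "wide",
                        column_map = unlist(y$data$column_map)))
  }
  syn_args <- y$synthetic %||% list()
  synthetic <- do.call(synthetic_config, syn_args)
  training <- do.call(training_config, y$training %||% list())
  pipeline_config(data = data, synthetic = synthetic,
                  training = training,
                  clustering = y$clustering %||% list(),
                  evaluation = y$evaluation %||% list(),
                  hidden = y$hidden %||% 2L, seed = y$seed %||% 1L,
                  out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage seeds fan out deterministically from the global seed so that, e.g.,
# changing only the clustering seed cannot alter the trained model.
stage_seed <- function(seed, stage) {
  offs <- c(synthetic = 0L, training = 1000L, clustering = 2000L,
            loocv = 3000L, robustness = 4000L)
  as.integer((seed + offs[[stage]]) %% 2147483647)
}

#' Run the full replication pipeline
#'
#' Executes the declared stage order on one cohort: load or simulate the
#' cohort, z-score the 18 measures, train the age-classification network,
#' record resubstitution accuracy, probe hidden activations, k-means
#' cluster the latent space, canonicalize labels, compute the composition
#' table, cluster profiles and cluster-wise ANOVAs, run leave-one-out
#' cross-validation on the configured feature subsets with the
#' item-versus-associate ablation difference, and compute the univariate
#' statistics (split-plot mixed ANOVA, per-measure age t tests, post-hoc
#' stimulus comparisons). Fully reproducible under the global seed; when
#' `out_dir` is set, every intermediate table is persisted as CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; see the elements persisted in
#'   `report.json`.
#' @export
run_replication <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load data"
  report <- tryCatch({
    if (!is.null(config$data)) {
      cohort <- read_cohort(config$data$path,
                            config$data$dialect %||% list(layout = "wide"))
      truth <- NULL
    } else {
      syn_cfg <- config$synthetic
      syn_cfg$seed <- stage_seed(config$seed, "synthetic")
      syn <- generate_cohort(syn_cfg)
      cohort <- syn$cohort
      truth <- syn$truth
    }

    stage <- "normalize"
    feats_raw <- feature_matrix(cohort)
    feats_z <- zscore_normalize(feats_raw)
    targets <- encode_targets(cohort$age_group)

    stage <- "train"
    train_cfg <- config$training
    train_cfg$seed <- stage_seed(config$seed, "training")
    fit <- nn_train(feats_z, targets, train_cfg, hidden = config$hidden)
    resub <- resubstitution_accuracy(fit$params, feats_z,
                                     cohort$age_group)

    stage <- "probe + cluster"
    acts <- hidden_activations(fit$params, feats_z)
    sol <- kmeans_latent(acts, k = config$clustering$k,
                         restarts = config$clustering$restarts,
                         seed = stage_seed(config$seed, "clustering"))
    sol <- canonicalize_clusters(sol, cohort$age_group, feats_z)
    comp <- composition_table(sol$assignments, cohort$age_group)
    profiles <- cluster_profiles(feats_z, sol$assignments)
    anovas <- cluster_feature_anovas(feats_z, sol$assignments)

    stage <- "loocv"
    loocv_cfg <- train_cfg
    loocv_cfg$seed <- stage_seed(config$seed, "loocv")
    loocv_results <- list()
    for (ss in config$evaluation$subsets) {
      loocv_results[[ss]] <- loocv(feats_raw, cohort$age_group,
                                   loocv_cfg, subset = ss,
                                   hidden = config$hidden,
                                   correction =
                                     config$evaluation$correction)
    }
    ablation <- if (all(c("item", "associate") %in%
                        names(loocv_results))) {
      list(dprime_item = loocv_results$item$dprime$dprime,
           dprime_assoc = loocv_results$associate$dprime$dprime,
           difference = loocv_results$associate$dprime$dprime -
             loocv_results$item$dprime$dprime)
    }

    stage <- "univariate"
    uni_anova <- mixed_anova(cohort$performance_item,
                             cohort$performance_assoc,
                             cohort$age_group, cohort$condition)
    uni_t <- age_t_table(cohort)
    posthoc <- posthoc_stimulus_tests(cohort$performance_item,
                                      cohort$performance_assoc,
                                      cohort$condition)

    structure(list(
      seed = config$seed,
      stage_seeds = vapply(c("synthetic", "training", "clustering",
                             "loocv"),
                           function(s) stage_seed(config$seed, s),
                           integer(1L)),
      n = nrow(cohort), cohort = cohort, truth = truth,
      model = fit$params, training_history = fit$history,
      resubstitution_accuracy = resub,
      hidden_activations = acts, clusters = sol, composition = comp,
      cluster_profiles = profiles, cluster_anovas = anovas,
      loocv = loocv_results, ablation = ablation,
      mixed_anova = uni_anova, age_t_table = uni_t,
      posthoc = posthoc,
      version = as.character(utils::packageVersion("metamemnet"))),
      class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  resubstitution accuracy: %.3f\n",
              x$resubstitution_accuracy))
  cat("  cluster composition (young/old):",
      paste(apply(unclass(x$composition), 1L, paste, collapse = "-"),
            collapse = " / "), "\n")
  for (ss in names(x$loocv)) {
    cat(sprintf("  LOOCV d' (%s): %.3f\n", ss, x$loocv[[ss]]$dprime$dprime))
  }
  if (!is.null(x$ablation)) {
    cat(sprintf("  ablation difference (assoc - item): %.3f\n",
                x$ablation$difference))
  }
  invisible(x)
}

persist_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_cohort(report$cohort, path("cohort.csv"))
  if (!is.null(report$truth)) {
    utils::write.csv(report$truth, path("truth.csv"), row.names = FALSE)
  }
  model <- report$model
  jsonlite::write_json(list(W1 = model$W1, b1 = model$b1, w2 = model$w2,
                            b2 = model$b2, p = model$p, h = model$h,
                            final_error =
                              utils::tail(report$training_history$errors,
                                          1L),
                            epochs = report$training_history$epochs,
                            converged = report$training_history$converged),
                       path("model.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(data.frame(id = rownames(report$hidden_activations),
                              report$hidden_activations,
                              cluster = report$clusters$assignments),
                   path("hidden_activations.csv"), row.names = FALSE)
  utils::write.csv(report$cluster_profiles, path("cluster_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cluster_anovas, path("cluster_anovas.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$mixed_anova),
                   path("mixed_anova.csv"), row.names = FALSE)
  utils::write.csv(report$age_t_table, path("age_t_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$posthoc, path("posthoc.csv"), row.names = FALSE)
  if (length(report$loocv)) {
    jsonlite::write_json(
      lapply(report$loocv, function(r) {
        list(subset = r$subset, accuracy = r$accuracy,
             dprime = r$dprime[c("hits", "misses", "false_alarms",
                                 "correct_rejections", "hit_rate",
                                 "fa_rate", "dprime")],
             predictions = r$predictions)
      }), path("loocv.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "columns")
  }
  summary <- list(
    seed = report$seed, n = report$n,
    resubstitution_accuracy = report$resubstitution_accuracy,
    composition = as.data.frame(report$composition),
    loocv_dprime = lapply(report$loocv,
                          function(r) r$dprime$dprime),
    ablation = report$ablation, version = report$version)
  jsonlite::write_json(summary, path("report.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(out_dir)
}

#' Robustness check: repeated retraining and architecture variants
#'
#' Re-runs the replication pipeline `runs` times with derived seeds (and
#' once per entry of `hidden_variants`), and summarizes how often the
#' qualitative latent structure recurs: three canonical clusters in which
#' cluster 1 is majority-young, clusters 2 and 3 are majority-old, and
#' cluster 3 is the larger of the two older groups.
#'
#' @param config A [pipeline_config()].
#' @param runs Number of repeated runs per architecture (default 20).
#' @param hidden_variants Hidden-unit counts to test (default `c(2)`).
#' @return A list of class `robustness_summary` with per-variant data
#'   frames of per-run compositions and d-primes, and the fraction of
#'   runs reproducing the qualitative pattern.
#' @export
run_robustness <- function(config = pipeline_config(), runs = 20L,
                           hidden_variants = c(2L)) {
  if (runs < 1L) stop("runs must be at least 1")
  out <- list()
  for (h in hidden_variants) {
    rows <- vector("list", runs)
    for (r in seq_len(runs)) {
      cfg <- config
      cfg$hidden <- as.integer(h)
      cfg$out_dir <- NULL
      cfg$seed <- as.integer((config$seed +
                                stage_seed(config$seed, "robustness") +
                                r) %% 2147483647)
      rep <- run_replication(cfg)
      comp <- unclass(rep$composition)
      pattern <- nrow(comp) == 3L &&
        comp[1L, "young"] > comp[1L, "old"] &&
        comp[2L, "old"] > comp[2L, "young"] &&
        comp[3L, "old"] > comp[3L, "young"] &&
        sum(comp[3L, ]) > sum(comp[2L, ])
      rows[[r]] <- data.frame(
        run = r, seed = cfg$seed, hidden = h,
        resubstitution_accuracy = rep$resubstitution_accuracy,
        dprime_item = rep$ablation$dprime_item %||% NA_real_,
        dprime_assoc = rep$ablation$dprime_assoc %||% NA_real_,
        qualitative_pattern = pattern,
        composition = paste(apply(comp, 1L, paste, collapse = "-"),
                            collapse = "/"),
        stringsAsFactors = FALSE)
    }
    out[[paste0("hidden", h)]] <- do.call(rbind, rows)
  }
  structure(list(runs = out,
                 pattern_fraction = vapply(out, function(d) {
                   mean(d$qualitative_pattern)
                 }, numeric(1L))),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  for (v in names(x$runs)) {
    cat(v, ": qualitative pattern in ",
        sum(x$runs[[v]]$qualitative_pattern), "/", nrow(x$runs[[v]]),
        " runs\n", sep = "")
  }
  invisible(x)
}
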