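#' Pipeline configuration
#'
#' Collects every tunable of the six-stage workflow (screen, select
#' commons, split, fit SOM and PCA on the urban block, project the
#' industrial block, compare) with its default.
#'
#' @param simulate generate input data with [generate_synthetic()]
#'   (otherwise `areas`/`samples`/`compounds`/blank paths must be given).
#' @param synthetic a [synthetic_config()] used when `simulate = TRUE`.
#' @param areas_path,samples_path,compounds_path,blank_areas_path,blank_samples_path
#'   CSV inputs when `simulate = FALSE` (blanks share `compounds_path`).
#' @param blank_factor blank filter multiple (default 5).
#' @param ttest_alpha dilution t-test significance level (default 0.05).
#' @param ttest_method `"paired"` (default) or `"welch"`, see
#'   [dilution_ttest_filter()].
#' @param ttest_log10 run the t-test on log10 areas (default TRUE).
#' @param k,delta common-selection cluster count and peculiarity
#'   threshold, see [select_unknown_common()].
#' @param presence_threshold urban-absence cutoff used inside peculiar
#'   clusters, see [select_unknown_common()].
#' @param manual_ids optional explicit unknown-common id list.
#' @param som_mode,som_dims map sizing: `"explicit"` with `som_dims`
#'   (default `c(4, 3)`, the 12-node map), or `"regular"`/`"small"`.
#' @param rough_epochs,finetune_epochs SOM training schedule.
#' @param qe_multiplier SOM outlier threshold multiplier.
#' @param pca_ncomp `"auto"` (Kaiser) or integer.
#' @param pca_alpha,pca_gamma extreme/outlier significance levels.
#' @param out_dir optional directory; when set, every stage's
#'   intermediate tables and the fitted models are written there.
#' @param seed seed for the synthetic generator (overrides the one in
#'   `synthetic`) when simulating.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            synthetic = synthetic_config(),
                            areas_path = NULL, samples_path = NULL,
                            compounds_path = NULL,
                            blank_areas_path = NULL,
                            blank_samples_path = NULL,
                            blank_factor = 5,
                            ttest_alpha = 0.05,
                            ttest_method = "paired",
                            ttest_log10 = TRUE,
                            k = 4L, delta = 1.0, manual_ids = NULL,
                            presence_threshold = 1e-4,
                            som_mode = "explicit", som_dims = c(4L, 3L),
                            rough_epochs = 50L, finetune_epochs = 100L,
                            qe_multiplier = 1,
                            pca_ncomp = "auto",
                            pca_alpha = 0.05, pca_gamma = 0.05,
                            out_dir = NULL, seed = NULL) {
  cfg <- as.list(environment())
  if (!simulate) {
    need <- c("areas_path", "samples_path", "compounds_path",
              "blank_areas_path", "blank_samples_path")
    missing <- need[vapply(cfg[need], is.null, TRUE)]
    if (length(missing)) {
      stop("simulate = FALSE requires: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) cfg$synthetic$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full anomaly-detection workflow
#'
#' Executes, in order: compound screening (blank filter, dilution
#' t-test, Correctness), z-scoring and two-way Ward clustering with
#' unknown-common selection, the urban/industrial split, urban-block
#' z-scoring, SOM and PCA model building on the urban block, projection
#' of the industrial block onto both models, and a comparison of the
#' two outlier calls.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: per-stage dimensions
#'   (`dims`), combined `filter_report`, `selection`, the fitted
#'   `som_model`/`pca_model`, projections and distance records for both
#'   blocks, candidate-map `quality_table`, outlier id lists, and the
#'   SOM/PCA `agreement` summary from [compare_models()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  emit <- function(name, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(obj, "feature_table")) {
      write_feature_table(obj, file.path(out_dir, name))
    } else if (is.data.frame(obj)) {
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           force = TRUE)
    }
  }

  dat <- stage("input", {
    if (config$simulate) {
      generate_synthetic(config$synthetic)
    } else {
      list(table = read_feature_table(config$areas_path,
                                      config$samples_path,
                                      config$compounds_path),
           blanks = read_feature_table(config$blank_areas_path,
                                       config$blank_samples_path,
                                       config$compounds_path),
           truth = NULL)
    }
  })
  dims <- list(input = dim(dat$table$areas))

  scr <- stage("screening", {
    b <- blank_filter(dat$table, dat$blanks, factor = config$blank_factor)
    t <- dilution_ttest_filter(b$table, alpha = config$ttest_alpha,
                               method = config$ttest_method,
                               log10_areas = config$ttest_log10)
    c <- correctness_filter(t$table)
    list(table = c$table,
         report = filter_report_merge(b$report, t$report, c$report))
  })
  if (ncol(scr$table$areas) < 2L) {
    stop("pipeline stage 'selection' failed: fewer than 2 compounds ",
         "survived screening", call. = FALSE)
  }
  dims$screened <- dim(scr$table$areas)
  emit("screened", scr$table)

  sel <- stage("selection", {
    scale_all <- zscore_fit(scr$table)
    z_all <- zscore_apply(scr$table, scale_all)
    cdend <- hca(z_all, axis = "compounds")
    sdend <- hca(z_all, axis = "samples")
    choice <- select_unknown_common(z_all, cdend, k = config$k,
                                    delta = config$delta,
                                    manual_ids = config$manual_ids,
                                    raw_table = scr$table,
                                    presence_threshold =
                                      config$presence_threshold)
    if (!is.null(out_dir)) {
      hm <- heatmap_matrix(z_all, sdend, cdend)
      utils::write.csv(data.frame(sample_id = rownames(hm), hm,
                                  check.names = FALSE),
                       file.path(out_dir, "heatmap.csv"), row.names = FALSE)
    }
    list(choice = choice,
         table = ft_subset(scr$table,
                           compounds = choice$unknown_common_ids))
  })
  dims$unknown_common <- dim(sel$table$areas)
  emit("unknown_common",
       data.frame(compound_id = sel$choice$unknown_common_ids,
                  confidence_level = sel$table$compounds$confidence_level))

  blocks <- stage("split", split_subsets(sel$table))
  if (nrow(blocks$urban$areas) < 2L) {
    stop("pipeline stage 'split' failed: urban block has < 2 samples",
         call. = FALSE)
  }
  dims$urban <- dim(blocks$urban$areas)
  dims$industrial <- dim(blocks$industrial$areas)
  emit("urban", blocks$urban)
  emit("industrial", blocks$industrial)

  models <- stage("model_building", {
    scaling <- zscore_fit(blocks$urban)
    z_urban <- zscore_apply(blocks$urban, scaling)
    grid <- map_size(nrow(z_urban$areas),
                     eigen_ratio = tryCatch(eigen_ratio(z_urban$areas),
                                            error = function(e) 1),
                     mode = config$som_mode, dims = config$som_dims)
    som <- som_train(z_urban$areas, grid,
                     rough_epochs = config$rough_epochs,
                     finetune_epochs = config$finetune_epochs,
                     scaling = scaling)
    quality_table <- som_candidates(
      z_urban$areas,
      extra_dims = list(c(som$grid$xdim, som$grid$ydim)),
      rough_epochs = config$rough_epochs,
      finetune_epochs = config$finetune_epochs)
    pca <- pca_fit(z_urban$areas, n_components = config$pca_ncomp,
                   scaling = scaling)
    train_dist <- pca_distances(pca, z_urban$areas)
    limits <- pca_critical_limits(train_dist, alpha = config$pca_alpha,
                                  gamma = config$pca_gamma)
    list(scaling = scaling, z_urban = z_urban, som = som, pca = pca,
         limits = limits, train_dist = train_dist,
         quality_table = quality_table)
  })
  emit("quality_table", models$quality_table)
  if (!is.null(out_dir)) {
    serialize_model(models$som, file.path(out_dir, "som.json"))
    serialize_model(models$scaling, file.path(out_dir, "scaling.json"))
  }

  proj <- stage("projection", {
    z_ind <- zscore_apply(blocks$industrial, models$scaling)
    som_train_proj <- som_project(models$som, models$z_urban,
                                  multiplier = config$qe_multiplier)
    som_ind_proj <- som_project(models$som, z_ind,
                                multiplier = config$qe_multiplier)
    ind_dist <- pca_distances(models$pca, z_ind)
    train_cls <- pca_classify(models$train_dist, models$limits)
    ind_cls <- pca_classify(ind_dist, models$limits)
    list(som_train = som_train_proj, som_industrial = som_ind_proj,
         pca_train = train_cls, pca_industrial = ind_cls)
  })
  emit("projection", rbind(proj$som_train, proj$som_industrial))
  emit("distances", rbind(proj$pca_train, proj$pca_industrial))

  agreement <- stage("comparison", {
    som_all <- rbind(proj$som_train, proj$som_industrial)
    pca_all <- rbind(proj$pca_train, proj$pca_industrial)
    compare_models(som_all, pca_all)
  })
  emit("comparison", agreement$per_sample)

  report <- structure(
    list(config = config,
         dims = dims,
         filter_report = scr$report,
         selection = sel$choice,
         som = models$som,
         pca = models$pca,
         limits = models$limits,
         quality_table = models$quality_table,
         som_projection = rbind(proj$som_train, proj$som_industrial),
         pca_records = rbind(proj$pca_train, proj$pca_industrial),
         som_outliers = proj$som_industrial$sample_id[
           proj$som_industrial$is_outlier],
         som_train_outliers = proj$som_train$sample_id[
           proj$som_train$is_outlier],
         pca_outliers = proj$pca_industrial$sample_id[
           proj$pca_industrial$category == "outlier"],
         pca_train_outliers = proj$pca_train$sample_id[
           proj$pca_train$category == "outlier"],
         agreement = agreement,
         truth = dat$truth),
    class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  d <- x$dims
  cat("run_report\n")
  cat(sprintf("  input: %d samples x %d compounds\n", d$input[1], d$input[2]))
  cat(sprintf("  screened: %d compounds | unknown common: %d\n",
              d$screened[2], d$unknown_common[2]))
  cat(sprintf("  split: urban %d x %d, industrial %d x %d\n",
              d$urban[1], d$urban[2], d$industrial[1], d$industrial[2]))
  cat(sprintf("  SOM outliers: %d/%d industrial (threshold %.3g)\n",
              length(x$som_outliers), d$industrial[1],
              attr(x$som_projection, "threshold")))
  cat(sprintf("  PCA outliers: %d/%d industrial\n",
              length(x$pca_outliers), d$industrial[1]))
  cat(sprintf("  SOM/PCA outlier agreement (Jaccard): %.3f\n",
              x$agreement$jaccard))
  invisible(x)
}

#' Compare SOM and PCA outlier calls
#'
#' Joins the per-sample quantization errors and PCA distances, computes
#' the Jaccard index of the two outlier sets and lists disagreements.
#'
#' @param som_projection a [som_project()] data.frame over all samples.
#' @param pca_records a classified [pca_distances()] data.frame over the
#'   same samples.
#' @return list with `per_sample` (sample_id, qe, som_outlier, sd, od,
#'   pca_outlier), `jaccard`, `disagreements` (sample ids flagged by
#'   exactly one model).
#' @export
compare_models <- function(som_projection, pca_records) {
  if (!setequal(som_projection$sample_id, pca_records$sample_id)) {
    stop("SOM and PCA results cover different sample sets", call. = FALSE)
  }
  idx <- match(som_projection$sample_id, pca_records$sample_id)
  per_sample <- data.frame(
    sample_id = som_projection$sample_id,
    qe = som_projection$qe,
    som_outlier = som_projection$is_outlier,
    sd = pca_records$sd[idx],
    od = pca_records$od[idx],
    pca_outlier = pca_records$category[idx] == "outlier",
    stringsAsFactors = FALSE)
  a <- per_sample$sample_id[per_sample$som_outlier]
  b <- per_sample$sample_id[per_sample$pca_outlier]
  uni <- union(a, b)
  jaccard <- if (length(uni) == 0L) 1 else
    length(intersect(a, b)) / length(uni)
  list(per_sample = per_sample,
       jaccard = jaccard,
       disagreements = setdiff(uni, intersect(a, b)))
}
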