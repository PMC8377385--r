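#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with any field
#' overridden via `...` (nested lists are merged shallowly per section).
#' When no `inputs` section points at existing expression/clinical/network
#' files, the `simulate` section (arguments of [demo_cohort_spec()]) is used
#' to generate the cohort as stage 1.
#'
#' @param out_dir Run directory (required).
#' @param seed Master seed; stage seeds derive from it.
#' @param ... Overrides, e.g. `select = list(alpha = 0.01)`.
#' @return Configuration list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    class_col = "class", log2 = FALSE, pseudocount = 1,
    mode = "paper",
    inputs = NULL,
    gmt = NULL,
    simulate = list(n_per_class = 150, n_pairs = 20, n_effect_pairs = 2,
                    rho = 0.6, delta = 1, beta = 1, n_hazard_edges = 2,
                    censor_fraction = 0.2, informative_stage = FALSE),
    select = list(alpha = 0.05, folds = 5, lambda_rule = "min"),
    evaluate = list(iters = 100, train_fraction = 0.8, num_trees = 1000,
                    min_node_size = 15, covariates = "stage"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !is.null(names(dots[[nm]])))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the full edge-biomarker pipeline
#'
#' Executes the staged analysis — simulate (or load inputs), edge
#' construction, differential feature selection, prognostic evaluation,
#' and gene-set enrichment — writing each stage's artifacts and a
#' `manifest.json` (package/R versions, seeds, per-stage input checksums,
#' output checksums, timings) into the run directory. On re-runs, stages
#' whose input checksums and recorded outputs are unchanged are skipped,
#' so a run can resume after interruption. Identical configuration and seed
#' give byte-identical selection and C-index tables.
#'
#' @param config Configuration list from [pipeline_config()], or the path
#'   of a YAML file with the same structure.
#' @param resume Reuse completed stages with matching checksums (default
#'   TRUE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config lacks `out_dir`")
  cfg <- do.call(pipeline_config,
                 c(list(out_dir = config$out_dir),
                   config[setdiff(names(config), "out_dir")]))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  else list()
  manifest$package <- as.character(utils::packageVersion("edgekin"))
  manifest$r_version <- as.character(getRversion())
  manifest$seed <- cfg$seed
  if (is.null(manifest$stages)) manifest$stages <- list()

  save_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

  run_stage <- function(name, key_obj, input_files, out_files, fun) {
    key <- stage_key(key_obj, input_files)
    st <- manifest$stages[[name]]
    if (resume && !is.null(st) && identical(st$status, "done") &&
        identical(st$key, key) && all(file.exists(out_files)) &&
        identical(unname(tools::md5sum(out_files)),
                  unlist(st$outputs_md5, use.names = FALSE))) {
      message("stage ", name, ": unchanged, skipped")
      manifest$stages[[name]]$skipped <<- TRUE
      save_manifest()
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", key = key,
                                       error = conditionMessage(e))
      save_manifest()
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "done", key = key, skipped = FALSE,
      elapsed = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(unname(out_files)),
      outputs_md5 = as.list(unname(tools::md5sum(out_files))))
    save_manifest()
    invisible(NULL)
  }

  # --- stage 1: simulate or register external inputs -----------------------
  external <- !is.null(cfg$inputs)
  sim_dir <- file.path(out, "simulate")
  if (external) {
    paths <- c(expression = cfg$inputs$expression,
               clinical = cfg$inputs$clinical,
               network = cfg$inputs$network)
    if (!all(file.exists(paths)))
      stop("input file(s) missing: ",
           paste(paths[!file.exists(paths)], collapse = ", "))
    manifest$stages[["simulate"]] <- list(status = "external",
                                          inputs = as.list(unname(paths)))
    save_manifest()
  } else {
    paths <- c(expression = file.path(sim_dir, "expression.tsv"),
               clinical = file.path(sim_dir, "clinical.tsv"),
               network = file.path(sim_dir, "network.tsv"))
    run_stage("simulate", list(sim = cfg$simulate, seed = cfg$seed),
              character(),
              c(paths, truth = file.path(sim_dir, "truth.yaml")), function() {
      spec <- do.call(demo_cohort_spec,
                      c(list(seed = cfg$seed), cfg$simulate))
      write_cohort(simulate_cohort(spec), sim_dir)
    })
  }

  # --- stage 2: edge features ---------------------------------------------
  edges_dir <- file.path(out, "edges")
  dir.create(edges_dir, showWarnings = FALSE)
  features_path <- file.path(edges_dir, "features.tsv")
  params_path <- file.path(edges_dir, "params.tsv")
  run_stage("edges",
            list(class_col = cfg$class_col, log2 = cfg$log2,
                 pseudocount = cfg$pseudocount),
            paths, c(features_path, params_path), function() {
    mat <- read_expression(paths[["expression"]])
    clinical <- read_clinical(paths[["clinical"]], class_col = cfg$class_col)
    net <- read_network(paths[["network"]])
    al <- align_cohort(mat, clinical, net, class_col = cfg$class_col)
    expr <- log2_zscore(al$expr, pseudocount = cfg$pseudocount,
                        log2 = isTRUE(cfg$log2))
    params <- class_params(expr)
    feats <- edge_transform(expr, al$network, params = NULL)
    write_features(feats, features_path)
    utils::write.table(as.data.frame(params), params_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # --- stage 3: selection --------------------------------------------------
  select_dir <- file.path(out, "select")
  dir.create(select_dir, showWarnings = FALSE)
  selection_path <- file.path(select_dir, "selection.tsv")
  metrics_path <- file.path(select_dir, "metrics.yaml")
  run_stage("select", cfg$select, c(features_path, paths[["clinical"]]),
            c(selection_path, metrics_path), function() {
    feats <- read_expression(features_path)
    clinical <- read_clinical(paths[["clinical"]], class_col = cfg$class_col)
    cls <- clinical[[cfg$class_col]][match(colnames(feats),
                                           clinical$sample_id)]
    sel <- select_features(feats, cls, alpha = cfg$select$alpha,
                           n_folds = cfg$select$folds,
                           seed = cfg$seed,
                           lambda_rule = cfg$select$lambda_rule)
    utils::write.table(sel$selected, selection_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(oof_auc = sel$oof_auc, lambda = sel$lambda,
                          n_selected = nrow(sel$selected),
                          n_prefilter = length(sel$prefilter_survivors),
                          seed = cfg$seed), metrics_path)
  })

  # --- stage 4: prognostic evaluation -------------------------------------
  eval_dir <- file.path(out, "evaluate")
  dir.create(eval_dir, showWarnings = FALSE)
  cindex_path <- file.path(eval_dir, "cindex.tsv")
  comparison_path <- file.path(eval_dir, "comparison.yaml")
  run_stage("evaluate", c(cfg$evaluate, mode = cfg$mode),
            c(features_path, selection_path, paths[["clinical"]]),
            c(cindex_path, comparison_path), function() {
    feats <- read_expression(features_path)
    clinical <- read_clinical(paths[["clinical"]], class_col = cfg$class_col)
    clinical <- clinical[clinical$sample_id %in% colnames(feats), ,
                         drop = FALSE]
    sel <- utils::read.delim(selection_path, stringsAsFactors = FALSE)
    if (!nrow(sel)) stop("selection is empty; nothing to evaluate")
    covs <- cfg$evaluate$covariates
    variants <- list(
      Clinical = list(features = character(), covariates = covs),
      KinSub = list(features = sel$feature_id, covariates = character()),
      `Clinical+KinSub` = list(features = sel$feature_id,
                               covariates = covs))
    ci <- mc_cv_cindex(clinical, variants, features = feats,
                       mode = "paper",
                       n_iter = cfg$evaluate$iters,
                       train_fraction = cfg$evaluate$train_fraction,
                       seed = cfg$seed,
                       num_trees = cfg$evaluate$num_trees,
                       min_node_size = cfg$evaluate$min_node_size)
    long <- data.frame(
      variant = rep(colnames(ci), each = nrow(ci)),
      iteration = rep(seq_len(nrow(ci)), ncol(ci)),
      train_fraction = cfg$evaluate$train_fraction,
      seed = rep(attr(ci, "split_seeds"), ncol(ci)),
      cindex = sprintf("%.10f", as.vector(ci)))
    utils::write.table(long, cindex_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pw <- compare_variants(ci)
    yaml::write_yaml(list(
      mean_cindex = as.list(round(colMeans(ci), 6)),
      rank_sum_p = lapply(seq_len(ncol(pw)), function(i)
        as.list(stats::setNames(pw[i, -i], colnames(pw)[-i])))),
      comparison_path)
  })

  # --- stage 5: enrichment -------------------------------------------------
  enrich_dir <- file.path(out, "enrich")
  enrichment_path <- file.path(enrich_dir, "enrichment.tsv")
  if (is.null(cfg$gmt)) {
    manifest$stages[["enrich"]] <- list(status = "skipped",
                                        reason = "no gene sets supplied")
    save_manifest()
  } else {
    dir.create(enrich_dir, showWarnings = FALSE)
    run_stage("enrich", list(), c(selection_path, cfg$gmt, paths[["network"]],
                                  paths[["expression"]]),
              enrichment_path, function() {
      sel <- utils::read.delim(selection_path, stringsAsFactors = FALSE)
      sets <- read_gmt(cfg$gmt)
      mat <- read_expression(paths[["expression"]])
      net <- read_network(paths[["network"]])
      universe <- intersect(network_genes(net), rownames(mat))
      res <- hypergeom_enrich(feature_genes(sel), sets, universe)
      utils::write.table(res, enrichment_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }

  invisible(manifest)
}

# Checksum key for a stage: configuration subset (canonical YAML) plus the
# md5 of every input file.
stage_key <- function(key_obj, input_files) {
  s <- paste(yaml::as.yaml(key_obj),
             paste(unname(tools::md5sum(input_files)), collapse = ","))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
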