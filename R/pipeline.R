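#' Default run configuration
#'
#' A fully serializable description of a pipeline run: either a synthetic
#' world (`simulate` block) or paths to real inputs (`paths` block), the
#' predictor settings, the model and CV draw budgets, prediction and LISA
#' settings, and a single global seed from which every stage derives its
#' own stream.
#'
#' @param seed global seed
#' @param out_dir output directory
#' @return a `run_config` list
#' @export
default_run_config <- function(seed = 42, out_dir = "deprivmap-out") {
  structure(list(
    seed = seed, out_dir = out_dir,
    simulate = list(n_neighbourhoods = 4, eas_per_neighbourhood = 25,
                    v_sd = 0, raster_resolution_m = 30),
    paths = NULL,
    predictors = list(standardize = TRUE, buffer_km = 5),
    model = list(prior_family = "normal", prior_scale = 0.98,
                 random_effects = FALSE, n_iter = 400, burn_in = 300,
                 n_chains = 2, thin = 1),
    cv = list(fractions = default_cv_fractions(), n_iter = 200,
              burn_in = 150, n_chains = 2),
    predict = list(threshold = 0.80, policy = "marginalize"),
    lisa = list(variables = c("flush_toilet", "pop_density"),
                n_perm = 199, alpha = 0.05)),
    class = "run_config")
}

#' Read / write a run configuration (JSON, or YAML when available)
#' @param path config file (`.json`, or `.yaml`/`.yml` when the yaml
#'   package is installed)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_run_config: YAML config requires the yaml package; ",
           "use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]])) {
      for (kk in names(cfg[[k]])) base[[k]][[kk]] <- cfg[[k]][[kk]]
    } else base[[k]] <- cfg[[k]]
  }
  # an explicit (non-empty) paths block replaces simulation
  if (length(cfg$paths)) base$simulate <- NULL else base$paths <- NULL
  base
}

#' @rdname read_run_config
#' @param cfg a `run_config`
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipeline_stages <- c("simulate", "predictors", "fit", "select", "predict",
                     "lisa", "report")

#' Run the deprivation-mapping pipeline
#'
#' Executes, in order: simulate (optional) -> build-predictors -> fit ->
#' select -> predict -> lisa -> report. Stages not requested read their
#' inputs from `out_dir` (so the CLI can run them one at a time); a
#' missing input aborts with the stage and file named. A manifest with
#' seeds, diagnostics and file hashes is written at the end.
#'
#' @param cfg a `run_config` (see [default_run_config()])
#' @param stages character subset of stages to run (default all)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(cfg, stages = pipeline_stages) {
  stopifnot(all(stages %in% pipeline_stages))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out, f)
  need <- function(f, stage) {
    if (!file.exists(f))
      stop("run_pipeline[", stage, "]: required input missing: ", f)
    f
  }
  written <- character(0)
  note <- function(f) written <<- c(written, f)

  need_inputs <- any(c("simulate", "predictors", "fit", "select", "predict",
                       "lisa") %in% stages)
  need_X <- any(c("predictors", "fit", "select", "predict", "lisa") %in%
                  stages)
  need_fit <- any(c("fit", "predict") %in% stages)

  # --- inputs: simulate or load ---
  frame <- hh <- dem <- ndvi_r <- NULL
  if (!need_inputs) {
    # report-only invocation
  } else if ("simulate" %in% stages && !is.null(cfg$simulate)) {
    sim <- cfg$simulate
    scfg <- synthetic_config(
      n_neighbourhoods = sim$n_neighbourhoods %||% 4,
      eas_per_neighbourhood = sim$eas_per_neighbourhood %||% 25,
      cell_size_km = sim$cell_size_km %||% 0.2236,
      true_alpha = sim$true_alpha %||% -1,
      true_beta = if (is.null(sim$true_beta)) default_true_beta() else
        unlist(sim$true_beta),
      v_sd = sim$v_sd %||% 0,
      raster_resolution_m = sim$raster_resolution_m %||% 30,
      seed = derive_seed(cfg$seed, "landscape"))
    world <- gen_world(scfg)
    frame <- world$frame; hh <- world$households
    dem <- world$rasters$dem; ndvi_r <- world$rasters$ndvi
    for (f in write_world(world, out)) note(f)
  } else {
    src <- cfg$paths %||% list(eas = pth("eas.geojson"),
                               households = pth("households.csv"),
                               dem = pth("dem.asc"), ndvi = pth("ndvi.asc"))
    frame <- read_ea_geojson(need(src$eas, "load"))
    hh <- read.csv(need(src$households, "load"), stringsAsFactors = FALSE)
    dem <- read_asc(need(src$dem, "load"))
    ndvi_r <- read_asc(need(src$ndvi, "load"))
  }

  # --- predictors ---
  X <- NULL
  if ("predictors" %in% stages) {
    X <- build_matrix(frame, hh, default_category_map(), dem = dem,
                      ndvi_raster = ndvi_r,
                      standardize = isTRUE(cfg$predictors$standardize),
                      buffer_km = cfg$predictors$buffer_km %||% 5)
    note(write_predictors(X, pth("predictors.csv")))
  } else if (need_X) {
    X <- read_predictors(need(pth("predictors.csv"), "predictors"))
  }

  train <- if (!is.null(frame)) which(frame$urban & !is.na(frame$deprived))
           else integer(0)
  mc <- cfg$model %||% list()
  spec <- model_spec(
    prior_family = mc$prior_family %||% "normal",
    prior_scale = mc$prior_scale %||% 0.98,
    random_effects = isTRUE(mc$random_effects),
    n_iter = mc$n_iter %||% 400, burn_in = mc$burn_in %||% 300,
    n_chains = mc$n_chains %||% 2, thin = mc$thin %||% 1,
    seed = derive_seed(cfg$seed, "fit"))

  # --- fit ---
  ftt <- NULL
  if ("fit" %in% stages) {
    ftt <- fit(spec, X[train, , drop = FALSE], frame$deprived[train],
               frame$neighbourhood[train], store_loglik = TRUE)
    note(write_draws(ftt, pth("draws.csv")))
    wa <- waic(ftt$loglik)
    jsonlite::write_json(wa, pth("waic.json"), auto_unbox = TRUE,
                         digits = NA)
    note(pth("waic.json"))
  } else if (need_fit) {
    ftt <- read_draws(need(pth("draws.csv"), "fit"))
  }

  # --- select ---
  if ("select" %in% stages) {
    cvspec <- spec
    cvspec$n_iter <- cfg$cv$n_iter %||% 200
    cvspec$burn_in <- cfg$cv$burn_in %||% 150
    cvspec$n_chains <- cfg$cv$n_chains %||% 2
    cvr <- holdout_cv(cvspec, X[train, , drop = FALSE],
                      frame$deprived[train], frame$neighbourhood[train],
                      fractions = cfg$cv$fractions %||%
                        default_cv_fractions(),
                      seed = derive_seed(cfg$seed, "cv"))
    write.csv(cv_summary(cvr), pth("cv_report.csv"), row.names = FALSE)
    note(pth("cv_report.csv"))
  }

  # --- predict ---
  urban <- if (!is.null(frame)) which(frame$urban) else integer(0)
  if ("predict" %in% stages) {
    pred <- posterior_predict(ftt, X[urban, , drop = FALSE],
                              frame$neighbourhood[urban],
                              policy = cfg$predict$policy %||% "marginalize",
                              threshold = cfg$predict$threshold %||% 0.80,
                              seed = derive_seed(cfg$seed, "predict"))
    write.csv(pred, pth("predictions.csv"), row.names = FALSE)
    note(pth("predictions.csv"))
    pf <- frame[urban, , drop = FALSE]
    pf$p_mean <- pred$p_mean; pf$p_low <- pred$p_low
    pf$p_high <- pred$p_high
    pf$quintile_bin <- as.character(pred$quintile_bin)
    pf$flag_deprived <- pred$deprived
    note(write_ea_geojson(pf, pth("predictions.geojson")))
    qt <- quintile_table(pred, frame)
    write.csv(qt, pth("quintile_table.csv"), row.names = FALSE)
    note(pth("quintile_table.csv"))
    cl <- find_clusters(frame[urban, , drop = FALSE], pred$deprived,
                        min_size = 3)
    jsonlite::write_json(cl, pth("clusters.json"), auto_unbox = TRUE,
                         digits = NA)
    note(pth("clusters.json"))
  }

  # --- lisa ---
  if ("lisa" %in% stages) {
    uf <- frame[urban, , drop = FALSE]
    w <- queen_weights(uf)
    lvars <- intersect(cfg$lisa$variables %||% character(0), colnames(X))
    if (!length(lvars)) lvars <- utils::head(colnames(X), 1)
    lf <- uf
    for (v in lvars) {
      lr <- local_morans_i(X[urban, v], w,
                           n_perm = cfg$lisa$n_perm %||% 199,
                           alpha = cfg$lisa$alpha %||% 0.05,
                           seed = derive_seed(cfg$seed, "lisa"))
      write.csv(data.frame(ea_id = uf$ea_id, lr),
                pth(paste0("lisa_", v, ".csv")), row.names = FALSE)
      note(pth(paste0("lisa_", v, ".csv")))
      lf[[paste0("lisa_", v)]] <- lr$class
    }
    note(write_ea_geojson(lf, pth("lisa.geojson")))
  }

  # --- report/manifest ---
  manifest <- list(
    package_version = as.character(utils::packageVersion("deprivmap")),
    seed = cfg$seed,
    stages = stages,
    files = as.list(tools::md5sum(sort(unique(written)))),
    diagnostics = if (!is.null(ftt) && !is.null(ftt$diagnostics))
      list(max_rhat = max(ftt$diagnostics$rhat, na.rm = TRUE),
           min_ess = min(ftt$diagnostics$ess, na.rm = TRUE)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
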