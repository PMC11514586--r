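#' End-to-end 3D-QSAR pipeline
#'
#' Orchestrates the whole analysis: read (or take) structures and
#' activities, assign types and charges, compute GRIND descriptors,
#' stratified train/test split, FFD variable selection, PLS with
#' LOO-selected latent variables, internal/external validation,
#' applicability domain and the interpretation tables. All stage outputs
#' are written as plain CSV/JSON files carrying the configuration hash, so
#' a rerun with the same config and seed reproduces them.
#'
#' @param config A [pipeline_config()].
#' @param molecules Optional list of [molecule()]s (otherwise read from
#'   `config$sdf_path`).
#' @param activity Optional activity tibble (otherwise read from
#'   `config$activity_path`, or taken from the molecules).
#' @param descriptors Optional precomputed descriptor tibble from
#'   [grind_descriptors()] (skips the field stage).
#' @param output_dir Directory for outputs (`NULL` = no files written).
#' @param verbose Log stage progress.
#' @return A `grind_pipeline` result: list with `descriptors`, `split`,
#'   `ffd`, `model`, `ncomp`, `validation`, `variable_report`,
#'   `predictions`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), molecules = NULL,
                         activity = NULL, descriptors = NULL,
                         output_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                                   sprintf(...)))
  cfg_hash <- config_hash(config)
  if (is.null(descriptors)) {
    if (is.null(molecules)) {
      say("stage structures: reading %s", config$sdf_path)
      molecules <- read_sdf(config$sdf_path)
    }
    molecules <- lapply(molecules, function(m) {
      if (all(is.na(m$atoms$hba))) m <- assign_pharmacophore_types(m)
      if (anyNA(m$atoms$charge)) m <- assign_partial_charges(m)
      m
    })
    say("stage fields/encode: %d molecules", length(molecules))
    params <- load_probe_params(config$probe_params_path)
    descriptors <- grind_descriptors(
      molecules, spacing = config$spacing, margin = config$margin,
      n_nodes = config$n_nodes, w = config$w, bin_width = config$bin_width,
      max_distance = config$max_distance, params = params, verbose = verbose)
  }
  if (is.null(activity)) {
    if (!is.null(config$activity_path)) {
      activity <- read_activity(config$activity_path)
    } else if (!is.null(molecules)) {
      activity <- tibble(id = map_chr(molecules, "id"),
                         pIC50 = map_dbl(molecules, "activity"),
                         cluster = map_chr(molecules, "cluster"),
                         set = "unassigned")
    } else abort("no activity table available")
  }
  if (!"pIC50" %in% names(activity))
    abort("activity table lacks the required column 'pIC50'")
  if (anyNA(activity$pIC50)) abort("missing pIC50 values in the activity table")
  activity <- activity[match(descriptors$id, activity$id), ]
  if (anyNA(activity$id)) abort("activity table does not cover all compounds")

  say("stage split: n_test = %d", config$n_test)
  split <- make_split(activity, n_test = config$n_test, seed = config$seed)
  X <- descriptor_matrix(descriptors)
  y <- setNames(activity$pIC50, activity$id)
  itr <- match(split$train, rownames(X))
  Xtr <- X[itr, , drop = FALSE]
  ytr <- y[itr]

  say("stage ffd: selecting variables")
  ffd <- ffd_select(Xtr, ytr, ncomp = config$ffd_ncomp,
                    dummy_fraction = config$ffd_dummy_fraction,
                    n_runs = config$ffd_n_runs, seed = config$seed,
                    scaling = config$scaling)
  Xsel <- Xtr[, ffd$retained_idx, drop = FALSE]

  say("stage fit: selecting latent variables (max %d)", config$ncomp_max)
  sel <- select_components(Xsel, ytr, ncomp_max = config$ncomp_max,
                           scaling = config$scaling)
  model <- fit_pls(Xsel, ytr, ncomp = sel$ncomp, scaling = config$scaling)
  model$meta <- attr(descriptors, "meta")

  say("stage validate")
  validation <- validate_model(model, X[, ffd$retained_idx, drop = FALSE],
                               y, split)
  report <- rank_variables(model, meta = model$meta,
                           top_n = min(config$top_n, length(model$coefficients)))
  preds <- validation$predictions |>
    left_join(select(split$table, "id", "cluster"), by = "id")

  manifest <- list(
    package = "grindqsar",
    version = as.character(utils::packageVersion("grindqsar")),
    config = unclass(config), config_hash = cfg_hash,
    seed = config$seed, n_compounds = nrow(descriptors),
    n_variables_total = ncol(X), n_variables_retained = length(ffd$retained_idx),
    ncomp = sel$ncomp, timestamp = format(Sys.time(), tz = "UTC")
  )
  result <- structure(list(
    descriptors = descriptors, split = split, ffd = ffd, model = model,
    ncomp = sel$ncomp, ncomp_profile = sel$profile, validation = validation,
    variable_report = report, predictions = preds, manifest = manifest
  ), class = "grind_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the package defaults:
#' grid spacing 0.5 A, margin 5 A, 100 nodes per probe, greedy weight 0.5,
#' bin width 0.4 A up to 25 A, autoscaling, LOO-selected latent variables
#' up to 5, FFD with 20% dummies, 15 test compounds.
#'
#' @param sdf_path,activity_path,probe_params_path Input file paths
#'   (optional when objects are passed to [run_pipeline()] directly).
#' @param spacing,margin Grid parameters (Angstrom).
#' @param n_nodes,w Node extraction parameters.
#' @param bin_width,max_distance Correlogram binning (Angstrom).
#' @param scaling `"autoscale"`, `"pareto"` or `"none"`.
#' @param ncomp_max Largest latent-variable count tried.
#' @param ffd_ncomp Latent variables used inside FFD runs.
#' @param ffd_dummy_fraction,ffd_n_runs FFD design parameters.
#' @param n_test Test-set size.
#' @param top_n Entries in the variable-interpretation report.
#' @param seed Integer seed for split and FFD design (required).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sdf_path = NULL, activity_path = NULL,
                            probe_params_path = NULL,
                            spacing = 0.5, margin = 5.0, n_nodes = 100,
                            w = 0.5, bin_width = 0.4, max_distance = 25,
                            scaling = "autoscale", ncomp_max = 5,
                            ffd_ncomp = 2, ffd_dummy_fraction = 0.2,
                            ffd_n_runs = NULL, n_test = 15, top_n = 10,
                            seed = 1) {
  stopifnot(spacing > 0, margin >= 0, n_nodes >= 1, w >= 0, w <= 1,
            bin_width > 0, max_distance > bin_width, ncomp_max >= 1,
            ffd_ncomp >= 1, ffd_dummy_fraction > 0, n_test >= 3)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$manifest$config_hash
  stamp <- function(tbl) {
    attr(tbl, "config_hash") <- hash
    tbl
  }
  write_descriptors(stamp(result$descriptors), file.path(output_dir, "descriptors.csv"))
  write_activity(result$split$table, file.path(output_dir, "activity_split.csv"))
  readr::write_csv(result$variable_report, file.path(output_dir, "variable_report.csv"))
  readr::write_csv(result$predictions, file.path(output_dir, "predictions.csv"))
  readr::write_csv(as_tibble(result$validation$williams),
                   file.path(output_dir, "williams.csv"))
  write_validation_json(result$validation, file.path(output_dir, "validation.json"))
  write_pls_json(result$model, file.path(output_dir, "model.json"))
  jsonlite::write_json(result$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(output_dir)
}

#' Serialise / restore a PLS model as versioned JSON
#' @param model A `grind_pls`.
#' @param path JSON path.
#' @return `path` (write); a `grind_pls` (read).
#' @export
write_pls_json <- function(model, path) {
  payload <- list(
    format = "grindqsar-pls", format_version = 1L,
    scaling = model$scaling, ncomp = model$ncomp,
    variables = model$variables,
    coefficients = unname(model$coefficients), intercept = model$intercept,
    coef_scaled = unname(model$coef_scaled),
    x_means = model$x_means, x_scales = model$x_scales, y_mean = model$y_mean,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, train_ids = model$train_ids
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_json
#' @export
read_pls_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "grindqsar-pls"))
    abort("not a grindqsar PLS model file")
  structure(list(
    coefficients = setNames(p$coefficients, p$variables),
    intercept = p$intercept,
    coef_scaled = setNames(p$coef_scaled, p$variables),
    weights = p$weights, loadings = p$loadings, y_loadings = p$y_loadings,
    scores = NULL, ncomp = p$ncomp, scaling = p$scaling,
    x_means = p$x_means, x_scales = p$x_scales, y_mean = p$y_mean,
    fitted = NULL, y = NULL, train_ids = p$train_ids,
    variables = p$variables, meta = NULL
  ), class = "grind_pls")
}

#' @export
print.grind_pipeline <- function(x, ...) {
  cat(sprintf("<grindqsar pipeline: %d compounds, %d/%d variables retained, A = %d>\n",
              nrow(x$descriptors), x$manifest$n_variables_retained,
              x$manifest$n_variables_total, x$ncomp))
  print(x$validation)
  invisible(x)
}
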