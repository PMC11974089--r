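#' Configure a full pipeline run
#'
#' @param out_dir Output directory.
#' @param seed Master seed; recorded in the manifest and used to derive the
#'   phantom and cohort seeds when they are not set explicitly.
#' @param phantom A [phantom_spec()] (its `seed` is overridden by `seed`
#'   unless `keep_seeds = TRUE`).
#' @param cohort A [cohort_spec()] (same seed handling).
#' @param gtab A [gradient_table()].
#' @param fit_method `"wls"` or `"ols"`.
#' @param analyze Run the statistical battery on the simulated cohort.
#' @param write_imaging Write NIfTI intermediates (can be disabled for quick
#'   cohort-only runs).
#' @param keep_seeds Keep the seeds already inside `phantom`/`cohort`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, phantom = phantom_spec(),
                       cohort = cohort_spec(), gtab = make_gradient_table(48),
                       fit_method = "wls", analyze = TRUE,
                       write_imaging = TRUE, keep_seeds = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"),
             inherits(gtab, "gradient_table"))
  if (!keep_seeds) {
    phantom$seed <- as.integer(seed)
    cohort$seed <- as.integer(seed) + 1L
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, cohort = cohort, gtab = gtab,
                 fit_method = match.arg(fit_method, c("wls", "ols")),
                 analyze = isTRUE(analyze),
                 write_imaging = isTRUE(write_imaging)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file may set `seed`, `out_dir`, `fit_method`, `analyze`,
#' `write_imaging`, a `gradient` block (`n_directions`, `b`, `n_b0`) and
#' `phantom` / `cohort` blocks whose entries are passed to [phantom_spec()]
#' and [cohort_spec()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param out_dir Override for the output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  flatten <- function(block) {
    # YAML maps arrive as nested lists; spec arguments are atomic vectors
    lapply(as.list(block), function(x) if (is.list(x)) unlist(x) else x)
  }
  gt <- do.call(make_gradient_table, c(cfg$gradient %||%
                                         list(n_directions = 48)))
  args <- list(out_dir = out_dir %||% cfg$out_dir %||% ".",
               seed = cfg$seed %||% 1L,
               phantom = do.call(phantom_spec, flatten(cfg$phantom)),
               cohort = do.call(cohort_spec, flatten(cfg$cohort)),
               gtab = gt)
  for (k in c("fit_method", "analyze", "write_imaging"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(run_config, args)
}

#' Run the phantom-to-report pipeline
#'
#' Executes, in order: phantom synthesis, tensor fitting, automatic VOI
#' placement and the per-phantom ALPS index, volumetrics on the phantom
#' label mask, cohort simulation, and (optionally) the statistical battery.
#' Every artifact is written under `config$out_dir` and hashed (MD5) into
#' `manifest.json`, which also records the master seed; the run is
#' deterministic, so re-running a config yields an identical manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `alps` (the phantom's `alps_result`),
#'   `volumes`, `cohort`, `report` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  message("[phantom] synthesizing DWI")
  ph <- stage("phantom", synthesize_dwi(config$phantom, config$gtab))
  message("[fit] tensor estimation (", config$fit_method, ")")
  tf <- stage("fit", fit_tensor(ph, method = config$fit_method))
  message("[alps] VOI placement and index")
  vois <- stage("alps", auto_alps_vois(ph$labels))
  tside <- if (config$phantom$tumor_radius > 0) config$phantom$tumor_side
  alps <- stage("alps", subject_alps(tf, vois, tside))
  message("[volumes] label-mask volumetry")
  vols <- stage("volumes", subject_volumes(
    label_mask(ph$labels, ph$affine)))
  message("[cohort] simulating subjects")
  cohort <- stage("cohort", simulate_cohort(config$cohort))
  write_cohort(cohort, file.path(out, "cohort.tsv"))
  report <- NULL
  if (config$analyze) {
    message("[analyze] statistical battery")
    report <- stage("analyze", cohort_report(cohort))
    write_stat_report(report, file.path(out, "report"))
  }
  if (config$write_imaging) {
    write_dwi(ph, file.path(out, "dwi"))
    write_nifti_array(ph$labels, ph$affine, file.path(out, "labels.nii"))
    write_tensor_maps(tf, file.path(out, "tensors"))
    write_vois(vois, file.path(out, "vois.json"))
  }
  jsonlite::write_json(list(
    alps = alps[c("left", "right", "bilateral_mean")],
    volumes = vols[c("csf", "tumor", "ptbe")]),
    file.path(out, "phantom_results.json"), auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  manifest <- list(seed = config$seed,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   files = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest[c("seed", "files")],
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(alps = alps, volumes = vols, cohort = cohort,
                 report = report, manifest = manifest))
}
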