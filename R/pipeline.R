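#' Pipeline run configuration
#'
#' Bundles everything a full run needs: either a `simulate` block (a
#' [cohort_design()]) or input paths (a cohort directory in the layout of
#' [write_cohort()]), the sparsity grid, the graph flavors, the null-model
#' settings, statistics options, the output directory and a base seed.
#' Exactly one of `simulate` / `input_dir` must be given.
#'
#' @param simulate a [cohort_design()], or `NULL` to read data from disk.
#' @param input_dir cohort directory with per-subject time-series CSVs,
#'   `phenotype.csv` and optionally `cytokines.csv`.
#' @param out_dir output directory for all artifacts.
#' @param grid a [sparsity_grid()].
#' @param flavors subset of `c("binary", "weighted")`.
#' @param null_config a [null_model_config()].
#' @param alpha FDR-corrected significance level.
#' @param covariates partial-correlation covariates.
#' @param seed base seed; every random stage derives its own stream from it.
#' @param verbose log per-stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL, out_dir = "swtopo_run",
                       grid = sparsity_grid(),
                       flavors = c("binary", "weighted"),
                       null_config = null_model_config(),
                       alpha = 0.05,
                       covariates = c("age", "sex", "education"),
                       seed = 1, verbose = TRUE) {
  if (is.null(simulate) == is.null(input_dir))
    stop("exactly one of `simulate` and `input_dir` must be given")
  flavors <- match.arg(flavors, c("binary", "weighted"), several.ok = TRUE)
  if (length(flavors) == 0) stop("at least one flavor is required")
  structure(list(simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, grid = grid, flavors = flavors,
                 null_config = null_config, alpha = alpha,
                 covariates = covariates, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors [run_config()]: top-level keys `simulate` (a
#' [cohort_design()] argument list) or `input_dir`, plus optional `out_dir`,
#' `grid` (`start`/`stop`/`step`), `flavors`, `null_model`
#' (`n_random`/`n_swaps_per_edge`), `alpha`, `covariates`, `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  simulate <- if (!is.null(raw$simulate))
    do.call(cohort_design, raw$simulate) else NULL
  grid <- if (!is.null(raw$grid)) do.call(sparsity_grid, raw$grid)
          else sparsity_grid()
  null_cfg <- if (!is.null(raw$null_model))
    do.call(null_model_config, raw$null_model) else null_model_config()
  args <- list(simulate = simulate, input_dir = raw$input_dir, grid = grid,
               null_config = null_cfg)
  for (k in c("out_dir", "flavors", "alpha", "covariates", "seed",
              "verbose"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(run_config, args)
}

#' Connectivity matrices for every subject of a cohort
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @return named list of [connectivity_matrix()] objects.
#' @export
cohort_connectivity <- function(cohort) {
  out <- lapply(names(cohort$timeseries), function(id) {
    tryCatch(
      pearson_connectivity(timeseries_panel(cohort$timeseries[[id]],
                                            subject_id = id)),
      error = function(e) stop("connectivity failed for subject ", id, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  names(out) <- names(cohort$timeseries)
  out
}

#' Run the full pipeline: simulate/load, connectivity, metrics, statistics
#'
#' Executes every stage for each requested flavor and writes all artifacts
#' under `config$out_dir`: per-flavor subject metrics CSVs, per-flavor study
#' reports, a binary/weighted sign-concordance table when both flavors run,
#' and `manifest.json` recording the configuration, seeds, package version,
#' per-stage timings and output files. Rerunning the same configuration
#' reproduces all numeric outputs exactly.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_msg <- function(...) if (config$verbose) message("[swtopo] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    log_msg("stage: ", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    out
  }

  cohort <- stage("data", {
    if (!is.null(config$simulate)) {
      design <- config$simulate
      design$seed <- derive_seed(config$seed, "simulate", design$seed)
      generate_cohort(design)
    } else {
      read_cohort(config$input_dir)
    }
  })
  conns <- stage("connectivity", cohort_connectivity(cohort))

  metric_files <- character(0)
  report_files <- character(0)
  metric_tables <- list()
  reports <- list()
  for (fl in config$flavors) {
    metric_tables[[fl]] <- stage(paste0("metrics_", fl), {
      cohort_metrics(conns, config$grid, fl, config$null_config,
                     base_seed = derive_seed(config$seed, "nulls"),
                     verbose = config$verbose)
    })
    mf <- file.path(config$out_dir, paste0("subject_metrics_", fl, ".csv"))
    write_subject_metrics(metric_tables[[fl]], mf)
    metric_files <- c(metric_files, mf)
    reports[[fl]] <- stage(paste0("statistics_", fl), {
      run_study_statistics(metric_tables[[fl]], cohort$phenotype,
                           cohort$cytokines, alpha = config$alpha,
                           covariates = config$covariates)
    })
    rd <- file.path(config$out_dir, paste0("report_", fl))
    write_study_report(reports[[fl]], rd)
    report_files <- c(report_files, rd)
  }

  concordance <- NULL
  if (all(c("binary", "weighted") %in% names(reports))) {
    concordance <- stage("concordance", {
      b <- reports$binary$global
      w <- reports$weighted$global
      data.frame(variable = b$variable,
                 binary_statistic = b$statistic,
                 weighted_statistic = w$statistic[match(b$variable,
                                                        w$variable)],
                 sign_concordant = sign(b$statistic) ==
                   sign(w$statistic[match(b$variable, w$variable)]),
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(concordance,
                     file.path(config$out_dir, "flavor_concordance.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "swtopo",
    version = as.character(utils::packageVersion("swtopo")),
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    config = list(
      simulated = !is.null(config$simulate),
      input_dir = config$input_dir,
      grid = list(start = attr(config$grid, "start"),
                  stop = attr(config$grid, "stop"),
                  step = attr(config$grid, "step"),
                  n_thresholds = length(config$grid)),
      flavors = config$flavors,
      null_model = unclass(config$null_config),
      alpha = config$alpha,
      covariates = config$covariates,
      simulate = if (!is.null(config$simulate)) {
        s <- unclass(config$simulate)
        s[!vapply(s, is.null, logical(1))]
      }),
    n_subjects = length(conns),
    timings_sec = timings,
    outputs = c(metric_files, report_files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done in ",
          round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  invisible(c(manifest,
              list(metrics = metric_tables, reports = reports,
                   concordance = concordance)))
}

#' Head-motion quality-control flags
#'
#' Flags subjects whose motion summary strictly exceeds any of the
#' conventional exclusion thresholds: 2 mm maximum displacement, 2 degrees
#' maximum rotation, or 0.2 mm mean frame-wise displacement. Motion is
#' metadata here — the pipeline starts at ROI time series — so this helper
#' only produces an exclusion list.
#'
#' @param motion data frame with columns `subject_id`, `max_displacement`
#'   (mm), `max_rotation` (degrees), `mean_fd` (mm).
#' @param max_displacement,max_rotation,mean_fd exclusion thresholds.
#' @return character vector of excluded subject ids (empty for an empty
#'   table).
#' @export
qc_motion_flags <- function(motion, max_displacement = 2, max_rotation = 2,
                            mean_fd = 0.2) {
  required <- c("subject_id", "max_displacement", "max_rotation", "mean_fd")
  if (!is.data.frame(motion) || !all(required %in% colnames(motion)))
    stop("motion table needs columns: ", paste(required, collapse = ", "))
  if (nrow(motion) == 0) return(character(0))
  bad <- motion$max_displacement > max_displacement |
    motion$max_rotation > max_rotation |
    motion$mean_fd > mean_fd
  motion$subject_id[bad]
}
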