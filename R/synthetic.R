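#' Design of a synthetic two-group connectome cohort
#'
#' Describes the generating model for a patient/control cohort: modular
#' multivariate-normal ROI time series whose patient group has degraded
#' segregation (lower within-module, higher between-module correlation), a
#' 17-analyte serum cytokine panel with designed patient elevations on the
#' log10 scale, and a designed coupling between IL-8 and each patient's own
#' topology-degradation factor. Defaults mirror the study conditions the
#' package is built around: 65 patients / 50 controls, 116 ROIs, 200 time
#' points, a 34/30 cytokine subsample, and elevated IL-8, IL-10, G-CSF,
#' MCP-1 and MIP-1beta in patients.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_rois,n_timepoints dimensions of each subject's ROI-by-time
#'   matrix.
#' @param n_modules number of correlation modules; when it does not divide
#'   `n_rois`, earlier modules take the extra nodes, in label order.
#' @param within_module_r,between_module_r control-group correlations inside
#'   and between modules; require `within_module_r > between_module_r >= 0`.
#' @param patient_segregation_delta mean of the per-patient degradation
#'   factor `d`: a patient's within-module correlation is reduced by `d` and
#'   the between-module correlation increased by `d/3`.
#' @param segregation_sd standard deviation of the per-patient degradation
#'   factor (truncated so covariances stay valid).
#' @param ar1_phi optional AR(1) temporal autocorrelation of the innovations
#'   (0 = temporally white, the default; Pearson connectivity depends only
#'   on the spatial covariance).
#' @param cytokine_names ordered labels of the 17-analyte panel.
#' @param cytokine_log_means baseline log10 concentration means, one per
#'   analyte.
#' @param cytokine_log_sd log10-scale standard deviation shared by analytes.
#' @param elevated_cytokines analytes shifted upward in patients.
#' @param cytokine_shift patient log10 mean shift for elevated analytes.
#' @param il8_topology_coupling designed correlation in `[-1, 1]` between
#'   log10 IL-8 and topology integrity among patients: negative values (the
#'   default) make IL-8 co-vary positively with each patient's own
#'   degradation factor while keeping the IL-8 marginal SD at
#'   `cytokine_log_sd`, so that IL-8 correlates negatively with small-world
#'   segregation by construction. 0 disables the coupling.
#' @param n_cytokine_patients,n_cytokine_controls size of the cytokine
#'   subsample per group (capped at the group size).
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   design.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 65, n_controls = 50,
                          n_rois = 116, n_timepoints = 200,
                          n_modules = 4,
                          within_module_r = 0.3, between_module_r = 0.05,
                          patient_segregation_delta = 0.15,
                          segregation_sd = 0.05,
                          ar1_phi = 0,
                          cytokine_names = cytokine_panel(),
                          cytokine_log_means = NULL,
                          cytokine_log_sd = 0.25,
                          elevated_cytokines = c("IL-8", "IL-10", "G-CSF",
                                                 "MCP-1", "MIP-1beta"),
                          cytokine_shift = 0.2,
                          il8_topology_coupling = -0.5,
                          n_cytokine_patients = 34, n_cytokine_controls = 30,
                          seed = 1) {
  if (length(cytokine_names) != 17)
    stop("cytokine_names must have exactly 17 entries")
  if (anyDuplicated(cytokine_names)) stop("cytokine_names must be unique")
  if (!(within_module_r > between_module_r && between_module_r >= 0 &&
        within_module_r < 1))
    stop("require within_module_r > between_module_r >= 0 (and < 1), got ",
         within_module_r, " / ", between_module_r)
  if (!all(elevated_cytokines %in% cytokine_names))
    stop("elevated_cytokines must be a subset of cytokine_names")
  if (is.null(cytokine_log_means))
    cytokine_log_means <- stats::setNames(
      c(0.9, 0.6, 0.5, 0.4, 0.8, 1.0, 1.1, 0.7, 1.2, 0.5, 0.6, 1.3, 0.4,
        1.0, 1.9, 1.8, 1.1), cytokine_names)
  if (length(cytokine_log_means) != 17)
    stop("cytokine_log_means must have one entry per analyte")
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)")
  if (abs(il8_topology_coupling) > 1)
    stop("il8_topology_coupling is a correlation and must lie in [-1, 1]")
  design <- list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 n_modules = as.integer(n_modules),
                 within_module_r = within_module_r,
                 between_module_r = between_module_r,
                 patient_segregation_delta = patient_segregation_delta,
                 segregation_sd = segregation_sd,
                 ar1_phi = ar1_phi,
                 cytokine_names = as.character(cytokine_names),
                 cytokine_log_means = stats::setNames(
                   as.numeric(cytokine_log_means), cytokine_names),
                 cytokine_log_sd = cytokine_log_sd,
                 elevated_cytokines = as.character(elevated_cytokines),
                 cytokine_shift = cytokine_shift,
                 il8_topology_coupling = il8_topology_coupling,
                 n_cytokine_patients = as.integer(min(n_cytokine_patients,
                                                      n_patients)),
                 n_cytokine_controls = as.integer(min(n_cytokine_controls,
                                                      n_controls)),
                 seed = as.integer(seed))
  # the control covariance must factorize before any data is drawn
  module_covariance(design$n_rois, design$n_modules,
                    within_module_r, between_module_r)
  structure(design, class = "cohort_design")
}

#' The 17-analyte serum cytokine panel
#'
#' Standard Bio-Plex 17-plex analyte labels (ASCII spellings of the Greek
#' letters).
#'
#' @return character vector of 17 analyte names.
#' @export
cytokine_panel <- function() {
  c("IL-1beta", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-10",
    "IL-12", "IL-13", "IL-17", "G-CSF", "GM-CSF", "IFN-gamma", "MCP-1",
    "MIP-1beta", "TNF-alpha")
}

# Module assignment: earlier modules absorb the remainder, in label order.
module_assignment <- function(n_rois, n_modules) {
  base <- n_rois %/% n_modules
  extra <- n_rois %% n_modules
  sizes <- rep(base, n_modules) + c(rep(1, extra), rep(0, n_modules - extra))
  rep(seq_len(n_modules), times = sizes)
}

# Block compound-symmetry correlation matrix; fails by name if the
# requested parameters do not give a positive-definite matrix.
module_covariance <- function(n_rois, n_modules, within, between) {
  mod <- module_assignment(n_rois, n_modules)
  sigma <- matrix(between, n_rois, n_rois)
  for (m in seq_len(n_modules)) {
    idx <- which(mod == m)
    sigma[idx, idx] <- within
  }
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("requested covariance is not positive definite ",
         "(within_module_r = ", within, ", between_module_r = ", between,
         ", n_modules = ", n_modules, ")")
  list(sigma = sigma, chol = ch, modules = mod)
}

# Normal draws truncated to [lo, hi] by rejection (bounds are generous in
# all uses, so iteration counts stay small).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# One subject's ROI x time matrix from a covariance Cholesky factor,
# optionally with AR(1) temporal structure in the innovations (spatial
# covariance is unchanged: the AR filter is variance-preserving).
draw_timeseries <- function(chol_sigma, n_rois, n_timepoints, phi) {
  z <- matrix(stats::rnorm(n_rois * n_timepoints), n_rois, n_timepoints)
  if (phi != 0) {
    scale <- sqrt(1 - phi^2)
    for (t in 2:n_timepoints) z[, t] <- phi * z[, t - 1] + scale * z[, t]
  }
  t(chol_sigma) %*% z
}

#' Generate a synthetic two-group cohort
#'
#' Draws ROI time series, phenotype and cytokine tables from a
#' [cohort_design()]. Controls share one modular covariance; each patient
#' gets a personal degradation factor `d >= 0` (truncated normal around
#' `patient_segregation_delta`) that lowers within-module and raises
#' between-module correlation, so subject-level topology varies and the
#' IL-8 coupling is estimable. Patients satisfy the clinical inclusion
#' pattern (HDRS > 20, YMRS < 7). All draws are governed by `design$seed`.
#'
#' @param design a [cohort_design()].
#' @return an object of class `synthetic_cohort`: list with `timeseries`
#'   (named list of ROI-by-time matrices), `phenotype` (data frame),
#'   `cytokines` (data frame over the measured subsample, linear scale) and
#'   `truth` (generating parameters, incl. per-patient degradation factors).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  labels <- paste0("ROI", seq_len(d$n_rois))
  ctrl <- module_covariance(d$n_rois, d$n_modules, d$within_module_r,
                            d$between_module_r)
  with_seed(d$seed, {
    ids <- c(sprintf("P%03d", seq_len(d$n_patients)),
             sprintf("C%03d", seq_len(d$n_controls)))
    group <- rep(c("patient", "control"), c(d$n_patients, d$n_controls))

    # per-patient degradation factor, truncated so the patient covariance
    # keeps within >= between (a block compound-symmetry matrix loses
    # definiteness when the between-module correlation overtakes the
    # within-module one); the factorization re-checks each subject anyway
    d_max <- max(0, (d$within_module_r - d$between_module_r) * 3 / 4 - 1e-3)
    degradation <- stats::setNames(rep(0, length(ids)), ids)
    if (d$patient_segregation_delta == 0 && d$segregation_sd == 0) {
      # exact null design: both groups share one generating model
    } else {
      degradation[group == "patient"] <-
        rtruncnorm(d$n_patients, d$patient_segregation_delta,
                   max(d$segregation_sd, 1e-12), 0, max(d_max, 0))
    }

    timeseries <- vector("list", length(ids))
    names(timeseries) <- ids
    for (s in seq_along(ids)) {
      if (degradation[s] == 0) {
        ch <- ctrl$chol
      } else {
        cv <- module_covariance(d$n_rois, d$n_modules,
                                d$within_module_r - degradation[s],
                                d$between_module_r + degradation[s] / 3)
        ch <- cv$chol
      }
      x <- draw_timeseries(ch, d$n_rois, d$n_timepoints, d$ar1_phi)
      rownames(x) <- labels
      timeseries[[s]] <- x
    }

    n <- length(ids)
    is_pat <- group == "patient"
    age <- round(rtruncnorm(n, 27, 8, 18, 55), 1)
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male")
    education <- round(rtruncnorm(n, 13, 3, 6, 20))
    hdrs <- ifelse(is_pat, 21L + stats::rpois(n, 6), stats::rpois(n, 2))
    ymrs <- ifelse(is_pat, pmin(stats::rpois(n, 2), 6L), pmin(stats::rpois(n, 1), 6L))
    onset <- rep(NA_real_, n)
    onset[is_pat] <- round(pmin(rtruncnorm(sum(is_pat), 22, 5, 16, 54),
                                age[is_pat] - 0.5), 1)
    duration <- round(age - onset, 1)
    episodes <- rep(NA_integer_, n)
    episodes[is_pat] <- 1L + stats::rpois(sum(is_pat), 2)
    phenotype <- data.frame(subject_id = ids, group = group, age = age,
                            sex = sex, education = education,
                            HDRS = as.integer(hdrs), YMRS = as.integer(ymrs),
                            onset_age = onset, n_episodes = episodes,
                            illness_duration = duration,
                            stringsAsFactors = FALSE)

    measured <- c(ids[is_pat][seq_len(d$n_cytokine_patients)],
                  ids[!is_pat][seq_len(d$n_cytokine_controls)])
    # degradation factor of the measured patients, standardized by its
    # realized moments so truncation cannot leak into the IL-8 group mean
    z_deg <- rep(0, length(measured))
    pat_measured <- measured[measured %in% ids[is_pat]]
    if (length(pat_measured) > 1) {
      dm <- degradation[pat_measured]
      if (stats::sd(dm) > 0)
        z_deg[match(pat_measured, measured)] <- (dm - mean(dm)) / stats::sd(dm)
    }
    log10_conc <- matrix(NA_real_, length(measured), 17,
                         dimnames = list(measured, d$cytokine_names))
    for (k in seq_len(17)) {
      name <- d$cytokine_names[k]
      mu <- rep(d$cytokine_log_means[k], length(measured))
      if (name %in% d$elevated_cytokines)
        mu <- mu + ifelse(measured %in% ids[is_pat], d$cytokine_shift, 0)
      if (name == "IL-8" && d$il8_topology_coupling != 0) {
        # variance-preserving: corr(log10 IL-8, degradation) is the designed
        # coupling (sign-flipped, since degradation is anti-topology)
        cc <- -d$il8_topology_coupling
        log10_conc[, k] <- mu + d$cytokine_log_sd *
          (cc * z_deg + sqrt(1 - cc^2) * stats::rnorm(length(measured)))
      } else {
        log10_conc[, k] <- stats::rnorm(length(measured), mu,
                                        d$cytokine_log_sd)
      }
    }
    cytokines <- data.frame(subject_id = measured,
                            10^log10_conc, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE)

    structure(list(timeseries = timeseries, phenotype = phenotype,
                   cytokines = cytokines,
                   truth = list(design = unclass(d),
                                degradation = degradation,
                                modules = ctrl$modules,
                                node_labels = labels,
                                measured_subjects = measured)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  g <- table(x$phenotype$group)
  cat("<synthetic_cohort>", g[["patient"]], "patients /", g[["control"]],
      "controls;", nrow(x$timeseries[[1]]), "ROIs x",
      ncol(x$timeseries[[1]]), "time points;",
      nrow(x$cytokines), "cytokine-measured subjects\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' One time-series CSV per subject (rows = time points, header = ROI
#' labels), `phenotype.csv`, `cytokines.csv` and `truth.json`. Existing
#' files are never clobbered unless `overwrite = TRUE`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @param overwrite allow replacing existing files.
#' @return invisibly, a data frame manifest of written files.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(paste0(names(cohort$timeseries), ".csv"),
             "phenotype.csv", "cytokines.csv", "truth.json")
  paths <- file.path(dir, files)
  if (!overwrite && any(file.exists(paths)))
    stop("refusing to overwrite existing files: ",
         paste(basename(paths[file.exists(paths)]), collapse = ", "),
         " (set overwrite = TRUE)")
  for (id in names(cohort$timeseries)) {
    m <- t(cohort$timeseries[[id]])
    utils::write.csv(as.data.frame(m), file.path(dir, paste0(id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$cytokines, file.path(dir, "cytokines.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(data.frame(
    file = files,
    type = c(rep("timeseries", length(cohort$timeseries)),
             "phenotype", "cytokines", "truth"),
    stringsAsFactors = FALSE))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-subject CSVs, `phenotype.csv`,
#'   `cytokines.csv` and optionally `truth.json`.
#' @return a `synthetic_cohort`-shaped list (the `truth` element is `NULL`
#'   when `truth.json` is absent, e.g. for real data laid out the same way).
#' @export
read_cohort <- function(dir) {
  phenotype <- utils::read.csv(file.path(dir, "phenotype.csv"),
                               check.names = FALSE, stringsAsFactors = FALSE)
  cy_path <- file.path(dir, "cytokines.csv")
  cytokines <- if (file.exists(cy_path))
    utils::read.csv(cy_path, check.names = FALSE, stringsAsFactors = FALSE)
  else NULL
  timeseries <- lapply(phenotype$subject_id, function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(p)) stop("missing time-series file for subject ", id)
    df <- utils::read.csv(p, check.names = FALSE)
    t(as.matrix(df))
  })
  names(timeseries) <- phenotype$subject_id
  tr_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(tr_path)) jsonlite::read_json(tr_path,
                                                         simplifyVector = TRUE)
  else NULL
  structure(list(timeseries = timeseries, phenotype = phenotype,
                 cytokines = cytokines, truth = truth),
            class = "synthetic_cohort")
}
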