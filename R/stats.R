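#' Normality-gated choice of two-group test
#'
#' Applies a Kolmogorov-Smirnov test of normality to each group (against a
#' normal with moment-estimated mean and SD, i.e. without the Lilliefors
#' small-sample correction; the corrected variant is available via
#' `lilliefors = TRUE` and requires the `nortest` package). If neither group
#' rejects normality at `alpha`, the independent-sample t-test is chosen;
#' otherwise the Mann-Whitney U test. The uncorrected KS gate is
#' anticonservative as a normality test (it under-rejects), which biases the
#' gate toward the t-test; this matches common practice in the field and is
#' documented rather than silently corrected.
#'
#' @param x,y numeric samples for the two groups (each n >= 4).
#' @param alpha gate level.
#' @param lilliefors use the Lilliefors-corrected test instead.
#' @return `"t"` or `"mann-whitney"`.
#' @export
normality_gate <- function(x, y, alpha = 0.05, lilliefors = FALSE) {
  if (length(x) < 4 || length(y) < 4)
    stop("normality gate needs at least 4 observations per group")
  pval <- function(v) {
    if (lilliefors) {
      if (!requireNamespace("nortest", quietly = TRUE))
        stop("lilliefors = TRUE requires the nortest package")
      nortest::lillie.test(v)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
    }
  }
  if (pval(x) > alpha && pval(y) > alpha) "t" else "mann-whitney"
}

# Tie-corrected Mann-Whitney normal approximation reported as a z
# statistic, the form in which such comparisons are conventionally printed.
mann_whitney_z <- function(x, y, continuity = FALSE) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(r)
  tie_term <- sum(nt^3 - nt)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) stop("all values tied: Mann-Whitney variance is zero")
  dev <- u - mu
  if (continuity) dev <- sign(dev) * max(0, abs(dev) - 0.5)
  z <- dev / sqrt(sig2)
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)), U = u)
}

#' Two-group comparison with the gated test
#'
#' Runs the test selected by [normality_gate()] (or forced via `choice`).
#' The t branch is the equal-variance independent-sample t-test, reported
#' with its t statistic, mean and SD per group. The Mann-Whitney branch is
#' reported via the tie-corrected normal-approximation z statistic (no
#' continuity correction by default), with median and quartiles per group;
#' `exact = TRUE` switches the p-value to the exact U distribution for small
#' untied samples.
#'
#' @inheritParams normality_gate
#' @param choice `NULL` (gate decides), `"t"` or `"mann-whitney"`.
#' @param variable label carried into the result.
#' @param exact exact Mann-Whitney p instead of the z approximation.
#' @param continuity apply the 0.5 continuity correction to z.
#' @param var_equal pooled-variance t-test (the conventional
#'   "independent-sample t-test"); set `FALSE` for Welch.
#' @return a `group_comparison` list: `variable`, `test`, `statistic`, `p`,
#'   and per-group summaries in the style matching the test.
#' @export
compare_groups <- function(x, y, choice = NULL, variable = "value",
                           exact = FALSE, continuity = FALSE,
                           var_equal = TRUE, alpha = 0.05,
                           lilliefors = FALSE) {
  if (is.null(choice)) choice <- normality_gate(x, y, alpha, lilliefors)
  choice <- match.arg(choice, c("t", "mann-whitney"))
  if (choice == "t") {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    res <- list(variable = variable, test = "t",
                statistic = unname(tt$statistic), p = tt$p.value,
                summary = data.frame(
                  group = c("x", "y"),
                  mean = c(mean(x), mean(y)),
                  sd = c(stats::sd(x), stats::sd(y))))
  } else {
    mw <- mann_whitney_z(x, y, continuity)
    p <- mw$p
    if (exact) {
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value)
    }
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    qx <- qs(x); qy <- qs(y)
    res <- list(variable = variable, test = "mann-whitney",
                statistic = mw$statistic, p = p, U = mw$U,
                summary = data.frame(
                  group = c("x", "y"),
                  median = c(qx[2], qy[2]),
                  q25 = c(qx[1], qy[1]),
                  q75 = c(qx[3], qy[3])))
  }
  structure(res, class = "group_comparison")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, input order
#' preserved (a thin, validating wrapper over `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after each is regressed on an
#' intercept plus the covariates; the p-value comes from the t distribution
#' with `n - 2 - k` degrees of freedom (k = number of covariates),
#' two-tailed. With no covariates this is exactly the plain Pearson
#' correlation test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix/data frame with one row per
#'   observation, or `NULL`.
#' @return a `partial_correlation` list: `r`, `p`, `n`, `df`, `covariates`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (is.null(covariates)) {
    cm <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    if (nrow(cm) != n) stop("covariates must have one row per observation")
  }
  k <- ncol(cm)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  design <- cbind(`(intercept)` = 1, cm)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[-seq_len(qr_d$rank)]
    stop("covariates are rank deficient with the intercept: ",
         paste(bad, collapse = ", "))
  }
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("a variable is perfectly explained by the covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p = p, n = n, df = df,
                 covariates = colnames(cm)),
            class = "partial_correlation")
}

# One family of group comparisons -> Table-2/3 style data frame.
comparison_table <- function(values, group, variables,
                             alpha = 0.05, lilliefors = FALSE) {
  rows <- lapply(variables, function(v) {
    x <- values[group == "patient", v]
    y <- values[group == "control", v]
    cmp <- compare_groups(x, y, variable = v, alpha = alpha,
                          lilliefors = lilliefors)
    if (cmp$test == "t") {
      data.frame(variable = v, test = "t",
                 patient_summary = sprintf("%.4g (%.4g)", cmp$summary$mean[1],
                                           cmp$summary$sd[1]),
                 control_summary = sprintf("%.4g (%.4g)", cmp$summary$mean[2],
                                           cmp$summary$sd[2]),
                 statistic = cmp$statistic, p = cmp$p,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, test = "mann-whitney",
                 patient_summary = sprintf("%.4g [%.4g-%.4g]",
                                           cmp$summary$median[1],
                                           cmp$summary$q25[1],
                                           cmp$summary$q75[1]),
                 control_summary = sprintf("%.4g [%.4g-%.4g]",
                                           cmp$summary$median[2],
                                           cmp$summary$q25[2],
                                           cmp$summary$q75[2]),
                 statistic = cmp$statistic, p = cmp$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out
}

#' Full study statistics: group comparisons and partial correlations
#'
#' Reproduces the statistical layer of the analysis: (a) normality-gated
#' two-group comparison of the five global AUC metrics and of every nodal
#' efficiency AUC, FDR-corrected within each family; (b) the same comparison
#' of the 17 base-10 log-transformed cytokines, FDR-corrected across the
#' panel; (c) partial Pearson correlations (controlling for age, sex and
#' education; sex coded 0 = male, 1 = female), restricted to the patient
#' group, between the FDR-significant metrics and both the FDR-significant
#' cytokines and the clinical variables. Correlation p-values are reported
#' uncorrected, with a flag marking which would survive FDR within their
#' family.
#'
#' @param metrics a [cohort_metrics()] table (single flavor).
#' @param phenotype phenotype data frame with `subject_id`, `group`
#'   (`"patient"`/`"control"`), the covariates, and the clinical variables.
#' @param cytokines data frame `subject_id` + 17 analyte columns on the
#'   linear scale (may cover only a subsample of subjects).
#' @param alpha significance level after FDR.
#' @param covariates phenotype columns to control for in correlations.
#' @param clinical_vars clinical phenotype columns correlated with the
#'   significant metrics (patients only).
#' @param lilliefors passed to the normality gate.
#' @return a `study_report` list with elements `global`, `nodal`,
#'   `cytokines` (comparison tables), `correlations`, `alpha`, `n`.
#' @export
run_study_statistics <- function(metrics, phenotype, cytokines = NULL,
                                 alpha = 0.05,
                                 covariates = c("age", "sex", "education"),
                                 clinical_vars = c("HDRS", "YMRS",
                                                   "onset_age", "n_episodes",
                                                   "illness_duration"),
                                 lilliefors = FALSE) {
  metrics <- as.data.frame(metrics)
  orphans <- setdiff(metrics$subject_id, phenotype$subject_id)
  if (length(orphans) > 0)
    stop("metric rows without phenotype: ", paste(orphans, collapse = ", "))
  ph <- phenotype[match(metrics$subject_id, phenotype$subject_id), ]
  group <- ph$group

  global_vars <- c("gamma_auc", "lambda_auc", "sigma_auc", "Eglob_auc",
                   "Eloc_auc")
  nodal_vars <- grep("^Enodal_auc_", colnames(metrics), value = TRUE)
  global_tab <- comparison_table(metrics, group, global_vars, alpha,
                                 lilliefors)
  nodal_tab <- comparison_table(metrics, group, nodal_vars, alpha,
                                lilliefors)

  cyto_tab <- NULL
  log_cyto <- NULL
  if (!is.null(cytokines)) {
    orphans <- setdiff(cytokines$subject_id, phenotype$subject_id)
    if (length(orphans) > 0)
      stop("cytokine rows without phenotype: ",
           paste(orphans, collapse = ", "))
    analytes <- setdiff(colnames(cytokines), "subject_id")
    conc <- as.matrix(cytokines[, analytes, drop = FALSE])
    if (any(conc <= 0)) stop("cytokine concentrations must be positive")
    log_cyto <- data.frame(subject_id = cytokines$subject_id,
                           log10(conc), check.names = FALSE,
                           stringsAsFactors = FALSE)
    cyto_group <- phenotype$group[match(cytokines$subject_id,
                                        phenotype$subject_id)]
    cyto_tab <- comparison_table(log_cyto, cyto_group, analytes, alpha,
                                 lilliefors)
  }

  # correlations in the patient group: significant metrics vs significant
  # cytokines, and significant metrics vs clinical variables
  sig_metrics <- c(global_tab$variable[global_tab$p_fdr < alpha],
                   nodal_tab$variable[nodal_tab$p_fdr < alpha])
  sig_cytos <- if (!is.null(cyto_tab))
    cyto_tab$variable[cyto_tab$p_fdr < alpha] else character(0)

  pat <- ph$group == "patient"
  cov_frame <- ph[, covariates, drop = FALSE]
  if ("sex" %in% colnames(cov_frame))
    cov_frame$sex <- as.numeric(cov_frame$sex %in% c("female", "F", "1", 1))
  cors <- list()
  add_cor <- function(metric_name, other_name, other_values, keep, family) {
    keep <- keep & is.finite(other_values)
    if (sum(keep) < length(covariates) + 4) return(NULL)
    pc <- partial_pearson(metrics[keep, metric_name], other_values[keep],
                          cov_frame[keep, , drop = FALSE])
    data.frame(metric = metric_name, variable = other_name, family = family,
               r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  }
  for (mv in sig_metrics) {
    for (cv in sig_cytos) {
      vals <- rep(NA_real_, nrow(metrics))
      idx <- match(metrics$subject_id, log_cyto$subject_id)
      vals[!is.na(idx)] <- log_cyto[idx[!is.na(idx)], cv]
      cors[[length(cors) + 1]] <- add_cor(mv, cv, vals, pat, "cytokine")
    }
    for (cl in intersect(clinical_vars, colnames(ph))) {
      cors[[length(cors) + 1]] <- add_cor(mv, cl, as.numeric(ph[[cl]]), pat,
                                          "clinical")
    }
  }
  correlations <- if (length(cors) > 0) do.call(rbind, cors) else NULL
  if (!is.null(correlations) && nrow(correlations) > 0) {
    correlations$p_fdr <- NA_real_
    for (fam in unique(correlations$family)) {
      i <- correlations$family == fam
      correlations$p_fdr[i] <- fdr_adjust(correlations$p[i])
    }
    correlations$survives_fdr <- correlations$p_fdr < alpha
  }

  structure(list(global = global_tab, nodal = nodal_tab,
                 cytokines = cyto_tab, correlations = correlations,
                 alpha = alpha,
                 covariates = covariates,
                 n = c(patients = sum(group == "patient"),
                       controls = sum(group == "control"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$n["patients"], "patients vs", x$n["controls"],
      "controls (alpha =", x$alpha, "after FDR)\n\nGlobal AUC metrics:\n")
  print(x$global, digits = 4)
  sig_nodal <- x$nodal[x$nodal$p_fdr < x$alpha, ]
  cat("\nFDR-significant nodal efficiencies:", nrow(sig_nodal), "of",
      nrow(x$nodal), "\n")
  if (nrow(sig_nodal) > 0 && nrow(sig_nodal) <= 20) print(sig_nodal, digits = 4)
  if (!is.null(x$cytokines)) {
    cat("\nCytokines (log10):\n")
    print(x$cytokines, digits = 4)
  }
  if (!is.null(x$correlations)) {
    cat("\nPartial correlations in patients (covariates:",
        paste(x$covariates, collapse = ", "), "):\n")
    print(x$correlations, digits = 4)
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `report.json` plus CSV mirrors of the comparison tables
#' (`global_metrics.csv`, `nodal_metrics.csv`, `cytokines.csv`) and the
#' correlation table (`correlations.csv`).
#'
#' @param report a [run_study_statistics()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$global, "global_metrics.csv")
  wr(report$nodal, "nodal_metrics.csv")
  wr(report$cytokines, "cytokines.csv")
  wr(report$correlations, "correlations.csv")
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, jp))
}
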