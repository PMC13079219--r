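# Shared simulation harness for the calibration / recovery / concordance
# studies. One replicate = generate a cohort, run connectivity -> sparsity
# sweep -> AUC metrics -> group statistics.

sim_grid <- function() sparsity_grid(0.1, 0.4, 0.05)

sim_replicate <- function(seed, n_per_group, n_rois, n_modules,
                          null_cohort = FALSE, flavors = "binary",
                          n_random = 6, with_cytokines = TRUE) {
  args <- list(n_patients = n_per_group, n_controls = n_per_group,
               n_rois = n_rois, n_timepoints = 200, n_modules = n_modules,
               seed = seed)
  if (null_cohort)
    args <- c(args, list(patient_segregation_delta = 0, segregation_sd = 0,
                         cytokine_shift = 0, il8_topology_coupling = 0))
  co <- generate_cohort(do.call(cohort_design, args))
  conns <- cohort_connectivity(co)
  out <- list(cohort = co)
  for (fl in flavors) {
    tbl <- cohort_metrics(conns, sim_grid(), fl,
                          null_model_config(n_random, 10, seed))
    out[[fl]] <- list(
      table = tbl,
      report = run_study_statistics(
        tbl, co$phenotype,
        if (with_cytokines) co$cytokines else NULL))
  }
  out
}

# Patient-group partial correlation between log10 IL-8 and a metric AUC,
# controlling for age, sex and education.
sim_il8_partial_r <- function(rep, metric = "gamma_auc", flavor = "binary") {
  co <- rep$cohort
  tbl <- rep[[flavor]]$table
  ph <- co$phenotype[match(co$cytokines$subject_id,
                           co$phenotype$subject_id), ]
  keep <- ph$group == "patient"
  m <- tbl[match(co$cytokines$subject_id, tbl$subject_id), metric]
  covs <- data.frame(age = ph$age,
                     sex = as.numeric(ph$sex == "female"),
                     education = ph$education)
  partial_pearson(m[keep], log10(co$cytokines[["IL-8"]])[keep],
                  covs[keep, ])$r
}

sim_group_diff <- function(rep, metric, flavor = "binary") {
  tbl <- rep[[flavor]]$table
  grp <- rep$cohort$phenotype$group[match(tbl$subject_id,
                                          rep$cohort$phenotype$subject_id)]
  mean(tbl[grp == "patient", metric]) - mean(tbl[grp == "control", metric])
}
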