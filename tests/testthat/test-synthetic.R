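# Small designs keep the generator tests fast; the acceptance suite runs the
# larger simulation studies.
small_design <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 6, n_controls = 5, n_rois = 20, n_timepoints = 40,
         n_modules = 4, n_cytokine_patients = 6, n_cytokine_controls = 5),
    list(...))
  do.call(cohort_design, args)
}

test_that("cohorts are deterministic in the seed and vary across seeds", {
  a <- generate_cohort(small_design(seed = 5))
  b <- generate_cohort(small_design(seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(small_design(seed = 6))
  expect_false(identical(a$timeseries[[1]], c$timeseries[[1]]))
})

test_that("cohort structure honours the design invariants", {
  co <- generate_cohort(small_design(seed = 1))
  expect_length(co$timeseries, 11)
  for (x in co$timeseries) {
    expect_equal(dim(x), c(20, 40))
    expect_true(all(is.finite(x)))
  }
  ph <- co$phenotype
  pat <- ph[ph$group == "patient", ]
  expect_true(all(pat$HDRS > 20))
  expect_true(all(pat$YMRS < 7))
  expect_true(all(pat$onset_age <= pat$age))
  cyto <- as.matrix(co$cytokines[, -1])
  expect_true(all(cyto > 0))               # log10 always defined
  expect_equal(colnames(co$cytokines)[-1], cytokine_panel())
  expect_length(cytokine_panel(), 17)
})

test_that("empirical within-module correlation converges to the design", {
  d <- cohort_design(n_patients = 1, n_controls = 3, n_rois = 20,
                     n_timepoints = 2000, n_modules = 4,
                     within_module_r = 0.5, between_module_r = 0.1,
                     patient_segregation_delta = 0, segregation_sd = 0,
                     n_cytokine_patients = 1, n_cytokine_controls = 3,
                     seed = 8)
  co <- generate_cohort(d)
  mods <- co$truth$modules
  within <- upper.tri(diag(20)) & outer(mods, mods, `==`)
  between <- upper.tri(diag(20)) & !outer(mods, mods, `==`)
  r_within <- mean(sapply(co$timeseries, function(x) mean(cor(t(x))[within])))
  r_between <- mean(sapply(co$timeseries, function(x) mean(cor(t(x))[between])))
  expect_lt(abs(r_within - 0.5), 0.05)
  expect_lt(abs(r_between - 0.1), 0.05)
})

test_that("modules absorb remainder nodes front-first", {
  d <- small_design(n_rois = 10, n_modules = 3, seed = 2)
  co <- generate_cohort(d)
  expect_equal(unname(table(co$truth$modules)), c(4, 3, 3),
               ignore_attr = TRUE)
})

test_that("degenerate and invalid designs fail loudly", {
  expect_error(small_design(within_module_r = 0.1, between_module_r = 0.2),
               "within_module_r > between_module_r")
  expect_error(small_design(il8_topology_coupling = -2), "correlation")
  expect_error(cohort_design(cytokine_names = letters[1:5]), "17")
})

test_that("patients carry a positive degradation factor, controls none", {
  co <- generate_cohort(small_design(seed = 3))
  deg <- co$truth$degradation
  ph <- co$phenotype
  expect_true(all(deg[ph$subject_id[ph$group == "patient"]] > 0))
  expect_true(all(deg[ph$subject_id[ph$group == "control"]] == 0))
})

test_that("IL-8 tracks the degradation factor with the designed sign", {
  d <- cohort_design(n_patients = 60, n_controls = 5, n_rois = 12,
                     n_timepoints = 10, n_modules = 3,
                     il8_topology_coupling = -0.8,
                     n_cytokine_patients = 60, n_cytokine_controls = 5,
                     seed = 9)
  co <- generate_cohort(d)
  pat_ids <- co$phenotype$subject_id[co$phenotype$group == "patient"]
  il8 <- log10(co$cytokines[match(pat_ids, co$cytokines$subject_id), "IL-8"])
  r <- cor(il8, co$truth$degradation[pat_ids])
  expect_gt(r, 0.5)   # degradation is anti-topology, so coupling flips sign
})

test_that("write_cohort round-trips and refuses to clobber", {
  co <- generate_cohort(small_design(seed = 4))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(sum(manifest$type == "timeseries"), 11)
  expect_error(write_cohort(co, dir), "overwrite")
  back <- read_cohort(dir)
  expect_equal(back$phenotype, co$phenotype)
  expect_equal(back$cytokines, co$cytokines, tolerance = 1e-12)
  for (id in names(co$timeseries))
    expect_equal(back$timeseries[[id]], co$timeseries[[id]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(c("subject_id", "group", "age", "sex", "education",
                    "HDRS", "YMRS", "onset_age", "n_episodes",
                    "illness_duration") %in% colnames(back$phenotype)))
})
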