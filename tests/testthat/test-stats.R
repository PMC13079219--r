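test_that("normality gate keeps the t-test for normal data, drops it for heavy tails", {
  choices_norm <- vapply(1:20, function(s) {
    set.seed(s)
    normality_gate(rnorm(50), rnorm(50))
  }, character(1))
  expect_gte(mean(choices_norm == "t"), 0.85)

  choices_heavy <- vapply(1:20, function(s) {
    set.seed(100 + s)
    normality_gate(exp(rnorm(50, sd = 1.5)), rnorm(50))
  }, character(1))
  expect_gte(mean(choices_heavy == "mann-whitney"), 0.8)

  set.seed(1); x <- rnorm(30); y <- rnorm(30)
  expect_identical(normality_gate(x, y), normality_gate(y, x))
  expect_error(normality_gate(rnorm(3), rnorm(10)), "at least 4")
})

test_that("Mann-Whitney on fully separated tiny groups gives exact p = 0.1", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6), choice = "mann-whitney",
                        exact = TRUE)
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p, 0.1)   # 2 / choose(6, 3)
})

test_that("the z approximation matches the standard normal-approx p-value", {
  set.seed(12)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  cmp <- compare_groups(x, y, choice = "mann-whitney")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-12)
  # label swap flips the statistic sign, not the p-value
  rev <- compare_groups(y, x, choice = "mann-whitney")
  expect_equal(rev$p, cmp$p, tolerance = 1e-12)
  expect_equal(rev$statistic, -cmp$statistic, tolerance = 1e-12)
})

test_that("t branch reports t statistics and handles identical groups", {
  x <- c(1, 2, 3, 4)
  cmp <- compare_groups(x, x, choice = "t")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_groups(rep(1, 5), rep(1, 5), choice = "mann-whitney"),
               "tied")
})

test_that("location shifts cannot shrink the t statistic", {
  set.seed(31)
  x <- rnorm(20); y <- rnorm(20)
  base <- abs(compare_groups(x, y, choice = "t")$statistic)
  for (delta in c(0.5, 1, 2)) {
    shifted <- abs(compare_groups(x + delta, y, choice = "t")$statistic)
    prev <- abs(compare_groups(x + delta - 0.5, y, choice = "t")$statistic)
    expect_gte(shifted + 1e-12, prev)
  }
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(0.03), 0.03)
  set.seed(14)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("partial correlation with no covariates is plain Pearson", {
  set.seed(15)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  pc <- partial_pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(partial_pearson(x, x)$r, 1)
})

test_that("residual and matrix-inversion partial correlations agree", {
  set.seed(16)
  for (rep in 1:10) {
    n <- 30
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- 0.5 * z1 + rnorm(n)
    y <- -0.3 * z1 + 0.2 * z2 + rnorm(n)
    covs <- cbind(z1 = z1, z2 = z2)
    pc <- partial_pearson(x, y, covs)
    # independent route: invert the correlation matrix
    R <- cor(cbind(x, y, covs))
    P <- solve(R)
    r_inv <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(pc$r, r_inv, tolerance = 1e-12)
  }
  # tiny 4-point case, checked against explicitly coded projections
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4); cc <- c(1, 1, 2, 2)
  pc <- partial_pearson(x, y, cbind(c = cc))
  X <- cbind(1, cc)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  rx <- x - H %*% x; ry <- y - H %*% y
  expect_equal(pc$r, as.numeric(cor(rx, ry)), tolerance = 1e-12)
  expect_equal(pc$df, 1)
})

test_that("rank-deficient covariates are rejected by name", {
  x <- rnorm(10); y <- rnorm(10)
  expect_error(partial_pearson(x, y, cbind(z = rep(2, 10))), "rank deficient")
  expect_error(partial_pearson(x[1:4], y[1:4], cbind(a = rnorm(4), b = rnorm(4))),
               "n >")
})

test_that("study statistics join tables by subject and flag orphans", {
  set.seed(18)
  co <- generate_cohort(cohort_design(
    n_patients = 8, n_controls = 8, n_rois = 16, n_timepoints = 60,
    n_modules = 4, n_cytokine_patients = 8, n_cytokine_controls = 8,
    seed = 18))
  tbl <- cohort_metrics(cohort_connectivity(co), sparsity_grid(0.2, 0.4, 0.1),
                        "binary", null_model_config(3, 5, 2))
  report <- run_study_statistics(tbl, co$phenotype, co$cytokines)
  expect_s3_class(report, "study_report")
  expect_equal(nrow(report$global), 5)
  expect_equal(nrow(report$nodal), 16)
  expect_equal(nrow(report$cytokines), 17)
  expect_true(all(report$global$p_fdr >= report$global$p - 1e-15))

  # deterministic: same inputs, same report
  report2 <- run_study_statistics(tbl, co$phenotype, co$cytokines)
  expect_identical(report, report2)

  bad <- tbl
  bad$subject_id[1] <- "GHOST"
  expect_error(run_study_statistics(bad, co$phenotype), "GHOST")
})
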