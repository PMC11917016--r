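# cohort_stats: classification, ANCOVA, Cohen's d, standardized regression,
# Mann-Whitney U, transforms, dichotomization.

test_that("classify_subjects applies the CDR + amyloid predicates", {
  tab <- data.frame(cdr_global = c(0.5, 0, 0, 1, 0.5),
                    abeta_ratio = c(0.04, 0.09, 0.04, 0.05, 0.06))
  labels <- suppressMessages(classify_subjects(tab, cutoff = 0.05))
  expect_identical(labels, c("AD", "HC", NA, "AD", NA))
  # DELCODE-style cutoff: ratio just above 0.08 with CDR 0 -> HC
  expect_identical(
    suppressMessages(classify_subjects(
      data.frame(cdr_global = 0, abeta_ratio = 0.09), cutoff = 0.08)), "HC")
  # boundary is inclusive on the amyloid-positive side
  expect_identical(
    suppressMessages(classify_subjects(
      data.frame(cdr_global = 0.5, abeta_ratio = 0.05), cutoff = 0.05)), "AD")
  # ratio recomputed from components
  tab2 <- data.frame(cdr_global = 0.5, abeta42 = 0.06, abeta40 = 1.5)
  expect_identical(suppressMessages(classify_subjects(tab2, 0.05)), "AD")
  expect_alps_error(classify_subjects(data.frame(cdr_global = 1), 0.05),
                    "alpsdti_missing_data")
  expect_message(classify_subjects(tab, 0.05), "unclassified")
})

test_that("cohens_d matches hand-computed pooled-variance values", {
  # {0,1} vs {2,3}: means 0.5/2.5, pooled var 0.5 -> d = -2/sqrt(0.5)
  expect_equal(cohens_d(c(0, 1), c(2, 3)), -2 / sqrt(0.5), tolerance = 1e-15)
  expect_identical(cohens_d(summary_x = c(1.2, 0.1, 10),
                            summary_y = c(1.2, 0.1, 12)), 0)
  # printed cohort summaries reproduce the printed effect sizes
  d_act <- cohens_d(summary_x = c(1.217, 0.122, 16),
                    summary_y = c(1.356, 0.139, 18))
  expect_lt(abs(d_act - (-1.063)), 0.01)
  d_del <- cohens_d(summary_x = c(1.262, 0.180, 54),
                    summary_y = c(1.336, 0.197, 67))
  expect_lt(abs(d_del - (-0.392)), 0.01)
  expect_alps_error(cohens_d(c(1, 1), c(1, 1)), "alpsdti_undefined_d")
  expect_alps_error(cohens_d(1, c(1, 2)), "alpsdti_insufficient_group")
})

test_that("ANCOVA recovers exact group gaps with orthogonal covariates", {
  # covariates exactly balanced across groups: coefficient = raw gap
  n <- 8L
  tab <- data.frame(group = rep(c("AD", "HC"), each = n),
                    age = rep(c(70, 72, 74, 76, 70, 72, 74, 76), 2),
                    sex = rep(c(0, 1), n))
  delta <- -0.14
  tab$alps <- 1.3 + delta * (tab$group == "AD") + 0.01 * tab$age + 0.2 * tab$sex
  res <- ancova_group(tab, "alps", "group", c("age", "sex"))
  expect_equal(res$coefficient, delta, tolerance = 1e-12)
  expect_equal(res$coefficient, mean(tab$alps[tab$group == "AD"]) -
                 mean(tab$alps[tab$group == "HC"]) , tolerance = 1e-12)
  expect_lt(res$p, 1e-10) # noise-free fit

  # identical groups (mirrored outcomes and covariates): d = 0, p = 1
  set.seed(44)
  tab2 <- tab
  tab2$alps <- rep(rnorm(n, 1.3, 0.1), 2)
  res2 <- ancova_group(tab2, "alps", "group", c("age", "sex"))
  expect_equal(res2$cohens_d, 0, tolerance = 1e-12)
  expect_gt(res2$p, 0.999)

  expect_alps_error(
    ancova_group(tab[c(1, 9:16), ], "alps", "group", c("age", "sex")),
    "alpsdti_insufficient_group")
  tab3 <- tab
  tab3$age <- 70
  tab3$dup <- 1
  expect_alps_error(ancova_group(tab3, "alps", "group", c("age", "dup")),
                    "alpsdti_design_error")
})

test_that("ANCOVA agrees with lm() on unbalanced noisy data", {
  set.seed(12)
  tab <- data.frame(group = rep(c("AD", "HC"), c(13, 19)),
                    age = rnorm(32, 73, 6), sex = rbinom(32, 1, 0.5))
  tab$alps <- 1.3 - 0.1 * (tab$group == "AD") + 0.002 * tab$age +
    rnorm(32, 0, 0.1)
  res <- ancova_group(tab, "alps", "group", c("age", "sex"))
  ref <- summary(stats::lm(alps ~ I(group == "AD") + age + sex, tab))
  expect_equal(res$coefficient, ref$coefficients[2, 1], tolerance = 1e-12)
  expect_equal(res$se, ref$coefficients[2, 2], tolerance = 1e-12)
  expect_equal(res$p, ref$coefficients[2, 4], tolerance = 1e-12)
})

test_that("standardized regression matches the normal-equations oracle", {
  # fixed 6-row fixture
  fix <- data.frame(
    y = c(1.31, 1.12, 1.45, 1.22, 1.38, 1.05),
    x = c(0.042, 0.055, 0.031, 0.060, 0.038, 0.071),
    age = c(71, 68, 75, 80, 66, 73))
  res <- linreg_standardized(fix, "y", "x", "age")
  ora <- normal_eq_standardized(fix, "y", "x", "age")
  expect_equal(res$beta, ora$beta, tolerance = 1e-12)
  expect_equal(res$se, ora$se, tolerance = 1e-12)
  expect_equal(res$adj_r_squared, ora$adj_r2, tolerance = 1e-12)
  expect_lte(res$adj_r_squared, res$r_squared)

  # outcome == predictor -> beta 1, adjusted R^2 1
  ident <- data.frame(y = c(1, 2, 3, 4, 5, 7), x = c(1, 2, 3, 4, 5, 7))
  res_id <- linreg_standardized(ident, "y", "x")
  expect_equal(res_id$beta, 1, tolerance = 1e-12)
  expect_equal(res_id$adj_r_squared, 1, tolerance = 1e-12)

  # orthogonal predictor at large n -> beta near 0
  set.seed(5)
  big <- data.frame(y = rnorm(4000), x = rnorm(4000))
  expect_lt(abs(linreg_standardized(big, "y", "x")$beta), 3 / sqrt(4000))

  expect_alps_error(linreg_standardized(fix[1:3, ], "y", "x", "age"),
                    "alpsdti_design_error")
})

test_that("standardized beta is invariant to affine rescaling", {
  set.seed(21)
  tab <- data.frame(y = rnorm(40), x = rnorm(40), age = rnorm(40, 70, 5),
                    sex = rbinom(40, 1, 0.5))
  base <- linreg_standardized(tab, "y", "x", c("age", "sex"))
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    c2 <- runif(1, 0.1, 10); d2 <- rnorm(1, 0, 50)
    tab2 <- tab
    tab2$y <- a * tab$y + b
    tab2$x <- c2 * tab$x + d2
    res <- linreg_standardized(tab2, "y", "x", c("age", "sex"))
    expect_equal(res$beta, base$beta, tolerance = 1e-10)
    expect_equal(res$adj_r_squared, base$adj_r_squared, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U: exact enumeration, oracle agreement, U + U' = n1 n2", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(res$U, 0)
  expect_equal(res$p, 2 / 6, tolerance = 1e-15)
  expect_identical(res$method, "exact")

  # exact p equals wilcox.test's exact p for tie-free inputs, n1 + n2 <= 8
  set.seed(77)
  for (i in 1:25) {
    nx <- sample(2:5, 1)
    ny <- sample(2:4, 1)
    x <- round(rnorm(nx), 6)
    y <- round(rnorm(ny) + 0.4, 6)
    res <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(res$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    # U + U' symmetry
    expect_equal(res$U + mann_whitney_u(y, x)$U, nx * ny, tolerance = 1e-12)
  }

  # all tied -> U = n1 n2 / 2 by midrank symmetry
  expect_identical(mann_whitney_u(rep(2, 3), rep(2, 5))$U, 7.5)

  # large-sample normal path tracks wilcox.test with continuity correction
  set.seed(8)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  res <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(res$method, "normal")
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_alps_error(mann_whitney_u(numeric(0), 1), "alpsdti_validation_error")
})

test_that("Mann-Whitney p values are near-uniform under the null", {
  set.seed(123)
  ps <- replicate(400, mann_whitney_u(rnorm(12), rnorm(12))$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 1e-3) # discrete p-grid; gross non-uniformity only
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("log transform and dichotomization rules", {
  expect_identical(log_transform_wmh(c(0, 9, 999)), c(0, 1, 3))
  expect_alps_error(log_transform_wmh(-1), "alpsdti_validation_error")

  tab <- data.frame(mmse = c(30, 27, 26, 10), cdr_global = c(0, 0.5, 1, 0))
  expect_identical(as.character(dichotomize(tab, "mmse", "mmse")),
                   c("high", "high", "low", "low"))
  expect_identical(as.character(dichotomize(tab, "cdr_global", "cdr")),
                   c("low", "high", "high", "low"))
  expect_alps_error(dichotomize(tab, "mmse", "median"),
                    "alpsdti_invalid_config")
})
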