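# Cohort-level statistics: amyloid/CDR subject classification, ANCOVA group
# contrasts with Cohen's d, standardized-beta multiple regression,
# Mann-Whitney U tests (exact by enumeration for small tie-free samples,
# tie- and continuity-corrected normal approximation otherwise), and the
# log10(v + 1) transform applied to skewed WMH volumes.

#' Classify subjects into AD and control groups
#'
#' AD: CDR global >= 0.5 and amyloid-positive (CSF Abeta42/40 ratio at or
#' below the cohort cutoff, boundary inclusive). HC: CDR = 0 and ratio above
#' the cutoff. Subjects meeting neither predicate are unclassified (NA) and
#' their count is reported via message.
#'
#' @param table Data frame with `cdr_global` and `abeta_ratio` columns
#'   (ratio recomputed from `abeta42`/`abeta40` when absent).
#' @param cutoff Cohort-specific Abeta42/40 cutoff (0.05 for Elecsys/ELISA
#'   assays in two of the reference cohorts, 0.08 in the third).
#' @return Character vector (`"AD"`, `"HC"`, or `NA`), one per row.
#' @export
classify_subjects <- function(table, cutoff = 0.05) {
  if (is.null(table$abeta_ratio)) {
    if (is.null(table$abeta42) || is.null(table$abeta40))
      abort("need abeta_ratio or abeta42 + abeta40", "alpsdti_missing_data")
    table$abeta_ratio <- table$abeta42 / table$abeta40
  }
  if (is.null(table$cdr_global))
    abort("need cdr_global column", "alpsdti_missing_data")
  lab <- rep(NA_character_, nrow(table))
  lab[table$cdr_global >= 0.5 & table$abeta_ratio <= cutoff] <- "AD"
  lab[table$cdr_global == 0 & table$abeta_ratio > cutoff] <- "HC"
  n_un <- sum(is.na(lab))
  if (n_un > 0L)
    message(n_un, " subject(s) unclassified (dropped from group analyses)")
  lab
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_x - mean_y) / s_pooled`,
#' `s_pooled^2 = ((n_x-1) s_x^2 + (n_y-1) s_y^2) / (n_x + n_y - 2)`.
#'
#' @param x,y Numeric samples (n >= 2 each), or NULL when using summaries.
#' @param summary_x,summary_y Alternatively, `c(mean, sd, n)` summaries.
#' @return Signed d (x minus y).
#' @export
cohens_d <- function(x = NULL, y = NULL, summary_x = NULL, summary_y = NULL) {
  sm <- function(v, s) {
    if (!is.null(v)) c(mean(v), stats::sd(v), length(v)) else as.numeric(s)
  }
  a <- sm(x, summary_x)
  b <- sm(y, summary_y)
  if (a[3] < 2 || b[3] < 2)
    abort("each group needs n >= 2", "alpsdti_insufficient_group")
  sp2 <- ((a[3] - 1) * a[2]^2 + (b[3] - 1) * b[2]^2) / (a[3] + b[3] - 2)
  if (sp2 <= 0)
    abort("zero pooled SD: d undefined", "alpsdti_undefined_d")
  (a[1] - b[1]) / sqrt(sp2)
}

#' ANCOVA group contrast with covariate adjustment
#'
#' Least-squares fit of `outcome ~ group + covariates` with a two-sided t
#' test on the group coefficient; raw (unadjusted) group means, SDs and
#' pooled-SD Cohen's d are reported alongside, matching the convention of
#' printing raw summaries next to the adjusted test.
#'
#' @param table Data frame.
#' @param outcome Outcome column name.
#' @param group Group column name (two levels; the contrast is
#'   first-level minus second-level after sorting, i.e. AD minus HC).
#' @param covariates Character vector of covariate column names.
#' @return A `group_diff_result` list: group summaries, `coefficient`,
#'   `se`, `t`, `p`, `cohens_d`, `n`.
#' @export
ancova_group <- function(table, outcome, group = "group",
                         covariates = c("age", "sex")) {
  cols <- c(outcome, group, covariates)
  tab <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols,
               drop = FALSE]
  g <- factor(tab[[group]])
  if (nlevels(g) != 2L)
    abort("group must have exactly two levels", "alpsdti_design_error")
  if (min(table(g)) < 2L)
    abort("each group needs >= 2 subjects", "alpsdti_insufficient_group")
  # indicator 1 for the first sorted level (AD before HC alphabetically)
  ind <- as.numeric(g == levels(g)[1])
  X <- cbind(1, ind)
  for (cv in covariates) X <- cbind(X, as.numeric(tab[[cv]]))
  colnames(X) <- c("(Intercept)", "group", covariates)
  y <- as.numeric(tab[[outcome]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    abort("rank-deficient ANCOVA design", "alpsdti_design_error")
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- fit$coefficients["group"] / se[2]
  p <- 2 * stats::pt(-abs(tval), df)
  x1 <- y[ind == 1]
  x2 <- y[ind == 0]
  structure(list(
    levels = levels(g),
    mean_1 = mean(x1), sd_1 = stats::sd(x1), n_1 = length(x1),
    mean_2 = mean(x2), sd_2 = stats::sd(x2), n_2 = length(x2),
    coefficient = unname(fit$coefficients["group"]), se = unname(se[2]),
    t = unname(tval), p = unname(p),
    cohens_d = cohens_d(x1, x2), n = length(y)
  ), class = "group_diff_result")
}

#' Multiple linear regression with standardized coefficients
#'
#' The outcome and every continuous predictor are z-scored before the
#' least-squares fit; binary variables (exactly two distinct values) are
#' coded 0/1 and left unscaled. Reports the standardized beta, SE, p for the
#' predictor of interest and the model's adjusted R-squared, with listwise
#' deletion and the n actually used.
#'
#' @param table Data frame.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate column names.
#' @return A `regression_result` list: `beta`, `se`, `t`, `p`,
#'   `r_squared`, `adj_r_squared`, `n`.
#' @export
linreg_standardized <- function(table, outcome, predictor,
                                covariates = character(0)) {
  cols <- c(outcome, predictor, covariates)
  tab <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols,
               drop = FALSE]
  p_terms <- c(predictor, covariates)
  n <- nrow(tab)
  if (n <= length(p_terms) + 2L)
    abort("too few rows for the requested model", "alpsdti_design_error")
  zscore <- function(v) {
    v <- as.numeric(v)
    u <- unique(v)
    if (length(u) == 2L) return(as.numeric(v == max(u))) # binary -> 0/1
    s <- stats::sd(v)
    if (s == 0) abort("constant column in design", "alpsdti_design_error")
    (v - mean(v)) / s
  }
  y <- zscore(tab[[outcome]])
  X <- cbind(`(Intercept)` = rep(1, n))
  for (v in p_terms) X <- cbind(X, zscore(tab[[v]]))
  colnames(X) <- c("(Intercept)", p_terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    abort("rank-deficient regression design", "alpsdti_design_error")
  kap <- kappa(qr.R(qrX), exact = TRUE)
  if (kap > 1e8)
    warning("near-collinear design (condition number ", format(kap), ")")
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qrX))))
  beta <- unname(fit$coefficients[predictor])
  seb <- unname(se[which(colnames(X) == predictor)])
  tval <- beta / seb
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(fit$residuals^2) / tss
  npred <- ncol(X) - 1L
  structure(list(
    beta = beta, se = seb, t = tval, p = 2 * stats::pt(-abs(tval), df),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - npred - 1),
    n = n
  ), class = "regression_result")
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-sided p
#' value is exact by complete enumeration of all group labellings when
#' `n_x + n_y <= 12` and there are no ties, otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (for the first sample), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    abort("both samples must be non-empty", "alpsdti_validation_error")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx + ny <= 12L) {
    p <- mwu_exact_p(U, nx, ny)
    method <- "exact"
  } else {
    N <- nx + ny
    tie_tab <- table(c(x, y))
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = unname(U), p = min(1, unname(p)), method = method)
}

# Exact two-sided p by enumeration of all C(nx+ny, nx) assignments of the
# ranks 1..N to the first group: p = 2 * min(P(U <= u), P(U >= u)), capped
# at 1. Valid only for tie-free data.
mwu_exact_p <- function(u, nx, ny) {
  combos <- utils::combn(nx + ny, nx)
  us <- colSums(combos) - nx * (nx + 1) / 2
  ple <- mean(us <= u)
  pge <- mean(us >= u)
  min(1, 2 * min(ple, pge))
}

#' Log-transform WMH volumes
#'
#' `log10(v + 1)`, the variance-stabilising transform applied to skewed
#' lesion-volume distributions before parametric tests.
#'
#' @param volumes_mm3 Non-negative volumes.
#' @return Transformed values.
#' @export
log_transform_wmh <- function(volumes_mm3) {
  if (any(volumes_mm3 < 0, na.rm = TRUE))
    abort("WMH volumes must be non-negative", "alpsdti_validation_error")
  log10(volumes_mm3 + 1)
}

#' Dichotomize a clinical variable
#'
#' Rules: `"mmse"` - high when MMSE >= 27, low below; `"cdr"` - low when
#' CDR = 0, high when CDR > 0.
#'
#' @param table Data frame.
#' @param variable Column name.
#' @param rule `"mmse"` or `"cdr"`.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
dichotomize <- function(table, variable, rule = c("cdr", "mmse")) {
  rule <- tryCatch(match.arg(rule),
                   error = function(e) abort("unknown dichotomization rule",
                                             "alpsdti_invalid_config"))
  v <- table[[variable]]
  if (is.null(v)) abort("variable not found", "alpsdti_missing_data")
  hi <- switch(rule, mmse = v >= 27, cdr = v > 0)
  factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
}
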