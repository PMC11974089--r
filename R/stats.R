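#' Normality gate for choosing parametric versus rank-based tests
#'
#' Applies the Shapiro-Wilk test within each group; the comparison is
#' treated as parametric only if no group rejects normality at `alpha`.
#' Constant-valued groups (for which Shapiro-Wilk is undefined) route to the
#' nonparametric branch. Groups larger than 5000 are subsampled to 5000 for
#' the test (its implementation limit), deterministically.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  split_vals <- split(values, groups)
  ns <- lengths(split_vals)
  if (any(ns < 3L))
    stop("every group needs n >= 3 for the normality gate (smallest n = ",
         min(ns), ")")
  ps <- vapply(split_vals, function(x) {
    if (length(unique(x)) == 1L) return(0)        # degenerate: nonparametric
    if (length(x) > 5000L) x <- x[round(seq(1, length(x), length.out = 5000L))]
    stats::shapiro.test(x)$p.value
  }, 0)
  if (all(ps >= alpha)) "parametric" else "nonparametric"
}

.summarize_group <- function(x, gate) {
  if (gate == "parametric")
    sprintf("%.3f ± %.3f", mean(x), stats::sd(x))
  else
    sprintf("%.3f(%.3f)", stats::median(x), stats::IQR(x))
}

.comparison_result <- function(variable, groups, summaries, test, statistic,
                               p, n, posthoc = NULL, gate = NA_character_) {
  structure(list(variable = variable, groups = groups,
                 summaries = summaries, test = test,
                 statistic = unname(statistic), p = unname(p), n = n,
                 posthoc = posthoc, gate = gate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$variable, ": ", paste(x$groups, "=", x$summaries, collapse = " vs "),
      "\n  ", x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format.pval(x$p, digits = 3), " (n = ",
      paste(x$n, collapse = "/"), ")\n", sep = "")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Two-group comparison with normality gating
#'
#' Student's pooled-variance t test on the parametric branch (Welch by
#' request), Wilcoxon rank-sum on the nonparametric branch using the normal
#' approximation with tie correction and no continuity correction. Two-tailed.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector.
#' @param gate `"parametric"`, `"nonparametric"`, or `NULL` to decide via
#'   [normality_gate()].
#' @param welch Use Welch's unequal-variance t test on the parametric branch.
#' @param variable Label for reporting.
#' @return A `comparison_result`.
#' @export
compare_two_groups <- function(values, groups, gate = NULL, welch = FALSE,
                               variable = deparse(substitute(values))) {
  force(variable)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) != 2L)
    stop("need exactly 2 groups (found ", nlevels(groups), ")")
  if (is.null(gate)) gate <- normality_gate(values, groups)
  sv <- split(values, groups)
  if (gate == "parametric") {
    ht <- stats::t.test(sv[[1]], sv[[2]], var.equal = !welch)
    test <- if (welch) "Welch t test" else "Student t test"
  } else {
    ht <- stats::wilcox.test(sv[[1]], sv[[2]], exact = FALSE,
                             correct = FALSE)
    test <- "Wilcoxon rank-sum test"
  }
  .comparison_result(variable, levels(groups),
                     vapply(sv, .summarize_group, "", gate = gate),
                     test, ht$statistic, ht$p.value, lengths(sv),
                     gate = gate)
}

# Dunn's z post hoc after Kruskal-Wallis, with tie correction; p raw and
# Holm-adjusted. No installed package provides it, so it is computed from
# the joint ranks directly.
.dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sv <- split(r, groups)
  rbar <- vapply(sv, mean, 0)
  n <- lengths(sv)
  cmb <- utils::combn(names(sv), 2)
  z <- p <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(contrast = paste(cmb[1, ], cmb[2, ], sep = " - "),
             statistic = z, p = p, p_holm = stats::p.adjust(p, "holm"),
             stringsAsFactors = FALSE)
}

#' Multi-group comparison with post hoc tests
#'
#' Parametric branch: one-way ANOVA followed by Fisher's least significant
#' difference (LSD) post hoc — pairwise t tests on the pooled residual mean
#' square with no multiplicity adjustment, which is what LSD means.
#' Nonparametric branch: tie-corrected Kruskal-Wallis followed by Dunn's z
#' tests, whose p-values are reported both raw and Holm-adjusted (Holm
#' recommended). With fewer than 3 groups the call redirects to
#' [compare_two_groups()].
#'
#' @inheritParams compare_two_groups
#' @return A `comparison_result` with a `posthoc` data frame.
#' @export
compare_k_groups <- function(values, groups, gate = NULL,
                             variable = deparse(substitute(values))) {
  force(variable)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 3L)
    return(compare_two_groups(values, groups, gate, variable = variable))
  if (is.null(gate)) gate <- normality_gate(values, groups)
  sv <- split(values, groups)
  if (gate == "parametric") {
    fit <- stats::aov(values ~ groups)
    at <- stats::anova(fit)
    mse <- at["Residuals", "Mean Sq"]
    dfe <- at["Residuals", "Df"]
    m <- vapply(sv, mean, 0); n <- lengths(sv)
    cmb <- utils::combn(names(sv), 2)
    tt <- (m[cmb[1, ]] - m[cmb[2, ]]) /
      sqrt(mse * (1 / n[cmb[1, ]] + 1 / n[cmb[2, ]]))
    ph <- data.frame(contrast = paste(cmb[1, ], cmb[2, ], sep = " - "),
                     statistic = unname(tt),
                     p = unname(2 * stats::pt(-abs(tt), dfe)),
                     stringsAsFactors = FALSE)
    res <- .comparison_result(variable, levels(groups),
                              vapply(sv, .summarize_group, "", gate = gate),
                              "one-way ANOVA + LSD",
                              at["groups", "F value"],
                              at["groups", "Pr(>F)"], n, ph, gate)
  } else {
    ht <- stats::kruskal.test(values, groups)
    res <- .comparison_result(variable, levels(groups),
                              vapply(sv, .summarize_group, "", gate = gate),
                              "Kruskal-Wallis + Dunn", ht$statistic,
                              ht$p.value, lengths(sv),
                              .dunn_posthoc(values, groups), gate)
  }
  res
}

#' Paired hemispheric comparison
#'
#' Two-tailed paired t test on the within-subject differences between the
#' tumor-affected and contralateral hemispheric ALPS indices (or left/right
#' for controls).
#'
#' @param tumor_side,contralateral Numeric vectors, one entry per subject.
#' @param variable Label for reporting.
#' @return A `comparison_result`; `statistic` is the paired t.
#' @export
paired_hemisphere_test <- function(tumor_side, contralateral,
                                   variable = "ALPS index") {
  ok <- is.finite(tumor_side) & is.finite(contralateral)
  d <- tumor_side[ok] - contralateral[ok]
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    # degenerate pairing: constant difference has no sampling variability
    ht <- list(statistic = if (abs(mean(d)) < .Machine$double.eps^0.5) 0
               else sign(mean(d)) * Inf,
               p.value = as.numeric(abs(mean(d)) < .Machine$double.eps^0.5))
  } else ht <- stats::t.test(tumor_side[ok], contralateral[ok], paired = TRUE)
  .comparison_result(variable, c("tumor side", "contralateral"),
                     c(.summarize_group(tumor_side[ok], "parametric"),
                       .summarize_group(contralateral[ok], "parametric")),
                     "paired t test", ht$statistic, ht$p.value, sum(ok))
}

#' Pearson's chi-square test for categorical variables
#'
#' Plain Pearson chi-square without continuity correction; the expected
#' counts are attached to the result.
#'
#' @param tab A contingency table (matrix), or two factors to cross.
#' @param y Second factor when `tab` is a factor.
#' @param variable Label for reporting.
#' @return A `comparison_result` with the expected counts in `posthoc`.
#' @export
chi_square_test <- function(tab, y = NULL, variable = "categorical") {
  if (!is.null(y)) tab <- table(tab, y)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .comparison_result(variable, colnames(tab),
                     apply(tab, 2, paste, collapse = "/"),
                     "Pearson chi-square", ht$statistic, ht$p.value,
                     sum(tab), posthoc = as.data.frame.matrix(ht$expected))
}

#' Spearman rank-correlation matrix
#'
#' Pairwise-complete Spearman correlations (average ranks for ties) with
#' two-tailed p-values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param data A data frame.
#' @param vars Column names to correlate.
#' @return An object of class `spearman_matrix`: list of matrices `r`, `p`,
#'   and `n` (effective pairwise sample sizes).
#' @export
spearman_matrix <- function(data, vars) {
  stopifnot(all(vars %in% names(data)))
  k <- length(vars)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    x <- data[[vars[i]]]; y <- data[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    r[i, j] <- r[j, i] <- rho
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
    nm[i, j] <- nm[j, i] <- n
  }
  diag(nm) <- vapply(vars, function(v) sum(is.finite(data[[v]])), 0)
  structure(list(r = r, p = p, n = nm), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman rank correlations (pairwise complete):\n")
  print(round(x$r, 3))
  cat("p-values:\n")
  print(signif(x$p, 3))
  invisible(x)
}

#' Two-stage regression screen with standardized coefficients
#'
#' Stage 1 fits a simple linear regression of the outcome on each candidate
#' and reports the unstandardized slope, the standardized coefficient
#' (slope after z-scoring outcome and predictor, equal to
#' `b * SD(x) / SD(y)` in the single-predictor case) and its p-value.
#' Stage 2 enters every candidate with stage-1 `p < entry_alpha` into one
#' multivariable ordinary-least-squares fit and reports standardized
#' coefficients from the fully z-scored model. Factor predictors with two
#' levels are coded 0/1 in level order (so grade coded LGG = 0, HGG = 1).
#'
#' @param data A data frame.
#' @param outcome Name of the continuous outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_alpha Stage-2 entry threshold on the stage-1 p-value.
#' @return An object of class `regression_screen`: list with `univariate`
#'   and `multivariate` data frames (columns `term`, `b`, `beta`, `p`, `n`),
#'   `entered`, `outcome` and `entry_alpha`.
#' @export
regression_screen <- function(data, outcome, candidates, entry_alpha = 0.05) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  num <- function(v) {
    x <- data[[v]]
    if (is.character(x)) {
      # tumor grade gets its conventional coding LGG = 0, HGG = 1
      x <- if (setequal(unique(stats::na.omit(x)), c("LGG", "HGG")))
        factor(x, levels = c("LGG", "HGG")) else factor(x)
    }
    if (is.factor(x)) {
      if (nlevels(droplevels(x)) != 2L)
        stop("candidate '", v, "' is categorical with != 2 levels; code it ",
             "numerically or use compare_k_groups()")
      x <- as.numeric(droplevels(x)) - 1
    }
    as.numeric(x)
  }
  y <- as.numeric(data[[outcome]])
  uni <- do.call(rbind, lapply(candidates, function(v) {
    x <- num(v)
    ok <- is.finite(x) & is.finite(y)
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)$coefficients
    data.frame(term = v, b = sm[2, 1],
               beta = sm[2, 1] * stats::sd(x[ok]) / stats::sd(y[ok]),
               p = sm[2, 4], n = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL
  entered <- uni$term[uni$p < entry_alpha]
  multi <- NULL
  if (length(entered)) {
    Xz <- vapply(entered, function(v) num(v), numeric(nrow(data)))
    ok <- stats::complete.cases(Xz) & is.finite(y)
    Xz <- scale(Xz[ok, , drop = FALSE])
    kap <- kappa(cbind(1, Xz), exact = TRUE)
    if (kap > 1e8)
      stop("collinear multivariable design (condition number ",
           format(kap, digits = 3), "); predictors: ",
           paste(entered, collapse = ", "))
    yz <- as.vector(scale(y[ok]))
    fit <- stats::lm(yz ~ Xz)
    sm <- summary(fit)$coefficients
    sdx <- apply(vapply(entered, num, numeric(nrow(data)))[ok, , drop = FALSE],
                 2, stats::sd)
    multi <- data.frame(term = entered,
                        b = sm[-1, 1] * stats::sd(y[ok]) / sdx,
                        beta = sm[-1, 1], p = sm[-1, 4], n = sum(ok),
                        stringsAsFactors = FALSE)
    rownames(multi) <- NULL
  }
  structure(list(univariate = uni, multivariate = multi, entered = entered,
                 outcome = outcome, entry_alpha = entry_alpha),
            class = "regression_screen")
}

#' @export
print.regression_screen <- function(x, ...) {
  cat("Regression screen for ", x$outcome, " (entry alpha = ",
      x$entry_alpha, ")\nUnivariate:\n", sep = "")
  print(x$univariate, row.names = FALSE, digits = 4)
  if (is.null(x$multivariate)) {
    cat("No candidates entered the multivariable stage.\n")
  } else {
    cat("Multivariable (", paste(x$entered, collapse = ", "), "):\n",
        sep = "")
    print(x$multivariate, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Full statistical battery over a cohort table
#'
#' Runs the study's comparison/correlation/regression battery on an
#' `alps_cohort` (or any data frame with the same columns): glioma-control
#' comparisons of the ALPS index and CSF volume, grade and IDH comparisons of
#' all four imaging markers, the three-level glioma-type comparison with post
#' hocs, the paired hemispheric test, the sex chi-square, the Spearman matrix
#' among ALPS and the three volumes (gliomas), and the two-stage regression
#' of the ALPS index on grade, age and Olig-2 (gliomas).
#'
#' @param cohort A cohort data frame (see [simulate_cohort()]).
#' @param entry_alpha Entry threshold for the regression screen.
#' @return An object of class `stat_report`: list of `comparisons` (named
#'   `comparison_result`s), `spearman`, `regression` and `paired`.
#' @export
cohort_report <- function(cohort, entry_alpha = 0.05) {
  g <- cohort[cohort$group == "glioma", , drop = FALSE]
  cmp <- list()
  for (v in c("alps_mean", "csf_volume", "age"))
    cmp[[paste0(v, ".group")]] <-
      compare_two_groups(cohort[[v]], cohort$group, variable = v)
  for (v in c("alps_mean", "csf_volume", "tumor_volume", "ptbe_volume")) {
    cmp[[paste0(v, ".grade")]] <-
      compare_two_groups(g[[v]], g$grade, variable = v)
    cmp[[paste0(v, ".idh")]] <-
      compare_two_groups(g[[v]], g$idh, variable = v)
    cmp[[paste0(v, ".type")]] <-
      compare_k_groups(g[[v]], g$type, variable = v)
  }
  cmp[["sex.group"]] <- chi_square_test(factor(cohort$sex),
                                        factor(cohort$group),
                                        variable = "sex")
  structure(list(
    comparisons = cmp,
    paired = paired_hemisphere_test(g$alps_tumor_side,
                                    g$alps_contralateral),
    spearman = spearman_matrix(g, c("alps_mean", "tumor_volume",
                                    "ptbe_volume", "csf_volume")),
    regression = regression_screen(g, "alps_mean",
                                   c("grade", "age", "olig2"),
                                   entry_alpha)), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("=== Group comparisons ===\n")
  for (r in x$comparisons) print(r)
  cat("=== Paired hemispheres ===\n"); print(x$paired)
  cat("=== Correlations (gliomas) ===\n"); print(x$spearman)
  cat("=== Regression screen ===\n"); print(x$regression)
  invisible(x)
}

#' Write a stat report as TSV tables plus a JSON summary
#'
#' @param report A `stat_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_stat_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
    r <- report$comparisons[[nm]]
    data.frame(contrast = nm, variable = r$variable, test = r$test,
               statistic = r$statistic, p = r$p,
               n = paste(r$n, collapse = "/"),
               summary = paste(r$groups, r$summaries, sep = ": ",
                               collapse = " | "),
               stringsAsFactors = FALSE)
  }))
  paths <- c(comparisons = file.path(dir, "comparisons.tsv"),
             spearman_r = file.path(dir, "spearman_r.tsv"),
             spearman_p = file.path(dir, "spearman_p.tsv"),
             regression = file.path(dir, "regression.tsv"),
             summary = file.path(dir, "report.json"))
  utils::write.table(comp, paths["comparisons"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$spearman$r, paths["spearman_r"], sep = "\t",
                     quote = FALSE)
  utils::write.table(report$spearman$p, paths["spearman_p"], sep = "\t",
                     quote = FALSE)
  reg <- rbind(cbind(stage = "univariate", report$regression$univariate),
               if (!is.null(report$regression$multivariate))
                 cbind(stage = "multivariate", report$regression$multivariate))
  utils::write.table(reg, paths["regression"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    paired = report$paired[c("statistic", "p", "n")],
    entered = report$regression$entered), paths["summary"],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
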