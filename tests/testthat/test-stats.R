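test_that("normality gate routes clean Gaussians and heavy tails correctly", {
  set.seed(1)
  x <- rnorm(300); y <- rnorm(300, 1)
  expect_equal(normality_gate(c(x, y), rep(1:2, each = 300)), "parametric")
  z <- exp(rnorm(200, sd = 1.5))               # heavily log-normal group
  expect_equal(normality_gate(c(x, z), rep(1:2, c(300, 200))),
               "nonparametric")
  # a constant group routes to the rank branch rather than erroring
  expect_equal(normality_gate(c(x, rep(2, 50)), rep(1:2, c(300, 50))),
               "nonparametric")
  expect_error(normality_gate(c(1, 2, 1, 2, 3), c(1, 1, 2, 2, 2)), "n >= 3")
})

test_that("two-group statistics match hand-computed oracles on toy tables", {
  x <- c(5.1, 4.8, 5.6, 5.0, 4.7, 5.3)
  y <- c(4.2, 4.9, 4.0, 4.6, 4.4, 4.1)
  res <- compare_two_groups(c(x, y), rep(c("a", "b"), each = 6),
                            gate = "parametric")
  orc <- oracle_t_pooled(x, y)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-8)
  expect_equal(res$p, orc$p, tolerance = 1e-8)
  expect_match(res$test, "Student")
  # rank-sum branch with ties
  xt <- c(1.2, 3.4, 3.4, 2.2, 5.0, 2.2, 4.1)
  yt <- c(0.5, 2.2, 1.1, 0.9, 3.4)
  resw <- compare_two_groups(c(xt, yt), rep(c("a", "b"), c(7, 5)),
                             gate = "nonparametric")
  orw <- oracle_wilcox_z(xt, yt)
  expect_equal(unname(resw$statistic), orw$statistic, tolerance = 1e-8)
  expect_equal(resw$p, orw$p, tolerance = 1e-8)
  # identical groups: no signal
  resi <- compare_two_groups(rep(c(1, 2, 3, 4), 2), rep(1:2, each = 4),
                             gate = "parametric")
  expect_equal(unname(resi$statistic), 0)
  expect_equal(resi$p, 1)
  expect_error(compare_two_groups(1:5, rep("a", 5)), "2 groups")
})

test_that("three-group parametric path matches ANOVA + LSD oracles", {
  set.seed(3)
  vals <- c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 1.5))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  res <- compare_k_groups(vals, grp, gate = "parametric")
  # omnibus F against aov directly
  ft <- anova(lm(vals ~ grp))
  expect_equal(unname(res$statistic), ft[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p, ft[1, "Pr(>F)"], tolerance = 1e-10)
  # LSD = unadjusted pairwise t on pooled variance
  ptt <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                         pool.sd = TRUE)
  expect_equal(res$posthoc$p[res$posthoc$contrast == "g1 - g2"],
               ptt$p.value["g2", "g1"], tolerance = 1e-10)
  expect_equal(res$posthoc$p[res$posthoc$contrast == "g2 - g3"],
               ptt$p.value["g3", "g2"], tolerance = 1e-10)
  # only contrasts involving the shifted group should be significant
  sig <- res$posthoc$p < 0.05
  expect_equal(sig[res$posthoc$contrast %in% c("g1 - g3", "g2 - g3")],
               c(TRUE, TRUE))
  expect_false(sig[res$posthoc$contrast == "g1 - g2"])
})

test_that("identical groups give a null omnibus and null post hocs", {
  vals <- rep(c(2.0, 2.5, 3.0, 3.5), 3)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- compare_k_groups(vals, grp, gate = "parametric")
  expect_lt(abs(res$statistic), 1e-12)
  expect_true(all(res$posthoc$p > 0.999))
})

test_that("Kruskal-Wallis and Dunn match brute-force rank computation", {
  vals <- c(2.1, 3.3, 2.1, 5.0, 4.4, 4.4, 6.2, 7.0, 5.5, 8.1, 6.2, 9.3)
  grp <- rep(c("lo", "mid", "hi"), each = 4)
  res <- compare_k_groups(vals, grp, gate = "nonparametric")
  expect_equal(unname(res$statistic), oracle_kruskal_h(vals, grp),
               tolerance = 1e-8)
  kt <- kruskal.test(vals, factor(grp))
  expect_equal(unname(res$statistic), unname(kt$statistic),
               tolerance = 1e-10)
  z_oracle <- oracle_dunn_z(vals, grp, "hi", "lo")
  row <- res$posthoc[res$posthoc$contrast == "hi - lo", ]
  expect_equal(row$statistic, z_oracle, tolerance = 1e-8)
  expect_equal(row$p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-8)
  expect_equal(res$posthoc$p_holm,
               p.adjust(res$posthoc$p, "holm"), tolerance = 1e-12)
})

test_that("paired test behaves at the degenerate extremes", {
  x <- c(1.1, 1.4, 1.3, 1.2, 1.5)
  same <- paired_hemisphere_test(x, x)
  expect_true(is.nan(same$statistic) || abs(same$statistic) < 1e-12)
  shifted <- paired_hemisphere_test(x + 0.2, x)
  expect_lt(shifted$p, 1e-6)
  # t statistic equals the hand formula on a fixed toy pairing
  a <- c(1.25, 1.10, 1.32, 1.05, 1.40, 1.22)
  b <- c(1.31, 1.18, 1.30, 1.12, 1.49, 1.27)
  res <- paired_hemisphere_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(unname(res$statistic), t_hand, tolerance = 1e-10)
})

test_that("chi-square matches sum((O-E)^2/E) and the published sex table", {
  tab <- matrix(c(20, 10, 15, 25, 12, 18), 2)
  res <- chi_square_test(tab)
  expect_equal(unname(res$statistic), oracle_chisq(tab), tolerance = 1e-8)
  # perfectly proportional table: statistic exactly 0
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_lt(abs(chi_square_test(prop)$statistic), 1e-12)
  # glioma/control sex split: no association expected
  sex <- matrix(c(63, 49, 29, 27), 2,
                dimnames = list(c("male", "female"),
                                c("glioma", "control")))
  res_sex <- chi_square_test(sex)
  expect_gt(res_sex$p, 0.05)
})

test_that("spearman matrix matches the rank oracle and handles monotonicity", {
  d <- data.frame(x = c(3.1, 1.2, 5.5, 2.2, 4.8, 0.7, 6.3, 2.9),
                  y = c(10, 4, 18, 7, 15, 2, 21, 8),
                  w = c(0.5, 2.5, -3.1, 1.0, -2.0, 3.3, -4.0, 0.9))
  sm <- spearman_matrix(d, c("x", "y", "w"))
  orc <- oracle_spearman(d$x, d$w)
  expect_equal(sm$r["x", "w"], orc$r, tolerance = 1e-8)
  expect_equal(sm$p["x", "w"], orc$p, tolerance = 1e-8)
  expect_equal(sm$r["x", "y"], 1)          # y strictly increasing in x
  d$z <- -d$x^3                            # monotone decreasing transform
  expect_equal(spearman_matrix(d, c("x", "z"))$r["x", "z"], -1)
  # pairwise-complete handling
  d$y[2] <- NA
  sm2 <- spearman_matrix(d, c("x", "y"))
  expect_equal(sm2$n["x", "y"], 7)
})

test_that("regression screen recovers exact and null relationships", {
  d <- data.frame(x = seq(-3, 3, length.out = 40))
  d$y <- -d$x
  rs <- suppressWarnings(regression_screen(d, "y", "x"))  # exact fit
  expect_equal(rs$univariate$beta, -1, tolerance = 1e-10)
  expect_lt(rs$univariate$p, 1e-20)
  # standardized beta equals b * sd(x) / sd(y) in the single-predictor case
  set.seed(11)
  d2 <- data.frame(x = rnorm(60))
  d2$y <- 0.4 * d2$x + rnorm(60)
  rs2 <- regression_screen(d2, "y", "x")
  expect_equal(rs2$univariate$beta,
               rs2$univariate$b * sd(d2$x) / sd(d2$y), tolerance = 1e-10)
  # invariance to affine rescaling of predictor and outcome
  d3 <- d2; d3$x <- 100 * d3$x + 7; d3$y <- 0.01 * d3$y - 2
  rs3 <- regression_screen(d3, "y", "x")
  expect_equal(rs3$univariate$beta, rs2$univariate$beta, tolerance = 1e-10)
  # collinear design is refused
  d4 <- data.frame(a = rnorm(30))
  d4$b <- 2 * d4$a
  d4$y <- d4$a + rnorm(30)
  expect_error(regression_screen(d4, "y", c("a", "b")), "collinear")
})

test_that("null outcomes rarely enter the multivariable stage", {
  set.seed(21)
  empty <- replicate(100, {
    d <- data.frame(y = rnorm(60), a = rnorm(60), b = rnorm(60),
                    c = rnorm(60))
    length(regression_screen(d, "y", c("a", "b", "c"))$entered) == 0
  })
  # P(all three null candidates stay out) = 0.95^3 ~ 0.857
  expect_gt(mean(empty), 0.70)
})

test_that("correlated non-causal predictors attenuate in the joint fit", {
  set.seed(31)
  hits <- replicate(50, {
    x1 <- rnorm(150)
    x2 <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(150)   # correlated, non-causal
    y <- 0.5 * x1 + rnorm(150)
    rs <- regression_screen(data.frame(y = y, x1 = x1, x2 = x2),
                            "y", c("x1", "x2"))
    if (!all(c("x1", "x2") %in% rs$entered)) return(NA)
    m <- rs$multivariate
    u <- rs$univariate
    abs(m$beta[m$term == "x2"]) < abs(u$beta[u$term == "x2"])
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.9)
})

test_that("grade coding runs LGG = 0, HGG = 1 in the screen", {
  set.seed(41)
  n <- 200
  grade <- sample(rep(c("LGG", "HGG"), each = n / 2))
  y <- 1.3 - 0.12 * (grade == "HGG") + rnorm(n, sd = 0.2)
  rs <- regression_screen(data.frame(alps = y, grade = grade),
                          "alps", "grade")
  expect_lt(rs$univariate$beta, 0)   # HGG lowers the outcome
  expect_lt(abs(rs$univariate$b - (-0.12)), 0.09)  # ~3 SE at n = 200
})

test_that("the full cohort battery produces a coherent report", {
  co <- simulate_cohort(seeded_spec(51))
  rep_ <- cohort_report(co)
  expect_s3_class(rep_, "stat_report")
  alps_grp <- rep_$comparisons[["alps_mean.group"]]
  expect_lt(alps_grp$p, 0.05)
  expect_true(all(vapply(rep_$comparisons, function(r)
    r$p >= 0 && r$p <= 1, TRUE)))
  expect_equal(unname(rep_$spearman$n["alps_mean", "tumor_volume"]), 112)
  expect_equal(rep_$comparisons[["alps_mean.type"]]$groups,
               c("astrocytoma", "glioblastoma", "oligodendroglioma"))
  expect_equal(nrow(rep_$comparisons[["alps_mean.type"]]$posthoc), 3)
  paths <- write_stat_report(rep_, tempfile())
  expect_true(all(file.exists(paths)))
})
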