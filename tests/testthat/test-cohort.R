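test_that("log-normal parameters reproduce the printed median and IQR", {
  for (mi in list(c(29.77, 36.79), c(37.48, 65.11), c(20, 25))) {
    p <- lnorm_from_median_iqr(mi[1], mi[2])
    expect_equal(unname(qlnorm(0.5, p[1], p[2])), mi[1], tolerance = 1e-10)
    expect_equal(unname(qlnorm(0.75, p[1], p[2]) - qlnorm(0.25, p[1], p[2])),
                 mi[2], tolerance = 1e-10)
  }
  expect_error(lnorm_from_median_iqr(-1, 2), "positive")
})

test_that("cohorts carry the configured composition exactly", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  g <- co[co$group == "glioma", ]
  ctrl <- co[co$group == "control", ]
  expect_equal(nrow(g), 112)
  expect_equal(nrow(ctrl), 56)
  expect_equal(sum(g$grade == "LGG"), 35)
  expect_equal(sum(g$idh == "mutant"), 36)
  expect_equal(as.integer(table(g$type)[c("astrocytoma", "oligodendroglioma",
                                          "glioblastoma")]), c(44L, 14L, 54L))
  expect_equal(as.integer(table(g$tumor_side)[c("left", "right", "both")]),
               c(60L, 42L, 10L))
  expect_equal(sum(g$sex == "female"), 49)
  expect_equal(sum(ctrl$sex == "female"), 27)
  # glioblastomas are all high grade
  expect_true(all(g$grade[g$type == "glioblastoma"] == "HGG"))
  # controls carry no tumor-specific fields
  expect_true(all(is.na(ctrl$grade)) && all(is.na(ctrl$tumor_volume)))
  # the bilateral mean is exactly the average of the two sides
  expect_equal(g$alps_mean, (g$alps_tumor_side + g$alps_contralateral) / 2)
  expect_true(all(co$alps_mean > 0))
})

test_that("simulation is deterministic per seed and seed-sensitive", {
  expect_identical(simulate_cohort(seeded_spec(9)),
                   simulate_cohort(seeded_spec(9)))
  expect_false(identical(simulate_cohort(seeded_spec(9)),
                         simulate_cohort(seeded_spec(10))))
})

test_that("marginals are recovered within 3 standard errors at n = 10000", {
  spec <- cohort_spec(n_glioma = 10000, n_lgg = 3125, n_control = 10000,
                      n_female = c(4375, 4821),
                      n_idh_mut = 3214,
                      n_types = c(astrocytoma = 3929,
                                  oligodendroglioma = 1250,
                                  glioblastoma = 4821),
                      n_sides = c(left = 5357, right = 3750, both = 893),
                      seed = 31)
  co <- simulate_cohort(spec)
  g <- co[co$group == "glioma", ]
  ctrl <- co[co$group == "control", ]
  se <- function(sd, n) sd / sqrt(n)
  expect_lt(abs(mean(g$alps_mean) - 1.266), 3 * se(0.258, 1e4))
  expect_lt(abs(sd(g$alps_mean) - 0.258), 0.01)
  expect_lt(abs(mean(ctrl$alps_mean) - 1.395), 3 * se(0.174, 1e4))
  expect_lt(abs(mean(g$csf_volume) - 174.53), 3 * se(34.89, 1e4))
  expect_lt(abs(mean(ctrl$csf_volume) - 154.25), 3 * se(20.89, 1e4))
  expect_lt(abs(mean(g$alps_tumor_side) - 1.233), 3 * se(0.297, 1e4))
  expect_lt(abs(mean(g$alps_contralateral) - 1.299), 3 * se(0.296, 1e4))
  expect_lt(abs(sd(g$alps_tumor_side) - 0.2965), 0.01)
  expect_lt(abs(median(g$tumor_volume) - 29.77), 1.5)
  expect_lt(abs(IQR(g$tumor_volume) - 36.79), 2.5)
  expect_lt(abs(median(g$ptbe_volume) - 37.48), 2)
  expect_lt(abs(median(g$ki67) - 20), 1.5)
  expect_lt(abs(mean(g$age) - 52.8), 3 * se(13.1, 1e4))
  # the configured grade contrast emerges in the ALPS means
  expect_lt(mean(g$alps_mean[g$grade == "HGG"]),
            mean(g$alps_mean[g$grade == "LGG"]))
})

test_that("copula rank correlations are recovered within 0.05 at n = 10000", {
  spec <- cohort_spec(n_glioma = 10000, n_lgg = 3125, n_control = 56,
                      n_female = c(4375, 27), n_idh_mut = 3214,
                      n_types = c(astrocytoma = 3929,
                                  oligodendroglioma = 1250,
                                  glioblastoma = 4821),
                      n_sides = c(left = 5357, right = 3750, both = 893),
                      seed = 77)
  g <- simulate_cohort(spec)
  g <- g[g$group == "glioma", ]
  sp <- function(a, b) cor(g[[a]], g[[b]], method = "spearman")
  expect_lt(abs(sp("alps_mean", "tumor_volume") - (-0.353)), 0.05)
  expect_lt(abs(sp("alps_mean", "ptbe_volume") - (-0.266)), 0.05)
  expect_lt(abs(sp("tumor_volume", "ptbe_volume") - 0.427), 0.05)
  expect_lt(abs(sp("alps_mean", "csf_volume")), 0.05)
})

test_that("zero copula and zero paired shift give null structure", {
  spec <- cohort_spec(spearman = c(alps_tumor = 0, alps_ptbe = 0,
                                   tumor_ptbe = 0, alps_csf = 0,
                                   tumor_csf = 0, ptbe_csf = 0),
                      alps_sides = c(1.266, 1.266),
                      alps_side_sd = c(0.29, 0.29),
                      n_glioma = 1000, n_lgg = 313, n_control = 56,
                      n_female = c(438, 27), n_idh_mut = 321,
                      n_types = c(astrocytoma = 393,
                                  oligodendroglioma = 125,
                                  glioblastoma = 482),
                      n_sides = c(left = 536, right = 375, both = 89),
                      seed = 15)
  g <- simulate_cohort(spec)
  g <- g[g$group == "glioma", ]
  expect_lt(abs(cor(g$alps_mean, g$tumor_volume, method = "spearman")), 0.1)
  expect_lt(abs(mean(g$alps_tumor_side - g$alps_contralateral)), 0.03)
})

test_that("infeasible specifications fail loudly", {
  expect_error(cohort_spec(alps_side_sd = c(0.05, 0.05)), "inconsistent")
  expect_error(cohort_spec(alps_sides = c(1.0, 1.3)), "must equal")
  expect_error(cohort_spec(n_types = c(astrocytoma = 10,
                                       oligodendroglioma = 10,
                                       glioblastoma = 92)),
               "high-grade")
  expect_error(cohort_spec(spearman = c(alps_tumor = -0.99, alps_ptbe = 0.99,
                                        tumor_ptbe = -0.99, alps_csf = 0,
                                        tumor_csf = 0, ptbe_csf = 0)))
  expect_error(cohort_spec(alps_glioma = c(1.266, -1)), "positive")
})

test_that("cohort tables round-trip through TSV", {
  co <- simulate_cohort(seeded_spec(4))
  p <- tempfile(fileext = ".tsv")
  write_cohort(co, p)
  back <- read_cohort(p)
  expect_equal(back$alps_mean, co$alps_mean, tolerance = 1e-9)
  expect_identical(back$grade, co$grade)
})
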