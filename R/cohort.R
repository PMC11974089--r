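#' Log-normal parameters from a printed median and IQR
#'
#' Clinical volume variables are commonly summarized as median (interquartile
#' range). For a log-normal variable with log-mean `mu` and log-SD `sigma`,
#' the median is `exp(mu)` and the IQR is
#' `2 * median * sinh(qnorm(0.75) * sigma)`, which inverts in closed form.
#'
#' @param median,iqr Printed median and interquartile range (same units).
#' @return Named numeric `c(meanlog =, sdlog =)`.
#' @examples
#' p <- lnorm_from_median_iqr(29.77, 36.79)
#' qlnorm(0.5, p["meanlog"], p["sdlog"])  # 29.77
#' @export
lnorm_from_median_iqr <- function(median, iqr) {
  if (median <= 0 || iqr <= 0) stop("median and iqr must be positive")
  c(meanlog = log(median),
    sdlog = asinh(iqr / (2 * median)) / stats::qnorm(0.75))
}

#' Specify a synthetic glioma/control cohort
#'
#' Defines the generative model for subject-level records carrying the
#' statistical structure the downstream analysis assumes: Gaussian marginals
#' for the bilateral-mean ALPS index and CSF volume, log-normal marginals for
#' tumor volume, PTBE volume and Ki-67 (parameterized from medians and IQRs),
#' a paired hemispheric ALPS model, a Gaussian copula carrying the rank
#' correlations among ALPS and the three volumes, and a linear
#' grade/age/Olig-2 effect on the ALPS index expressed directly as
#' standardized regression coefficients.
#'
#' The default values are the published group structure of a 112-glioma
#' (35 low-grade + 77 high-grade) / 56-control study. Two quantities are
#' derived rather than free: the within-subject correlation between the two
#' hemispheric ALPS values is implied by the three ALPS SDs
#' (`rho = (4*sd_mean^2 - sd_side[1]^2 - sd_side[2]^2) /
#' (2*sd_side[1]*sd_side[2])`, 0.514 at the defaults), and the paired shift
#' is the difference of the configured side means.
#'
#' @param n_glioma,n_lgg,n_control Group sizes; `n_lgg` low-grade gliomas out
#'   of `n_glioma`.
#' @param alps_glioma,alps_control Mean and SD of the bilateral-mean ALPS
#'   index per group, `c(mean, sd)`.
#' @param alps_sides Means of tumor-side and contralateral ALPS,
#'   `c(tumor_side, contralateral)`; their average must equal
#'   `alps_glioma[1]` within 0.005.
#' @param alps_side_sd SDs of the two hemispheric ALPS values.
#' @param csf_glioma,csf_control CSF volume mean and SD per group, cm^3.
#' @param tumor_median,tumor_iqr,ptbe_median,ptbe_iqr,ki67_median,ki67_iqr
#'   Median and IQR of the log-normal tumor volume (cm^3), PTBE volume
#'   (cm^3) and Ki-67 (%) marginals.
#' @param age_glioma,age_control Age mean and SD per group, years.
#' @param n_female Females per group, `c(glioma, control)`.
#' @param n_idh_mut IDH-mutant count among gliomas.
#' @param n_types Named counts of glioma types
#'   (astrocytoma/oligodendroglioma/glioblastoma); glioblastomas are assigned
#'   within the high-grade stratum.
#' @param n_sides Named counts of tumor laterality (left/right/both).
#' @param spearman Target Spearman rank correlations, named
#'   `alps_tumor`, `alps_ptbe`, `tumor_ptbe`, `alps_csf`, `tumor_csf`,
#'   `ptbe_csf`. Mapped to latent Pearson correlations via
#'   `2*sin(pi*rho/6)` (Gaussian copula).
#' @param beta_grade,beta_age,beta_olig2 True standardized multivariable
#'   coefficients of grade (LGG=0/HGG=1), age and Olig-2 on the ALPS index.
#' @param r_grade_age,r_grade_olig2,r_age_olig2 Correlations among the three
#'   predictors.
#' @param olig2 Mean and SD of the Olig-2 expression score (%).
#' @param control_side_sd SD of the left-right ALPS difference in controls
#'   (their side means are equal).
#' @param seed Integer seed; [simulate_cohort()] is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_glioma = 112L, n_lgg = 35L, n_control = 56L,
                        alps_glioma = c(1.266, 0.258),
                        alps_control = c(1.395, 0.174),
                        alps_sides = c(1.233, 1.299),
                        alps_side_sd = c(0.297, 0.296),
                        csf_glioma = c(174.53, 34.89),
                        csf_control = c(154.25, 20.89),
                        tumor_median = 29.77, tumor_iqr = 36.79,
                        ptbe_median = 37.48, ptbe_iqr = 65.11,
                        ki67_median = 20.0, ki67_iqr = 25.0,
                        age_glioma = c(52.8, 13.1),
                        age_control = c(53.4, 10.7),
                        n_female = c(49L, 27L),
                        n_idh_mut = 36L,
                        n_types = c(astrocytoma = 44L,
                                    oligodendroglioma = 14L,
                                    glioblastoma = 54L),
                        n_sides = c(left = 60L, right = 42L, both = 10L),
                        spearman = c(alps_tumor = -0.353, alps_ptbe = -0.266,
                                     tumor_ptbe = 0.427, alps_csf = 0,
                                     tumor_csf = 0, ptbe_csf = 0),
                        beta_grade = -0.244, beta_age = -0.2036,
                        beta_olig2 = -0.3166,
                        r_grade_age = 0.10, r_grade_olig2 = -0.1338,
                        r_age_olig2 = 0,
                        olig2 = c(50, 20),
                        control_side_sd = 0.15,
                        seed = 1L) {
  if (n_lgg >= n_glioma) stop("n_lgg must be smaller than n_glioma")
  sds <- c(alps_glioma[2], alps_control[2], alps_side_sd, csf_glioma[2],
           csf_control[2], age_glioma[2], age_control[2], olig2[2])
  if (any(sds <= 0)) stop("all SDs must be positive")
  if (abs(mean(alps_sides) - alps_glioma[1]) > 0.005)
    stop("mean of alps_sides must equal the glioma bilateral-mean ALPS")
  if (sum(n_types) != n_glioma) stop("glioma type counts must sum to n_glioma")
  if (n_types[["glioblastoma"]] > n_glioma - n_lgg)
    stop("more glioblastomas than high-grade gliomas")
  if (sum(n_sides) != n_glioma) stop("tumor side counts must sum to n_glioma")
  need <- c("alps_tumor", "alps_ptbe", "tumor_ptbe", "alps_csf",
            "tumor_csf", "ptbe_csf")
  if (!all(need %in% names(spearman)))
    stop("spearman must name all of: ", paste(need, collapse = ", "))
  rho <- (4 * alps_glioma[2]^2 - sum(alps_side_sd^2)) / (2 * prod(alps_side_sd))
  if (abs(rho) >= 1)
    stop("ALPS side SDs are inconsistent with the bilateral-mean SD ",
         "(implied paired correlation ", format(rho), ")")
  spec <- structure(as.list(environment()), class = "cohort_spec")
  spec[c("sds", "need", "rho")] <- NULL
  spec$paired_rho <- rho
  spec$paired_shift <- alps_sides[1] - alps_sides[2]
  spec$paired_sd <- sqrt(sum(alps_side_sd^2) - 2 * rho * prod(alps_side_sd))
  spec$latent_corr <- .cohort_latent_corr(spec)   # validates positive definiteness
  spec
}

# assemble and validate the 4x4 latent correlation matrix of
# (ALPS residual e, tumor, PTBE, CSF); corr(e, volume) is inflated by 1/sd_e
# so that corr(ALPS latent, volume latent) hits the copula target.
.cohort_latent_corr <- function(spec) {
  s <- spec$spearman
  pearson <- function(r) 2 * sin(pi * r / 6)
  Sx <- matrix(c(1, spec$r_grade_age, spec$r_grade_olig2,
                 spec$r_grade_age, 1, spec$r_age_olig2,
                 spec$r_grade_olig2, spec$r_age_olig2, 1), 3, 3)
  beta <- c(spec$beta_grade, spec$beta_age, spec$beta_olig2)
  r2 <- drop(t(beta) %*% Sx %*% beta)
  if (r2 >= 1)
    stop("grade/age/Olig-2 standardized effects explain >= 100% of ALPS variance")
  sd_e <- sqrt(1 - r2)
  re <- pearson(c(s[["alps_tumor"]], s[["alps_ptbe"]], s[["alps_csf"]])) / sd_e
  if (any(abs(re) >= 1))
    stop("requested ALPS-volume correlations exceed what the ALPS residual ",
         "variance allows")
  C <- diag(4)
  C[1, 2:4] <- C[2:4, 1] <- re
  C[2, 3] <- C[3, 2] <- pearson(s[["tumor_ptbe"]])
  C[2, 4] <- C[4, 2] <- pearson(s[["tumor_csf"]])
  C[3, 4] <- C[4, 3] <- pearson(s[["ptbe_csf"]])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("latent copula correlation matrix is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  attr(C, "sd_e") <- sd_e
  C
}

# exact-count random assignment of a factor
.assign_counts <- function(counts) {
  sample(rep(names(counts), times = counts))
}

#' Simulate a subject-level cohort
#'
#' Draws one synthetic cohort from a [cohort_spec()]. Per glioma subject the
#' generator (i) assigns grade, glioma type, IDH status, sex and tumor side by
#' exact-count permutation; (ii) builds correlated standardized grade, age and
#' Olig-2 scores; (iii) draws the 4-dimensional Gaussian-copula latents and
#' forms the standardized ALPS latent as the configured linear predictor plus
#' the copula residual; (iv) maps latents through the configured marginals
#' (Gaussian ALPS and CSF, log-normal tumor/PTBE/Ki-67); and (v) splits the
#' bilateral-mean ALPS into tumor-side and contralateral values using the
#' paired shift and the within-subject correlation implied by the configured
#' SDs, so `alps_mean` is exactly the average of the two sides. Controls get
#' Gaussian ALPS and CSF, a zero-mean left-right split, and `NA` for
#' tumor-specific fields. Deterministic for a fixed `spec$seed`.
#'
#' For subjects with bilateral tumors the affected-hemisphere label used in
#' the paired columns is drawn at random; in the imaging pipeline the
#' convention is the hemisphere holding the larger tumor fraction.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` (class `alps_cohort`) with one row per subject:
#'   `id`, `group`, `grade`, `idh`, `type`, `age`, `sex`, `tumor_side`,
#'   `alps_tumor_side`, `alps_contralateral`, `alps_mean`, `csf_volume`,
#'   `tumor_volume`, `ptbe_volume`, `ki67`, `olig2`. For controls the two
#'   side columns hold the left and right hemispheric indices.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ng <- spec$n_glioma; nc <- spec$n_control
  n_hgg <- ng - spec$n_lgg
  p_hgg <- n_hgg / ng

  grade <- .assign_counts(c(LGG = spec$n_lgg, HGG = n_hgg))
  g <- as.numeric(grade == "HGG")
  gs <- (g - p_hgg) / sqrt(p_hgg * (1 - p_hgg))   # standardized binary grade

  # predictor scores with the configured correlation structure (exact
  # covariances by linear construction; grade is binary, age/Olig-2 Gaussian)
  ea <- stats::rnorm(ng); eo <- stats::rnorm(ng)
  a_star <- spec$r_grade_age * gs + sqrt(1 - spec$r_grade_age^2) * ea
  lam <- (spec$r_age_olig2 - spec$r_grade_age * spec$r_grade_olig2) /
    sqrt(1 - spec$r_grade_age^2)
  c3 <- 1 - spec$r_grade_olig2^2 - lam^2
  if (c3 < 0) stop("predictor correlations are jointly infeasible")
  o_star <- spec$r_grade_olig2 * gs + lam * ea + sqrt(c3) * eo

  C <- spec$latent_corr
  sd_e <- attr(C, "sd_e")
  Z <- MASS::mvrnorm(ng, mu = rep(0, 4), Sigma = C)
  z_alps <- spec$beta_grade * gs + spec$beta_age * a_star +
    spec$beta_olig2 * o_star + sd_e * Z[, 1]

  alps_mean <- spec$alps_glioma[1] + spec$alps_glioma[2] * z_alps
  d <- spec$paired_shift + spec$paired_sd * stats::rnorm(ng)
  alps_ts <- alps_mean + d / 2
  alps_cl <- alps_mean - d / 2

  tum <- lnorm_from_median_iqr(spec$tumor_median, spec$tumor_iqr)
  ptb <- lnorm_from_median_iqr(spec$ptbe_median, spec$ptbe_iqr)
  ki <- lnorm_from_median_iqr(spec$ki67_median, spec$ki67_iqr)
  tumor_volume <- exp(tum[1] + tum[2] * Z[, 2])
  ptbe_volume <- exp(ptb[1] + ptb[2] * Z[, 3])
  csf_g <- spec$csf_glioma[1] + spec$csf_glioma[2] * Z[, 4]
  ki67 <- exp(ki[1] + ki[2] * stats::rnorm(ng))
  age_g <- spec$age_glioma[1] + spec$age_glioma[2] * a_star
  olig2 <- spec$olig2[1] + spec$olig2[2] * o_star

  type <- rep(NA_character_, ng)
  n_gbm <- spec$n_types[["glioblastoma"]]
  hgg_rest <- n_hgg - n_gbm
  # glioblastomas are high-grade by definition; remaining type counts are
  # split across strata to honor the configured totals
  n_astro_hgg <- round(hgg_rest * spec$n_types[["astrocytoma"]] /
                         (spec$n_types[["astrocytoma"]] +
                            spec$n_types[["oligodendroglioma"]]))
  type[grade == "HGG"] <- .assign_counts(c(
    glioblastoma = n_gbm, astrocytoma = n_astro_hgg,
    oligodendroglioma = hgg_rest - n_astro_hgg))
  type[grade == "LGG"] <- .assign_counts(c(
    astrocytoma = spec$n_types[["astrocytoma"]] - n_astro_hgg,
    oligodendroglioma = spec$n_types[["oligodendroglioma"]] -
      (hgg_rest - n_astro_hgg)))

  glioma <- data.frame(
    id = sprintf("G%03d", seq_len(ng)), group = "glioma", grade = grade,
    idh = .assign_counts(c(mutant = spec$n_idh_mut,
                           wildtype = ng - spec$n_idh_mut)),
    type = type,
    age = age_g,
    sex = .assign_counts(c(female = spec$n_female[1],
                           male = ng - spec$n_female[1])),
    tumor_side = .assign_counts(spec$n_sides),
    alps_tumor_side = alps_ts, alps_contralateral = alps_cl,
    alps_mean = alps_mean, csf_volume = csf_g,
    tumor_volume = tumor_volume, ptbe_volume = ptbe_volume,
    ki67 = ki67, olig2 = olig2, stringsAsFactors = FALSE)

  alps_c <- spec$alps_control[1] + spec$alps_control[2] * stats::rnorm(nc)
  dc <- spec$control_side_sd * stats::rnorm(nc)
  control <- data.frame(
    id = sprintf("C%03d", seq_len(nc)), group = "control",
    grade = NA_character_, idh = NA_character_, type = NA_character_,
    age = spec$age_control[1] + spec$age_control[2] * stats::rnorm(nc),
    sex = .assign_counts(c(female = spec$n_female[2],
                           male = nc - spec$n_female[2])),
    tumor_side = NA_character_,
    alps_tumor_side = alps_c + dc / 2, alps_contralateral = alps_c - dc / 2,
    alps_mean = alps_c, csf_volume = spec$csf_control[1] +
      spec$csf_control[2] * stats::rnorm(nc),
    tumor_volume = NA_real_, ptbe_volume = NA_real_, ki67 = NA_real_,
    olig2 = NA_real_, stringsAsFactors = FALSE)

  out <- rbind(glioma, control)
  rownames(out) <- NULL
  class(out) <- c("alps_cohort", "data.frame")
  out
}

#' Read/write cohort tables as TSV
#'
#' @param cohort An `alps_cohort` data frame.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("alps_cohort", "data.frame")
  out
}
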