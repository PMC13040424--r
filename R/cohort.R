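#' Parameters for the synthetic cohort simulator
#'
#' The simulator emulates a late-gestation first-vaginal-birth cohort:
#' demographics sampled uniformly within the stated ranges, cervical
#' biometry built around a latent cervical length, and birth outcomes drawn
#' from logistic models on the biometry. Defaults reproduce the study
#' conditions the statistical battery assumes: maternal age 19-42 years,
#' BMI 18-32, gestational age 35.71-40.14 weeks, a caesarean odds ratio of
#' 1.09 per cm3 of total cervical volume, a mean internal-minus-external os
#' diameter difference of 3.5 mm with the internal os larger in 81.8% of
#' subjects, and an induction odds ratio of 0.83 per mm of external os
#' diameter. Effect magnitudes the study does not print (volume baselines,
#' length slopes, noise SDs) are package defaults chosen to give realistic
#' late-gestation cervix dimensions; they are configuration, not reported
#' values.
#'
#' @param n cohort size.
#' @param age_range,bmi_range,ga_range uniform sampling ranges (years,
#'   kg/m2, weeks).
#' @param stroma_vol_age_slope cm3 per year of maternal age (> 0 by
#'   default, the direction the battery tests).
#' @param caesarean_or_per_cm3 odds ratio for caesarean per cm3 of total
#'   cervical volume.
#' @param baseline_caesarean_prob caesarean probability at mean volume.
#' @param ethnicity_mix named probabilities over ethnicity categories.
#' @param internal_gt_external_frac target fraction of subjects with
#'   internal os diameter larger than external.
#' @param os_diff_mean_mm target mean internal-minus-external os difference.
#'   When both targets are active the difference SD is implied:
#'   `os_diff_mean_mm / qnorm(internal_gt_external_frac)`.
#' @param induction_or_per_mm odds ratio for induction of labour per mm of
#'   external os diameter.
#' @param baseline_induction_prob induction probability at mean diameter.
#' @param length_range_mm latent 2-point cervical length range.
#' @param stroma_vol_base_cm3,stroma_vol_len_slope,stroma_vol_sd stroma
#'   volume model: base + slope x (length - mean) + age term + Gaussian
#'   noise.
#' @param canal_vol_base_cm3,canal_vol_len_slope,canal_vol_sd canal volume
#'   model.
#' @param ext_os_base_mm,ext_os_len_slope,ext_os_sd external os model (the
#'   slope is per mm of length and negative: os diameters shrink as the
#'   cervix lengthens).
#' @param uca_base_deg,uca_len_slope,uca_sd utero-cervical angle model.
#' @param os_diff_sd_mm fallback difference SD used when the fraction
#'   target is 0.5 or the mean is 0 (null configurations).
#' @param seed integer seed; generation is a pure function of (params, seed).
#' @return Object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n,
                              age_range = c(19, 42),
                              bmi_range = c(18, 32),
                              ga_range = c(35.71, 40.14),
                              stroma_vol_age_slope = 0.25,
                              caesarean_or_per_cm3 = 1.09,
                              baseline_caesarean_prob = 0.25,
                              ethnicity_mix = c(White = 0.55, Black = 0.12,
                                                Asian = 0.20, Mixed = 0.06,
                                                Other = 0.07),
                              internal_gt_external_frac = 0.818,
                              os_diff_mean_mm = 3.5,
                              induction_or_per_mm = 0.83,
                              baseline_induction_prob = 0.35,
                              length_range_mm = c(22, 45),
                              stroma_vol_base_cm3 = 40,
                              stroma_vol_len_slope = 0.5,
                              stroma_vol_sd = 5,
                              canal_vol_base_cm3 = 3,
                              canal_vol_len_slope = 0.05,
                              canal_vol_sd = 0.8,
                              ext_os_base_mm = 9,
                              ext_os_len_slope = -0.15,
                              ext_os_sd = 2,
                              uca_base_deg = 140,
                              uca_len_slope = -0.8,
                              uca_sd = 10,
                              os_diff_sd_mm = 3.85,
                              seed = 1L) {
  stopifnot(n >= 1, length(ethnicity_mix) >= 1, all(ethnicity_mix >= 0),
            abs(sum(ethnicity_mix) - 1) < 1e-8,
            internal_gt_external_frac >= 0, internal_gt_external_frac <= 1,
            baseline_caesarean_prob > 0, baseline_caesarean_prob < 1,
            baseline_induction_prob > 0, baseline_induction_prob < 1,
            caesarean_or_per_cm3 > 0, induction_or_per_mm > 0)
  p <- as.list(environment())
  p$n <- as.integer(n)
  p$seed <- as.integer(seed)
  structure(p, class = "cohort_sim_params")
}

#' Simulate a synthetic cohort
#'
#' Draws one cohort according to [cohort_sim_params()]. The os-diameter
#' pair is drawn so the internal-larger fraction and the mean difference
#' match their targets in expectation; the caesarean outcome follows a
#' logistic model in total cervical volume (centered), induction a logistic
#' model in external os diameter (centered).
#'
#' @param p a [cohort_sim_params()].
#' @return Data frame (the cohort table) with columns `id`, `age`, `bmi`,
#'   `ethnicity`, `ga_weeks`, `parity`, `length_2pt_mm`, `stroma_vol_cm3`,
#'   `canal_vol_cm3`, `total_vol_cm3`, `int_os_diam_mm`, `ext_os_diam_mm`,
#'   `uca_deg`, `caesarean`, `induced`.
#' @export
make_cohort <- function(p) {
  stopifnot(inherits(p, "cohort_sim_params"))
  set.seed(p$seed)
  n <- p$n
  age <- runif(n, p$age_range[1], p$age_range[2])
  bmi <- runif(n, p$bmi_range[1], p$bmi_range[2])
  ga <- runif(n, p$ga_range[1], p$ga_range[2])
  eth <- sample(names(p$ethnicity_mix), n, replace = TRUE,
                prob = p$ethnicity_mix)
  parity <- rbinom(n, 1L, 0.1)  # mostly nulliparous, some VBAC
  len <- runif(n, p$length_range_mm[1], p$length_range_mm[2])
  len_c <- len - mean(p$length_range_mm)
  age_c <- age - mean(p$age_range)

  stroma <- p$stroma_vol_base_cm3 + p$stroma_vol_len_slope * len_c +
    p$stroma_vol_age_slope * age_c + rnorm(n, 0, p$stroma_vol_sd)
  stroma <- pmax(stroma, 5)
  canal <- pmax(p$canal_vol_base_cm3 + p$canal_vol_len_slope * len_c +
                  rnorm(n, 0, p$canal_vol_sd), 0.3)
  total <- stroma + canal

  ext_os <- pmax(p$ext_os_base_mm + p$ext_os_len_slope * len_c +
                   rnorm(n, 0, p$ext_os_sd), 1)
  f <- p$internal_gt_external_frac
  sd_diff <- if (abs(f - 0.5) > 1e-9 && abs(p$os_diff_mean_mm) > 1e-9)
    p$os_diff_mean_mm / qnorm(f) else p$os_diff_sd_mm
  os_diff <- rnorm(n, p$os_diff_mean_mm, sd_diff)
  int_os <- pmax(ext_os + os_diff, 0.2)

  uca <- pmin(pmax(p$uca_base_deg + p$uca_len_slope * len_c +
                     rnorm(n, 0, p$uca_sd), 5), 178)

  lp_cs <- qlogis(p$baseline_caesarean_prob) +
    log(p$caesarean_or_per_cm3) * (total - mean(total))
  caesarean <- rbinom(n, 1L, plogis(lp_cs))
  lp_ind <- qlogis(p$baseline_induction_prob) +
    log(p$induction_or_per_mm) * (ext_os - mean(ext_os))
  induced <- rbinom(n, 1L, plogis(lp_ind))

  data.frame(id = sprintf("S%05d", seq_len(n)),
             age = age, bmi = bmi, ethnicity = eth, ga_weeks = ga,
             parity = parity, length_2pt_mm = len,
             stroma_vol_cm3 = stroma, canal_vol_cm3 = canal,
             total_vol_cm3 = total, int_os_diam_mm = int_os,
             ext_os_diam_mm = ext_os, uca_deg = uca,
             caesarean = caesarean, induced = induced,
             stringsAsFactors = FALSE)
}

#' Null configuration of the cohort simulator
#'
#' Convenience wrapper returning [cohort_sim_params()] with every effect
#' zeroed (unit odds ratios, zero slopes, symmetric os difference), used
#' for type-I-error calibration of the association battery.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return A `cohort_sim_params` with all effects null.
#' @export
null_cohort_params <- function(n, seed = 1L) {
  cohort_sim_params(n = n,
                    stroma_vol_age_slope = 0,
                    caesarean_or_per_cm3 = 1,
                    internal_gt_external_frac = 0.5,
                    os_diff_mean_mm = 0,
                    induction_or_per_mm = 1,
                    stroma_vol_len_slope = 0,
                    canal_vol_len_slope = 0,
                    ext_os_len_slope = 0,
                    uca_len_slope = 0,
                    seed = seed)
}

#' Simulate rater replicates of a measurement list
#'
#' Each rater observes every true value plus independent Gaussian rater
#' noise, emulating repeated manual measurement of the same scans.
#'
#' @param true_values numeric vector of true measurements (one per subject).
#' @param rater_sd Gaussian rater noise SD (same units as the values).
#' @param n_raters number of raters (columns).
#' @param seed integer seed.
#' @return `length(true_values)` x `n_raters` matrix.
#' @export
make_rating_replicates <- function(true_values, rater_sd, n_raters,
                                   seed = 1L) {
  stopifnot(rater_sd >= 0, n_raters >= 1, length(true_values) >= 1)
  set.seed(as.integer(seed))
  n <- length(true_values)
  true_values + matrix(rnorm(n * n_raters, 0, rater_sd), n, n_raters)
}
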