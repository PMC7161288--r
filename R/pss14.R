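# Default synthetic scenario: a PSS-14-like instrument. Fourteen five-point
# items, a negatively worded "Perceived Stress" subscale (items 1, 2, 3, 8,
# 11, 12, 14) and a positively worded "Perceived Control" subscale (items 4,
# 5, 6, 7, 9, 10, 13) driven by two correlated latent traits; uniform LD and
# DIF terms with calibrated partial-gamma magnitudes; and deliberately
# under-discriminating items (12 and 8 on the stress side; 9, 13, 4, 5 on
# the control side) so the stepwise exclusion loop has real work to do.

pss14_alpha <- function(loc, off) lapply(loc, function(L) c(0, -cumsum(L + off)))

# threshold shape shared by the stress items: wide low gaps, compressed high
# gaps, so the information maximum sits well above the population mean score
.pss_stress_off <- c(-2.8, -0.6, 1.3, 2.3)
.pss_control_off <- c(-2.4, 0.2, 1.3, 2.0)

#' Default PSS-14-like simulation configuration
#'
#' The package's reference synthetic scenario. Covariate prevalences follow
#' the emulated survey sample (61.9% female; 67.5% technical/university
#' education). The stress subscale carries LD between items 1 and 2 and
#' uniform DIF of item 1 by sex (+), item 3 by sex (+), and item 1 by
#' education (-); the control subscale carries LD between items 7 and 10 and
#' DIF of item 10 by sex (-), item 6 by sex (-), and item 10 by education
#' (-). Interaction magnitudes are rank-one scalars calibrated (by
#' [calibrate_effect()] against large simulated samples, stratifying over
#' the post-exclusion item sets) to the partial-gamma targets 0.18, 0.24,
#' 0.33, -0.14 (stress) and 0.22, -0.23, -0.15, -0.17 (control). Items 12
#' and 8 (stress) and 9, 13, 4, 5 (control) under-discriminate
#' (discrimination multiplier < 1). The trait correlation is calibrated so
#' that the reverse-scored stress subscale total and the control subscale
#' total correlate at gamma ~ 0.53. Latent mean shifts (women higher
#' stress, tertiary-educated higher control) produce the observed-score
#' subgroup pattern.
#'
#' @param n sample size (default 3857, the emulated survey's size).
#' @param ld_stress,dif1_sex,dif3_sex,dif1_edu rank-one magnitudes of the
#'   stress-subscale interaction terms.
#' @param ld_control,dif10_sex,dif6_sex,dif10_edu control-subscale
#'   magnitudes.
#' @param trait_cor latent correlation between the stress and control traits
#'   on their native orientations (negative: more stress, less control).
#' @param sex_effect_stress latent stress-mean shift for women.
#' @param edu_effect_control latent control-mean shift for the
#'   technical/university level.
#' @param correlates include criterion-validity correlates (a social-support
#'   style negative correlate and an effort-imbalance style positive
#'   correlate of the stress trait)?
#' @return a [sim_config()].
#' @export
pss14_sim_config <- function(n = 3857,
                             ld_stress = 0.2520,
                             dif1_sex = 0.6445,
                             dif3_sex = 0.7734,
                             dif1_edu = -0.2344,
                             ld_control = 0.3633,
                             dif10_sex = -0.7734,
                             dif6_sex = -0.6562,
                             dif10_edu = -0.3281,
                             trait_cor = -0.7938,
                             sex_effect_stress = 0.267,
                             edu_effect_control = 0.34,
                             correlates = TRUE) {
  stress_items <- paste0("item", c(1, 2, 3, 8, 11, 12, 14))
  control_items <- paste0("item", c(4, 5, 6, 7, 9, 10, 13))
  stress_loc <- c(item1 = 0.5, item2 = 0.7, item3 = 0.6, item8 = 0.7,
                  item11 = 0.8, item12 = 0.6, item14 = 0.7)
  control_loc <- c(item4 = 0.9, item5 = 1.0, item6 = 0.9, item7 = 1.0,
                   item9 = 1.0, item10 = 1.1, item13 = 1.0)
  stress <- sim_scale(
    items = stress_items,
    alpha = pss14_alpha(stress_loc[stress_items], .pss_stress_off),
    discrimination = c(item12 = 0.33, item8 = 0.68),
    ld = list(c("item1", "item2")), ld_scalar = ld_stress,
    dif = list(list(item = "item1", covariate = "sex"),
               list(item = "item3", covariate = "sex"),
               list(item = "item1", covariate = "education")),
    dif_scalar = c(dif1_sex, dif3_sex, dif1_edu),
    trait_sd = 1.4,
    trait_effects = list(sex = c(Male = 0, Female = sex_effect_stress)),
    target_gamma = c("LD(item1,item2)" = 0.18, "DIF(item1,sex)" = 0.24,
                     "DIF(item3,sex)" = 0.33, "DIF(item1,education)" = -0.14))
  control <- sim_scale(
    items = control_items,
    alpha = pss14_alpha(control_loc[control_items], .pss_control_off),
    discrimination = c(item9 = 0.52, item13 = 0.52, item4 = 0.62, item5 = 0.40),
    ld = list(c("item10", "item7")), ld_scalar = ld_control,
    dif = list(list(item = "item10", covariate = "sex"),
               list(item = "item6", covariate = "sex"),
               list(item = "item10", covariate = "education")),
    dif_scalar = c(dif10_sex, dif6_sex, dif10_edu),
    trait_sd = 1.4,
    trait_effects = list(
      education = c(UpToHighSchool = 0, TechnicalOrUniversity = edu_effect_control)),
    target_gamma = c("LD(item10,item7)" = 0.22, "DIF(item10,sex)" = -0.23,
                     "DIF(item6,sex)" = -0.15, "DIF(item10,education)" = -0.17))
  sim_config(
    n = n,
    covariates = list(
      sex = c(Male = 0.381, Female = 0.619),
      education = c(UpToHighSchool = 0.325, TechnicalOrUniversity = 0.675)),
    scales = list(stress = stress, control = control),
    trait_cor = trait_cor,
    correlates = if (correlates)
      list(social_support = list(scale = "stress", tau = -0.25),
           effort_imbalance = list(scale = "stress", tau = 0.25))
      else list(),
    target_subscale_gamma = 0.527)
}

#' Post-exclusion item sets of the default scenario
#'
#' The item sets the stepwise analysis is expected to retain: stress items
#' 1, 2, 3, 11, 14 and control items 6, 7, 10 (the under-discriminating
#' items 12, 8, 9, 13, 4, 5 excluded).
#'
#' @return named list of character vectors.
#' @export
pss14_final_items <- function() {
  list(stress = paste0("item", c(1, 2, 3, 11, 14)),
       control = paste0("item", c(6, 7, 10)))
}

#' Compact scenario for structure-recovery experiments
#'
#' The post-exclusion stress subscale (5 well-behaved items with the LD pair
#' and three DIF terms of the default scenario) plus one under-discriminating
#' decoy item, on a single latent trait. The second scale slot is a minimal
#' independent two-item filler (the configuration container requires two
#' scales); recovery experiments use only the stress items.
#'
#' @param n sample size.
#' @param decoy_discrimination discrimination multiplier of the decoy.
#' @return a [sim_config()].
#' @export
pss_stress_decoy_config <- function(n = 3857, decoy_discrimination = 0.33) {
  cfg <- pss14_sim_config(n = n, correlates = FALSE)
  stress <- cfg$scales$stress
  keep <- paste0("item", c(1, 2, 3, 11, 14, 12))  # item12 is the decoy
  stress$items <- keep
  stress$alpha <- stress$alpha[keep]
  stress$discrimination <- stress$discrimination[keep]
  stress$discrimination["item12"] <- decoy_discrimination
  filler <- sim_scale(items = c("f1", "f2"),
                      alpha = pss14_alpha(c(f1 = 0, f2 = 0), .pss_control_off),
                      trait_sd = 1)
  sim_config(n = n, covariates = cfg$covariates,
             scales = list(stress = stress, filler = filler),
             trait_cor = 0)
}
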