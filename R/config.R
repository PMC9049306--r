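#' Model configuration
#'
#' A single nested list drives every stage: synthetic-claims generation,
#' cohort derivation, index fitting, calibration, simulation, and the
#' economic analysis. `default_config()` returns the package defaults;
#' `load_config()` reads a YAML file and merges it over the defaults, so a
#' user file only needs to state what it changes.
#'
#' Payer scenarios carry the published cohort moments for US public-payer
#' SCD populations: Medicaid (mean age at enrollment 16.9, SD 13.9, 53.4%
#' female), Medicare (62.3, SD 16.2, 60.2%), and dual-eligible (33.3,
#' SD 19.5, 58.1%), with cohort weights proportional to the published
#' cohort sizes. The commercial scenario is a package-invented placeholder.
#'
#' @name config
NULL

# Annual per-attribute claim probability implied by a lifetime-in-window
# prevalence P (%) under a nominal mean observed follow-up of `years`:
# p = 1 - (1 - P)^(1/years).
annual_prob_from_prevalence <- function(percent, years = 5) {
  1 - (1 - clamp(percent / 100, 0, 0.995))^(1 / years)
}

# location parameter of a normal truncated at zero whose realised mean is m
tnorm_location <- function(m, sd) {
  f <- function(mu) {
    a <- -mu / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - m
  }
  stats::uniroot(f, c(m - 4 * sd, m + sd))$root
}

rtnorm0 <- function(n, mu, sd, u = stats::runif(n)) {
  p0 <- stats::pnorm(0, mu, sd)
  stats::qnorm(p0 + u * (1 - p0), mu, sd)
}

#' @rdname config
#' @return A nested configuration list of class `scd_config`.
#' @export
default_config <- function() {
  targets <- prevalence_targets()
  attr_probs <- function(payer_col) {
    p <- annual_prob_from_prevalence(targets[[payer_col]])
    stats::setNames(p, targets$attribute)
  }
  cfg <- list(
    seed = 20080101L,
    study_window = c(2008L, 2016L),
    payers = list(
      medicaid = list(n = 2000L, weight = 39366, age_mean = 16.9, age_sd = 13.9,
                      prop_female = 0.534, attr_probs = attr_probs("medicaid")),
      medicare = list(n = 400L, weight = 6522, age_mean = 62.3, age_sd = 16.2,
                      prop_female = 0.602, attr_probs = attr_probs("medicare")),
      dual = list(n = 1800L, weight = 36846, age_mean = 33.3, age_sd = 19.5,
                  prop_female = 0.581, attr_probs = attr_probs("dual")),
      commercial = list(n = 1000L, weight = 20000, age_mean = 25.0, age_sd = 18.0,
                        prop_female = 0.55, attr_probs = attr_probs("combined"))
    ),
    generator = list(
      case_probability = 0.92,        # share of beneficiaries who are true SCD cases
      scd_claims_per_year = 3.0,      # Poisson mean of SCD-coded claims per enrolled year
      noise_claims_per_year = 2.0,    # non-SCD noise claims per enrolled year
      claims_per_event = 0.4,         # extra claims per attribute-event (Poisson mean)
      trait_coder_probability = 0.05, # non-cases occasionally coded with trait codes
      enrollment_mean_months = 72,    # exponential mean of primary span length
      gap_probability = 0.25,         # chance of a second, shorter span after a gap
      setting_mix = c(inpatient = 0.08, ED = 0.22, outpatient = 0.55,
                      ambulatory = 0.15),
      hydroxyurea_user_prob = 0.35,
      chronic_transfusion_prob = 0.08,
      acute_transfusion_prob = 0.30,  # given >=1 acute event that year
      complication_probs = c(leukopenia = 0.06, thrombocytopenia = 0.05,
                             oligospermia_azospermia = 0.02,
                             iron_overload = 0.10, transfusion_reaction = 0.04,
                             transfusion_infection = 0.03),
      hsct_annual_prob = 0.003,
      mortality_multiplier = 2.2      # SCD excess over background in the claims world
    ),
    cohort = list(min_enrollment_months = 12L),
    mortality = list(
      type = "gompertz",
      makeham = 0.001, gompertz_b = 3e-05, gompertz_c = 0.085,
      female_log_hr = -0.15,
      attr_log_hr = c(
        vaso_occlusive_pain = 0.10, stroke = 0.45, acute_chest_syndrome = 0.30,
        multi_organ_failure = 0.90, bacteremia_sepsis = 0.45,
        acute_renal_failure = 0.35, myocardial_infarction = 0.40,
        chronic_renal_disease = 0.45, pulmonary_hypertension_cvd = 0.45,
        chronic_lung_disease = 0.25, chronic_pain = 0.10,
        graft_versus_host_disease = 0.50, secondary_malignancy = 0.80,
        graft_failure = 0.50
      )
    ),
    simulation = list(horizon_age = 100L, n = 10000L),
    baseline_history = list(voe_rate = 0.20, stroke_annual = 0.004),
    eligibility = list(min_severe_events = 3L, stroke_qualifies = TRUE),
    strategies = list(
      common_care = list(p_symptom_free = 0, risk_ratio = 1, cost = 0,
                         complications = NULL),
      hsct = list(
        p_symptom_free = 0.90, risk_ratio = 0, cost = 250000,
        complications = list(
          graft_versus_host_disease = c(0.15, 0.02), graft_failure = c(0.08, 0.01),
          bronchiolitis_obliterans = c(0.03, 0.005), osteoporosis = c(0.05, 0.01),
          iron_overload = c(0.10, 0.02), depression_psychosis = c(0.10, 0.02),
          posterior_reversible_encephalopathy = c(0.05, 0.005),
          post_transplant_lymphoproliferative_disorder = c(0.02, 0.002),
          secondary_malignancy = c(0.01, 0.003)
        )
      ),
      gene_therapy = list(
        p_symptom_free = 0.85, risk_ratio = 0, cost = 1800000,
        complications = list(
          graft_failure = c(0.05, 0.005), bronchiolitis_obliterans = c(0.02, 0.003),
          osteoporosis = c(0.04, 0.008), iron_overload = c(0.08, 0.015),
          depression_psychosis = c(0.08, 0.015),
          posterior_reversible_encephalopathy = c(0.04, 0.004),
          post_transplant_lymphoproliferative_disorder = c(0.015, 0.002),
          secondary_malignancy = c(0.015, 0.004)
        )
      )
    ),
    utility = list(
      base_by_age = c(`0` = 0.92, `18` = 0.90, `40` = 0.87, `65` = 0.82),
      female_delta = 0,
      pain_decrement = 0.12,
      decrements = c(
        vaso_occlusive_pain = 0.06, stroke = 0.10, fever = 0.01,
        splenic_disease = 0.02, priapism = 0.02, dactylitis = 0.01,
        acute_chest_syndrome = 0.05, myocardial_infarction = 0.08,
        infections = 0.02, acute_renal_failure = 0.05,
        multi_organ_failure = 0.15, bacteremia_sepsis = 0.06, acute_anemia = 0.02,
        fatigue = 0.04, asthma = 0.03, leg_ulcers = 0.04,
        hepatobiliary_liver_disease = 0.03, sleep_disordered_breathing = 0.03,
        depression_psychosis = 0.06, chronic_renal_disease = 0.08,
        pulmonary_hypertension_cvd = 0.08, chronic_lung_disease = 0.05,
        ocular_complications = 0.03, cognitive_impairment = 0.06,
        avascular_necrosis = 0.05, leukopenia = 0.01, thrombocytopenia = 0.01,
        oligospermia_azospermia = 0.02, iron_overload = 0.03,
        transfusion_reaction = 0.02, transfusion_infection = 0.02,
        graft_versus_host_disease = 0.10, graft_failure = 0.08,
        bronchiolitis_obliterans = 0.06, osteoporosis = 0.03,
        posterior_reversible_encephalopathy = 0.05,
        post_transplant_lymphoproliferative_disorder = 0.08,
        secondary_malignancy = 0.12
      )
    ),
    costs = list(
      unit = c(inpatient = 15000, ED = 1500, outpatient = 300),
      hydroxyurea_annual = 1500,
      acute_transfusion_annual = 3000,
      chronic_transfusion_annual = 45000,
      time_use_hours = 2000, wage_rate = 40,
      caregiver_child = 8000, caregiver_adult = 4000,
      future_unrelated_by_age = c(`0` = 3000, `18` = 4500, `40` = 8000, `65` = 15000),
      end_of_life = 25000
    ),
    discount_rate = 0.03,
    calibration = list(tolerance = 2.0, n_sim = 2000L, max_iter = 8L),
    psa = list(n_draws = 100L, n_per_draw = 500L, cost_cv = 0.2,
               utility_cv = 0.15, wtp_grid = seq(0, 500000, by = 25000))
  )
  class(cfg) <- c("scd_config", "list")
  cfg
}

#' @rdname config
#' @param path Path to a YAML configuration file.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_defaults(default_config(), user)
  class(cfg) <- c("scd_config", "list")
  cfg
}

# recursive merge: user values override defaults, lists merge by name
modify_defaults <- function(defaults, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    if (nm %in% names(defaults) && is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' A small configuration for demonstrations and smoke tests
#'
#' Scales every stage down (hundreds of beneficiaries, short PSA) so the
#' full pipeline completes in a couple of minutes on one CPU.
#'
#' @export
demo_config <- function() {
  cfg <- default_config()
  cfg$payers$medicaid$n <- 800L
  cfg$payers$medicare$n <- 150L
  cfg$payers$dual$n <- 700L
  cfg$payers$commercial$n <- 0L
  cfg$simulation$n <- 1000L
  cfg$calibration$n_sim <- 1000L
  cfg$calibration$max_iter <- 4L
  cfg$psa$n_draws <- 20L
  cfg$psa$n_per_draw <- 100L
  cfg
}

# step function lookup for age-banded parameters, e.g. base_by_age
age_band_value <- function(age, banded) {
  cuts <- as.numeric(names(banded))
  unname(banded[findInterval(age, cuts)])
}
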