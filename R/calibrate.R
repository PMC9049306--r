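#' Published lifetime-prevalence calibration targets
#'
#' Lifetime prevalence (percent of beneficiaries ever exhibiting each
#' disease attribute during follow-up) reported for US public-payer SCD
#' claims cohorts: Medicaid (N = 39,366), Medicare (N = 6,522),
#' dual-eligible (N = 36,846), and the combined cohort (N = 82,734). These
#' are the external targets the simulation's incidence intercepts are
#' calibrated against; the same table is shipped as
#' `inst/extdata/prevalence_targets.csv`.
#'
#' @return Tibble with columns `attribute`, `medicaid`, `medicare`, `dual`,
#'   `combined` (percent).
#' @export
prevalence_targets <- function() {
  tibble::tribble(
    ~attribute, ~medicaid, ~medicare, ~dual, ~combined,
    "vaso_occlusive_pain",        78.1, 42.4, 71.8, 72.5,
    "stroke",                      9.1, 21.4, 15.4, 12.9,
    "fever",                      61.4, 29.5, 55.6, 56.3,
    "splenic_disease",            11.7,  5.8,  8.6,  9.8,
    "priapism",                    3.5,  1.0,  3.9,  3.5,
    "dactylitis",                  2.9,  5.0,  5.1,  4.1,
    "acute_chest_syndrome",       31.6, 15.6, 32.0, 30.5,
    "myocardial_infarction",       0.9,  5.7,  3.8,  2.5,
    "infections",                 79.4, 73.0, 82.1, 80.1,
    "acute_renal_failure",         7.9, 30.9, 22.4, 16.2,
    "multi_organ_failure",         2.0,  5.6,  6.0,  4.0,
    "bacteremia_sepsis",          17.5, 20.1, 28.4, 22.6,
    "acute_anemia",                8.5,  5.4, 10.4,  9.1,
    "chronic_pain",               18.0, 31.0, 39.6, 28.7,
    "fatigue",                    20.2, 57.4, 44.7, 34.0,
    "asthma",                     36.5, 24.3, 37.1, 35.8,
    "leg_ulcers",                  0.9,  3.9,  3.1,  2.1,
    "hepatobiliary_liver_disease",19.2, 22.6, 25.5, 22.3,
    "sleep_disordered_breathing", 25.8, 29.6, 32.5, 29.1,
    "depression_psychosis",       15.1, 28.3, 32.3, 23.8,
    "chronic_renal_disease",      14.2, 54.0, 35.1, 26.6,
    "pulmonary_hypertension_cvd", 35.5, 71.1, 59.6, 49.0,
    "chronic_lung_disease",       21.8, 38.3, 36.3, 29.6,
    "ocular_complications",        4.2,  9.7,  7.3,  6.0,
    "cognitive_impairment",        9.3, 15.7, 12.1, 11.1,
    "avascular_necrosis",         11.9, 14.9, 20.3, 15.9
  )
}

#' Build a calibration-target table for one payer column
#'
#' @param payer `"medicaid"`, `"medicare"`, `"dual"`, or `"combined"`.
#' @param tolerance Convergence tolerance in percentage points.
#' @param targets Source table (defaults to [prevalence_targets()]).
#' @return Tibble `attribute`, `payer`, `target`, `tolerance`.
#' @export
calibration_targets <- function(payer = "combined", tolerance = 2.0,
                                targets = prevalence_targets()) {
  stopifnot(payer %in% setdiff(names(targets), "attribute"), tolerance > 0)
  target_values <- targets[[payer]]
  out <- tibble::tibble(attribute = targets$attribute, payer = payer,
                        target = target_values, tolerance = tolerance)
  if (any(out$target < 0 | out$target > 100)) {
    abort_sim("targets must lie in [0, 100]", "calibration_error")
  }
  out
}

#' Calibrate incidence intercepts to lifetime-prevalence targets
#'
#' Per-attribute one-dimensional root search on the incidence intercept
#' (a log-odds shift) against the lifetime prevalence of a simulated Common
#' Care cohort. The searches share simulations: each global pass simulates
#' one cohort under the current shifts (with common random numbers across
#' passes) and applies a damped logit-scale step -- secant-refined once two
#' evaluations per attribute exist -- to every attribute at once. Iteration
#' stops when all targets are inside tolerance or `max_iter` passes are
#' spent; unreachable targets are flagged `converged = FALSE`, not fatal.
#'
#' @param models An [scd_models()].
#' @param targets Target table from [calibration_targets()] (columns
#'   `attribute`, `target`, `tolerance`).
#' @param population A [population_spec()] matching the target column (e.g.
#'   Medicaid-only spec for Medicaid targets).
#' @param n_sim Individuals per calibration simulation (>= 1000).
#' @param max_iter Maximum global passes.
#' @param seed Integer seed (one simulation seed is reused across passes so
#'   the search sees a deterministic objective).
#' @return An `scd_calibration`: list with `report` (attribute, target,
#'   achieved, shift, converged, iterations) and `models` (shift-applied).
#' @export
calibrate_to_prevalence <- function(models, targets, population,
                                    n_sim = 2000L, max_iter = 8L, seed = 1L) {
  stopifnot(n_sim >= 1000L)
  unknown <- setdiff(targets$attribute,
                     disease_attributes(models$registry)$name)
  if (length(unknown)) {
    abort_sim(paste0("target(s) reference unregistered attribute(s): ",
                     paste(unknown, collapse = ", ")), "calibration_error")
  }
  strategy <- scd_strategy("common_care", models$config)
  sim_seed <- substream_seed(seed, "calibrate")
  tol <- targets$tolerance
  tgt <- clamp(targets$target / 100, 1 / (2 * n_sim), 1 - 1 / (2 * n_sim))
  nm <- targets$attribute

  shift <- stats::setNames(rep(0, length(nm)), nm)
  prev_shift <- prev_lgt <- stats::setNames(rep(NA_real_, length(nm)), nm)
  achieved <- rep(NA_real_, length(nm))
  iterations <- 0L
  converged <- rep(FALSE, length(nm))

  base_shifts <- models$shifts[setdiff(names(models$shifts), nm)]
  simulate_prev <- function(sh) {
    m <- models
    m$shifts <- c(base_shifts, sh)
    res <- run_cohort(n_sim, population, strategy, m, seed = sim_seed,
                      keep_trajectories = FALSE)
    p <- res$prevalence$prevalence[match(nm, res$prevalence$attribute)]
    clamp(p / 100, 1 / (2 * n_sim), 1 - 1 / (2 * n_sim))
  }

  for (iter in seq_len(max_iter)) {
    iterations <- iter
    sim <- simulate_prev(shift)
    achieved <- 100 * sim
    converged <- abs(achieved - targets$target) <= tol
    if (all(converged)) break
    lgt <- logit(sim)
    step <- logit(tgt) - lgt
    # secant refinement where a previous evaluation exists and moved
    have <- !is.na(prev_lgt) & abs(shift - prev_shift) > 1e-8 &
      abs(lgt - prev_lgt) > 1e-8
    slope <- rep(1, length(nm))
    slope[have] <- clamp((lgt[have] - prev_lgt[have]) /
                           (shift[have] - prev_shift[have]), 0.2, 5)
    prev_shift <- shift
    prev_lgt <- lgt
    shift <- shift + clamp(0.9 * step / slope, -2, 2) * !converged
    if (iter == max_iter) {
      sim <- simulate_prev(shift)
      achieved <- 100 * sim
      converged <- abs(achieved - targets$target) <= tol
    }
  }

  report <- tibble::tibble(
    attribute = nm, target = targets$target, achieved = achieved,
    shift = unname(shift), converged = converged, iterations = iterations
  )
  out_models <- models
  out_models$shifts <- c(base_shifts, shift)
  structure(list(report = report, models = out_models, n_sim = n_sim,
                 seed = seed),
            class = "scd_calibration")
}

#' @export
print.scd_calibration <- function(x, ...) {
  cat(sprintf("<scd_calibration> %d/%d targets converged in %d pass(es)\n",
              sum(x$report$converged), nrow(x$report),
              max(x$report$iterations)))
  invisible(x)
}

#' @export
tidy.scd_calibration <- function(x, ...) x$report

#' @export
glance.scd_calibration <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$report),
                 n_converged = sum(x$report$converged),
                 max_abs_error = max(abs(x$report$achieved - x$report$target)),
                 iterations = max(x$report$iterations), n_sim = x$n_sim)
}

#' External validation report
#'
#' Side-by-side comparison of simulated statistics against supplied
#' published estimates (e.g. survey-based vaso-occlusive episode rates that
#' claims under-capture). Reports ratios and flags values outside a band;
#' it never adjusts anything -- adjustment is [calibrate_to_prevalence()]'s
#' job.
#'
#' @param simulated Tibble `attribute`, `value` of simulated statistics.
#' @param estimates Tibble `attribute`, `statistic`, `value`, `source`.
#' @param band Acceptable simulated/published ratio range.
#' @param registry An `scd_registry`.
#' @return Tibble with `ratio` and `flagged` columns.
#' @export
validate_external <- function(simulated, estimates, band = c(0.5, 2),
                              registry = default_registry()) {
  if (!nrow(estimates)) {
    return(tibble::tibble(attribute = character(), statistic = character(),
                          published = numeric(), simulated = numeric(),
                          source = character(), ratio = numeric(),
                          flagged = logical()))
  }
  unknown <- setdiff(estimates$attribute, registry$attributes$name)
  if (length(unknown)) {
    abort_sim(paste0("unknown attribute(s) in estimates: ",
                     paste(unknown, collapse = ", ")), "validation_error")
  }
  out <- dplyr::inner_join(
    dplyr::rename(estimates, published = "value"),
    dplyr::rename(simulated, simulated = "value"), by = "attribute")
  dplyr::mutate(out, ratio = .data$simulated / .data$published,
                flagged = .data$ratio < band[1] | .data$ratio > band[2])
}
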