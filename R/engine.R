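#' Simulation model bundle
#'
#' Packs everything the engine needs: the fitted prediction indices, the
#' registry, the mortality model, calibration intercept shifts, and the
#' configuration (strategy definitions, eligibility rule, baseline-history
#' parameters).
#'
#' @param index_set An `scd_index_set` from [fit_index_set()] (or
#'   [constant_index_set()] for analytic checks).
#' @param registry An `scd_registry`.
#' @param config An `scd_config`.
#' @param shifts Named numeric vector of log-odds intercept shifts applied
#'   to incidence indices (usually produced by [calibrate_to_prevalence()]).
#' @return An object of class `scd_models`.
#' @export
scd_models <- function(index_set, registry = default_registry(),
                       config = default_config(), shifts = numeric()) {
  structure(list(index_set = index_set, registry = registry, config = config,
                 mortality = config$mortality, shifts = shifts),
            class = "scd_models")
}

#' @export
print.scd_models <- function(x, ...) {
  cat("<scd_models>", if (length(x$shifts)) "calibrated" else "uncalibrated",
      "\n")
  print(x$index_set)
  invisible(x)
}

#' Apply calibration intercept shifts
#' @param models An `scd_models`.
#' @param shifts Named log-odds shifts (added to any existing shifts).
#' @export
apply_shifts <- function(models, shifts) {
  all_names <- union(names(models$shifts), names(shifts))
  s <- stats::setNames(rep(0, length(all_names)), all_names)
  s[names(models$shifts)] <- models$shifts
  s[names(shifts)] <- s[names(shifts)] + shifts
  models$shifts <- s
  models
}

#' Treatment strategy
#'
#' `common_care` is the comparator (no treatment, hydroxyurea, or
#' transfusion, without HSCT): identity effect, zero one-time cost. `hsct`
#' and `gene_therapy` apply a durable-response draw at model entry to
#' eligible individuals; responders have attribute incidence multiplied by
#' the configured risk ratios (0 = fully suppressed), non-responders keep
#' common-care dynamics, and both carry the attempted therapy's complication
#' risks.
#'
#' @param name `"common_care"`, `"hsct"`, or `"gene_therapy"`.
#' @param config An `scd_config` supplying effect parameters.
#' @param durability_half_life Optional waning half-life in years (scenario
#'   analysis): responder suppression decays toward no effect.
#' @return An object of class `scd_strategy`.
#' @export
scd_strategy <- function(name = c("common_care", "hsct", "gene_therapy"),
                         config = default_config(),
                         durability_half_life = NULL) {
  name <- match.arg(name)
  sc <- config$strategies[[name]]
  structure(list(
    name = name,
    p_symptom_free = sc$p_symptom_free,
    risk_ratio = sc$risk_ratio,
    risk_ratios = sc$risk_ratios %||% NULL,
    complications = sc$complications,
    cost = sc$cost,
    durability_half_life = durability_half_life,
    eligibility = config$eligibility
  ), class = "scd_strategy")
}

#' Severity-restricted treatment eligibility
#'
#' The default rule declares an individual eligible for curative therapy if
#' their lifetime count of severity-marked acute events (vaso-occlusive
#' episodes, acute chest syndrome, multi-organ failure, stroke) reaches the
#' configured threshold, or they have any stroke in history.
#'
#' @param state An [individual_state()].
#' @param rule List with `min_severe_events` and `stroke_qualifies`
#'   (defaults from config).
#' @param registry An `scd_registry`.
#' @return Logical.
#' @export
check_eligibility <- function(state, rule = default_config()$eligibility,
                              registry = default_registry()) {
  sev <- severity_attributes(registry)
  counts <- state$acute_event_history
  n_sev <- sum(counts[intersect(names(counts), sev)])
  eligible <- n_sev >= rule$min_severe_events
  if (isTRUE(rule$stroke_qualifies) && !is.na(counts["stroke"]) &&
      counts["stroke"] > 0) {
    eligible <- TRUE
  }
  eligible
}

#' A single simulated individual
#'
#' @param age Entry age in years.
#' @param sex `"female"` or `"male"`.
#' @param payer Payer scenario label.
#' @param birth_year Birth year (defaults to entry year 2016 minus age).
#' @param acute_event_history Named counts of lifetime acute events at entry.
#' @param chronic_disorders Character vector of chronic disorders already
#'   present at entry.
#' @return A list of class `scd_individual`.
#' @export
individual_state <- function(age, sex = "male", payer = "medicaid",
                             birth_year = NULL,
                             acute_event_history = numeric(),
                             chronic_disorders = character()) {
  structure(list(
    age = age, sex = sex, payer = payer,
    birth_year = birth_year %||% (2016L - floor(age)),
    alive = TRUE,
    acute_event_history = acute_event_history,
    chronic_disorders = chronic_disorders,
    cured = FALSE, strategy_received = NA_character_
  ), class = "scd_individual")
}

#' Constant-probability index set for analytic checks
#'
#' Builds an index set whose every index is intercept-only: all disease
#' attributes share one annual probability, as do treatments, complications,
#' and utilization rates. With these, simulated statistics have closed
#' forms (e.g. lifetime prevalence `1 - (1-p)^L`) against which the engine
#' is validated.
#'
#' @param registry An `scd_registry`.
#' @param incidence_p Annual event/onset probability for all attributes, or
#'   a named vector per attribute.
#' @param treatment_p Annual treatment-use probability.
#' @param complication_p Annual common-care complication probability.
#' @param utilization_rate Mean annual count per utilization category.
#' @return An `scd_index_set`.
#' @export
constant_index_set <- function(registry = default_registry(),
                               incidence_p = 0.05, treatment_p = 0,
                               complication_p = 0, utilization_rate = 0.5) {
  schema <- covariate_schema(registry, decades = integer())
  da <- disease_attributes(registry)
  pinc <- if (length(incidence_p) == 1L) {
    stats::setNames(rep(incidence_p, nrow(da)), da$name)
  } else incidence_p
  eps <- 1e-12
  sets <- list(
    incidence = purrr::map(rlang::set_names(da$name), function(nm) {
      intercept_index(nm, "incidence", schema, p = clamp(pinc[[nm]], eps, 1 - eps))
    }),
    treatment_use = purrr::map(rlang::set_names(TREATMENTS), function(nm) {
      intercept_index(nm, "treatment_use", schema,
                      p = clamp(treatment_p, eps, 1 - eps))
    }),
    complication = purrr::map(rlang::set_names(schema$complications),
                              function(nm) {
      intercept_index(nm, "complication", schema,
                      p = clamp(complication_p, eps, 1 - eps))
    }),
    utilization = purrr::map(rlang::set_names(UTILIZATION), function(nm) {
      intercept_index(nm, "utilization", schema,
                      rate = max(utilization_rate, eps))
    })
  )
  structure(list(indices = sets, schema = schema), class = "scd_index_set")
}

# ---- engine internals -----------------------------------------------------

N_ENTRY_DRAWS <- 8L

# compile the index set into per-family coefficient matrices aligned to the
# covariate layout, with calibration shifts folded into incidence intercepts
prepare_engine <- function(models) {
  set <- models$index_set
  schema <- set$schema
  registry <- models$registry
  da <- disease_attributes(registry)
  ca <- complication_attributes(registry)

  fams <- purrr::map(names(set$indices), function(fam) {
    ixs <- set$indices[[fam]]
    covars <- schema$family_covariates[[fam]]
    B <- matrix(0, length(covars), length(ixs),
                dimnames = list(covars, names(ixs)))
    b0 <- stats::setNames(numeric(length(ixs)), names(ixs))
    for (nm in names(ixs)) {
      cf <- ixs[[nm]]$coefficients
      b0[nm] <- cf[["(Intercept)"]]
      hit <- intersect(names(cf), covars)
      B[hit, nm] <- cf[hit]
    }
    if (fam == "incidence" && length(models$shifts)) {
      sh <- models$shifts[intersect(names(models$shifts), names(b0))]
      b0[names(sh)] <- b0[names(sh)] + sh
    }
    list(B = B, b0 = b0, covars = covars)
  })
  names(fams) <- names(set$indices)

  attr_names <- da$name
  per <- da$persistence
  cx_names <- ca$name
  cx_per <- ca$persistence
  mort_lhr <- stats::setNames(rep(0, length(attr_names) + length(cx_names)),
                              c(attr_names, cx_names))
  cfg_lhr <- models$mortality$attr_log_hr %||% numeric()
  hit <- intersect(names(cfg_lhr), names(mort_lhr))
  mort_lhr[hit] <- cfg_lhr[hit]

  n_cx <- length(cx_names)
  K <- 3L + length(attr_names) + n_cx + 3L + 1L
  list(
    schema = schema, fams = fams, registry = registry,
    attr_names = attr_names, persistence = per,
    i_acute = which(per == "instantaneous"),
    i_sub = which(per == "subacute"),
    i_chron = which(per == "chronic"),
    i_pain = which(da$dimension == "chronic_pain"),
    cx_names = cx_names, cx_sub = which(cx_per == "subacute"),
    cx_common = match(schema$complications, cx_names),
    mort_lhr = mort_lhr,
    K = K,
    ch_tx = 1:3, ch_inc = 3L + seq_along(attr_names),
    ch_cx = 3L + length(attr_names) + seq_len(n_cx),
    ch_util = 3L + length(attr_names) + n_cx + 1:3,
    ch_mort = K
  )
}

# draw the uniform matrix: one row per individual, each from its own seeded
# substream, consumed by fixed (year, channel) position
draw_uniforms <- function(n, seed, horizon_years, K) {
  len <- N_ENTRY_DRAWS + horizon_years * K
  U <- matrix(NA_real_, n, len)
  for (i in seq_len(n)) {
    set.seed(person_seed(seed, i))
    U[i, ] <- stats::runif(len)
  }
  U
}

#' Population specification for simulation entry cohorts
#'
#' Entry demographics mirror the configured payer scenarios; a multi-payer
#' spec samples payers proportionally to their configured cohort weights.
#' Baseline disease history at entry (lifetime vaso-occlusive episode
#' counts and prior stroke, which drive curative-therapy eligibility) is
#' drawn from simple age-scaled processes set in the config.
#'
#' @param config An `scd_config`.
#' @param payers Payer scenarios to mix (default: the three public payers,
#'   i.e. the combined cohort).
#' @return A list of class `scd_population_spec`.
#' @export
population_spec <- function(config = default_config(),
                            payers = c("medicaid", "medicare", "dual")) {
  w <- purrr::map_dbl(config$payers[payers], "weight")
  structure(list(config = config, payers = payers, weights = w / sum(w)),
            class = "scd_population_spec")
}

# vectorised entry sampling from per-person entry draws
sample_entry <- function(spec, U) {
  n <- nrow(U)
  cfg <- spec$config
  cum <- cumsum(spec$weights)
  payer <- spec$payers[findInterval(U[, 1], cum, left.open = TRUE) + 1L]
  age <- numeric(n)
  for (p in spec$payers) {
    i <- payer == p
    if (!any(i)) next
    pc <- cfg$payers[[p]]
    mu <- tnorm_location(pc$age_mean, pc$age_sd)
    age[i] <- floor(rtnorm0(sum(i), mu, pc$age_sd, u = U[i, 2]))
  }
  female <- U[, 3] < purrr::map_dbl(cfg$payers[payer], "prop_female")
  bh <- cfg$baseline_history
  voe <- stats::qpois(U[, 4], bh$voe_rate * age)
  stroke <- U[, 5] < (1 - (1 - bh$stroke_annual)^age)
  tibble::tibble(age = age, female = female, payer = payer,
                 birth_year = 2016L - as.integer(age),
                 base_voe = voe, base_stroke = as.integer(stroke))
}

#' Simulate a cohort of independent lifetimes
#'
#' Runs `n` individuals through annual cycles under a strategy. Each cycle
#' applies the fixed within-cycle order: ageing and acute-event reset,
#' treatment-use draws, chronic/subacute incidence draws (chronic onsets
#' absorbing, chronic pain drawn in its own dimension), acute-event draws
#' (instantaneous), complication draws, utilization draws, then mortality.
#' Incidence probabilities are multiplied by the strategy's risk ratios for
#' durable responders. Each individual consumes its own random substream,
#' so growing `n` leaves earlier trajectories unchanged.
#'
#' @param n Number of individuals.
#' @param population A [population_spec()], or a tibble of entry rows with
#'   columns `age`, `female`, `payer`, `birth_year`, `base_voe`,
#'   `base_stroke`.
#' @param strategy An [scd_strategy()].
#' @param models An [scd_models()].
#' @param seed Integer seed.
#' @param horizon_age Age cap (default 100).
#' @param keep_trajectories Keep the person-year trajectory table (turn off
#'   for prevalence-only runs such as calibration).
#' @return An `scd_cohort_result`: list with `prevalence` (lifetime
#'   prevalence per attribute, percent), `summary` (mean survival, events
#'   per person-year, eligibility/receipt rates), `entry`, and
#'   `trajectories` (person-year tibble or `NULL`).
#' @export
run_cohort <- function(n, population, strategy, models, seed = 1L,
                       horizon_age = NULL, keep_trajectories = TRUE) {
  stopifnot(n >= 1)
  eng <- prepare_engine(models)
  horizon_age <- horizon_age %||% models$config$simulation$horizon_age
  H <- as.integer(horizon_age)
  U <- draw_uniforms(n, seed, H, eng$K)
  entry <- if (inherits(population, "scd_population_spec")) {
    sample_entry(population, U)
  } else {
    stopifnot(nrow(population) >= n)
    population[seq_len(n), ]
  }
  sim_cohort(entry, U, strategy, eng, models, horizon_age, keep_trajectories)
}

# core vectorised annual-cycle loop
sim_cohort <- function(entry, U, strategy, eng, models, horizon_age,
                       keep_trajectories) {
  n <- nrow(entry)
  A <- length(eng$attr_names); NC <- length(eng$cx_names)
  age <- as.numeric(entry$age)
  female <- as.logical(entry$female)
  birth_year <- as.integer(entry$birth_year)
  alive <- rep(TRUE, n)
  chr_onset <- matrix(NA_integer_, n, length(eng$i_chron))
  sub_last <- matrix(-10L, n, length(eng$i_sub))
  prev_acute <- matrix(FALSE, n, length(eng$i_acute))
  acute_hist <- matrix(0, n, length(eng$i_acute),
                       dimnames = list(NULL, eng$attr_names[eng$i_acute]))
  acute_hist[, "vaso_occlusive_pain"] <- entry$base_voe
  acute_hist[, "stroke"] <- entry$base_stroke
  if ("base_chronic" %in% names(entry)) {
    chron_names <- eng$attr_names[eng$i_chron]
    for (i in seq_len(n)) {
      hit <- match(intersect(entry$base_chronic[[i]], chron_names), chron_names)
      if (length(hit)) chr_onset[i, hit] <- 0L
    }
  }
  pain_years <- numeric(n)
  cx_onset <- matrix(NA_integer_, n, NC)
  cx_last <- matrix(-10L, n, NC)
  tx <- matrix(FALSE, n, 3L, dimnames = list(NULL, TREATMENTS))
  tx_prev <- tx
  ever_attr <- matrix(FALSE, n, A, dimnames = list(NULL, eng$attr_names))
  ever_cx <- matrix(FALSE, n, NC, dimnames = list(NULL, eng$cx_names))
  survival <- numeric(n)
  died_year <- rep(NA_integer_, n)

  # strategy at entry: severity-restricted eligibility, durable-response draw
  sev <- intersect(severity_attributes(eng$registry), colnames(acute_hist))
  n_sev <- rowSums(acute_hist[, sev, drop = FALSE])
  rule <- strategy$eligibility
  eligible <- n_sev >= rule$min_severe_events |
    (isTRUE(rule$stroke_qualifies) & acute_hist[, "stroke"] > 0)
  received <- eligible & strategy$name != "common_care"
  responder <- received & U[, 7] < strategy$p_symptom_free

  rr_base <- rep(1, A)
  if (strategy$name != "common_care") {
    rr_base <- rep(strategy$risk_ratio, A)
    if (!is.null(strategy$risk_ratios)) {
      hit <- intersect(names(strategy$risk_ratios), eng$attr_names)
      rr_base[match(hit, eng$attr_names)] <- strategy$risk_ratios[hit]
    }
  }
  if (any(rr_base < 0)) abort_sim("negative risk ratio", "effect_error")

  p_ther <- function(t) {
    # attempted-therapy complication probabilities, first vs later years
    out <- stats::setNames(rep(0, NC + A), c(eng$cx_names, eng$attr_names))
    for (nm in names(strategy$complications %||% list())) {
      pr <- strategy$complications[[nm]]
      out[nm] <- if (t == 1L) pr[1] else pr[2]
    }
    out
  }

  traj <- if (keep_trajectories) vector("list", horizon_age) else NULL
  layout <- eng$schema$layout
  fam_cols <- purrr::map(eng$fams, ~ match(.x$covars, layout))

  t <- 0L
  while (any(alive) && t < horizon_age) {
    t <- t + 1L
    ia <- which(alive & age < horizon_age)
    if (!length(ia)) break
    m <- length(ia)
    base <- N_ENTRY_DRAWS + (t - 1L) * eng$K
    Ut <- U[ia, base + seq_len(eng$K), drop = FALSE]

    # (1) age one year, clear current-year acute events
    age[ia] <- age[ia] + 1

    X <- matrix(0, m, length(layout), dimnames = list(NULL, layout))
    X[, "female"] <- as.numeric(female[ia])
    X[, eng$schema$age_bands] <- age_band_matrix(age[ia], eng$schema)
    if (length(eng$schema$decades)) {
      X[, sprintf("cohort_%d", eng$schema$decades)] <-
        cohort_matrix(birth_year[ia], eng$schema)
    }
    # previous-year health status and history
    X[, paste0("prev_", eng$attr_names[eng$i_acute])] <-
      prev_acute[ia, , drop = FALSE] + 0
    X[, paste0("prev_", eng$attr_names[eng$i_chron])] <-
      (!is.na(chr_onset[ia, , drop = FALSE])) + 0
    X[, paste0("prev_", eng$attr_names[eng$i_sub])] <-
      (sub_last[ia, , drop = FALSE] >= t - 3L) + 0
    X[, paste0("act_", eng$attr_names[eng$i_sub])] <-
      (sub_last[ia, , drop = FALSE] >= t - 2L) + 0
    X[, paste0("hist_n_", eng$attr_names[eng$i_acute])] <-
      acute_hist[ia, , drop = FALSE]
    X[, "hist_pain_years"] <- pain_years[ia]
    dur <- t - chr_onset[ia, , drop = FALSE]
    dur[is.na(dur)] <- 0
    X[, paste0("dur_", eng$attr_names[eng$i_chron])] <- dur
    X[, paste0("prev_tx_", TREATMENTS)] <- tx_prev[ia, , drop = FALSE] + 0
    X[, paste0("prev_cx_", eng$cx_names[eng$cx_common])] <-
      prev_cx_flags(cx_onset, cx_last, eng, t, ia) + 0

    # (2) treatment-use draws
    fm <- eng$fams$treatment_use
    p_tx <- inv_logit(sweep(X[, fam_cols$treatment_use, drop = FALSE] %*% fm$B,
                            2, fm$b0, "+"))
    new_tx <- Ut[, eng$ch_tx, drop = FALSE] < p_tx
    new_tx[responder[ia], ] <- FALSE  # durable responders come off Common Care
    new_tx[new_tx[, "chronic_transfusion"], "acute_transfusion"] <- FALSE
    tx[ia, ] <- new_tx

    # (3)-(4) incidence draws under strategy risk ratios
    fm <- eng$fams$incidence
    p_inc <- inv_logit(sweep(X[, fam_cols$incidence, drop = FALSE] %*% fm$B,
                             2, fm$b0[eng$attr_names], "+"))
    rr_t <- rr_row(rr_base, strategy, t)
    p_eff <- p_inc
    resp <- responder[ia]
    if (any(resp)) {
      p_eff[resp, ] <- sweep(p_inc[resp, , drop = FALSE], 2, rr_t, "*")
    }
    pt <- p_ther(t)[eng$attr_names]
    if (any(pt > 0) && any(received[ia])) {
      rec <- received[ia]
      p_eff[rec, ] <- 1 - (1 - p_eff[rec, , drop = FALSE]) *
        matrix(1 - pt, sum(rec), A, byrow = TRUE)
    }
    if (any(p_eff > 1 + 1e-12)) {
      bad <- eng$attr_names[which(p_eff > 1, arr.ind = TRUE)[1, 2]]
      abort_sim(paste0("probability above 1 after treatment effect for '",
                       bad, "'"), "effect_error")
    }
    hits <- Ut[, eng$ch_inc, drop = FALSE] < p_eff

    new_chron <- hits[, eng$i_chron, drop = FALSE] &
      is.na(chr_onset[ia, , drop = FALSE])
    chr_onset[ia, ][new_chron] <- t
    sub_hit <- hits[, eng$i_sub, drop = FALSE]
    sl <- sub_last[ia, , drop = FALSE]
    sl[sub_hit] <- t
    sub_last[ia, ] <- sl
    acute_evt <- hits[, eng$i_acute, drop = FALSE]

    cur_chron <- !is.na(chr_onset[ia, , drop = FALSE])
    cur_sub <- sub_last[ia, , drop = FALSE] >= t - 2L

    # (5) complication draws given current treatment and attempted therapy
    X[, paste0("cur_", eng$attr_names[eng$i_acute])] <- acute_evt + 0
    X[, paste0("cur_", eng$attr_names[eng$i_chron])] <- cur_chron + 0
    X[, paste0("cur_", eng$attr_names[eng$i_sub])] <- cur_sub + 0
    X[, paste0("cur_tx_", TREATMENTS)] <- tx[ia, , drop = FALSE] + 0
    fm <- eng$fams$complication
    p_cxc <- inv_logit(sweep(X[, fam_cols$complication, drop = FALSE] %*% fm$B,
                             2, fm$b0, "+"))
    p_cx <- matrix(0, m, NC, dimnames = list(NULL, eng$cx_names))
    p_cx[, eng$cx_common] <- p_cxc
    ptc <- p_ther(t)[eng$cx_names]
    if (any(ptc > 0) && any(received[ia])) {
      rec <- received[ia]
      p_cx[rec, ] <- 1 - (1 - p_cx[rec, , drop = FALSE]) *
        matrix(1 - ptc, sum(rec), NC, byrow = TRUE)
    }
    cx_hits <- Ut[, eng$ch_cx, drop = FALSE] < p_cx
    chron_cx <- setdiff(seq_len(NC), eng$cx_sub)
    oc <- cx_onset[ia, , drop = FALSE]
    oc[, chron_cx][cx_hits[, chron_cx, drop = FALSE] &
                     is.na(oc[, chron_cx, drop = FALSE])] <- t
    cx_onset[ia, ] <- oc
    cl <- cx_last[ia, , drop = FALSE]
    cl[, eng$cx_sub][cx_hits[, eng$cx_sub, drop = FALSE]] <- t
    cx_last[ia, ] <- cl
    cur_cx <- matrix(FALSE, m, NC, dimnames = list(NULL, eng$cx_names))
    cur_cx[, chron_cx] <- !is.na(cx_onset[ia, chron_cx, drop = FALSE])
    cur_cx[, eng$cx_sub] <- cx_last[ia, eng$cx_sub, drop = FALSE] >= t - 2L

    # (6) utilization draws (log-link counts)
    X[, paste0("cur_cx_", eng$cx_names[eng$cx_common])] <-
      cur_cx[, eng$cx_common, drop = FALSE] + 0
    fm <- eng$fams$utilization
    lam <- exp(sweep(X[, fam_cols$utilization, drop = FALSE] %*% fm$B,
                     2, fm$b0, "+"))
    lam <- pmin(lam, 365)
    util <- matrix(stats::qpois(Ut[, eng$ch_util, drop = FALSE], lam), m, 3L,
                   dimnames = list(NULL, UTILIZATION))

    # (7) mortality from combined annual probability
    cur_flags <- matrix(FALSE, m, A, dimnames = list(NULL, eng$attr_names))
    cur_flags[, eng$i_acute] <- acute_evt
    cur_flags[, eng$i_chron] <- cur_chron
    cur_flags[, eng$i_sub] <- cur_sub
    h_bg <- -log(1 - clamp(background_mortality(age[ia], ifelse(female[ia],
                                                                "female", "male"),
                                                models$mortality),
                           0, 0.999999))
    lhr <- cbind(cur_flags, cur_cx) %*% eng$mort_lhr
    q <- clamp01(1 - exp(-h_bg * exp(drop(lhr))))
    died <- Ut[, eng$ch_mort] < q

    survival[ia] <- survival[ia] + 1
    ever_attr[ia, ] <- ever_attr[ia, , drop = FALSE] | cur_flags
    ever_cx[ia, ] <- ever_cx[ia, , drop = FALSE] | cur_cx

    if (keep_trajectories) {
      traj[[t]] <- tibble::tibble(
        person = ia, year_index = t, age = age[ia],
        female = female[ia], payer = entry$payer[ia],
        received = received[ia], responder = responder[ia],
        tibble::as_tibble(cur_flags + 0),
        tibble::as_tibble(`colnames<-`(cur_cx + 0,
                                       paste0("cx_", eng$cx_names))),
        tibble::as_tibble(`colnames<-`(tx[ia, , drop = FALSE] + 0,
                                       paste0("tx_", TREATMENTS))),
        tibble::as_tibble(`colnames<-`(util, paste0("util_",
                                                    tolower(UTILIZATION)))),
        died = died
      )
    }

    # end of cycle: history and lag updates, deaths
    acute_hist[ia, ] <- acute_hist[ia, , drop = FALSE] + acute_evt
    pain_years[ia] <- pain_years[ia] + cur_sub[, match(eng$i_pain, eng$i_sub)]
    prev_acute[ia, ] <- acute_evt
    tx_prev[ia, ] <- tx[ia, , drop = FALSE]
    if (any(died)) {
      died_year[ia[died]] <- t
      alive[ia[died]] <- FALSE
    }
    alive[age >= horizon_age] <- FALSE
  }

  prevalence <- tibble::tibble(
    attribute = eng$attr_names,
    prevalence = 100 * colMeans(ever_attr)
  )
  trajectories <- if (keep_trajectories) {
    tr <- dplyr::bind_rows(traj)
    oto <- strategy$cost * (received + 0)
    tr$therapy_cost <- ifelse(tr$year_index == 1L, oto[tr$person], 0)
    tr
  } else NULL
  events_ppy <- sum(acute_hist) - sum(entry$base_voe) - sum(entry$base_stroke)
  res <- list(
    prevalence = prevalence,
    summary = tibble::tibble(
      n = n, mean_survival = mean(survival),
      events_per_person_year = events_ppy / max(sum(survival), 1),
      prop_eligible = mean(eligible), prop_received = mean(received),
      prop_responder = mean(responder)
    ),
    entry = entry,
    survival = survival, died_year = died_year,
    ever = tibble::as_tibble(cbind(ever_attr, ever_cx)),
    trajectories = trajectories,
    strategy = strategy$name
  )
  structure(res, class = "scd_cohort_result")
}

prev_cx_flags <- function(cx_onset, cx_last, eng, t, ia) {
  out <- matrix(FALSE, length(ia), length(eng$cx_common))
  for (j in seq_along(eng$cx_common)) {
    k <- eng$cx_common[j]
    out[, j] <- if (k %in% eng$cx_sub) {
      cx_last[ia, k] >= t - 3L
    } else {
      !is.na(cx_onset[ia, k])
    }
  }
  out
}

rr_row <- function(rr_base, strategy, t) {
  hl <- strategy$durability_half_life
  if (is.null(hl) || !is.finite(hl)) return(rr_base)
  # waning scenario: suppression decays toward no effect with half-life hl
  1 - (1 - rr_base) * 0.5^((t - 1) / hl)
}

#' @export
print.scd_cohort_result <- function(x, ...) {
  cat(sprintf("<scd_cohort_result> strategy=%s n=%d mean survival=%.1fy\n",
              x$strategy, x$summary$n, x$summary$mean_survival))
  invisible(x)
}

#' Simulate one lifetime
#'
#' Single-individual path through the same kernel as [run_cohort()]; with
#' `seed` equal to the cohort's first person substream the trajectory is
#' identical to the first trajectory of the cohort run.
#'
#' @param state An [individual_state()].
#' @param strategy An [scd_strategy()].
#' @param models An [scd_models()].
#' @param horizon_age Age cap.
#' @param seed Integer seed for this individual's stream.
#' @return An `scd_cohort_result` with a single-person trajectory.
#' @export
simulate_lifetime <- function(state, strategy, models, horizon_age = 100,
                              seed = 1L) {
  eng <- prepare_engine(models)
  set.seed(seed)
  U <- matrix(stats::runif(N_ENTRY_DRAWS + horizon_age * eng$K), 1)
  hist <- state$acute_event_history
  entry <- tibble::tibble(
    age = state$age, female = state$sex == "female", payer = state$payer,
    birth_year = state$birth_year,
    base_voe = unname(hist["vaso_occlusive_pain"] %|NA|% 0),
    base_stroke = unname(hist["stroke"] %|NA|% 0),
    base_chronic = list(state$chronic_disorders)
  )
  sim_cohort(entry, U, strategy, eng, models, horizon_age,
             keep_trajectories = TRUE)
}

`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Advance one individual by a single model cycle
#'
#' Exposes the engine's within-cycle update order for a single individual:
#' ageing, treatment use, incidence, acute events, complications,
#' utilization, mortality. Mainly useful for inspecting the transition
#' mechanics; cohort work should use [run_cohort()].
#'
#' @param state An [individual_state()].
#' @param models An [scd_models()].
#' @param strategy An [scd_strategy()] (default Common Care).
#' @param seed Integer seed for the cycle's draws.
#' @return A list with `state` (updated) and `record` (one-row tibble).
#' @export
advance_year <- function(state, models, strategy = NULL, seed = 1L) {
  if (!state$alive) abort_sim("cannot advance a dead individual", "state_error")
  strategy <- strategy %||% scd_strategy("common_care", models$config)
  res <- simulate_lifetime(state, strategy, models,
                           horizon_age = state$age + 1, seed = seed)
  record <- res$trajectories[1, ]
  new_state <- state
  new_state$age <- state$age + 1
  new_state$alive <- !record$died
  da <- disease_attributes(models$registry)
  acute <- da$name[da$persistence == "instantaneous"]
  hist <- stats::setNames(rep(0, length(acute)), acute)
  hist[names(new_state$acute_event_history)] <- new_state$acute_event_history
  new_state$acute_event_history <- hist + unlist(record[acute])
  new_state$chronic_disorders <- union(
    state$chronic_disorders,
    da$name[da$persistence == "chronic"][unlist(record[da$name[da$persistence == "chronic"]]) > 0]
  )
  list(state = new_state, record = record)
}
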