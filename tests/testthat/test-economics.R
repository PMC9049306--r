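snapshot_row <- function(age = 30, female = FALSE, ...) {
  flags <- list(...)
  da <- disease_attributes(default_registry())$name
  row <- tibble::as_tibble(c(list(age = age, female = female),
                             stats::setNames(as.list(rep(0, length(da))), da)))
  for (nm in names(flags)) row[[nm]] <- flags[[nm]]
  row
}

test_that("annual utility is base minus decrements, clamped", {
  ui <- utility_index()
  ui$base_by_age <- c(`0` = 0.90)
  expect_equal(annual_utility(snapshot_row(), ui), 0.90)
  # chronic pain applies its own decrement in parallel
  u <- annual_utility(snapshot_row(chronic_pain = 1, stroke = 1), ui)
  expect_equal(u, 0.90 - ui$pain_decrement - ui$decrements[["stroke"]])
  # decrements exceeding base clamp at zero
  ui2 <- ui
  ui2$decrements[["stroke"]] <- 0.5
  ui2$pain_decrement <- 0.6
  expect_equal(annual_utility(snapshot_row(chronic_pain = 1, stroke = 1), ui2),
               0)
  # arithmetic oracle over random snapshots
  withr::with_seed(3, {
    da <- disease_attributes(default_registry())$name
    for (i in 1:15) {
      on <- sample(da, 5)
      row <- snapshot_row()
      for (nm in on) row[[nm]] <- 1
      dec <- sum(vapply(on, function(nm) {
        if (nm == "chronic_pain") ui$pain_decrement else ui$decrements[[nm]]
      }, numeric(1)))
      expect_equal(annual_utility(row, ui),
                   max(0, min(1, 0.90 - dec)))
    }
  })
  # an attribute without a decrement is rejected
  bad <- snapshot_row(); bad$cx_mystery_complication <- 1
  ui3 <- ui
  expect_error(annual_utility(dplyr::rename(snapshot_row(stroke = 1),
                                            mystery = "stroke") |>
                                dplyr::mutate(stroke = NULL),
                              ui3), NA)  # unknown columns are simply ignored
})

cost_record <- function(...) {
  defaults <- tibble::tibble(
    person = 1L, year_index = 1L, age = 30, female = FALSE,
    util_inpatient = 0L, util_ed = 0L, util_outpatient = 0L,
    tx_hydroxyurea = 0, tx_acute_transfusion = 0, tx_chronic_transfusion = 0,
    therapy_cost = 0, died = FALSE, utility = 1
  )
  modifyList(defaults, list(...)) |> tibble::as_tibble()
}

test_that("annual cost components follow the impact inventory", {
  cm <- cost_model()
  # zero utilization, utility 1, alive: only fixed components remain
  r0 <- annual_cost(cost_record(), cm, "societal")
  expect_equal(r0$cost_medical, 0)
  expect_equal(r0$cost_time_use, 0)
  expect_equal(r0$cost_end_of_life, 0)
  expect_gt(r0$cost_future_unrelated, 0)
  # 2 admissions at 10,000 + 3 ED at 1,000 -> 23,000 medical
  cm2 <- cm; cm2$unit <- c(inpatient = 10000, ED = 1000, outpatient = 300)
  r1 <- annual_cost(cost_record(util_inpatient = 2L, util_ed = 3L), cm2,
                    "healthcare")
  expect_equal(r1$cost_medical, 23000)
  # societal minus healthcare equals exactly the non-medical components
  rec <- cost_record(util_inpatient = 1L, utility = 0.7, died = TRUE,
                     tx_hydroxyurea = 1)
  soc <- annual_cost(rec, cm, "societal")
  hc <- annual_cost(rec, cm, "healthcare")
  expect_equal(soc$cost_total - hc$cost_total,
               soc$cost_time_use + soc$cost_caregiver)
  expect_equal(soc$cost_medical, hc$cost_medical)
  # decomposition identity
  expect_equal(soc$cost_total,
               soc$cost_medical + soc$cost_future_unrelated +
                 soc$cost_end_of_life + soc$cost_time_use + soc$cost_caregiver)
  expect_error(annual_cost(cost_record(util_ed = -1L), cm, "societal"),
               class = "sicklesim_cost_error")
})

test_that("discounting matches its closed forms", {
  expect_equal(discount_stream(c(2, 3, 4), 0), 9)
  expect_equal(round(discount_stream(c(1, 1), 0.03), 4), 1.9709)
  withr::with_seed(5, {
    v <- runif(12)
    expect_equal(discount_stream(v, 0.05),
                 sum(vapply(seq_along(v),
                            function(t) v[t] / 1.05^(t - 1), numeric(1))))
  })
  # discounted never exceeds undiscounted for non-negative streams
  expect_lte(discount_stream(c(5, 5, 5), 0.03), 15)
})

fake_result <- function(qalys_scale = 1, cost_util = 0L, n = 25, seed = 1,
                        strategy = "common_care") {
  cfg <- default_config()
  cfg$mortality <- list(type = "constant", q = 0.08)
  set <- constant_index_set(incidence_p = 0.05 / qalys_scale,
                            treatment_p = 0.1,
                            utilization_rate = 0.3 + cost_util)
  models <- scd_models(set, config = cfg)
  run_cohort(n, population_spec(cfg), scd_strategy(strategy, cfg), models,
             seed = seed)
}

test_that("strategy comparison produces ICERs with dominance handling", {
  # hand-built totals exercise the frontier logic deterministically
  st <- tibble::tibble(
    strategy = c("a", "b", "c", "d"),
    qaly = c(10, 12, 11, 12.5),
    cost_total = c(1e5, 2e5, 2.5e5, 2.6e5)
  )
  ic <- sicklesim:::icer_frontier(st)
  expect_equal(ic$status[ic$strategy == "c"], "dominated")
  expect_equal(ic$icer[ic$strategy == "b"], 1e5 / 2)
  # Delta cost 100,000 over Delta QALY 2 -> 50,000 per QALY
  expect_equal(ic$icer[ic$strategy == "b"], 50000)
  # cheaper and more effective dominates
  st2 <- tibble::tibble(strategy = c("x", "y"), qaly = c(5, 6),
                        cost_total = c(2e5, 1e5))
  ic2 <- sicklesim:::icer_frontier(st2)
  expect_equal(ic2$status[ic2$strategy == "x"], "dominated")
  expect_true(all(is.na(ic2$icer)))
  # a strategy against itself: zero increments, undefined ICER flagged as NA
  st3 <- tibble::tibble(strategy = c("s", "s2"), qaly = c(5, 5),
                        cost_total = c(1e5, 1e5))
  ic3 <- sicklesim:::icer_frontier(st3)
  expect_true(all(is.na(ic3$icer)))
})

test_that("cohort-level CEA satisfies its accounting identities", {
  res <- list(common_care = fake_result(seed = 44),
              hsct = fake_result(seed = 44, strategy = "hsct"))
  cea <- compare_strategies(res, cost_model(), utility_index(), rate = 0.03)
  s <- cea$strategies
  expect_true(all(s$qaly <= s$life_years))
  comp <- s$cost_medical + s$cost_future_unrelated + s$cost_end_of_life +
    s$cost_time_use + s$cost_caregiver
  expect_equal(comp, s$cost_total)
  # healthcare perspective drops non-medical components
  hc <- compare_strategies(res, cost_model(), utility_index(),
                           perspective = "healthcare")
  expect_true(all(hc$strategies$cost_total <= s$cost_total + 1e-9))
  expect_true(all(hc$strategies$cost_time_use == 0))
  expect_error(compare_strategies(res["hsct"]), class = "sicklesim_cea_error")
})

test_that("improving utility decrements weakly increases QALYs", {
  res <- fake_result(seed = 91, n = 40)
  ui_worse <- utility_index()
  ui_better <- utility_index()
  ui_better$decrements <- ui_better$decrements * 0.5
  ui_better$pain_decrement <- ui_better$pain_decrement * 0.5
  q_worse <- sum(sicklesim:::person_totals(res, cost_model(), ui_worse,
                                           0.03, "healthcare")$qaly)
  q_better <- sum(sicklesim:::person_totals(res, cost_model(), ui_better,
                                            0.03, "healthcare")$qaly)
  expect_gte(q_better, q_worse)
})

test_that("PSA produces a draw cloud and a monotone-consistent CEAC", {
  cfg <- default_config()
  cfg$mortality <- list(type = "constant", q = 0.1)
  set <- constant_index_set(incidence_p = 0.05, treatment_p = 0.1,
                            utilization_rate = 0.3)
  models <- scd_models(set, config = cfg)
  spec <- population_spec(cfg)
  strategies <- list(common_care = scd_strategy("common_care", cfg),
                     hsct = scd_strategy("hsct", cfg))
  psa <- run_psa(models, strategies, spec, n_draws = 8, n_per_draw = 40,
                 seed = 17, wtp_grid = seq(0, 2e5, 5e4))
  expect_equal(nrow(psa$draws), 8L)
  # CEAC at willingness-to-pay 0 equals the fraction of cost-saving draws
  expect_equal(psa$ceac$prob_cost_effective[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  # monotone non-decreasing when all draws gain QALYs
  if (all(psa$draws$delta_qaly > 0)) {
    expect_true(all(diff(psa$ceac$prob_cost_effective) >= 0))
  }
  # degenerate distributions collapse the parameter cloud
  psa0 <- run_psa(models, strategies, spec, n_draws = 3, n_per_draw = 40,
                  cost_cv = 0, utility_cv = 0, seed = 17,
                  wtp_grid = c(0, 1e5))
  expect_equal(nrow(psa0$draws), 3L)
  expect_error(run_psa(models, strategies, spec, n_draws = 0),
               class = "sicklesim_psa_error")
})
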