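#' Health-state utility index
#'
#' Annual utility is a base value by age band (and sex shift) minus additive
#' decrements for each active disease attribute and treatment complication,
#' with the chronic-pain decrement applied in parallel with all others, then
#' clamped to `[0, 1]`. Optional pairwise interaction terms (named
#' `"a:b"`) adjust the sum when both attributes are active.
#'
#' @param config An `scd_config` supplying defaults.
#' @param interactions Optional named numeric vector of pairwise adjustments.
#' @return An object of class `scd_utility_index`.
#' @export
utility_index <- function(config = default_config(), interactions = NULL) {
  u <- config$utility
  structure(list(base_by_age = u$base_by_age, female_delta = u$female_delta,
                 pain_decrement = u$pain_decrement, decrements = u$decrements,
                 interactions = interactions),
            class = "scd_utility_index")
}

#' Annual utility for person-year snapshots
#'
#' @param snapshot A trajectory tibble (rows = living person-years) with
#'   attribute flag columns as produced by [run_cohort()].
#' @param index An [utility_index()].
#' @param registry An `scd_registry` naming the attribute columns.
#' @return Numeric vector of utilities in `[0, 1]`.
#' @export
annual_utility <- function(snapshot, index, registry = default_registry()) {
  base <- age_band_value(snapshot$age, index$base_by_age) +
    ifelse(snapshot$female, index$female_delta, 0)
  dec_names <- names(index$decrements)
  attr_cols <- c(
    intersect(names(snapshot), disease_attributes(registry)$name),
    intersect(names(snapshot),
              paste0("cx_", complication_attributes(registry)$name))
  )
  plain <- sub("^cx_", "", attr_cols)
  unknown <- setdiff(setdiff(plain, "chronic_pain"), dec_names)
  if (length(unknown)) {
    abort_sim(paste0("no utility decrement for attribute(s): ",
                     paste(unknown, collapse = ", ")), "utility_error")
  }
  total <- rep(0, nrow(snapshot))
  for (i in seq_along(attr_cols)) {
    nm <- plain[i]
    d <- if (nm == "chronic_pain") index$pain_decrement else index$decrements[[nm]]
    total <- total + snapshot[[attr_cols[i]]] * d
  }
  for (nm in names(index$interactions %||% c())) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    ca <- intersect(c(pair[1], paste0("cx_", pair[1])), names(snapshot))[1]
    cb <- intersect(c(pair[2], paste0("cx_", pair[2])), names(snapshot))[1]
    total <- total + snapshot[[ca]] * snapshot[[cb]] * index$interactions[[nm]]
  }
  clamp01(base - total)
}

#' Cost model
#'
#' @param config An `scd_config` supplying unit costs, treatment costs,
#'   time-use and caregiver coefficients, future-unrelated age schedule,
#'   and the end-of-life cost.
#' @return An object of class `scd_cost_model`.
#' @export
cost_model <- function(config = default_config()) {
  structure(config$costs, class = "scd_cost_model")
}

#' Annual cost breakdown for person-year records
#'
#' Medical costs are utilization times unit costs plus treatment costs (and
#' any one-time therapy price in the record). The societal perspective adds
#' time-use/productivity costs -- linear in the utility shortfall `(1 - u)`
#' times an hours coefficient and a wage-plus-fringe rate -- and unpaid
#' caregiver time. Future unrelated medical costs (age-specific) and the
#' end-of-life cost in the death year are counted in both perspectives.
#'
#' @param records Trajectory tibble with utilization, treatment, flag and
#'   `died` columns; a `utility` column is required for the societal
#'   perspective (add via [annual_utility()]).
#' @param costs An [cost_model()].
#' @param perspective `"societal"` or `"healthcare"`.
#' @return The records tibble with cost component columns
#'   (`cost_medical`, `cost_future_unrelated`, `cost_end_of_life`,
#'   `cost_time_use`, `cost_caregiver`) and `cost_total`.
#' @export
annual_cost <- function(records, costs, perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  if (any(records$util_inpatient < 0 | records$util_ed < 0 |
            records$util_outpatient < 0)) {
    abort_sim("negative utilization count", "cost_error")
  }
  medical <- records$util_inpatient * costs$unit[["inpatient"]] +
    records$util_ed * costs$unit[["ED"]] +
    records$util_outpatient * costs$unit[["outpatient"]] +
    records$tx_hydroxyurea * costs$hydroxyurea_annual +
    records$tx_acute_transfusion * costs$acute_transfusion_annual +
    records$tx_chronic_transfusion * costs$chronic_transfusion_annual +
    (records$therapy_cost %||% 0)
  future <- age_band_value(records$age, costs$future_unrelated_by_age)
  eol <- as.numeric(records$died) * costs$end_of_life
  out <- dplyr::mutate(records, cost_medical = medical,
                       cost_future_unrelated = unname(future),
                       cost_end_of_life = eol)
  if (perspective == "societal") {
    if (!"utility" %in% names(records)) {
      abort_sim("societal costing needs a 'utility' column", "cost_error")
    }
    any_active <- rowSums(dplyr::select(
      records, dplyr::any_of(disease_attributes(default_registry())$name))) > 0
    out$cost_time_use <- (1 - records$utility) * costs$time_use_hours *
      costs$wage_rate
    out$cost_caregiver <- ifelse(records$age < 18, costs$caregiver_child,
                                 costs$caregiver_adult) * any_active
  } else {
    out$cost_time_use <- 0
    out$cost_caregiver <- 0
  }
  out$cost_total <- out$cost_medical + out$cost_future_unrelated +
    out$cost_end_of_life + out$cost_time_use + out$cost_caregiver
  out
}

#' Present value of an annual stream
#'
#' @param values Numeric stream, indexed from year 0 (i.e. the first element
#'   is undiscounted).
#' @param rate Annual discount rate (default 3%).
#' @return Scalar present value.
#' @examples
#' discount_stream(c(1, 1), 0.03)  # 1.9709
#' @export
discount_stream <- function(values, rate = 0.03) {
  stopifnot(rate > -1)
  sum(values / (1 + rate)^(seq_along(values) - 1))
}

# per-person discounted totals for one strategy's trajectories
person_totals <- function(result, costs, uindex, rate, perspective) {
  tr <- result$trajectories
  tr$utility <- annual_utility(tr, uindex)
  tr <- annual_cost(tr, costs, perspective)
  tr$.disc <- (1 + rate)^-(tr$year_index - 1)
  comp_cols <- grep("^cost_", names(tr), value = TRUE)
  tr |>
    dplyr::group_by(.data$person) |>
    dplyr::summarise(
      life_years = dplyr::n(),
      qaly = sum(.data$utility * .data$.disc),
      dplyr::across(dplyr::all_of(comp_cols),
                    ~ sum(.x * .data$.disc)),
      .groups = "drop"
    )
}

#' Compare strategies: discounted costs, QALYs, and ICERs
#'
#' Computes per-strategy mean discounted costs (by component), QALYs and
#' life years, then incremental cost-effectiveness ratios along the
#' non-dominated frontier. Strictly dominated strategies (costlier and less
#' effective) and extended-dominated strategies are flagged and excluded
#' from ICER computation. Run the strategies with common seeds (common
#' random numbers) for variance reduction.
#'
#' @param results Named list of `scd_cohort_result` objects (one per
#'   strategy, trajectories kept).
#' @param costs An [cost_model()].
#' @param uindex An [utility_index()].
#' @param rate Annual discount rate for both costs and QALYs.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return An `scd_cea`: list with `strategies` (per-strategy means),
#'   `icers`, `perspective`, `rate`.
#' @export
compare_strategies <- function(results, costs = cost_model(),
                               uindex = utility_index(), rate = 0.03,
                               perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  if (length(results) < 2L) abort_sim("need at least 2 strategies", "cea_error")
  per <- purrr::imap(results, function(res, nm) {
    pt <- person_totals(res, costs, uindex, rate, perspective)
    comp <- dplyr::summarise(pt, dplyr::across(dplyr::where(is.numeric), mean))
    dplyr::mutate(comp, strategy = nm, person = NULL, .before = 1)
  })
  strategies <- dplyr::bind_rows(per)
  icers <- icer_frontier(strategies)
  structure(list(strategies = strategies, icers = icers,
                 perspective = perspective, rate = rate),
            class = "scd_cea")
}

# standard CEA frontier: order by cost; strict then extended dominance
icer_frontier <- function(strategies) {
  s <- dplyr::arrange(strategies[, c("strategy", "cost_total", "qaly")],
                      .data$cost_total, .data$qaly)
  s$status <- "frontier"
  s$icer <- NA_real_
  # strict dominance
  repeat {
    dominated <- rep(FALSE, nrow(s))
    front <- which(s$status == "frontier")
    for (i in front) {
      others <- setdiff(front, i)
      dominated[i] <- any(s$qaly[others] >= s$qaly[i] &
                            s$cost_total[others] <= s$cost_total[i] &
                            (s$qaly[others] > s$qaly[i] |
                               s$cost_total[others] < s$cost_total[i]))
    }
    if (!any(dominated)) break
    s$status[dominated] <- "dominated"
  }
  # sequential ICERs with extended dominance
  repeat {
    front <- which(s$status == "frontier")
    s$icer[front] <- NA_real_
    if (length(front) >= 2L) {
      for (k in 2:length(front)) {
        i <- front[k]; j <- front[k - 1]
        dq <- s$qaly[i] - s$qaly[j]
        dc <- s$cost_total[i] - s$cost_total[j]
        s$icer[i] <- if (abs(dq) < 1e-12) NA_real_ else dc / dq
      }
      ic <- s$icer[front][-1]
      ext <- which(diff(ic) < 0)
      if (length(ext)) {
        s$status[front[ext + 1]] <- "extended_dominated"
        next
      }
    }
    break
  }
  s$icer[s$status != "frontier"] <- NA_real_
  tibble::as_tibble(s)
}

#' @export
print.scd_cea <- function(x, ...) {
  cat(sprintf("<scd_cea> %s perspective, %.0f%% discount\n", x$perspective,
              100 * x$rate))
  print(as.data.frame(x$icers), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.scd_cea <- function(x, ...) {
  dplyr::left_join(x$strategies,
                   x$icers[, c("strategy", "status", "icer")],
                   by = "strategy")
}

#' @export
glance.scd_cea <- function(x, ...) {
  front <- x$icers[x$icers$status == "frontier", ]
  tibble::tibble(perspective = x$perspective, rate = x$rate,
                 n_strategies = nrow(x$strategies),
                 n_frontier = nrow(front),
                 max_icer = suppressWarnings(max(front$icer, na.rm = TRUE)))
}

#' Probabilistic sensitivity analysis
#'
#' Each draw perturbs the model parameters -- one bootstrap coefficient
#' replicate per index when a bootstrap set is supplied, gamma-distributed
#' unit costs, and beta-like utility decrements -- then reruns a reduced-n
#' cohort per strategy with common random numbers, recording incremental
#' cost and QALYs of the second strategy versus the first. The
#' cost-effectiveness acceptability curve (CEAC) is the fraction of draws
#' cost-effective across a willingness-to-pay grid.
#'
#' @param models An [scd_models()].
#' @param strategies Named list of exactly two [scd_strategy()] objects
#'   (comparator first).
#' @param population A [population_spec()].
#' @param costs,uindex Cost model and utility index point estimates.
#' @param n_draws Number of PSA draws.
#' @param n_per_draw Cohort size per draw.
#' @param bootstrap Optional named list of `scd_bootstrap` objects keyed by
#'   incidence outcome; when present a replicate is sampled per draw.
#' @param cost_cv,utility_cv Coefficients of variation for cost/utility
#'   parameter distributions (degenerate at 0).
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param rate Discount rate.
#' @param seed Integer seed.
#' @return An `scd_psa`: `draws` tibble (delta_cost, delta_qaly) and `ceac`
#'   tibble (wtp, prob_cost_effective).
#' @export
run_psa <- function(models, strategies, population, costs = cost_model(),
                    uindex = utility_index(), n_draws = 100L,
                    n_per_draw = 500L, bootstrap = NULL, cost_cv = 0.2,
                    utility_cv = 0.15, wtp_grid = seq(0, 5e5, by = 25000),
                    rate = 0.03, seed = 1L) {
  if (n_draws < 1L) abort_sim("n_draws must be >= 1", "psa_error")
  stopifnot(length(strategies) == 2L)
  draws <- purrr::map_dfr(seq_len(n_draws), function(d) {
    dseed <- substream_seed(seed, paste0("psa_", d))
    withr::with_seed(dseed, {
      m_d <- models
      if (!is.null(bootstrap)) {
        for (nm in names(bootstrap)) {
          reps <- bootstrap[[nm]]$replicates
          if (nrow(reps) > 0L) {
            pick <- reps[sample(nrow(reps), 1L), ]
            m_d$index_set$indices$incidence[[nm]]$coefficients <- pick
          }
        }
      }
      c_d <- costs
      if (cost_cv > 0) {
        g <- function(x) x * stats::rgamma(length(x), shape = 1 / cost_cv^2,
                                          scale = cost_cv^2)
        c_d$unit <- g(c_d$unit)
        c_d$end_of_life <- g(c_d$end_of_life)
      }
      u_d <- uindex
      if (utility_cv > 0) {
        u_d$decrements <- clamp01(u_d$decrements *
                                    stats::rgamma(length(u_d$decrements),
                                                  shape = 1 / utility_cv^2,
                                                  scale = utility_cv^2))
        u_d$pain_decrement <- clamp01(u_d$pain_decrement *
                                        stats::rgamma(1, 1 / utility_cv^2,
                                                      scale = utility_cv^2))
      }
      cseed <- substream_seed(dseed, "cohort")
      res <- purrr::map(strategies, ~ run_cohort(
        n_per_draw, population, .x, m_d, seed = cseed,
        keep_trajectories = TRUE))
      tot <- purrr::map(res, ~ person_totals(.x, c_d, u_d, rate, "societal"))
      tibble::tibble(
        draw = d,
        delta_cost = mean(tot[[2]]$cost_total) - mean(tot[[1]]$cost_total),
        delta_qaly = mean(tot[[2]]$qaly) - mean(tot[[1]]$qaly)
      )
    })
  })
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = purrr::map_dbl(
      wtp_grid, ~ mean(.x * draws$delta_qaly - draws$delta_cost > 0))
  )
  structure(list(draws = draws, ceac = ceac), class = "scd_psa")
}

#' @export
print.scd_psa <- function(x, ...) {
  cat(sprintf("<scd_psa> %d draws; mean dCost=%.0f, mean dQALY=%.2f\n",
              nrow(x$draws), mean(x$draws$delta_cost),
              mean(x$draws$delta_qaly)))
  invisible(x)
}
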