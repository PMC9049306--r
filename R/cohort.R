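#' Cohort definition
#'
#' @param payer Optional payer filter (character vector).
#' @param window Study window, first and last calendar year.
#' @param min_enrollment_months Required continuous enrollment after the
#'   index date (default 12).
#' @return A list of class `scd_cohort_definition`.
#' @export
cohort_definition <- function(payer = NULL, window = c(2008L, 2016L),
                              min_enrollment_months = 12L) {
  if (length(window) != 2L || window[2] < window[1]) {
    abort_sim("empty study window", "config_error")
  }
  structure(list(payer = payer, window = as.integer(window),
                 min_enrollment_months = as.integer(min_enrollment_months)),
            class = "scd_cohort_definition")
}

#' Identify SCD cases from a claims table
#'
#' A beneficiary is a case with one inpatient claim carrying an SCD
#' diagnosis in any position, or claims on two distinct dates in the
#' outpatient / ED / ambulatory settings with an SCD diagnosis in any
#' position. Sickle cell trait codes never qualify.
#'
#' @param claims Claims tibble (long in diagnosis position).
#' @param registry An `scd_registry`.
#' @return Character vector of case beneficiary ids.
#' @export
identify_cases <- function(claims, registry = default_registry()) {
  if (!nrow(claims)) return(character())
  scd <- claims[scd_claim_rows(claims, registry), ]
  inpat <- unique(scd$beneficiary_id[scd$setting == "inpatient"])
  outp <- scd[scd$setting %in% c("outpatient", "ED", "ambulatory"), ]
  two <- outp |>
    dplyr::distinct(.data$beneficiary_id, .data$service_date) |>
    dplyr::count(.data$beneficiary_id) |>
    dplyr::filter(.data$n >= 2L)
  sort(unique(c(inpat, two$beneficiary_id)))
}

scd_claim_rows <- function(claims, registry) {
  out <- rep(FALSE, nrow(claims))
  for (ed in c("icd9", "icd10")) {
    i <- claims$edition == ed
    if (any(i)) out[i] <- is_scd_code(claims$code[i], ed, registry)
  }
  out
}

#' Index date: first SCD-coded utilization during enrollment
#'
#' @param claims Claims tibble.
#' @param enrollment Enrollment spans tibble (`start_month`, `end_month`).
#' @param registry An `scd_registry`.
#' @param ids Optional beneficiary ids that must receive an index date; an
#'   id with no in-span SCD claim raises an error (it signals a selection
#'   bug upstream).
#' @return Tibble `beneficiary_id`, `index_date`.
#' @export
compute_index_date <- function(claims, enrollment,
                               registry = default_registry(), ids = NULL) {
  scd <- claims[scd_claim_rows(claims, registry), ]
  scd <- claims_in_spans(scd, enrollment)
  idx <- scd |>
    dplyr::group_by(.data$beneficiary_id) |>
    dplyr::summarise(index_date = min(.data$service_date), .groups = "drop")
  if (!is.null(ids)) {
    missing <- setdiff(ids, idx$beneficiary_id)
    if (length(missing)) {
      abort_sim(paste0("case(s) with no in-span SCD claim: ",
                       paste(utils::head(missing, 5), collapse = ", ")),
                "index_error")
    }
    idx <- idx[idx$beneficiary_id %in% ids, ]
  }
  idx
}

claims_in_spans <- function(claims, enrollment) {
  sp <- dplyr::mutate(enrollment, s = ym_index(.data$start_month),
                      e = ym_index(.data$end_month))
  x <- dplyr::inner_join(
    dplyr::mutate(claims, m = ym_index(.data$service_date)),
    sp[, c("beneficiary_id", "s", "e")],
    by = "beneficiary_id", relationship = "many-to-many"
  )
  x <- x[x$m >= x$s & x$m <= x$e, ]
  dplyr::distinct(dplyr::select(x, -"s", -"e", -"m"))
}

# longest span per beneficiary; ties break to the earliest start
longest_spans <- function(enrollment) {
  sp <- dplyr::mutate(enrollment, s = ym_index(.data$start_month),
                      e = ym_index(.data$end_month))
  check_spans(sp)
  sp |>
    dplyr::mutate(len = .data$e - .data$s + 1L) |>
    dplyr::group_by(.data$beneficiary_id) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$s, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

check_spans <- function(sp) {
  bad <- sp |>
    dplyr::group_by(.data$beneficiary_id) |>
    dplyr::arrange(.data$s, .by_group = TRUE) |>
    dplyr::mutate(overlap = .data$s <= dplyr::lag(.data$e, default = -1L)) |>
    dplyr::ungroup()
  if (any(bad$overlap)) {
    abort_sim(paste0("overlapping enrollment spans for: ",
                     paste(utils::head(unique(bad$beneficiary_id[bad$overlap]), 5),
                           collapse = ", ")), "span_error")
  }
  invisible(sp)
}

#' Build the annual person-year panel
#'
#' Implements the claims-analysis procedure: case identification, index
#' date within the (single, longest) enrollment span, a 12-month continuous
#' enrollment requirement after index, censoring at the earliest of death,
#' disenrollment, the year preceding HSCT, or the window end, and annual
#' attribute flags under the persistence semantics (acute: qualifying claim
#' that year; subacute: qualifying claim in the current or two preceding
#' years; chronic: every year from the first qualifying claim). Partial
#' first/last years count as whole panel years; the death year is included;
#' the disenrollment year is excluded when the span ends mid-year.
#'
#' @param population An `scd_population` (or an equivalent list of tables).
#' @param definition A [cohort_definition()].
#' @param registry An `scd_registry`.
#' @return A tibble of class `scd_panel`, one row per (beneficiary, year),
#'   with `evt_*` (qualifying claim that year), `flag_*` (persistence
#'   semantics), complication `evt_cx_*`/`flag_cx_*`, treatment `tx_*`,
#'   utilization `util_*` columns and a `censored_reason` on each final
#'   row. The attrition table is attached as `attr(panel, "attrition")`.
#' @export
build_panel <- function(population, definition = cohort_definition(),
                        registry = default_registry()) {
  ben <- population$beneficiaries
  claims <- population$claims
  enrollment <- population$enrollment
  if (!is.null(definition$payer)) {
    ben <- ben[ben$payer %in% definition$payer, ]
    claims <- claims[claims$beneficiary_id %in% ben$beneficiary_id, ]
    enrollment <- enrollment[enrollment$beneficiary_id %in% ben$beneficiary_id, ]
  }
  attrition <- list(beneficiaries = nrow(ben))

  cases <- identify_cases(claims, registry)
  attrition$cases <- length(cases)

  sp <- longest_spans(enrollment[enrollment$beneficiary_id %in% cases, ])
  spans_tbl <- tibble::tibble(beneficiary_id = sp$beneficiary_id,
                              start_month = sp$start_month,
                              end_month = sp$end_month)
  idx <- compute_index_date(claims, spans_tbl, registry)
  attrition$with_index_in_longest_span <- nrow(idx)

  info <- idx |>
    dplyr::inner_join(sp, by = "beneficiary_id") |>
    dplyr::mutate(index_m = ym_index(.data$index_date))
  # continuous enrollment: the (gapless) span must cover the index month
  # plus min_enrollment_months - 1 further months
  info <- info[info$e - info$index_m + 1L >= definition$min_enrollment_months, ]
  attrition$continuously_enrolled <- nrow(info)

  hsct <- claims |>
    dplyr::filter(.data$procedure == "hsct") |>
    dplyr::mutate(hy = as.integer(format(.data$service_date, "%Y"))) |>
    dplyr::distinct(.data$beneficiary_id, .data$hy) |>
    dplyr::arrange(.data$beneficiary_id, .data$hy) |>
    dplyr::distinct(.data$beneficiary_id, .keep_all = TRUE) |>
    dplyr::rename(hsct_year = "hy")
  info <- info |>
    dplyr::left_join(ben[, c("beneficiary_id", "payer", "sex", "birth_year",
                             "death_year")], by = "beneficiary_id") |>
    dplyr::left_join(hsct, by = "beneficiary_id") |>
    dplyr::mutate(
      index_year = .data$index_m %/% 12L,
      # a span ending mid-year drops the disenrollment year -- unless the
      # span ends because of death, where the death year counts in full
      disenroll_year = dplyr::if_else(
        !is.na(.data$death_year) & .data$e %/% 12L == .data$death_year,
        .data$death_year,
        .data$e %/% 12L - as.integer(.data$e %% 12L != 11L)),
      end_candidates = pmin(
        dplyr::coalesce(.data$death_year, .Machine$integer.max),
        dplyr::coalesce(.data$hsct_year - 1L, .Machine$integer.max),
        .data$disenroll_year, definition$window[2]
      ),
      censored_reason = dplyr::case_when(
        !is.na(.data$death_year) & .data$end_candidates == .data$death_year ~ "death",
        !is.na(.data$hsct_year) & .data$end_candidates == .data$hsct_year - 1L ~ "pre_hsct",
        .data$end_candidates == .data$disenroll_year ~ "disenrollment",
        TRUE ~ "window_end"
      )
    ) |>
    dplyr::filter(.data$end_candidates >= .data$index_year)
  attrition$with_followup <- nrow(info)

  rows <- info |>
    dplyr::rowwise() |>
    dplyr::mutate(year = list(seq(.data$index_year, .data$end_candidates))) |>
    dplyr::ungroup() |>
    tidyr::unnest("year") |>
    dplyr::transmute(
      beneficiary_id = .data$beneficiary_id, payer = .data$payer,
      sex = .data$sex, birth_year = .data$birth_year,
      year = as.integer(.data$year), age = .data$year - .data$birth_year,
      censored_reason = ifelse(.data$year == .data$end_candidates,
                               .data$censored_reason, NA_character_)
    )

  span_claims <- claims_in_spans(
    claims[claims$beneficiary_id %in% info$beneficiary_id, ], spans_tbl)
  span_claims$year <- as.integer(format(span_claims$service_date, "%Y"))

  panel <- rows |>
    add_attribute_columns(span_claims, registry) |>
    add_treatment_columns(span_claims) |>
    add_utilization_columns(span_claims)

  panel <- structure(panel, class = c("scd_panel", class(panel)))
  attr(panel, "attrition") <- tibble::tibble(
    stage = names(attrition), n = unlist(attrition, use.names = FALSE))
  panel
}

# qualifying-claim years per (beneficiary, attribute): prefix match of claim
# codes against attribute code lists
attribute_event_years <- function(span_claims, registry) {
  pat <- attribute_code_table(registry)
  hits <- vector("list", nrow(pat))
  code_norm <- normalize_icd(span_claims$code)
  for (i in seq_len(nrow(pat))) {
    j <- span_claims$edition == pat$edition[i] &
      startsWith(code_norm, pat$code[i])
    if (any(j)) {
      hits[[i]] <- tibble::tibble(
        beneficiary_id = span_claims$beneficiary_id[j],
        year = span_claims$year[j], attribute = pat$attribute[i])
    }
  }
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    out <- tibble::tibble(beneficiary_id = character(), year = integer(),
                          attribute = character())
  }
  dplyr::distinct(out)
}

add_attribute_columns <- function(rows, span_claims, registry) {
  events <- attribute_event_years(span_claims, registry)
  all_attrs <- registry$attributes
  for (i in seq_len(nrow(all_attrs))) {
    nm <- all_attrs$name[i]
    is_cx <- all_attrs$dimension[i] == "treatment_complication"
    pre <- if (is_cx) "cx_" else ""
    ev <- events[events$attribute == nm, ]
    key_rows <- paste(rows$beneficiary_id, rows$year)
    rows[[paste0("evt_", pre, nm)]] <- key_rows %in% paste(ev$beneficiary_id, ev$year)
    rows[[paste0("flag_", pre, nm)]] <- switch(
      all_attrs$persistence[i],
      instantaneous = rows[[paste0("evt_", pre, nm)]],
      subacute = key_rows %in% c(paste(ev$beneficiary_id, ev$year),
                                 paste(ev$beneficiary_id, ev$year + 1L),
                                 paste(ev$beneficiary_id, ev$year + 2L)),
      chronic = {
        if (nrow(ev)) {
          first <- ev |> dplyr::group_by(.data$beneficiary_id) |>
            dplyr::summarise(first_year = min(.data$year), .groups = "drop")
          fy <- first$first_year[match(rows$beneficiary_id, first$beneficiary_id)]
          !is.na(fy) & rows$year >= fy
        } else rep(FALSE, nrow(rows))
      }
    )
  }
  rows
}

add_treatment_columns <- function(rows, span_claims) {
  tx <- span_claims |>
    dplyr::filter(.data$procedure %in% c("hydroxyurea", "transfusion")) |>
    dplyr::distinct(.data$claim_id, .data$beneficiary_id, .data$year,
                    .data$procedure) |>
    dplyr::count(.data$beneficiary_id, .data$year, .data$procedure)
  hu <- tx[tx$procedure == "hydroxyurea", ]
  tr <- tx[tx$procedure == "transfusion", ]
  key_rows <- paste(rows$beneficiary_id, rows$year)
  rows$tx_hydroxyurea <- key_rows %in% paste(hu$beneficiary_id, hu$year)
  # claims convention: 8+ transfusion claims in a year indicate a chronic
  # transfusion program, fewer an acute/episodic transfusion
  rows$tx_chronic_transfusion <- key_rows %in%
    paste(tr$beneficiary_id[tr$n >= 8L], tr$year[tr$n >= 8L])
  rows$tx_acute_transfusion <- key_rows %in%
    paste(tr$beneficiary_id[tr$n < 8L], tr$year[tr$n < 8L])
  rows
}

add_utilization_columns <- function(rows, span_claims) {
  u <- span_claims |>
    dplyr::distinct(.data$claim_id, .data$beneficiary_id, .data$year,
                    .data$setting) |>
    dplyr::mutate(cat = dplyr::case_when(
      .data$setting == "inpatient" ~ "util_inpatient",
      .data$setting == "ED" ~ "util_ed",
      TRUE ~ "util_outpatient"
    )) |>
    dplyr::count(.data$beneficiary_id, .data$year, .data$cat) |>
    tidyr::pivot_wider(names_from = "cat", values_from = "n", values_fill = 0L)
  rows <- dplyr::left_join(rows, u, by = c("beneficiary_id", "year"))
  for (col in c("util_inpatient", "util_ed", "util_outpatient")) {
    if (!col %in% names(rows)) rows[[col]] <- 0L
    rows[[col]] <- dplyr::coalesce(rows[[col]], 0L)
  }
  rows
}

#' Lifetime prevalence of disease attributes
#'
#' Percent of beneficiaries with the attribute flag true in at least one of
#' their panel years, per payer and pooled (`combined`).
#'
#' @param panel An `scd_panel` (or a simulated panel with the same columns).
#' @param registry An `scd_registry`.
#' @return Tibble `attribute`, `dimension`, `payer`, `prevalence` (percent).
#' @export
lifetime_prevalence <- function(panel, registry = default_registry()) {
  da <- disease_attributes(registry)
  flag_cols <- paste0("flag_", da$name)
  per_bene <- panel |>
    dplyr::group_by(.data$beneficiary_id, .data$payer) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(flag_cols), any),
                     .groups = "drop")
  long <- function(d, label) {
    tibble::tibble(
      attribute = da$name, dimension = da$dimension, payer = label,
      prevalence = purrr::map_dbl(flag_cols, ~ 100 * mean(d[[.x]]))
    )
  }
  payer_parts <- per_bene |>
    dplyr::group_by(.data$payer) |>
    dplyr::group_map(~ long(.x, .y$payer))
  dplyr::bind_rows(payer_parts, long(per_bene, "combined"))
}
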