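#' Generate a synthetic beneficiary population with claims
#'
#' Produces beneficiary, enrollment-span, and dated-claim tables whose
#' statistical structure emulates public-payer SCD claims cohorts: entry
#' ages and sex mix follow the configured payer moments, enrollment is
#' month-granular with occasional gaps, claims carry positioned ICD-9/10
#' diagnosis codes (edition switching with service year), HSCT shows up as
#' a procedure flag, and an age-dependent annual mortality process truncates
#' enrollment. A configurable share of beneficiaries are true SCD cases
#' (emitting case-definition claims and per-attribute event claims); the
#' remainder emit only noise claims -- including occasional sickle-cell
#' trait codes -- so case identification has true negatives.
#'
#' Deterministic given the seed; each payer draws from its own substream so
#' payer scenarios can be regenerated independently.
#'
#' @param config An `scd_config` (see [default_config()]).
#' @param payers Character vector of payer scenarios to generate.
#' @param seed Integer master seed (defaults to the config seed).
#' @param registry An `scd_registry`.
#' @return An `scd_population`: list of tibbles `beneficiaries`,
#'   `enrollment`, `claims`.
#' @examples
#' cfg <- demo_config()
#' cfg$payers$medicaid$n <- 50L
#' pop <- generate_population(cfg, payers = "medicaid", seed = 1)
#' dplyr::count(pop$claims, setting)
#' @export
generate_population <- function(config = default_config(),
                                payers = NULL, seed = NULL,
                                registry = default_registry()) {
  seed <- seed %||% config$seed
  if (is.null(payers)) {
    payers <- names(config$payers)[purrr::map_int(config$payers, "n") > 0L]
  }
  check_generator_config(config, payers)
  parts <- purrr::map(payers, function(p) {
    generate_payer(config, p, substream_seed(seed, paste0("gen_", p)), registry)
  })
  pop <- list(
    beneficiaries = purrr::map_dfr(parts, "beneficiaries"),
    enrollment = purrr::map_dfr(parts, "enrollment"),
    claims = purrr::map_dfr(parts, "claims")
  )
  structure(pop, class = "scd_population", seed = seed)
}

check_generator_config <- function(config, payers) {
  for (p in payers) {
    pc <- config$payers[[p]]
    if (is.null(pc)) abort_sim(paste0("unknown payer scenario: ", p),
                               "config_error")
    if (pc$n < 1L) abort_sim("n_beneficiaries must be >= 1", "config_error")
    probs <- c(pc$attr_probs, config$generator$case_probability,
               config$generator$complication_probs)
    if (any(probs < 0 | probs > 1)) {
      abort_sim("generator probabilities must lie in [0, 1]", "config_error")
    }
  }
  w <- config$study_window
  if (length(w) != 2L || w[2] < w[1]) abort_sim("empty study window",
                                                "config_error")
  invisible(config)
}

#' @export
print.scd_population <- function(x, ...) {
  cat(sprintf("<scd_population> %d beneficiaries, %d spans, %d claim rows\n",
              nrow(x$beneficiaries), nrow(x$enrollment), nrow(x$claims)))
  invisible(x)
}

REGIONS <- c("northeast", "midwest", "south", "west")
NOISE_CODES_ICD9 <- c("4659", "7840", "5589", "8470", "V700", "2724", "4019")
NOISE_CODES_ICD10 <- c("J069", "R51", "R197", "S134", "Z0000", "E785", "I10")

claim_edition <- function(year) ifelse(year >= 2016L, "icd10", "icd9")

# one payer scenario; everything below is vectorised over beneficiaries or
# beneficiary-years
generate_payer <- function(config, payer, seed, registry) {
  pc <- config$payers[[payer]]
  gc <- config$generator
  w <- config$study_window
  n <- pc$n
  withr::with_seed(seed, {
    mu <- tnorm_location(pc$age_mean, pc$age_sd)
    age <- rtnorm0(n, mu, pc$age_sd)
    sex <- ifelse(stats::runif(n) < pc$prop_female, "female", "male")
    region <- sample(REGIONS, n, replace = TRUE)
    is_case <- stats::runif(n) < gc$case_probability
    trait_coder <- !is_case & stats::runif(n) < gc$trait_coder_probability

    m_lo <- w[1] * 12L
    m_hi <- (w[2] + 1L) * 12L - 1L
    entry_m <- m_lo + floor(stats::runif(n) * (m_hi - m_lo - 11L))
    entry_year <- entry_m %/% 12L
    birth_year <- entry_year - floor(age)

    len1 <- pmax(12L, floor(stats::rexp(n, 1 / gc$enrollment_mean_months)) + 6L)
    end_m <- pmin(entry_m + len1 - 1L, m_hi)

    # age-dependent death process (discrete annual), truncating enrollment
    death_m <- rep(NA_integer_, n)
    alive <- rep(TRUE, n)
    for (k in 0:((m_hi %/% 12L) - min(entry_year))) {
      yr <- entry_year + k
      at_risk <- alive & yr <= (m_hi %/% 12L) & yr >= entry_year
      if (!any(at_risk)) break
      q <- background_mortality(age[at_risk] + k, sex[at_risk],
                                config$mortality) * gc$mortality_multiplier
      died <- at_risk
      died[at_risk] <- stats::runif(sum(at_risk)) < clamp01(q)
      newly <- died & alive
      if (any(newly)) {
        death_m[newly] <- yr[1] * 0L + (entry_year[newly] + k) * 12L +
          floor(stats::runif(sum(newly)) * 12)
        alive[newly] <- FALSE
      }
    }
    death_m[!is.na(death_m) & death_m < entry_m] <- NA_integer_
    end_m <- pmin(end_m, dplyr::coalesce(death_m, m_hi))
    end_m <- pmax(end_m, entry_m)

    ben <- tibble::tibble(
      beneficiary_id = sprintf("%s-%05d", payer, seq_len(n)),
      payer = payer, sex = sex, region = region,
      birth_year = as.integer(birth_year),
      death_year = as.integer(ifelse(is.na(death_m), NA, death_m %/% 12L))
    )

    spans <- make_spans(ben$beneficiary_id, entry_m, end_m, gc$gap_probability)
    yrs <- span_years(spans)

    claims <- dplyr::bind_rows(
      scd_definition_claims(ben, yrs, is_case, gc, registry),
      attribute_claims(ben, yrs, is_case, pc, gc, registry),
      treatment_claims(ben, yrs, is_case, pc, gc, registry),
      noise_claims(ben, yrs, trait_coder, gc)
    )
    claims <- finalize_claims(claims, gc)
    list(beneficiaries = ben, enrollment = spans_to_dates(spans),
         claims = claims)
  })
}

background_mortality <- function(age, sex, mortality) {
  if (identical(mortality$type, "constant")) {
    return(rep(mortality$q, length(age)))
  }
  h <- mortality$makeham + mortality$gompertz_b * exp(mortality$gompertz_c * age)
  h <- h * exp(ifelse(sex == "female", mortality$female_log_hr, 0))
  1 - exp(-h)
}

# enrollment spans in month-index space; a gap splits the primary span
make_spans <- function(ids, start_m, end_m, gap_prob) {
  n <- length(ids)
  has_gap <- stats::runif(n) < gap_prob & (end_m - start_m) >= 18L
  gap_at <- start_m + 6L + floor(stats::runif(n) *
                                   pmax(1, (end_m - start_m - 12L)))
  gap_len <- 1L + floor(stats::runif(n) * 6)
  one <- tibble::tibble(beneficiary_id = ids, start_m = start_m,
                        end_m = ifelse(has_gap, gap_at - 1L, end_m))
  two <- tibble::tibble(beneficiary_id = ids[has_gap],
                        start_m = (gap_at + gap_len)[has_gap],
                        end_m = end_m[has_gap])
  two <- two[two$start_m <= two$end_m, ]
  dplyr::arrange(dplyr::bind_rows(one, two), .data$beneficiary_id,
                 .data$start_m)
}

spans_to_dates <- function(spans) {
  tibble::tibble(beneficiary_id = spans$beneficiary_id,
                 start_month = ym_to_date(spans$start_m),
                 end_month = ym_to_date(spans$end_m))
}

# one row per (beneficiary, calendar year, months enrolled in that year)
span_years <- function(spans) {
  spans |>
    dplyr::mutate(y0 = .data$start_m %/% 12L, y1 = .data$end_m %/% 12L) |>
    dplyr::rowwise() |>
    dplyr::mutate(year = list(seq(.data$y0, .data$y1))) |>
    dplyr::ungroup() |>
    tidyr::unnest("year") |>
    dplyr::mutate(
      m0 = pmax(.data$start_m, .data$year * 12L),
      m1 = pmin(.data$end_m, .data$year * 12L + 11L),
      months = .data$m1 - .data$m0 + 1L
    ) |>
    dplyr::select("beneficiary_id", "year", "m0", "m1", "months")
}

rand_dates <- function(m0, m1) {
  m <- m0 + floor(stats::runif(length(m0)) * (m1 - m0 + 1L))
  ym_to_date(m) + floor(stats::runif(length(m0)) * 28)
}

sample_setting <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# claims satisfying the SCD case definition; the first enrolled year of a
# case always carries at least one, so the index date sits near entry
scd_definition_claims <- function(ben, yrs, is_case, gc, registry) {
  case_ids <- ben$beneficiary_id[is_case]
  y <- yrs[yrs$beneficiary_id %in% case_ids, ]
  if (!nrow(y)) return(NULL)
  first <- y |> dplyr::group_by(.data$beneficiary_id) |>
    dplyr::summarise(first_year = min(.data$year), .groups = "drop")
  y <- dplyr::left_join(y, first, by = "beneficiary_id")
  lambda <- gc$scd_claims_per_year * y$months / 12
  k <- stats::rpois(nrow(y), lambda) + as.integer(y$year == y$first_year)
  y <- y[rep(seq_len(nrow(y)), k), ]
  if (!nrow(y)) return(NULL)
  ed <- claim_edition(y$year)
  # disease-without-crisis codes only: crisis codes belong to the
  # vaso-occlusive event attribute and would inflate its event process
  inc9 <- c("28260", "28241")
  inc10 <- c("D571", "D5780")
  tibble::tibble(
    beneficiary_id = y$beneficiary_id,
    service_date = rand_dates(y$m0, y$m1),
    setting = sample_setting(nrow(y), gc$setting_mix),
    code = ifelse(ed == "icd9", sample(inc9, nrow(y), TRUE),
                  sample(inc10, nrow(y), TRUE)),
    edition = ed, procedure = ""
  )
}

# annual per-attribute event process with claims-per-event amplification
attribute_claims <- function(ben, yrs, is_case, pc, gc, registry) {
  case_ids <- ben$beneficiary_id[is_case]
  y <- yrs[yrs$beneficiary_id %in% case_ids, ]
  if (!nrow(y)) return(NULL)
  da <- disease_attributes(registry)
  out <- vector("list", nrow(da))
  for (i in seq_len(nrow(da))) {
    nm <- da$name[i]
    p <- unname(pc$attr_probs[nm])
    if (is.na(p) || p <= 0) next
    hit <- stats::runif(nrow(y)) < p * y$months / 12
    if (!any(hit)) next
    yy <- y[hit, ]
    reps <- 1L + stats::rpois(nrow(yy), gc$claims_per_event)
    yy <- yy[rep(seq_len(nrow(yy)), reps), ]
    ed <- claim_edition(yy$year)
    codes9 <- da$icd9[[i]]; codes10 <- da$icd10[[i]]
    acute <- da$persistence[i] == "instantaneous"
    mix <- if (acute) c(inpatient = 0.3, ED = 0.5, outpatient = 0.2)
           else c(outpatient = 0.7, ambulatory = 0.3)
    out[[i]] <- tibble::tibble(
      beneficiary_id = yy$beneficiary_id,
      service_date = rand_dates(yy$m0, yy$m1),
      setting = sample_setting(nrow(yy), mix),
      code = ifelse(ed == "icd9",
                    sample(codes9, nrow(yy), TRUE),
                    sample(codes10, nrow(yy), TRUE)),
      edition = ed, procedure = "", attribute = nm
    )
  }
  dplyr::bind_rows(out)
}

# hydroxyurea / transfusion / HSCT procedure claims plus their complications
treatment_claims <- function(ben, yrs, is_case, pc, gc, registry) {
  case_ids <- ben$beneficiary_id[is_case]
  hu_user <- ben$beneficiary_id[is_case & stats::runif(nrow(ben)) < gc$hydroxyurea_user_prob]
  ct_user <- ben$beneficiary_id[is_case & stats::runif(nrow(ben)) < gc$chronic_transfusion_prob]
  y <- yrs[yrs$beneficiary_id %in% case_ids, ]
  if (!nrow(y)) return(NULL)
  out <- list()

  emit <- function(yy, k, procedure, setting_mix) {
    yy <- yy[rep(seq_len(nrow(yy)), k), ]
    if (!nrow(yy)) return(NULL)
    tibble::tibble(
      beneficiary_id = yy$beneficiary_id,
      service_date = rand_dates(yy$m0, yy$m1),
      setting = sample_setting(nrow(yy), setting_mix),
      code = ifelse(claim_edition(yy$year) == "icd9", "28260", "D571"),
      edition = claim_edition(yy$year), procedure = procedure
    )
  }
  hu <- y[y$beneficiary_id %in% hu_user, ]
  out$hu <- emit(hu, 1L + stats::rpois(nrow(hu), 3), "hydroxyurea",
                 c(outpatient = 0.8, ambulatory = 0.2))
  ct <- y[y$beneficiary_id %in% ct_user, ]
  out$ct <- emit(ct, 10L + stats::rpois(nrow(ct), 3), "transfusion",
                 c(outpatient = 0.9, ambulatory = 0.1))
  at <- y[!(y$beneficiary_id %in% ct_user) &
            stats::runif(nrow(y)) < gc$acute_transfusion_prob * y$months / 12, ]
  out$at <- emit(at, 1L + stats::rpois(nrow(at), 1), "transfusion",
                 c(inpatient = 0.5, ED = 0.2, outpatient = 0.3))

  # complication claims conditional on therapy exposure
  ca <- complication_attributes(registry)
  for (ther in c("hydroxyurea", "transfusion")) {
    users <- if (ther == "hydroxyurea") hu_user else
      unique(c(ct_user, at$beneficiary_id))
    yy <- y[y$beneficiary_id %in% users, ]
    if (!nrow(yy)) next
    for (nm in registry$therapies[[ther]]) {
      p <- gc$complication_probs[[nm]] %||% 0.02
      hit <- yy[stats::runif(nrow(yy)) < p * yy$months / 12, ]
      if (!nrow(hit)) next
      j <- match(nm, ca$name)
      ed <- claim_edition(hit$year)
      out[[paste0("cx_", ther, "_", nm)]] <- tibble::tibble(
        beneficiary_id = hit$beneficiary_id,
        service_date = rand_dates(hit$m0, hit$m1),
        setting = sample_setting(nrow(hit), c(outpatient = 0.8, inpatient = 0.2)),
        code = ifelse(ed == "icd9", sample(ca$icd9[[j]], nrow(hit), TRUE),
                      sample(ca$icd10[[j]], nrow(hit), TRUE)),
        edition = ed, procedure = ""
      )
    }
  }
  hs <- y[stats::runif(nrow(y)) < gc$hsct_annual_prob * y$months / 12, ]
  out$hsct <- emit(hs, rep(1L, nrow(hs)), "hsct", c(inpatient = 1))
  dplyr::bind_rows(out)
}

noise_claims <- function(ben, yrs, trait_coder, gc) {
  y <- yrs
  k <- stats::rpois(nrow(y), gc$noise_claims_per_year * y$months / 12)
  y <- y[rep(seq_len(nrow(y)), k), ]
  if (!nrow(y)) return(NULL)
  ed <- claim_edition(y$year)
  is_trait <- y$beneficiary_id %in% ben$beneficiary_id[trait_coder] &
    stats::runif(nrow(y)) < 0.5
  code <- ifelse(ed == "icd9",
                 sample(NOISE_CODES_ICD9, nrow(y), TRUE),
                 sample(NOISE_CODES_ICD10, nrow(y), TRUE))
  code[is_trait] <- ifelse(ed[is_trait] == "icd9", "2825", "D573")
  tibble::tibble(
    beneficiary_id = y$beneficiary_id,
    service_date = rand_dates(y$m0, y$m1),
    setting = sample_setting(nrow(y), gc$setting_mix),
    code = code, edition = ed, procedure = ""
  )
}

# assign claim ids, coding noise, and secondary diagnosis positions
finalize_claims <- function(claims, gc) {
  if (is.null(claims) || !nrow(claims)) {
    return(empty_claims())
  }
  claims <- dplyr::arrange(claims, .data$beneficiary_id, .data$service_date,
                           .data$code)
  claims$claim_id <- sprintf("C%07d", seq_len(nrow(claims)))
  claims$attribute <- NULL
  # a second, noise diagnosis on ~40% of claims; the substantive code takes a
  # random position, exercising "any position" logic downstream
  extra <- stats::runif(nrow(claims)) < 0.4
  sec <- claims[extra, ]
  sec$code <- ifelse(sec$edition == "icd9",
                     sample(NOISE_CODES_ICD9, nrow(sec), TRUE),
                     sample(NOISE_CODES_ICD10, nrow(sec), TRUE))
  claims$position <- 1L
  sec$position <- 2L
  flip <- extra & stats::runif(nrow(claims)) < 0.5
  claims$position[flip] <- 2L
  sec$position[flip[extra]] <- 1L
  out <- dplyr::bind_rows(claims, sec)
  dplyr::select(
    dplyr::arrange(out, .data$beneficiary_id, .data$service_date,
                   .data$claim_id, .data$position),
    "claim_id", "beneficiary_id", "service_date", "setting", "position",
    "code", "edition", "procedure"
  )
}

empty_claims <- function() {
  tibble::tibble(claim_id = character(), beneficiary_id = character(),
                 service_date = as.Date(character()), setting = character(),
                 position = integer(), code = character(),
                 edition = character(), procedure = character())
}

# ---- CSV dialect ----------------------------------------------------------

CLAIMS_SCHEMA <- list(
  beneficiaries = c("beneficiary_id", "payer", "sex", "region", "birth_year",
                    "death_year"),
  enrollment = c("beneficiary_id", "start_month", "end_month"),
  claims = c("claim_id", "beneficiary_id", "service_date", "setting",
             "position", "code", "edition", "procedure")
)

#' Write / read the three claims-world CSV files
#'
#' The dialect is plain CSV with a header row, ISO dates, and a fixed column
#' order (`beneficiaries.csv`, `enrollment.csv`, `claims.csv`); the claims
#' table is long in diagnosis position (one row per positioned code). The
#' round trip is lossless.
#'
#' @param population An `scd_population`.
#' @param dir Directory to write into (created if needed).
#' @return `write_claims` returns the directory invisibly; `read_claims`
#'   returns an `scd_population`.
#' @export
write_claims <- function(population, dir) {
  check_population_schema(population)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in names(CLAIMS_SCHEMA)) {
    readr::write_csv(population[[tbl]][, CLAIMS_SCHEMA[[tbl]]],
                     file.path(dir, paste0(tbl, ".csv")), na = "")
  }
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  cols <- list(
    beneficiaries = readr::cols(beneficiary_id = "c", payer = "c", sex = "c",
                                region = "c", birth_year = "i",
                                death_year = "i"),
    enrollment = readr::cols(beneficiary_id = "c", start_month = "D",
                             end_month = "D"),
    claims = readr::cols(claim_id = "c", beneficiary_id = "c",
                         service_date = "D", setting = "c", position = "i",
                         code = "c", edition = "c", procedure = "c")
  )
  pop <- purrr::imap(cols, function(ct, tbl) {
    path <- file.path(dir, paste0(tbl, ".csv"))
    if (!file.exists(path)) abort_sim(paste0("missing file: ", path),
                                      "schema_error")
    header <- strsplit(readr::read_lines(path, n_max = 1L), ",")[[1]]
    missing <- setdiff(CLAIMS_SCHEMA[[tbl]], header)
    if (length(missing)) {
      abort_sim(sprintf("table '%s' is missing column(s): %s", tbl,
                        paste(missing, collapse = ", ")), "schema_error")
    }
    x <- readr::read_csv(path, col_types = ct, na = "")
    x$procedure <- if ("procedure" %in% names(x))
      dplyr::coalesce(x$procedure, "") else NULL
    x
  })
  pop <- structure(pop, class = "scd_population")
  check_population_schema(pop)
  pop
}

check_population_schema <- function(population) {
  for (tbl in names(CLAIMS_SCHEMA)) {
    missing <- setdiff(CLAIMS_SCHEMA[[tbl]], names(population[[tbl]]))
    if (length(missing)) {
      abort_sim(sprintf("table '%s' is missing column(s): %s", tbl,
                        paste(missing, collapse = ", ")), "schema_error")
    }
  }
  invisible(population)
}
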