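#' Covariate schema for the prediction indices
#'
#' Four families of penalized-regression indices drive the simulation, each
#' with its own covariate timing contract:
#'
#' * `incidence` -- predicts each acute event, subacute activity, or chronic
#'   onset from health status, history, treatment and complications in the
#'   **previous** year (chronic onsets are absorbing: person-years already
#'   carrying the disorder are excluded from its design).
#' * `treatment_use` -- predicts hydroxyurea / acute transfusion / chronic
#'   transfusion use from the status available at the treatment decision:
#'   chronic status carried into the year, subacute activity within the
#'   two-year lookback, previous-year acute events, history, and
#'   previous-year treatment and complications.
#' * `complication` -- predicts common-care treatment complications from
#'   current-year status and treatment, history, and previous-year
#'   complications.
#' * `utilization` -- log-link count models for inpatient admissions, ED
#'   visits and outpatient visits from all current-year blocks.
#'
#' Demographics enter every family as sex, 5-year age-band indicators, and
#' birth-decade indicators.
#'
#' @param registry An `scd_registry`.
#' @param decades Integer vector of birth decades present in the data
#'   (e.g. `c(1950, 1960)`), used to name the cohort indicators.
#' @return A list of named covariate blocks plus a `family_covariates`
#'   lookup.
#' @export
covariate_schema <- function(registry, decades = integer()) {
  da <- disease_attributes(registry)
  acute <- da$name[da$persistence == "instantaneous"]
  subac <- da$name[da$persistence == "subacute"]
  chron <- da$name[da$persistence == "chronic"]
  cx <- common_care_complications(registry)

  age_cuts <- seq(0, 85, by = 5)
  age_bands <- c(sprintf("age_%02d_%02d", age_cuts[-length(age_cuts)],
                         age_cuts[-1] - 1), "age_85_plus")
  demo <- c("female", age_bands,
            if (length(decades)) sprintf("cohort_%d", sort(decades)))

  blocks <- list(
    demo = demo,
    prev_attr = paste0("prev_", da$name),
    act_sub = paste0("act_", subac),
    cur_attr = paste0("cur_", da$name),
    hist = c(paste0("hist_n_", acute), "hist_pain_years", paste0("dur_", chron)),
    prev_tx = paste0("prev_tx_", TREATMENTS),
    cur_tx = paste0("cur_tx_", TREATMENTS),
    prev_cx = paste0("prev_cx_", cx),
    cur_cx = paste0("cur_cx_", cx)
  )
  fam <- list(
    incidence = c(blocks$demo, blocks$prev_attr, blocks$hist, blocks$prev_tx,
                  blocks$prev_cx),
    treatment_use = c(blocks$demo, paste0("prev_", c(acute, chron)),
                      blocks$act_sub, blocks$hist, blocks$prev_tx,
                      blocks$prev_cx),
    complication = c(blocks$demo, blocks$cur_attr, blocks$cur_tx, blocks$hist,
                     blocks$prev_cx),
    utilization = c(blocks$demo, blocks$cur_attr, blocks$hist, blocks$cur_tx,
                    blocks$cur_cx)
  )
  list(blocks = blocks, family_covariates = fam,
       layout = unique(unlist(blocks, use.names = FALSE)),
       acute = acute, subacute = subac, chronic = chron, complications = cx,
       age_cuts = age_cuts, age_bands = age_bands, decades = sort(decades))
}

TREATMENTS <- c("hydroxyurea", "acute_transfusion", "chronic_transfusion")
UTILIZATION <- c("inpatient", "ED", "outpatient")
FAMILIES <- c("incidence", "treatment_use", "complication", "utilization")

# the complication attributes reachable under Common Care
common_care_complications <- function(registry) {
  ca <- complication_attributes(registry)$name
  intersect(unique(c(registry$therapies$hydroxyurea, registry$therapies$transfusion)),
            ca)
}

# indicator matrix helpers --------------------------------------------------

age_band_matrix <- function(age, schema) {
  idx <- findInterval(age, schema$age_cuts)
  idx[idx > length(schema$age_bands)] <- length(schema$age_bands)
  idx[idx < 1L] <- 1L
  m <- matrix(0, length(age), length(schema$age_bands),
              dimnames = list(NULL, schema$age_bands))
  m[cbind(seq_along(age), idx)] <- 1
  m
}

cohort_matrix <- function(birth_year, schema) {
  if (!length(schema$decades)) return(matrix(0, length(birth_year), 0))
  dec <- pmin(pmax(floor(birth_year / 10) * 10, min(schema$decades)),
              max(schema$decades))
  m <- matrix(0, length(birth_year), length(schema$decades),
              dimnames = list(NULL, sprintf("cohort_%d", schema$decades)))
  hit <- match(dec, schema$decades)
  m[cbind(seq_along(birth_year), hit)] <- 1
  m
}

# Add every engineered covariate column to a panel: lagged flags, subacute
# activity lookbacks, event-history counts, chronic durations, demographics.
# Rows without a consecutive previous year get .has_lag = FALSE.
panel_features <- function(panel, registry, schema) {
  da <- disease_attributes(registry)
  cxn <- schema$complications
  panel <- dplyr::arrange(panel, .data$beneficiary_id, .data$year)
  g <- dplyr::group_by(panel, .data$beneficiary_id)

  feats <- dplyr::mutate(
    g,
    .has_lag = !is.na(dplyr::lag(.data$year)) &
      .data$year - dplyr::lag(.data$year) == 1L,
    dplyr::across(dplyr::all_of(paste0("flag_", da$name)),
                  ~ dplyr::lag(.x, default = FALSE),
                  .names = "prev_{sub('flag_', '', .col)}"),
    dplyr::across(dplyr::all_of(paste0("flag_cx_", cxn)),
                  ~ dplyr::lag(.x, default = FALSE),
                  .names = "prev_cx_{sub('flag_cx_', '', .col)}"),
    dplyr::across(dplyr::all_of(paste0("tx_", TREATMENTS)),
                  ~ dplyr::lag(.x, default = FALSE),
                  .names = "prev_tx_{sub('tx_', '', .col)}"),
    dplyr::across(dplyr::all_of(paste0("evt_", schema$subacute)),
                  ~ dplyr::lag(.x, default = FALSE) |
                    dplyr::lag(.x, 2L, default = FALSE),
                  .names = "act_{sub('evt_', '', .col)}"),
    dplyr::across(dplyr::all_of(paste0("evt_", schema$acute)),
                  ~ dplyr::lag(cumsum(.x), default = 0),
                  .names = "hist_n_{sub('evt_', '', .col)}"),
    hist_pain_years = dplyr::lag(cumsum(.data$flag_chronic_pain), default = 0),
    dplyr::across(dplyr::all_of(paste0("flag_", schema$chronic)),
                  ~ dplyr::lag(cumsum(.x), default = 0),
                  .names = "dur_{sub('flag_', '', .col)}")
  )
  feats <- dplyr::ungroup(feats)
  feats <- dplyr::rename_with(feats, ~ sub("^flag_cx_", "cur_cx_", .x),
                              dplyr::starts_with("flag_cx_"))
  feats <- dplyr::rename_with(feats, ~ sub("^flag_", "cur_", .x),
                              dplyr::all_of(paste0("flag_", da$name)))
  feats <- dplyr::rename_with(feats, ~ sub("^tx_", "cur_tx_", .x),
                              dplyr::all_of(paste0("tx_", TREATMENTS)))
  demo <- cbind(female = as.numeric(feats$sex == "female"),
                age_band_matrix(feats$age, schema),
                cohort_matrix(feats$birth_year, schema))
  dplyr::bind_cols(feats, tibble::as_tibble(demo))
}

#' Build the design table for one prediction index
#'
#' Returns one row per eligible person-year with an `.outcome` column,
#' `.beneficiary` identifiers (used for beneficiary-level splitting and
#' bootstrap), and the covariates of the requested family.
#'
#' @param panel An annual panel from [build_panel()] (or the simulator).
#' @param outcome Outcome name: a disease attribute (incidence), a treatment
#'   (`hydroxyurea`, `acute_transfusion`, `chronic_transfusion`), a
#'   common-care complication, or a utilization category (`inpatient`,
#'   `ED`, `outpatient`).
#' @param family One of `"incidence"`, `"treatment_use"`, `"complication"`,
#'   `"utilization"`.
#' @param registry An `scd_registry`.
#' @param schema Optional precomputed [covariate_schema()]; defaults to one
#'   built from the panel's birth decades.
#' @return A tibble of class `scd_design` with attributes `outcome`,
#'   `family`, and `link`.
#' @export
build_design <- function(panel, outcome, family, registry = default_registry(),
                         schema = NULL) {
  family <- match.arg(family, FAMILIES)
  if (is.null(schema)) {
    schema <- covariate_schema(registry,
                               unique(floor(panel$birth_year / 10) * 10))
  }
  da <- disease_attributes(registry)
  valid <- switch(family,
    incidence = da$name,
    treatment_use = TREATMENTS,
    complication = schema$complications,
    utilization = UTILIZATION
  )
  if (!outcome %in% valid) {
    abort_sim(sprintf("outcome '%s' is not valid for family '%s'", outcome,
                      family), "design_error")
  }
  feats <- panel_features(panel, registry, schema)
  lagged <- family %in% c("incidence", "treatment_use", "complication")
  if (lagged) feats <- feats[feats$.has_lag, ]

  y <- switch(family,
    incidence = {
      per <- da$persistence[da$name == outcome]
      if (per == "chronic") {
        feats <- feats[!feats[[paste0("prev_", outcome)]], ]
        as.numeric(feats[[paste0("cur_", outcome)]])
      } else {
        as.numeric(feats[[paste0("evt_", outcome)]])
      }
    },
    treatment_use = as.numeric(feats[[paste0("cur_tx_", outcome)]]),
    complication = as.numeric(feats[[paste0("cur_cx_", outcome)]]),
    utilization = as.numeric(feats[[paste0("util_", tolower(outcome))]])
  )
  covars <- schema$family_covariates[[family]]
  out <- dplyr::bind_cols(
    tibble::tibble(.beneficiary = feats$beneficiary_id, .year = feats$year,
                   .outcome = y),
    dplyr::mutate(feats[, covars], dplyr::across(dplyr::everything(),
                                                 as.numeric))
  )
  structure(out, class = c("scd_design", class(out)),
            outcome = outcome, family = family,
            link = if (family == "utilization") "log" else "logit")
}

#' Split a panel into training and two test parts at the beneficiary level
#'
#' All person-years of a beneficiary land in the same part, preventing
#' person-year leakage between training and evaluation. Default fractions
#' are 50% training, 25% first test set (bootstrap/calibration), 25% held
#' out for the decision model.
#'
#' @param panel A panel tibble with a `beneficiary_id` column.
#' @param fractions Numeric length-3, summing to 1.
#' @param seed Integer seed.
#' @return Named list `train`, `test1`, `test2` of disjoint panels.
#' @export
split_sample <- function(panel, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort_sim("split fractions must sum to 1", "split_error")
  }
  ids <- unique(panel$beneficiary_id)
  if (length(ids) < 4L) abort_sim("need at least 4 beneficiaries to split",
                                  "split_error")
  ids <- sort(ids)
  shuffled <- withr::with_seed(substream_seed(seed, "split"), sample(ids))
  n <- length(ids)
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  parts <- list(train = shuffled[seq_len(n1)],
                test1 = shuffled[n1 + seq_len(n2)],
                test2 = shuffled[-seq_len(n1 + n2)])
  purrr::map(parts, ~ panel[panel$beneficiary_id %in% .x, ])
}
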