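test_that("case identification follows the inpatient / two-outpatient rule", {
  claims <- dplyr::bind_rows(
    # one inpatient claim, SCD code in 3rd position -> case
    claim_row("A", "2016-03-01", "J069", "inpatient", position = 1),
    claim_row("A", "2016-03-01", "R51", "inpatient", position = 2),
    claim_row("A", "2016-03-01", "D57.0", "inpatient", position = 3),
    # one outpatient claim only -> not a case
    claim_row("B", "2016-04-01", "D57.1", "outpatient"),
    # two ED claims coded only with the trait -> not a case
    claim_row("C", "2016-05-01", "282.5", "ED", edition = "icd9"),
    claim_row("C", "2016-06-01", "282.5", "ED", edition = "icd9"),
    # two distinct-date outpatient claims -> case
    claim_row("D", "2015-05-01", "282.60", edition = "icd9"),
    claim_row("D", "2015-07-01", "282.62", edition = "icd9"),
    # two same-date outpatient claims -> not a case
    claim_row("E", "2015-05-01", "282.60", edition = "icd9", claim_id = "e1"),
    claim_row("E", "2015-05-01", "282.62", edition = "icd9", claim_id = "e2")
  )
  expect_equal(identify_cases(claims), c("A", "D"))
  expect_equal(identify_cases(claims[0, ]), character())
})

test_that("index date is the first in-span SCD-coded claim", {
  spans <- span_row("A", "2010-01-01", "2014-12-01")
  claims <- dplyr::bind_rows(
    claim_row("A", "2009-01-01", "J069"),               # non-SCD, earlier
    claim_row("A", "2010-05-01", "282.61", edition = "icd9"),
    claim_row("A", "2011-05-01", "282.62", edition = "icd9")
  )
  idx <- compute_index_date(claims, spans)
  expect_equal(idx$index_date, as.Date("2010-05-01"))

  # SCD claim outside any span, later one inside -> the in-span date
  spans2 <- span_row("B", "2012-01-01", "2015-12-01")
  claims2 <- dplyr::bind_rows(
    claim_row("B", "2011-06-01", "282.60", edition = "icd9"),
    claim_row("B", "2013-02-01", "282.60", edition = "icd9")
  )
  expect_equal(compute_index_date(claims2, spans2)$index_date,
               as.Date("2013-02-01"))

  # same earliest date in two settings -> that date, setting irrelevant
  claims3 <- dplyr::bind_rows(
    claim_row("A", "2010-05-01", "282.61", "inpatient", edition = "icd9"),
    claims
  )
  expect_equal(compute_index_date(claims3, spans)$index_date,
               as.Date("2010-05-01"))

  expect_error(compute_index_date(claims, spans, ids = c("A", "ghost")),
               class = "sicklesim_index_error")
})

make_case_claims <- function(id, year = 2009) {
  dplyr::bind_rows(
    claim_row(id, sprintf("%d-01-15", year), "282.60", "inpatient",
              edition = "icd9"))
}

test_that("panel persistence semantics: subacute, chronic, HSCT censoring", {
  ben <- tibble::tibble(beneficiary_id = c("A", "B", "C"), payer = "medicaid",
                        sex = "female", region = "south", birth_year = 2000L,
                        death_year = NA_integer_)
  enr <- dplyr::bind_rows(span_row("A", "2009-01-01", "2016-12-01"),
                          span_row("B", "2009-01-01", "2016-12-01"),
                          span_row("C", "2009-01-01", "2016-12-01"))
  claims <- dplyr::bind_rows(
    make_case_claims("A"), make_case_claims("B"), make_case_claims("C"),
    # A: single chronic-pain claim in 2010 (subacute persistence)
    claim_row("A", "2010-06-01", "338.29", edition = "icd9"),
    # B: single chronic renal disease claim in 2011 (chronic persistence)
    claim_row("B", "2011-06-01", "585.6", edition = "icd9"),
    # C: HSCT procedure in 2014
    claim_row("C", "2014-03-01", "D57.1", "inpatient", procedure = "hsct")
  )
  pop <- tiny_population(ben, enr, claims)
  panel <- build_panel(pop)

  a <- panel[panel$beneficiary_id == "A", ]
  expect_equal(a$flag_chronic_pain[match(2010:2013, a$year)],
               c(TRUE, TRUE, TRUE, FALSE))
  b <- panel[panel$beneficiary_id == "B", ]
  expect_true(all(b$flag_chronic_renal_disease[b$year >= 2011]))
  expect_false(any(b$flag_chronic_renal_disease[b$year < 2011]))
  cc <- panel[panel$beneficiary_id == "C", ]
  expect_equal(max(cc$year), 2013L)
  expect_equal(cc$censored_reason[cc$year == 2013], "pre_hsct")
  # rows are consecutive years per beneficiary
  gaps <- panel |>
    dplyr::group_by(beneficiary_id) |>
    dplyr::summarise(ok = all(diff(year) == 1))
  expect_true(all(gaps$ok))
})

test_that("enrollment filters: 12-month rule, longest span, mid-year end", {
  ben <- tibble::tibble(beneficiary_id = c("S", "L"), payer = "medicaid",
                        sex = "male", region = "west", birth_year = 1995L,
                        death_year = NA_integer_)
  enr <- dplyr::bind_rows(
    span_row("S", "2015-09-01", "2016-03-01"),  # 7 months: dropped
    span_row("L", "2009-01-01", "2010-06-01"),  # 18 months
    span_row("L", "2011-01-01", "2014-06-01")   # 42 months: the longest
  )
  claims <- dplyr::bind_rows(
    make_case_claims("S", 2015),
    make_case_claims("L", 2009), make_case_claims("L", 2011)
  )
  panel <- build_panel(tiny_population(ben, enr, claims))
  expect_false("S" %in% panel$beneficiary_id)
  l <- panel[panel$beneficiary_id == "L", ]
  # follow-up confined to the longest span; index there is 2011
  expect_equal(min(l$year), 2011L)
  # span ends 2014-06 (mid-year): 2014 excluded, censored at 2013
  expect_equal(max(l$year), 2013L)
  expect_equal(l$censored_reason[l$year == 2013], "disenrollment")
})

test_that("death year is included as the final panel year", {
  ben <- tibble::tibble(beneficiary_id = "D", payer = "dual", sex = "female",
                        region = "south", birth_year = 1980L,
                        death_year = 2012L)
  enr <- span_row("D", "2009-01-01", "2012-07-01")
  claims <- make_case_claims("D", 2009)
  panel <- build_panel(tiny_population(ben, enr, claims))
  expect_equal(max(panel$year), 2012L)
  expect_equal(panel$censored_reason[panel$year == 2012], "death")
})

test_that("overlapping spans for one beneficiary raise an error", {
  ben <- tibble::tibble(beneficiary_id = "X", payer = "medicaid",
                        sex = "male", region = "south", birth_year = 2000L,
                        death_year = NA_integer_)
  enr <- dplyr::bind_rows(span_row("X", "2010-01-01", "2012-01-01"),
                          span_row("X", "2011-06-01", "2013-01-01"))
  expect_error(build_panel(tiny_population(ben, enr, make_case_claims("X", 2010))),
               class = "sicklesim_span_error")
})

test_that("panel flags and prevalence equal brute-force oracles", {
  cfg <- small_config(100L)
  cfg$payers$dual$n <- 80L
  pop <- generate_population(cfg, payers = c("medicaid", "dual"), seed = 99)
  reg <- default_registry()
  panel <- build_panel(pop)
  expect_lte(dplyr::n_distinct(panel$beneficiary_id), 200L)

  ids <- sample(unique(panel$beneficiary_id), 40)
  for (id in ids) {
    rows <- panel[panel$beneficiary_id == id, ]
    orc <- oracle_flags(pop, id, reg)
    expect_equal(min(rows$year), orc$index_year, info = id)
    for (anm in c("vaso_occlusive_pain", "chronic_pain", "asthma",
                  "chronic_renal_disease", "infections",
                  "pulmonary_hypertension_cvd")) {
      got <- rows[[paste0("flag_", anm)]]
      want <- vapply(rows$year, orc$flag_fun[[anm]], logical(1))
      expect_equal(got, want, info = paste(id, anm))
    }
  }

  prev <- lifetime_prevalence(panel, reg)
  comb <- prev[prev$payer == "combined", ]
  for (anm in comb$attribute) {
    expect_equal(comb$prevalence[comb$attribute == anm],
                 oracle_prevalence(panel, anm), info = anm)
  }
  # prevalence is invariant to beneficiary ordering
  shuffled <- panel[sample(nrow(panel)), ]
  prev2 <- lifetime_prevalence(shuffled, reg)
  expect_equal(dplyr::arrange(prev, payer, attribute),
               dplyr::arrange(prev2, payer, attribute))
  # removing all claims of an attribute zeroes its prevalence
  pop0 <- pop
  pop0$claims <- pop0$claims[!startsWith(pop0$claims$code, "7071") &
                               !startsWith(pop0$claims$code, "L979"), ]
  prev0 <- lifetime_prevalence(build_panel(pop0), reg)
  expect_true(all(prev0$prevalence[prev0$attribute == "leg_ulcers"] == 0))
})

test_that("chronic flags are monotone within person", {
  panel <- fixture_panel()
  da <- disease_attributes(default_registry())
  for (anm in da$name[da$persistence == "chronic"]) {
    mono <- panel |>
      dplyr::group_by(beneficiary_id) |>
      dplyr::summarise(ok = !is.unsorted(.data[[paste0("flag_", anm)]]))
    expect_true(all(mono$ok), info = anm)
  }
})
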