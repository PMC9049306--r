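# Shared fixtures, built once per test run.

.fix <- new.env()

small_config <- function(n_medicaid = 300L) {
  cfg <- demo_config()
  cfg$payers$medicaid$n <- n_medicaid
  cfg$payers$medicare$n <- 60L
  cfg$payers$dual$n <- 240L
  cfg$payers$commercial$n <- 0L
  cfg
}

fixture_population <- function() {
  if (is.null(.fix$pop)) {
    .fix$pop <- generate_population(small_config(),
                                    payers = c("medicaid", "medicare", "dual"),
                                    seed = 404)
  }
  .fix$pop
}

fixture_panel <- function() {
  if (is.null(.fix$panel)) .fix$panel <- build_panel(fixture_population())
  .fix$panel
}

fixture_index_set <- function() {
  if (is.null(.fix$set)) {
    split <- split_sample(fixture_panel(), seed = 404)
    .fix$set <- suppressWarnings(
      fit_index_set(split$train, penalty = penalty_spec(seed = 404)))
  }
  .fix$set
}

# minimal hand-built population for exact-rule tests
tiny_population <- function(beneficiaries, enrollment, claims) {
  defaults_b <- tibble::tibble(beneficiary_id = character(), payer = "medicaid",
                               sex = "female", region = "south",
                               birth_year = 2000L, death_year = NA_integer_)
  b <- dplyr::bind_rows(defaults_b, beneficiaries)
  structure(list(beneficiaries = b, enrollment = enrollment, claims = claims),
            class = "scd_population")
}

claim_row <- function(id, date, code, setting = "outpatient",
                      edition = NULL, position = 1L, procedure = "",
                      claim_id = NULL) {
  yr <- as.integer(format(as.Date(date), "%Y"))
  tibble::tibble(
    claim_id = claim_id %||% paste0("c", substr(rlang::hash(list(id, date, code,
                                                                 setting, position)),
                                                1, 8)),
    beneficiary_id = id, service_date = as.Date(date), setting = setting,
    position = as.integer(position), code = code,
    edition = edition %||% (if (yr >= 2016) "icd10" else "icd9"),
    procedure = procedure
  )
}

span_row <- function(id, from, to) {
  tibble::tibble(beneficiary_id = id, start_month = as.Date(from),
                 end_month = as.Date(to))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- independent brute-force oracles (nested loops, no vectorised reuse) --

oracle_is_scd <- function(code, edition) {
  x <- toupper(gsub(".", "", code, fixed = TRUE))
  if (edition == "icd9") {
    inc <- any(vapply(c("2826", "28241", "28242"),
                      function(p) startsWith(x, p), logical(1)))
    exc <- startsWith(x, "2825")
  } else {
    inc <- any(vapply(c("D57", "D578"),
                      function(p) startsWith(x, p), logical(1)))
    exc <- startsWith(x, "D573")
  }
  inc && !exc
}

oracle_cases <- function(claims) {
  out <- character()
  for (id in unique(claims$beneficiary_id)) {
    cl <- claims[claims$beneficiary_id == id, ]
    scd <- vapply(seq_len(nrow(cl)),
                  function(i) oracle_is_scd(cl$code[i], cl$edition[i]),
                  logical(1))
    if (any(scd & cl$setting == "inpatient")) { out <- c(out, id); next }
    dates <- unique(cl$service_date[scd & cl$setting %in%
                                      c("outpatient", "ED", "ambulatory")])
    if (length(dates) >= 2) out <- c(out, id)
  }
  sort(out)
}

# per-person scan of a panel: lifetime prevalence by attribute
oracle_prevalence <- function(panel, attribute) {
  ids <- unique(panel$beneficiary_id)
  n_ever <- 0
  for (id in ids) {
    rows <- panel[panel$beneficiary_id == id, ]
    if (any(rows[[paste0("flag_", attribute)]])) n_ever <- n_ever + 1
  }
  100 * n_ever / length(ids)
}

# independent re-derivation of annual flags from claims for one beneficiary
oracle_flags <- function(pop, id, registry) {
  reg_attrs <- registry$attributes
  # longest span (ties: earliest)
  sp <- pop$enrollment[pop$enrollment$beneficiary_id == id, ]
  months <- function(d) as.integer(format(d, "%Y")) * 12L +
    as.integer(format(d, "%m")) - 1L
  len <- months(sp$end_month) - months(sp$start_month) + 1L
  best <- which(len == max(len))
  best <- best[which.min(months(sp$start_month)[best])]
  s <- months(sp$start_month)[best]; e <- months(sp$end_month)[best]

  cl <- pop$claims[pop$claims$beneficiary_id == id, ]
  cl_m <- months(cl$service_date)
  cl <- cl[cl_m >= s & cl_m <= e, ]
  if (!nrow(cl)) return(NULL)
  scd <- vapply(seq_len(nrow(cl)),
                function(i) oracle_is_scd(cl$code[i], cl$edition[i]),
                logical(1))
  if (!any(scd)) return(NULL)
  index_year <- min(as.integer(format(cl$service_date[scd], "%Y")))

  cl$year <- as.integer(format(cl$service_date, "%Y"))
  years <- sort(unique(cl$year))
  event_years <- function(anm) {
    i <- match(anm, reg_attrs$name)
    codes9 <- reg_attrs$icd9[[i]]; codes10 <- reg_attrs$icd10[[i]]
    ys <- integer()
    for (r in seq_len(nrow(cl))) {
      codes <- if (cl$edition[r] == "icd9") codes9 else codes10
      x <- toupper(gsub(".", "", cl$code[r], fixed = TRUE))
      if (any(vapply(codes, function(p) startsWith(x, p), logical(1)))) {
        ys <- c(ys, cl$year[r])
      }
    }
    sort(unique(ys))
  }
  make_flag_fun <- function(ev, per) {
    force(ev); force(per)
    function(y) {
      switch(per,
             instantaneous = y %in% ev,
             subacute = any(ev %in% c(y, y - 1L, y - 2L)),
             chronic = length(ev) > 0 && y >= min(ev))
    }
  }
  out <- list()
  for (anm in reg_attrs$name) {
    out[[anm]] <- make_flag_fun(event_years(anm),
                                reg_attrs$persistence[match(anm, reg_attrs$name)])
  }
  list(index_year = index_year, flag_fun = out)
}
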