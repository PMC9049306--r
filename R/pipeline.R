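#' End-to-end pipeline
#'
#' Executes the stages generate -> derive -> fit -> calibrate -> simulate ->
#' cea in order (respecting toggles), writing per-stage outputs and a manifest
#' recording the configuration hash, seeds, package version, per-stage row
#' counts, and file checksums. A rerun with the same configuration and seed
#' reproduces every stochastic output bit-identically.
#'
#' @param config An `scd_config` (e.g. [demo_config()]).
#' @param outdir Output directory.
#' @param seed Master seed (defaults to the config's).
#' @param stages Character vector of stages to run.
#' @param payers Payer scenarios for generation/derivation.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = demo_config(), outdir, seed = NULL,
                         stages = c("generate", "derive", "fit", "calibrate",
                                    "simulate", "cea"),
                         payers = c("medicaid", "medicare", "dual")) {
  seed <- seed %||% config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  registry <- default_registry()
  manifest <- list(config_hash = rlang::hash(config), seed = seed,
                   package_version = as.character(utils::packageVersion("sicklesim")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] done")
  }

  if ("generate" %in% stages) {
    pop <- generate_population(config, payers = payers, seed = seed,
                               registry = registry)
    write_claims(pop, outdir)
    note("generate", seed = substream_seed(seed, "gen_medicaid"),
         beneficiaries = nrow(pop$beneficiaries), claims = nrow(pop$claims))
  }

  if ("derive" %in% stages) {
    pop <- read_stage_input(outdir, "beneficiaries.csv", "derive",
                            function() read_claims(outdir))
    panel <- build_panel(pop, cohort_definition(window = config$study_window,
                                                min_enrollment_months =
                                                  config$cohort$min_enrollment_months),
                         registry)
    readr::write_csv(panel, file.path(outdir, "panel.csv"))
    prev <- lifetime_prevalence(panel, registry)
    readr::write_csv(prev, file.path(outdir, "prevalence.csv"))
    readr::write_csv(attr(panel, "attrition"),
                     file.path(outdir, "attrition.csv"))
    message(paste(utils::capture.output(print(as.data.frame(
      attr(panel, "attrition")))), collapse = "\n"))
    note("derive", person_years = nrow(panel),
         beneficiaries = dplyr::n_distinct(panel$beneficiary_id))
  }

  if ("fit" %in% stages) {
    panel <- read_stage_input(outdir, "panel.csv", "fit",
                              function() read_panel(file.path(outdir, "panel.csv")))
    split <- split_sample(panel, seed = seed)
    set <- fit_index_set(split$train, registry,
                         penalty_spec(seed = substream_seed(seed, "fit")))
    write_indices(set, file.path(outdir, "indices.json"))
    note("fit", n_indices = sum(purrr::map_int(set$indices, length)),
         train_beneficiaries = dplyr::n_distinct(split$train$beneficiary_id))
  }

  if ("calibrate" %in% stages) {
    set <- read_stage_input(outdir, "indices.json", "calibrate",
                            function() read_indices(file.path(outdir, "indices.json")))
    models <- scd_models(set, registry, config)
    cal <- calibrate_to_prevalence(
      models, calibration_targets("combined",
                                  tolerance = config$calibration$tolerance),
      population_spec(config, payers),
      n_sim = config$calibration$n_sim,
      max_iter = config$calibration$max_iter,
      seed = substream_seed(seed, "calibrate"))
    write_indices(cal$models$index_set, file.path(outdir, "calibrated_indices.json"),
                  shifts = cal$models$shifts)
    readr::write_csv(cal$report, file.path(outdir, "calibration_report.csv"))
    note("calibrate", converged = sum(cal$report$converged),
         targets = nrow(cal$report))
  }

  results <- list()
  if ("simulate" %in% stages) {
    models <- read_calibrated_models(outdir, registry, config, "simulate")
    spec <- population_spec(config, payers)
    sim_seed <- substream_seed(seed, "simulate")
    for (strat in c("common_care", "hsct")) {
      results[[strat]] <- run_cohort(config$simulation$n, spec,
                                     scd_strategy(strat, config), models,
                                     seed = sim_seed)
    }
    tr <- dplyr::bind_rows(purrr::imap(
      results, ~ dplyr::mutate(.x$trajectories, strategy = .y, .before = 1)))
    readr::write_csv(tr, file.path(outdir, "trajectories.csv"))
    readr::write_csv(
      dplyr::bind_rows(purrr::imap(results, ~ dplyr::mutate(
        .x$summary, strategy = .y, .before = 1))),
      file.path(outdir, "summary.csv"))
    note("simulate", n = config$simulation$n,
         strategies = length(results))
  }

  if ("cea" %in% stages) {
    if (!length(results)) {
      abort_sim("stage 'cea' needs simulated trajectories; run 'simulate'",
                "pipeline_error")
    }
    cea <- compare_strategies(results, cost_model(config),
                              utility_index(config),
                              rate = config$discount_rate)
    readr::write_csv(tidy(cea), file.path(outdir, "cea_summary.csv"))
    readr::write_csv(cea$icers, file.path(outdir, "icers.csv"))
    models <- read_calibrated_models(outdir, registry, config, "cea")
    psa <- run_psa(models,
                   list(common_care = scd_strategy("common_care", config),
                        hsct = scd_strategy("hsct", config)),
                   population_spec(config, payers),
                   cost_model(config), utility_index(config),
                   n_draws = config$psa$n_draws,
                   n_per_draw = config$psa$n_per_draw,
                   cost_cv = config$psa$cost_cv,
                   utility_cv = config$psa$utility_cv,
                   wtp_grid = config$psa$wtp_grid,
                   rate = config$discount_rate,
                   seed = substream_seed(seed, "psa"))
    readr::write_csv(psa$draws, file.path(outdir, "psa_draws.csv"))
    readr::write_csv(psa$ceac, file.path(outdir, "ceac.csv"))
    note("cea", icer = cea$icers$icer[cea$icers$strategy == "hsct"])
  }

  files <- list.files(outdir, pattern = "\\.(csv|json)$")
  manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

read_stage_input <- function(outdir, file, stage, reader) {
  path <- file.path(outdir, file)
  if (!file.exists(path)) {
    abort_sim(sprintf("stage '%s' needs missing prerequisite '%s'", stage,
                      file), "pipeline_error")
  }
  reader()
}

read_calibrated_models <- function(outdir, registry, config, stage) {
  path <- file.path(outdir, "calibrated_indices.json")
  if (!file.exists(path)) {
    abort_sim(sprintf("stage '%s' needs missing prerequisite '%s'", stage,
                      "calibrated_indices.json"), "pipeline_error")
  }
  parsed <- read_indices(path, with_shifts = TRUE)
  scd_models(parsed$set, registry, config, shifts = parsed$shifts)
}

#' Read a panel CSV written by the pipeline
#' @param path Path to `panel.csv`.
#' @return An `scd_panel` tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  flagish <- grep("^(evt_|flag_|tx_)", names(panel), value = TRUE)
  panel <- dplyr::mutate(panel, dplyr::across(dplyr::all_of(flagish),
                                              as.logical))
  structure(panel, class = c("scd_panel", class(panel)))
}

#' Serialize / deserialize an index set as JSON
#'
#' The JSON schema is one object per index keyed by family then outcome,
#' carrying outcome, family, link, alpha, lambda, n, and the named
#' coefficient vector; calibration shifts, when present, are a top-level
#' `shifts` object.
#'
#' @param set An `scd_index_set`.
#' @param path File path.
#' @param shifts Optional named shifts to embed.
#' @export
write_indices <- function(set, path, shifts = NULL) {
  payload <- list(
    decades = set$schema$decades,
    families = purrr::map(set$indices, function(fam) {
      purrr::map(fam, function(ix) {
        list(outcome = ix$outcome, family = ix$family, link = ix$link,
             alpha = ix$alpha,
             lambda = if (is.finite(ix$lambda)) ix$lambda else "Inf",
             n = ix$n, coefficients = as.list(ix$coefficients))
      })
    })
  )
  if (!is.null(shifts)) payload$shifts <- as.list(shifts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_indices
#' @param with_shifts Also return embedded calibration shifts.
#' @param registry An `scd_registry`.
#' @export
read_indices <- function(path, with_shifts = FALSE,
                         registry = default_registry()) {
  payload <- jsonlite::read_json(path)
  schema <- covariate_schema(registry,
                             as.integer(unlist(payload$decades %||% list())))
  indices <- purrr::map(payload$families, function(fam) {
    purrr::map(fam, function(ix) {
      beta <- unlist(ix$coefficients)
      structure(list(outcome = ix$outcome, family = ix$family, link = ix$link,
                     coefficients = beta, alpha = ix$alpha,
                     lambda = as.numeric(ix$lambda), n = ix$n,
                     schema = schema$family_covariates[[ix$family]]),
                class = "scd_index")
    })
  })
  set <- structure(list(indices = indices, schema = schema),
                   class = "scd_index_set")
  if (with_shifts) {
    list(set = set, shifts = unlist(payload$shifts %||% list()) %||% numeric())
  } else {
    set
  }
}
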