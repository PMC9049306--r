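#' Disease-attribute registry
#'
#' The registry is the taxonomy every other module consumes. Sickle cell
#' disease is represented along four parallel dimensions of health:
#' chronic pain, acute events, chronic disorders, and treatment
#' complications. The default registry carries the 26 disease attributes
#' (13 acute events, 7 subacute disorders including chronic pain, and 6
#' absorbing chronic disorders) plus the complication sets associated with
#' hydroxyurea, transfusion, hematopoietic stem cell transplant (HSCT), and
#' gene therapy.
#'
#' Persistence semantics:
#' * `instantaneous` -- acute events; present only in the year they occur.
#' * `subacute` -- can remit; present in a year if a qualifying claim
#'   occurred in that year or the two preceding years.
#' * `chronic` -- absorbing; present in every year from first diagnosis.
#'
#' Chronic pain is stored with subacute persistence but carries its own
#' dimension so the simulation draws it in parallel with everything else.
#'
#' @name registry
NULL

.registry_cache <- new.env(parent = emptyenv())

DIMENSIONS <- c("chronic_pain", "acute_event", "chronic_disorder",
                "treatment_complication")
PERSISTENCE <- c("instantaneous", "subacute", "chronic")

#' Load an attribute registry from a configuration file or list
#'
#' @param config Path to a YAML registry file, or an already-parsed list with
#'   sections `attributes`, `therapies`, and `scd_case_definition`. `NULL`
#'   loads the packaged default registry.
#' @return An object of class `scd_registry`: a list with `attributes`
#'   (a tibble: name, dimension, persistence, icd9, icd10, severity_marker),
#'   `therapies` (named list of attribute-name vectors), and `case_codes`.
#' @examples
#' reg <- load_registry()
#' dplyr::count(reg$attributes, dimension)
#' @export
load_registry <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "registry.yaml", package = "sicklesim")
  }
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  attrs <- purrr::map_dfr(config$attributes, function(a) {
    tibble::tibble(
      name = a$name,
      dimension = a$dimension,
      persistence = a$persistence,
      icd9 = list(as.character(a$icd9 %||% character())),
      icd10 = list(as.character(a$icd10 %||% character())),
      severity_marker = isTRUE(a$severity_marker)
    )
  })
  therapies <- purrr::map(config$therapies %||% list(), as.character)
  cd <- config$scd_case_definition %||% list()
  case_codes <- list(
    include_icd9 = as.character(cd$include_icd9 %||% character()),
    include_icd10 = as.character(cd$include_icd10 %||% character()),
    exclude_icd9 = as.character(cd$exclude_icd9 %||% character()),
    exclude_icd10 = as.character(cd$exclude_icd10 %||% character())
  )
  reg <- structure(
    list(attributes = attrs, therapies = therapies, case_codes = case_codes),
    class = "scd_registry"
  )
  validate_registry(reg)
  reg
}

#' @rdname registry
#' @param x,... For `print.scd_registry`: object and ignored arguments.
#' @export
print.scd_registry <- function(x, ...) {
  n <- table(factor(x$attributes$dimension, levels = DIMENSIONS))
  cat("<scd_registry> ", nrow(x$attributes), " attributes\n", sep = "")
  cat(sprintf("  chronic pain: %d | acute events: %d | chronic disorders: %d | complications: %d\n",
              n[["chronic_pain"]], n[["acute_event"]], n[["chronic_disorder"]],
              n[["treatment_complication"]]))
  cat("  therapies:", paste(names(x$therapies), collapse = ", "), "\n")
  invisible(x)
}

validate_registry <- function(reg) {
  a <- reg$attributes
  if (anyDuplicated(a$name)) {
    abort_sim(paste0("duplicate attribute name(s): ",
                     paste(unique(a$name[duplicated(a$name)]), collapse = ", ")),
              "registry_error")
  }
  bad_dim <- setdiff(unique(a$dimension), DIMENSIONS)
  if (length(bad_dim)) {
    abort_sim(paste0("unknown dimension: ", paste(bad_dim, collapse = ", ")),
              "registry_error")
  }
  bad_per <- setdiff(unique(a$persistence), PERSISTENCE)
  if (length(bad_per)) {
    abort_sim(paste0("unknown persistence: ", paste(bad_per, collapse = ", ")),
              "registry_error")
  }
  # instantaneous persistence and the acute-event dimension coincide
  if (any((a$persistence == "instantaneous") != (a$dimension == "acute_event"))) {
    abort_sim("persistence 'instantaneous' is required for (and only for) acute events",
              "registry_error")
  }
  cp <- a[a$dimension == "chronic_pain", ]
  if (nrow(cp) && any(cp$persistence != "subacute")) {
    abort_sim("chronic pain must have subacute persistence", "registry_error")
  }
  undefined <- setdiff(unlist(reg$therapies, use.names = FALSE), a$name)
  if (length(undefined)) {
    abort_sim(paste0("therapy set references undefined attribute(s): ",
                     paste(unique(undefined), collapse = ", ")),
              "registry_error")
  }
  # attribute codes must be disjoint from the trait exclusion set
  excl <- normalize_icd(c(reg$case_codes$exclude_icd9, reg$case_codes$exclude_icd10))
  codes <- normalize_icd(unlist(c(a$icd9, a$icd10), use.names = FALSE))
  if (length(intersect(codes, excl))) {
    abort_sim("attribute codes overlap the sickle cell trait exclusion set",
              "registry_error")
  }
  invisible(reg)
}

#' The packaged default registry (memoized)
#' @return An `scd_registry`.
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$default)) {
    .registry_cache$default <- load_registry()
  }
  .registry_cache$default
}

#' Write a registry back to its YAML file representation
#'
#' `write_registry()` followed by [load_registry()] round-trips the registry
#' exactly.
#'
#' @param registry An `scd_registry`.
#' @param path Output file path.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "scd_registry"))
  a <- registry$attributes
  cfg <- list(
    scd_case_definition = registry$case_codes,
    attributes = purrr::pmap(a, function(name, dimension, persistence, icd9,
                                         icd10, severity_marker) {
      list(name = name, dimension = dimension, persistence = persistence,
           icd9 = icd9, icd10 = icd10, severity_marker = severity_marker)
    }),
    therapies = registry$therapies
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Disease attributes = everything outside the treatment_complication dimension,
# in registry order. This is the 26-attribute set.
disease_attributes <- function(registry) {
  registry$attributes[registry$attributes$dimension != "treatment_complication", ]
}

complication_attributes <- function(registry) {
  registry$attributes[registry$attributes$dimension == "treatment_complication", ]
}

severity_attributes <- function(registry) {
  a <- disease_attributes(registry)
  a$name[a$severity_marker]
}

#' Does an ICD code meet the SCD case definition?
#'
#' Matching is prefix-based on normalized codes (dots stripped,
#' case-insensitive); trait exclusions are applied after inclusions, so a
#' stem inclusion such as `D57` does not capture the trait code `D57.3`.
#'
#' @param code Character vector of ICD codes.
#' @param edition `"icd9"` or `"icd10"`.
#' @param registry Registry supplying the case definition.
#' @return Logical vector.
#' @examples
#' is_scd_code("282.62", "icd9")
#' is_scd_code("D57.3", "icd10")
#' @export
is_scd_code <- function(code, edition, registry = default_registry()) {
  if (any(!nzchar(code))) abort_sim("empty ICD code", "icd_error")
  edition <- match.arg(edition, c("icd9", "icd10"))
  cc <- registry$case_codes
  inc <- normalize_icd(cc[[paste0("include_", edition)]])
  exc <- normalize_icd(cc[[paste0("exclude_", edition)]])
  x <- normalize_icd(code)
  has_prefix(x, inc) & !has_prefix(x, exc)
}

# attribute-code lookup table: one row per (attribute, code, edition)
attribute_code_table <- function(registry) {
  a <- registry$attributes
  dplyr::bind_rows(
    tidyr::unnest(dplyr::transmute(a, attribute = .data$name,
                                   code = .data$icd9, edition = "icd9"),
                  "code"),
    tidyr::unnest(dplyr::transmute(a, attribute = .data$name,
                                   code = .data$icd10, edition = "icd10"),
                  "code")
  ) |>
    dplyr::mutate(code = normalize_icd(.data$code))
}
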