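#' Penalty specification for index fitting
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param lambda Either `"cv"` (choose by k-fold cross-validation on the
#'   supplied design, the default) or a non-negative number (0 gives an
#'   essentially unpenalized fit).
#' @param nfolds Folds for cross-validation.
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `scd_penalty`.
#' @export
penalty_spec <- function(alpha = 0.5, lambda = "cv", nfolds = 5L, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.numeric(lambda)) stopifnot(lambda >= 0)
  structure(list(alpha = alpha, lambda = lambda, nfolds = nfolds, seed = seed),
            class = "scd_penalty")
}

#' Fit one prediction index
#'
#' Fits a penalized (elastic-net) regression for a single outcome on a
#' design table from [build_design()]. Binary outcomes use a logit link,
#' utilization counts a log link (Poisson). When `lambda = "cv"` the penalty
#' strength is chosen by seeded k-fold cross-validation on the rows
#' supplied -- pass the training split only.
#'
#' @param design An `scd_design` tibble.
#' @param penalty A [penalty_spec()].
#' @return An object of class `scd_index`: outcome, family, link, named
#'   coefficient vector (including `(Intercept)`), penalty used, and the
#'   covariate schema it expects.
#' @export
fit_index <- function(design, penalty = penalty_spec()) {
  outcome <- attr(design, "outcome")
  family <- attr(design, "family")
  link <- attr(design, "link")
  covars <- setdiff(names(design), c(".beneficiary", ".year", ".outcome"))
  x <- as.matrix(design[, covars])
  y <- design$.outcome
  glm_family <- if (link == "log") "poisson" else "binomial"
  if (glm_family == "binomial" && (sum(y > 0) == 0L || sum(y == 0) == 0L)) {
    abort_sim(sprintf("degenerate outcome '%s': all %s", outcome,
                      if (sum(y > 0) == 0L) "non-events" else "events"),
              "degenerate_outcome")
  }
  if (glm_family == "poisson" && all(y == 0)) {
    abort_sim(sprintf("degenerate outcome '%s': all zero counts", outcome),
              "degenerate_outcome")
  }
  if (is.numeric(penalty$lambda)) {
    lam <- max(penalty$lambda, 1e-10)  # glmnet wants a positive value
    fit <- glmnet::glmnet(x, y, family = glm_family, alpha = penalty$alpha,
                          lambda = lam)
    lambda_used <- penalty$lambda
  } else {
    # an outcome too rare to cross-validate gets an intercept-only index at
    # its observed rate
    if (glm_family == "binomial" &&
        min(sum(y > 0), sum(y == 0)) < 2L * penalty$nfolds) {
      warning("outcome '", outcome, "' too rare for cross-validation; ",
              "using an intercept-only index at the observed rate",
              call. = FALSE)
      sch <- covars
      rate <- clamp(mean(y > 0), 1 / (2 * length(y)), 1 - 1 / (2 * length(y)))
      beta <- stats::setNames(c(logit(rate), rep(0, length(sch))),
                              c("(Intercept)", sch))
      return(structure(
        list(outcome = outcome, family = family, link = link,
             coefficients = beta, alpha = penalty$alpha, lambda = Inf,
             n = length(y), schema = sch),
        class = "scd_index"))
    }
    # stratified fold assignment keeps every fold populated with events
    foldid <- withr::with_seed(
      substream_seed(penalty$seed, paste0("cv_", outcome)), {
        f <- integer(length(y))
        for (cls in unique(y > 0)) {
          i <- which((y > 0) == cls)
          f[i] <- sample(rep_len(seq_len(penalty$nfolds), length(i)))
        }
        f
      }
    )
    cv <- glmnet::cv.glmnet(x, y, family = glm_family, alpha = penalty$alpha,
                            foldid = foldid)
    fit <- cv$glmnet.fit
    lambda_used <- cv$lambda.min
  }
  beta <- as.matrix(stats::coef(fit, s = max(lambda_used, 1e-10)))[, 1]
  names(beta)[1] <- "(Intercept)"
  structure(
    list(outcome = outcome, family = family, link = link,
         coefficients = beta, alpha = penalty$alpha, lambda = lambda_used,
         n = length(y), schema = covars),
    class = "scd_index"
  )
}

#' @export
print.scd_index <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("<scd_index> %s (%s, %s link): %d/%d nonzero covariates, lambda=%.4g, n=%d\n",
              x$outcome, x$family, x$link, nz, length(x$coefficients) - 1,
              x$lambda, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.scd_index <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.scd_index <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, family = x$family, link = x$link,
                 alpha = x$alpha, lambda = x$lambda, n = x$n,
                 n_nonzero = sum(x$coefficients[-1] != 0))
}

#' Evaluate an index on new covariates
#'
#' @param index An `scd_index`.
#' @param newdata A named numeric vector, or a data frame / matrix with the
#'   index's covariates as columns.
#' @return For logit-link indices, probabilities in `[0, 1]`; for log-link
#'   (utilization) indices, expected annual counts.
#' @export
predict_probability <- function(index, newdata) {
  if (is.numeric(newdata) && !is.matrix(newdata)) {
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  missing <- setdiff(index$schema, colnames(newdata))
  if (length(missing)) {
    abort_sim(paste0("missing covariate(s): ", paste(missing, collapse = ", ")),
              "schema_error")
  }
  eta <- drop(newdata[, index$schema, drop = FALSE] %*%
                index$coefficients[index$schema]) +
    index$coefficients[["(Intercept)"]]
  if (index$link == "logit") inv_logit(eta) else exp(eta)
}

#' Bootstrap parameter uncertainty for one index
#'
#' Refits the index on beneficiary-level resamples (with replacement) of the
#' supplied design -- intended to be the first test split, giving
#' out-of-sample replicates. Resamples whose outcome is degenerate are
#' redrawn (bounded retries) with a warning.
#'
#' @param design An `scd_design` (typically restricted to the first test
#'   split).
#' @param penalty A [penalty_spec()]; cross-validated lambda is re-used from
#'   the point estimate rather than re-tuned per replicate.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return An `scd_bootstrap`: list with `replicates` (matrix, one row per
#'   replicate) and the point-estimate index.
#' @export
bootstrap_uncertainty <- function(design, penalty = penalty_spec(),
                                  n_replicates = 100L, seed = 1L) {
  point <- fit_index(design, penalty)
  fixed <- penalty
  fixed$lambda <- point$lambda
  ids <- unique(design$.beneficiary)
  reps <- matrix(NA_real_, n_replicates, length(point$coefficients),
                 dimnames = list(NULL, names(point$coefficients)))
  if (n_replicates > 0L) {
    withr::with_seed(substream_seed(seed, paste0("boot_", point$outcome)), {
      for (r in seq_len(n_replicates)) {
        for (try in 1:10) {
          take <- sample(ids, length(ids), replace = TRUE)
          idx <- unlist(purrr::map(take, ~ which(design$.beneficiary == .x)),
                        use.names = FALSE)
          res <- design[idx, ]
          attributes(res)[c("outcome", "family", "link")] <-
            attributes(design)[c("outcome", "family", "link")]
          ok <- length(unique(res$.outcome > 0)) > 1 ||
            attr(design, "link") == "log"
          if (ok) break
          warning("degenerate bootstrap resample for '", point$outcome,
                  "', redrawing")
        }
        reps[r, ] <- fit_index(res, fixed)$coefficients
      }
    })
  }
  structure(list(replicates = reps, point = point, n_replicates = n_replicates),
            class = "scd_bootstrap")
}

#' Fit the full set of prediction indices
#'
#' Fits one index per outcome: incidence for every disease attribute,
#' treatment use for the three Common Care treatments, complication models
#' for the common-care complications, and utilization count models. Outcomes
#' that are degenerate in the training data (no events) fall back to an
#' intercept-only index at a configurable floor probability, with a warning.
#'
#' @param panel Training panel (use [split_sample()] first).
#' @param registry An `scd_registry`.
#' @param penalty A [penalty_spec()].
#' @param families Which families to fit (default all four).
#' @param floor_probability Fallback annual probability for degenerate
#'   outcomes.
#' @return An `scd_index_set`: named list of families, each a named list of
#'   `scd_index` objects, plus the covariate schema.
#' @export
fit_index_set <- function(panel, registry = default_registry(),
                          penalty = penalty_spec(), families = FAMILIES,
                          floor_probability = 1e-4) {
  schema <- covariate_schema(registry, unique(floor(panel$birth_year / 10) * 10))
  outcomes <- list(
    incidence = disease_attributes(registry)$name,
    treatment_use = TREATMENTS,
    complication = schema$complications,
    utilization = UTILIZATION
  )
  sets <- purrr::map(families, function(fam) {
    purrr::map(rlang::set_names(outcomes[[fam]]), function(out) {
      design <- build_design(panel, out, fam, registry, schema)
      tryCatch(
        fit_index(design, penalty),
        sicklesim_degenerate_outcome = function(e) {
          warning("outcome '", out, "' degenerate in training data; ",
                  "using intercept-only floor index", call. = FALSE)
          intercept_index(out, fam, schema,
                          p = floor_probability)
        }
      )
    })
  })
  structure(list(indices = rlang::set_names(sets, families), schema = schema),
            class = "scd_index_set")
}

# intercept-only index at a fixed probability (or count rate for log link)
intercept_index <- function(outcome, family, schema, p = NULL, rate = NULL) {
  covars <- schema$family_covariates[[family]]
  link <- if (family == "utilization") "log" else "logit"
  b0 <- if (link == "logit") logit(p) else log(rate %||% p)
  beta <- stats::setNames(c(b0, rep(0, length(covars))),
                          c("(Intercept)", covars))
  structure(list(outcome = outcome, family = family, link = link,
                 coefficients = beta, alpha = 0, lambda = Inf, n = 0L,
                 schema = covars),
            class = "scd_index")
}

#' @export
print.scd_index_set <- function(x, ...) {
  cat("<scd_index_set>\n")
  for (fam in names(x$indices)) {
    cat(sprintf("  %s: %d indices\n", fam, length(x$indices[[fam]])))
  }
  invisible(x)
}

#' @export
tidy.scd_index_set <- function(x, ...) {
  purrr::map_dfr(names(x$indices), function(fam) {
    purrr::map_dfr(x$indices[[fam]], function(ix) {
      dplyr::mutate(tidy(ix), outcome = ix$outcome, family = fam,
                    .before = 1)
    })
  })
}

#' @export
glance.scd_index_set <- function(x, ...) {
  purrr::map_dfr(x$indices, ~ purrr::map_dfr(.x, glance))
}
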