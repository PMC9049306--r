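# synthetic logistic design with known coefficients
logistic_design <- function(n, beta, intercept, seed, outcome = "stroke") {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("z", seq_along(beta))))
    p <- plogis(intercept + drop(x %*% beta))
    y <- rbinom(n, 1, p)
  })
  d <- dplyr::bind_cols(
    tibble::tibble(.beneficiary = sprintf("b%06d", seq_len(n)),
                   .year = 2010L, .outcome = y),
    tibble::as_tibble(x)
  )
  structure(d, class = c("scd_design", class(d)), outcome = outcome,
            family = "incidence", link = "logit")
}

test_that("an essentially unpenalized fit recovers known coefficients", {
  beta <- c(0.8, -0.5, 0.3, 0, 0.6, -0.2)
  d <- logistic_design(20000, beta, intercept = -1, seed = 42)
  ix <- fit_index(d, penalty_spec(alpha = 0.5, lambda = 0))
  ref <- glm(.outcome ~ ., family = binomial(),
             data = dplyr::select(d, -".beneficiary", -".year"))
  se <- summary(ref)$coefficients[, "Std. Error"]
  truth <- c(-1, beta)
  est <- ix$coefficients[c("(Intercept)", paste0("z", seq_along(beta)))]
  expect_true(all(abs(est - truth) < 1.96 * se + 0.02))
})

test_that("an overwhelming penalty zeroes all non-intercept coefficients", {
  d <- logistic_design(2000, c(1, -1, 0.5), intercept = 0, seed = 7)
  ix <- fit_index(d, penalty_spec(lambda = 1e6))
  expect_true(all(ix$coefficients[-1] == 0))
  # the intercept-only prediction equals the event rate
  expect_equal(unname(plogis(ix$coefficients[1])), mean(d$.outcome),
               tolerance = 1e-6)
})

test_that("increasing the penalty never increases the active set", {
  d <- logistic_design(2000, c(1, -1, 0.5, 0.2, 0), intercept = -0.5, seed = 8)
  lambdas <- c(0.001, 0.01, 0.05, 0.2, 1)
  nnz <- vapply(lambdas, function(l) {
    sum(fit_index(d, penalty_spec(alpha = 1, lambda = l))$coefficients[-1] != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("collinear covariates are handled under elastic-net mixing", {
  d <- logistic_design(1000, c(1, -0.5), intercept = 0, seed = 9)
  d$z_dup <- d$z1
  expect_no_error(fit_index(d, penalty_spec(alpha = 0.5, lambda = 0.01)))
})

test_that("degenerate outcomes raise a named error", {
  d <- logistic_design(200, c(0.5), intercept = -30, seed = 10,
                       outcome = "priapism")
  expect_true(all(d$.outcome == 0))
  expect_error(fit_index(d, penalty_spec()), "priapism",
               class = "sicklesim_degenerate_outcome")
})

test_that("prediction matches direct inverse-link arithmetic", {
  schema <- c("a", "b", "c")
  mk <- function(coefs) {
    structure(list(outcome = "x", family = "incidence", link = "logit",
                   coefficients = coefs, alpha = 0.5, lambda = 0.1, n = 10,
                   schema = schema), class = "scd_index")
  }
  zero <- mk(c("(Intercept)" = 0, a = 0, b = 0, c = 0))
  expect_equal(predict_probability(zero, c(a = 1, b = 2, c = 3)), 0.5)
  quarter <- mk(c("(Intercept)" = log(1 / 3), a = 0, b = 0, c = 0))
  expect_equal(predict_probability(quarter, c(a = 0, b = 0, c = 0)), 0.25)
  withr::with_seed(1, {
    for (i in 1:20) {
      cf <- rnorm(4); names(cf) <- c("(Intercept)", schema)
      v <- rnorm(3); names(v) <- schema
      expect_equal(predict_probability(mk(cf), v),
                   plogis(cf[["(Intercept)"]] + sum(cf[schema] * v)))
    }
  })
  expect_error(predict_probability(zero, c(a = 1, b = 2)), "c",
               class = "sicklesim_schema_error")
})

test_that("bootstrap replicates are seeded and consistent", {
  d <- logistic_design(1500, c(0.8, -0.4), intercept = -0.5, seed = 12)
  # beneficiary resampling needs repeated ids to matter; collapse to 300
  d$.beneficiary <- rep(sprintf("g%03d", 1:300), each = 5)
  b0 <- bootstrap_uncertainty(d, penalty_spec(lambda = 0.01),
                              n_replicates = 0, seed = 1)
  expect_equal(nrow(b0$replicates), 0L)
  b1 <- bootstrap_uncertainty(d, penalty_spec(lambda = 0.01),
                              n_replicates = 30, seed = 1)
  b2 <- bootstrap_uncertainty(d, penalty_spec(lambda = 0.01),
                              n_replicates = 30, seed = 1)
  expect_identical(b1$replicates, b2$replicates)
  # replicate-mean intercept within 3 bootstrap SE of the point estimate
  m <- mean(b1$replicates[, "(Intercept)"])
  se <- sd(b1$replicates[, "(Intercept)"]) / 1  # SE of the distribution
  expect_lt(abs(m - b1$point$coefficients[["(Intercept)"]]), 3 * se)
})

test_that("the fitted index set covers every outcome family", {
  set <- fixture_index_set()
  expect_named(set$indices,
               c("incidence", "treatment_use", "complication", "utilization"))
  expect_equal(length(set$indices$incidence), 26L)
  expect_equal(length(set$indices$treatment_use), 3L)
  expect_equal(length(set$indices$utilization), 3L)
  td <- tidy(set)
  expect_true(all(c("outcome", "family", "term", "estimate") %in% names(td)))
  g <- glance(set)
  expect_true(all(g$lambda >= 0))
})

test_that("calibration slope of refit incidence indices is near 1", {
  # simulate person-years from a known sparse logistic model, refit with
  # cross-validated elastic net, and regress outcome on the linear predictor
  beta <- c(rep(0, 10), 0.9, -0.7, 0.5)
  d <- logistic_design(20000, beta, intercept = -2, seed = 77)
  train <- d[1:12000, ]
  test <- d[12001:20000, ]
  attributes(train)[c("outcome", "family", "link")] <-
    attributes(d)[c("outcome", "family", "link")]
  ix <- fit_index(train, penalty_spec(alpha = 0.5, seed = 3))
  eta <- qlogis(pmin(pmax(
    predict_probability(ix, as.matrix(dplyr::select(
      test, dplyr::starts_with("z")))), 1e-12), 1 - 1e-12))
  slope <- unname(coef(glm(test$.outcome ~ eta, family = binomial()))[2])
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
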