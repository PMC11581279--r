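make_ph_cohort <- function(n, beta = log(2), seed = 1, scale = 120,
                           shape = 1.2) {
  cb <- codebook(list(arm = list(levels = c("a", "b"))))
  p <- generator_params(cb, list(arm = list(marginal = c(0.5, 0.5))),
                        list(arm = c(0, beta)), shape = shape, scale = scale,
                        horizon = 60)
  generate_cohort(p, n, seed = seed)$cohort
}

test_that("dummy coding follows the codebook reference layout", {
  cb <- ec_codebook()
  df <- as.data.frame(lapply(n_levels(cb), function(k) 1L))
  names(df) <- names(cb)
  df$follow_up_months <- 60L; df$event <- 0L
  ref_rec <- cohort(df, cb)
  d <- dummy_encode(ref_rec)
  expect_identical(ncol(d$X), 25L)           # sum(levels - 1)
  expect_true(all(d$X == 0))                 # all-reference record
  df2 <- df; df2$age <- 4L                   # "70-79"
  d2 <- dummy_encode(cohort(df2, cb))
  age_block <- grep("^age=", colnames(d2$X))
  expect_identical(unname(d2$X[1, age_block]), c(0, 0, 1, 0))
  expect_identical(colnames(d2$X)[age_block[3]], "age=70-79")
  expect_error(dummy_encode(ref_rec, "nope"), "unknown")
})

test_that("the null partial likelihood has its closed form", {
  # distinct event times: at beta = 0 the nll is the sum of log risk-set sizes
  cb <- toy_codebook(1, 2)
  x <- toy_cohort(matrix(rep(1:2, 5), 10, 1),
                  event = rep(1L, 10), months = c(3, 8, 11, 15, 21, 26, 33,
                                                  41, 50, 59), cb = cb)
  d <- dummy_encode(x)
  expect_equal(negative_log_partial_likelihood(0, d),
               sum(log(10:1)), tolerance = 1e-12)
  # no events -> empty product -> zero
  x0 <- toy_cohort(matrix(1:2, 4, 1), event = rep(0L, 4),
                   months = rep(60L, 4), cb = cb)
  expect_identical(negative_log_partial_likelihood(0, dummy_encode(x0)), 0)
  expect_error(negative_log_partial_likelihood(c(0, 0), d), "columns")
})

test_that("analytic gradient matches central finite differences", {
  for (rep in 1:5) {
    set.seed(rep * 7)
    x <- random_cohort(30, 3, 2, seed = rep * 7 + 1)
    x$data$follow_up_months <- sample.int(60, 30, replace = TRUE)
    x$data$event <- rbinom(30, 1, 0.6)
    if (sum(x$data$event) == 0) next
    d <- dummy_encode(x)
    beta <- rnorm(ncol(d$X), 0, 0.5)
    for (ties in c("efron", "breslow")) {
      g <- unname(partial_likelihood_gradient(beta, d, ties))
      gn <- numeric_gradient(function(b)
        negative_log_partial_likelihood(b, d, ties), beta)
      expect_equal(g, gn, tolerance = 1e-6)
    }
  }
})

test_that("one-parameter Newton fit agrees with golden-section search", {
  x <- make_ph_cohort(300, beta = 0.7, seed = 23)
  fit <- cox_ph(x)
  d <- dummy_encode(x)
  for (ties in c("efron", "breslow")) {
    f <- suppressWarnings(cox_ph(x, ties = ties))
    b_gs <- golden_section(function(b)
      negative_log_partial_likelihood(b, d, ties), -3, 3)
    expect_equal(unname(coef(f)), b_gs, tolerance = 1e-6)
  }
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("coefficients match an independent Cox implementation", {
  skip_if_not_installed("survival")
  g <- generate_cohort(default_generator_params(), 400, seed = 31)
  sdf <- g$cohort$data
  # well-populated variables only: levels with a handful of records can put
  # both optimizers on a monotone-likelihood ridge where estimates diverge
  vars <- c("age", "tumor_grade", "tumor_stage", "chemotherapy",
            "tumor_size", "lymph_node_metastasis", "depth_of_invasion")
  d <- dummy_encode(g$cohort, vars)
  for (ties in c("efron", "breslow")) {
    fit <- suppressWarnings(cox_ph(g$cohort, variables = vars, ties = ties))
    ref <- survival::coxph(
      survival::Surv(sdf$follow_up_months, sdf$event) ~ d$X,
      ties = ties, control = survival::coxph.control(eps = 1e-10, iter.max = 50))
    expect_equal(unname(coef(fit)[fit$kept]), unname(coef(ref)[fit$kept]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se[fit$kept]),
                 unname(sqrt(diag(vcov(ref)))[fit$kept]), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("Efron and Breslow coincide when all event times are distinct", {
  cb <- toy_codebook(2, 2)
  set.seed(41)
  x <- toy_cohort(matrix(sample.int(2, 80, replace = TRUE), 40, 2),
                  event = rep(1L, 40), months = sample(1:60, 40), cb = cb)
  fe <- cox_ph(x, ties = "efron")
  fb <- cox_ph(x, ties = "breslow")
  expect_lt(max(abs(coef(fe) - coef(fb))), 1e-8)
})

test_that("a true hazard ratio of 2 is recovered across seeds", {
  est <- vapply(1:20, function(s)
    unname(coef(cox_ph(make_ph_cohort(1000, beta = log(2), seed = s)))),
    numeric(1))
  hr <- exp(mean(est))
  expect_gte(hr, 1.8)
  expect_lte(hr, 2.2)
})

test_that("null effects stay within two standard errors", {
  ok <- vapply(1:20, function(s) {
    fit <- cox_ph(make_ph_cohort(1000, beta = 0, seed = 100 + s))
    abs(coef(fit)) < 2 * fit$se
  }, logical(1))
  expect_gte(sum(ok), 18L)
})

test_that("hazard ratios and Wald statistics follow their definitions", {
  x <- make_ph_cohort(300, beta = 0.7, seed = 51)
  fit <- cox_ph(x)
  expect_equal(unname(hazard_ratios(fit)), exp(unname(coef(fit))))
  wz <- wald_statistics(fit)
  expect_equal(wz$z, unname(coef(fit) / fit$se))
  # two-sided normal p against a numeric-integration CDF oracle
  upper <- stats::integrate(stats::dnorm, abs(wz$z[1]), Inf,
                            rel.tol = 1e-12)$value
  expect_equal(wz$p[1], 2 * upper, tolerance = 1e-10)
})

test_that("the univariate screen reports df = observed levels - 1", {
  g <- generate_cohort(default_generator_params(), 618, seed = 61)
  res <- univariate_lr_test(g$cohort, "age")
  expect_identical(res$df, 4L)
  expect_gte(res$LR, 0)
  # definitional identity against the underlying log-likelihoods
  fit <- cox_ph(g$cohort, variables = "age")
  expect_equal(res$LR, 2 * (fit$loglik - fit$loglik_null), tolerance = 1e-10)
  one <- g$cohort; one$data$age <- 1L
  expect_error(univariate_lr_test(one, "age"), "single observed level")
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  # 6-record hand example: deaths at months 10 (1 of 6 at risk), 20 (1 of 4),
  # 40 (2 of 3); censorings at 15 and 60
  cb <- toy_codebook(1, 2)
  x <- toy_cohort(matrix(c(1, 2, 1, 2, 1, 2), 6, 1),
                  event = c(1L, 0L, 1L, 1L, 1L, 0L),
                  months = c(10L, 15L, 20L, 40L, 40L, 60L), cb = cb)
  fit <- cox_ph(x)
  fit$coefficients[] <- 0                      # evaluate the estimator at 0
  bl <- breslow_baseline(fit)
  expect_equal(bl$time, c(10, 20, 40))
  expect_equal(bl$hazard, cumsum(c(1 / 6, 1 / 4, 2 / 3)), tolerance = 1e-12)
  expect_equal(bl$survival, exp(-bl$hazard), tolerance = 1e-12)
})

test_that("baseline survival is monotone and 1 before the first event", {
  x <- make_ph_cohort(300, seed = 71)
  fit <- cox_ph(x)
  bl <- breslow_baseline(fit)
  expect_true(all(diff(bl$survival) <= 0))
  expect_true(all(diff(bl$hazard) >= 0))
  expect_equal(tansurv:::baseline_survival_at(bl, min(bl$time) - 1), 1)
})

test_that("survival prediction obeys the proportional-hazards power law", {
  x <- make_ph_cohort(500, beta = 0.7, seed = 81)
  fit <- cox_ph(x)
  bl <- breslow_baseline(fit)
  s0 <- tansurv:::baseline_survival_at(bl, 60)
  pred <- predict_survival_probability(fit, x, horizon = 60)
  eta <- predict(fit, x, type = "lp")
  expect_equal(pred, s0^exp(eta), tolerance = 1e-12)
  ref_rows <- which(x$data$arm == 1L)
  expect_equal(unique(pred[ref_rows]), s0, tolerance = 1e-12)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("predicted 60-month survival tracks the generating Weibull truth", {
  cb <- codebook(list(arm = list(levels = c("a", "b"))))
  p <- generator_params(cb, list(arm = list(marginal = c(0.5, 0.5))),
                        list(arm = c(0, log(2))), shape = 1.2, scale = 120,
                        horizon = 60)
  g <- generate_cohort(p, 4000, seed = 91)
  fit <- cox_ph(g$cohort)
  pred <- predict_survival_probability(fit, g$cohort, horizon = 60)
  err <- vapply(1:2, function(lev) {
    truth <- exp(-(60 / 120)^1.2 * exp(c(0, log(2))[lev]))
    mean(pred[g$cohort$data$arm == lev]) - truth
  }, numeric(1))
  expect_lt(mean(abs(err)), 0.03)
})

test_that("constant columns are dropped with a warning", {
  g <- generate_cohort(default_generator_params(), 60, seed = 95)
  g$cohort$data$radiotherapy <- 1L
  expect_warning(fit <- cox_ph(g$cohort), "constant column")
  expect_true("radiotherapy=Yes" %in% fit$dropped)
  expect_true(is.na(coef(fit)["radiotherapy=Yes"]))
})

test_that("the univariate LR test holds its nominal size", {
  # covariate independent of survival: rejection rate at 0.05 over 400
  # replicates of n = 200 must sit in the stated band
  cb <- codebook(list(noise = list(levels = c("a", "b"))))
  p <- generator_params(cb, list(noise = list(marginal = c(0.5, 0.5))),
                        list(noise = c(0, 0)), shape = 1.2, scale = 120,
                        horizon = 60)
  pvals <- vapply(1:400, function(s) {
    g <- generate_cohort(p, 200, seed = 1000 + s)
    univariate_lr_test(g$cohort, "noise")$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
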