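test_that("multicollinearity screen scores and flags association types", {
  set.seed(51)
  n <- 600
  x <- rnorm(n)
  dat <- data.frame(x = x, y = x, z = rnorm(n),
                    g = factor(rep(c("a", "b"), each = n / 2)),
                    h = factor(rep(c("u", "v"), each = n / 2)),
                    const = 1)
  scr <- check_multicollinearity(dat, c("x", "y", "z", "g", "h", "const"))
  expect_equal(scr$measure["x", "y"], 1)
  expect_true(scr$flagged["x", "y"])
  expect_false(scr$flagged["x", "z"])
  # perfectly aligned 2x2 factors give Cramer's V = 1
  expect_equal(scr$measure["g", "h"], 1)
  expect_true(scr$flagged["g", "h"])
  expect_identical(scr$degenerate, "const")
  expect_true(all(is.na(scr$measure["const", c("x", "y")])))

  # independent simulated predictors raise no flags
  set.seed(52)
  ind <- data.frame(a = rnorm(5000), b = rnorm(5000),
                    c = factor(sample(letters[1:3], 5000, TRUE)),
                    d = factor(sample(letters[4:5], 5000, TRUE)))
  scr2 <- check_multicollinearity(ind, c("a", "b", "c", "d"))
  expect_false(any(scr2$flagged))
})

test_that("the mixed model recovers variance components and degenerate limits", {
  out <- simulate_analysis_frame(seed = 53, n_dogs = 300,
                                 records_per_dog_mean = 40)
  fit <- fit_lmm(out$frame, full_model_spec())
  share <- fit$var_random / (fit$var_random + fit$var_residual)
  expect_lt(abs(share - 0.5), 0.05)
  expect_true(all(fit$coefficients$ci_lower <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$estimate <= fit$coefficients$ci_upper))

  # near-noise-free data: coefficients equal generating values to 3 decimals
  nf <- simulate_analysis_frame(seed = 54, n_dogs = 120,
                                records_per_dog_mean = 25,
                                tau2 = 0, sigma2 = 1e-8)
  fit_nf <- fit_lmm(nf$frame, full_model_spec())
  truth <- expected_fixed_effects(nf$truth, fit_nf$coefficients$term)
  # active minutes are emitted rounded to 0.1 min, so agreement is bounded
  # by that measurement granularity (~1e-3 on the log scale)
  expect_lt(max(abs(fit_nf$coefficients$estimate - unname(truth))), 2e-3)
  expect_lt(fit_nf$var_random, 1e-6)

  # identical response pattern in every dog: zero between-dog variance,
  # flagged as a singular fit rather than erroring
  flat <- data.frame(dog_key = rep(sprintf("d%02d", 1:30), each = 4),
                     day_type = rep(c("weekday", "weekday", "weekend",
                                      "weekend"), 30),
                     active_minutes = rep(c(40, 42, 50, 52), 30))
  fit_s0 <- fit_lmm(flat, model_spec(fixed = "day_type", group = "dog_key",
                                     age_var = NULL))
  expect_true(fit_s0$singular)
  expect_equal(fit_s0$var_random, 0, tolerance = 1e-10)
})

test_that("with no random variance the fixed effect equals the OLS group contrast", {
  set.seed(55)
  n <- 400
  dat <- data.frame(
    dog_key = rep(sprintf("d%03d", 1:40), each = 10),
    grp = rep(c("ctl", "trt"), each = n / 2),
    active_minutes = exp(rnorm(n, rep(c(3.5, 3.8), each = n / 2), 0.3)))
  spec <- model_spec(fixed = "grp", group = "dog_key", age_var = NULL)
  fit <- fit_lmm(dat, spec)
  ols <- coef(lm(log(active_minutes) ~ grp, dat))
  expect_equal(fit$coefficients$estimate[2], unname(ols[2]), tolerance = 1e-6)
  # and it equals the difference of group log-means in the balanced design
  gm <- tapply(log(dat$active_minutes), dat$grp, mean)
  expect_equal(fit$coefficients$estimate[2], unname(gm["trt"] - gm["ctl"]),
               tolerance = 1e-6)
})

test_that("model specification is validated", {
  expect_error(model_spec(fixed = "dog_key", group = "dog_key"),
               "grouping variable")
  expect_error(model_spec(fixed = "a", interactions = list(c("a", "b"))),
               "declared fixed effects")
  out <- simulate_analysis_frame(seed = 56, n_dogs = 30,
                                 records_per_dog_mean = 10)
  spec <- full_model_spec()
  expect_error(select_interactions(out$frame, spec,
                                   list(c("breed_size", "bogus"))),
               "absent main effect")
  one_dog <- out$frame[out$frame$dog_key == out$frame$dog_key[1L], ]
  expect_error(fit_lmm(one_dog, spec), "two grouping levels")
  neg <- out$frame
  neg$active_minutes[1] <- 0
  expect_error(fit_lmm(neg, spec), "strictly positive")
})

test_that("an empty candidate list leaves the specification unchanged", {
  out <- simulate_analysis_frame(seed = 57, n_dogs = 60,
                                 records_per_dog_mean = 15)
  spec <- full_model_spec(interactions = list())
  sel <- select_interactions(out$frame, spec, list())
  expect_identical(sel$interactions, list())
  expect_identical(sel$fixed, spec$fixed)
})

test_that("aggregation means the intervals and counts zero-covering fractions", {
  est <- matrix(c(0, 1.25, 2), 3, 1, dimnames = list(NULL, "b"))
  lo <- matrix(c(-1, 0.5, 1), 3, 1, dimnames = list(NULL, "b"))
  hi <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "b"))
  agg <- aggregate_repetitions(est, lo, hi)
  expect_equal(agg$p_value, 1 / 3)
  expect_equal(agg$estimate, mean(c(0, 1.25, 2)))
  expect_equal(agg$ci_lower, mean(lo))
  expect_equal(agg$ci_upper, mean(hi))
})

test_that("a single repetition reproduces the single fit with a 0/1 p-value", {
  out <- simulate_analysis_frame(seed = 58, n_dogs = 80,
                                 records_per_dog_mean = 20)
  spec <- full_model_spec(interactions = list())
  agg <- resampled_inference(out$frame, spec, K = 1e6, R = 1, seed = 4)
  # K larger than any dog's record count: the one repetition is the full fit
  fit <- fit_lmm(out$frame, spec)
  expect_equal(agg$terms$estimate, fit$coefficients$estimate, tolerance = 1e-8)
  expect_true(all(agg$terms$p_value %in% c(0, 1)))
  # aggregated estimates lie within the per-repetition range by construction
  agg2 <- resampled_inference(out$frame, spec, K = 10, R = 5, seed = 5)
  expect_true(all(agg2$terms$estimate >= apply(agg2$estimates, 2, min) - 1e-12))
  expect_true(all(agg2$terms$estimate <= apply(agg2$estimates, 2, max) + 1e-12))
  # reproducibility under the seed
  agg3 <- resampled_inference(out$frame, spec, K = 10, R = 5, seed = 5)
  expect_identical(agg2$terms, agg3$terms)
})

test_that("marginal means back-transform the linear predictor exactly", {
  out <- simulate_analysis_frame(seed = 59, n_dogs = 100,
                                 records_per_dog_mean = 25)
  spec <- full_model_spec(interactions = list())
  fit <- fit_lmm(out$frame, spec)
  mm <- estimate_marginal_means(fit, out$frame, "day_type")
  expect_identical(mm$level, c("weekday", "weekend"))
  expect_true(all(mm$response > 0))
  # round-trip identity with the bias correction off
  expect_equal(log(mm$response), mm$linear_predictor, tolerance = 1e-12)
  # two-level factor: ratio of marginal means equals exp(coefficient)
  b <- with(fit$coefficients, estimate[term == "day_typeweekend"])
  expect_equal(mm$response[2] / mm$response[1], exp(b), tolerance = 1e-10)
  # bias correction shifts every prediction by one multiplicative constant
  mm_bc <- estimate_marginal_means(fit, out$frame, "day_type",
                                   bias_correct = TRUE)
  expect_equal(mm_bc$response / mm$response,
               rep(exp((fit$var_random + fit$var_residual) / 2), 2),
               tolerance = 1e-10)
  expect_error(estimate_marginal_means(fit, out$frame, "day_type",
                                       grid = c("weekday", "midweek")),
               "absent from model")
  expect_error(estimate_marginal_means(fit, out$frame, "bogus"), "not in the model")
  # constant model: every level predicts exp(intercept)
  set.seed(60)
  flat <- data.frame(dog_key = rep(sprintf("d%02d", 1:20), each = 5),
                     grp = sample(c("a", "b"), 100, TRUE),
                     active_minutes = exp(3 + rnorm(100, 0, 1e-6)))
  sfit <- fit_lmm(flat, model_spec(fixed = "grp", group = "dog_key",
                                   age_var = NULL))
  smm <- estimate_marginal_means(sfit, flat, "grp")
  expect_equal(smm$response, rep(exp(3), 2), tolerance = 1e-3)
})

test_that("marginal means from aggregated inference track the mean coefficients", {
  out <- simulate_analysis_frame(seed = 61, n_dogs = 100,
                                 records_per_dog_mean = 30)
  spec <- full_model_spec(interactions = list())
  agg <- resampled_inference(out$frame, spec, K = 15, R = 8, seed = 6)
  mm <- estimate_marginal_means(agg, out$frame, "sex")
  b <- with(agg$terms, estimate[term == "sexfemale"])
  expect_equal(mm$response[2] / mm$response[1], exp(b), tolerance = 1e-10)
  expect_true(all(mm$ci_lower <= mm$response & mm$response <= mm$ci_upper))
})

test_that("grouped k-fold keeps dogs together and reports fold spread", {
  out <- simulate_analysis_frame(seed = 62, n_dogs = 120,
                                 records_per_dog_mean = 30)
  spec <- full_model_spec(interactions = list())
  kf <- grouped_kfold_consistency(out$frame, spec, k = 3, seed = 7)
  expect_identical(nrow(kf$folds), 3L)
  expect_false(kf$degenerate)
  expect_true(is.finite(kf$r2_sd))
  expect_error(grouped_kfold_consistency(out$frame, spec, k = 1000),
               "fewer dogs")
  # k = 1 degenerates to a single fit with undefined spread
  kf1 <- grouped_kfold_consistency(out$frame, spec, k = 1, seed = 7)
  expect_true(kf1$degenerate)
  expect_true(is.na(kf1$r2_sd))
})

test_that("duplicated dogs across folds give identical per-fold coefficients", {
  set.seed(63)
  base <- simulate_analysis_frame(seed = 63, n_dogs = 40,
                                  records_per_dog_mean = 25)$frame
  # three exact copies of the cohort under distinct dog keys
  copies <- lapply(1:3, function(i) {
    d <- base
    d$dog_key <- paste0(d$dog_key, "_copy", i)
    d
  })
  dat <- do.call(rbind, copies)
  spec <- model_spec(fixed = c("dog_age", "sex", "day_type"),
                     group = "dog_key",
                     reference_levels = c(sex = "male", day_type = "weekday"))
  # folds built from the copy label: every fold holds the same cohort
  fold_map <- stats::setNames(rep(1:3, each = length(unique(base$dog_key))),
                              unique(dat$dog_key))
  kf <- grouped_kfold_consistency(dat, spec, folds = fold_map)
  expect_lt(max(kf$coef_sd), 1e-6)
})
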