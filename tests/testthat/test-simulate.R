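test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_dogs = 0), "at least 1")
  expect_error(sim_config(tau2 = -0.1), "non-negative")
  expect_error(sim_config(anomaly_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(end_date = as.Date("2020-01-01")), "follow")
  expect_error(simulate_visits(data.frame(), sim_config()), "empty")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_dogs = 40, records_per_dog_mean = 15, seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$dogs, s2$dogs)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$activity, s2$activity)
  expect_identical(s1$truth$u, s2$truth$u)
})

test_that("unlinkable-dog and anomalous-record fractions match their probabilities", {
  cfg <- sim_config(n_dogs = 1000, records_per_dog_mean = 10,
                    unlinkable_prob = 0.1, anomaly_prob = 0.2, seed = 22)
  co <- simulate_cohort(cfg)
  n_pert <- sum(co$dogs$unlinkable)
  expect_lt(abs(n_pert - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # perturbed dogs differ on the EHR side key; others are identical
  pert <- co$dogs[co$dogs$unlinkable, ]
  clean <- co$dogs[!co$dogs$unlinkable, ]
  expect_true(all(pert$ehr_name != pert$name |
                    pert$ehr_birth_date != pert$birth_date))
  expect_identical(clean$ehr_name, clean$name)
  expect_identical(clean$ehr_birth_date, clean$birth_date)

  act <- simulate_activity(co$dogs, co$truth, cfg)
  frac_out <- mean(act$active_minutes < 10 | act$active_minutes > 600)
  p_anom <- cfg$anomaly_prob
  # anomalies are all out of range; genuine records can stray outside too,
  # so the observed fraction sits at or above the anomaly rate
  expect_gte(frac_out + 2e-3, p_anom - 3 * sqrt(p_anom * (1 - p_anom) / nrow(act)))
  expect_lt(abs(mean(act$anomaly) - p_anom),
            3 * sqrt(p_anom * (1 - p_anom) / nrow(act)))
  expect_true(all(act$active_minutes[act$anomaly] < 10 |
                    act$active_minutes[act$anomaly] > 600))
})

test_that("breed-size categories follow the configured frequencies", {
  cfg <- sim_config(n_dogs = 1200, seed = 23)
  co <- simulate_cohort(cfg)
  # equal-weight draw: override by resampling with uniform probabilities
  set.seed(23)
  draw <- sample(c("toy", "small", "medium_small", "medium_large", "large",
                   "giant"), 1200, replace = TRUE)
  gof <- chisq.test(table(factor(draw)))
  expect_gt(gof$p.value, 0.01)
  # and the default unequal frequencies put medium-large first
  expect_identical(names(which.max(table(co$dogs$breed_size))),
                   "medium_large")
})

test_that("visit counts, illness degenerate case and weight inflation behave", {
  cfg <- sim_config(n_dogs = 100, visit_rate = 3, seed = 24,
                    start_date = as.Date("2021-01-01"),
                    end_date = as.Date("2022-12-31"))
  co <- simulate_cohort(cfg)
  visits <- simulate_visits(co$dogs, cfg)
  years <- as.numeric(cfg$end_date - cfg$start_date + 180) / 365.25
  rate <- nrow(visits) / (100 * years)
  expect_lt(abs(rate - 3), 3 * sqrt(3 / (100 * years)))

  cfg0 <- sim_config(n_dogs = 60, chronic_prob = 0, injury_prob = 0, seed = 25)
  co0 <- simulate_cohort(cfg0)
  v0 <- simulate_visits(co0$dogs, cfg0)
  cls <- classify_visit_health(v0$diagnoses, v0$visit_reason)
  expect_false(any(cls$health_status == "unhealthy"))
  expect_false(any(cls$injury))

  # an obese recording inflates the ideal weight by 1/0.6 in expectation
  cfg5 <- sim_config(n_dogs = 400, overweight_prob = 1, seed = 26)
  co5 <- simulate_cohort(cfg5)
  v5 <- simulate_visits(co5$dogs, cfg5)
  v5$ideal <- co5$dogs$ideal_weight_kg[match(v5$dog_key, co5$dogs$ehr_key)]
  obese <- v5[v5$bcs5 == 5L, ]
  expect_gt(nrow(obese), 200)
  expect_lt(abs(mean(obese$weight_kg / obese$ideal) - 1 / 0.6), 0.02)
  # recorded 9-point scores translate back to the drawn 5-point score
  on9 <- v5[v5$bcs_scale == 9L, ]
  expect_identical(map_bcs9_to_5(on9$bcs_recorded), on9$bcs5)
})

test_that("noise-free activity equals the exponential linear predictor", {
  cfg <- sim_config(n_dogs = 25, records_per_dog_mean = 8, tau2 = 0,
                    sigma2 = 0, anomaly_prob = 0, seed = 27)
  co <- simulate_cohort(cfg)
  act <- simulate_activity(co$dogs, co$truth, cfg)
  af <- activity_analysis_frame(co$dogs, act)
  # independent reconstruction of the linear predictor from the preset
  # effect dictionaries, term by term
  ef <- cfg$effects; ia <- cfg$interactions
  lp <- cfg$intercept +
    (cfg$beta_age + ia$size_age[af$breed_size]) * af$dog_age^-2 +
    ef$breed_size[af$breed_size] + ef$sex[af$sex] +
    ef$neuter_status[af$neuter_status] + ef$weight_status[af$weight_status] +
    ef$owner_age[af$owner_age] + ef$location_type[af$location_type] +
    ef$climate[af$climate] + ef$latitude * af$latitude +
    ef$season[af$season] + ef$day_type[af$day_type]
  cs <- ia$climate_season[paste(af$season, af$climate, sep = ":")]
  od <- ifelse(af$day_type == "weekend", ia$owner_day[af$owner_age], 0)
  lp <- lp + ifelse(is.na(cs), 0, cs) + ifelse(is.na(od), 0, od)
  expect_equal(af$active_minutes, round(exp(unname(lp)), 1), tolerance = 1e-8)
})

test_that("a preset weekend effect reappears as the weekend/weekday ratio", {
  ef <- default_effect_presets()
  for (nm in setdiff(names(ef), "day_type")) {
    ef[[nm]] <- ef[[nm]] * 0
  }
  ef$day_type <- c(weekday = 0, weekend = log(44.7 / 41.3))
  ia <- default_interaction_presets()
  for (nm in names(ia)) ia[[nm]] <- ia[[nm]] * 0
  cfg <- sim_config(n_dogs = 300, records_per_dog_mean = 60, beta_age = 0,
                    effects = ef, interactions = ia, anomaly_prob = 0,
                    seed = 28)
  co <- simulate_cohort(cfg)
  act <- simulate_activity(co$dogs, co$truth, cfg)
  af <- activity_analysis_frame(co$dogs, act)
  gm <- tapply(log(af$active_minutes), af$day_type, mean)
  expect_lt(abs((gm[["weekend"]] - gm[["weekday"]]) - log(44.7 / 41.3)),
            0.02)
})

test_that("between-dog variance share matches tau2 / (tau2 + sigma2)", {
  ef <- default_effect_presets()
  for (nm in names(ef)) ef[[nm]] <- ef[[nm]] * 0
  ia <- default_interaction_presets()
  for (nm in names(ia)) ia[[nm]] <- ia[[nm]] * 0
  shares <- vapply(1:3, function(s) {
    cfg <- sim_config(n_dogs = 500, records_per_dog_mean = 100, beta_age = 0,
                      effects = ef, interactions = ia, anomaly_prob = 0,
                      tau2 = 0.2, sigma2 = 0.2, seed = 28 + s)
    co <- simulate_cohort(cfg)
    act <- simulate_activity(co$dogs, co$truth, cfg)
    af <- activity_analysis_frame(co$dogs, act)
    y <- log(af$active_minutes)
    ms <- summary(stats::aov(y ~ factor(af$dog_key)))[[1]]$`Mean Sq`
    tau2_hat <- (ms[1] - ms[2]) / mean(table(af$dog_key))
    tau2_hat / (tau2_hat + ms[2])
  }, numeric(1L))
  expect_lt(abs(mean(shares) - 0.5), 0.02)
})

test_that("zeroing a coefficient removes the marginal association", {
  ef <- default_effect_presets()
  ef$sex <- c(male = 0, female = 0)
  zs <- numeric(0)
  for (s in 1:8) {
    cfg <- sim_config(n_dogs = 200, records_per_dog_mean = 20, effects = ef,
                      anomaly_prob = 0, seed = 300 + s)
    co <- simulate_cohort(cfg)
    act <- simulate_activity(co$dogs, co$truth, cfg)
    af <- activity_analysis_frame(co$dogs, act)
    dog_mean <- tapply(log(af$active_minutes), af$dog_key, mean)
    dog_sex <- tapply(af$sex, af$dog_key, `[`, 1L)
    tt <- t.test(dog_mean[dog_sex == "male"], dog_mean[dog_sex == "female"])
    zs <- c(zs, unname(tt$statistic))
  }
  # mean |t| over seeds stays small when the generating effect is zero
  expect_lt(mean(abs(zs)), qnorm(1 - 0.01 / 2))
})

test_that("the two demographic sources share keys except for perturbed dogs", {
  cfg <- sim_config(n_dogs = 150, unlinkable_prob = 0.2, seed = 31)
  co <- simulate_cohort(cfg)
  a <- activity_source(co$dogs)
  e <- ehr_source(co$dogs)
  expect_identical(names(a), names(e))
  same <- a$name == e$name & format(a$birth_date, "%Y-%m") ==
    format(e$birth_date, "%Y-%m")
  expect_identical(unname(same), !co$dogs$unlinkable)
})
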