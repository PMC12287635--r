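mk_demo <- function(key, household = "hh1", sex = "male", name = "Rex",
                    birth = "2018-05-15") {
  data.frame(dog_key = key, household = household, species = "dog",
             sex = sex, name = name, birth_date = as.Date(birth),
             stringsAsFactors = FALSE)
}

test_that("dogs match on the full household/species/sex/name/birth-month key", {
  m <- match_dogs(mk_demo("a1"), mk_demo("e1"))
  expect_identical(m$activity_key, "a1")
  expect_identical(m$ehr_key, "e1")

  # name normalization: case, whitespace, punctuation
  m2 <- match_dogs(mk_demo("a1", name = " Rex! "), mk_demo("e1", name = "rex"))
  expect_identical(nrow(m2), 1L)

  # same day, same month: still a match (month-year precision)
  m3 <- match_dogs(mk_demo("a1", birth = "2018-05-01"),
                   mk_demo("e1", birth = "2018-05-28"))
  expect_identical(nrow(m3), 1L)

  # differing birth month breaks the key
  m4 <- match_dogs(mk_demo("a1", birth = "2018-05-15"),
                   mk_demo("e1", birth = "2018-06-15"))
  expect_identical(nrow(m4), 0L)
  expect_identical(attr(m4, "unmatched_activity"), "a1")

  expect_error(match_dogs(mk_demo("a1")[, -2], mk_demo("e1")), "key field")
})

test_that("same-name littermates are ambiguous and excluded from both sides", {
  ehr <- rbind(mk_demo("e1"), mk_demo("e2"))  # identical full keys
  m <- match_dogs(mk_demo("a1"), ehr)
  expect_identical(nrow(m), 0L)
  expect_true(all(c("e1", "e2") %in% attr(m, "ambiguous")))
  expect_true("a1" %in% attr(m, "ambiguous"))
})

test_that("activity records join the closest prior visit within one year", {
  visits <- data.frame(dog_key = "d1",
                       visit_date = as.Date(c("2022-05-01", "2022-06-05")),
                       weight_kg = c(10, 11))
  # D-30 and D+5 relative to the activity date: the prior visit wins
  act <- data.frame(dog_key = "d1", date = as.Date("2022-05-31"),
                    active_minutes = 50)
  out <- link_activity_to_visit(act, visits)
  expect_identical(out$visit_date, as.Date("2022-05-01"))

  # D-10 beats D-100
  visits2 <- data.frame(dog_key = "d1",
                        visit_date = as.Date(c("2022-02-20", "2022-05-21")),
                        weight_kg = c(9, 10))
  out2 <- link_activity_to_visit(act, visits2)
  expect_identical(out2$visit_date, as.Date("2022-05-21"))

  # only a visit 400 days earlier: row dropped
  visits3 <- data.frame(dog_key = "d1",
                        visit_date = as.Date("2022-05-31") - 400,
                        weight_kg = 9)
  out3 <- link_activity_to_visit(act, visits3)
  expect_identical(nrow(out3), 0L)
  # exactly 365 days earlier: kept
  visits4 <- data.frame(dog_key = "d1",
                        visit_date = as.Date("2022-05-31") - 365,
                        weight_kg = 9)
  expect_identical(nrow(link_activity_to_visit(act, visits4)), 1L)
  # same-day visit counts as prior
  visits5 <- data.frame(dog_key = "d1", visit_date = as.Date("2022-05-31"),
                        weight_kg = 9)
  out5 <- link_activity_to_visit(act, visits5)
  expect_identical(out5$days_since_visit, 0)
})

test_that("minute bounds are strict at 10 and 600", {
  base <- planted_filter_fixture()[1:9, ]  # dogA only, will survive
  probe <- base[1:4, ]
  probe$active_minutes <- c(9.5, 10, 600, 600.5)
  dat <- rbind(base, probe)
  out <- as.data.frame(apply_filters(dat))
  expect_identical(nrow(out), 9L + 2L)
  expect_true(all(c(10, 600) %in% out$active_minutes))
  expect_false(any(c(9.5, 600.5) %in% out$active_minutes))
})

test_that("the planted 20-row fixture survives exactly as hand-computed", {
  fx <- planted_filter_fixture()
  expect_identical(nrow(fx), 20L)
  out <- apply_filters(fx)
  dat <- as.data.frame(out)
  expect_identical(nrow(dat), 9L)
  expect_identical(unique(dat$dog_key), "dogA")
  prov <- provenance(out)
  expect_identical(prov$stage,
                   c("bounds_10_600", "activity_visit_ratio",
                     "adult_age_window", "min_records_per_dog"))
  expect_identical(prov$rows_in, c(20L, 19L, 17L, 16L))
  expect_identical(prov$rows_out, c(19L, 17L, 16L, 9L))
  expect_identical(prov$dogs_out, c(3L, 2L, 2L, 1L))
})

test_that("a dog below the five-to-one activity:visit ratio loses all rows", {
  rows <- do.call(rbind, lapply(seq_len(12), function(i) {
    data.frame(dog_key = "dogR", date = as.Date("2022-06-01") + i,
               active_minutes = 50,
               visit_date = as.Date(c("2022-01-01", "2022-03-01",
                                      "2022-05-01"))[1 + (i %% 3)],
               age_at_activity = 5, age_at_visit = 4.8)
  }))
  out <- as.data.frame(apply_filters(rows))  # 12 rows / 3 visits = ratio 4
  expect_identical(nrow(out), 0L)
})

test_that("the filter cascade is idempotent and its counts reconcile", {
  fx <- planted_filter_fixture()
  once <- apply_filters(fx)
  twice <- apply_filters(once)
  expect_identical(as.data.frame(twice)[names(fx)], as.data.frame(once)[names(fx)])
  p2 <- provenance(twice)
  expect_identical(p2$rows_in[5:8], p2$rows_out[5:8])  # second pass removes nothing
  p1 <- provenance(once)
  expect_identical(sum(p1$rows_in - p1$rows_out), 20L - 9L)
  expect_true(all(p1$rows_out <= p1$rows_in))
})

test_that("bounds-stage removal tracks the simulator's anomaly rate", {
  p <- 0.15
  cfg <- sim_config(n_dogs = 150, records_per_dog_mean = 60,
                    anomaly_prob = p, unlinkable_prob = 0, seed = 33)
  co <- simulate_cohort(cfg)
  act <- simulate_activity(co$dogs, co$truth, cfg)
  af <- activity_analysis_frame(co$dogs, act, drop_anomalies = FALSE)
  af$visit_date <- af$date - 30
  af$age_at_activity <- af$dog_age
  af$age_at_visit <- af$dog_age
  out <- apply_filters(af)
  prov <- provenance(out)
  bounds <- prov[prov$stage == "bounds_10_600", ]
  removed <- (bounds$rows_in - bounds$rows_out) / bounds$rows_in
  # genuine extreme draws add a little on top of the anomaly channel
  expect_lt(abs(removed - p), 3 * sqrt(p * (1 - p) / bounds$rows_in) + 0.02)
})

test_that("the healthy-visits subset is nested in all-visits and needs classification", {
  fx <- planted_filter_fixture()
  filt <- apply_filters(fx)
  expect_error(split_healthy(filt), "classification")
  dat <- as.data.frame(filt)
  dat$health_status <- factor(rep(c("healthy", "unhealthy", "other"),
                                  length.out = nrow(dat)),
                              levels = c("healthy", "unhealthy", "other"))
  dat$injury <- rep(c(FALSE, TRUE), length.out = nrow(dat))
  relinked <- caniact:::new_linked_dataset(dat, provenance(filt))
  out <- split_healthy(relinked)
  d <- as.data.frame(out)
  expect_true(all(d$in_healthy_visits <= d$in_all_visits))
  expect_true(all(d$health_status[d$in_healthy_visits] == "healthy"))
  expect_false(any(d$injury[d$in_healthy_visits]))

  # all-healthy case: subsets coincide
  dat2 <- dat
  dat2$health_status <- factor("healthy",
                               levels = c("healthy", "unhealthy", "other"))
  dat2$injury <- FALSE
  out2 <- as.data.frame(split_healthy(
    caniact:::new_linked_dataset(dat2, provenance(filt))))
  expect_identical(out2$in_healthy_visits, out2$in_all_visits)

  # unclassified visit is an error naming the offender
  dat3 <- dat
  dat3$health_status[2] <- NA
  expect_error(split_healthy(caniact:::new_linked_dataset(dat3, NULL)),
               "unclassified")
})
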