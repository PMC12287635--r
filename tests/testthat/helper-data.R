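# Shared fixtures built in code.

# the full analysis model over every generated covariate
full_model_spec <- function(interactions = list(c("breed_size", "dog_age"),
                                                c("season", "climate"),
                                                c("owner_age", "day_type"))) {
  model_spec(
    outcome = "active_minutes",
    fixed = c("dog_age", "breed_size", "weight_status", "sex",
              "neuter_status", "owner_age", "location_type", "climate",
              "latitude", "season", "day_type"),
    interactions = interactions,
    group = "dog_key",
    reference_levels = c(breed_size = "medium_large", sex = "male",
                         neuter_status = "intact", weight_status = "ideal",
                         owner_age = "18-30", location_type = "rural",
                         climate = "cold", season = "spring",
                         day_type = "weekday"))
}

# simulate a cohort and return the recovery-ready analysis frame plus truth
simulate_analysis_frame <- function(seed, n_dogs = 150,
                                    records_per_dog_mean = 40, ...) {
  cfg <- sim_config(n_dogs = n_dogs,
                    records_per_dog_mean = records_per_dog_mean,
                    anomaly_prob = 0, unlinkable_prob = 0, seed = seed, ...)
  co <- simulate_cohort(cfg)
  act <- simulate_activity(co$dogs, co$truth, cfg)
  list(frame = activity_analysis_frame(co$dogs, act), truth = co$truth,
       dogs = co$dogs, config = cfg)
}

# 20-row planted filter fixture: dogA is fully clean (9 rows); dogB carries
# one out-of-bounds row and one over-age row, leaving exactly 7 rows, which
# the >7-records rule then removes; dogC has 2 rows against 1 visit (ratio
# 2 < 5). Hand-computed survivors: dogA's 9 rows only.
planted_filter_fixture <- function() {
  row <- function(dog, minutes, age_act = 5, age_vis = 4.9,
                  visit = "2022-01-01") {
    data.frame(dog_key = dog, date = as.Date("2022-06-01"),
               active_minutes = minutes, visit_date = as.Date(visit),
               age_at_activity = age_act, age_at_visit = age_vis,
               stringsAsFactors = FALSE)
  }
  rbind(
    do.call(rbind, lapply(30 + seq_len(9), function(m) row("dogA", m))),
    row("dogB", 9.5),                       # bounds violation
    row("dogB", 50, age_act = 13, age_vis = 12.9),  # age violation
    do.call(rbind, lapply(40 + seq_len(7), function(m) row("dogB", m))),
    row("dogC", 55), row("dogC", 56)        # ratio 2:1 violation
  )
}
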