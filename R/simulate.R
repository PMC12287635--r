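#' Default log-scale effect presets
#'
#' Named effect sizes, on the log active-minutes scale, used by
#' [sim_config()]. Signs and magnitudes follow the broad pattern reported for
#' real dog-activity cohorts (activity falls with age, rises with breed size
#' up to large breeds, is higher in males, on weekends, in spring and in
#' hot-dry or marine climates) but are presets for a synthetic world, not
#' reproductions of any fitted model. Reference levels carry effect 0.
#'
#' @return Named list of named numeric vectors (plus scalar `latitude`,
#'   per degree).
#' @export
default_effect_presets <- function() {
  list(
    breed_size = c(toy = -0.24, small = -0.20, medium_small = -0.05,
                   medium_large = 0, large = 0.05, giant = -0.03),
    sex = c(male = 0, female = -0.045),
    neuter_status = c(intact = 0, neutered = -0.017),
    weight_status = c(ideal = 0, overweight = -0.002),
    owner_age = c("18-30" = 0, "30-45" = -0.031, "45-60" = -0.027,
                  "60+" = -0.029),
    location_type = c(rural = 0, urban = -0.027),
    climate = c(cold = 0, hot_humid = -0.006, hot_dry = 0.060,
                marine = 0.061),
    season = c(spring = 0, summer = -0.009, autumn = -0.012,
               winter = -0.082),
    day_type = c(weekday = 0, weekend = 0.114),
    latitude = 0.005
  )
}

#' Default interaction presets
#'
#' `size_age` multiplies the inverse-square-age predictor per breed size
#' (larger breeds get a larger positive coefficient, i.e. a steeper age
#' decline). `climate_season` entries are named `"season:climate"`.
#' `owner_day` entries apply on weekend days, named by owner age band.
#'
#' @return Named list.
#' @export
default_interaction_presets <- function() {
  list(
    size_age = c(toy = -0.6, small = -0.3, medium_small = -0.1,
                 medium_large = 0, large = 0.4, giant = 0.8),
    climate_season = c("summer:hot_humid" = -0.039, "summer:hot_dry" = -0.047,
                       "summer:marine" = 0.025, "autumn:hot_humid" = -0.004,
                       "autumn:hot_dry" = -0.012, "autumn:marine" = -0.010,
                       "winter:hot_humid" = 0.043, "winter:hot_dry" = 0.059,
                       "winter:marine" = 0.010),
    owner_day = c("30-45" = -0.018, "45-60" = -0.030, "60+" = -0.064)
  )
}

sim_levels <- list(
  breed_size = c("toy", "small", "medium_small", "medium_large", "large",
                 "giant"),
  sex = c("male", "female"),
  neuter_status = c("intact", "neutered"),
  weight_status = c("ideal", "overweight"),
  owner_age = c("18-30", "30-45", "45-60", "60+"),
  location_type = c("rural", "urban"),
  climate = c("cold", "hot_humid", "hot_dry", "marine"),
  season = c("spring", "summer", "autumn", "winter"),
  day_type = c("weekday", "weekend")
)

# ideal-weight bands (kg) per breed-size category; draws keep a 2% margin
# from the classification boundaries so body-condition noise does not flip
# the derived category.
size_weight_bands <- list(
  toy = c(3.0, 6.37), small = c(6.63, 8.82), medium_small = c(9.18, 14.7),
  medium_large = c(15.3, 29.4), large = c(30.6, 39.2), giant = c(40.8, 60)
)

#' Simulation configuration
#'
#' Defines the synthetic two-source study: cohort composition, visit and
#' activity record generation, the log-scale linear data-generating process
#' with a per-dog random intercept, and the measurement artefacts
#' (out-of-range daily records, unlinkable dogs) that the linkage and filter
#' stages must handle.
#'
#' @param n_dogs Number of dogs (>= 1).
#' @param start_date,end_date Study window for activity records.
#' @param records_per_dog_mean,records_per_dog_dispersion Negative-binomial
#'   mean and size for the number of activity records per dog.
#' @param visit_rate Expected veterinary visits per dog-year.
#' @param intercept Log active minutes at all reference levels.
#' @param beta_age Coefficient on `age^-2` (fractional years).
#' @param effects Named list of log-scale effects, as
#'   [default_effect_presets()].
#' @param interactions Named list, as [default_interaction_presets()].
#' @param tau2 Variance of the per-dog random intercept (log scale).
#' @param sigma2 Residual variance (log scale).
#' @param anomaly_prob Probability that a daily record is replaced by an
#'   out-of-range value (< 10 or > 600 minutes).
#' @param unlinkable_prob Probability that a dog's EHR-side match key is
#'   perturbed so the two sources cannot be linked.
#' @param overweight_prob Probability a dog is in overweight condition.
#' @param chronic_prob Per-visit probability of a chronic-illness diagnosis
#'   code.
#' @param injury_prob Per-visit probability of an injury code.
#' @param bcs9_prob Probability a visit records body condition on the 9-point
#'   scale.
#' @param age_mean,age_sd Age (years) distribution at the window start,
#'   truncated to `age_range`. The floor keeps ages (and hence the
#'   inverse-square age predictor) well defined for every record and visit
#'   date while leaving dogs outside the 1.5-12-year inclusion window for
#'   the age filter to remove.
#' @param age_range Admissible ages at the window start.
#' @param seed Integer seed; each generation stage derives its own stream
#'   from it. `NULL` leaves the RNG state untouched.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_dogs = 500,
                       start_date = as.Date("2021-01-01"),
                       end_date = as.Date("2022-12-31"),
                       records_per_dog_mean = 100,
                       records_per_dog_dispersion = 2,
                       visit_rate = 3,
                       intercept = log(45),
                       beta_age = 2.4,
                       effects = default_effect_presets(),
                       interactions = default_interaction_presets(),
                       tau2 = 0.2,
                       sigma2 = 0.2,
                       anomaly_prob = 0.05,
                       unlinkable_prob = 0.05,
                       overweight_prob = 0.34,
                       chronic_prob = 0.15,
                       injury_prob = 0.05,
                       bcs9_prob = 0.3,
                       age_mean = 6,
                       age_sd = 2.75,
                       age_range = c(1, 13),
                       seed = NULL) {
  if (!is.numeric(n_dogs) || n_dogs < 1) {
    stop("n_dogs must be at least 1", call. = FALSE)
  }
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must follow start_date", call. = FALSE)
  probs <- c(anomaly_prob, unlinkable_prob, overweight_prob, chronic_prob,
             injury_prob, bcs9_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (tau2 < 0 || sigma2 < 0) stop("variances must be non-negative", call. = FALSE)
  if (visit_rate <= 0 || records_per_dog_mean <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  cfg <- list(n_dogs = as.integer(n_dogs), start_date = start_date,
              end_date = end_date,
              records_per_dog_mean = records_per_dog_mean,
              records_per_dog_dispersion = records_per_dog_dispersion,
              visit_rate = visit_rate, intercept = intercept,
              beta_age = beta_age, effects = effects,
              interactions = interactions, tau2 = tau2, sigma2 = sigma2,
              anomaly_prob = anomaly_prob, unlinkable_prob = unlinkable_prob,
              overweight_prob = overweight_prob, chronic_prob = chronic_prob,
              injury_prob = injury_prob, bcs9_prob = bcs9_prob,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
  invisible(NULL)
}

dog_names_pool <- c(
  "bella", "charlie", "luna", "max", "daisy", "cooper", "lucy", "milo",
  "bailey", "rocky", "sadie", "buddy", "molly", "tucker", "coco", "bear",
  "stella", "duke", "maggie", "oliver", "penny", "zeus", "ruby", "jack",
  "rosie", "toby", "lola", "finn", "gracie", "murphy", "zoe", "leo",
  "abby", "oscar", "piper", "henry", "nala", "sam", "willow", "gus"
)

#' Simulate the dog cohort and its ground truth
#'
#' Draws the dog-level attributes (breed size, sex, neuter status, birth
#' date, household, name, owner age band, location attributes, overweight
#' condition), the per-dog random intercepts, and the two-source match keys.
#' A fraction `unlinkable_prob` of dogs get a perturbed EHR-side key (name or
#' birth month) and cannot be matched across sources.
#'
#' @param config A [sim_config()].
#' @return List with `dogs` (data frame, one row per dog, carrying both the
#'   activity-source key `act_key` and the EHR-source key `ehr_key`) and
#'   `truth` (class `simulation_truth`: the generating coefficients, variance
#'   components and per-dog random intercepts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 0L)
  n <- config$n_dogs
  age_start <- stats::rnorm(n, config$age_mean, config$age_sd)
  age_start <- pmin(pmax(age_start, config$age_range[1L]),
                    config$age_range[2L])
  birth_date <- config$start_date - round(age_start * 365.25)
  breed_size <- sample(sim_levels$breed_size, n, replace = TRUE,
                       prob = c(0.178, 0.116, 0.132, 0.372, 0.162, 0.040))
  ideal_weight <- vapply(breed_size, function(b) {
    stats::runif(1L, size_weight_bands[[b]][1L], size_weight_bands[[b]][2L])
  }, numeric(1L))
  n_house <- max(1L, ceiling(n / 1.05))
  household <- sprintf("hh%05d", sample(rep_len(seq_len(n_house), n)))
  dogs <- data.frame(
    dog_id = sprintf("dog%05d", seq_len(n)),
    act_key = sprintf("a%05d", seq_len(n)),
    ehr_key = sprintf("e%05d", seq_len(n)),
    household = household,
    species = "dog",
    name = sample(dog_names_pool, n, replace = TRUE),
    sex = sample(sim_levels$sex, n, replace = TRUE, prob = c(0.526, 0.474)),
    birth_date = birth_date,
    neuter_status = sample(sim_levels$neuter_status, n, replace = TRUE,
                           prob = c(0.06, 0.94)),
    breed_size = breed_size,
    ideal_weight_kg = ideal_weight,
    overweight = stats::runif(n) < config$overweight_prob,
    owner_age = sample(sim_levels$owner_age, n, replace = TRUE,
                       prob = c(0.15, 0.35, 0.30, 0.20)),
    location_type = sample(sim_levels$location_type, n, replace = TRUE,
                           prob = c(0.3, 0.7)),
    climate = sample(sim_levels$climate, n, replace = TRUE,
                     prob = c(0.35, 0.35, 0.15, 0.15)),
    latitude = round(stats::runif(n, 25, 48), 2),
    stringsAsFactors = FALSE
  )
  dogs$unlinkable <- stats::runif(n) < config$unlinkable_prob
  dogs$ehr_name <- dogs$name
  dogs$ehr_birth_date <- dogs$birth_date
  if (any(dogs$unlinkable)) {
    idx <- which(dogs$unlinkable)
    mode_name <- stats::runif(length(idx)) < 0.5
    dogs$ehr_name[idx[mode_name]] <-
      paste0(dogs$name[idx[mode_name]], "y")       # misspelled name
    dogs$ehr_birth_date[idx[!mode_name]] <-
      dogs$birth_date[idx[!mode_name]] + 40L       # birth month off by one
  }
  u <- stats::rnorm(n, 0, sqrt(config$tau2))
  truth <- structure(
    list(intercept = config$intercept, beta_age = config$beta_age,
         effects = config$effects, interactions = config$interactions,
         tau2 = config$tau2, sigma2 = config$sigma2,
         u = stats::setNames(u, dogs$dog_id),
         seed = config$seed, config = config),
    class = "simulation_truth"
  )
  list(dogs = dogs, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d dogs, tau2 = %.3f, sigma2 = %.3f\n",
              length(x$u), x$tau2, x$sigma2))
  invisible(x)
}

#' Simulate veterinary visit records
#'
#' Visit counts are Poisson around `visit_rate` visits per dog-year over the
#' study window (visits may precede the window by up to 180 days so that
#' early activity records have a prior visit). Recorded weight is the dog's
#' ideal weight inflated by the visit's body condition score (the inverse of
#' the 0.8 / 0.6 correction multipliers) times small measurement noise.
#' Diagnoses and visit reasons carry chronic-illness and injury codes with
#' the configured probabilities.
#'
#' @param dogs Dog table from [simulate_cohort()].
#' @param config A [sim_config()].
#' @return Data frame of visit records keyed by `ehr_key` (column `dog_key`).
#' @export
simulate_visits <- function(dogs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(dogs) || nrow(dogs) == 0L) {
    stop("dogs table is empty", call. = FALSE)
  }
  stage_seed(config, 1L)
  years <- as.numeric(config$end_date - config$start_date + 180) / 365.25
  n_visits <- stats::rpois(nrow(dogs), config$visit_rate * years)
  n_visits <- pmax(n_visits, 1L)  # every dog is registered at least once
  idx <- rep(seq_len(nrow(dogs)), n_visits)
  m <- length(idx)
  visit_date <- config$start_date - 180 +
    round(stats::runif(m) * as.numeric(config$end_date -
                                         (config$start_date - 180)))
  overweight <- dogs$overweight[idx]
  bcs5 <- integer(m)
  bcs5[overweight] <- sample(4:5, sum(overweight), replace = TRUE,
                             prob = c(0.75, 0.25))
  bcs5[!overweight] <- sample(1:3, sum(!overweight), replace = TRUE,
                              prob = c(0.05, 0.15, 0.80))
  inflate <- c(1, 1, 1, 1 / 0.8, 1 / 0.6)
  weight_kg <- dogs$ideal_weight_kg[idx] * inflate[bcs5] *
    exp(stats::rnorm(m, 0, 0.03))
  on9 <- stats::runif(m) < config$bcs9_prob
  # two 9-point values per 5-point unit: b5 -> {2*b5 - 2, 2*b5 - 1}, b5 = 1 -> 1
  bcs_recorded <- bcs5
  bcs_recorded[on9] <- ifelse(bcs5[on9] == 1L, 1L,
                              2L * bcs5[on9] - sample(c(1L, 2L), sum(on9),
                                                      replace = TRUE))
  chronic <- stats::runif(m) < config$chronic_prob
  injury <- stats::runif(m) < config$injury_prob
  benign <- stats::runif(m) < 0.3
  rules <- health_rules()
  dx <- mapply(function(ch, inj, ben) {
    codes <- character()
    if (ch) codes <- c(codes, sample(rules$unhealthy_codes, 1L))
    if (inj) codes <- c(codes, sample(rules$injury_codes, 1L))
    if (ben) codes <- c(codes, sample(c("dental_calculus", "dermatitis",
                                        "otitis_externa", "healthy_pet"), 1L))
    paste(codes, collapse = ";")
  }, chronic, injury, benign)
  reason <- sample(c("vaccination", "preventive_care", "anthelmintic",
                     "grooming", "consultation", "dental_cleaning"),
                   m, replace = TRUE,
                   prob = c(0.35, 0.15, 0.10, 0.05, 0.25, 0.10))
  data.frame(
    dog_key = dogs$ehr_key[idx],
    visit_date = visit_date,
    weight_kg = round(weight_kg, 2),
    bcs_scale = ifelse(on9, 9L, 5L),
    bcs_recorded = bcs_recorded,
    bcs5 = bcs5,
    diagnoses = dx,
    visit_reason = reason,
    neutered_at_visit = dogs$neuter_status[idx] == "neutered",
    owner_age = dogs$owner_age[idx],
    location_type = dogs$location_type[idx],
    climate = dogs$climate[idx],
    latitude = dogs$latitude[idx],
    stringsAsFactors = FALSE
  )
}

# Log-scale linear predictor for activity records; `records` needs columns
# dog_id, age, breed_size, sex, neuter_status, weight_status, owner_age,
# location_type, climate, latitude, season, day_type.
truth_linear_predictor <- function(truth, records, include_random = TRUE) {
  ef <- truth$effects
  ia <- truth$interactions
  agei2 <- records$age^(-2)
  lp <- truth$intercept +
    (truth$beta_age + unname(ia$size_age[records$breed_size])) * agei2 +
    unname(ef$breed_size[records$breed_size]) +
    unname(ef$sex[records$sex]) +
    unname(ef$neuter_status[records$neuter_status]) +
    unname(ef$weight_status[records$weight_status]) +
    unname(ef$owner_age[records$owner_age]) +
    unname(ef$location_type[records$location_type]) +
    unname(ef$climate[records$climate]) +
    ef$latitude * records$latitude +
    unname(ef$season[records$season]) +
    unname(ef$day_type[records$day_type])
  cs <- ia$climate_season[paste(records$season, records$climate, sep = ":")]
  cs[is.na(cs)] <- 0
  od <- ifelse(records$day_type == "weekend",
               ia$owner_day[records$owner_age], 0)
  od[is.na(od)] <- 0
  lp <- lp + unname(cs) + unname(od)
  if (include_random) lp <- lp + unname(truth$u[records$dog_id])
  lp
}

#' Simulate daily activity records
#'
#' For dog *i* on date *j* the log active minutes are the linear predictor
#' (intercept, inverse-square age, breed size with its age interaction, sex,
#' neuter status, weight status, owner age, location, climate, latitude,
#' season, day type, the configured interactions) plus the dog's random
#' intercept and Gaussian residual noise; active minutes are the exponential.
#' With probability `anomaly_prob` a record is replaced by an out-of-range
#' value (below 10 or above 600 minutes), emulating device artefacts.
#'
#' @param dogs Dog table from [simulate_cohort()].
#' @param truth The matching `simulation_truth`.
#' @param config A [sim_config()].
#' @param visits Optional visit table (not used by the generating process;
#'   accepted so the three stages compose naturally).
#' @return Data frame with columns `dog_key` (activity-source key), `date`,
#'   `active_minutes`, plus an `anomaly` flag.
#' @export
simulate_activity <- function(dogs, truth, config, visits = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "simulation_truth"))
  if (!is.data.frame(dogs) || nrow(dogs) == 0L) {
    stop("dogs table is empty", call. = FALSE)
  }
  stage_seed(config, 2L)
  days <- seq(config$start_date, config$end_date, by = "day")
  n_rec <- stats::rnbinom(nrow(dogs), mu = config$records_per_dog_mean,
                          size = config$records_per_dog_dispersion)
  n_rec <- pmin(pmax(n_rec, 1L), length(days))
  idx <- rep(seq_len(nrow(dogs)), n_rec)
  date <- as.Date(unlist(lapply(n_rec, function(k)
    sort(sample(days, k))), use.names = FALSE), origin = "1970-01-01")
  cal <- assign_calendar_vars(date)
  records <- data.frame(
    dog_id = dogs$dog_id[idx],
    dog_key = dogs$act_key[idx],
    date = date,
    age = as.numeric(date - dogs$birth_date[idx]) / 365.25,
    breed_size = dogs$breed_size[idx],
    sex = dogs$sex[idx],
    neuter_status = dogs$neuter_status[idx],
    weight_status = ifelse(dogs$overweight[idx], "overweight", "ideal"),
    owner_age = dogs$owner_age[idx],
    location_type = dogs$location_type[idx],
    climate = dogs$climate[idx],
    latitude = dogs$latitude[idx],
    season = as.character(cal$season),
    day_type = as.character(cal$day_type),
    stringsAsFactors = FALSE
  )
  lp <- truth_linear_predictor(truth, records) +
    stats::rnorm(nrow(records), 0, sqrt(config$sigma2))
  minutes <- exp(lp)
  anomaly <- stats::runif(nrow(records)) < config$anomaly_prob
  if (any(anomaly)) {
    low <- stats::runif(sum(anomaly)) < 0.7
    out_of_range <- ifelse(low, stats::runif(sum(anomaly), 0, 9.5),
                           stats::runif(sum(anomaly), 601, 1000))
    minutes[anomaly] <- out_of_range
  }
  data.frame(dog_key = records$dog_key, date = records$date,
             active_minutes = round(minutes, 1), anomaly = anomaly,
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-source study
#'
#' Runs [simulate_cohort()], [simulate_visits()] and [simulate_activity()]
#' and assembles the two source tables that the linkage stage consumes.
#'
#' @param config A [sim_config()].
#' @return List with `dogs`, `truth`, `visits`, `activity`,
#'   `activity_dogs` (demographics as held by the activity source) and
#'   `ehr_dogs` (demographics as held by the EHR source, with perturbed keys
#'   for unlinkable dogs).
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  visits <- simulate_visits(cohort$dogs, config)
  activity <- simulate_activity(cohort$dogs, cohort$truth, config,
                                visits = visits)
  list(dogs = cohort$dogs, truth = cohort$truth, visits = visits,
       activity = activity,
       activity_dogs = activity_source(cohort$dogs),
       ehr_dogs = ehr_source(cohort$dogs))
}

#' Source-specific demographic tables
#'
#' The activity source holds each dog's true demographics under its activity
#' key; the EHR source holds the (possibly key-perturbed) demographics under
#' its EHR key. Both carry the full match key: household, species, sex, name
#' and date of birth.
#'
#' @param dogs Dog table from [simulate_cohort()].
#' @return Data frame with columns `dog_key`, `household`, `species`, `sex`,
#'   `name`, `birth_date`.
#' @export
activity_source <- function(dogs) {
  data.frame(dog_key = dogs$act_key, household = dogs$household,
             species = dogs$species, sex = dogs$sex, name = dogs$name,
             birth_date = dogs$birth_date, stringsAsFactors = FALSE)
}

#' @rdname activity_source
#' @export
ehr_source <- function(dogs) {
  data.frame(dog_key = dogs$ehr_key, household = dogs$household,
             species = dogs$species, sex = dogs$sex, name = dogs$ehr_name,
             birth_date = dogs$ehr_birth_date, stringsAsFactors = FALSE)
}

#' Per-record analysis frame directly from the cohort
#'
#' Joins the simulated activity records back to the cohort's true dog-level
#' attributes and the calendar covariates, bypassing linkage. This is the
#' frame used for parameter-recovery studies, where the question is whether
#' the inference machinery recovers the generating coefficients, not whether
#' linkage reconstructs the covariates.
#'
#' @param dogs Dog table from [simulate_cohort()].
#' @param activity Activity table from [simulate_activity()].
#' @param drop_anomalies Drop records flagged as out-of-range artefacts
#'   (default TRUE).
#' @return Data frame with the analysis columns (`dog_key`, `active_minutes`,
#'   `dog_age`, `breed_size`, `sex`, `neuter_status`, `weight_status`,
#'   `owner_age`, `location_type`, `climate`, `latitude`, `season`,
#'   `day_type`).
#' @export
activity_analysis_frame <- function(dogs, activity, drop_anomalies = TRUE) {
  act <- as.data.frame(activity)
  if (drop_anomalies && "anomaly" %in% names(act)) {
    act <- act[!act$anomaly, , drop = FALSE]
  }
  i <- match(act$dog_key, dogs$act_key)
  if (anyNA(i)) stop("activity rows with unknown dog_key", call. = FALSE)
  cal <- assign_calendar_vars(act$date)
  data.frame(
    dog_key = act$dog_key,
    date = act$date,
    active_minutes = act$active_minutes,
    dog_age = as.numeric(act$date - dogs$birth_date[i]) / 365.25,
    breed_size = dogs$breed_size[i],
    sex = dogs$sex[i],
    neuter_status = dogs$neuter_status[i],
    weight_status = ifelse(dogs$overweight[i], "overweight", "ideal"),
    owner_age = dogs$owner_age[i],
    location_type = dogs$location_type[i],
    climate = dogs$climate[i],
    latitude = dogs$latitude[i],
    season = as.character(cal$season),
    day_type = as.character(cal$day_type),
    stringsAsFactors = FALSE
  )
}
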