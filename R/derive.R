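#' Breed-size classification scale
#'
#' Weight cut-points (kg) separating the six breed-size categories. Intervals
#' are left-open right-closed except the extremes: mean corrected adult weight
#' <= 6.5 kg is toy, > 40 kg is giant.
#'
#' @param thresholds Strictly increasing cut-points, one fewer than `labels`.
#' @param labels Category labels, smallest first.
#' @return List of class `breed_size_scale`.
#' @export
breed_size_scale <- function(thresholds = c(6.5, 9, 15, 30, 40),
                             labels = c("toy", "small", "medium_small",
                                        "medium_large", "large", "giant")) {
  stopifnot(length(labels) == length(thresholds) + 1L,
            all(diff(thresholds) > 0))
  structure(list(thresholds = thresholds, labels = labels),
            class = "breed_size_scale")
}

#' Correct a recorded body weight for body condition
#'
#' Overweight body condition inflates recorded weight relative to the dog's
#' ideal weight: scores of 4/5 and 5/5 are corrected by multiplying the
#' recorded weight by 0.8 and 0.6 respectively; scores 1-3 are returned
#' unchanged. Vectorized over both arguments.
#'
#' @param weight_kg Positive recorded weight(s) in kg.
#' @param bcs5 Body condition score(s) on the 5-point scale, integer 1-5.
#' @return Corrected weight(s) in kg.
#' @examples
#' correct_weight(10, 4)  # 8
#' correct_weight(10, 5)  # 6
#' @export
correct_weight <- function(weight_kg, bcs5) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  bcs5 <- check_bcs(bcs5, 5L)
  mult <- c(1, 1, 1, 0.8, 0.6)
  weight_kg * mult[bcs5]
}

check_bcs <- function(bcs, top) {
  b <- as.integer(bcs)
  if (any(is.na(b)) || any(b != bcs) || any(b < 1L) || any(b > top)) {
    stop("body condition score must be an integer in 1..", top, call. = FALSE)
  }
  b
}

#' Map a 9-point body condition score to the 5-point scale
#'
#' Two points on the 9-point scale correspond to one unit on the 5-point
#' scale: 4-5 -> 3 (ideal), 6-7 -> 4 (overweight), 8-9 -> 5 (obese), and by
#' the same rule 1 -> 1, 2-3 -> 2.
#'
#' @param bcs9 Integer score(s) in 1..9.
#' @return Integer score(s) in 1..5.
#' @export
map_bcs9_to_5 <- function(bcs9) {
  b <- check_bcs(bcs9, 9L)
  c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L)[b]
}

#' Assign a breed-size category from adult weight measurements
#'
#' Each recorded adult weight is first corrected for body condition with
#' [correct_weight()]; the mean corrected weight is then classified against
#' the [breed_size_scale()]. The result is invariant to the order of the
#' measurements.
#'
#' @param weight_kg Positive adult weights (kg), one per measurement.
#' @param bcs5 Matching 5-point body condition scores.
#' @param scale A [breed_size_scale()].
#' @return A single category label (character).
#' @examples
#' assign_breed_size(5, 3)            # "toy"
#' assign_breed_size(40, 5)           # corrected 24 kg -> "medium_large"
#' @export
assign_breed_size <- function(weight_kg, bcs5, scale = breed_size_scale()) {
  if (length(weight_kg) == 0L) stop("no weight measurements", call. = FALSE)
  stopifnot(length(weight_kg) == length(bcs5))
  m <- mean(correct_weight(weight_kg, bcs5))
  classify_weight_kg(m, scale)
}

classify_weight_kg <- function(w, scale = breed_size_scale()) {
  as.character(cut(w, breaks = c(-Inf, scale$thresholds, Inf),
                   labels = scale$labels, right = TRUE))
}

#' Binary weight status from body condition score
#'
#' @param bcs5 Integer score(s) in 1..5.
#' @return `"ideal"` for scores 1-3 (underweight or ideal), `"overweight"`
#'   for 4-5.
#' @export
derive_weight_status <- function(bcs5) {
  b <- check_bcs(bcs5, 5L)
  c("ideal", "ideal", "ideal", "overweight", "overweight")[b]
}

#' Health classification rule set
#'
#' Editable dictionaries of diagnosis and visit-reason codes used by
#' [classify_visit_health()]. The defaults cover chronic illness and organ
#' failure, cardiovascular, musculoskeletal, metabolic and endocrine
#' disorders and neoplasia (unhealthy); mobility-affecting events (injury);
#' and general preventive care reasons (healthy).
#'
#' @param unhealthy_codes Diagnosis tokens marking a visit unhealthy.
#' @param injury_codes Diagnosis/procedure tokens raising the injury flag.
#' @param healthy_reasons Visit-reason tokens counting as preventive care.
#' @return List of class `health_rules`.
#' @export
health_rules <- function(
    unhealthy_codes = c("organ_failure", "renal_failure", "heart_murmur",
                        "cardiomyopathy", "osteoarthritis", "hip_dysplasia",
                        "cruciate_disease", "diabetes_mellitus",
                        "hypothyroidism", "hyperadrenocorticism",
                        "neoplasia"),
    injury_codes = c("fracture", "road_traffic_accident", "surgery",
                     "anesthesia"),
    healthy_reasons = c("vaccination", "anthelmintic", "grooming",
                        "preventive_care", "wellness_exam")) {
  if (length(intersect(unhealthy_codes, healthy_reasons))) {
    stop("unhealthy_codes and healthy_reasons must be disjoint", call. = FALSE)
  }
  structure(list(unhealthy_codes = unhealthy_codes,
                 injury_codes = injury_codes,
                 healthy_reasons = healthy_reasons),
            class = "health_rules")
}

#' @rdname health_rules
#' @param path YAML file with keys `unhealthy_codes`, `injury_codes`,
#'   `healthy_reasons`.
#' @export
read_health_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  health_rules(unhealthy_codes = as.character(cfg$unhealthy_codes),
               injury_codes = as.character(cfg$injury_codes),
               healthy_reasons = as.character(cfg$healthy_reasons))
}

#' Classify visits as healthy, unhealthy or other
#'
#' A visit is `unhealthy` if any of its diagnosis codes (including historic
#' ones carried on the record) is in the unhealthy dictionary; otherwise it
#' is `healthy` if its visit reason is a preventive-care reason; otherwise
#' `other`. The injury flag is independent of the status and is raised when
#' any code is in the injury dictionary.
#'
#' @param diagnoses Character vector, each element a `";"`-separated list of
#'   diagnosis codes (may be empty), or a list of character vectors.
#' @param visit_reason Character vector of visit-reason tokens.
#' @param rules A [health_rules()].
#' @return Data frame with columns `health_status` (factor healthy /
#'   unhealthy / other) and `injury` (logical).
#' @examples
#' classify_visit_health("organ_failure", "consultation")
#' classify_visit_health("", "vaccination")
#' classify_visit_health("fracture", "vaccination")  # healthy but injured
#' @export
classify_visit_health <- function(diagnoses, visit_reason,
                                  rules = health_rules()) {
  stopifnot(inherits(rules, "health_rules"))
  if (!is.list(diagnoses)) {
    diagnoses <- strsplit(as.character(diagnoses), ";", fixed = TRUE)
  }
  diagnoses <- lapply(diagnoses, function(d) trimws(d[nzchar(trimws(d))]))
  stopifnot(length(diagnoses) == length(visit_reason))
  unhealthy <- vapply(diagnoses, function(d)
    any(d %in% rules$unhealthy_codes), logical(1L))
  injury <- vapply(diagnoses, function(d)
    any(d %in% rules$injury_codes), logical(1L))
  status <- ifelse(unhealthy, "unhealthy",
                   ifelse(visit_reason %in% rules$healthy_reasons,
                          "healthy", "other"))
  data.frame(health_status = factor(status,
                                    levels = c("healthy", "unhealthy", "other")),
             injury = injury)
}

#' Calendar covariates for activity dates
#'
#' Meteorological seasons for the northern hemisphere (Mar-May spring,
#' Jun-Aug summer, Sep-Nov autumn, Dec-Feb winter) and the weekday/weekend
#' day type (Saturday and Sunday are weekend).
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Data frame with factor columns `season` and `day_type`.
#' @examples
#' assign_calendar_vars(as.Date("2023-06-15"))  # summer, weekday
#' @export
assign_calendar_vars <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("invalid date", call. = FALSE)
  mo <- as.POSIXlt(date)$mon + 1L
  season <- c("winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "autumn", "autumn",
              "autumn", "winter")[mo]
  wday <- as.POSIXlt(date)$wday
  day_type <- ifelse(wday %in% c(0L, 6L), "weekend", "weekday")
  data.frame(
    season = factor(season, levels = c("spring", "summer", "autumn", "winter")),
    day_type = factor(day_type, levels = c("weekday", "weekend"))
  )
}
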