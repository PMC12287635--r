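#' Normalize a match-key component
#'
#' Lower-cases, trims and strips punctuation; idempotent.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_key <- function(x) {
  gsub("[^a-z0-9]", "", tolower(trimws(as.character(x))))
}

match_key_fields <- c("dog_key", "household", "species", "sex", "name",
                      "birth_date")

build_match_key <- function(df) {
  missing <- setdiff(match_key_fields, names(df))
  if (length(missing)) {
    stop("match table lacks key field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  paste(normalize_key(df$household), normalize_key(df$species),
        normalize_key(df$sex), normalize_key(df$name),
        format(as.Date(df$birth_date), "%Y-%m"), sep = "|")
}

#' Match dogs across the activity and EHR sources
#'
#' Deterministic exact matching within household on species, sex, normalized
#' name and date of birth to month-year precision. Dogs whose full key
#' matches zero or two-or-more candidates on the other side are left
#' unmatched (ambiguous keys, e.g. same-name littermates, are excluded from
#' both sides rather than arbitrarily assigned).
#'
#' @param activity_dogs,ehr_dogs Data frames carrying `dog_key`, `household`,
#'   `species`, `sex`, `name`, `birth_date`.
#' @return Data frame with columns `activity_key`, `ehr_key` (one row per
#'   matched dog). Attributes `unmatched_activity`, `unmatched_ehr` and
#'   `ambiguous` list the excluded keys.
#' @export
match_dogs <- function(activity_dogs, ehr_dogs) {
  ka <- build_match_key(activity_dogs)
  ke <- build_match_key(ehr_dogs)
  dup_a <- unique(ka[duplicated(ka)])
  dup_e <- unique(ke[duplicated(ke)])
  ambiguous <- union(dup_a, dup_e)
  ok_a <- !(ka %in% ambiguous)
  ok_e <- !(ke %in% ambiguous)
  pos <- match(ka, ke[ok_e])
  matched <- ok_a & !is.na(pos)
  map <- data.frame(activity_key = activity_dogs$dog_key[matched],
                    ehr_key = ehr_dogs$dog_key[ok_e][pos[matched]],
                    stringsAsFactors = FALSE)
  attr(map, "unmatched_activity") <-
    activity_dogs$dog_key[!matched & !(ka %in% ambiguous)]
  attr(map, "unmatched_ehr") <-
    setdiff(ehr_dogs$dog_key[ok_e], map$ehr_key)
  attr(map, "ambiguous") <-
    c(activity_dogs$dog_key[ka %in% ambiguous],
      ehr_dogs$dog_key[ke %in% ambiguous])
  map
}

new_linked_dataset <- function(rows, provenance) {
  structure(rows, provenance = provenance,
            class = c("linked_dataset", "data.frame"))
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat(sprintf("<linked_dataset> %d rows, %d dogs\n",
              nrow(x), length(unique(x$dog_key))))
  print(provenance(x))
  invisible(x)
}

#' Filter provenance of a linked dataset
#'
#' @param linked A `linked_dataset`.
#' @return Data frame with one row per processing stage: `stage`, `rows_in`,
#'   `rows_out`, `dogs_in`, `dogs_out`.
#' @export
provenance <- function(linked) {
  attr(linked, "provenance")
}

add_stage <- function(prov, stage, rows_in, rows_out, dogs_in, dogs_out) {
  rbind(prov, data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
                         dogs_in = dogs_in, dogs_out = dogs_out,
                         stringsAsFactors = FALSE))
}

#' Link daily activity records to the closest prior veterinary visit
#'
#' Each activity record joins the visit with the greatest `visit_date` that
#' is on or before the activity date and at most 365 days earlier (one
#' calendar year interpreted as a 365-day span). Records with no qualifying
#' visit are dropped. One visit may serve many activity records.
#'
#' @param activity Data frame with `dog_key`, `date`, `active_minutes` (any
#'   further columns are carried through). `dog_key` must already be on the
#'   EHR keying (apply the [match_dogs()] mapping first).
#' @param visits Data frame of visit records with `dog_key`, `visit_date`
#'   (further columns carried with a `visit_` prefix where they would clash).
#' @param max_lag_days Maximum allowed activity-minus-visit gap (default 365).
#' @return A `linked_dataset`: activity columns plus the linked visit's
#'   columns and `days_since_visit`, with a provenance record for the link
#'   stage.
#' @export
link_activity_to_visit <- function(activity, visits, max_lag_days = 365) {
  stopifnot(all(c("dog_key", "date", "active_minutes") %in% names(activity)),
            all(c("dog_key", "visit_date") %in% names(visits)))
  activity$date <- as.Date(activity$date)
  visits$visit_date <- as.Date(visits$visit_date)
  rows_in <- nrow(activity)
  dogs_in <- length(unique(activity$dog_key))
  ord <- order(activity$dog_key, activity$date)
  activity <- activity[ord, , drop = FALSE]
  visit_idx <- rep(NA_integer_, nrow(activity))
  v_by_dog <- split(seq_len(nrow(visits)), visits$dog_key)
  a_by_dog <- split(seq_len(nrow(activity)), activity$dog_key)
  for (dog in names(a_by_dog)) {
    vi <- v_by_dog[[dog]]
    if (is.null(vi)) next
    vi <- vi[order(visits$visit_date[vi])]
    ai <- a_by_dog[[dog]]
    pos <- findInterval(as.numeric(activity$date[ai]),
                        as.numeric(visits$visit_date[vi]))
    hit <- pos >= 1L
    visit_idx[ai[hit]] <- vi[pos[hit]]
  }
  lag <- as.numeric(activity$date - visits$visit_date[visit_idx])
  keep <- !is.na(visit_idx) & lag <= max_lag_days
  out <- activity[keep, , drop = FALSE]
  vcols <- visits[visit_idx[keep], setdiff(names(visits), "dog_key"),
                  drop = FALSE]
  clash <- intersect(names(vcols), names(out))
  names(vcols)[names(vcols) %in% clash] <- paste0("visit_", clash)
  out <- cbind(out, vcols)
  out$days_since_visit <- lag[keep]
  rownames(out) <- NULL
  prov <- add_stage(NULL, "link_within_year", rows_in, nrow(out),
                    dogs_in, length(unique(out$dog_key)))
  new_linked_dataset(out, prov)
}

#' Filter thresholds
#'
#' Defaults implement the study inclusion rules: daily records outside
#' \[10, 600\] active minutes are removed; dogs with fewer than five activity
#' records per linked visit are removed; rows where the dog is not strictly
#' between 1.5 and 12 years old at both the activity date and the linked
#' visit date are removed; and dogs must end with more than seven (i.e. at
#' least eight) surviving records.
#'
#' @param min_minutes,max_minutes Inclusive bounds on daily active minutes.
#' @param min_ratio Minimum activity-records-per-distinct-visit ratio.
#' @param min_age,max_age Exclusive age bounds (years) at record and at visit.
#' @param min_records Dogs need strictly more than this many surviving rows.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_minutes = 10, max_minutes = 600,
                          min_ratio = 5, min_age = 1.5, max_age = 12,
                          min_records = 7) {
  structure(list(min_minutes = min_minutes, max_minutes = max_minutes,
                 min_ratio = min_ratio, min_age = min_age, max_age = max_age,
                 min_records = min_records),
            class = "filter_config")
}

#' Apply the record-cleaning filter cascade
#'
#' Stages run in a fixed, logged order: (1) bounds — drop rows with active
#' minutes below `min_minutes` or above `max_minutes`; (2) ratio — drop every
#' row of dogs whose ratio of activity rows to distinct linked visits is
#' below `min_ratio`; (3) age — drop rows where the dog's age at the activity
#' date or at the linked visit date is at or outside (`min_age`, `max_age`);
#' (4) minimum records — drop dogs with no more than `min_records` surviving
#' rows. Each stage appends its row and dog counts to the provenance, and the
#' cascade is idempotent. Surviving rows get `in_all_visits = TRUE`.
#'
#' @param linked A `linked_dataset` from [link_activity_to_visit()] with
#'   columns `age_at_activity` and `age_at_visit` (years).
#' @param config A [filter_config()].
#' @return The filtered `linked_dataset`.
#' @export
apply_filters <- function(linked, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("active_minutes", "age_at_activity", "age_at_visit", "dog_key")
  missing <- setdiff(need, names(linked))
  if (length(missing)) {
    stop("linked dataset lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  prov <- provenance(linked)
  stage <- function(dat, name, keep) {
    out <- dat[keep, , drop = FALSE]
    prov <<- add_stage(prov, name, nrow(dat), nrow(out),
                       length(unique(dat$dog_key)),
                       length(unique(out$dog_key)))
    out
  }
  dat <- as.data.frame(linked)
  dat <- stage(dat, "bounds_10_600",
               dat$active_minutes >= config$min_minutes &
                 dat$active_minutes <= config$max_minutes)
  n_rows <- table(dat$dog_key)
  n_visits <- tapply(dat$visit_date, dat$dog_key,
                     function(v) length(unique(v)))
  ratio <- as.numeric(n_rows[dat$dog_key]) /
    as.numeric(n_visits[dat$dog_key])
  dat <- stage(dat, "activity_visit_ratio", ratio >= config$min_ratio)
  dat <- stage(dat, "adult_age_window",
               dat$age_at_activity > config$min_age &
                 dat$age_at_activity < config$max_age &
                 dat$age_at_visit > config$min_age &
                 dat$age_at_visit < config$max_age)
  n_rows <- table(dat$dog_key)
  dat <- stage(dat, "min_records_per_dog",
               as.numeric(n_rows[dat$dog_key]) > config$min_records)
  dat$in_all_visits <- rep(TRUE, nrow(dat))
  rownames(dat) <- NULL
  new_linked_dataset(dat, prov)
}

#' Flag the healthy-visits subset
#'
#' Marks rows whose linked visit is classified healthy and carries no injury
#' flag: `in_healthy_visits = in_all_visits & health_status == "healthy" &
#' !injury`. Requires the visit classification columns produced by
#' [classify_visit_health()].
#'
#' @param linked A filtered `linked_dataset` with columns `health_status` and
#'   `injury`.
#' @return The dataset with an `in_healthy_visits` column and a provenance
#'   entry for the split.
#' @export
split_healthy <- function(linked) {
  if (!all(c("health_status", "injury") %in% names(linked))) {
    stop("visit health classification missing; run classify_visit_health()",
         call. = FALSE)
  }
  if (anyNA(linked$health_status)) {
    bad <- which(is.na(linked$health_status))[1L]
    stop("unclassified visit at row ", bad,
         " (visit date ", linked$visit_date[bad], ")", call. = FALSE)
  }
  prov <- provenance(linked)
  all_flag <- if ("in_all_visits" %in% names(linked)) linked$in_all_visits
              else rep(TRUE, nrow(linked))
  dat <- as.data.frame(linked)
  dat$in_healthy_visits <- all_flag &
    dat$health_status == "healthy" & !dat$injury
  prov <- add_stage(prov, "healthy_visits_subset",
                    sum(all_flag), sum(dat$in_healthy_visits),
                    length(unique(dat$dog_key[all_flag])),
                    length(unique(dat$dog_key[dat$in_healthy_visits])))
  new_linked_dataset(dat, prov)
}
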