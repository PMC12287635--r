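dog_exposures <- c("dog_age", "breed_size", "weight_status", "sex",
                   "neuter_status")
env_exposures <- c("season", "climate", "latitude", "location_type",
                   "day_type", "owner_age")

reference_levels_default <- c(
  breed_size = "medium_large", sex = "male", neuter_status = "intact",
  weight_status = "ideal", owner_age = "18-30", location_type = "rural",
  climate = "cold", season = "spring", day_type = "weekday"
)

#' Pipeline run configuration
#'
#' Bundles the simulation settings, DAG, filter thresholds, health rules,
#' model settings and seeds for one end-to-end [run_pipeline()] run. The
#' single `seed` fans out to fixed per-stage offsets so every stage is
#' individually reproducible.
#'
#' @param seed Master integer seed.
#' @param sim A [sim_config()]; its own seed defaults to `seed`.
#' @param dag A [causal_dag()] or path to a DAG file; defaults to the
#'   bundled [activity_dag()].
#' @param filters A [filter_config()].
#' @param rules A [health_rules()].
#' @param K,R Per-dog subsample size and repetition count for
#'   [resampled_inference()].
#' @param k_folds Folds for [grouped_kfold_consistency()].
#' @param candidate_interactions_dog,candidate_interactions_env Candidate
#'   interaction pairs for the two models.
#' @param flexible_validation Run the boosted-tree comparison (default TRUE).
#' @param bias_correct Log-normal bias correction for marginal means.
#' @param alpha Level for DAG-consistency independence tests.
#' @param ci_test_rows Row cap for the independence tests (subsampled for
#'   speed).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = NULL,
                       dag = NULL,
                       filters = filter_config(),
                       rules = health_rules(),
                       K = 50L, R = 1000L, k_folds = 5L,
                       candidate_interactions_dog = list(
                         c("breed_size", "dog_age"),
                         c("weight_status", "dog_age"),
                         c("neuter_status", "dog_age"),
                         c("owner_age", "dog_age"),
                         c("breed_size", "weight_status"),
                         c("breed_size", "owner_age"),
                         c("weight_status", "neuter_status"),
                         c("neuter_status", "sex")),
                       candidate_interactions_env = list(
                         c("season", "climate"),
                         c("season", "day_type"),
                         c("day_type", "location_type"),
                         c("day_type", "owner_age")),
                       flexible_validation = TRUE,
                       bias_correct = FALSE,
                       alpha = 0.05,
                       ci_test_rows = 5000L) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(sim$seed)) sim$seed <- as.integer(seed)
  if (is.null(dag)) dag <- activity_dag()
  if (is.character(dag)) dag <- read_dag(dag)
  structure(list(seed = as.integer(seed), sim = sim, dag = dag,
                 filters = filters, rules = rules, K = K, R = R,
                 k_folds = k_folds,
                 candidate_interactions_dog = candidate_interactions_dog,
                 candidate_interactions_env = candidate_interactions_env,
                 flexible_validation = flexible_validation,
                 bias_correct = bias_correct, alpha = alpha,
                 ci_test_rows = ci_test_rows),
            class = "run_config")
}

#' Assemble the analysis table from linked records
#'
#' Adds the derived covariates to a linked dataset: visit health
#' classification, 5-point body condition (translating 9-point recordings),
#' weight status, per-dog breed size from corrected adult visit weights,
#' ages at activity and at visit, calendar variables, and the analysis
#' column names that match the DAG nodes.
#'
#' @param linked A `linked_dataset` from [link_activity_to_visit()].
#' @param ehr_dogs EHR-side demographics (`dog_key`, `sex`, `birth_date`).
#' @param visits The full visit table (for per-dog breed-size averaging).
#' @param rules A [health_rules()].
#' @param adult_age Age (years) above which visit weights count as adult.
#' @return The linked dataset with derived columns appended.
#' @export
build_analysis_table <- function(linked, ehr_dogs, visits,
                                 rules = health_rules(), adult_age = 1.5) {
  prov <- provenance(linked)
  dat <- as.data.frame(linked)
  demo <- ehr_dogs[match(dat$dog_key, ehr_dogs$dog_key), ]
  dat$sex <- demo$sex
  dat$birth_date <- as.Date(demo$birth_date)
  cls <- classify_visit_health(dat$diagnoses, dat$visit_reason, rules)
  dat$health_status <- cls$health_status
  dat$injury <- cls$injury
  dat$bcs5 <- ifelse(dat$bcs_scale == 9L,
                     map_bcs9_to_5(dat$bcs_recorded), dat$bcs_recorded)
  dat$weight_status <- derive_weight_status(dat$bcs5)
  dat$age_at_activity <- as.numeric(dat$date - dat$birth_date) / 365.25
  dat$age_at_visit <- as.numeric(as.Date(dat$visit_date) - dat$birth_date) /
    365.25
  # per-dog breed size from BCS-corrected adult visit weights
  v <- as.data.frame(visits)
  v$birth_date <- as.Date(ehr_dogs$birth_date[match(v$dog_key,
                                                    ehr_dogs$dog_key)])
  v$age <- as.numeric(as.Date(v$visit_date) - v$birth_date) / 365.25
  v$bcs5 <- ifelse(v$bcs_scale == 9L, map_bcs9_to_5(v$bcs_recorded),
                   v$bcs_recorded)
  size_of <- vapply(split(v, v$dog_key), function(dv) {
    adult <- dv[!is.na(dv$age) & dv$age > adult_age, ]
    if (nrow(adult) == 0L) adult <- dv
    assign_breed_size(adult$weight_kg, adult$bcs5)
  }, character(1L))
  dat$breed_size <- unname(size_of[dat$dog_key])
  cal <- assign_calendar_vars(dat$date)
  dat$season <- as.character(cal$season)
  dat$day_type <- as.character(cal$day_type)
  dat$dog_age <- dat$age_at_activity
  dat$neuter_status <- ifelse(dat$neutered_at_visit, "neutered", "intact")
  dat$unhealthy_diagnosis <- as.numeric(dat$health_status == "unhealthy")
  new_linked_dataset(dat, prov)
}

union_adjustment <- function(dag, exposures, outcome) {
  sets <- lapply(exposures, function(x) {
    s <- minimal_adjustment_sets(dag, x, outcome)
    if (length(s)) s[[1L]] else character()
  })
  sort(setdiff(unique(unlist(sets, use.names = FALSE)), c(exposures, outcome)))
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  report$stages <- rbind(report$stages, data.frame(
    stage = name, status = if (res$ok) "ok" else "failed",
    detail = if (res$ok) "" else as.character(res$value),
    stringsAsFactors = FALSE))
  list(report = report, ok = res$ok,
       value = if (res$ok) res$value else NULL)
}

#' Run the full analysis pipeline
#'
#' Sequences simulate -> match -> link -> derive -> filter -> DAG checks ->
#' mixed-model inference (all-visits and healthy-visits dog-attribute
#' models, all-visits environmental model) -> grouped k-fold consistency ->
#' flexible-model validation, and assembles a machine-readable report. The
#' dog-attribute models adjust for the covariate set the DAG indicates for
#' the exposures age, breed size, weight status, sex and neuter status; the
#' environmental model uses the environmental exposures with no extra
#' adjustment. A failed stage marks the report and skips downstream stages.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(seed = config$seed,
                 stages = data.frame(stage = character(), status = character(),
                                     detail = character(),
                                     stringsAsFactors = FALSE))
  class(report) <- "pipeline_report"

  st <- run_stage(report, "simulate", simulate_study(config$sim))
  report <- st$report
  if (!st$ok) return(report)
  study <- st$value
  report$counts <- list(dogs_simulated = nrow(study$dogs),
                        activity_rows = nrow(study$activity),
                        visit_rows = nrow(study$visits))

  st <- run_stage(report, "match",
                  match_dogs(study$activity_dogs, study$ehr_dogs))
  report <- st$report
  if (!st$ok) return(report)
  map <- st$value
  report$counts$dogs_matched <- nrow(map)
  report$counts$dogs_ambiguous <- length(attr(map, "ambiguous"))

  st <- run_stage(report, "link", {
    act <- study$activity
    act$dog_key <- map$ehr_key[match(act$dog_key, map$activity_key)]
    act <- act[!is.na(act$dog_key), , drop = FALSE]
    link_activity_to_visit(act, study$visits)
  })
  report <- st$report
  if (!st$ok) return(report)
  linked <- st$value

  st <- run_stage(report, "derive",
                  build_analysis_table(linked, study$ehr_dogs, study$visits,
                                       rules = config$rules))
  report <- st$report
  if (!st$ok) return(report)
  linked <- st$value

  st <- run_stage(report, "filter", {
    out <- apply_filters(linked, config$filters)
    split_healthy(out)
  })
  report <- st$report
  if (!st$ok) return(report)
  linked <- st$value
  report$provenance <- provenance(linked)

  analysis <- as.data.frame(linked)
  analysis$active_minutes <- as.numeric(analysis$active_minutes)
  all_visits <- analysis[analysis$in_all_visits, , drop = FALSE]
  healthy <- analysis[analysis$in_healthy_visits, , drop = FALSE]
  report$counts$rows_all_visits <- nrow(all_visits)
  report$counts$dogs_all_visits <- length(unique(all_visits$dog_key))
  report$counts$rows_healthy_visits <- nrow(healthy)
  report$counts$dogs_healthy_visits <- length(unique(healthy$dog_key))
  report$counts$mean_active_minutes <- mean(all_visits$active_minutes)

  st <- run_stage(report, "dag_checks", {
    dag <- config$dag
    adj_dog <- union_adjustment(dag, dog_exposures, "active_minutes")
    adj_env <- union_adjustment(dag, env_exposures, "active_minutes")
    claims <- implied_independences(dag, observed_only = TRUE)
    test_dat <- all_visits
    test_dat$active_minutes <- log(test_dat$active_minutes)
    have <- vapply(seq_len(nrow(claims)), function(i)
      all(c(claims$x[i], claims$y[i], claims$given[[i]]) %in%
            names(test_dat)), logical(1L))
    claims <- claims[have, , drop = FALSE]
    if (nrow(test_dat) > config$ci_test_rows) {
      set.seed(config$seed + 10L)
      test_dat <- test_dat[sample(nrow(test_dat), config$ci_test_rows), ]
    }
    tested <- test_claims_by_unit(claims, test_dat, alpha = config$alpha)
    list(adjustment_dog = adj_dog, adjustment_env = adj_env,
         independences = tested,
         rejection_rate = mean(tested$rejected[!tested$skipped]))
  })
  report <- st$report
  if (!st$ok) return(report)
  report$dag <- st$value

  spec_dog <- model_spec(
    outcome = "active_minutes",
    fixed = c(dog_exposures, report$dag$adjustment_dog),
    group = "dog_key",
    reference_levels = reference_levels_default,
    age_var = "dog_age")
  spec_env <- model_spec(
    outcome = "active_minutes",
    fixed = env_exposures,
    group = "dog_key",
    reference_levels = reference_levels_default,
    age_var = NULL)

  st <- run_stage(report, "fit_models", {
    spec_dog_sel <- select_interactions(all_visits, spec_dog,
                                        config$candidate_interactions_dog)
    spec_env_sel <- select_interactions(all_visits, spec_env,
                                        config$candidate_interactions_env)
    agg_dog <- resampled_inference(all_visits, spec_dog_sel,
                                   K = config$K, R = config$R,
                                   seed = config$seed + 11L)
    agg_dog_healthy <- resampled_inference(healthy, spec_dog_sel,
                                           K = config$K, R = config$R,
                                           seed = config$seed + 12L)
    agg_env <- resampled_inference(all_visits, spec_env_sel,
                                   K = config$K, R = config$R,
                                   seed = config$seed + 13L)
    list(spec_dog = spec_dog_sel, spec_env = spec_env_sel,
         dog_all = agg_dog, dog_healthy = agg_dog_healthy, env = agg_env)
  })
  report <- st$report
  if (!st$ok) return(report)
  report$models <- st$value

  st <- run_stage(report, "marginal_means", {
    bc <- config$bias_correct
    list(
      breed_size = estimate_marginal_means(report$models$dog_all, all_visits,
                                           "breed_size", bias_correct = bc),
      dog_age = estimate_marginal_means(report$models$dog_all, all_visits,
                                        "dog_age", grid = 2:11,
                                        bias_correct = bc),
      day_type = estimate_marginal_means(report$models$env, all_visits,
                                         "day_type", bias_correct = bc),
      season = estimate_marginal_means(report$models$env, all_visits,
                                       "season", bias_correct = bc),
      climate = estimate_marginal_means(report$models$env, all_visits,
                                        "climate", bias_correct = bc))
  })
  report <- st$report
  if (!st$ok) return(report)
  report$marginal_means <- st$value

  st <- run_stage(report, "kfold", {
    grouped_kfold_consistency(all_visits, report$models$spec_dog,
                              k = config$k_folds, seed = config$seed + 14L)
  })
  report <- st$report
  if (st$ok) report$kfold <- st$value

  if (config$flexible_validation) {
    st <- run_stage(report, "flexible_validation", {
      predictors <- c(dog_exposures, env_exposures, "unhealthy_diagnosis",
                      "injury")
      flex <- fit_flexible_model(all_visits, predictors, group = "dog_key",
                                 seed = config$seed + 15L)
      list(
        model_engine = flex$engine,
        age = compare_marginal_curves(report$marginal_means$dog_age, flex,
                                      all_visits, "dog_age"),
        breed_size = compare_marginal_curves(report$marginal_means$breed_size,
                                             flex, all_visits, "breed_size"),
        day_type = compare_marginal_curves(report$marginal_means$day_type,
                                           flex, all_visits, "day_type"))
    })
    report <- st$report
    if (st$ok) report$flexible <- st$value
  }

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$counts)) {
    cat(sprintf("all-visits: %d rows / %d dogs; healthy-visits: %d rows / %d dogs\n",
                x$counts$rows_all_visits %||% NA,
                x$counts$dogs_all_visits %||% NA,
                x$counts$rows_healthy_visits %||% NA,
                x$counts$dogs_healthy_visits %||% NA))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$models)) {
    utils::write.csv(report$models$dog_all$terms,
                     file.path(out_dir, "coefficients_dog_all_visits.csv"),
                     row.names = FALSE)
    utils::write.csv(report$models$dog_healthy$terms,
                     file.path(out_dir, "coefficients_dog_healthy_visits.csv"),
                     row.names = FALSE)
    utils::write.csv(report$models$env$terms,
                     file.path(out_dir, "coefficients_environmental.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$marginal_means)) {
    mm <- do.call(rbind, lapply(names(report$marginal_means), function(nm) {
      cbind(focal = nm, as.data.frame(report$marginal_means[[nm]]))
    }))
    utils::write.csv(mm, file.path(out_dir, "marginal_means.csv"),
                     row.names = FALSE)
  }
  diag <- list(
    seed = report$seed, counts = report$counts,
    provenance = report$provenance,
    adjustment_dog = report$dag$adjustment_dog,
    adjustment_env = report$dag$adjustment_env,
    ci_rejection_rate = report$dag$rejection_rate,
    template_dog = if (!is.null(report$models)) {
      t <- report$models$dog_all$template
      list(r2_conditional = t$r2_conditional, rmse = t$rmse,
           var_random_share = t$var_random_share)
    },
    kfold = if (!is.null(report$kfold)) {
      list(r2_sd = report$kfold$r2_sd, rmse_sd = report$kfold$rmse_sd)
    },
    flexible = if (!is.null(report$flexible)) {
      list(age_rank_correlation = report$flexible$age$rank_correlation,
           engine = report$flexible$model_engine)
    })
  jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

# Repeated daily records are not independent observations: claims are tested
# on the coarsest observational unit their variables allow. Dog-constant
# attributes (and dog age, as its per-dog mean) are tested across dogs;
# visit-level variables (constant within dog x visit) are averaged per dog
# when everything else is dog-level, or tested on one row per visit when a
# calendar variable is involved; purely record-level claims stay on rows.
test_claims_by_unit <- function(claims, test_dat, alpha = 0.05) {
  if (nrow(claims) == 0L) return(claims)
  visit_id <- paste(test_dat$dog_key, test_dat$visit_date, sep = "|")
  level_of <- vapply(names(test_dat), function(v) {
    z <- as.character(test_dat[[v]])
    if (anyNA(z)) return("record")
    if (all(tapply(z, test_dat$dog_key,
                   function(w) length(unique(w))) == 1L)) return("dog")
    if (all(tapply(z, visit_id,
                   function(w) length(unique(w))) == 1L)) return("visit")
    "record"
  }, character(1L))
  level_of["dog_age"] <- "dog"

  per_dog <- test_dat[!duplicated(test_dat$dog_key), , drop = FALSE]
  per_dog$dog_age <- as.numeric(
    tapply(test_dat$dog_age, test_dat$dog_key, mean)[per_dog$dog_key])
  # visit-level numerics can be summarized as per-dog means
  dogable <- level_of == "dog"
  for (v in names(level_of)[level_of == "visit"]) {
    if (is.numeric(test_dat[[v]]) || is.logical(test_dat[[v]])) {
      per_dog[[v]] <- as.numeric(
        tapply(as.numeric(test_dat[[v]]), test_dat$dog_key,
               mean)[per_dog$dog_key])
      dogable[v] <- TRUE
    }
  }
  per_visit <- test_dat[!duplicated(visit_id), , drop = FALSE]

  unit <- vapply(seq_len(nrow(claims)), function(i) {
    vars <- c(claims$x[i], claims$y[i], claims$given[[i]])
    if (all(dogable[vars])) "dog"
    else if (any(level_of[vars] == "visit")) "visit"
    else "record"
  }, character(1L))
  rbind(
    test_independences(claims[unit == "dog", , drop = FALSE], per_dog,
                       alpha = alpha),
    test_independences(claims[unit == "visit", , drop = FALSE], per_visit,
                       alpha = alpha),
    test_independences(claims[unit == "record", , drop = FALSE], test_dat,
                       alpha = alpha))
}
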