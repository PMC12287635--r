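#' Specify a mixed model for log active minutes
#'
#' The outcome is log-transformed inside the model formula; the age variable
#' (if listed among the fixed effects) enters as its inverse square,
#' `I(age^-2)`. The random effect is an intercept per dog.
#'
#' @param outcome Column holding daily active minutes (strictly positive).
#' @param fixed Character vector of fixed-effect columns.
#' @param interactions List of character pairs, each pair a candidate or
#'   selected interaction between two fixed effects.
#' @param group Grouping column (dog identifier) for the random intercept.
#' @param reference_levels Named character vector mapping categorical fixed
#'   effects to their reference level.
#' @param age_var Name of the age column that enters as `I(age^-2)`
#'   (set `NULL` for none).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(outcome = "active_minutes",
                       fixed = character(),
                       interactions = list(),
                       group = "dog_key",
                       reference_levels = character(),
                       age_var = "dog_age") {
  if (group %in% fixed) {
    stop("the grouping variable cannot also be a fixed effect", call. = FALSE)
  }
  for (pair in interactions) {
    if (length(pair) != 2L || !all(pair %in% fixed)) {
      stop("interaction members must be pairs of declared fixed effects: ",
           paste(pair, collapse = ":"), call. = FALSE)
    }
  }
  structure(list(outcome = outcome, fixed = fixed,
                 interactions = interactions, group = group,
                 reference_levels = reference_levels, age_var = age_var),
            class = "model_spec")
}

term_label <- function(spec, var) {
  if (!is.null(spec$age_var) && var == spec$age_var) {
    sprintf("I(%s^-2)", var)
  } else {
    var
  }
}

build_formula <- function(spec) {
  mains <- vapply(spec$fixed, function(v) term_label(spec, v), character(1L))
  ints <- vapply(spec$interactions, function(p)
    paste(term_label(spec, p[1L]), term_label(spec, p[2L]), sep = ":"),
    character(1L))
  rhs <- paste(c(mains, ints, sprintf("(1 | %s)", spec$group)),
               collapse = " + ")
  stats::as.formula(paste0("log(", spec$outcome, ") ~ ", rhs),
                    env = globalenv())
}

fixed_rhs_formula <- function(spec) {
  mains <- vapply(spec$fixed, function(v) term_label(spec, v), character(1L))
  ints <- vapply(spec$interactions, function(p)
    paste(term_label(spec, p[1L]), term_label(spec, p[2L]), sep = ":"),
    character(1L))
  stats::as.formula(paste("~", paste(c(mains, ints), collapse = " + ")),
                    env = globalenv())
}

prepare_model_data <- function(data, spec) {
  cols <- unique(c(spec$outcome, spec$fixed, spec$group))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("model variable(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(data)[cols]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (any(dat[[spec$outcome]] <= 0)) {
    stop("outcome must be strictly positive before log transformation",
         call. = FALSE)
  }
  dat[[spec$group]] <- factor(dat[[spec$group]])
  if (nlevels(dat[[spec$group]]) < 2L) {
    stop("at least two grouping levels (dogs) are required", call. = FALSE)
  }
  dropped <- character()
  for (v in spec$fixed) {
    if (is.character(dat[[v]]) || is.logical(dat[[v]])) {
      dat[[v]] <- factor(dat[[v]])
    }
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2L) {
        # a factor collapsing to one level carries no contrast to estimate
        dropped <- c(dropped, v)
        next
      }
      ref <- spec$reference_levels[v]
      if (!is.na(ref) && !is.null(ref) && length(ref)) {
        if (!ref %in% levels(dat[[v]])) {
          stop("reference level '", ref, "' absent from ", v, call. = FALSE)
        }
        dat[[v]] <- stats::relevel(dat[[v]], ref = unname(ref))
      }
    } else if (length(unique(dat[[v]])) < 2L) {
      dropped <- c(dropped, v)
    }
  }
  if (length(dropped)) {
    spec$fixed <- setdiff(spec$fixed, dropped)
    spec$interactions <- Filter(function(p) all(p %in% spec$fixed),
                                spec$interactions)
    message("dropping constant fixed effect(s): ",
            paste(dropped, collapse = ", "))
  }
  list(data = dat, spec = spec)
}

#' Fit the linear mixed model
#'
#' Restricted-maximum-likelihood fit of log active minutes on the spec's
#' fixed effects with a per-dog random intercept, via [lme4::lmer()].
#' Coefficients carry Wald 95% confidence intervals (estimate +/- 1.96 SE).
#' The conditional pseudo-R-squared is (fixed + random variance) / total;
#' `var_random_share` is the random intercept's share of the total variance;
#' RMSE is on the log scale.
#'
#' @param data Data frame of analysis rows.
#' @param spec A [model_spec()].
#' @param reml Fit by REML (default) or maximum likelihood.
#' @return Object of class `activity_lmm` with elements `model` (the
#'   `lmerMod`), `coefficients` (data frame: term, estimate, std_error,
#'   ci_lower, ci_upper), `aic`, `r2_conditional`, `rmse`, `var_random`,
#'   `var_residual`, `var_fixed`, `var_random_share`, `singular`, `spec`.
#' @export
fit_lmm <- function(data, spec, reml = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_model_data(data, spec)
  fit_lmm_prepared(prep$data, prep$spec, reml = reml)
}

fit_lmm_prepared <- function(dat, spec, reml = TRUE) {
  fml <- build_formula(spec)
  msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(fml, data = dat, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  b <- lme4::fixef(model)
  se <- sqrt(Matrix::diag(stats::vcov(model)))
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      std_error = unname(se),
                      ci_lower = unname(b - 1.96 * se),
                      ci_upper = unname(b + 1.96 * se),
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(model)
  var_random <- as.numeric(vc[[spec$group]][1L, 1L])
  var_residual <- stats::sigma(model)^2
  eta <- as.numeric(lme4::getME(model, "X") %*% b)
  var_fixed <- stats::var(eta)
  total <- var_fixed + var_random + var_residual
  structure(
    list(model = model, coefficients = coefs, aic = stats::AIC(model),
         r2_conditional = (var_fixed + var_random) / total,
         rmse = sqrt(mean(stats::residuals(model)^2)),
         var_random = var_random, var_residual = var_residual,
         var_fixed = var_fixed, var_random_share = var_random / total,
         singular = lme4::isSingular(model, tol = 1e-4),
         messages = msgs, spec = spec),
    class = "activity_lmm"
  )
}

#' @export
print.activity_lmm <- function(x, ...) {
  cat(sprintf(
    "<activity_lmm> %d fixed-effect terms | R2(cond) = %.3f | RMSE = %.3f | random-intercept share = %.3f%s\n",
    nrow(x$coefficients), x$r2_conditional, x$rmse, x$var_random_share,
    if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Pairwise multicollinearity screen
#'
#' Continuous pairs are scored by absolute Pearson correlation, categorical
#' pairs by Cramer's V, and mixed pairs by the multiple correlation of the
#' continuous member on the indicator-encoded categorical. Values above the
#' threshold are flagged for further consideration; constant columns are
#' marked degenerate rather than raising an error.
#'
#' @param data Data frame.
#' @param predictors Columns to screen.
#' @param threshold Flagging threshold (default 0.5).
#' @return Object of class `collinearity_screen`: list with `measure` (named
#'   matrix), `flagged` (logical matrix) and `degenerate` (character vector
#'   of constant columns).
#' @export
check_multicollinearity <- function(data, predictors, threshold = 0.5) {
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    stop("predictor(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- length(predictors)
  m <- matrix(NA_real_, p, p, dimnames = list(predictors, predictors))
  degenerate <- predictors[vapply(data[predictors], function(v)
    length(unique(v[!is.na(v)])) < 2L, logical(1L))]
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i >= j) next
      a <- predictors[i]; b <- predictors[j]
      if (a %in% degenerate || b %in% degenerate) next
      m[i, j] <- m[j, i] <- pairwise_association(data[[a]], data[[b]])
    }
  }
  diag(m) <- 1
  flagged <- !is.na(m) & m > threshold
  diag(flagged) <- FALSE
  structure(list(measure = m, flagged = flagged, degenerate = degenerate,
                 threshold = threshold),
            class = "collinearity_screen")
}

pairwise_association <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  num_x <- is.numeric(x); num_y <- is.numeric(y)
  if (num_x && num_y) {
    return(abs(stats::cor(x, y)))
  }
  if (!num_x && !num_y) {
    tab <- table(x, y)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    return(as.numeric(sqrt(chi / (sum(tab) * (min(dim(tab)) - 1L)))))
  }
  num <- if (num_x) x else y
  cat_ <- factor(if (num_x) y else x)
  sqrt(summary(stats::lm(num ~ cat_))$r.squared)
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("<collinearity_screen> %d predictors, %d pair(s) above %.2f",
              nrow(x$measure), sum(x$flagged) / 2L, x$threshold))
  if (length(x$degenerate)) {
    cat(", degenerate:", paste(x$degenerate, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Select interactions by likelihood ratio and AIC
#'
#' Candidates are evaluated one at a time in the given order against the
#' current specification: both models are refitted by maximum likelihood and
#' compared by a likelihood-ratio test; the interaction is kept only when
#' the test is significant at `alpha` *and* the AIC decreases.
#'
#' @param data Data frame of analysis rows.
#' @param base A [model_spec()] holding the main effects.
#' @param candidates List of character pairs (members must be fixed effects
#'   of `base`).
#' @param alpha Significance level (default 0.05).
#' @return The updated `model_spec`; attribute `decisions` records the
#'   per-candidate p-value, AIC change and verdict.
#' @export
select_interactions <- function(data, base, candidates, alpha = 0.05) {
  stopifnot(inherits(base, "model_spec"))
  for (pair in candidates) {
    if (length(pair) != 2L || !all(pair %in% base$fixed)) {
      stop("candidate references absent main effect(s): ",
           paste(pair, collapse = ":"), call. = FALSE)
    }
  }
  prep <- prepare_model_data(data, base)
  spec <- prep$spec
  dat <- prep$data
  candidates <- Filter(function(p) all(p %in% spec$fixed), candidates)
  decisions <- data.frame(interaction = character(), p_value = numeric(),
                          delta_aic = numeric(), kept = logical(),
                          stringsAsFactors = FALSE)
  for (pair in candidates) {
    spec_with <- spec
    spec_with$interactions <- c(spec$interactions, list(pair))
    m0 <- fit_lmm_prepared(dat, spec, reml = FALSE)
    m1 <- fit_lmm_prepared(dat, spec_with, reml = FALSE)
    cmp <- suppressMessages(stats::anova(m0$model, m1$model))
    p <- cmp$`Pr(>Chisq)`[2L]
    d_aic <- m1$aic - m0$aic
    keep <- is.finite(p) && p < alpha && d_aic < 0
    if (keep) spec <- spec_with
    decisions <- rbind(decisions, data.frame(
      interaction = paste(pair, collapse = ":"), p_value = p,
      delta_aic = d_aic, kept = keep, stringsAsFactors = FALSE))
  }
  attr(spec, "decisions") <- decisions
  spec
}

#' Aggregate repeated-subsample fits
#'
#' The aggregation rule for repeated-subsample inference: per-term point
#' estimate and confidence bounds are the arithmetic means of the per-fit
#' values, and the p-value is the fraction of repetitions whose confidence
#' interval contains zero.
#'
#' @param estimates,ci_lower,ci_upper Numeric matrices, one row per
#'   repetition, one column per term (column names are term names).
#' @return Data frame with columns `term`, `estimate`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
aggregate_repetitions <- function(estimates, ci_lower, ci_upper) {
  stopifnot(is.matrix(estimates),
            all(dim(estimates) == dim(ci_lower)),
            all(dim(estimates) == dim(ci_upper)))
  data.frame(
    term = colnames(estimates),
    estimate = colMeans(estimates),
    ci_lower = colMeans(ci_lower),
    ci_upper = colMeans(ci_upper),
    p_value = colMeans(ci_lower <= 0 & ci_upper >= 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Repeated-subsample mixed-model inference
#'
#' Repeats `R` times: draw `K` activity records per dog without replacement
#' (dogs with fewer than `K` records contribute all their records), fit the
#' mixed model, and collect coefficients and Wald intervals. Results are
#' aggregated with [aggregate_repetitions()]: mean estimates, mean interval
#' bounds, and p-values equal to the fraction of repetitions whose interval
#' contains zero.
#'
#' @param data Data frame of analysis rows.
#' @param spec A [model_spec()].
#' @param K Records subsampled per dog per repetition.
#' @param R Number of repetitions.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `aggregated_inference`: `terms` (the aggregated
#'   data frame), `estimates`, `ci_lower`, `ci_upper` (R x p matrices),
#'   `R`, `K`, `seed`, `n_skipped`, and `template` (one full `activity_lmm`
#'   used for prediction scaffolding). Errors if more than 10% of
#'   repetitions fail to fit.
#' @export
resampled_inference <- function(data, spec, K = 50, R = 1000, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), K >= 1, R >= 1)
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_model_data(data, spec)
  dat <- prep$data
  spec <- prep$spec
  rows_by_dog <- split(seq_len(nrow(dat)), dat[[spec$group]])
  est <- lo <- hi <- NULL
  n_skipped <- 0L
  template <- NULL
  for (r in seq_len(R)) {
    idx <- unlist(lapply(rows_by_dog, function(ix)
      if (length(ix) <= K) ix else sample(ix, K)), use.names = FALSE)
    fit <- tryCatch(fit_lmm_prepared(dat[idx, , drop = FALSE], spec),
                    error = function(e) NULL)
    if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
    cf <- fit$coefficients
    if (is.null(est)) {
      p <- nrow(cf)
      est <- lo <- hi <- matrix(NA_real_, R, p,
                                dimnames = list(NULL, cf$term))
      template <- fit
    }
    if (!identical(cf$term, colnames(est))) { n_skipped <- n_skipped + 1L; next }
    est[r, ] <- cf$estimate
    lo[r, ] <- cf$ci_lower
    hi[r, ] <- cf$ci_upper
  }
  if (n_skipped > 0.1 * R || is.null(est)) {
    stop(n_skipped, " of ", R, " repetitions failed to fit", call. = FALSE)
  }
  keep <- stats::complete.cases(est)
  est <- est[keep, , drop = FALSE]
  lo <- lo[keep, , drop = FALSE]
  hi <- hi[keep, , drop = FALSE]
  structure(
    list(terms = aggregate_repetitions(est, lo, hi),
         estimates = est, ci_lower = lo, ci_upper = hi,
         R = R, K = K, seed = seed, n_skipped = n_skipped,
         template = template),
    class = "aggregated_inference"
  )
}

#' @export
print.aggregated_inference <- function(x, ...) {
  cat(sprintf("<aggregated_inference> %d terms over %d repetitions (K = %d, %d skipped)\n",
              nrow(x$terms), x$R, x$K, x$n_skipped))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Marginal means on the response scale
#'
#' Predicted active minutes for each level (or value) of a focal predictor,
#' holding other categorical predictors at their reference levels, continuous
#' predictors at their data means, and the random effect at zero. The
#' log-scale linear predictor is back-transformed with a plain exponential;
#' the optional log-normal bias correction `exp((var_random + var_residual)/2)`
#' is off by default. For a single fit the interval is the Wald interval of
#' the linear predictor; for aggregated inference it is the 2.5-97.5
#' percentile band of the per-repetition linear predictors.
#'
#' @param object An `activity_lmm` or `aggregated_inference`.
#' @param data The analysis data (source of continuous-variable means).
#' @param focal Focal predictor (must be in the model).
#' @param grid Levels or numeric values to predict at; defaults to the
#'   model's factor levels for a categorical focal.
#' @param bias_correct Apply the log-normal mean correction (default FALSE).
#' @return Data frame of class `marginal_means`: `level`, `linear_predictor`,
#'   `response`, `ci_lower`, `ci_upper`.
#' @export
estimate_marginal_means <- function(object, data, focal, grid = NULL,
                                    bias_correct = FALSE) {
  if (inherits(object, "aggregated_inference")) {
    fit <- object$template
    est_matrix <- object$estimates
  } else if (inherits(object, "activity_lmm")) {
    fit <- object
    est_matrix <- NULL
  } else {
    stop("object must be an activity_lmm or aggregated_inference", call. = FALSE)
  }
  spec <- fit$spec
  if (!focal %in% spec$fixed) {
    stop("focal predictor '", focal, "' is not in the model", call. = FALSE)
  }
  frame <- stats::model.frame(fit$model)
  xlev <- lapply(Filter(is.factor, frame), levels)
  dat <- as.data.frame(data)
  newdata <- list()
  for (v in spec$fixed) {
    col <- frame[[v]]
    if (is.factor(col)) {
      newdata[[v]] <- factor(levels(col)[1L], levels = levels(col))
    } else {
      newdata[[v]] <- mean(dat[[v]], na.rm = TRUE)
    }
  }
  if (is.null(grid)) {
    if (!is.factor(frame[[focal]])) {
      stop("grid must be supplied for a continuous focal predictor",
           call. = FALSE)
    }
    grid <- levels(frame[[focal]])
  }
  newdata <- as.data.frame(newdata)[rep(1L, length(grid)), , drop = FALSE]
  if (is.factor(frame[[focal]])) {
    bad <- setdiff(as.character(grid), levels(frame[[focal]]))
    if (length(bad)) {
      stop("grid level(s) absent from model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    newdata[[focal]] <- factor(as.character(grid),
                               levels = levels(frame[[focal]]))
  } else {
    newdata[[focal]] <- as.numeric(grid)
  }
  rownames(newdata) <- NULL
  X <- stats::model.matrix(fixed_rhs_formula(spec), newdata)
  b <- fit$coefficients$estimate
  names(b) <- fit$coefficients$term
  X <- X[, names(b), drop = FALSE]
  shift <- if (bias_correct) (fit$var_random + fit$var_residual) / 2 else 0
  if (is.null(est_matrix)) {
    eta <- as.numeric(X %*% b)
    V <- as.matrix(stats::vcov(fit$model))
    se <- sqrt(rowSums((X %*% V) * X))
    lo <- eta - 1.96 * se
    hi <- eta + 1.96 * se
  } else {
    etas <- X %*% t(est_matrix[, colnames(X), drop = FALSE])
    eta <- rowMeans(etas)
    qs <- apply(etas, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    lo <- qs[1L, ]
    hi <- qs[2L, ]
  }
  structure(
    data.frame(level = as.character(grid), linear_predictor = eta,
               response = exp(eta + shift),
               ci_lower = exp(lo + shift), ci_upper = exp(hi + shift),
               stringsAsFactors = FALSE),
    class = c("marginal_means", "data.frame")
  )
}

#' Grouped k-fold consistency check
#'
#' Dogs are partitioned into `k` near-equal groups (all records of a dog in
#' the same group); the model is fitted to each group and the spread of the
#' coefficients and performance metrics across folds is reported.
#'
#' @param data Data frame of analysis rows.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5); `k = 1` degenerates to a single fit
#'   with undefined SDs (flagged).
#' @param seed Integer seed for the dog shuffle.
#' @param folds Optional named integer vector assigning each dog to a fold,
#'   overriding the random partition.
#' @return List of class `kfold_consistency`: `folds` (per-fold `r2`,
#'   `rmse`), `coefficients` (k x p matrix), `coef_sd`, `r2_sd`, `rmse_sd`,
#'   `degenerate`.
#' @export
grouped_kfold_consistency <- function(data, spec, k = 5, seed = NULL,
                                      folds = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_model_data(data, spec)
  dat <- prep$data
  spec <- prep$spec
  dogs <- unique(as.character(dat[[spec$group]]))
  if (!is.null(folds)) {
    missing <- setdiff(dogs, names(folds))
    if (length(missing)) {
      stop("fold assignment missing for ", length(missing), " dog(s)",
           call. = FALSE)
    }
    fold_of <- folds[dogs]
    k <- length(unique(fold_of))
  }
  stopifnot(k >= 1)
  if (length(dogs) < k) {
    stop("fewer dogs (", length(dogs), ") than folds (", k, ")", call. = FALSE)
  }
  if (is.null(folds)) {
    fold_of <- stats::setNames(rep_len(seq_len(k), length(dogs)),
                               sample(dogs))
  }
  fits <- lapply(seq_len(k), function(f) {
    fold <- droplevels(dat[fold_of[as.character(dat[[spec$group]])] == f, ,
                           drop = FALSE])
    # a factor collapsing to one level within a fold makes its term
    # inestimable there; fit that fold without it
    estimable <- vapply(spec$fixed, function(v)
      is.numeric(fold[[v]]) || nlevels(fold[[v]]) >= 2L, logical(1L))
    fold_spec <- spec
    fold_spec$fixed <- spec$fixed[estimable]
    fold_spec$interactions <- Filter(function(p)
      all(p %in% fold_spec$fixed), spec$interactions)
    fit_lmm_prepared(fold, fold_spec)
  })
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  coefs <- t(vapply(fits, function(f) {
    stats::setNames(f$coefficients$estimate, f$coefficients$term)[terms]
  }, stats::setNames(numeric(length(terms)), terms)))
  colnames(coefs) <- terms
  folds <- data.frame(fold = seq_len(k),
                      r2 = vapply(fits, `[[`, numeric(1L), "r2_conditional"),
                      rmse = vapply(fits, `[[`, numeric(1L), "rmse"))
  degenerate <- k == 1L
  structure(
    list(folds = folds, coefficients = coefs,
         coef_sd = if (degenerate) rep(NA_real_, length(terms)) else
           apply(coefs, 2L, stats::sd, na.rm = TRUE),
         r2_sd = if (degenerate) NA_real_ else stats::sd(folds$r2),
         rmse_sd = if (degenerate) NA_real_ else stats::sd(folds$rmse),
         degenerate = degenerate),
    class = "kfold_consistency"
  )
}

#' True fixed-effect values for a fitted model's terms
#'
#' Maps a `simulation_truth` to the coefficient names of the standard
#' analysis model so recovered estimates can be compared with the generating
#' values term by term.
#'
#' @param truth A `simulation_truth` from [simulate_cohort()].
#' @param terms Character vector of model coefficient names.
#' @param age_var Age column name used in the model (default `"dog_age"`).
#' @return Named numeric vector of generating values, in `terms` order.
#' @export
expected_fixed_effects <- function(truth, terms, age_var = "dog_age") {
  ef <- truth$effects
  ia <- truth$interactions
  age_term <- sprintf("I(%s^-2)", age_var)
  dict <- c("(Intercept)" = truth$intercept,
            stats::setNames(truth$beta_age, age_term),
            latitude = unname(ef$latitude))
  for (v in c("breed_size", "sex", "neuter_status", "weight_status",
              "owner_age", "location_type", "climate", "season",
              "day_type")) {
    dict <- c(dict, stats::setNames(unname(ef[[v]]),
                                    paste0(v, names(ef[[v]]))))
  }
  for (lv in names(ia$size_age)) {
    val <- unname(ia$size_age[lv])
    dict <- c(dict,
              stats::setNames(val, paste0("breed_size", lv, ":", age_term)),
              stats::setNames(val, paste0(age_term, ":breed_size", lv)))
  }
  for (nm in names(ia$climate_season)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]  # season:climate
    val <- unname(ia$climate_season[nm])
    dict <- c(dict,
              stats::setNames(val, paste0("season", parts[1L], ":climate",
                                          parts[2L])),
              stats::setNames(val, paste0("climate", parts[2L], ":season",
                                          parts[1L])))
  }
  for (lv in names(ia$owner_day)) {
    val <- unname(ia$owner_day[lv])
    dict <- c(dict,
              stats::setNames(val, paste0("owner_age", lv, ":day_typeweekend")),
              stats::setNames(val, paste0("day_typeweekend:owner_age", lv)))
  }
  missing <- setdiff(terms, names(dict))
  if (length(missing)) {
    stop("no generating value for term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dict[terms]
}
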