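#' Fit a flexible boosted-tree model with a per-dog grouping adjustment
#'
#' Nonparametric companion to the linear mixed model: a gradient-boosted
#' tree ensemble is fitted to log active minutes on every supplied predictor
#' (no adjustment-set selection — a flexible learner is insensitive to which
#' covariates are confounders, so all of them go in). The repeated-measures
#' grouping is handled by a one-step backfit: after an initial fit, per-dog
#' residual means are shrunk empirical-Bayes style (using moment estimates of
#' the between- and within-dog variances) and the ensemble is refitted to the
#' outcome minus these shrunken dog effects. The dog effects are retained so
#' predictions for known dogs can include them.
#'
#' @param data Data frame of analysis rows.
#' @param predictors Character vector of predictor columns.
#' @param group Dog identifier column (needs at least 2 distinct dogs).
#' @param outcome Column of daily active minutes (strictly positive).
#' @param seed Integer seed (the fit is deterministic given the seed).
#' @param nrounds Boosting rounds per stage.
#' @param params Optional overrides of the boosting parameters.
#' @return Object of class `flexible_activity_model`.
#' @export
fit_flexible_model <- function(data, predictors, group, outcome = "active_minutes",
                               seed = 1L, nrounds = 400L, params = list()) {
  dat <- as.data.frame(data)
  missing <- setdiff(c(predictors, group, outcome), names(dat))
  if (length(missing)) {
    stop("column(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dogs <- as.character(dat[[group]])
  if (length(unique(dogs)) < 2L) {
    stop("at least two grouping levels (dogs) are required", call. = FALSE)
  }
  if (any(dat[[outcome]] <= 0)) {
    stop("outcome must be strictly positive before log transformation",
         call. = FALSE)
  }
  y <- log(dat[[outcome]])
  levels_map <- lapply(dat[predictors], function(v)
    if (is.numeric(v)) NULL else sort(unique(as.character(v))))
  X <- encode_predictors(dat, predictors, levels_map)
  pars <- utils::modifyList(
    list(objective = "reg:squarederror", eta = 0.05, max_depth = 4,
         subsample = 1, colsample_bytree = 1, min_child_weight = 10,
         nthread = 1, seed = seed),
    params)
  boost <- function(label) {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(label))
    xgboost::xgb.train(params = pars, data = dtrain,
                       nrounds = nrounds, verbose = 0)
  }
  stage1 <- boost(y)
  resid <- y - stats::predict(stage1, xgboost::xgb.DMatrix(X))
  r_dog <- tapply(resid, dogs, mean)
  n_dog <- tapply(resid, dogs, length)
  sigma2_hat <- sum((resid - r_dog[dogs])^2) /
    max(1L, length(resid) - length(r_dog))
  tau2_hat <- max(0, stats::var(as.numeric(r_dog)) -
                    sigma2_hat * mean(1 / n_dog))
  u <- r_dog * tau2_hat / (tau2_hat + sigma2_hat / n_dog)
  stage2 <- boost(y - u[dogs])
  structure(
    list(booster = stage2, u = u, predictors = predictors, group = group,
         outcome = outcome, levels_map = levels_map, seed = seed,
         tau2 = tau2_hat, sigma2 = sigma2_hat, nrounds = nrounds,
         engine = "xgboost gradient boosting with shrunken dog-effect backfit"),
    class = "flexible_activity_model"
  )
}

encode_predictors <- function(dat, predictors, levels_map) {
  mats <- lapply(predictors, function(v) {
    col <- dat[[v]]
    if (is.null(levels_map[[v]])) {
      m <- matrix(as.numeric(col), ncol = 1L)
      colnames(m) <- v
      m
    } else {
      lev <- levels_map[[v]]
      m <- outer(as.character(col), lev, `==`) * 1
      colnames(m) <- paste0(v, "=", lev)
      m
    }
  })
  do.call(cbind, mats)
}

#' Predict log or response-scale activity from a flexible model
#'
#' @param object A `flexible_activity_model`.
#' @param newdata Data frame with the predictor columns (and the group
#'   column when `include_group = TRUE`).
#' @param include_group Add the shrunken dog effect for known dogs
#'   (unknown dogs get 0).
#' @param type `"log"` (default) or `"response"` (exp back-transform).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.flexible_activity_model <- function(object, newdata,
                                            include_group = TRUE,
                                            type = c("log", "response"), ...) {
  type <- match.arg(type)
  X <- encode_predictors(as.data.frame(newdata), object$predictors,
                         object$levels_map)
  pred <- stats::predict(object$booster, xgboost::xgb.DMatrix(X))
  if (include_group && object$group %in% names(newdata)) {
    uu <- as.vector(object$u[as.character(newdata[[object$group]])])
    uu[is.na(uu)] <- 0
    pred <- pred + uu
  }
  if (type == "response") exp(pred) else pred
}

#' Partial dependence of a flexible model
#'
#' For each grid point the focal column is set to that value over the whole
#' data set, predictions (without dog effects) are averaged on the log scale
#' and back-transformed.
#'
#' @param model A `flexible_activity_model`.
#' @param data Data frame to average over.
#' @param focal Focal predictor.
#' @param grid Values/levels to evaluate.
#' @return Data frame with `level`, `linear_predictor` (mean log prediction)
#'   and `response`.
#' @export
partial_dependence <- function(model, data, focal, grid) {
  stopifnot(focal %in% model$predictors)
  dat <- as.data.frame(data)
  eta <- vapply(grid, function(g) {
    dat[[focal]] <- if (is.null(model$levels_map[[focal]])) as.numeric(g)
                    else as.character(g)
    mean(predict(model, dat, include_group = FALSE))
  }, numeric(1L))
  data.frame(level = as.character(grid), linear_predictor = eta,
             response = exp(eta), stringsAsFactors = FALSE)
}

#' Compare two prediction curves
#'
#' @param levels Grid labels common to both curves.
#' @param lmm Response-scale predictions from the linear mixed model.
#' @param flexible Response-scale predictions from the flexible model.
#' @param focal Optional focal-variable name for labelling.
#' @return Object of class `curve_comparison`: the per-level table plus
#'   `max_abs_diff` (minutes) and `rank_correlation` (Spearman).
#' @export
compare_curves <- function(levels, lmm, flexible, focal = NULL) {
  stopifnot(length(levels) == length(lmm), length(lmm) == length(flexible))
  rho <- if (length(lmm) >= 2L) {
    suppressWarnings(stats::cor(lmm, flexible, method = "spearman"))
  } else {
    NA_real_
  }
  structure(
    list(table = data.frame(level = as.character(levels), lmm = lmm,
                            flexible = flexible, stringsAsFactors = FALSE),
         max_abs_diff = max(abs(lmm - flexible)),
         rank_correlation = rho, focal = focal),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("<curve_comparison>%s rank correlation = %.3f, max |diff| = %.1f min\n",
              if (is.null(x$focal)) "" else paste0(" ", x$focal, ":"),
              x$rank_correlation, x$max_abs_diff))
  invisible(x)
}

#' Compare linear-model marginal means with flexible partial dependence
#'
#' Evaluates the flexible model's partial dependence on the marginal-means
#' grid and compares the two response-scale curves.
#'
#' @param lmm_table A `marginal_means` table from
#'   [estimate_marginal_means()].
#' @param flex_model A `flexible_activity_model`.
#' @param data Data frame for the partial-dependence average.
#' @param focal Focal predictor (same as used for `lmm_table`).
#' @param grid Grid; defaults to the marginal-means levels.
#' @return A [compare_curves()] object.
#' @export
compare_marginal_curves <- function(lmm_table, flex_model, data, focal,
                                    grid = NULL) {
  if (is.null(grid)) {
    grid <- if (is.null(flex_model$levels_map[[focal]]))
      as.numeric(lmm_table$level) else lmm_table$level
  }
  if (length(grid) != nrow(lmm_table) ||
      !identical(as.character(grid), lmm_table$level)) {
    stop("grid does not match the marginal-means table", call. = FALSE)
  }
  pd <- partial_dependence(flex_model, data, focal, grid)
  compare_curves(lmm_table$level, lmm_table$response, pd$response,
                 focal = focal)
}
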