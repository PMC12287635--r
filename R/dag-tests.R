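#' Test implied conditional independences against data
#'
#' Each claim `x _||_ y | given` is tested in the linear regime: both sides
#' are residualized on the (indicator-encoded) conditioning set by least
#' squares and the residual association is tested at level `alpha`.
#' Scalar-scalar pairs use the partial-correlation t test with
#' `df = n - 2 - q` (q = number of encoded conditioning columns); pairs with
#' one categorical member use the equivalent added-variable F test; pairs of
#' two categoricals use Pillai's trace on the indicator matrices.
#'
#' @param claims An `independence_claims` data frame from
#'   [implied_independences()] (or any data frame with columns `x`, `y` and a
#'   `given` list column).
#' @param data Data frame containing every claim variable as a column.
#'   Character columns are treated as categorical.
#' @param alpha Rejection level (default 0.05).
#' @return The claims with `p_value`, `rejected` and `skipped` filled in.
#'   Claims involving a constant column are skipped with a warning.
#' @examples
#' g <- parse_dag("A -> B\nB -> C")
#' dat <- simulate_dag_gaussian(g, 500, seed = 1)
#' test_independences(implied_independences(g), dat)
#' @export
test_independences <- function(claims, data, alpha = 0.05) {
  stopifnot(is.data.frame(claims), is.data.frame(data),
            alpha > 0, alpha < 1)
  vars <- unique(c(claims$x, claims$y, unlist(claims$given, use.names = FALSE)))
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("claim variable(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(claims))) {
    x <- claims$x[i]; y <- claims$y[i]
    given <- claims$given[[i]]
    cols <- c(x, y, given)
    dat <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
    if (any(vapply(dat, function(v) length(unique(v)) < 2L, logical(1L)))) {
      warning("claim ", x, " _||_ ", y, " skipped: constant column",
              call. = FALSE)
      claims$skipped[i] <- TRUE
      claims$p_value[i] <- NA_real_
      claims$rejected[i] <- NA
      next
    }
    p <- ci_test_p(dat[[x]], dat[[y]],
                   if (length(given)) dat[given] else NULL)
    claims$p_value[i] <- p
    claims$rejected[i] <- p < alpha
    claims$skipped[i] <- FALSE
  }
  claims
}

# Indicator encoding: factors/characters expand to treatment contrasts
# (intercept dropped), numerics pass through.
encode_columns <- function(df) {
  mats <- lapply(df, function(v) {
    if (is.numeric(v)) {
      matrix(v, ncol = 1L)
    } else {
      f <- factor(v)
      stats::model.matrix(~f)[, -1L, drop = FALSE]
    }
  })
  do.call(cbind, mats)
}

# p-value for x _||_ y | Z in the linear-residual regime.
ci_test_p <- function(x, y, Z = NULL) {
  Zm <- if (is.null(Z) || length(Z) == 0L) NULL else encode_columns(Z)
  n <- length(x)
  q <- if (is.null(Zm)) 0L else ncol(Zm)
  xm <- encode_columns(data.frame(v = x))
  ym <- encode_columns(data.frame(v = y))
  design0 <- cbind(`(Intercept)` = rep(1, n), Zm)
  rx <- stats::lm.fit(design0, xm)$residuals
  ry <- stats::lm.fit(design0, ym)$residuals
  rx <- as.matrix(rx); ry <- as.matrix(ry)
  if (ncol(rx) == 1L && ncol(ry) == 1L) {
    r <- stats::cor(rx[, 1L], ry[, 1L])
    df <- n - 2L - q
    if (df < 1L) return(NA_real_)
    if (1 - r^2 < 1e-12) return(0)
    tt <- r * sqrt(df / (1 - r^2))
    return(2 * stats::pt(-abs(tt), df))
  }
  if (ncol(rx) == 1L || ncol(ry) == 1L) {
    # added-variable F test with the scalar side as response
    if (ncol(ry) == 1L) { resp <- ry[, 1L]; pred <- rx } else {
      resp <- rx[, 1L]; pred <- ry
    }
    fit <- stats::lm.fit(cbind(1, pred), resp)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((resp - mean(resp))^2)
    p_num <- ncol(pred)
    df2 <- n - 1L - q - p_num
    if (df2 < 1L || rss1 < 1e-12) return(if (rss1 < 1e-12) 0 else NA_real_)
    Fstat <- ((rss0 - rss1) / p_num) / (rss1 / df2)
    return(stats::pf(Fstat, p_num, df2, lower.tail = FALSE))
  }
  # both categorical: Pillai's trace on residualized indicator matrices
  fit <- stats::manova(ry ~ rx)
  s <- summary(fit, test = "Pillai")$stats
  unname(s["rx", "Pr(>F)"])
}
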