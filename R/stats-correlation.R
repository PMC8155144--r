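#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (ties receive their average rank),
#' the robust default for modest samples where parametric assumptions may
#' fail. Two-tailed p from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval); pairwise-complete observations are used.
#' @return One-row tibble: `method`, `estimate`, `n`, `df`, `statistic`,
#'   `p.value`.
#' @export
cor_spearman <- function(data, x, y) {
  x <- data[[as_name(enquo(x))]]
  y <- data[[as_name(enquo(y))]]
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined.")
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    stat <- sign(r) * Inf
    p <- 0
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(stat), n - 2)
  }
  tibble(method = "spearman", estimate = r, n = n, df = n - 2L,
         statistic = stat, p.value = p)
}

#' Pearson (partial) correlation via covariate residualization
#'
#' With covariates, correlates the OLS residuals of `x` and `y` each
#' regressed on the covariates (plus intercept); with none, reduces to the
#' plain Pearson correlation. Two-level factors among the covariates are
#' dummy-coded. Two-tailed p from the t distribution on `n - 2 - k` df,
#' where k is the number of covariate columns. Optionally attaches a
#' percentile bootstrap confidence interval from case resampling.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @param boot_B If non-NULL, number of bootstrap resamples for a 95%
#'   percentile CI.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return One-row tibble: `method`, `estimate`, `n`, `df`, `statistic`,
#'   `p.value`, `covariates`, and `conf.low`/`conf.high` when bootstrapped.
#' @export
cor_partial <- function(data, x, y, covariates = character(),
                        boot_B = NULL, boot_seed = NULL) {
  x_col <- as_name(enquo(x))
  y_col <- as_name(enquo(y))
  assert_cols(data, c(x_col, y_col, covariates), "`data`")
  d <- as_tibble(data)[c(x_col, y_col, covariates)]
  d <- d[complete.cases(d), ]
  n <- nrow(d)

  Z <- if (length(covariates)) {
    mm <- model.matrix(~ ., data = d[covariates])
    mm[, -1, drop = FALSE]
  } else {
    matrix(nrow = n, ncol = 0)
  }
  k <- ncol(Z)
  if (n < k + 3) abort("need at least k + 3 complete cases.")
  if (k > 0 && qr(cbind(1, Z))$rank < k + 1) {
    abort("rank-deficient covariate set.")
  }

  xv <- as.numeric(d[[x_col]])
  yv <- as.numeric(d[[y_col]])
  rx <- if (k > 0) stats::lm.fit(cbind(1, Z), xv)$residuals else xv - mean(xv)
  ry <- if (k > 0) stats::lm.fit(cbind(1, Z), yv)$residuals else yv - mean(yv)
  tol_x <- 1e-10 * (sd(xv) + 1)
  tol_y <- 1e-10 * (sd(yv) + 1)
  if (sd(rx) <= tol_x || sd(ry) <= tol_y) {
    warn("a residualized variable is (numerically) constant; partial correlation set to 0.")
    r <- 0
  } else {
    r <- cor(rx, ry)
  }
  df <- n - 2L - k
  if (abs(r) >= 1) {
    stat <- sign(r) * Inf
    p <- 0
  } else {
    stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(stat), df)
  }
  out <- tibble(method = if (k > 0) "pearson_partial" else "pearson",
                estimate = r, n = n, df = df, statistic = stat, p.value = p,
                covariates = paste(covariates, collapse = ";"))
  if (!is.null(boot_B)) {
    ci <- bootstrap_ci(
      d, function(dd) {
        suppressWarnings(
          cor_partial(dd, !!rlang::sym(x_col), !!rlang::sym(y_col),
                      covariates = covariates)$estimate)
      },
      B = boot_B, seed = boot_seed)
    out$conf.low <- ci$conf.low
    out$conf.high <- ci$conf.high
  }
  out
}
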