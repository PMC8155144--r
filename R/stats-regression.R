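#' Hierarchical regression with a forced block and stepwise second block
#'
#' Block 1 terms are always in the model; block 2 candidates enter and
#' leave by the probability-of-F stepwise rule (enter the best candidate
#' while its p-value is below `entry`, remove the worst retained block-2
#' term while its p-value exceeds `removal`). Continuous predictors are
#' mean-centered before any products are formed; two-level categorical
#' predictors are dummy-coded 0/1 (and left uncentered). Interaction terms
#' are written `"a:b"` (product of the processed component columns) and
#' squared terms `"a^2"` (square of the centered column).
#'
#' The block-level change statistic compares the block-1-only model with
#' the final model:
#' `F = ((R2_full - R2_block1) / dk) / ((1 - R2_full) / df_resid_full)`.
#' Standardized coefficients are `b * sd(x) / sd(y)` over the design
#' columns actually entered (including dummy codes).
#'
#' @param data A data frame.
#' @param response Response column (tidy-eval).
#' @param block1 Character vector of forced terms.
#' @param block2 Character vector of stepwise candidate terms.
#' @param entry,removal Probability-of-F thresholds (defaults 0.05 / 0.10).
#' @param center Mean-center continuous predictors (default TRUE).
#' @return Object of class `hier_reg` with `terms`, `steps`, the final
#'   `lm` fit and block-comparison statistics; `tidy()` returns the term
#'   table, `glance()` the model-level summary.
#' @export
hierarchical_regression <- function(data, response, block1, block2 = character(),
                                    entry = 0.05, removal = 0.10,
                                    center = TRUE) {
  resp_col <- as_name(enquo(response))
  assert_cols(data, resp_col, "`data`")
  if (removal < entry) {
    abort("`removal` must be >= `entry` to prevent stepwise cycling.")
  }
  all_terms <- unique(c(block1, block2))
  cols <- build_design_columns(data, all_terms, center = center)
  y <- as.numeric(data[[resp_col]])
  keep <- complete.cases(y, cols)
  y <- y[keep]
  cols <- cols[keep, , drop = FALSE]
  n <- length(y)
  if (n <= length(all_terms) + 1) abort("too few complete cases for the design.")
  if (qr(cbind(1, as.matrix(cols)))$rank < ncol(cols) + 1) {
    abort("collinear design: some terms are linearly dependent.")
  }
  # model columns get syntactic names; `san_map` restores the term labels
  san <- function(t) gsub("[:^()]", "_", t)
  san_map <- setNames(all_terms, san(all_terms))
  names(cols) <- san(names(cols))

  fit_terms <- function(terms) {
    d <- cols[san(terms)]
    d$.y <- y
    lm(.y ~ ., data = d)
  }
  r2_of <- function(fit) summary(fit)$r.squared
  term_p <- function(fit, term) {
    co <- summary(fit)$coefficients
    co[san(term), 4]
  }

  in_model <- block1
  candidates <- setdiff(block2, block1)
  steps <- list()
  step_no <- 0L
  prev_r2 <- r2_of(fit_terms(in_model))
  repeat {
    changed <- FALSE
    if (length(candidates)) {
      ps <- purrr::map_dbl(candidates, function(tm) {
        term_p(fit_terms(c(in_model, tm)), tm)
      })
      ps[is.na(ps)] <- 1  # aliased or saturated fits never enter
      if (min(ps) < entry) {
        best <- candidates[which.min(ps)]
        in_model <- c(in_model, best)
        candidates <- setdiff(candidates, best)
        step_no <- step_no + 1L
        r2 <- r2_of(fit_terms(in_model))
        df2 <- n - length(in_model) - 1L
        fch <- ((r2 - prev_r2) / 1) / ((1 - r2) / df2)
        steps[[step_no]] <- tibble(
          step = step_no, action = "enter", term = best,
          r.squared = r2, delta_r2 = r2 - prev_r2,
          f_change = fch, df1 = 1L, df2 = df2,
          p.value = pf(fch, 1, df2, lower.tail = FALSE))
        prev_r2 <- r2
        changed <- TRUE
      }
    }
    removable <- setdiff(in_model, block1)
    if (length(removable)) {
      fit <- fit_terms(in_model)
      ps <- purrr::map_dbl(removable, function(tm) term_p(fit, tm))
      ps[is.na(ps)] <- 1  # aliased terms are dropped
      if (max(ps) > removal) {
        worst <- removable[which.max(ps)]
        in_model <- setdiff(in_model, worst)
        candidates <- union(candidates, worst)
        step_no <- step_no + 1L
        r2 <- r2_of(fit_terms(in_model))
        df2_prev <- n - length(in_model) - 2L
        fch <- ((prev_r2 - r2) / 1) / ((1 - prev_r2) / df2_prev)
        steps[[step_no]] <- tibble(
          step = step_no, action = "remove", term = worst,
          r.squared = r2, delta_r2 = r2 - prev_r2,
          f_change = fch, df1 = 1L, df2 = df2_prev,
          p.value = pf(fch, 1, df2_prev, lower.tail = FALSE))
        prev_r2 <- r2
        changed <- TRUE
      }
    }
    if (!changed || step_no > 50L) break
  }

  final <- fit_terms(in_model)
  sm <- summary(final)
  co <- sm$coefficients
  labels <- c("(Intercept)", unname(san_map[rownames(co)[-1]]))
  sds <- vapply(cols[rownames(co)[-1]], sd, numeric(1))
  terms_tbl <- tibble(
    term = labels,
    estimate = unname(co[, 1]),
    std_beta = unname(c(NA_real_, co[-1, 1] * sds / sd(y))),
    std.error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    df = final$df.residual,
    p.value = unname(co[, 4])
  )
  r2_b1 <- r2_of(fit_terms(block1))
  r2_full <- sm$r.squared
  dk <- length(in_model) - length(block1)
  df2 <- final$df.residual
  f_change <- if (dk > 0) ((r2_full - r2_b1) / dk) / ((1 - r2_full) / df2) else NA_real_
  structure(
    list(terms = terms_tbl,
         steps = if (length(steps)) bind_rows(steps) else
           tibble(step = integer(), action = character(), term = character(),
                  r.squared = double(), delta_r2 = double(),
                  f_change = double(), df1 = integer(), df2 = integer(),
                  p.value = double()),
         entered = in_model, block1 = block1,
         fit = final, n = n,
         r.squared = r2_full, adj.r.squared = sm$adj.r.squared,
         block1_r2 = r2_b1, delta_r2 = r2_full - r2_b1,
         f_change = f_change, f_change_df1 = dk, f_change_df2 = df2,
         p.value_change = if (dk > 0) pf(f_change, dk, df2, lower.tail = FALSE)
         else NA_real_),
    class = "hier_reg"
  )
}

#' @export
tidy.hier_reg <- function(x, ...) x$terms

#' @export
glance.hier_reg <- function(x, ...) {
  f <- summary(x$fit)$fstatistic
  tibble(r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
         block1_r2 = x$block1_r2, delta_r2 = x$delta_r2,
         f_change = x$f_change, f_change_df1 = x$f_change_df1,
         f_change_df2 = x$f_change_df2, p.value_change = x$p.value_change,
         statistic = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
         p.value = pf(f[1], f[2], f[3], lower.tail = FALSE), n = x$n)
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("Hierarchical regression (n = %d): block 1 [%s]; entered [%s]\n",
              x$n, paste(x$block1, collapse = ", "),
              paste(setdiff(x$entered, x$block1), collapse = ", ")))
  cat(sprintf("R2 = %.4f (block 1: %.4f); dR2 = %.4f, F-change(%d,%d) = %.3f, p = %.4g\n",
              x$r.squared, x$block1_r2, x$delta_r2, x$f_change_df1,
              x$f_change_df2, x$f_change, x$p.value_change))
  print(x$terms)
  invisible(x)
}

# Build processed design columns for term strings: plain columns
# (centered if continuous), "a^2" squares of centered columns, and "a:b"
# products of processed components. Two-level factors become 0/1 dummies.
build_design_columns <- function(data, terms, center = TRUE) {
  base_cache <- list()
  base_col <- function(nm) {
    if (!is.null(base_cache[[nm]])) return(base_cache[[nm]])
    if (!nm %in% names(data)) {
      abort(sprintf("term component `%s` is not a column of `data`.", nm))
    }
    v <- data[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) != 2) {
        abort(sprintf("`%s`: only two-level factors are dummy-coded; recode first.", nm))
      }
      out <- as.numeric(f) - 1
    } else if (is.logical(v)) {
      out <- as.numeric(v)
    } else {
      out <- as.numeric(v)
      if (center) out <- out - mean(out, na.rm = TRUE)
    }
    base_cache[[nm]] <<- out
    out
  }
  term_col <- function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, term_col))
    } else if (grepl("\\^2$", tm)) {
      base_col(sub("\\^2$", "", tm))^2
    } else {
      base_col(tm)
    }
  }
  out <- purrr::map(setNames(terms, terms), term_col)
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Quadratic-term model comparison
#'
#' Tests whether a centered quadratic term improves on the linear model:
#' fits `y ~ x` and `y ~ x + x^2` (x mean-centered before squaring) and
#' reports the R-squared change with its F test, alongside the quadratic
#' model's own fit statistics.
#'
#' @param data A data frame.
#' @param response,x Columns (tidy-eval).
#' @return One-row tibble with the linear and quadratic R-squared, the
#'   quadratic model's adjusted R-squared and overall F, the quadratic
#'   coefficient, and the `delta_r2` F-change test.
#' @export
quadratic_term_model <- function(data, response, x) {
  resp_col <- as_name(enquo(response))
  x_col <- as_name(enquo(x))
  assert_cols(data, c(resp_col, x_col), "`data`")
  d <- tibble(y = as.numeric(data[[resp_col]]),
              x = as.numeric(data[[x_col]]))
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n < 4) abort("need at least 4 complete cases.")
  d$xc <- d$x - mean(d$x)
  d$xc2 <- d$xc^2
  fit1 <- lm(y ~ xc, data = d)
  fit2 <- lm(y ~ xc + xc2, data = d)
  s1 <- summary(fit1)
  s2 <- summary(fit2)
  df2 <- fit2$df.residual
  delta <- s2$r.squared - s1$r.squared
  fch <- if (s2$r.squared >= 1) Inf else (delta / 1) / ((1 - s2$r.squared) / df2)
  tibble(
    n = n,
    r2_linear = s1$r.squared,
    r2_quadratic = s2$r.squared,
    adj_r2_quadratic = s2$adj.r.squared,
    estimate_linear = unname(coef(fit2)["xc"]),
    estimate_quadratic = unname(coef(fit2)["xc2"]),
    f_model = unname(s2$fstatistic[1]),
    df1_model = unname(s2$fstatistic[2]),
    df2_model = unname(s2$fstatistic[3]),
    p_model = pf(s2$fstatistic[1], s2$fstatistic[2], s2$fstatistic[3],
                 lower.tail = FALSE),
    delta_r2 = delta,
    f_change = fch,
    df1 = 1,
    df2 = df2,
    p.value = if (is.infinite(fch)) 0 else pf(fch, 1, df2, lower.tail = FALSE)
  )
}
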