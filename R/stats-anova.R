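#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot F tests for a balanced within-subject factor, an optional
#' between-subject grouping factor, and their interaction. The
#' Greenhouse-Geisser epsilon is computed from the pooled within-subject
#' covariance (group-mean centered, error df n - g) through orthonormal
#' contrasts, together with Mauchly's sphericity test. With `gg = "auto"`
#' the corrected degrees of freedom are adopted for the within-stratum
#' tests when the within factor has more than two levels and Mauchly's
#' test rejects at `sphericity_alpha`; `"always"` forces the correction
#' and `"never"` disables it (both uncorrected and corrected p-values are
#' always reported). Polynomial (linear, quadratic, ...) within-factor
#' contrasts are tested on per-subject contrast scores, with the
#' between-group interaction contrast when a grouping factor is present.
#'
#' With unbalanced groups the omnibus table uses sequential
#' (within-stratum orthogonal) sums of squares from [stats::aov()].
#'
#' @param data Long table, one row per subject x within-level.
#' @param subject,within,response Columns (tidy-eval).
#' @param between Optional between-subject factor column (tidy-eval).
#' @param gg Sphericity-handling rule: `"auto"`, `"always"`, `"never"`.
#' @param sphericity_alpha Rejection level of the Mauchly pretest under
#'   `"auto"`.
#' @return Object of class `rm_anova`: `effects` tibble (per-effect F,
#'   uncorrected and GG-corrected df/p, whether the correction was
#'   applied), `epsilon`, `mauchly_w`, `mauchly_p`, `contrasts` tibble,
#'   `n_subjects`, `k_levels`. `tidy()` returns the effects table.
#' @export
rm_anova_gg <- function(data, subject, within, response, between = NULL,
                        gg = c("auto", "always", "never"),
                        sphericity_alpha = 0.05) {
  gg <- match.arg(gg)
  subj_col <- as_name(enquo(subject))
  within_col <- as_name(enquo(within))
  resp_col <- as_name(enquo(response))
  btw_quo <- enquo(between)
  btw_col <- if (rlang::quo_is_null(btw_quo)) NULL else as_name(btw_quo)
  assert_cols(data, c(subj_col, within_col, resp_col, btw_col), "`data`")

  d <- tibble(
    .subj = factor(data[[subj_col]]),
    .w = factor(data[[within_col]]),
    .y = as.numeric(data[[resp_col]]),
    .g = if (is.null(btw_col)) factor("all") else factor(data[[btw_col]])
  )
  if (anyNA(d$.y)) abort("missing response cells are not supported.")
  k <- nlevels(d$.w)
  if (k < 2) abort("the within factor needs at least 2 levels.")

  wide <- tidyr::pivot_wider(d, id_cols = c(".subj", ".g"),
                             names_from = ".w", values_from = ".y")
  Y <- as.matrix(wide[-(1:2)])
  if (anyNA(Y)) abort("unbalanced within-factor design: missing cells.")
  n <- nrow(Y)
  grp <- wide$.g
  g <- nlevels(droplevels(grp))
  if (n - g < 1) abort("no residual degrees of freedom between subjects.")

  # pooled within-group covariance of the k within-level responses
  gf <- droplevels(grp)
  Yc <- Y
  for (lev in levels(gf)) {
    idx <- gf == lev
    Yc[idx, ] <- scale(Y[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  S <- crossprod(Yc) / (n - g)
  C <- t(contr.poly(k)) # orthonormal contrast rows
  M <- C %*% S %*% t(C)
  tr <- sum(diag(M))
  if (tr <= 0) {
    eps <- 1
    mauchly_w <- NA_real_
    mauchly_p <- NA_real_
  } else {
    eps <- tr^2 / ((k - 1) * sum(M * M))
    if (k == 2) {
      mauchly_w <- 1
      mauchly_p <- NA_real_
    } else {
      # sphericity pretest on the orthonormal contrasts of the mlm residuals
      mt <- tryCatch({
        mlm <- if (g > 1) lm(Y ~ gf) else lm(Y ~ 1)
        stats::mauchly.test(mlm, X = ~ 1,
                            idata = data.frame(.w = factor(seq_len(k))))
      }, error = function(e) NULL)
      if (is.null(mt)) {
        mauchly_w <- NA_real_
        mauchly_p <- NA_real_
      } else {
        mauchly_w <- unname(mt$statistic)
        mauchly_p <- mt$p.value
      }
    }
  }

  form <- if (g > 1) .y ~ .g * .w + Error(.subj) else .y ~ .w + Error(.subj)
  fit <- aov(form, data = d)
  tabs <- summary(fit)
  effects <- purrr::imap(tabs, function(tab, stratum) {
    tt <- as.data.frame(tab[[1]])
    tt$term <- trimws(rownames(tt))
    tt$stratum <- gsub("^Error: ", "", stratum)
    tt
  }) |>
    bind_rows() |>
    as_tibble()
  resid_rows <- effects$term == "Residuals"
  ms_resid <- setNames(effects$`Mean Sq`[resid_rows], effects$stratum[resid_rows])
  df_resid <- setNames(effects$Df[resid_rows], effects$stratum[resid_rows])
  effects <- filter(effects, .data$term != "Residuals")

  rename_term <- function(t) {
    t <- gsub("\\.g", btw_col %||% "group", t)
    gsub("\\.w", within_col, t)
  }
  within_stratum <- effects$stratum != ".subj"
  correct <- gg == "always" || (gg == "auto" && k > 2 &&
                                  !is.na(mauchly_p) &&
                                  mauchly_p < sphericity_alpha)
  ss_tol <- 1e-10 * max(sum(abs(effects$`Sum Sq`)), sum(Yc^2), 1)
  null_effect <- effects$`Sum Sq` < ss_tol
  out <- tibble(
    effect = rename_term(effects$term),
    within_stratum = within_stratum,
    df1 = unname(effects$Df),
    df2 = unname(df_resid[effects$stratum]),
    statistic = if_else(null_effect, 0, unname(effects$`F value`)),
    p.value = if_else(null_effect, 1, unname(effects$`Pr(>F)`))
  ) |>
    mutate(
      df1_gg = if_else(.data$within_stratum, .data$df1 * eps, .data$df1),
      df2_gg = if_else(.data$within_stratum, .data$df2 * eps, .data$df2),
      p.value_gg = if_else(
        .data$statistic == 0, 1,
        pf(.data$statistic, .data$df1_gg, .data$df2_gg, lower.tail = FALSE)),
      gg_applied = correct & .data$within_stratum
    )

  # polynomial within-factor contrasts on per-subject scores
  poly_names <- c("linear", "quadratic", "cubic",
                  paste0("order", seq_len(max(0, k - 4)) + 4))
  contrasts <- purrr::map(seq_len(k - 1), function(j) {
    s <- as.numeric(Y %*% contr.poly(k)[, j])
    if (g > 1) {
      gf <- droplevels(grp)
      cf <- lm(s ~ gf, contrasts = list(gf = "contr.sum"))
      sm <- summary(cf)$coefficients
      an <- anova(cf)
      bind_rows(
        tibble(term = within_col, contrast = poly_names[j],
               df1 = 1, df2 = n - g,
               statistic = sm[1, 3]^2, p.value = sm[1, 4]),
        tibble(term = paste0(btw_col %||% "group", ":", within_col),
               contrast = poly_names[j],
               df1 = an$Df[1], df2 = n - g,
               statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1])
      )
    } else {
      m <- mean(s)
      se <- sd(s) / sqrt(n)
      stat <- if (se == 0) 0 else (m / se)^2
      tibble(term = within_col, contrast = poly_names[j],
             df1 = 1, df2 = n - 1,
             statistic = stat,
             p.value = if (se == 0) 1 else pf(stat, 1, n - 1, lower.tail = FALSE))
    }
  }) |> bind_rows()

  structure(
    list(effects = select(out, -"within_stratum"),
         epsilon = eps, mauchly_w = mauchly_w, mauchly_p = mauchly_p,
         gg_applied = correct, contrasts = contrasts,
         n_subjects = n, k_levels = k),
    class = "rm_anova"
  )
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(epsilon = x$epsilon, mauchly_w = x$mauchly_w,
         mauchly_p = x$mauchly_p, gg_applied = x$gg_applied,
         n_subjects = x$n_subjects, k_levels = x$k_levels)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (n = %d subjects, %d within levels)\n",
    x$n_subjects, x$k_levels))
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f (Mauchly W = %s, p = %s); %s\n",
              x$epsilon,
              format(x$mauchly_w, digits = 4),
              format(x$mauchly_p, digits = 4),
              if (x$gg_applied) "correction applied" else "uncorrected df reported"))
  print(x$effects)
  invisible(x)
}
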