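test_that("spearman correlation is the rank Pearson with averaged ties", {
  d <- tibble::tibble(x = 1:8, y = (1:8)^3)
  expect_equal(cor_spearman(d, x, y)$estimate, 1)
  expect_equal(cor_spearman(dplyr::mutate(d, y = -y), x, y)$estimate, -1)
  # tie case: average ranks (1.5, 1.5, 3) vs (1, 3, 2) are uncorrelated
  tie <- tibble::tibble(x = c(1, 1, 2), y = c(3, 5, 4))
  expect_equal(cor_spearman(tie, x, y)$estimate, 0)
  withr::with_seed(1, {
    r <- tibble::tibble(x = rnorm(40), y = rnorm(40) + 0.5 * x)
  })
  ct <- suppressWarnings(cor.test(r$x, r$y, method = "spearman"))
  mine <- cor_spearman(r, x, y)
  expect_equal(mine$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(mine$df, 38)
  expect_error(cor_spearman(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "constant")
})

test_that("partial correlation agrees with the recursive closed form", {
  withr::with_seed(2, {
    d <- tibble::tibble(z = rnorm(8), x = rnorm(8) + z, y = rnorm(8) - z)
  })
  mine <- cor_partial(d, x, y, covariates = "z")
  rxy <- cor(d$x, d$y)
  rxz <- cor(d$x, d$z)
  ryz <- cor(d$y, d$z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(mine$estimate, closed, tolerance = 1e-10)
  expect_equal(mine$df, 8 - 2 - 1)
  # residual-correlation path and recursion agree on larger random draws too
  withr::with_seed(3, {
    big <- tibble::tibble(z1 = rnorm(60), z2 = rnorm(60),
                          x = rnorm(60) + z1 - z2, y = rnorm(60) + z2)
  })
  two <- cor_partial(big, x, y, covariates = c("z1", "z2"))
  r_xy.1 <- function(a, b, c) (a - b * c) / sqrt((1 - b^2) * (1 - c^2))
  step1_xy <- r_xy.1(cor(big$x, big$y), cor(big$x, big$z1), cor(big$y, big$z1))
  step1_xz2 <- r_xy.1(cor(big$x, big$z2), cor(big$x, big$z1), cor(big$z2, big$z1))
  step1_yz2 <- r_xy.1(cor(big$y, big$z2), cor(big$y, big$z1), cor(big$z2, big$z1))
  expect_equal(two$estimate, r_xy.1(step1_xy, step1_xz2, step1_yz2),
               tolerance = 1e-10)
})

test_that("partial correlation reduces to Pearson and guards degenerate y", {
  withr::with_seed(4, d <- tibble::tibble(x = rnorm(20), y = rnorm(20)))
  expect_equal(cor_partial(d, x, y)$estimate, cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(cor_partial(d, x, y)$method, "pearson")
  lin <- dplyr::mutate(d, w = 2 * x + 1, y2 = 3 * x - 2)
  expect_warning(res <- cor_partial(lin, w, y2, covariates = "x"), "constant")
  expect_equal(res$estimate, 0)
  expect_error(cor_partial(dplyr::mutate(d, z1 = x, z2 = x), z1, y,
                           covariates = c("z1", "z2")), "rank-deficient")
})

test_that("two-level factors are dummy-coded as partial covariates", {
  withr::with_seed(5, {
    d <- tibble::tibble(g = rep(c("a", "b"), 15),
                        x = rnorm(30) + (g == "b"),
                        y = rnorm(30) - (g == "b"))
  })
  via_factor <- cor_partial(d, x, y, covariates = "g")
  via_dummy <- cor_partial(dplyr::mutate(d, gd = as.numeric(g == "b")),
                           x, y, covariates = "gd")
  expect_equal(via_factor$estimate, via_dummy$estimate, tolerance = 1e-12)
  expect_equal(via_factor$df, 30 - 3)
})

test_that("repeated-measures ANOVA matches the hand-worked within-subject toy", {
  y <- c(10, 12, 14, 11, 11, 15, 9, 13, 12, 12, 14, 18, 10, 10, 13, 11, 12, 16)
  d <- tibble::tibble(subj = rep(1:6, each = 3),
                      tp = rep(c("t1", "t2", "t3"), 6), y = y)
  a <- rm_anova_gg(d, subj, tp, y)
  eff <- tidy(a)
  # frozen oracle values from an independent repeated-measures implementation
  expect_equal(eff$statistic[eff$effect == "tp"], 21.283185840708,
               tolerance = 1e-9)
  expect_equal(eff$p.value[eff$effect == "tp"], 2.491494842564e-04,
               tolerance = 1e-8)
  expect_equal(a$epsilon, 0.747687082797, tolerance = 1e-9)
  expect_equal(eff$p.value_gg[eff$effect == "tp"], 1.199576512269e-03,
               tolerance = 1e-8)
  expect_equal(a$mauchly_w, 0.662542094134, tolerance = 1e-9)
  expect_equal(a$mauchly_p, 4.389620264998e-01, tolerance = 1e-8)
  # corrected df are epsilon times the uncorrected df
  expect_equal(eff$df1_gg[eff$effect == "tp"], 2 * a$epsilon)
  expect_equal(eff$df2_gg[eff$effect == "tp"], 10 * a$epsilon)
})

test_that("ANOVA degenerate and two-level cases behave as defined", {
  d0 <- tibble::tibble(subj = rep(1:5, each = 3),
                       tp = rep(c("a", "b", "c"), 5),
                       y = rep(c(3, 7, 1, 5, 2), each = 3))
  a0 <- rm_anova_gg(d0, subj, tp, y)
  expect_equal(tidy(a0)$statistic[tidy(a0)$effect == "tp"], 0)
  d2 <- tibble::tibble(subj = rep(1:6, each = 2), tp = rep(c("a", "b"), 6),
                       y = rnorm(12))
  a2 <- rm_anova_gg(d2, subj, tp, y)
  expect_equal(a2$epsilon, 1)
  eff2 <- tidy(a2)
  expect_equal(eff2$df1_gg, eff2$df1)
  expect_equal(eff2$df2_gg, eff2$df2)
})

test_that("epsilon is exactly 1 under compound symmetry and bounded otherwise", {
  # rows = all permutations of (1,2,3): the sample covariance is exactly
  # compound symmetric
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  d <- tibble::tibble(subj = rep(1:6, each = 3),
                      tp = rep(c("a", "b", "c"), 6),
                      y = as.numeric(t(perms)))
  expect_equal(rm_anova_gg(d, subj, tp, y)$epsilon, 1, tolerance = 1e-12)
  withr::with_seed(6, {
    for (k in c(3, 4, 5)) {
      n <- 12
      y <- as.numeric(t(matrix(rnorm(n * k), n, k) %*%
                          matrix(rnorm(k * k), k, k)))
      dd <- tibble::tibble(subj = rep(1:n, each = k),
                           tp = rep(paste0("t", 1:k), n), y = y)
      eps <- rm_anova_gg(dd, subj, tp, y)$epsilon
      expect_gte(eps, 1 / (k - 1) - 1e-12)
      expect_lte(eps, 1 + 1e-12)
    }
  })
})

test_that("Mauchly's test agrees with the reference implementation", {
  withr::with_seed(7, Y <- matrix(rnorm(60), 15, 4))
  d <- tibble::tibble(subj = rep(1:15, each = 4),
                      tp = rep(paste0("t", 1:4), 15),
                      y = as.numeric(t(Y)))
  a <- rm_anova_gg(d, subj, tp, y)
  mlm <- lm(Y ~ 1)
  ref <- mauchly.test(mlm, X = ~ 1,
                      idata = data.frame(tp = factor(1:4)))
  expect_equal(a$mauchly_w, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(a$mauchly_p, ref$p.value, tolerance = 1e-9)
})

test_that("split-plot ANOVA separates between and within strata", {
  withr::with_seed(8, {
    d <- tidyr::expand_grid(subj = 1:12, tp = c("pre", "post")) |>
      dplyr::mutate(grp = ifelse(subj <= 6, "ctrl", "case"),
                    y = rnorm(24) + 2 * (grp == "case") +
                      1.5 * (tp == "post" & grp == "case"))
  })
  a <- rm_anova_gg(d, subj, tp, y, between = grp)
  eff <- tidy(a)
  expect_setequal(eff$effect, c("grp", "tp", "grp:tp"))
  # cross-check all three F statistics against stats::aov on the same data
  d$tp <- factor(d$tp)
  d$grp <- factor(d$grp)
  ref <- summary(aov(y ~ grp * tp + Error(factor(subj)), data = d))
  ref_f <- c(ref[[1]][[1]]$`F value`[1], ref[[2]][[1]]$`F value`[1:2])
  expect_equal(eff$statistic[match(c("grp", "tp", "grp:tp"), eff$effect)],
               ref_f, tolerance = 1e-9)
  # polynomial contrasts exist for the within factor and the interaction
  expect_setequal(a$contrasts$term, c("tp", "grp:tp"))
})

test_that("stepwise hierarchical regression obeys entry and removal rules", {
  withr::with_seed(9, {
    n <- 120
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
    d$y <- 2 * d$x1 + 0.8 * d$x2 + rnorm(n)
    # candidate exactly orthogonal to the response given block 1
    d$orth <- resid(lm(rnorm(n) ~ d$x1 + d$x2 + d$y))
  })
  fit <- hierarchical_regression(d, y, block1 = "x1",
                                 block2 = c("x2", "orth"))
  expect_true("x2" %in% fit$entered)
  expect_false("orth" %in% fit$entered)
  expect_equal(fit$steps$term[1], "x2")
  expect_identical(fit$steps$action, "enter")
  # same data and thresholds give an identical trace
  fit2 <- hierarchical_regression(d, y, block1 = "x1",
                                  block2 = c("x2", "orth"))
  expect_equal(fit$steps, fit2$steps)
  # an exact block-1 fit leaves nothing to enter
  d$y_exact <- 3 * d$x1 - 1
  fit3 <- suppressWarnings(
    hierarchical_regression(d, y_exact, block1 = "x1",
                            block2 = c("x2", "orth")))
  expect_equal(fit3$r.squared, 1, tolerance = 1e-12)
  expect_length(setdiff(fit3$entered, "x1"), 0)
})

test_that("the block F-change matches its closed form on a small table", {
  withr::with_seed(10, {
    d <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10))
    d$y <- d$x1 + 2 * d$x2 + rnorm(10, 0, 0.3)
  })
  fit <- hierarchical_regression(d, y, block1 = "x1", block2 = "x2",
                                 entry = 0.99, removal = 0.995)
  r2_1 <- summary(lm(y ~ x1, data = d))$r.squared
  r2_2 <- summary(lm(y ~ x1 + x2, data = d))$r.squared
  f_manual <- ((r2_2 - r2_1) / 1) / ((1 - r2_2) / 7)
  expect_equal(fit$f_change, f_manual, tolerance = 1e-10)
  expect_equal(fit$block1_r2, r2_1, tolerance = 1e-12)
  # the entering step's F-change equals the squared t of the new term
  t_x2 <- summary(lm(y ~ x1 + x2, data = d))$coefficients["x2", 3]
  expect_equal(fit$steps$f_change[1], t_x2^2, tolerance = 1e-10)
})

test_that("interaction and squared terms are built from centered columns", {
  withr::with_seed(11, {
    d <- tibble::tibble(a = rnorm(80, 10), g = rep(c("x", "z"), 40))
    d$y <- 0.5 * (d$a - mean(d$a)) * (d$g == "z") + rnorm(80, 0, 0.4)
  })
  fit <- hierarchical_regression(d, y, block1 = c("a", "g"), block2 = "a:g")
  expect_true("a:g" %in% fit$entered)
  tt <- tidy(fit)
  # the built interaction column is centered(a) * dummy(g): the estimate
  # equals a direct lm on those columns
  ac <- d$a - mean(d$a)
  gd <- as.numeric(d$g == "z")
  ref <- lm(d$y ~ ac + gd + I(ac * gd))
  expect_equal(unname(tt$estimate[tt$term == "a:g"]),
               unname(coef(ref)[4]), tolerance = 1e-10)
  # standardized beta uses sd(x)/sd(y) of the built column
  built <- ac * gd
  b <- unname(tt$estimate[tt$term == "a:g"])
  expect_equal(unname(tt$std_beta[tt$term == "a:g"]),
               b * sd(built) / sd(d$y), tolerance = 1e-10)
  quad <- hierarchical_regression(
    dplyr::mutate(d, y2 = (a - mean(a))^2 + rnorm(80, 0, 0.1)),
    y2, block1 = "a", block2 = "a^2")
  expect_true("a^2" %in% quad$entered)
})

test_that("quadratic-term comparison detects curvature and ignores lines", {
  x <- seq(-3, 3, length.out = 30)
  pure <- tibble::tibble(pss = x, y = 2 + 0.5 * x - 1.2 * (x - mean(x))^2)
  q <- suppressWarnings(quadratic_term_model(pure, y, pss))
  expect_equal(q$r2_quadratic, 1, tolerance = 1e-12)
  expect_equal(q$estimate_quadratic, -1.2, tolerance = 1e-9)
  expect_lt(q$p.value, 1e-12)
  # under a purely linear law the quadratic term's type-I rate is nominal
  withr::with_seed(12, {
    pvals <- replicate(200, {
      d <- tibble::tibble(pss = rnorm(40, 10, 4))
      d$y <- 1 - 2 * d$pss + rnorm(40)
      quadratic_term_model(d, y, pss)$p.value
    })
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("Steiger's Z has the stated symmetries and matches the frozen oracle", {
  expect_equal(steiger_z(0.4, 0.4, 0.2, 30)$statistic, 0)
  a <- steiger_z(0.5, 0.1, 0.3, 50)
  b <- steiger_z(0.1, 0.5, 0.3, 50)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  # independent implementation of the Z1* formula gives these values
  expect_equal(a$statistic, 2.525652018198823, tolerance = 1e-10)
  expect_equal(a$p.value, 0.01154838062745734, tolerance = 1e-10)
  expect_error(steiger_z(1, 0.5, 0.2, 30), "\\|r\\| < 1")
  expect_error(steiger_z(0.5, 0.2, 0.1, 3), "n >= 4")
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  x <- rep(4.2, 25)
  ci <- bootstrap_ci(x, mean, B = 200, seed = 1)
  expect_equal(ci$conf.low, 4.2)
  expect_equal(ci$conf.high, 4.2)
  withr::with_seed(13, y <- rnorm(40))
  c1 <- bootstrap_ci(y, mean, B = 500, seed = 99)
  c2 <- bootstrap_ci(y, mean, B = 500, seed = 99)
  expect_equal(c1, c2)
  expect_lte(c1$conf.low, c1$conf.high)
  # data-frame resampling uses rows
  d <- tibble::tibble(a = y, b = 2 * y)
  cd <- bootstrap_ci(d, function(dd) cor(dd$a, dd$b), B = 50, seed = 1)
  expect_equal(cd$estimate, 1)
})

test_that("t tests carry conventional statistics and zero-variance guards", {
  expect_equal(t_test_paired(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(t_test_paired(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               class = "glustress_zero_variance")
  d <- tibble::tibble(y = c(1, 2, 3, 2, 4, 6), g = rep(c("a", "b"), each = 3))
  r <- t_test_groups(d, y, g)
  # pooled-variance hand computation: t = -2 / sqrt(2.5 * 2/3)
  expect_equal(r$statistic, -2 / sqrt(2.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_error(t_test_groups(tibble::tibble(y = c(1, 1, 2, 2),
                                            g = c("a", "a", "b", "b")),
                             y, g), class = "glustress_zero_variance")
  # negating the response flips the statistic but not the p-value
  r2 <- t_test_groups(dplyr::mutate(d, y = -y), y, g)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p.value, r$p.value)
})
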