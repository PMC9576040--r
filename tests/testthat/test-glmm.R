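sim_binom_groups <- function(n_groups, per_group, beta0, beta1, sd_g,
                             seed) {
  set.seed(seed)
  g <- rep(sprintf("g%03d", seq_len(n_groups)), each = per_group)
  b <- stats::rnorm(n_groups, 0, sd_g)
  x <- stats::runif(n_groups * per_group, -1, 1)
  eta <- beta0 + beta1 * x + b[as.integer(factor(g))]
  data.frame(y = stats::rbinom(length(eta), 1, stats::plogis(eta)),
             x = x, g = g, stringsAsFactors = FALSE)
}

test_that("flat prior and negligible random variance reproduce the GLM", {
  d <- data.frame(y = c(rep(1, 3), rep(0, 7)), g = "g1")
  f <- fit_glmm(d, "y", groups = "g", family = "binomial", prior_sd = Inf)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients[1]), stats::qlogis(0.3),
               tolerance = 1e-4)
  expect_lt(f$random_sd, 0.01)  # single group: variance shrinks to zero

  set.seed(31)
  n <- 300
  dd <- data.frame(x = factor(sample(letters[1:3], n, TRUE)), g = "g1")
  dd$y <- stats::rbinom(n, 1, stats::plogis(
    c(a = -0.5, b = 0.3, c = 1)[as.character(dd$x)]))
  fg <- fit_glmm(dd, "y", fixed = "x", groups = "g", family = "binomial",
                 prior_sd = Inf)
  gl <- stats::glm(y ~ x, stats::binomial, dd)
  expect_equal(unname(fg$coefficients), unname(stats::coef(gl)),
               tolerance = 1e-5)

  # poisson and gaussian families against their GLM counterparts
  dp <- data.frame(y = stats::rpois(n, exp(c(a = 0, b = 1,
    c = 0.5)[as.character(dd$x)])), x = dd$x, g = "g1")
  fp <- fit_glmm(dp, "y", "x", "g", family = "poisson", prior_sd = Inf)
  expect_equal(unname(fp$coefficients),
               unname(stats::coef(stats::glm(y ~ x, stats::poisson, dp))),
               tolerance = 1e-5)
  dgs <- data.frame(y = stats::rnorm(n, c(a = 1, b = 3,
    c = 2)[as.character(dd$x)]), x = dd$x, g = "g1")
  fgs <- fit_glmm(dgs, "y", "x", "g", family = "gaussian", prior_sd = Inf)
  expect_equal(unname(fgs$coefficients),
               unname(stats::coef(stats::lm(y ~ x, dgs))), tolerance = 1e-4)
})

test_that("the prior keeps estimates finite under complete separation", {
  d <- data.frame(y = c(rep(0, 12), rep(1, 6), rep(0, 6)),
                  x = factor(rep(c("a", "b"), each = 12)),
                  g = rep(sprintf("g%d", 1:6), 4))
  f <- fit_glmm(d, "y", "x", "g", family = "binomial", prior_sd = 2.5)
  expect_true(f$converged)
  expect_true(all(is.finite(f$coefficients)))
  # pulled within a few prior SDs rather than diverging
  expect_lt(max(abs(f$coefficients)), 4 * 2.5)
  expect_true(all(is.finite(f$se)))
})

test_that("binomial mixed-model estimates recover the generating parameters", {
  d <- sim_binom_groups(n_groups = 60, per_group = 12, beta0 = -0.3,
                        beta1 = 0.8, sd_g = 1.0, seed = 33)
  f <- fit_glmm(d, "y", fixed = "x", groups = "g", family = "binomial",
                prior_sd = 2.5)
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[["x"]] - 0.8), 3 * f$se[2] + 0.05)
  expect_gt(f$random_sd, 0.4)
  expect_lt(f$random_sd, 1.8)
  # cross-check against the Laplace fit of lme4 on the same data
  lf <- lme4::glmer(y ~ x + (1 | g), data = d, family = stats::binomial)
  expect_equal(unname(f$coefficients), unname(lme4::fixef(lf)),
               tolerance = 0.08)
  expect_equal(unname(f$random_sd),
               unname(sqrt(unlist(lme4::VarCorr(lf)))), tolerance = 0.15)
})

test_that("Wald factor tests reduce to closed forms", {
  d <- sim_binom_groups(40, 10, 0, 0.6, 0.5, seed = 34)
  f <- fit_glmm(d, "y", fixed = "x", groups = "g", family = "binomial")
  w <- wald_factor_test(f, "x")
  # single-coefficient block: chi-square = (coef / se)^2, df = 1
  expect_equal(w$statistic_value,
               unname((f$coefficients[["x"]] / f$se[2])^2), tolerance = 1e-8)
  expect_equal(w$df, 1L)
  expect_error(wald_factor_test(f, "nope"), "not in the fit")
})

test_that("pairwise comparisons adjust p-values coherently", {
  set.seed(35)
  n <- 400
  d <- data.frame(x = factor(sample(letters[1:4], n, TRUE)),
                  g = sample(sprintf("g%d", 1:20), n, TRUE))
  d$y <- stats::rbinom(n, 1, 0.4)  # no level effect
  f <- fit_glmm(d, "y", "x", "g", family = "binomial")
  ss <- pairwise_comparisons(f, "x", adjust = "single-step")
  bf <- pairwise_comparisons(f, "x", adjust = "bonferroni")
  un <- pairwise_comparisons(f, "x", adjust = "none")
  expect_equal(nrow(ss), choose(4, 2))
  # adjusted p >= unadjusted p; single-step <= Bonferroni
  expect_true(all(ss$p_adjusted >= un$p_adjusted - 1e-8))
  expect_true(all(ss$p_adjusted <= bf$p_adjusted + 1e-8))
  # null data: no adjusted p should be extreme
  expect_gt(min(ss$p_adjusted), 0.01)
  # simultaneous intervals at least as wide as unadjusted ones
  expect_true(all(ss$upper - ss$lower >= un$upper - un$lower - 1e-8))

  # two levels: adjustment is a no-op
  d2 <- d[d$x %in% c("a", "b"), ]
  d2$x <- droplevels(d2$x)
  f2 <- fit_glmm(d2, "y", "x", "g", family = "binomial")
  s2 <- pairwise_comparisons(f2, "x", adjust = "single-step")
  u2 <- pairwise_comparisons(f2, "x", adjust = "none")
  expect_equal(s2$p_adjusted, u2$p_adjusted, tolerance = 1e-6)
})

test_that("crossed random factors are accepted and variances stay non-negative", {
  set.seed(36)
  n <- 300
  d <- data.frame(x = factor(sample(c("a", "b"), n, TRUE)),
                  id = sample(sprintf("s%d", 1:25), n, TRUE),
                  yr = sample(sprintf("y%d", 1:8), n, TRUE))
  b_id <- stats::rnorm(25, 0, 0.8)
  d$y <- stats::rbinom(n, 1, stats::plogis(
    0.2 + b_id[as.integer(factor(d$id))]))
  f <- fit_glmm(d, "y", "x", groups = c("id", "yr"), family = "binomial")
  expect_true(f$converged)
  expect_equal(names(f$random_sd), c("id", "yr"))
  expect_true(all(f$random_sd >= 0))
  expect_gt(f$random_sd[["id"]], f$random_sd[["yr"]])
})
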