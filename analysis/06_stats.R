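#!/usr/bin/env Rscript
# Stage 6: statistical comparisons between the sexes.
#
# Rank tests on the return histories, a two-sample Anderson-Darling test on
# return-interval distributions, and separation-robust MAP GLMMs (normal
# priors on fixed effects, shark-ID random intercepts) for the within-season
# metrics and monthly arrival proportions, with Wald factor tests and
# Tukey-style adjusted pairwise comparisons.

library(matesite)

h <- utils::read.csv("results/histories.csv")
ss <- utils::read.csv("results/season_summaries.csv")
mep_strings <- utils::read.csv("results/strings.csv")
mep_strings$arrival <- parse_instant(mep_strings$arrival)
mep_strings$departure <- parse_instant(mep_strings$departure)
registry <- load_registry("results/data/registry.csv")

ret <- h[h$is_returning == "TRUE" | h$is_returning == TRUE, ]
tests <- list()

## seasons detected and time-at-large between sexes (rank test)
mw1 <- mann_whitney_u(ret$n_seasons[ret$sex == "F"],
                      ret$n_seasons[ret$sex == "M"])
mw2 <- mann_whitney_u(ret$time_at_large_years[ret$sex == "F"],
                      ret$time_at_large_years[ret$sex == "M"])
cat(sprintf("seasons detected F vs M: U = %.1f, p = %.4g (%s)\n",
            mw1$statistic_value, mw1$p_value, mw1$method_detail))
cat(sprintf("time-at-large F vs M:    U = %.1f, p = %.4g\n",
            mw2$statistic_value, mw2$p_value))
tests$seasons_detected <- mw1
tests$time_at_large <- mw2

## return-interval distributions between sexes (Anderson-Darling)
iv_of <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(unlist(strsplit(s, "|", fixed = TRUE)))
}
iv_f <- unlist(lapply(h$intervals[h$sex == "F"], iv_of))
iv_m <- unlist(lapply(h$intervals[h$sex == "M"], iv_of))
ad <- anderson_darling_2sample(iv_f, iv_m, n_perm = 2000, seed = 61)
cat(sprintf("return intervals F vs M: A2 = %.3f, permutation p = %.4g\n",
            ad$statistic_value, ad$p_value))
tests$return_intervals <- ad

## within-season metrics: GLMMs with shark-ID random intercepts
ss$sex <- factor(ss$sex)
fits <- list(
  n_visits = fit_glmm(ss, "n_visits", "sex", "shark_id",
                      family = "poisson"),
  duration = fit_glmm(ss, "mean_visit_duration_h", "sex", "shark_id",
                      family = "gaussian"),
  cumulative = fit_glmm(ss, "cumulative_days", "sex", "shark_id",
                        family = "gaussian"),
  span = fit_glmm(ss[!is.na(ss$span_days), ], "span_days", "sex", "shark_id",
                  family = "gaussian"))
wald_rows <- do.call(rbind, lapply(names(fits), function(nm) {
  w <- wald_factor_test(fits[[nm]], "sex")
  cbind(metric = nm, w)
}))
print(wald_rows, row.names = FALSE)
write_table(wald_rows, "results/stats_wald.csv")

## monthly arrival proportions (females): one-vs-rest binomial encoding,
## shark and year random intercepts, Wald + adjusted pairwise comparisons
sex_of <- setNames(registry$sex, registry$shark_id)
arr <- mep_strings[mep_strings$n_detections >= 2 &
                     !mep_strings$excluded_tagging_bias &
                     !mep_strings$left_censored &
                     sex_of[mep_strings$shark_id] == "F", ]
arr$month <- factor(month.abb[as.integer(format(arr$arrival, "%m"))],
                    levels = month.abb)
arr$year <- factor(format(arr$arrival, "%Y"))
months_seen <- levels(droplevels(arr$month))
long <- do.call(rbind, lapply(months_seen, function(m) {
  data.frame(y = as.integer(arr$month == m), month = m,
             shark_id = arr$shark_id, year = arr$year)
}))
long$month <- factor(long$month, levels = months_seen)
fit_arr <- fit_glmm(long, "y", "month", c("shark_id", "year"),
                    family = "binomial", prior_sd = 2.5)
w_arr <- wald_factor_test(fit_arr, "month")
cat(sprintf("female arrival month effect: chi-square = %.1f (df %d), p = %.3g\n",
            w_arr$statistic_value, w_arr$df, w_arr$p_value))
cmp <- pairwise_comparisons(fit_arr, "month", adjust = "single-step")
write_table(cmp, "results/stats_arrival_pairwise.csv")
sig <- cmp[cmp$p_adjusted < 0.05, "contrast"]
cat(sprintf("%d of %d month contrasts significant after adjustment\n",
            length(sig), nrow(cmp)))

coef_tab <- do.call(rbind, lapply(c(fits, list(arrival_month = fit_arr)),
  function(f) data.frame(term = names(f$coefficients),
                         estimate = unname(f$coefficients),
                         se = unname(f$se), converged = f$converged)))
coef_tab <- cbind(model = rep(c(names(fits), "arrival_month"),
                              c(vapply(fits, function(f)
                                length(f$coefficients), 0L),
                                length(fit_arr$coefficients))),
                  coef_tab)
write_table(coef_tab, "results/stats_coefficients.csv")
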