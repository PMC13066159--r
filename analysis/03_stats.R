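#!/usr/bin/env Rscript
# Step 3 — group statistics on the measured tables.
#
# Replicate droplets are averaged within sample; samples are the unit of
# analysis. Reports:
#   * per-group mean +/- SEM of lambda_p at T = 120 min and the exact
#     two-tailed Mann-Whitney test between groups;
#   * Kruskal-Wallis across groups as the omnibus check;
#   * the Grubbs outlier test inside each group at T = 120 min;
#   * per-annulus P1 summaries and the exact Mann-Whitney on the first
#     exterior annulus;
#   * a curve permutation test on the lambda_p(t) timecourse.

suppressMessages(library(mucotrace))

res_dir <- "results"
lam <- utils::read.csv(file.path(res_dir, "endpoint_lambda_p.csv"))
agg <- utils::read.csv(file.path(res_dir, "endpoint_aggregation.csv"))
tc <- utils::read.csv(file.path(res_dir, "timecourse_lambda_p.csv"))

sample_means <- function(df, col) {
  sm <- stats::aggregate(df[[col]], by = list(group = df$group,
                                              sample = df$sample),
                         FUN = function(v) mean(v, na.rm = TRUE))
  split(sm$x, sm$group)
}

t_final <- max(lam$t_min)
lam_f <- lam[lam$t_min == t_final, ]
lm_means <- sample_means(lam_f, "lambda_p_um")
message(sprintf("lambda_p at T = %g min: suckling %.1f um, weaned %.1f um",
                t_final, mean(lm_means$suckling), mean(lm_means$weaned)))
mw <- mann_whitney_exact(lm_means$suckling, lm_means$weaned)
message(sprintf("  exact Mann-Whitney: U = %g, p = %.3g", mw$statistic,
                mw$p_value))
kw <- kruskal_wallis(lm_means)
message(sprintf("  Kruskal-Wallis: H = %.3f, p = %.3g", kw$statistic,
                kw$p_value))
for (g in names(lm_means)) {
  gr <- grubbs_test(lm_means[[g]])
  message(sprintf("  Grubbs (%s): G = %.2f, p = %.3g, extreme sample value %.1f",
                  g, gr$statistic, gr$p_value, gr$outlier))
}

first_ext <- agg[agg$annulus == 10, ]
p1_means <- sample_means(first_ext, "P1")
mw_p1 <- mann_whitney_exact(p1_means$suckling, p1_means$weaned)
message(sprintf("P1 in the first exterior annulus: suckling %.2f, weaned %.2f (exact MW p = %.3g)",
                mean(p1_means$suckling), mean(p1_means$weaned), mw_p1$p_value))

cp <- curve_permutation_test(tc, "t_min", "lambda_p_um", n_perm = 999,
                             seed = 7L)
message(sprintf("lambda_p(t) curve permutation test: max|t| = %.2f, p = %.3g%s",
                cp$statistic, cp$p_value,
                if (cp$exact) " (exhaustive)" else ""))

stats_tab <- data.frame(
  test = c("mann_whitney_lambda_final", "kruskal_wallis_lambda_final",
           "mann_whitney_P1_first_exterior", "curve_permutation_lambda_t"),
  statistic = c(mw$statistic, kw$statistic, mw_p1$statistic, cp$statistic),
  p_value = c(mw$p_value, kw$p_value, mw_p1$p_value, cp$p_value))
write_results(list(group_tests = stats_tab,
                   summary_lambda = summarize_group(lam, "t_min", "lambda_p_um"),
                   summary_P1 = summarize_group(agg, "r_over_R_mid", "P1")),
              res_dir)
message("Stats tables written under ", res_dir)
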