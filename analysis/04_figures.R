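#!/usr/bin/env Rscript
# Step 4 — figures: lambda_p(t) mean +/- SEM per group (timecourse) and the
# normalized aggregation profile P1 vs r/R per group (endpoint).

suppressMessages(library(mucotrace))

res_dir <- "results"
tc <- utils::read.csv(file.path(res_dir, "timecourse_lambda_p.csv"))
agg <- utils::read.csv(file.path(res_dir, "endpoint_aggregation.csv"))
cols <- c(suckling = "darkorange2", weaned = "dodgerblue3")

sl <- summarize_group(tc, "t_min", "lambda_p_um")
grDevices::png(file.path(res_dir, "lambda_p_timecourse.png"), 800, 600,
               res = 110)
plot(NA, xlim = range(sl$t_min), ylim = c(0, max(sl$mean + sl$sem, na.rm = TRUE)),
     xlab = "time (min)", ylab = expression(lambda[p] ~ (mu * m)),
     main = "Penetration length over time")
for (g in names(cols)) {
  d <- sl[sl$group == g, ]
  lines(d$t_min, d$mean, col = cols[g], lwd = 2)
  points(d$t_min, d$mean, col = cols[g], pch = 16)
  suppressWarnings(arrows(d$t_min, d$mean - d$sem, d$t_min, d$mean + d$sem, angle = 90,
         code = 3, length = 0.03, col = cols[g]))
}
legend("topleft", legend = names(cols), col = cols, lwd = 2, bty = "n")
grDevices::dev.off()

sp <- summarize_group(agg, "r_over_R_mid", "P1")
sp <- sp[sp$r_over_R_mid <= 1.55, ]
grDevices::png(file.path(res_dir, "aggregation_profile.png"), 800, 600,
               res = 110)
plot(NA, xlim = range(sp$r_over_R_mid), ylim = c(0, max(sp$mean + sp$sem,
                                                        na.rm = TRUE)),
     xlab = "r / R", ylab = expression(P^1),
     main = "Normalized aggregated-bacteria fraction by annulus")
abline(v = 1, lty = 2, col = "grey40")
for (g in names(cols)) {
  d <- sp[sp$group == g, ]
  lines(d$r_over_R_mid, d$mean, col = cols[g], lwd = 2, type = "b", pch = 16)
  suppressWarnings(arrows(d$r_over_R_mid, d$mean - d$sem, d$r_over_R_mid, d$mean + d$sem,
         angle = 90, code = 3, length = 0.03, col = cols[g]))
}
text(1, par("usr")[4] * 0.95, "middle boundary", pos = 4, col = "grey40")
legend("topright", legend = names(cols), col = cols, lwd = 2, bty = "n")
grDevices::dev.off()

message("Figures written: results/lambda_p_timecourse.png, ",
        "results/aggregation_profile.png")
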