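#!/usr/bin/env Rscript
# Figure-style diagnostics from the archive written by 01_simulate_study.R:
#  - per-run bias scatter (e_bar_Ri - e_i against run index) for the
#    best-for-bootstrap (p = 1) and worst-for-bootstrap (p = 5) cells;
#  - mean relative bias BIAS/e per configuration;
#  - |BIAS|/SD(BIAS) against the 0.25 acceptability threshold.
suppressPackageStartupMessages({
  library(cvbias)
  library(ggplot2)
})

res <- read.csv("results/study_results.csv")
arc <- read.csv("results/study_archive.csv")
dir.create("results", showWarnings = FALSE)

scatter_cell <- function(p, n, delta, methods = c("kCVn", "BCVn")) {
  d <- arc[arc$p == p & arc$n == n & arc$delta == delta &
             arc$cov_case == "equal" & arc$scheme %in% methods, ]
  ggplot(d, aes(run, bias_i)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    geom_point(size = 0.6, alpha = 0.6) +
    facet_wrap(~scheme) +
    labs(x = "simulation run", y = "per-run bias (mean estimate - true error)",
         title = sprintf("p = %d, n = %d, delta = %g", p, n, delta)) +
    theme_bw()
}

ggsave("results/fig_bias_scatter_p1.pdf", scatter_cell(1, 50, 1),
       width = 7, height = 3.5)
if (any(arc$p == 5))
  ggsave("results/fig_bias_scatter_p5.pdf", scatter_cell(5, 50, 1),
         width = 7, height = 3.5)

res$rel_bias <- res$bias_bar / res$e_bar
res$ratio <- abs(res$bias_bar) / res$sd_bias
res$family <- ifelse(grepl("^BCV", res$method), "bootstrap CV",
                     "permutation CV")
res$config <- interaction(res$p, res$delta, res$cov_case, res$n, sep = "/")

g_rel <- ggplot(res, aes(config, rel_bias, colour = family,
                         shape = method)) +
  geom_hline(yintercept = 0, linetype = 2) +
  geom_point(size = 2) +
  labs(x = "configuration (p/delta/cov/n)", y = "mean relative bias BIAS/e") +
  theme_bw() + theme(axis.text.x = element_text(angle = 60, hjust = 1))
ggsave("results/fig_relative_bias.pdf", g_rel, width = 9, height = 4.5)

g_ratio <- ggplot(res, aes(config, ratio, colour = family, shape = method)) +
  geom_hline(yintercept = 0.25, linetype = 2, colour = "red") +
  geom_point(size = 2) +
  labs(x = "configuration (p/delta/cov/n)", y = "|BIAS| / SD(BIAS)",
       caption = "dashed line: 0.25 acceptability rule of thumb") +
  theme_bw() + theme(axis.text.x = element_text(angle = 60, hjust = 1))
ggsave("results/fig_bias_sd_ratio.pdf", g_ratio, width = 9, height = 4.5)

message("wrote results/fig_bias_scatter_*.pdf, fig_relative_bias.pdf, ",
        "fig_bias_sd_ratio.pdf")
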