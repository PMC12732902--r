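#!/usr/bin/env Rscript
# Group statistics on the simulated replicates (one-way ANOVA, Tukey HSD,
# compact letter display per compound) and the expression-compound Pearson
# correlation matrix across units, with the |r| > 0.8 & p < 0.05 highlights.

suppressPackageStartupMessages(library(umamikit))

dir.create("results", showWarnings = FALSE)

tab <- read_concentration_table("results/sim/compounds.csv", quiet = TRUE)
stats_rows <- NULL
for (cmp in unique(tab$compound)) {
  d <- tab[tab$compound == cmp, ]
  groups <- split(d$concentration, d$species)
  if (length(groups) < 2L) next
  aov_res <- anova_oneway(groups)
  cld <- compact_letter_display(tukey_hsd(groups),
                                means = vapply(groups, mean, numeric(1)))
  stats_rows <- rbind(stats_rows, data.frame(
    compound = cmp, species = names(cld),
    mean = round_half_up(vapply(groups, mean, numeric(1))[names(cld)]),
    letters = unname(cld), f = round_half_up(aov_res$f_statistic),
    p = signif(aov_res$p_value, 3)))
}
write.csv(stats_rows, "results/group_letters.csv", row.names = FALSE)
cat("per-compound ANOVA + Tukey letters written",
    "(groups sharing a letter are not significantly different):\n")
print(head(stats_rows[stats_rows$compound == "GMP", ], 6), row.names = FALSE)

# correlation across the coupled simulated units
latent <- read.csv("results/sim/latent.csv")
expr_wide <- data.frame(GLUD1 = latent$expression_fold)
comp_wide <- data.frame(Glu = latent$concentration)
corr <- pearson_matrix(expr_wide, comp_wide)
write.csv(corr, "results/correlations.csv", row.names = FALSE)
cat(sprintf("\nGLUD1 ~ Glu across %d units: r = %.3f%s (p = %.3g)\n",
            corr$n, corr$r, corr$stars, corr$p_value))
hits <- highlight_correlations(corr)
cat("associations passing |r| > 0.8 and p < 0.05:",
    if (nrow(hits)) paste(hits$gene, hits$variable, sep = "~") else "none",
    "\n")
cat("wrote results/group_letters.csv, results/correlations.csv\n")
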