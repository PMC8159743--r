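#!/usr/bin/env Rscript
# Stage 5: observed-variable path model of the trait network.
#
# Builds the structural model implied by the scans: fat mass gain on sex,
# the sex:diet interaction and the three fat-gain loci; serum HDL on sex
# and its chromosome-1 locus; residual covariance between the two
# outcomes. Prunes non-significant paths and reports standardized
# coefficients with per-predictor variance shares.

library(dietcross)

cross <- read_cross("results/qc/pheno_clean.csv",
                    "results/cross/f2_geno.csv",
                    "results/cross/f2_map.csv")
geno <- filter_markers(cross$geno)$geno
pheno <- cross$pheno

qtl_table <- read.csv("results/scan/qtl_table.csv",
                      colClasses = c(chrom = "character"))
mk <- function(tr, ch) qtl_table$top_marker[qtl_table$trait == tr &
                                              qtl_table$chrom == ch][1]
spec <- path_model_spec(
  equations = list(
    list(outcome = "fat_mass_gain",
         predictors = c("sex", "sex:diet",
                        mk("fat_mass_gain", "1"), mk("fat_mass_gain", "5"),
                        mk("fat_mass_gain", "7"))),
    list(outcome = "hdl",
         predictors = c("sex", mk("hdl", "1")))),
  residual_covariances = list(c("fat_mass_gain", "hdl")))

pruned <- prune_paths(spec, pheno, geno, alpha = 0.05)
print(pruned$fit)

dir.create("results/path", recursive = TRUE, showWarnings = FALSE)
write.csv(pruned$fit$paths, "results/path/path_coefficients.csv",
          row.names = FALSE)
write.csv(pruned$fit$outcomes, "results/path/outcome_r2.csv",
          row.names = FALSE)
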