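#!/usr/bin/env Rscript
# Stage 2: pre-analysis quality control.
#
# Iterative 3-SD outlier screening per sex and trait, marker filtering
# (monomorphic / >10% missing), and sex/diet-adjusted trait correlations.
# Reads the cross written by 01_simulate.R; writes the cleaned phenotype
# table, the QC reports and the adjusted correlation matrix.

library(dietcross)

cross <- read_cross("results/cross/f2_pheno.csv",
                    "results/cross/f2_geno.csv",
                    "results/cross/f2_map.csv")

qc <- remove_outliers_iterative(cross$pheno, k = 3)
cat("Outliers set to missing:", nrow(qc$report), "\n")
if (nrow(qc$report)) print(qc$report)

mk <- filter_markers(cross$geno, max_missing = 0.1)
cat("Markers removed:", nrow(mk$report), "of", nrow(cross$map), "\n")

cors <- residual_correlations(qc$pheno)
cat("Sex/diet-adjusted trait correlations:\n")
print(round(cors, 3))

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.csv(qc$pheno, "results/qc/pheno_clean.csv", row.names = FALSE)
write.csv(qc$report, "results/qc/outliers.csv", row.names = FALSE)
write.csv(mk$report, "results/qc/markers_removed.csv", row.names = FALSE)
write.csv(as.data.frame(cors), "results/qc/adjusted_correlations.csv")
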