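#!/usr/bin/env Rscript
# Stage 6: cohort comparisons and heritability.
#
# Reproduces the descriptive arithmetic of the study design on the
# simulated cohorts: Welch/Wilcoxon group contrasts, fold changes between
# diet groups, sex contrasts in the F2, genotype-class contrasts at the
# serum-HDL locus, and broad-sense heritability of fat mass gain from the
# F2 vs F1 variance.

library(dietcross)

cross <- read_cross("results/qc/pheno_clean.csv",
                    "results/cross/f2_geno.csv",
                    "results/cross/f2_map.csv")
pheno <- cross$pheno
cohorts <- read.csv("results/cross/cohorts_pheno.csv")

# F2 sex contrast in fat mass gain
f <- pheno$fat_mass_gain[pheno$sex == "F"]
m <- pheno$fat_mass_gain[pheno$sex == "M"]
res <- welch_t(m, f)
cat(sprintf("F2 fat mass gain, males vs females: %.1f g (CI %.1f-%.1f, p = %.2g)\n",
            res$estimate, res$ci_low, res$ci_high, res$p))

# diet fold change in the F1 cohort (per sex)
for (sx in c("M", "F")) {
  am <- cohorts$fat_mass_gain[cohorts$generation == "F1" &
                                cohorts$sex == sx &
                                cohorts$diet == "american"]
  ke <- cohorts$fat_mass_gain[cohorts$generation == "F1" &
                                cohorts$sex == sx &
                                cohorts$diet == "ketogenic"]
  if (length(am) > 1 && length(ke) > 1) {
    w <- welch_t(am, ke)
    cat(sprintf("F1 %s american vs ketogenic: fold change %.2f, p = %.2g\n",
                sx, fold_change(mean(am), mean(ke)), w$p))
  }
}

# genotype-class contrasts at the serum-HDL chromosome-1 peak
qtl_table <- read.csv("results/scan/qtl_table.csv",
                      colClasses = c(chrom = "character"))
hdl1 <- qtl_table$top_marker[qtl_table$trait == "hdl" &
                               qtl_table$chrom == "1"][1]
g <- cross$geno$calls[match(pheno$id, rownames(cross$geno$calls)), hdl1]
for (pair in list(c(0, 1), c(0, 2), c(1, 2))) {
  a <- pheno$hdl[!is.na(g) & g == pair[2]]
  b <- pheno$hdl[!is.na(g) & g == pair[1]]
  w <- welch_t(a, b)
  cat(sprintf("HDL %s vs %s at %s: %.1f ng/mL (CI %.1f-%.1f, p = %.2g)\n",
              geno_labels(pair[2]), geno_labels(pair[1]), hdl1,
              w$estimate, w$ci_low, w$ci_high, w$p))
}
wlx <- wilcoxon_rank_sum(pheno$hdl[!is.na(g) & g == 2],
                         pheno$hdl[!is.na(g) & g == 0])
cat(sprintf("  (Wilcoxon FF vs BB: shift %.1f, p = %.2g)\n",
            wlx$estimate, wlx$p))

# broad-sense heritability of fat mass gain, per sex
for (sx in c("M", "F")) {
  v2 <- var(pheno$fat_mass_gain[pheno$sex == sx], na.rm = TRUE)
  v1 <- var(cohorts$fat_mass_gain[cohorts$generation == "F1" &
                                    cohorts$sex == sx])
  cat(sprintf("Broad-sense heritability of fat mass gain (%s): %.2f\n",
              sx, broad_sense_heritability(v2, v1)))
}
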