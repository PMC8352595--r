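#!/usr/bin/env Rscript
# Cohort statistics on the counts printed in the study: Mendelian
# genotype ratios of heterozygous intercross litters, and the 2x2 test
# of axonemal microtubule defects in mutant vs control tracheal cultures
# (13 of 81 vs 1 of 94 axonemes scored by electron microscopy).

suppressMessages(library(shiftbeat))
dir.create("results", showWarnings = FALSE)

out <- list()

# E13.5 litters: 7 +/+, 11 +/NRS, 4 NRS/NRS against 1:2:1
mend <- mendelian_chisq(c(7, 11, 4), c(1, 2, 1))
out$mendelian_e13 <- mend
cat(sprintf("E13.5 Mendelian: chi2 = %.3f (df %d), p = %.2f\n",
            mend$chi2, mend$df, mend$p))

# TEM defects pooled into defect/normal
tem_tbl <- matrix(c(13, 68, 1, 93), 2, 2, byrow = TRUE,
                  dimnames = list(c("NRS", "WT"), c("defect", "normal")))
tem <- pearson_chisq_2x2(tem_tbl)
tem_yates <- pearson_chisq_2x2(tem_tbl, yates = TRUE)
out$tem_defects <- c(tem, list(p_yates = tem_yates$p))
cat(sprintf("TEM defects: chi2 = %.2f, p = %.2g (Yates p = %.2g)\n",
            tem$chi2, tem$p, tem_yates$p))

# the same table under Fisher's exact test, the study's test of choice
# for motile/immotile bundle proportions
out$tem_defects_fisher_p <- fisher_exact_2x2(tem_tbl)
cat(sprintf("TEM defects, Fisher exact: p = %.2g\n",
            out$tem_defects_fisher_p))

jsonlite::write_json(out, "results/cohort_stats.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/cohort_stats.json\n")
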