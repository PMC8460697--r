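#!/usr/bin/env Rscript
# Candidate-CpG association scan with Bonferroni control, plus a small
# clump-and-threshold polygenic score demonstration on simulated genotypes.
suppressMessages(library(artgrowth))

cohort <- read_cohort("results/cohort")
subjects <- apply_eligibility(cohort$subjects)
ids <- sub("^cpg_", "", grep("^cpg_", names(subjects), value = TRUE))
scan <- candidate_cpg_scan(subjects, ids)
print(scan, row.names = FALSE)
cat("Bonferroni threshold over", nrow(scan), "sites:",
    signif(attr(scan, "bonferroni_threshold"), 3), "\n")
dir.create("results", showWarnings = FALSE)
write.csv(scan, "results/cpg_scan.csv", row.names = FALSE)

# toy genotype matrix: 40 SNPs in LD blocks on two chromosomes
set.seed(5)
n <- nrow(subjects)
info <- data.frame(snp_id = sprintf("rs%03d", 1:40),
                   chromosome = rep(1:2, each = 20),
                   position = rep(seq(1e5, 20e5, length.out = 20), 2),
                   gwas_beta = rnorm(40, 0, 0.08),
                   gwas_p = 10^runif(40, -9, -1))
G <- sapply(1:40, function(j) rbinom(n, 2, 0.3))
colnames(G) <- info$snp_id
for (j in seq(2, 40, by = 4)) { # induce local LD
  G[, j] <- ifelse(runif(n) < 0.9, G[, j - 1], rbinom(n, 2, 0.3))
}
bw <- vv_bw <- rnorm(n, 3.2, 0.4) + 0.05 * scale(G %*% info$gwas_beta)
anchors <- cbind(birth_weight = bw, bmi = rnorm(n, 16, 1.5))
prs <- clump_and_score(G, info, subjects$ethnicity, anchors)
cat("chosen p-value thresholds by ethnicity:\n")
print(unlist(prs$chosen_threshold))
cat("retained SNPs (chinese):", length(prs$retained$chinese), "\n")
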