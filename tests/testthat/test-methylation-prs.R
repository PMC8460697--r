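test_that("technical residualization removes batch structure exactly", {
  set.seed(60)
  n <- 80
  batch <- rep(c("A", "B"), each = n / 2)
  biology <- rnorm(n)
  m <- cbind(cpg1 = biology + 0.2 * (batch == "B") + rnorm(n, 0, 0.05),
             cpg2 = rnorm(n))
  tech <- data.frame(batch = batch, chip_pos = rep(1:4, n / 4))
  res <- residualize_technical(m, tech)
  # between-batch mean difference removed to numerical zero
  expect_lt(abs(mean(res[batch == "A", 1]) - mean(res[batch == "B", 1])),
            1e-10)
  # residuals orthogonal to every technical column
  X <- model.matrix(~ batch + chip_pos, tech)[, -1]
  for (j in seq_len(ncol(X))) {
    expect_lt(abs(cor(res[, 1], X[, j])), 1e-10)
    expect_lt(abs(cor(res[, 2], X[, j])), 1e-10)
  }
  expect_lt(max(abs(colMeans(res))), 1e-12)
  # constant covariates: centering only
  res2 <- residualize_technical(m, data.frame(batch = rep("A", n)))
  expect_equal(unname(res2[, 1]), unname(m[, 1] - mean(m[, 1])),
               tolerance = 1e-12)
  # aliased indicators are reported
  tech_bad <- data.frame(b1 = batch, b2 = batch)
  expect_error(residualize_technical(m, tech_bad), "aliased")
})

test_that("the candidate scan flags at alpha/m and reports skipped sites", {
  co <- small_cohort(seed = 61, n_treated = 250, n_untreated = 1250)
  s <- co$subjects
  scan <- candidate_cpg_scan(s, c("cg03904042", "cg00000101", "cg_absent"))
  expect_equal(attr(scan, "skipped"), "cg_absent")
  expect_equal(attr(scan, "bonferroni_threshold"), 0.05 / 2)
  expect_true(all(scan$p >= 0 & scan$p <= 1))
  expect_equal(scan$passes_bonferroni, scan$p < 0.05 / 2)
  # the causal site carries a negative ART coefficient; null site does not
  expect_lt(scan$beta[scan$cpg_id == "cg03904042"], 0)
})

test_that("scan p-values are uniform under a global null", {
  # 150 null CpGs at n = 800: KS test against U(0,1)
  set.seed(62)
  n <- 800
  s <- data.frame(art = rbinom(n, 1, 0.1), ethnicity = sample(c("a", "b"), n,
                  replace = TRUE), maternal_age = rnorm(n, 31, 5),
                  parity = rpois(n, 0.8), ppBMI = rnorm(n, 23, 4),
                  child_sex = rbinom(n, 1, 0.5))
  ids <- sprintf("null%03d", 1:150)
  for (id in ids) s[[paste0("cpg_", id)]] <- rnorm(n)
  scan <- candidate_cpg_scan(s, ids)
  expect_gt(stats::ks.test(scan$p, "punif")$p.value, 0.01)
})

test_that("scan power on a planted effect matches the noncentral-t oracle", {
  # ART effect -0.1 SD, n = 1177, Bonferroni-corrected alpha over 187 sites
  n <- 1177; n_treated <- 83; beta <- -0.1; alpha <- 0.05 / 187
  # closed-form power for the two-sided t test of a regression coefficient
  se_beta <- 1 / sqrt(n_treated * (1 - n_treated / n))
  ncp <- beta / se_beta
  tc <- qt(1 - alpha / 2, df = n - 2)
  power_oracle <- pt(-tc, df = n - 2, ncp = ncp) +
    1 - pt(tc, df = n - 2, ncp = ncp)
  set.seed(63)
  hits <- replicate(200, {
    art <- as.numeric(seq_len(n) <= n_treated)
    cpg <- beta * art + rnorm(n)
    f <- summary(lm(cpg ~ art))$coefficients
    f["art", 4] < alpha
  })
  expect_lt(abs(mean(hits) - power_oracle), 0.05)
})

make_geno <- function(n, info, seed, ld_groups = NULL) {
  set.seed(seed)
  G <- sapply(seq_len(nrow(info)), function(j) rbinom(n, 2, 0.3))
  colnames(G) <- info$snp_id
  if (!is.null(ld_groups)) {
    for (grp in ld_groups) { # near-copies create high LD
      for (s in grp[-1]) {
        G[, s] <- ifelse(runif(n) < 0.95, G[, grp[1]], rbinom(n, 2, 0.3))
      }
    }
  }
  G
}

test_that("clumping keeps the most significant SNP per linked window", {
  info <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chromosome = 1,
                     position = c(1e5, 1.5e5, 2e5),
                     gwas_beta = c(0.1, 0.2, 0.3),
                     gwas_p = c(1e-8, 1e-6, 1e-3))
  G <- make_geno(500, info, seed = 64, ld_groups = list(info$snp_id))
  anchors <- cbind(bw = rnorm(500), bmi = rnorm(500))
  res <- clump_and_score(G, info, rep("chinese", 500), anchors,
                         p_thresholds = 1)
  expect_equal(res$retained$chinese, "rs1")
})

test_that("the weighted allele sum and standardization are exact", {
  info <- data.frame(snp_id = c("a", "b"), chromosome = c(1, 2),
                     position = c(1e5, 1e5), gwas_beta = c(0.1, -0.2),
                     gwas_p = c(1e-4, 1e-5))
  # two independent SNPs with fixed counts for one subject
  n <- 200
  set.seed(65)
  G <- cbind(a = rbinom(n, 2, 0.5), b = rbinom(n, 2, 0.5))
  G[1, ] <- c(2, 1)
  eth <- rep(c("chinese", "malay"), each = n / 2)
  anchors <- cbind(bw = rnorm(n), bmi = rnorm(n))
  res <- clump_and_score(G, info, eth, anchors, p_thresholds = 1)
  expect_equal(res$raw_score[1], 0.1 * 2 - 0.2 * 1)
  for (e in unique(eth)) {
    z <- res$score[eth == e]
    expect_lt(abs(mean(z)), 1e-8)
    expect_lt(abs(var(z) - 1), 1e-6)
  }
})

test_that("clumping is invariant to input SNP ordering", {
  set.seed(66)
  n <- 300
  info <- data.frame(snp_id = sprintf("rs%02d", 1:12),
                     chromosome = rep(1:2, each = 6),
                     position = rep(seq(1e5, 6e5, by = 1e5), 2),
                     gwas_beta = rnorm(12, 0, 0.1),
                     gwas_p = 10^runif(12, -9, -1))
  G <- make_geno(n, info, seed = 67,
                 ld_groups = list(c("rs01", "rs02"), c("rs07", "rs09")))
  anchors <- cbind(bw = rnorm(n), bmi = rnorm(n))
  eth <- rep("indian", n)
  r1 <- clump_and_score(G, info, eth, anchors)
  perm <- sample(ncol(G))
  r2 <- clump_and_score(G[, perm], info[perm, ], eth, anchors)
  expect_setequal(r1$retained$indian, r2$retained$indian)
  expect_equal(r1$raw_score, r2$raw_score, tolerance = 1e-12)
})

test_that("monomorphic SNPs are treated as unlinked, empty sets warn", {
  info <- data.frame(snp_id = c("m1", "m2"), chromosome = 1,
                     position = c(1e5, 1.2e5), gwas_beta = c(0.3, 0.2),
                     gwas_p = c(1e-6, 1e-5))
  G <- cbind(m1 = rep(1, 50), m2 = rbinom(50, 2, 0.4))
  anchors <- cbind(bw = rnorm(50), bmi = rnorm(50))
  res <- clump_and_score(G, info, rep("x", 50), anchors, p_thresholds = 1)
  expect_setequal(res$retained$x, c("m1", "m2"))
  expect_warning(
    clump_and_score(G, info, rep("x", 50), anchors, p_thresholds = 1e-10),
    "empty retained set")
})
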