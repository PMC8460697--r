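#' Residualize methylation on technical covariates
#'
#' Regresses each CpG column on indicator-coded technical covariates (chip
#' position, extraction batch, bisulfite conversion batch, ...) and returns
#' the centered residuals, removing linear batch structure exactly.
#'
#' @param beta_matrix Samples x CpGs numeric matrix.
#' @param technical_covariates Data.frame of technical factors aligned to the
#'   rows of `beta_matrix`.
#' @return Residual matrix of the same dimension, columns centered at 0.
#' @export
residualize_technical <- function(beta_matrix, technical_covariates) {
  beta_matrix <- as.matrix(beta_matrix)
  if (nrow(beta_matrix) != nrow(technical_covariates)) {
    stop("residualize_technical: covariates not aligned to samples")
  }
  tc <- as.data.frame(technical_covariates)
  varying <- vapply(tc, function(x) length(unique(x)) > 1, logical(1))
  if (!any(varying)) {
    return(scale(beta_matrix, center = TRUE, scale = FALSE))
  }
  X <- stats::model.matrix(~ ., data = tc[varying])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("residualize_technical: rank-deficient technical design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  res <- beta_matrix - X %*% qr.coef(qrX, beta_matrix)
  scale(res, center = TRUE, scale = FALSE)
}

#' Candidate-CpG association scan
#'
#' One multivariable linear regression per candidate CpG, predicting the
#' (residualized) methylation value from ART status and adjustment
#' covariates; reports the ART coefficient, its two-sided p-value, and flags
#' at the Bonferroni bound alpha/m over the candidate set and at the
#' epigenome-wide threshold 3.6e-8.
#'
#' @param records Subject table with `art`, covariates, and `cpg_<id>`
#'   columns.
#' @param cpg_set Character vector of CpG ids to test.
#' @param covariates Adjustment covariate columns (default: the candidate-CpG
#'   model set — ethnicity, maternal age, parity, pre-pregnancy BMI, child
#'   sex).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param ewas_threshold Epigenome-wide significance bound (default 3.6e-8).
#' @param prefix Column prefix of methylation values (default "cpg_").
#' @return Data.frame with one row per tested CpG (missing columns are
#'   collected in attribute `skipped`): cpg_id, beta, se, p, n,
#'   passes_bonferroni, passes_ewas.
#' @export
candidate_cpg_scan <- function(records, cpg_set,
                               covariates = c("ethnicity", "maternal_age",
                                              "parity", "ppBMI", "child_sex"),
                               alpha = 0.05, ewas_threshold = 3.6e-8,
                               prefix = "cpg_") {
  cols <- paste0(prefix, cpg_set)
  present <- cols %in% names(records)
  skipped <- cpg_set[!present]
  tested <- cpg_set[present]
  m <- length(tested)
  if (m == 0) stop("candidate_cpg_scan: no candidate CpG columns found")
  bon <- bonferroni_threshold(alpha, m)
  rhs <- paste(c("art", covariates), collapse = " + ")
  rows <- lapply(tested, function(id) {
    d <- records
    d$..cpg <- d[[paste0(prefix, id)]]
    fit <- stats::lm(stats::as.formula(paste("..cpg ~", rhs)), data = d)
    s <- summary(fit)$coefficients
    data.frame(cpg_id = id, beta = s["art", 1], se = s["art", 2],
               p = s["art", 4], n = length(fit$residuals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$passes_bonferroni <- out$p < bon
  out$passes_ewas <- out$p < ewas_threshold
  attr(out, "bonferroni_threshold") <- bon
  attr(out, "skipped") <- skipped
  out
}

#' Two-round clump-and-threshold polygenic risk score
#'
#' Scores each subject by summing retained allele counts weighted by
#' published (GWAS) effect sizes, after two rounds of greedy clumping by
#' ascending GWAS p-value: round 1 removes SNPs within 250 kb of a retained
#' index SNP with squared allelic correlation above 0.5; round 2 repeats
#' (re-ranking the survivors) with a 5 Mb window and an R-squared bound of
#' 0.2. Within each ethnicity stratum the procedure runs over a grid of
#' GWAS p-value inclusion thresholds, the scores are standardized to mean 0
#' and variance 1, and the threshold whose standardized score has the
#' strongest mean absolute correlation with the anchor phenotypes (child
#' birth weight and BMI) is retained.
#'
#' @param genotypes Subjects x SNPs matrix of allele counts {0,1,2}; column
#'   names are SNP ids.
#' @param snp_info Data.frame with columns snp_id, chromosome, position
#'   (1-based), gwas_beta, gwas_p.
#' @param ethnicity Character vector per subject.
#' @param anchors Data.frame/matrix of anchor phenotypes per subject (e.g.
#'   birth weight and BMI columns).
#' @param p_thresholds Grid of inclusion thresholds (default 1e-10 ... 1).
#' @param windows_bp Window half-widths, round 1 and round 2 (bp).
#' @param r2_limits Squared-correlation pruning bounds, round 1 and round 2.
#' @return A `prs_result` list: per-subject `raw_score` and `score`
#'   (standardized within ethnicity), `chosen_threshold` per ethnicity,
#'   `retained` SNP ids per ethnicity, and the threshold-by-ethnicity
#'   anchor-correlation table.
#' @export
clump_and_score <- function(genotypes, snp_info, ethnicity, anchors,
                            p_thresholds = 10^seq(-10, 0, by = 2),
                            windows_bp = c(250e3, 5e6),
                            r2_limits = c(0.5, 0.2)) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == length(ethnicity))
  info <- snp_info[match(colnames(genotypes), snp_info$snp_id), ]
  if (any(is.na(info$snp_id))) stop("clump_and_score: SNPs missing metadata")
  anchors <- as.matrix(anchors)

  clump_round <- function(ids, window, r2max) {
    ord <- ids[order(info$gwas_p[match(ids, info$snp_id)])]
    kept <- character(0)
    active <- ord
    while (length(active) > 0) {
      idx <- active[1]
      kept <- c(kept, idx)
      i <- match(idx, info$snp_id)
      rest <- active[-1]
      if (length(rest) == 0) break
      j <- match(rest, info$snp_id)
      near <- info$chromosome[j] == info$chromosome[i] &
        abs(info$position[j] - info$position[i]) <= window
      drop <- rep(FALSE, length(rest))
      if (any(near)) {
        gi <- genotypes[, idx]
        r2 <- vapply(rest[near], function(s) {
          if (stats::sd(genotypes[, s]) == 0 || stats::sd(gi) == 0) {
            return(0) # monomorphic: correlation undefined, treat as unlinked
          }
          stats::cor(gi, genotypes[, s])^2
        }, numeric(1))
        drop[near] <- r2 > r2max
      }
      active <- rest[!drop]
    }
    kept
  }

  score_for <- function(ids, rows) {
    if (length(ids) == 0) return(rep(0, length(rows)))
    betas <- info$gwas_beta[match(ids, info$snp_id)]
    as.vector(genotypes[rows, ids, drop = FALSE] %*% betas)
  }

  n <- nrow(genotypes)
  raw <- numeric(n)
  std <- numeric(n)
  chosen <- list(); retained <- list(); corr_tab <- list()
  for (eth in unique(ethnicity)) {
    rows <- which(ethnicity == eth)
    best <- NULL
    for (thr in p_thresholds) {
      ids <- info$snp_id[info$gwas_p <= thr]
      if (length(ids) > 0) {
        ids <- clump_round(ids, windows_bp[1], r2_limits[1])
        ids <- clump_round(ids, windows_bp[2], r2_limits[2])
      }
      if (length(ids) == 0) {
        warning("clump_and_score: empty retained set at threshold ", thr,
                " (", eth, ")")
        s <- rep(0, length(rows))
      } else {
        s <- score_for(ids, rows)
      }
      z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
      cors <- apply(anchors[rows, , drop = FALSE], 2, function(a) {
        ok <- is.finite(a)
        if (stats::sd(z[ok]) == 0 || stats::sd(a[ok]) == 0) return(0)
        abs(stats::cor(z[ok], a[ok]))
      })
      crit <- mean(cors)
      corr_tab[[length(corr_tab) + 1]] <-
        data.frame(ethnicity = eth, p_threshold = thr,
                   mean_abs_cor = crit, n_snps = length(ids))
      if (is.null(best) || crit > best$crit) {
        best <- list(crit = crit, thr = thr, ids = ids, raw = s, z = z)
      }
    }
    raw[rows] <- best$raw
    std[rows] <- best$z
    chosen[[eth]] <- best$thr
    retained[[eth]] <- best$ids
  }
  structure(list(raw_score = raw, score = std,
                 chosen_threshold = chosen, retained = retained,
                 correlations = do.call(rbind, corr_tab)),
            class = "prs_result")
}
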