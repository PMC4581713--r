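#' Genotype probabilities in controls under Hardy-Weinberg proportions
#'
#' For risk-allele frequency `p`, the control genotype distribution over
#' risk-allele counts (0, 1, 2) is `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param p risk-allele frequency in (0, 1).
#' @return numeric length-3 probability vector.
#' @export
#' @examples
#' control_genotype_probs(0.3)  # (0.49, 0.42, 0.09)
control_genotype_probs <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("risk-allele frequency must lie in (0, 1)")
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Genotype probabilities in cases under the per-allele odds-ratio tilt
#'
#' Cases carry genotype `g` with probability proportional to
#' `OR^g * P_g(control)` — the canonical log-additive (multiplicative odds)
#' model.  This exponential tilt makes the case/control genotype odds at a
#' SNP exactly `OR^g`, so the log odds of disease is linear in the risk-allele
#' count with slope `log(OR)`.
#'
#' @param p risk-allele frequency in (0, 1).
#' @param or_allele per-allele odds ratio (> 0).
#' @return numeric length-3 probability vector.
#' @export
#' @examples
#' case_genotype_probs(0.5, 2)  # (1/9, 4/9, 4/9)
case_genotype_probs <- function(p, or_allele) {
  if (!is.numeric(or_allele) || length(or_allele) != 1L ||
      !is.finite(or_allele) || or_allele <= 0)
    stop("per-allele odds ratio must be > 0")
  q <- control_genotype_probs(p) * or_allele^(0:2)
  q / sum(q)
}

#' Simulate one genotype replicate conditional on case status
#'
#' Each subject's risk-allele count at each SNP is drawn independently from
#' the control triple ([control_genotype_probs()]) if she is a non-case and
#' from the case triple ([case_genotype_probs()]) if she is a case.  SNPs are
#' independent of each other and of all other covariates (no linkage
#' disequilibrium), the stated assumption of the simulation design.
#'
#' @param panel a [snp_panel()].
#' @param case_status 0/1 vector (1 = case).
#' @param seed integer seed.
#' @return integer matrix, subjects x SNPs, entries in \{0, 1, 2\}; columns
#'   named by `snp_id`.
#' @export
simulate_genotypes <- function(panel, case_status, seed) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(panel) == 0L) stop("empty SNP panel")
  status <- as.integer(case_status)
  if (any(is.na(status)) || any(!status %in% c(0L, 1L)))
    stop("case_status must be a 0/1 vector")
  n <- length(status)
  m <- nrow(panel)
  geno <- matrix(0L, n, m, dimnames = list(NULL, panel$snp_id))
  is_case <- status == 1L
  with_seed(seed, {
    u <- matrix(runif(n * m), n, m)
    for (j in seq_len(m)) {
      pc <- control_genotype_probs(panel$risk_allele_freq[j])
      qc <- case_genotype_probs(panel$risk_allele_freq[j],
                                panel$odds_ratio[j])
      cum1 <- ifelse(is_case, qc[1L], pc[1L])
      cum2 <- ifelse(is_case, qc[1L] + qc[2L], pc[1L] + pc[2L])
      geno[, j] <- (u[, j] > cum1) + (u[, j] > cum2)
    }
  })
  storage.mode(geno) <- "integer"
  geno
}

#' Simulate replicated virtual genotype datasets
#'
#' Generates `n_replicates` independent genotype datasets for the same cohort
#' (the published analysis used 1,000), each with its genetic risk score.
#' Replicate `r` uses the substream seed `derive_seed(seed, "genotypes/rep<r>")`
#' so any single replicate is reproducible in isolation.
#'
#' @inheritParams simulate_genotypes
#' @param n_replicates number of virtual datasets.
#' @return a list of length `n_replicates`; each element is a list with
#'   `replicate`, `seed`, `genotypes` (matrix) and `grs` (numeric vector).
#' @export
simulate_genotype_datasets <- function(panel, case_status, n_replicates, seed) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    sub <- derive_seed(seed, paste0("genotypes/rep", r))
    g <- simulate_genotypes(panel, case_status, seed = sub)
    list(replicate = r, seed = sub, genotypes = g,
         grs = genetic_risk_score(g, panel))
  })
}

#' Genetic risk score
#'
#' `GRS_i = sum_j log(OR_j) * g_ij`: the number of risk alleles carried at
#' each SNP weighted by the log per-allele odds ratio, summed over the panel.
#'
#' @param genotypes subjects x SNPs matrix of risk-allele counts.
#' @param panel a [snp_panel()] with one row per genotype column.
#' @return numeric vector of scores.
#' @export
genetic_risk_score <- function(genotypes, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (ncol(genotypes) != nrow(panel))
    stop("genotype matrix has ", ncol(genotypes),
         " columns but panel has ", nrow(panel), " SNPs")
  drop(genotypes %*% log(panel$odds_ratio))
}

#' Quintile labels for a score vector
#'
#' Boundaries are the empirical 20/40/60/80th percentiles of the pooled
#' cohort.  Ties are resolved by stable rank: scores exactly on a boundary
#' fall in the lower quintile, and a fully constant vector is labelled
#' quintile 1.
#'
#' @param grs numeric score vector, length >= 5.
#' @return integer vector of labels 1-5.
#' @export
#' @examples
#' grs_quintiles(1:10)  # 1 1 2 2 3 3 4 4 5 5
grs_quintiles <- function(grs) {
  n <- length(grs)
  if (n < 5L) stop("need at least 5 scores to form quintiles")
  r <- rank(grs, ties.method = "min")
  as.integer(ceiling(r * 5 / n))
}
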