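# One-time generator for the shipped synthetic 75-SNP panel.
# The published SNP list is unavailable, so (frequency, odds-ratio) pairs are
# drawn once here and calibrated so that the control-group GRS has mean 4.53
# and SD 0.37 — the location/scale implied by the published population
# quintile boundaries (4.22 / 4.43 / 4.62 / 4.84) under normal-quantile
# spacing.  Run from the repository root; output is committed.
set.seed(75)
m <- 75L
p0 <- runif(m, 0.10, 0.90)
w0 <- abs(rnorm(m, 0.08, 0.03))
w0 <- pmax(w0, 0.01)

target_mean <- 4.53
target_sd <- 0.37

ratio <- function(a) {
  p <- p0^a
  sum(2 * p * w0) / sqrt(sum(2 * p * (1 - p) * w0^2))
}
a <- uniroot(function(a) ratio(a) - target_mean / target_sd,
             lower = 0.05, upper = 20, tol = 1e-12)$root
p <- p0^a
cscale <- target_sd / sqrt(sum(2 * p * (1 - p) * w0^2))
w <- cscale * w0

panel <- data.frame(
  snp_id = sprintf("snp%02d_synth", seq_len(m)),
  risk_allele_freq = round(p, 4),
  odds_ratio = round(exp(w), 4)
)

wr <- log(panel$odds_ratio)
pr <- panel$risk_allele_freq
cat(sprintf("after rounding: mean %.4f sd %.4f (targets %.2f / %.2f)\n",
            sum(2 * pr * wr), sqrt(sum(2 * pr * (1 - pr) * wr^2)),
            target_mean, target_sd))
cat(sprintf("OR range: %.4f - %.4f; freq range: %.4f - %.4f\n",
            min(panel$odds_ratio), max(panel$odds_ratio),
            min(pr), max(pr)))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(panel, "inst/extdata/snp_panel_synthetic75.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote inst/extdata/snp_panel_synthetic75.tsv\n")
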