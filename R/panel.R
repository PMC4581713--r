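#' SNP panel constructor / validator
#'
#' A panel is one row per SNP: identifier, risk-allele frequency `p` in (0,1),
#' and per-allele odds ratio.  `log(odds_ratio)` is the weight of the SNP in
#' the genetic risk score.
#'
#' @param df data.frame with columns `snp_id`, `risk_allele_freq`,
#'   `odds_ratio`.
#' @return the validated data.frame with class `snp_panel` prepended.
#' @export
snp_panel <- function(df) {
  req <- c("snp_id", "risk_allele_freq", "odds_ratio")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop("panel has duplicate snp_id(s): ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  p <- df$risk_allele_freq
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("risk_allele_freq out of range: all frequencies must lie in (0, 1)")
  or <- df$odds_ratio
  if (any(!is.finite(or)) || any(or <= 0))
    stop("odds_ratio out of range: all odds ratios must be > 0")
  class(df) <- unique(c("snp_panel", class(df)))
  df
}

#' Read a SNP panel from TSV
#'
#' Expects a header line with columns `snp_id`, `risk_allele_freq`,
#' `odds_ratio`.
#'
#' @param path TSV file path.
#' @return a validated [snp_panel()].
#' @export
read_snp_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  snp_panel(df)
}

#' The default 75-SNP panel
#'
#' The published list of 75 susceptibility loci with their allele frequencies
#' and odds ratios is not available, so the package ships a synthetic stand-in
#' panel (`inst/extdata/snp_panel_synthetic75.tsv`): 75 `(frequency, odds
#' ratio)` pairs drawn once and calibrated so the genetic risk score among
#' non-cases has mean ~4.53 and standard deviation ~0.37, the location and
#' scale implied by the published population quintile boundaries
#' (4.22/4.43/4.62/4.84).  Any user panel in the same TSV schema can replace
#' it.
#'
#' @return a [snp_panel()] with 75 rows.
#' @export
default_snp_panel <- function() {
  path <- system.file("extdata", "snp_panel_synthetic75.tsv",
                      package = "brcarisk", mustWork = TRUE)
  read_snp_panel(path)
}

#' Theoretical GRS moments of a panel under Hardy-Weinberg controls
#'
#' Mean `sum(2 p w)` and standard deviation `sqrt(sum(2 p (1-p) w^2))` of the
#' genetic risk score among controls, with `w = log(odds_ratio)`; SNPs are
#' independent.
#'
#' @param panel a [snp_panel()].
#' @return named numeric `c(mean =, sd =)`.
#' @export
panel_grs_moments <- function(panel) {
  w <- log(panel$odds_ratio)
  p <- panel$risk_allele_freq
  c(mean = sum(2 * p * w), sd = sqrt(sum(2 * p * (1 - p) * w^2)))
}
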