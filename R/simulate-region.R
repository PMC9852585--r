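#' Simulate a summary-statistic region with LD for colocalisation tests
#'
#' Generates per-SNP effect estimates and standard errors for a GWAS trait
#' and an eQTL trait over one genomic region, together with the LD
#' (correlation) matrix, under a named causal scenario. LD follows an AR(1)
#' structure \eqn{R_{ij} = \rho^{|i-j|}}, which is positive definite for
#' \eqn{|\rho| < 1}. Marginal z-scores are drawn as
#' \eqn{z = R z_{joint} + MVN(0, R)} — the standard summary-statistic
#' sampling model — and converted to betas on the standardised scale with
#' \eqn{se = 1/\sqrt{n}}. Causal joint z-scores are set to 8 (GWAS) and 10
#' (eQTL) so the top association clears \eqn{|z| > 6} in non-null
#' scenarios.
#'
#' @param n_snps number of SNPs in the region (at least 2).
#' @param ld_decay AR(1) correlation parameter \eqn{\rho \in [0, 1)}.
#' @param scenario one of `"shared-causal"` (one variant drives both
#'   traits), `"distinct-causal"` (different variants), `"gwas-only"`,
#'   `"null"`.
#' @param n_gwas,n_eqtl sample sizes behind the two summary-statistic sets.
#' @param seed integer seed.
#' @return A list with data frames `gwas` and `eqtl` (columns snp, beta,
#'   se, z, n), the `ld` matrix, and `causal` (the causal index per trait,
#'   `NA` under the null).
#' @export
simulate_summary_region <- function(n_snps, ld_decay = 0.7,
                                    scenario = c("shared-causal", "distinct-causal",
                                                 "gwas-only", "null"),
                                    n_gwas = 10000, n_eqtl = 1000, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_snps < 2L) stop("n_snps must be at least 2")
  if (ld_decay < 0 || ld_decay >= 1)
    stop("ld_decay must lie in [0, 1) for a positive-definite LD matrix")
  set_sim_seed(seed)
  R <- ld_decay^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  L <- chol(R)
  cg <- ce <- NA_integer_
  if (scenario == "shared-causal") cg <- ce <- as.integer(ceiling(n_snps / 2))
  if (scenario == "distinct-causal") {
    # two causal variants in low but non-zero LD (a few SNPs apart), the
    # linkage alternative that SMR/HEIDI is designed to reject
    ce <- as.integer(ceiling(n_snps / 2))
    cg <- max(1L, ce - 3L)
  }
  if (scenario == "gwas-only") cg <- as.integer(ceiling(n_snps / 2))
  draw <- function(causal, z_top, n) {
    zj <- numeric(n_snps)
    if (!is.na(causal)) zj[causal] <- z_top
    z <- drop(R %*% zj) + drop(crossprod(L, rnorm(n_snps)))
    se <- rep(1 / sqrt(n), n_snps)
    data.frame(snp = sprintf("rsr%03d", seq_len(n_snps)),
               beta = z * se, se = se, z = z, n = n)
  }
  list(gwas = draw(cg, 8, n_gwas), eqtl = draw(ce, 10, n_eqtl),
       ld = R, causal = list(gwas = cg, eqtl = ce))
}
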