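#' Predicted replication standard error under the power formula
#'
#' For a variance-standardised phenotype and an additive per-allele effect,
#' the sampling standard error of the effect estimate in a replication
#' cohort of `n_repl` individuals at a variant with effect-allele frequency
#' `freq1` is \deqn{se = 1 / \sqrt{2\, n_{repl}\, freq1\,(1 - freq1)}.}
#' Assuming the discovery effect size carries over, this predicts whether a
#' signal is replicable at a given replication sample size.
#'
#' @param freq1 effect-allele frequency in (0, 1).
#' @param n_repl replication sample size (>= 1).
#' @return Predicted standard error (SD units per allele).
#' @examples
#' predicted_replication_se(0.58, 17787)  # ~0.011
#' @export
predicted_replication_se <- function(freq1, n_repl) {
  if (any(freq1 <= 0 | freq1 >= 1)) stop("freq1 must lie strictly in (0, 1)")
  if (any(n_repl < 1)) stop("n_repl must be at least 1")
  1 / sqrt(2 * n_repl * freq1 * (1 - freq1))
}

#' Expected replication P value given a discovery effect
#'
#' One-sided upper-tail standard-normal probability at the expected
#' replication z-score \eqn{|\beta_{disc}| / se_{pred}}: the P value the
#' replication analysis would be expected to produce if the discovery
#' effect size were exact.
#'
#' @param beta_disc discovery effect estimate.
#' @param se_pred predicted replication standard error (see
#'   [predicted_replication_se()]).
#' @return Expected one-sided replication P value.
#' @export
expected_replication_pvalue <- function(beta_disc, se_pred) {
  if (any(se_pred <= 0)) stop("se_pred must be positive")
  stats::pnorm(abs(beta_disc / se_pred), lower.tail = FALSE)
}

#' Select signals replicable at a given replication sample size
#'
#' Applies the power calculation to a table of discovery records and keeps
#' those whose expected replication P value is below `p_max`.
#'
#' @param records data frame with columns `beta1` (discovery effect) and
#'   `freq1` (effect-allele frequency).
#' @param n_repl replication sample size.
#' @param p_max selection cutoff on the expected replication P value.
#' @return The subset of `records`, with columns `se_pred` and `p_pred`
#'   added (the full annotated table is attached as attribute `all`).
#' @export
select_replicable <- function(records, n_repl, p_max) {
  records$se_pred <- predicted_replication_se(records$freq1, n_repl)
  records$p_pred <- expected_replication_pvalue(records$beta1, records$se_pred)
  out <- records[records$p_pred < p_max, , drop = FALSE]
  attr(out, "all") <- records
  out
}

#' One-sided replication P value
#'
#' Upper-tail standard-normal probability at
#' \eqn{sign(\beta_{disc}) \cdot \beta_{repl} / se_{repl}}: below 0.5 iff
#' the replication effect has the same sign as the discovery effect.
#'
#' @param beta_disc,beta_repl discovery and replication effect estimates.
#' @param se_repl replication standard error (> 0).
#' @return One-sided P value.
#' @export
one_sided_replication_pvalue <- function(beta_disc, beta_repl, se_repl) {
  if (any(se_repl <= 0)) stop("se_repl must be positive")
  stats::pnorm(sign(beta_disc) * beta_repl / se_repl, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, mapped back to the input
#' order. Wraps the standard step-up implementation.
#'
#' @param pvalues numeric vector of P values in \[0, 1\].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("pvalues must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Exact one-sided sign test for directional consistency
#'
#' Probability of observing at least `k_consistent` direction-consistent
#' results out of `n` under the null of sign agreement by chance:
#' \eqn{P(X \ge k) = \sum_{j=k}^{n} \binom{n}{j} 2^{-n}}.
#'
#' @param k_consistent number of direction-consistent pairs.
#' @param n number of pairs tested.
#' @return Exact one-sided binomial P value.
#' @examples
#' sign_test(19, 27)  # 0.0261
#' @export
sign_test <- function(k_consistent, n) {
  if (k_consistent < 0 || k_consistent > n) stop("need 0 <= k_consistent <= n")
  if (k_consistent == 0L) return(1)
  stats::binom.test(k_consistent, n, p = 0.5, alternative = "greater")$p.value
}

#' Replication test over a set of discovery signals
#'
#' Joins discovery records with replication summary statistics, computes
#' the one-sided replication P value per record, applies
#' Benjamini-Hochberg FDR over the tested set, and flags a record as
#' replicated when its effect direction agrees with discovery and its
#' q-value is below `fdr_level`. A zero replication effect counts as
#' direction-inconsistent. A sign test over all tested records summarises
#' directional consistency.
#'
#' @param discovery data frame with columns `rsid`, `trait`, `beta1`,
#'   optionally `se`, `freq1`.
#' @param replication data frame with columns `rsid`, `trait`, `beta`
#'   (replication effect), `se`.
#' @param fdr_level FDR threshold for successful replication (default 0.1).
#' @return Object of class `replication_result`: list with `records` (the
#'   joined table with `p_one_sided`, `q`, `consistent`, `replicated`),
#'   `n_tested`, `n_consistent`, `n_replicated`, `sign_test_p`, and
#'   `unmatched` (discovery records with no replication row).
#' @export
test_replication <- function(discovery, replication, fdr_level = 0.1) {
  key_d <- paste(discovery$rsid, discovery$trait, sep = "|")
  key_r <- paste(replication$rsid, replication$trait, sep = "|")
  idx <- match(key_d, key_r)
  unmatched <- discovery[is.na(idx), , drop = FALSE]
  matched <- which(!is.na(idx))
  rec <- discovery[matched, , drop = FALSE]
  rep_rows <- replication[idx[matched], , drop = FALSE]
  rec$beta_repl <- rep_rows$beta
  rec$se_repl <- rep_rows$se
  rec$p_one_sided <- one_sided_replication_pvalue(rec$beta1, rec$beta_repl, rec$se_repl)
  rec$q <- benjamini_hochberg(rec$p_one_sided)
  rec$consistent <- sign(rec$beta1) == sign(rec$beta_repl) & rec$beta_repl != 0
  rec$replicated <- rec$consistent & rec$q < fdr_level
  structure(list(records = rec,
                 n_tested = nrow(rec),
                 n_consistent = sum(rec$consistent),
                 n_replicated = sum(rec$replicated),
                 sign_test_p = sign_test(sum(rec$consistent), nrow(rec)),
                 fdr_level = fdr_level,
                 unmatched = unmatched),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Replication: %d/%d direction-consistent, %d replicated at FDR %.0f%%\n",
              x$n_consistent, x$n_tested, x$n_replicated, 100 * x$fdr_level))
  cat(sprintf("  sign test P = %.4g\n", x$sign_test_p))
  if (nrow(x$unmatched))
    cat(sprintf("  %d discovery record(s) had no replication match\n",
                nrow(x$unmatched)))
  invisible(x)
}

#' Published replication table of 27 prioritised signals
#'
#' Loads the bundled table of 27 prioritised loci with discovery and
#' replication summary statistics (effect allele, frequency, discovery
#' beta/se/P, replication beta/se/Q). Used by the worked examples and to
#' cross-check the directional-consistency count and sign test.
#'
#' @return Data frame with one row per SNP.
#' @export
replication_snps <- function() {
  utils::read.delim(system.file("extdata", "replication_snps.tsv",
                                package = "proxygwas"),
                    stringsAsFactors = FALSE)
}
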