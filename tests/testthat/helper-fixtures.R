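# shared fixtures, built in code

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_total = 600, n_measured = 150, m_variants = 40, n_causal = 2,
             seed = seed, ...)
}

# latent-scale config: no exponential map, no sex differences, no covariate
# effects, so analytic truth is directly comparable to raw-scale fits
latent_config <- function(...) {
  defaults <- list(positive_scale = FALSE,
                   sex_loading_scale = c(male = 1, female = 1),
                   sex_factor_shift = c(male = 0, female = 0),
                   covariate_effects = list(factor = rep(0, 4),
                                            proxies = rep(0, 4),
                                            target = rep(0, 4)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# chi-square goodness-of-fit test of Hardy-Weinberg proportions (1 df)
hwe_pvalue <- function(dosage) {
  n <- length(dosage)
  counts <- c(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expd < 1e-12)) return(1)
  x2 <- sum((counts - expd)^2 / expd)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

# Table of 27 prioritised SNPs with discovery + replication statistics
replication_table <- function() replication_snps()
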