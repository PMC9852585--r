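#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and [simulate_replication_cohort()]. The generative
#' model is a shared latent adiposity factor: causal variants act on a
#' target phenotype partly through the factor (the mediated share
#' \eqn{\delta_k}) and partly directly; proxy phenotypes load on the factor
#' only. This is the structure that makes proxy-based imputation of the
#' target informative for GWAS, and the mediation fraction is the dial that
#' controls how much of each variant's signal survives imputation.
#'
#' @param n_total number of individuals in the full cohort.
#' @param n_measured number of individuals with the target phenotype
#'   observed (the model-training subset).
#' @param m_variants number of simulated variants.
#' @param maf_range interval in (0, 0.5] from which per-variant allele
#'   frequencies are drawn uniformly.
#' @param n_causal number of causal variants.
#' @param effect_sizes per-causal-variant latent effect \eqn{b_k} in
#'   phenotype SD units per allele; recycled to length `n_causal`.
#' @param mediation_fractions per-causal-variant \eqn{\delta_k \in [0,1]},
#'   the share of the genetic effect acting through the proxy-shared
#'   factor; recycled to length `n_causal`.
#' @param n_proxies number of proxy phenotypes.
#' @param proxy_loadings per-proxy loading \eqn{\lambda_j} on the latent
#'   factor; recycled to length `n_proxies`.
#' @param proxy_noise_sd,factor_noise_sd,target_noise_sd residual SDs of
#'   the proxies, latent factor and target.
#' @param covariate_effects list with numeric vectors `factor`, `proxies`,
#'   `target`, each of length 4 giving the effects of (age, batch, pc1,
#'   pc2) on the latent factor, every proxy, and the target.
#' @param positive_scale logical; map latent values onto a positive scale
#'   by `exp(positive_mu + positive_s * value)` (so a natural-log transform
#'   recovers an affine image of the latent value).
#' @param positive_mu,positive_s location and scale of the exponential map.
#' @param sex_loading_scale named numeric (`male`, `female`): per-sex
#'   multiplier on the proxy loadings, giving the two strata different
#'   prediction models.
#' @param sex_factor_shift named numeric (`male`, `female`): per-sex mean
#'   shift of the latent factor.
#' @param n_replication size of the independent replication cohort.
#' @param seed integer seed; fully determines every simulated output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_total = 500, n_measured = 100, m_variants = 50,
#'                   n_causal = 1, seed = 1)
#' @export
sim_config <- function(n_total = 20000L,
                       n_measured = 1000L,
                       m_variants = 500L,
                       maf_range = c(0.05, 0.5),
                       n_causal = 5L,
                       effect_sizes = 0.25,
                       mediation_fractions = 1,
                       n_proxies = 3L,
                       proxy_loadings = c(0.9, 0.8, 0.7),
                       proxy_noise_sd = 0.5,
                       factor_noise_sd = 1,
                       target_noise_sd = 0.5,
                       covariate_effects = list(
                         factor  = c(age = 0.01, batch = 0.05, pc1 = 0.05, pc2 = 0.05),
                         proxies = c(age = 0.005, batch = 0.02, pc1 = 0, pc2 = 0),
                         target  = c(age = 0, batch = 0, pc1 = 0, pc2 = 0)),
                       positive_scale = TRUE,
                       positive_mu = 3,
                       positive_s = 0.25,
                       sex_loading_scale = c(male = 1, female = 1.15),
                       sex_factor_shift = c(male = 0, female = -0.3),
                       n_replication = 2000L,
                       seed = 1L) {
  cfg <- list(
    n_total = as.integer(n_total), n_measured = as.integer(n_measured),
    m_variants = as.integer(m_variants), maf_range = as.numeric(maf_range),
    n_causal = as.integer(n_causal),
    effect_sizes = rep_len(as.numeric(effect_sizes), max(n_causal, 1L))[seq_len(n_causal)],
    mediation_fractions = rep_len(as.numeric(mediation_fractions), max(n_causal, 1L))[seq_len(n_causal)],
    n_proxies = as.integer(n_proxies),
    proxy_loadings = rep_len(as.numeric(proxy_loadings), n_proxies),
    proxy_noise_sd = as.numeric(proxy_noise_sd),
    factor_noise_sd = as.numeric(factor_noise_sd),
    target_noise_sd = as.numeric(target_noise_sd),
    covariate_effects = covariate_effects,
    positive_scale = isTRUE(positive_scale),
    positive_mu = as.numeric(positive_mu), positive_s = as.numeric(positive_s),
    sex_loading_scale = sex_loading_scale,
    sex_factor_shift = sex_factor_shift,
    n_replication = as.integer(n_replication),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_total <= 0L) stop("n_total must be positive")
  if (cfg$n_measured <= 0L) stop("n_measured must be positive")
  if (cfg$n_measured > cfg$n_total) stop("n_measured must not exceed n_total")
  if (cfg$m_variants <= 0L) stop("m_variants must be positive")
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$m_variants)
    stop("n_causal must be in [0, m_variants]")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (cfg$n_causal > 0L &&
      (any(cfg$mediation_fractions < 0) || any(cfg$mediation_fractions > 1)))
    stop("mediation_fractions must lie in [0, 1]")
  if (cfg$proxy_noise_sd < 0 || cfg$factor_noise_sd < 0 || cfg$target_noise_sd < 0)
    stop("noise SDs must be non-negative")
  for (nm in c("factor", "proxies", "target")) {
    if (length(cfg$covariate_effects[[nm]]) != 4L)
      stop(sprintf("covariate_effects$%s must have length 4 (age, batch, pc1, pc2)", nm))
  }
  for (nm in c("male", "female")) {
    if (is.na(cfg$sex_loading_scale[nm])) stop("sex_loading_scale needs male and female entries")
    if (is.na(cfg$sex_factor_shift[nm])) stop("sex_factor_shift needs male and female entries")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d (measured subset: %d), replication: %d\n",
              x$n_total, x$n_measured, x$n_replication))
  cat(sprintf("  variants: %d (causal: %d), MAF in [%.3g, %.3g]\n",
              x$m_variants, x$n_causal, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  proxies: %d, positive scale: %s, seed: %d\n",
              x$n_proxies, x$positive_scale, x$seed))
  invisible(x)
}
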