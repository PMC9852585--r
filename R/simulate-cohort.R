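#' Simulate a cohort with proxy and target phenotypes sharing a latent factor
#'
#' Generates genotypes, covariates, proxy phenotypes and a target phenotype
#' under a latent-factor model with known ground truth. Genotype dosages are
#' drawn as Binomial(2, p) per variant (Hardy-Weinberg, no LD between
#' variants). Within each sex stratum the latent adiposity factor is
#' \deqn{A_i = shift_s + \sum_k \delta_k b_k (g_{ik} - 2p_k) + z_i'\gamma_A + N(0, \sigma_A^2),}
#' proxies are \eqn{x_{ij} = c_s \lambda_j A_i + z_i'\gamma_x + N(0,\sigma_x^2)}
#' and the target is
#' \eqn{y_i = A_i + \sum_k (1-\delta_k) b_k (g_{ik} - 2p_k) + z_i'\gamma_y + N(0,\sigma_y^2)},
#' where \eqn{z_i} holds centred covariates (age, batch, two PC-like axes)
#' and \eqn{c_s} is the per-sex loading scale. Positive-scale phenotypes are
#' obtained as \eqn{\exp(\mu + s\cdot value)}. The target is retained only
#' for a random subset of `n_measured` individuals.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `cohort` (data frame: id, sex, covariates,
#'   proxies, target, measured flag), `genotypes` (a `genotype_matrix`:
#'   dosage matrix plus variant metadata) and `truth` (a `truth_record`
#'   with causal indices, effects, mediation fractions, latent factor
#'   values, per-sex theoretical imputation R-squared and the theoretical
#'   marginal effects of each causal variant on the target and on its
#'   proxy-predictable component).
#' @examples
#' sim <- simulate_cohort(sim_config(n_total = 300, n_measured = 80,
#'                                   m_variants = 40, n_causal = 1, seed = 7))
#' str(sim$truth$r2_theory)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set_sim_seed(config$seed)
  panel <- draw_variant_panel(config)
  dat <- draw_individuals(config, config$n_total, panel)
  measured <- sort(sample.int(config$n_total, config$n_measured))
  cohort <- dat$cohort
  cohort$measured <- seq_len(config$n_total) %in% measured
  cohort$target[!cohort$measured] <- NA_real_
  theo <- theoretical_imputation(config, panel)
  truth <- structure(list(
    causal_index = panel$causal_index,
    causal_id = panel$variants$id[panel$causal_index],
    b = config$effect_sizes,
    delta = config$mediation_fractions,
    p = panel$p,
    A = dat$A,
    r2_theory = theo$r2,
    alpha = theo$alpha,
    var_y = theo$var_y,
    marginal_target = theo$marginal_target,
    marginal_imputed = theo$marginal_imputed,
    config = config), class = "truth_record")
  list(cohort = cohort,
       genotypes = new_genotype_matrix(dat$dosages, panel$variants),
       truth = truth)
}

#' Simulate an independent replication cohort under the same architecture
#'
#' Draws fresh individuals with the same variant frequencies and causal
#' effects as a prior [simulate_cohort()] call; every individual has the
#' target phenotype measured, mirroring a directly measured replication
#' sample.
#'
#' @param config the [sim_config()] used for the discovery cohort (its
#'   `n_replication` field sets the size).
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @return A list with elements `cohort` and `genotypes`.
#' @export
simulate_replication_cohort <- function(config, truth) {
  validate_sim_config(config)
  if (!inherits(truth, "truth_record")) stop("truth must come from simulate_cohort()")
  if (config$n_replication <= 0L) stop("n_replication must be positive")
  # same variant panel as discovery (replay the seeded panel draw), fresh
  # individuals from an offset stream
  set_sim_seed(config$seed)
  panel <- draw_variant_panel(config)
  stopifnot(identical(panel$p, truth$p))
  set_sim_seed(config$seed + 500009L)
  set_sim_seed(config$seed + 500009L)
  dat <- draw_individuals(config, config$n_replication, panel)
  cohort <- dat$cohort
  cohort$measured <- TRUE
  list(cohort = cohort,
       genotypes = new_genotype_matrix(dat$dosages, panel$variants))
}

# variant panel: frequencies, genomic placement, alleles, info scores.
# causal variants are evenly spaced across the panel so that simulated causal
# loci stay mutually independent under the 1-Mb clustering rule.
draw_variant_panel <- function(cfg) {
  m <- cfg$m_variants
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  n_chr <- min(22L, m)
  chr <- sort(rep_len(seq_len(n_chr), m))
  pos <- integer(m)
  for (c_ in unique(chr)) {
    i <- which(chr == c_)
    pos[i] <- cumsum(as.integer(runif(length(i), 2e5, 8e5))) + 1e6L
  }
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a0 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  info <- rbeta(m, 20, 1)
  causal_index <- if (cfg$n_causal > 0L) {
    unique(round(seq(1, m, length.out = cfg$n_causal + 2L)))[seq_len(cfg$n_causal) + 1L]
  } else integer(0)
  variants <- data.frame(
    id = sprintf("snp%04d", seq_len(m)), chr = as.character(chr), pos = pos,
    a1 = a1, a0 = a0, eaf = p, info = info, stringsAsFactors = FALSE)
  list(p = p, variants = variants, causal_index = causal_index)
}

draw_individuals <- function(cfg, n, panel) {
  m <- cfg$m_variants
  dos <- matrix(rbinom(n * m, 2L, rep(panel$p, each = n)), nrow = n, ncol = m)
  colnames(dos) <- panel$variants$id
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  age <- runif(n, 40, 70)
  batch <- sample.int(5L, n, replace = TRUE)
  pc1 <- rnorm(n); pc2 <- rnorm(n)
  z <- cbind(age - 55, batch - 3, pc1, pc2)
  ce <- cfg$covariate_effects
  g_cent <- sweep(dos[, panel$causal_index, drop = FALSE], 2L,
                  2 * panel$p[panel$causal_index], "-")
  gA <- if (cfg$n_causal > 0L)
    drop(g_cent %*% (cfg$mediation_fractions * cfg$effect_sizes)) else numeric(n)
  gD <- if (cfg$n_causal > 0L)
    drop(g_cent %*% ((1 - cfg$mediation_fractions) * cfg$effect_sizes)) else numeric(n)
  shift <- unname(cfg$sex_factor_shift[sex])
  A <- shift + gA + drop(z %*% ce$factor) + rnorm(n, 0, cfg$factor_noise_sd)
  lscale <- unname(cfg$sex_loading_scale[sex])
  x <- matrix(NA_real_, n, cfg$n_proxies)
  for (j in seq_len(cfg$n_proxies)) {
    x[, j] <- lscale * cfg$proxy_loadings[j] * A + drop(z %*% ce$proxies) +
      rnorm(n, 0, cfg$proxy_noise_sd)
  }
  colnames(x) <- paste0("proxy", seq_len(cfg$n_proxies))
  y <- A + gD + drop(z %*% ce$target) + rnorm(n, 0, cfg$target_noise_sd)
  if (cfg$positive_scale) {
    x <- exp(cfg$positive_mu + cfg$positive_s * x)
    y <- exp(cfg$positive_mu + cfg$positive_s * y)
  }
  cohort <- data.frame(id = sprintf("id%06d", seq_len(n)), sex = sex,
                       age = age, batch = batch, pc1 = pc1, pc2 = pc2,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(x))
  cohort$target <- y
  list(cohort = cohort, dosages = dos, A = A)
}

# closed-form second moments of the latent-scale generative model, per sex:
# best-linear-predictor R^2 of the target from the proxies, the composite
# loading alpha (slope of the predictable component on the latent factor),
# and the theoretical marginal effect of each causal variant on the target
# (b_k) and on its proxy-predictable component (delta_k * b_k * alpha).
theoretical_imputation <- function(cfg, panel) {
  v <- 2 * panel$p[panel$causal_index] * (1 - panel$p[panel$causal_index])
  b <- cfg$effect_sizes; d <- cfg$mediation_fractions
  VgA <- sum((d * b)^2 * v); VgD <- sum(((1 - d) * b)^2 * v)
  Cg <- sum(d * (1 - d) * b^2 * v)
  Sc <- diag(c(75, 2, 1, 1))  # var(age), var(batch), var(pc1), var(pc2)
  gA <- cfg$covariate_effects$factor
  gx <- cfg$covariate_effects$proxies
  gy <- cfg$covariate_effects$target
  out <- list(r2 = c(), alpha = c(), var_y = c(),
              marginal_target = b,
              marginal_imputed = list())
  for (s in c("male", "female")) {
    lam <- cfg$sex_loading_scale[[s]] * cfg$proxy_loadings
    varA <- VgA + drop(t(gA) %*% Sc %*% gA) + cfg$factor_noise_sd^2
    covAy <- varA + Cg + drop(t(gA) %*% Sc %*% gy)
    vary <- varA + VgD + 2 * Cg + 2 * drop(t(gA) %*% Sc %*% gy) +
      drop(t(gy) %*% Sc %*% gy) + cfg$target_noise_sd^2
    gAx <- drop(t(gA) %*% Sc %*% gx)
    gxx <- drop(t(gx) %*% Sc %*% gx)
    Sxx <- outer(lam, lam) * varA + outer(lam, rep(gAx, cfg$n_proxies)) +
      outer(rep(gAx, cfg$n_proxies), lam) + gxx +
      diag(cfg$proxy_noise_sd^2, cfg$n_proxies)
    Sxy <- lam * covAy + drop(t(gx) %*% Sc %*% (gA + gy))
    w <- solve(Sxx, Sxy)
    out$r2[s] <- drop(Sxy %*% w) / vary
    out$alpha[s] <- sum(lam * w)
    out$var_y[s] <- vary
    out$marginal_imputed[[s]] <- d * b * out$alpha[s]
  }
  out
}

new_genotype_matrix <- function(dosages, variants) {
  stopifnot(ncol(dosages) == nrow(variants))
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chr))))
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("Simulation truth: %d causal variant(s)\n", length(x$causal_index)))
  if (length(x$causal_index)) {
    cat("  ids:", paste(x$causal_id, collapse = ", "), "\n")
    cat("  b:", paste(signif(x$b, 3), collapse = ", "),
        " delta:", paste(signif(x$delta, 3), collapse = ", "), "\n")
  }
  cat(sprintf("  theoretical imputation R2: male %.3f, female %.3f\n",
              x$r2_theory[["male"]], x$r2_theory[["female"]]))
  invisible(x)
}
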