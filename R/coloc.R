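#' Wakefield approximate Bayes factor (log scale)
#'
#' Log approximate Bayes factor for a single association summary statistic
#' under a normal prior on the true effect with standard deviation
#' `prior_sd`: with shrinkage \eqn{r = W/(se^2 + W)}, \eqn{W = prior\_sd^2}
#' and \eqn{z = \beta/se},
#' \deqn{\ln ABF = \tfrac12 [\ln(1 - r) + r z^2].}
#'
#' @param beta effect estimate.
#' @param se its standard error (> 0).
#' @param prior_sd prior SD of the true effect (default 0.15, the
#'   quantitative-trait convention).
#' @return Log ABF (vectorised over `beta`/`se`).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_sd < 0) stop("prior_sd must be non-negative")
  W <- prior_sd^2
  r <- W / (se^2 + W)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalisation posterior probabilities from per-SNP log ABFs
#'
#' Single-causal-variant enumeration over a region shared by two traits.
#' Hypotheses: H0 no association; H1/H2 one trait associated; H3 both,
#' distinct causal variants; H4 both, one shared causal variant. Unnormalised
#' weights are
#' \deqn{H0 \propto 1,\quad H1 \propto p_1 \sum_i e^{l_{1i}},\quad
#' H2 \propto p_2 \sum_i e^{l_{2i}},}
#' \deqn{H3 \propto p_1 p_2 [(\sum_i e^{l_{1i}})(\sum_j e^{l_{2j}}) -
#' \sum_i e^{l_{1i}+l_{2i}}],\quad H4 \propto p_{12} \sum_i e^{l_{1i}+l_{2i}},}
#' computed in log space with log-sum-exp and normalised. A region is
#' flagged colocalised when PP(H4) exceeds `h4_threshold` (default 0.75).
#'
#' @param labf1,labf2 equal-length vectors of per-SNP log ABFs for the two
#'   traits over the same SNPs.
#' @param p1,p2 prior probability a SNP is causal for trait 1 / trait 2.
#' @param p12 prior probability a SNP is causal for both.
#' @param h4_threshold decision threshold on PP(H4).
#' @return Object of class `coloc_result`: list with `pp` (named PP.H0..
#'   PP.H4, summing to 1), `colocalised` flag, `n_snps` and the priors.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             h4_threshold = 0.75) {
  if (length(labf1) != length(labf2)) stop("labf1 and labf2 must have equal length")
  if (length(labf1) == 0L) stop("empty region")
  for (pr in c(p1, p2, p12)) stop_if_not_scalar_prob(pr, "prior")
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  lh <- c(H0 = 0,
          H1 = log(p1) + l1,
          H2 = log(p2) + l2,
          H3 = log(p1) + log(p2) + logdiffexp(l1 + l2, l12),
          H4 = log(p12) + l12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  structure(list(pp = pp, colocalised = unname(pp["PP.H4"]) > h4_threshold,
                 h4_threshold = h4_threshold, n_snps = length(labf1),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d SNPs (priors p1=%g, p2=%g, p12=%g)\n",
              x$n_snps, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  cat(sprintf("  colocalised (PP.H4 > %.2f): %s\n", x$h4_threshold, x$colocalised))
  invisible(x)
}

#' Summary-based Mendelian randomisation test
#'
#' Tests whether a gene's expression mediates a GWAS signal using the top
#' eQTL as instrument: the effect of expression on the phenotype is
#' \eqn{b_{xy} = b_{GWAS} / b_{eQTL}} and the test statistic is
#' \deqn{T_{SMR} = \frac{z_{GWAS}^2 z_{eQTL}^2}{z_{GWAS}^2 + z_{eQTL}^2},}
#' compared to a 1-df chi-square distribution.
#'
#' @param z_gwas,z_eqtl z-scores of the GWAS and eQTL associations at the
#'   instrument SNP (`z_eqtl` must be non-zero).
#' @param b_gwas,b_eqtl the corresponding effect estimates.
#' @return List with `b_xy`, `t_smr` and `p_smr`.
#' @export
smr_test <- function(z_gwas, z_eqtl, b_gwas, b_eqtl) {
  if (any(z_eqtl == 0)) stop("z_eqtl must be non-zero")
  t_smr <- (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
  list(b_xy = b_gwas / b_eqtl, t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (pleiotropy/causality) from
#' LD between distinct causal variants. For SNPs i in an LD window around
#' the top eQTL (\eqn{r^2} with the top SNP within `r2_window`), it
#' compares \eqn{d_i = b_{xy}(i) - b_{xy}(top)}; under a shared causal
#' variant all \eqn{d_i = 0}. The statistic \eqn{\sum_i z_{d_i}^2} follows
#' an LD-induced weighted sum of 1-df chi-squares whose tail probability is
#' evaluated numerically (Imhof integration over the eigenvalues of the
#' correlation matrix of the \eqn{d_i}).
#'
#' @param b_gwas,se_gwas,b_eqtl,se_eqtl per-SNP effects and standard errors
#'   for the two traits, aligned with `ld`.
#' @param ld SNP correlation matrix.
#' @param top index of the instrument (top eQTL) SNP.
#' @param r2_window inclusive r-squared eligibility window around the top
#'   SNP (default `c(0.05, 0.9)`).
#' @param max_snps maximum number of SNPs used (most significant eQTL
#'   z-scores kept; default 20).
#' @return List with `p_heidi` (`NA` with `tested = FALSE` when fewer than
#'   3 eligible SNPs), `n_snps` used and `tested`.
#' @export
heidi_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl, ld, top,
                       r2_window = c(0.05, 0.9), max_snps = 20L) {
  m <- length(b_gwas)
  stopifnot(length(se_gwas) == m, length(b_eqtl) == m, length(se_eqtl) == m,
            nrow(ld) == m, ncol(ld) == m, top >= 1L, top <= m)
  r2 <- ld[, top]^2
  elig <- setdiff(which(r2 >= r2_window[1] & r2 <= r2_window[2]), top)
  if (length(elig) > max_snps) {
    ze <- abs(b_eqtl[elig] / se_eqtl[elig])
    elig <- elig[order(-ze)][seq_len(max_snps)]
  }
  if (length(elig) < 3L)
    return(list(p_heidi = NA_real_, n_snps = length(elig), tested = FALSE))
  idx <- c(elig, top)
  k <- length(elig)
  bxy <- b_gwas / b_eqtl
  d <- bxy[elig] - bxy[top]
  # delta-method covariance of d: gradients w.r.t. (b_gwas, b_eqtl) at the
  # eligible SNPs and the top SNP; GWAS and eQTL samples are independent
  A <- matrix(0, k, length(idx))  # d(d_i)/d(b_gwas)
  B <- matrix(0, k, length(idx))  # d(d_i)/d(b_eqtl)
  for (i in seq_len(k)) {
    A[i, i] <- 1 / b_eqtl[elig[i]]
    A[i, k + 1L] <- -1 / b_eqtl[top]
    B[i, i] <- -b_gwas[elig[i]] / b_eqtl[elig[i]]^2
    B[i, k + 1L] <- b_gwas[top] / b_eqtl[top]^2
  }
  Cg <- ld[idx, idx] * tcrossprod(se_gwas[idx])
  Ce <- ld[idx, idx] * tcrossprod(se_eqtl[idx])
  V <- A %*% Cg %*% t(A) + B %*% Ce %*% t(B)
  sd_d <- sqrt(diag(V))
  z_d <- d / sd_d
  Rd <- V / tcrossprod(sd_d)
  stat <- sum(z_d^2)
  lam <- eigen((Rd + t(Rd)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10]
  p <- imhof_tail(stat, lam)
  list(p_heidi = p, n_snps = k, tested = TRUE, stat = stat)
}

# upper-tail probability of a weighted sum of independent 1-df chi-squares,
# by Imhof (numeric inversion of the characteristic function):
# P(Q > q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du
imhof_tail <- function(q, lambda, tol = 1e-10) {
  lambda <- lambda[lambda > 1e-12]
  # a non-positive quantile (or an all-zero weight vector) is below the
  # support of the positively weighted chi-square sum
  if (length(lambda) == 0L || q <= 0) return(1)
  theta1 <- function(u) 0.5 * sum(atan(lambda * u)) - 0.5 * q * u
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lr <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    sin(th) / (u * exp(lr))
  }
  # The integrand oscillates with slowly decaying amplitude, so a single
  # adaptive quadrature over (0, Inf) is inaccurate.  Instead integrate up
  # to the first phase zero past the point where the phase is provably
  # monotone, then sum one alternating half-period integral per phase zero
  # and collapse the alternating series by iterated averaging (Euler
  # transformation), which converges to near machine precision here.
  u_mono <- max(sqrt(sum(1 / lambda) / q), 1e-8)
  n0 <- ceiling(-theta1(u_mono) / pi) + 1
  step <- 2 * pi / q
  roots <- numeric(26)
  lo <- u_mono
  for (k in 0:25) {
    target <- -(n0 + k) * pi
    hi <- lo + step
    while (theta1(hi) > target) hi <- hi + step
    roots[k + 1] <- stats::uniroot(function(u) theta1(u) - target, c(lo, hi),
                                   tol = 1e-12)$root
    lo <- roots[k + 1]
  }
  base <- stats::integrate(f, 0, roots[1], rel.tol = tol, abs.tol = tol,
                           subdivisions = 2000L)$value
  terms <- vapply(seq_len(25), function(k)
    stats::integrate(f, roots[k], roots[k + 1], rel.tol = tol, abs.tol = tol,
                     subdivisions = 200L)$value, numeric(1))
  s <- cumsum(terms)
  while (length(s) > 1) s <- (s[-1] + s[-length(s)]) / 2
  min(max(0.5 + (base + s) / pi, 1e-12), 1)
}

#' SMR and HEIDI over a summary-statistic region
#'
#' Picks the top eQTL SNP as instrument, runs [smr_test()] there and
#' [heidi_test()] over the surrounding region.
#'
#' @param gwas,eqtl data frames with columns `beta`, `se` over the same
#'   SNPs (as produced by [simulate_summary_region()]).
#' @param ld SNP correlation matrix aligned with the rows.
#' @param ... passed to [heidi_test()].
#' @return List of class `smr_result`: top index, `b_xy`, `t_smr`, `p_smr`,
#'   `p_heidi`, `n_heidi_snps`, `heidi_tested`.
#' @export
smr_heidi <- function(gwas, eqtl, ld, ...) {
  ze <- eqtl$beta / eqtl$se
  top <- which.max(abs(ze))
  zg <- gwas$beta / gwas$se
  smr <- smr_test(zg[top], ze[top], gwas$beta[top], eqtl$beta[top])
  hd <- heidi_test(gwas$beta, gwas$se, eqtl$beta, eqtl$se, ld, top, ...)
  structure(list(top = top, b_xy = smr$b_xy, t_smr = smr$t_smr,
                 p_smr = smr$p_smr, p_heidi = hd$p_heidi,
                 n_heidi_snps = hd$n_snps, heidi_tested = hd$tested),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR: instrument SNP %d, b_xy = %.3f, T = %.2f, P = %.3g\n",
              x$top, x$b_xy, x$t_smr, x$p_smr))
  if (x$heidi_tested)
    cat(sprintf("HEIDI: P = %.3g over %d SNPs\n", x$p_heidi, x$n_heidi_snps))
  else cat("HEIDI: not tested (fewer than 3 eligible SNPs)\n")
  invisible(x)
}
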