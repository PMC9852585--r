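#' Per-variant additive association scan
#'
#' Regresses an analysis-ready phenotype on allelic dosage, one variant at a
#' time, under an additive genetic model: for variant k,
#' \eqn{\beta_k = cov(g_k, y)/var(g_k)},
#' \eqn{se_k = \sqrt{RSS_k / ((n-2)\sum (g_{ik}-\bar g_k)^2}} and a
#' two-sided P value from the t distribution with \eqn{n-2} degrees of
#' freedom. Variants failing the minor-allele-frequency or imputation-info
#' filters, or with zero dosage variance, are omitted and recorded with a
#' reason. Missing dosages are mean-substituted per variant.
#'
#' @param genotypes a `genotype_matrix` (dosages + variant metadata), or a
#'   plain numeric matrix of dosages.
#' @param phenotype an [preprocess_phenotype()] result or a numeric vector
#'   (NA = excluded individual), row-aligned with the dosage matrix.
#' @param maf_min minimum minor-allele frequency (default 0.001).
#' @param info_min minimum imputation info score (default 0.4).
#' @return A `gwas_result` data frame with columns `rsid, chr, pos, a1, a0,
#'   freq1, info, n, beta1, se, p`, with an `excluded` attribute listing
#'   filtered variants and reasons. P values are floored at 1e-300.
#' @export
run_gwas <- function(genotypes, phenotype, maf_min = 0.001, info_min = 0.4) {
  if (inherits(genotypes, "genotype_matrix")) {
    dos <- genotypes$dosages; meta <- genotypes$variants
  } else {
    dos <- as.matrix(genotypes)
    meta <- data.frame(id = colnames(dos) %||% paste0("v", seq_len(ncol(dos))),
                       chr = "1", pos = seq_len(ncol(dos)),
                       a1 = "A", a0 = "G", eaf = NA_real_, info = 1,
                       stringsAsFactors = FALSE)
  }
  y <- if (inherits(phenotype, "analysis_phenotype")) phenotype$values else as.numeric(phenotype)
  if (length(y) != nrow(dos))
    stop("phenotype length must equal the number of genotype rows")
  keep <- which(!is.na(y))
  n <- length(keep)
  if (n < 3L) stop("fewer than 3 analysed individuals")
  y <- y[keep]
  g <- dos[keep, , drop = FALSE]
  # per-variant mean substitution of missing dosages
  n_missing <- colSums(is.na(g))
  if (any(n_missing > 0L)) {
    for (j in which(n_missing > 0L)) {
      mj <- mean(g[, j], na.rm = TRUE)
      g[is.na(g[, j]), j] <- mj
    }
  }
  freq1 <- colMeans(g) / 2
  maf <- pmin(freq1, 1 - freq1)
  gbar <- colMeans(g)
  Sgg <- colSums(g^2) - n * gbar^2
  reason <- rep(NA_character_, ncol(g))
  reason[Sgg <= 0] <- "zero dosage variance"
  reason[is.na(reason) & maf < maf_min] <- "MAF filter"
  reason[is.na(reason) & meta$info < info_min] <- "info filter"
  ok <- which(is.na(reason))
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sgy <- drop(crossprod(g[, ok, drop = FALSE], yc))
  beta <- Sgy / Sgg[ok]
  rss <- pmax(Syy - beta^2 * Sgg[ok], 0)
  se <- sqrt(rss / ((n - 2) * Sgg[ok]))
  tstat <- ifelse(se > 0, beta / se, Inf)
  p <- pmax(2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE), 1e-300)
  out <- data.frame(rsid = meta$id[ok], chr = meta$chr[ok], pos = meta$pos[ok],
                    a1 = meta$a1[ok], a0 = meta$a0[ok],
                    freq1 = freq1[ok], info = meta$info[ok], n = n,
                    beta1 = beta, se = se, p = p,
                    n_dosage_imputed = n_missing[ok],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- data.frame(rsid = meta$id[!is.na(reason)],
                                      reason = reason[!is.na(reason)],
                                      stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("GWAS result: %d variants tested, n = %d individuals\n",
              nrow(x), if (nrow(x)) x$n[1] else 0L))
  excl <- attr(x, "excluded")
  if (!is.null(excl) && nrow(excl))
    cat(sprintf("  %d variant(s) filtered (%s)\n", nrow(excl),
                paste(names(table(excl$reason)), table(excl$reason),
                      sep = ": ", collapse = ", ")))
  if (nrow(x)) {
    top <- x[which.min(x$p), c("rsid", "chr", "pos", "beta1", "se", "p")]
    cat("  top hit:\n"); print.data.frame(top, row.names = FALSE)
  }
  invisible(x)
}
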