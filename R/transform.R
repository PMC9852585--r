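#' Inverse rank-normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks using the
#' Blom offset: \eqn{\Phi^{-1}((rank - 3/8) / (n + 1/4))}. Ties receive
#' averaged ranks; the ordering of distinct values is preserved, and the
#' sample median of an odd-length vector maps to 0.
#'
#' @param values numeric vector (n >= 2, finite).
#' @return Transformed numeric vector of the same length.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))  # middle value maps to 0
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    stop("all values equal: ranks are degenerate, cannot rank-normalise")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Preprocess a phenotype for association analysis
#'
#' Runs the full per-sex preprocessing cascade used before GWAS:
#' \enumerate{
#'   \item natural log transform (non-positive raw values are excluded with
#'     reason `log-undefined`);
#'   \item removal of values more than `trim_log_sd` (default 6) standard
#'     deviations from the stratum mean;
#'   \item OLS residualisation on the covariates (categorical covariates
#'     one-hot expanded);
#'   \item inverse rank-normal transformation;
#'   \item removal of values more than `trim_int_sd` (default 4) standard
#'     deviations from the stratum mean;
#' }
#' after which the male and female strata are merged into one analysis
#' vector. Trimming uses the mean/SD of the currently included values in a
#' single pass. Rows with a missing covariate are excluded up front with
#' reason `missing-covariate`.
#'
#' @param raw numeric vector of raw (positive-scale) phenotype values.
#' @param covariates data frame of covariates, row-aligned with `raw`;
#'   character and factor columns are treated as categorical.
#' @param sex character vector of stratum labels, row-aligned.
#' @param trim_log_sd,trim_int_sd trimming half-widths in SD units.
#' @return Object of class `analysis_phenotype`: list with `values`
#'   (full-length, `NA` where excluded), `included` (logical mask),
#'   `reason` (per-row exclusion code or `"ok"`), and `audit` (counts
#'   removed per step and stratum).
#' @export
preprocess_phenotype <- function(raw, covariates, sex,
                                 trim_log_sd = 6, trim_int_sd = 4) {
  n <- length(raw)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n || length(sex) != n)
    stop("raw, covariates and sex must be row-aligned")
  reason <- rep("ok", n)
  values <- rep(NA_real_, n)
  reason[is.na(raw) | raw <= 0] <- "log-undefined"
  reason[reason == "ok" & !stats::complete.cases(covariates)] <- "missing-covariate"
  audit <- list()
  for (s in unique(sex)) {
    in_s <- which(sex == s & reason == "ok")
    lv <- log(raw[in_s])
    # 6 SD trim on the log scale
    mu <- mean(lv); sdev <- stats::sd(lv)
    out6 <- if (is.na(sdev) || sdev == 0) rep(FALSE, length(lv))
            else abs(lv - mu) > trim_log_sd * sdev
    reason[in_s[out6]] <- "6SD"
    keep <- in_s[!out6]
    lv <- lv[!out6]
    # a constant stratum cannot be rank-normalised; fail before the
    # residualisation turns the exact ties into floating-point noise
    if (length(lv) >= 2L && stats::sd(lv) == 0)
      stop("stratum '", s,
           "': all values equal: ranks are degenerate, cannot rank-normalise")
    # covariate residualisation
    X <- stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix in stratum '", s, "'")
    res <- stats::lm.fit(X, lv)$residuals
    # rank-normalise; an all-equal stratum fails here with the stratum named
    tv <- tryCatch(inverse_normal_transform(res),
                   error = function(e) stop("stratum '", s, "': ", conditionMessage(e)))
    mu2 <- mean(tv); sd2 <- stats::sd(tv)
    out4 <- abs(tv - mu2) > trim_int_sd * sd2
    reason[keep[out4]] <- "4SD"
    values[keep[!out4]] <- tv[!out4]
    audit[[s]] <- c(n = length(in_s), removed_6sd = sum(out6),
                    removed_4sd = sum(out4))
  }
  structure(list(values = values, included = reason == "ok",
                 reason = reason, audit = audit),
            class = "analysis_phenotype")
}

#' @export
print.analysis_phenotype <- function(x, ...) {
  cat(sprintf("Analysis phenotype: %d included of %d\n",
              sum(x$included), length(x$values)))
  tab <- table(x$reason[x$reason != "ok"])
  if (length(tab)) print(tab)
  invisible(x)
}
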