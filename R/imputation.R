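#' Fit a sex-stratified linear imputation model for a target phenotype
#'
#' Ordinary-least-squares fit of an observed target phenotype on a set of
#' proxy phenotypes plus an intercept, within one sex stratum of the
#' measured subset: \eqn{y = \beta_0 + \beta_1 x_1 + \dots + \beta_n x_n +
#' \varepsilon}. The fitted coefficients are later applied cohort-wide to
#' individuals lacking the target measurement.
#'
#' Rows with a missing proxy or target value are excluded from fitting.
#' Collinear proxies raise an error naming the dependent columns.
#'
#' @param cohort data frame with one row per individual; must contain a
#'   `sex` column, the `trait` column and every proxy column.
#' @param trait name of the target phenotype column.
#' @param proxies character vector of proxy column names.
#' @param stratum sex label selecting the stratum (e.g. `"male"`).
#' @return An object of class `imputation_model` with components `trait`,
#'   `stratum`, `coefficients` (intercept first), `sigma2` (residual
#'   variance), `n`, and training-data accuracy `r` and `r2`.
#' @seealso [predict.imputation_model()], [assess_accuracy()],
#'   [effective_sample_size()]
#' @examples
#' d <- data.frame(sex = "male", height = 1:10, y = 2 * (1:10) + 3)
#' m <- fit_imputation_model(d, "y", "height", "male")
#' coef(m)  # intercept 3, slope 2
#' @export
fit_imputation_model <- function(cohort, trait, proxies, stratum) {
  if (!trait %in% names(cohort)) stop(sprintf("trait column '%s' not found", trait))
  missing_proxy <- setdiff(proxies, names(cohort))
  if (length(missing_proxy))
    stop("missing proxy column(s): ", paste(missing_proxy, collapse = ", "))
  if (anyDuplicated(proxies)) stop("duplicated proxy names: rank-deficient design")
  rows <- cohort$sex == stratum & !is.na(cohort[[trait]])
  rows <- rows & stats::complete.cases(cohort[proxies])
  d <- cohort[rows, , drop = FALSE]
  if (nrow(d) < length(proxies) + 2L)
    stop(sprintf("insufficient training rows in stratum '%s': %d (need at least %d)",
                 stratum, nrow(d), length(proxies) + 2L))
  X <- cbind(`(Intercept)` = 1, as.matrix(d[proxies]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient proxy matrix; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  y <- d[[trait]]
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  df <- nrow(d) - ncol(X)
  fitted <- y - res
  r <- if (stats::sd(fitted) > 0) stats::cor(fitted, y) else NA_real_
  structure(list(trait = trait, stratum = stratum, proxies = proxies,
                 coefficients = coefs, sigma2 = sum(res^2) / max(df, 1L),
                 n = nrow(d), r = r, r2 = r^2),
            class = "imputation_model")
}

#' Predict (impute) the target phenotype from proxies
#'
#' Applies a fitted imputation model to every row of a cohort:
#' \eqn{\hat y_i = \beta_0 + \sum_j \beta_j x_{ij}}. Rows with a missing
#' proxy value receive `NA` and are flagged rather than imputed.
#'
#' @param object an [fit_imputation_model()] result.
#' @param newdata data frame containing the model's proxy columns.
#' @param ... unused.
#' @return Numeric vector of predictions named by `newdata$id` when
#'   present, with attribute `incomplete` giving the row indices that had
#'   missing proxies.
#' @export
predict.imputation_model <- function(object, newdata, ...) {
  missing_proxy <- setdiff(object$proxies, names(newdata))
  if (length(missing_proxy))
    stop("missing proxy column(s): ", paste(missing_proxy, collapse = ", "))
  X <- as.matrix(newdata[object$proxies])
  pred <- drop(cbind(1, X) %*% object$coefficients)
  bad <- which(!stats::complete.cases(newdata[object$proxies]))
  pred[bad] <- NA_real_
  if (!is.null(newdata$id)) names(pred) <- newdata$id
  attr(pred, "incomplete") <- bad
  pred
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("Imputation model for '%s' (%s stratum), n = %d\n",
              x$trait, x$stratum, x$n))
  print(signif(x$coefficients, 4))
  cat(sprintf("training r = %.3f, R2 = %.3f, residual var = %.4g\n",
              x$r, x$r2, x$sigma2))
  invisible(x)
}

#' @export
summary.imputation_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.imputation_model <- function(object, ...) object$coefficients

#' Fit per-sex imputation models and impute the full cohort
#'
#' Convenience wrapper: fits one [fit_imputation_model()] per sex stratum
#' on the measured subset and returns sex-matched predictions for every
#' individual.
#'
#' @inheritParams fit_imputation_model
#' @param strata sex labels to fit (default both).
#' @return A list with `models` (per-stratum), `imputed` (full-length
#'   numeric, sex-matched predictions) and `accuracy` (per-stratum
#'   [assess_accuracy()] reports on the training rows).
#' @export
impute_trait <- function(cohort, trait, proxies, strata = c("male", "female")) {
  models <- lapply(strata, function(s) fit_imputation_model(cohort, trait, proxies, s))
  names(models) <- strata
  imputed <- rep(NA_real_, nrow(cohort))
  accuracy <- list()
  for (s in strata) {
    idx <- which(cohort$sex == s)
    imputed[idx] <- predict(models[[s]], cohort[idx, , drop = FALSE])
    train <- idx[!is.na(cohort[[trait]][idx])]
    accuracy[[s]] <- assess_accuracy(imputed[train], cohort[[trait]][train])
  }
  list(models = models, imputed = imputed, accuracy = accuracy)
}

#' Imputation accuracy: Pearson correlation and predictive R-squared
#'
#' @param predicted,observed paired numeric vectors (n >= 3, no NA after
#'   pairwise deletion).
#' @return List with `r` (Pearson correlation), `r2` (its square — equal to
#'   the OLS coefficient of determination when evaluated on the training
#'   data) and `n`.
#' @export
assess_accuracy <- function(predicted, observed) {
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  if (length(predicted) != length(observed)) stop("vectors must be paired")
  if (length(predicted) < 3L) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero variance in predicted or observed values")
  r <- stats::cor(predicted, observed)
  list(r = r, r2 = r^2, n = length(predicted))
}

#' Effective GWAS sample size of an imputed phenotype
#'
#' The information content of a GWAS run on an imputed phenotype in a
#' cohort of `n_cohort` individuals equals that of a directly measured
#' phenotype in roughly `mean_r2 * n_cohort` individuals.
#'
#' @param mean_r2 mean imputation R-squared across traits, in \[0, 1\].
#' @param n_cohort size of the imputation (GWAS) cohort.
#' @return Rounded effective sample size.
#' @examples
#' effective_sample_size(0.66, 392535)  # 259073
#' @export
effective_sample_size <- function(mean_r2, n_cohort) {
  if (mean_r2 < 0 || mean_r2 > 1) stop("mean_r2 must lie in [0, 1]")
  round(mean_r2 * n_cohort)
}

#' Write / read an imputation model store
#'
#' Long-format TSV with one row per model term plus per-model accuracy
#' columns, so a set of trait-by-sex models round-trips through plain text.
#'
#' @param models list of `imputation_model` objects.
#' @param path file path.
#' @return `write_model_store` returns `path` invisibly;
#'   `read_model_store` returns a list of `imputation_model` objects.
#' @export
write_model_store <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(trait = m$trait, stratum = m$stratum, n = m$n,
               r = m$r, r2 = m$r2, sigma2 = m$sigma2,
               term = names(m$coefficients), estimate = unname(m$coefficients),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_store
#' @export
read_model_store <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(rows[c("trait", "stratum")])
  models <- lapply(seq_len(nrow(keys)), function(i) {
    r <- rows[rows$trait == keys$trait[i] & rows$stratum == keys$stratum[i], ]
    coefs <- stats::setNames(r$estimate, r$term)
    structure(list(trait = keys$trait[i], stratum = keys$stratum[i],
                   proxies = setdiff(r$term, "(Intercept)"),
                   coefficients = coefs, sigma2 = r$sigma2[1], n = r$n[1],
                   r = r$r[1], r2 = r$r2[1]),
              class = "imputation_model")
  })
  names(models) <- paste(keys$trait, keys$stratum, sep = ".")
  models
}
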