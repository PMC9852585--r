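test_that("Wakefield log ABF matches a direct high-precision evaluation", {
  cases <- expand.grid(beta = c(-0.5, 0, 0.02, 0.3), se = c(0.01, 0.1, 1),
                       W = c(0.15^2, 0.04))
  for (i in seq_len(nrow(cases))) {
    b <- cases$beta[i]; s <- cases$se[i]; W <- cases$W[i]
    r <- W / (s^2 + W)
    direct <- 0.5 * (log(1 - r) + r * (b / s)^2)
    expect_equal(wakefield_log_abf(b, s, sqrt(W)), direct, tolerance = 1e-12)
  }
  # null effect shrinks evidence below zero
  expect_lt(wakefield_log_abf(0, 0.1), 0)
  # point-null prior limit
  expect_equal(wakefield_log_abf(0.3, 0.1, 0), 0)
  expect_error(wakefield_log_abf(1, 0), "se")
})

test_that("posterior probabilities are a proper distribution with H0 dominant under no evidence", {
  res <- coloc_posteriors(rep(0, 100), rep(0, 100))
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_true(all(res$pp >= 0 & res$pp <= 1))
  expect_equal(unname(which.max(res$pp)), 1L)   # H0
  expect_false(res$colocalised)
})

test_that("a single strong shared signal flags colocalisation", {
  l1 <- c(30, rep(0, 99)); l2 <- c(30, rep(0, 99))
  res <- coloc_posteriors(l1, l2)
  expect_gt(res$pp[["PP.H4"]], 0.75)
  expect_true(res$colocalised)
})

test_that("three-SNP region matches exhaustive causal-configuration enumeration", {
  coloc_oracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
    m <- length(l1)
    w <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
    for (i in seq_len(m)) {
      w["H1"] <- w["H1"] + p1 * exp(l1[i])
      w["H2"] <- w["H2"] + p2 * exp(l2[i])
      w["H4"] <- w["H4"] + p12 * exp(l1[i] + l2[i])
      for (j in seq_len(m)) if (j != i)
        w["H3"] <- w["H3"] + p1 * p2 * exp(l1[i] + l2[j])
    }
    w / sum(w)
  }
  set.seed(14)
  for (k in 1:10) {
    l1 <- rnorm(3, 0, 3); l2 <- rnorm(3, 0, 3)
    res <- coloc_posteriors(l1, l2)
    expect_equal(unname(res$pp), unname(coloc_oracle(l1, l2)), tolerance = 1e-10)
  }
  expect_error(coloc_posteriors(1:3, 1:2), "equal length")
  expect_error(coloc_posteriors(numeric(0), numeric(0)), "empty")
})

test_that("relative support for H1, H2 and H4 is invariant to a common prior scale", {
  set.seed(15)
  l1 <- rnorm(20, 0, 2); l2 <- rnorm(20, 0, 2)
  a <- coloc_posteriors(l1, l2, 1e-4, 1e-4, 1e-5)$pp
  b <- coloc_posteriors(l1, l2, 2e-4, 2e-4, 2e-5)$pp
  expect_equal(a[["PP.H1"]] / a[["PP.H4"]], b[["PP.H1"]] / b[["PP.H4"]],
               tolerance = 1e-9)
  expect_equal(a[["PP.H2"]] / a[["PP.H4"]], b[["PP.H2"]] / b[["PP.H4"]],
               tolerance = 1e-9)
})

test_that("scenario simulations drive the expected coloc hypothesis", {
  hyp <- t(vapply(1:20, function(s) {
    out <- vapply(c("shared-causal", "distinct-causal", "null"), function(sc) {
      r <- simulate_summary_region(50, 0.7, sc, seed = s)
      pp <- coloc_posteriors(wakefield_log_abf(r$gwas$beta, r$gwas$se),
                             wakefield_log_abf(r$eqtl$beta, r$eqtl$se))$pp
      which.max(pp)
    }, integer(1))
    out
  }, integer(3)))
  expect_gte(mean(hyp[, "shared-causal"] == 5), 0.9)  # H4
  expect_gte(mean(hyp[, "distinct-causal"] == 4), 0.9)  # H3
  expect_gte(mean(hyp[, "null"] == 1), 0.9)  # H0
})

test_that("SMR statistic follows its closed forms and bounds", {
  r <- smr_test(2, 2, 0.4, 0.8)
  expect_equal(r$t_smr, 2)                      # z^2 / 2 when z_g = z_e
  expect_equal(r$b_xy, 0.5)
  expect_equal(r$p_smr, pchisq(2, 1, lower.tail = FALSE))
  # strong-instrument limit
  expect_equal(smr_test(3, 1e8, 1, 1)$t_smr, 9, tolerance = 1e-6)
  # harmonic-mean bound
  set.seed(16)
  for (i in 1:10) {
    zg <- rnorm(1, 0, 4); ze <- rnorm(1, 5, 1)
    t <- smr_test(zg, ze, zg, ze)$t_smr
    expect_lte(t, min(zg^2, ze^2) + 1e-12)
  }
  expect_error(smr_test(1, 0, 1, 1), "z_eqtl")
})

test_that("HEIDI returns P = 1 for a perfect shared signal and guards small regions", {
  n <- 30
  ld <- 0.8^abs(outer(1:n, 1:n, "-"))
  top <- 15
  be <- ld[, top] * 0.8          # exact single-causal proportionality
  bg <- ld[, top] * 0.2
  res <- heidi_test(bg, rep(0.01, n), be, rep(0.01, n), ld, top)
  expect_true(res$tested)
  expect_equal(res$stat, 0, tolerance = 1e-16)
  expect_equal(res$p_heidi, 1, tolerance = 1e-6)
  # fewer than 3 eligible SNPs -> no-test flag
  ld2 <- diag(4); ld2[1, 2] <- ld2[2, 1] <- 0.5
  res2 <- heidi_test(rnorm(4), rep(0.1, 4), rnorm(4), rep(0.1, 4), ld2, 1)
  expect_false(res2$tested)
  expect_true(is.na(res2$p_heidi))
})

test_that("HEIDI rejects linkage between distinct causal variants", {
  rej <- vapply(1:20, function(s) {
    r <- simulate_summary_region(50, 0.7, "distinct-causal", seed = s)
    h <- smr_heidi(r$gwas, r$eqtl, r$ld)
    isTRUE(h$p_heidi < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("the joint SMR+HEIDI decision rule separates pleiotropy from linkage", {
  decide <- function(sc) vapply(1:20, function(s) {
    r <- simulate_summary_region(50, 0.7, sc, seed = s)
    h <- smr_heidi(r$gwas, r$eqtl, r$ld)
    h$p_smr < 0.05 && isTRUE(h$p_heidi > 0.05)
  }, logical(1))
  expect_gte(mean(decide("shared-causal")), 0.9)
  expect_lte(mean(decide("distinct-causal")), 0.1)
})

test_that("the weighted chi-square tail evaluation matches known distributions", {
  # single unit eigenvalue: plain 1-df chi-square
  expect_equal(proxygwas:::imhof_tail(3.84, 1),
               pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-9)
  # equal eigenvalues: 2-df chi-square
  expect_equal(proxygwas:::imhof_tail(5.99, c(1, 1)),
               pchisq(5.99, 2, lower.tail = FALSE), tolerance = 1e-9)
})
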