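test_that("predicted replication s.e. follows the power formula", {
  # printed example: EAF 0.58 in 17,787 participants -> 0.011 at 3 decimals
  expect_equal(round(predicted_replication_se(0.58, 17787), 3), 0.011)
  expect_equal(predicted_replication_se(0.5, 2), 1.0)
  expect_error(predicted_replication_se(0, 100), "freq1")
  expect_error(predicted_replication_se(1, 100), "freq1")
  # symmetric in freq <-> 1 - freq, strictly decreasing in n
  f <- runif(5, 0.05, 0.95)
  expect_equal(predicted_replication_se(f, 1000),
               predicted_replication_se(1 - f, 1000))
  ns <- c(100, 1000, 10000)
  expect_true(all(diff(predicted_replication_se(0.3, ns)) < 0))
})

test_that("expected replication P value is the one-sided tail at the expected z", {
  expect_equal(expected_replication_pvalue(0, 0.1), 0.5)
  expect_equal(expected_replication_pvalue(1.6449 * 0.1, 0.1), 0.05,
               tolerance = 1e-4)
  se <- predicted_replication_se(0.58, 18000)
  expect_equal(expected_replication_pvalue(0.022, se), 0.0197, tolerance = 0.001)
  expect_error(expected_replication_pvalue(0.1, 0), "se_pred")
})

test_that("replicable selection applies the composed power calculation", {
  rec <- data.frame(rsid = c("x", "y"), beta1 = c(0.022, 0.001),
                    freq1 = c(0.58, 0.3))
  expect_equal(nrow(select_replicable(rec, 18000, 1)), 2L)
  expect_equal(nrow(select_replicable(rec, 18000, 0)), 0L)
  sel <- select_replicable(rec, 18000, 0.05)
  expect_equal(sel$rsid, "x")
})

test_that("one-sided replication P is below 0.5 iff directions agree", {
  expect_equal(one_sided_replication_pvalue(0.5, 0, 0.1), 0.5)
  # consistent strong replication (printed-table row magnitudes)
  expect_equal(one_sided_replication_pvalue(-0.018, -0.035, 0.011),
               pnorm(0.035 / 0.011, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(one_sided_replication_pvalue(-0.018, -0.035, 0.011), 1e-3)
  # opposite signs at |z| = 2 -> ~0.977
  expect_equal(one_sided_replication_pvalue(1, -0.2, 0.1), pnorm(2),
               tolerance = 1e-12)
  expect_error(one_sided_replication_pvalue(1, 1, 0), "se_repl")
})

test_that("BH q-values match the hand-applied step-up and a brute-force oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "pvalues")
  # brute-force step-up oracle on random sets of <= 8 p-values
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(p[o][i:m] * m / (i:m))
    q[order(o)]
  }
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("sign test reproduces the exact binomial tail", {
  expect_equal(sign_test(19, 27), 0.0261, tolerance = 1e-3)
  expect_equal(round(sign_test(19, 27), 2), 0.03)
  expect_equal(sign_test(27, 27), 2^-27, tolerance = 1e-15)
  expect_equal(sign_test(14, 27), 0.5, tolerance = 1e-12)
  # brute-force binomial sum
  k <- 14; n <- 27
  expect_equal(sign_test(k, n), sum(choose(n, k:n)) / 2^n, tolerance = 1e-12)
  expect_error(sign_test(28, 27), "k_consistent")
})

test_that("the 27 prioritised SNPs recount to 19 consistent with 0.03 sign test", {
  tab <- replication_table()
  disc <- data.frame(rsid = tab$rsid, trait = tab$phenotype,
                     beta1 = tab$beta1_disc, freq1 = tab$freq1)
  repl <- data.frame(rsid = tab$rsid, trait = tab$phenotype,
                     beta = tab$beta1_repl, se = tab$se_repl)
  res <- test_replication(disc, repl)
  expect_equal(res$n_tested, 27L)
  expect_equal(res$n_consistent, 19L)
  expect_equal(round(res$sign_test_p, 2), 0.03)
  # recomputed successful replications form a subset of the published six
  published <- c("rs4820325", "rs1047891", "rs13072731", "rs17325374",
                 "rs12359330", "rs2242449")
  expect_true(all(res$records$rsid[res$records$replicated] %in% published))
  expect_gte(res$n_replicated, 5L)
})

test_that("replication joins report unmatched records and honour tie rules", {
  disc <- data.frame(rsid = c("a", "b"), trait = "t", beta1 = c(0.1, 0.2))
  repl <- data.frame(rsid = "a", trait = "t", beta = 0, se = 0.05)
  res <- test_replication(disc, repl)
  expect_equal(nrow(res$unmatched), 1L)
  expect_equal(res$unmatched$rsid, "b")
  # zero replication beta counts as direction-inconsistent
  expect_false(res$records$consistent[1])
  expect_equal(res$n_replicated, 0L)
})

test_that("replication power approaches one under true effects at large n", {
  cfg <- latent_config(n_total = 500, n_measured = 100, m_variants = 20,
                       n_causal = 2, effect_sizes = 0.5,
                       n_replication = 8000, seed = 23)
  sim <- simulate_cohort(cfg)
  rep <- simulate_replication_cohort(cfg, sim$truth)
  g <- run_gwas(rep$genotypes, scale(rep$cohort$target)[, 1])
  i <- match(sim$truth$causal_id, g$rsid)
  disc <- data.frame(rsid = sim$truth$causal_id, trait = "target",
                     beta1 = sim$truth$b, freq1 = g$freq1[i])
  repl <- data.frame(rsid = g$rsid[i], trait = "target",
                     beta = g$beta1[i], se = g$se[i])
  res <- test_replication(disc, repl)
  expect_equal(res$n_replicated, 2L)
})

test_that("selection by predicted power enriches for actual replication", {
  # strong and weak discovery effects at a fixed replication size: the
  # selected (well-powered) records replicate, the unselected mostly do not
  set.seed(29)
  n_rep <- 3000
  strong <- data.frame(rsid = paste0("s", 1:6), trait = "t",
                       beta1 = 0.12, freq1 = 0.4)
  weak <- data.frame(rsid = paste0("w", 1:6), trait = "t",
                     beta1 = 0.01, freq1 = 0.4)
  recs <- rbind(strong, weak)
  sel <- select_replicable(recs, n_rep, 0.05)
  expect_true(all(grepl("^s", sel$rsid)))
  se_true <- predicted_replication_se(0.4, n_rep)
  repl <- data.frame(rsid = recs$rsid, trait = "t",
                     beta = rnorm(12, recs$beta1, se_true), se = se_true)
  all_res <- test_replication(recs, repl)
  rate_sel <- mean(all_res$records$replicated[all_res$records$rsid %in% sel$rsid])
  rate_uns <- mean(all_res$records$replicated[!all_res$records$rsid %in% sel$rsid])
  expect_gt(rate_sel, rate_uns)
})
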