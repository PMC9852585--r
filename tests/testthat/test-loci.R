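mk_gwas <- function(rsid, chr, pos, p) {
  data.frame(rsid = rsid, chr = as.character(chr), pos = pos, p = p,
             stringsAsFactors = FALSE)
}

test_that("collation keeps the best trait per variant and counts traits", {
  g1 <- mk_gwas(c("a", "b"), 1, c(100, 200), c(1e-10, 1e-3))
  g2 <- mk_gwas(c("a", "b"), 1, c(100, 200), c(1e-12, 1e-9))
  sig <- collate_significant(list(t1 = g1, t2 = g2), 1.25e-8)
  expect_equal(nrow(sig), 2L)
  a <- sig[sig$rsid == "a", ]
  expect_equal(a$best_trait, "t2")
  expect_equal(a$trait_count, 2L)
  expect_equal(sig[sig$rsid == "b", ]$trait_count, 1L)
  # nothing significant -> empty set
  expect_equal(nrow(collate_significant(list(t1 = g1), 1e-20)), 0L)
  expect_error(collate_significant(list(), 1e-8), "no GWAS tables")
  # monotone in the threshold
  s1 <- collate_significant(list(t1 = g1, t2 = g2), 1.25e-8)
  s2 <- collate_significant(list(t1 = g1, t2 = g2), 5e-8)
  expect_true(all(s1$rsid %in% s2$rsid))
})

test_that("positional chaining forms the documented loci", {
  sig <- data.frame(rsid = c("a", "b", "c"), chr = "1",
                    pos = c(1.0e6, 1.5e6, 3.0e6), best_p = c(1e-9, 1e-10, 1e-11),
                    best_trait = "t", stringsAsFactors = FALSE)
  ls <- cluster_loci(sig)
  expect_equal(nrow(ls$loci), 2L)
  expect_equal(ls$loci$n_signals, c(2L, 1L))
  # chain rule: consecutive gaps of 0.9 Mb chain into one locus spanning 1.8 Mb
  sig2 <- data.frame(rsid = c("a", "b", "c"), chr = "1",
                     pos = c(1e6, 1.9e6, 2.8e6), best_p = rep(1e-9, 3),
                     best_trait = "t", stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_loci(sig2)$loci), 1L)
  # chromosomes never merge
  sig3 <- rbind(sig2, transform(sig2, chr = "2", rsid = c("d", "e", "f")))
  expect_equal(nrow(cluster_loci(sig3)$loci), 2L)
  # empty input -> empty output
  expect_equal(nrow(cluster_loci(sig[0, ])$loci), 0L)
})

test_that("lead variant carries the locus minimum P", {
  sig <- data.frame(rsid = c("a", "b"), chr = "1", pos = c(1e6, 1.2e6),
                    best_p = c(1e-9, 1e-15), best_trait = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  l <- cluster_loci(sig)$loci
  expect_equal(l$lead_rsid, "b")
  expect_equal(l$lead_p, 1e-15)
  expect_equal(l$lead_trait, "t2")
})

test_that("clustering partitions the signal set and is order invariant", {
  set.seed(12)
  sig <- data.frame(rsid = paste0("s", 1:60),
                    chr = as.character(sample(1:3, 60, TRUE)),
                    pos = sample.int(2e7, 60),
                    best_p = runif(60, 1e-12, 1e-9),
                    best_trait = "t", stringsAsFactors = FALSE)
  ls <- cluster_loci(sig)
  expect_equal(sum(ls$loci$n_signals), nrow(sig))
  expect_true(all(table(ls$signals$locus_id) ==
                    ls$loci$n_signals[order(ls$loci$locus_id)]))
  # nearest members of distinct loci on one chromosome are > gap apart
  for (c_ in unique(ls$loci$chr)) {
    l <- ls$loci[ls$loci$chr == c_, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(l$start[-1] - l$end[-nrow(l)] > 1e6))
  }
  ls2 <- cluster_loci(sig[sample(nrow(sig)), ])
  expect_equal(ls2$loci[order(ls2$loci$chr, ls2$loci$start),
                        c("chr", "start", "end", "n_signals")],
               ls$loci[order(ls$loci$chr, ls$loci$start),
                       c("chr", "start", "end", "n_signals")],
               ignore_attr = TRUE)
})

test_that("known-association filtering flags catalogue and reference overlaps", {
  sig <- data.frame(rsid = c("a", "b"), chr = "1", pos = c(1e6, 5e6),
                    best_p = c(1e-9, 1e-10), best_trait = "t",
                    stringsAsFactors = FALSE)
  ls <- cluster_loci(sig)
  # empty catalogue, no reference hits -> all novel
  f0 <- filter_known(ls, data.frame(chr = character(), pos = integer()))
  expect_true(all(f0$loci$novel))
  # catalogue entry at the lead -> flagged
  f1 <- filter_known(ls, data.frame(chr = "1", pos = 1e6))
  expect_equal(f1$loci$catalogue_overlap, c(TRUE, FALSE))
  # reference P threshold boundary: 1e-13 flags, 1e-11 does not
  ref13 <- list(data.frame(rsid = "b", p = 1e-13))
  ref11 <- list(data.frame(rsid = "b", p = 1e-11))
  expect_true(filter_known(ls, NULL, ref13)$loci$reference_overlap[2])
  expect_false(filter_known(ls, NULL, ref11)$loci$reference_overlap[2])
  # malformed catalogue reported with line numbers
  expect_error(filter_known(ls, data.frame(chr = c("1", NA), pos = c(1, NA))),
               "line")
})

test_that("gene annotation uses a closed +/- flank window ordered by distance", {
  sig <- data.frame(rsid = "a", chr = "1", pos = 2e6, best_p = 1e-9,
                    best_trait = "t", stringsAsFactors = FALSE)
  ls <- cluster_loci(sig)
  genes <- data.frame(chr = "1",
                      start = c(1.9e6, 1.4e6, 1e4),
                      end = c(2.1e6, 1.5e6, 2e4),
                      name = c("OVER", "NEAR", "FAR"),
                      stringsAsFactors = FALSE)
  ann <- annotate_genes(ls, genes)
  expect_equal(ann$loci$genes, "OVER,NEAR")   # overlapping first, FAR outside
  # boundary: gene ending exactly at lead - flank is included
  g2 <- data.frame(chr = "1", start = 1.4e6, end = 2e6 - 5e5, name = "EDGE")
  expect_equal(annotate_genes(ls, g2)$loci$genes, "EDGE")
  # nothing in range -> empty label
  g3 <- data.frame(chr = "2", start = 1, end = 10, name = "X")
  expect_equal(annotate_genes(ls, g3)$loci$genes, "")
})

test_that("simulated well-separated causal variants are each recovered as one novel locus", {
  cfg <- sim_config(n_total = 6000, n_measured = 6000, m_variants = 60,
                    n_causal = 3, effect_sizes = 0.4, positive_scale = FALSE,
                    seed = 31)
  sim <- simulate_cohort(cfg)
  v <- sim$genotypes$variants[sim$truth$causal_index, ]
  g <- run_gwas(sim$genotypes, scale(sim$cohort$target)[, 1])
  sig <- collate_significant(list(target = g), 1.25e-8)
  ls <- filter_known(cluster_loci(sig),
                     data.frame(chr = character(), pos = integer()))
  expect_equal(sum(ls$loci$novel), 3L)
  expect_setequal(ls$loci$lead_rsid, sim$truth$causal_id)
})
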