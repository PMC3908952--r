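test_that("strand-bias Fisher p matches hypergeometric enumeration", {
  # fully strand-separated 10+10 table
  site <- site_pileup("c", 1, "G", "t",
                      allele = rep(c("G", "A"), each = 10),
                      base_quality = rep(30, 20), mapping_quality = rep(60, 20),
                      strand = c(rep("+", 10), rep("-", 10)),
                      tail_dist = rep(20L, 20))
  p <- pv4(site, "A")[["strand"]]
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-9)
  # balanced table has no association
  expect_equal(pv4(bq30_pileup(16, 6), "A")[["strand"]], 1)
  # random tables with margins <= 30 against the enumeration oracle
  set.seed(17)
  for (rep in 1:20) {
    dp4 <- c(sample(0:15, 2, TRUE), sample(0:15, 2, TRUE))
    if (sum(dp4[1:2]) == 0 || sum(dp4[3:4]) == 0) next
    site <- site_pileup("c", 1, "G", "t",
                        allele = rep(c("G", "A"), c(sum(dp4[1:2]), sum(dp4[3:4]))),
                        base_quality = rep(30, sum(dp4)),
                        mapping_quality = rep(60, sum(dp4)),
                        strand = rep(c("+", "-", "+", "-"), dp4),
                        tail_dist = rep(20L, sum(dp4)))
    expect_equal(pv4(site, "A")[["strand"]],
                 brute_fisher2x2(matrix(dp4, 2, byrow = TRUE)),
                 tolerance = 1e-7)
  }
})

test_that("quality/tail bias tests are vacuous on identical groups and
           flag separated ones", {
  p4 <- pv4(bq30_pileup(20, 5), "A")
  expect_equal(p4[["baseq"]], 1)
  expect_equal(p4[["mapq"]], 1)
  expect_equal(p4[["tail"]], 1)
  # alternate reads squashed to the read tail
  site <- site_pileup("c", 1, "G", "t",
                      allele = rep(c("G", "A"), each = 8),
                      base_quality = c(rep(30, 8), c(rep(12, 7), 13)),
                      mapping_quality = rep(60, 16),
                      strand = rep_len(c("+", "-"), 16),
                      tail_dist = c(40:47, 0:7))
  p4 <- pv4(site, "A")
  expect_lt(p4[["baseq"]], 1e-4)
  expect_lt(p4[["tail"]], 1e-4)
  expect_equal(p4[["baseq"]],
               stats::t.test(rep(30, 8), c(rep(12, 7), 13))$p.value)
  # a group of one read cannot be tested
  expect_equal(pv4(bq30_pileup(10, 1), "A")[["baseq"]], 1)
})

test_that("HWE chi-square matches the closed form", {
  expect_equal(hwe_p(c(0, 3, 0)), pchisq(3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hwe_p(c(0, 3, 0)), 0.0833, tolerance = 1e-3)
  expect_equal(hwe_p(c(3, 0, 0)), 1)    # monomorphic
  expect_equal(hwe_p(c(1, 0, 0)), 1)    # single sample: vacuous
  expect_equal(hwe_p(c(5, 0, 5)), pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("homopolymer adjacency respects the >= 5 bp threshold", {
  expect_true(homopolymer_adjacent("TTAAAAAG", 8))    # AAAAA next to the G
  expect_true(homopolymer_adjacent("TTAAAAAG", 5))    # inside the run
  expect_false(homopolymer_adjacent("ACGTACGTA", 5))
  expect_false(homopolymer_adjacent("TTAAAAG", 7))    # run of 4 only
  expect_false(homopolymer_adjacent("AAAAACGTG", 9))  # run too far away
  expect_true(homopolymer_adjacent("AAAAACG", 6))     # adjacent within 1 bp
  expect_error(homopolymer_adjacent("ACGT", 9), "outside")
})

test_that("tier filters enforce their criteria and name failures", {
  rec <- function(qual = 30, dp4 = c(16L, 16L, 2L, 2L), pv4 = rep(1, 4),
                  gene = NA_character_)
    variant_record("chr1", 100, "G", "A", qual = qual, dp4 = dp4,
                   pv4 = pv4, gene = gene)
  t1 <- filter_config(1); t2 <- filter_config(2, flagged_genes = "MUC16")

  # the 65.1%-accuracy call is rejected by tier 1 on quality
  low <- rec(qual = 4.57)
  res <- apply_tier(low, t1)
  expect_false(res$pass)
  expect_identical(res$reasons, "min_qual")

  # 4 alternate reads on both strands pass both tiers
  expect_true(apply_tier(rec(), t1)$pass)
  expect_true(apply_tier(rec(), t2)$pass)

  # 2 alternate reads on one strand: tier-1 pass, tier-2 fail twice over
  one_strand <- rec(dp4 = c(17L, 17L, 2L, 0L))
  expect_true(apply_tier(one_strand, t1)$pass)
  res2 <- apply_tier(one_strand, t2)
  expect_false(res2$pass)
  expect_setequal(res2$reasons, c("min_alt", "alt_both_strands"))

  # flagged gene only matters in tier 2
  flagged <- rec(gene = "MUC16")
  expect_true(apply_tier(flagged, t1)$pass)
  expect_identical(apply_tier(flagged, t2)$reasons, "flagged_gene")

  # context-dependent criteria
  expect_identical(apply_tier(rec(), t1,
                              list(ref_context = "TTAAAAAG",
                                   site_offset = 8))$reasons, "homopolymer")
  expect_identical(apply_tier(rec(), t1,
                              list(genotype_counts = c(0, 40, 0)))$reasons,
                   "hwe")
  mask <- data.frame(chrom = "chr1", start = 90L, end = 110L)
  t1m <- filter_config(1, repeat_mask = mask)
  expect_identical(apply_tier(rec(), t1m)$reasons, "repeat_mask")

  # missing required field is a named error
  bad <- rec(); bad$qual <- NA_real_
  expect_error(apply_tier(bad, t1), "qual")
})

test_that("filters are monotone: improving one statistic never flips
           pass to fail", {
  set.seed(23)
  cfgs <- list(filter_config(1), filter_config(2))
  for (rep in 1:25) {
    dp4 <- c(sample(0:20, 2, TRUE), sample(0:8, 2, TRUE))
    r <- variant_record("chr1", 5, "G", "A",
                        qual = runif(1, 0, 40), dp4 = dp4,
                        pv4 = runif(4)^4)
    for (cfg in cfgs) {
      before <- apply_tier(r, cfg)$pass
      if (!before) next
      up <- r
      up$qual <- up$qual + 10
      up$dp4_af <- up$dp4_af + 2L; up$dp4_ar <- up$dp4_ar + 2L
      up$dp <- up$dp + 4L
      up$pv4_strand <- 1; up$pv4_baseq <- 1
      up$pv4_mapq <- 1; up$pv4_tail <- 1
      expect_true(apply_tier(up, cfg)$pass)
    }
  }
})

test_that("tier-2 passes only records with >= 3 alternate reads", {
  set.seed(29)
  t2 <- filter_config(2)
  for (rep in 1:40) {
    dp4 <- c(sample(0:20, 2, TRUE), sample(0:6, 2, TRUE))
    r <- variant_record("chr1", 5, "G", "A", qual = runif(1, 0, 40),
                        dp4 = dp4, pv4 = runif(4))
    if (apply_tier(r, t2)$pass)
      expect_gte(r$dp4_af + r$dp4_ar, 3L)
  }
})

test_that("filter_variants annotates the FILTER column", {
  recs <- rbind(
    variant_record("chr1", 1, "G", "A", qual = 30,
                   dp4 = c(10L, 10L, 3L, 3L)),
    variant_record("chr1", 2, "G", "A", qual = 4.57,
                   dp4 = c(10L, 10L, 3L, 3L)))
  class(recs) <- c("variant_table", "data.frame")
  out <- filter_variants(recs, filter_config(1))
  expect_identical(out$filter, c("PASS", "min_qual"))
})

test_that("recurrent_genes counts distinct samples carrying novel variants", {
  tab <- function(genes, novel = TRUE)
    data.frame(gene = genes, novel = novel, stringsAsFactors = FALSE)
  tables <- list(A = tab(c("g1", "g2")), B = tab("g2"),
                 C = tab(c("g2", "g3")))
  out <- recurrent_genes(tables, 2)
  expect_identical(out$gene, "g2")
  expect_identical(out$n_samples, 3L)
  expect_identical(recurrent_genes(tables, 3)$gene, "g2")
  expect_identical(nrow(recurrent_genes(tables, 4)), 0L)
  # duplicated hits within one sample count once
  dup <- list(A = tab(c("g9", "g9")), B = tab("g9"))
  expect_identical(recurrent_genes(dup, 2)$n_samples, 2L)
  # non-novel variants are invisible
  known <- list(A = tab("g5", novel = FALSE), B = tab("g5"))
  expect_identical(nrow(recurrent_genes(known, 2)), 0L)
  # boundary: in exactly 2 of 3 samples
  two <- list(A = tab("gx"), B = tab("gx"), C = tab("gy"))
  expect_identical(recurrent_genes(two, 2)$gene, "gx")
  expect_identical(nrow(recurrent_genes(two, 3)), 0L)
  expect_identical(nrow(recurrent_genes(list(), 2)), 0L)
})
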