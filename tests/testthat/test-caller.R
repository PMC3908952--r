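# The printed PL triples of the three patients (helper table2_gl) anchor
# the posterior/QUAL definition across all prior configurations.

test_that("QUAL reproduces every printed single-sample anchor", {
  cc <- function(model, theta = 0.001, p = 0.5)
    caller_config(afs_prior(model, 2, theta), threshold = p)
  qual <- function(gl, cfg) call_single(gl, cfg)$qual
  # patient 1, PL (185,0,236)
  expect_equal(round(qual(table2_gl$p1, cc("full"))), 155)
  expect_equal(round(qual(table2_gl$p1, cc("flat"))), 185)
  expect_equal(round(qual(table2_gl$p1, cc("cond2"))), 183)
  expect_equal(round(qual(table2_gl$p1, cc("full", 0.01))), 165)
  expect_equal(round(qual(table2_gl$p1, cc("full", 0.1))), 176)
  # patient 2, PL (12,0,233)
  expect_equal(signif(qual(table2_gl$p2, cc("flat")), 3), 12.3)
  expect_equal(signif(qual(table2_gl$p2, cc("cond2")), 3), 10.6)
  expect_equal(signif(qual(table2_gl$p2, cc("full", 0.1)), 3), 4.57)
  expect_equal(signif(qual(table2_gl$p2, cc("full")), 3), 0.0684)
  # patient 3, PL (179,0,197)
  expect_equal(round(qual(table2_gl$p3, cc("full"))), 149)
  expect_equal(round(qual(table2_gl$p3, cc("flat"))), 179)
})

test_that("the default prior misses the mosaic sample; flat and cond2 call it", {
  cc <- function(model, p = 0.5) caller_config(afs_prior(model, 2), p)
  expect_false(call_single(table2_gl$p2, cc("full"))$called)
  expect_true(call_single(table2_gl$p2, cc("flat"))$called)
  expect_true(call_single(table2_gl$p2, cc("cond2"))$called)
  # the missed site is emitted once the threshold is relaxed to 1
  expect_true(call_single(table2_gl$p2, cc("full", p = 1))$called)
  # called heterozygous under the flat prior
  expect_identical(call_single(table2_gl$p2, cc("flat"))$genotype, "0/1")
})

test_that("no-data call returns the prior itself", {
  gl <- genotype_likelihoods(c(0, 0, 0))
  for (model in c("full", "cond2", "flat")) {
    res <- call_single(gl, caller_config(afs_prior(model, 2)))
    expect_equal(res$p_ref, afs_prior(model, 2)$phi[1], tolerance = 1e-12)
  }
  expect_false(call_single(gl, caller_config(afs_prior("full", 2)))$called)
})

test_that("posterior is a distribution, QUAL matches p_ref, thresholds are
           monotone", {
  set.seed(5)
  for (rep in 1:20) {
    gl <- genotype_likelihoods(log10(runif(3, 1e-12, 1)))
    res <- call_single(gl, caller_config(afs_prior("full", 2)))
    expect_equal(sum(res$posterior_k), 1, tolerance = 1e-12)
    expect_equal(res$qual, -10 * log10(res$p_ref), tolerance = 1e-6)
    called_at <- vapply(c(0.5, 0.75, 1.0), function(p)
      call_single(gl, caller_config(afs_prior("full", 2), p))$called, TRUE)
    expect_true(all(diff(called_at) >= 0))  # 0.5 called => 0.75, 1.0 called
  }
  # with p = 1 any pileup with >= 1 alternate read is emitted
  gl <- genotype_log_likelihoods(bq30_pileup(60, 1), "A")
  expect_true(call_single(gl, caller_config(afs_prior("full", 2), 1))$called)
})

test_that("genotype ties break toward the reference", {
  res <- call_single(genotype_likelihoods(c(0, 0, 0)),
                     caller_config(afs_prior("flat", 2), 1))
  expect_identical(res$genotype, "0/0")
})

test_that("joint likelihood by convolution equals brute-force enumeration", {
  set.seed(9)
  for (n in 1:4) {
    for (rep in 1:5) {
      gls <- replicate(n, genotype_likelihoods(log10(runif(3, 1e-6, 1))),
                       simplify = FALSE)
      conv <- 10^mosaicall:::joint_log10_lik_by_count(gls)
      brute <- brute_joint_lik(gls)
      expect_equal(conv, brute, tolerance = 1e-9)
    }
  }
})

test_that("joint likelihood conserves total probability", {
  # sum_k C(2n,k) P(D|k) must equal prod_i sum_g C(2,g) L_i(g)
  set.seed(13)
  for (n in 2:4) {
    gls <- replicate(n, genotype_likelihoods(log10(runif(3, 1e-4, 1))),
                     simplify = FALSE)
    lhs <- sum(choose(2 * n, 0:(2 * n)) *
                 10^mosaicall:::joint_log10_lik_by_count(gls))
    rhs <- prod(vapply(gls, function(g) sum(c(1, 2, 1) * 10^g$log10_lik), 0))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("single-sample joint calling equals call_single exactly", {
  set.seed(21)
  for (rep in 1:10) {
    gl <- genotype_likelihoods(log10(runif(3, 1e-10, 1)))
    cfg <- caller_config(afs_prior("full", 2))
    a <- call_single(gl, cfg)
    b <- call_multi(list(gl), cfg)
    expect_equal(b$p_ref, a$p_ref, tolerance = 1e-12)
    expect_equal(b$qual, a$qual, tolerance = 1e-9)
    expect_identical(b$called, a$called)
  }
})

test_that("joint calling rescues a mosaic variant only when another sample
           carries it at high fraction", {
  # two low-fraction copies plus a negative sample: not called
  a <- multi_sample_experiment(list(c(36, 4), c(36, 4), c(27, 0)))
  expect_false(a$called)
  # one high-fraction carrier rescues the 11% sample, genotyped het,
  # with a single site QUAL shared by all samples
  b <- multi_sample_experiment(list(c(36, 15), c(36, 4), c(27, 0)))
  expect_true(b$called)
  expect_identical(b$genotypes[1:2], c("0/1", "0/1"))
  expect_identical(b$genotypes[3], "0/0")
  expect_length(b$qual, 1)
  # all-reference samples are never called
  c0 <- multi_sample_experiment(list(c(36, 0), c(36, 0)))
  expect_false(c0$called)
})

test_that("prior length must match the sample count", {
  gls <- replicate(3, gl_from_pl(c(0L, 10L, 20L)), simplify = FALSE)
  expect_error(call_multi(gls, caller_config(afs_prior("full", 4))),
               "samples")
  expect_error(call_single(gl_from_pl(c(0L, 1L, 2L)),
                           caller_config(afs_prior("full", 4))), "M = 2")
})

test_that("call_pileup assembles a VCF-ready record", {
  site <- simulate_site_pileup(36, 4, sample_id = "pt2")
  rec <- call_pileup(site, caller_config(afs_prior("flat", 2)))
  expect_s3_class(rec, "variant_table")
  expect_identical(rec$dp, 36L)
  expect_identical(c(rec$dp4_af, rec$dp4_ar), c(2L, 2L))
  expect_identical(rec$genotype, "0/1")
  # same site under the default prior is suppressed at p = 0.5
  expect_null(call_pileup(site, caller_config(afs_prior("full", 2))))
})
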