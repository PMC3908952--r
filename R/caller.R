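#' Caller configuration
#'
#' Bundles the AFS prior, the variant-calling threshold and the error
#' model.  A site is called variant when the posterior probability of the
#' non-variant state, `P(ref | D, F) = P(k = 0 | D, phi)`, falls below
#' `threshold`.  The standard pipeline uses the full prior with
#' theta = 0.001 and threshold 0.5; relaxing the threshold to 0.75 or 1
#' and switching the prior to flat/cond2 are the sensitivity-oriented
#' alternatives.
#'
#' @param prior An [afs_prior()].
#' @param threshold Calling threshold p in (0, 1]; default 0.5.
#' @param model An [error_model()] used when calling from pileups.
#' @param id Optional configuration label (used in sweep output).
#' @return Object of class `caller_config`.
#' @export
caller_config <- function(prior = afs_prior("full", 2, 0.001),
                          threshold = 0.5, model = error_model(),
                          id = NULL) {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  if (is.null(id))
    id <- sprintf("%s_theta%g_p%g", prior$model, prior$theta, threshold)
  structure(list(prior = prior, threshold = threshold, model = model,
                 id = id), class = "caller_config")
}

## joint log10 P(D | k) across samples by sequential polynomial
## convolution of the per-sample terms C(2, g) * L_i(g); the result is
## divided by C(2n, k).  Equivalent to (but never computed as) the
## explicit sum over all genotype vectors with sum g_i = k.
joint_log10_lik_by_count <- function(gls) {
  n <- length(gls)
  coef <- 1; logscale <- 0
  for (gl in gls) {
    ll <- gl$log10_lik
    m <- max(ll)
    logscale <- logscale + m
    ci <- c(1, 2, 1) * 10^(ll - m)
    new <- numeric(length(coef) + 2L)
    for (g in 0:2)                       # degree-2 polynomial multiply
      new[seq_along(coef) + g] <- new[seq_along(coef) + g] + coef * ci[g + 1]
    coef <- new
  }
  k <- 0:(2L * n)
  log10(pmax(coef, .Machine$double.xmin)) - lchoose(2L * n, k) / log(10) +
    logscale
}

#' Call a single sample at one site
#'
#' Combines a genotype-likelihood triple with an M = 2 AFS prior:
#' `posterior_k` is proportional to `phi_k * L(k)`; the site is called
#' variant when `p_ref = posterior_0` is below the configured threshold;
#' `QUAL = -10 log10 p_ref` (Phred-scaled confidence that the site is
#' variant); the genotype is the posterior mode (ties broken toward the
#' reference) and `GQ = min(99, round(-10 log10(1 - max posterior)))`.
#'
#' @param gl A [genotype_likelihoods()].
#' @param config A [caller_config()] whose prior has M = 2.
#' @return Object of class `call_result`: fields `p_ref`, `called`,
#'   `qual`, `posterior_k`, `genotype` ("0/0", "0/1" or "1/1"), `gq`.
#' @examples
#' gl <- gl_from_pl(c(12, 0, 233))
#' call_single(gl, caller_config(afs_prior("flat")))$qual   # ~12.3
#' @export
call_single <- function(gl, config = caller_config()) {
  if (config$prior$M != 2L)
    stop("call_single needs an M = 2 prior; use call_multi for joint calling")
  posterior_from_joint(gl$log10_lik, config)
}

## shared posterior machinery: log10 P(D|k) + prior -> call_result
posterior_from_joint <- function(log10_lik_k, config) {
  phi <- config$prior$phi
  w <- log10(phi + .Machine$double.xmin) + log10_lik_k
  tot <- log10_sum_exp(w)
  log10_post <- w - tot
  posterior_k <- 10^log10_post
  posterior_k <- posterior_k / sum(posterior_k)
  p_ref <- posterior_k[1]
  qual <- max(0, -10 * log10_post[1])
  kmax <- which.max(posterior_k) - 1L     # which.max: first max, prefers low k
  gq <- min(99, round_half_up(-10 * log10(max(
    1 - posterior_k[kmax + 1L], .Machine$double.xmin))))
  ## threshold 1 emits every site, even when p_ref saturates to 1.0
  called <- p_ref < config$threshold || config$threshold >= 1
  structure(list(p_ref = p_ref, called = called,
                 qual = qual, posterior_k = posterior_k,
                 genotype = c("0/0", "0/1", "1/1")[min(kmax, 2L) + 1L],
                 k_hat = kmax, gq = as.integer(gq)),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf("call_result: %s  QUAL=%.4g  P(ref|D,F)=%.4g  GT=%s GQ=%d\n",
              if (x$called) "CALLED" else "not called",
              x$qual, x$p_ref, x$genotype, x$gq))
  invisible(x)
}

#' Joint multi-sample calling
#'
#' Combines evidence across n samples.  The joint likelihood of seeing k
#' alternate alleles among the 2n chromosomes is
#' `P(D | k) = (1 / C(2n, k)) * sum over genotype vectors g with sum(g) = k
#' of prod_i C(2, g_i) L_i(g_i)`, computed by sequential polynomial
#' convolution over samples.  The site posterior over k then follows as
#' in [call_single()] with an M = 2n prior; the site QUAL is shared by
#' all samples.  Per-sample genotypes maximize
#' `L_i(g) * w_g(f_hat)` where `f_hat = E[k | D] / 2n` and `w` are the
#' Hardy-Weinberg weights `((1-f)^2, 2f(1-f), f^2)`; ties prefer the
#' genotype with fewer alternate alleles.
#'
#' Joint calling can rescue a low-fraction variant when another sample
#' carries it at high fraction, but a variant present only at low
#' fraction in every carrier is penalized relative to single-sample
#' calling with a permissive prior.
#'
#' @param gls List of per-sample [genotype_likelihoods()] (length n >= 1).
#' @param config A [caller_config()] whose prior has M = 2n.
#' @return A `call_result` with additional fields `sample_genotypes`
#'   (character vector) and `sample_gq` (integer vector).
#' @export
call_multi <- function(gls, config) {
  n <- length(gls)
  if (config$prior$M != 2L * n)
    stop("prior has M = ", config$prior$M, " but ", n,
         " samples were supplied (need M = ", 2L * n, ")")
  res <- posterior_from_joint(joint_log10_lik_by_count(gls), config)
  k <- 0:(2L * n)
  f_hat <- sum(k * res$posterior_k) / (2 * n)
  wg <- c((1 - f_hat)^2, 2 * f_hat * (1 - f_hat), f_hat^2)
  gts <- character(n); gqs <- integer(n)
  for (i in seq_len(n)) {
    sc <- gls[[i]]$log10_lik + log10(wg + .Machine$double.xmin)
    g <- which.max(sc) - 1L
    p <- 10^(sc - log10_sum_exp(sc))
    gts[i] <- c("0/0", "0/1", "1/1")[g + 1L]
    gqs[i] <- as.integer(min(99, round_half_up(-10 * log10(max(
      1 - p[g + 1L] / sum(p), .Machine$double.xmin)))))
  }
  res$sample_genotypes <- gts
  res$sample_gq <- gqs
  res$f_hat <- f_hat
  res
}

#' Call directly from a pileup, producing a VCF-ready record
#'
#' Convenience wrapper: computes genotype likelihoods under the
#' configured error model, calls the site, and assembles a one-row
#' variant record carrying QUAL, genotype, GQ, PL, DP, DP4 and the PV4
#' bias p-values.
#'
#' @param site A [site_pileup()].
#' @param config A [caller_config()] (M = 2).
#' @param alt_allele Optional explicit alternate allele.
#' @return A one-row data.frame in the [variant_record()] layout, or
#'   `NULL` when the site is not emitted (not called and threshold < 1).
#' @export
call_pileup <- function(site, config = caller_config(), alt_allele = NULL) {
  gl <- genotype_log_likelihoods(site, alt_allele, config$model)
  if (is.null(gl$alt_allele)) return(NULL)
  res <- call_single(gl, config)
  if (!res$called) return(NULL)
  dp4 <- pileup_dp4(site, gl$alt_allele)
  p4 <- pv4(site, gl$alt_allele)
  variant_record(chrom = site$chrom, pos = site$pos,
                 ref = site$ref_allele, alt = gl$alt_allele,
                 qual = res$qual, genotype = res$genotype, gq = res$gq,
                 pl = gl$pl, dp = length(site$allele), dp4 = dp4,
                 pv4 = p4, sample_id = site$sample_id)
}
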