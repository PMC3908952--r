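#' Sequencing error model configuration
#'
#' Controls how per-read error probabilities are derived from base and
#' mapping qualities when computing genotype likelihoods.
#'
#' In `independent` mode every read contributes independently with error
#' probability `e = 10^(-min(bq, mq, max_quality_cap)/10)`, clamped to at
#' most `max_error_cap`.
#'
#' In `correlated` mode, errors at a site are not treated as independent:
#' stacked reads that contradict a genotype hypothesis are progressively
#' discounted.  Under each genotype, the reads whose allele the genotype
#' cannot produce (non-reference reads under hom-ref, non-alternate reads
#' under hom-alt, third-allele reads under the het) are sorted by
#' descending quality and the i-th such read (0-based) has its effective
#' quality decayed geometrically to `q * eta^i` before conversion to an
#' error probability.  This reproduces the qualitative behaviour of the
#' samtools error-dependency model: a pile of identical mismatches is far
#' weaker evidence than the same number of independent errors would be.
#' `eta = 1` recovers the independent model exactly.
#'
#' The default `eta = 0.89` is the package's frozen calibration of the
#' decay rate against the sensitivity sweep of the simulated read grids
#' (see the package vignette).
#'
#' @param mode `"correlated"` (default) or `"independent"`.
#' @param eta Geometric decay rate of mismatch qualities, in (0, 1].
#' @param max_quality_cap Phred cap applied to combined qualities.
#' @param max_error_cap Upper clamp on any per-read error probability.
#' @return Object of class `error_model`.
#' @export
error_model <- function(mode = c("correlated", "independent"),
                        eta = 0.89, max_quality_cap = 63,
                        max_error_cap = 0.75) {
  mode <- match.arg(mode)
  if (!(eta > 0 && eta <= 1)) stop("eta must be in (0, 1]")
  if (max_quality_cap <= 0 || max_error_cap <= 0)
    stop("quality/error caps must be positive")
  structure(list(mode = mode, eta = eta,
                 max_quality_cap = max_quality_cap,
                 max_error_cap = max_error_cap),
            class = "error_model")
}

#' Per-read effective error probability
#'
#' Combines base and mapping quality by taking the minimum (a base call
#' can be no more reliable than its alignment), caps the result at
#' `max_quality_cap`, converts to a probability and clamps at
#' `max_error_cap`.
#'
#' @param base_quality,mapping_quality Phred vectors (recycled).
#' @param model An [error_model()].
#' @return Vector of error probabilities.
#' @examples
#' effective_error(30, 60)   # 0.001
#' effective_error(0, 60)    # clamped to 0.75
#' @export
effective_error <- function(base_quality, mapping_quality,
                            model = error_model()) {
  if (any(base_quality < 0) || any(mapping_quality < 0))
    stop("qualities must be non-negative")
  q <- pmin(base_quality, mapping_quality, model$max_quality_cap)
  pmin(10^(-q / 10), model$max_error_cap)
}

## decayed error probabilities for a mismatch class: qualities sorted
## descending, i-th (0-based) decayed to q * eta^i
decayed_errors <- function(q, model) {
  if (!length(q)) return(numeric(0))
  q <- sort(q, decreasing = TRUE)
  q <- q * model$eta^(seq_along(q) - 1)
  pmin(10^(-q / 10), model$max_error_cap)
}

#' Diploid genotype likelihoods from a pileup
#'
#' Computes log10 likelihoods of the data given g = 0, 1, 2 copies of the
#' alternate allele.  Per read with error probability e:
#' under hom-ref, a reference base contributes (1 - e) and any other base
#' e/3; under hom-alt symmetrically; under the het, a read carrying either
#' of the two alleles contributes exactly 1/2 (each chromosome equally
#' likely to have been sampled) and a third allele contributes e/3.
#' In the correlated error model the mismatch class of each genotype uses
#' geometrically decayed qualities (see [error_model()]).
#'
#' An empty pileup is uninformative: all log-likelihoods 0, PL (0,0,0).
#'
#' If `alt_allele` is `NULL` it is chosen as the non-reference allele with
#' the largest base-quality sum (remaining alleles are treated as errors),
#' matching biallelic VCF output downstream.
#'
#' @param site A [site_pileup()].
#' @param alt_allele Alternate allele, or `NULL` to auto-select.
#' @param model An [error_model()].
#' @return Object of class `genotype_likelihoods`: list with `log10_lik`
#'   (numeric triple), `pl` (integer Phred-scaled triple, min 0) and the
#'   chosen `alt_allele`.
#' @export
genotype_log_likelihoods <- function(site, alt_allele = NULL,
                                     model = error_model()) {
  if (is.null(alt_allele)) alt_allele <- pick_alt_allele(site)
  if (!is.null(alt_allele) && identical(alt_allele, site$ref_allele))
    stop("alt_allele must differ from the reference allele")
  n <- length(site$allele)
  if (n == 0L || is.null(alt_allele))
    return(genotype_likelihoods(c(0, 0, 0), alt_allele))
  q <- pmin(site$base_quality, site$mapping_quality, model$max_quality_cap)
  is_ref <- site$allele == site$ref_allele
  is_alt <- site$allele == alt_allele
  is_oth <- !is_ref & !is_alt
  correlated <- model$mode == "correlated"

  mismatch_sum <- function(qmis) {          # sum log10(e/3) for error class
    e <- if (correlated) decayed_errors(qmis, model) else
      pmin(10^(-qmis / 10), model$max_error_cap)
    sum(log10(e / 3))
  }
  e_full <- pmin(10^(-q / 10), model$max_error_cap)
  l0 <- sum(log10(1 - e_full[is_ref])) + mismatch_sum(q[!is_ref])
  l2 <- sum(log10(1 - e_full[is_alt])) + mismatch_sum(q[!is_alt])
  l1 <- sum(is_ref | is_alt) * log10(0.5) + mismatch_sum(q[is_oth])
  genotype_likelihoods(c(l0, l1, l2), alt_allele)
}

## non-reference allele with the highest base-quality sum, or NULL
pick_alt_allele <- function(site) {
  cand <- setdiff(c("A", "C", "G", "T"), site$ref_allele)
  qs <- vapply(cand, function(a)
    sum(site$base_quality[site$allele == a]), numeric(1))
  if (all(qs == 0)) return(NULL)
  cand[which.max(qs)]
}

#' Genotype likelihood container and PL conversion
#'
#' `genotype_likelihoods` wraps a log10 likelihood triple for 0/1/2
#' alternate-allele copies together with its Phred-scaled PL form.
#' `gl_to_pl` rescales a log10 triple relative to its maximum
#' (`PL_g = round(-10 * (log10 L_g - max))`, rounding half away from
#' zero), so the best genotype always has PL 0.  `gl_from_pl` builds a
#' `genotype_likelihoods` from a printed PL triple
#' (`log10 L_g = -PL_g / 10`).
#'
#' @param log10_lik Numeric triple of log10 likelihoods.
#' @param alt_allele Optional alternate allele the triple refers to.
#' @return `genotype_likelihoods` object with fields `log10_lik`, `pl`,
#'   `alt_allele`.
#' @examples
#' gl_to_pl(c(-1.2, 0, -23.3))    # 12 0 233
#' @export
genotype_likelihoods <- function(log10_lik, alt_allele = NULL) {
  stopifnot(length(log10_lik) == 3, all(is.finite(log10_lik)))
  structure(list(log10_lik = as.numeric(log10_lik),
                 pl = gl_to_pl(log10_lik),
                 alt_allele = alt_allele),
            class = "genotype_likelihoods")
}

#' @rdname genotype_likelihoods
#' @export
gl_to_pl <- function(log10_lik) {
  pl <- -10 * (log10_lik - max(log10_lik))
  as.integer(pmax(0L, round_half_up(pl)))
}

#' @rdname genotype_likelihoods
#' @param pl Integer PL triple (smallest entry 0).
#' @export
gl_from_pl <- function(pl, alt_allele = NULL) {
  stopifnot(length(pl) == 3, all(pl >= 0))
  genotype_likelihoods(-pl / 10, alt_allele)
}

#' Base alignment quality hook
#'
#' BAQ caps base qualities by the probability that a base is misaligned
#' near indels.  For indel-free alignments (all the data this package
#' simulates is gapless 100M) BAQ leaves qualities unchanged, so the
#' default hook is the identity.  Externally computed BAQ-adjusted
#' qualities can be injected by passing `quality` explicitly.
#'
#' @param site A [site_pileup()].
#' @param quality Optional replacement base-quality vector (one per
#'   observation), e.g. BAQ-capped qualities from an external tool.
#' @return The pileup with `base_quality` replaced when supplied.
#' @export
baq_adjust <- function(site, quality = NULL) {
  if (!is.null(quality)) {
    stopifnot(length(quality) == length(site$allele))
    site$base_quality <- as.numeric(quality)
  }
  site
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat("genotype_likelihoods  PL(00/01/11) =",
      paste(x$pl, collapse = ","), "\n")
  invisible(x)
}
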